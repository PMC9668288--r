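# Shared fixture builders. Everything is generated in code; no binary data.

# a minimal annotation row with clean site metrics
variant_row <- function(chrom = "1", pos = 1000L, ref = "A", alt = "T",
                        gene = "G1", consequence = "missense_variant",
                        maf_internal = 0.001, maf_external = 0.001,
                        revel_score = 0.7, mtr_percentile = 30,
                        ext_observed = TRUE, fs = 5, mq = 60, qual = 3000,
                        rprs = 0, mqrs = 0, filter_status = "PASS",
                        ext_coverage_frac = 0.95, ext_z = 0.5, ext_mq = 60,
                        ext_pass_frac = 0.99, ccds = TRUE,
                        site_missing_frac = 0, site_fail_frac = 0) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
             consequence = consequence, maf_internal = maf_internal,
             maf_external = maf_external, revel_score = revel_score,
             mtr_percentile = mtr_percentile, ext_observed = ext_observed,
             fs = fs, mq = mq, qual = qual, rprs = rprs, mqrs = mqrs,
             filter_status = filter_status,
             ext_coverage_frac = ext_coverage_frac, ext_z = ext_z,
             ext_mq = ext_mq, ext_pass_frac = ext_pass_frac, ccds = ccds,
             site_missing_frac = site_missing_frac,
             site_fail_frac = site_fail_frac, stringsAsFactors = FALSE)
}

# genotype_matrix from a dosage matrix with comfortable call metrics
gm_fixture <- function(dosage, dp = 100L, gq = 99L) {
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("S%03d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("v%03d", seq_len(ncol(dosage)))
  dpm <- matrix(dp, nrow(dosage), ncol(dosage), dimnames = dimnames(dosage))
  gqm <- matrix(gq, nrow(dosage), ncol(dosage), dimnames = dimnames(dosage))
  ad <- matrix(0L, nrow(dosage), ncol(dosage), dimnames = dimnames(dosage))
  ad[!is.na(dosage) & dosage == 1] <- as.integer(dp / 2)
  ad[!is.na(dosage) & dosage == 2] <- as.integer(dp * 0.98)
  genotype_matrix(dosage, dpm, gqm, ad)
}

# per-sample brute-force recessive carrier scan (independent of carrier_status)
brute_recessive <- function(dosage, male, x_linked, pos) {
  vapply(seq_len(nrow(dosage)), function(i) {
    d <- dosage[i, ]
    if (any(d == 2, na.rm = TRUE)) return(TRUE)
    het_pos <- unique(pos[!is.na(d) & d == 1])
    length(het_pos) >= 2
  }, logical(1))
}

# null-effect small simulation config
null_cfg <- function(n = 4000, n_genes = 20, zygosity = "dominant",
                     carrier_freq = 0.02, n_variants = 4L) {
  genes <- data.frame(gene = sprintf("NG%03d", seq_len(n_genes)), chrom = "2",
                      n_variants = n_variants, carrier_freq = carrier_freq,
                      zygosity = zygosity, n_syn = 0L, ptv_frac = 1)
  sim_config(n = n, genes = genes,
             binary_phenotypes = list(
               status = list(prevalence = 0.1, logor = c())),
             quantitative_phenotypes = list(),
             call_metrics = FALSE)
}
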