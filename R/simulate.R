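# Synthetic exome-cohort generator.
#
# The generator emulates the statistical structure the collapsing analysis
# assumes: ancestry strata with their own carrier frequencies, autosomal and
# X-linked rare-variant genes at Hardy-Weinberg proportions (hemizygous males
# carry 0 or 2 dosage on X), binary phenotypes from a logistic model whose
# intercept is solved to hit a configured prevalence, quantitative traits with
# effects in SD units and unit Gaussian noise, and an optional common risk
# haplotype (carried as a phased tag variant) whose interaction term can
# abolish a gene's effect in haplotype carriers.

.sub_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + 1000003 * stage) %% 2147483629)
}

#' Simulation configuration
#'
#' Assembles and validates the configuration consumed by [generate_cohort()].
#' Defaults describe a single-ancestry UK-Biobank-like stratum with one
#' X-linked recessive protective gene (carrier frequency 1.77%, diabetes odds
#' ratio 0.70, HbA1c effect -0.14 SD) and one autosomal null gene.
#'
#' @param n Total samples.
#' @param ancestry_props Named proportions per ancestry label (sums to 1).
#' @param female_frac Fraction of females (applied within each ancestry).
#' @param age_range Uniform age bounds in years.
#' @param genes Data frame with columns `gene`, `chrom`, `n_variants`,
#'   `carrier_freq` (target carrier fraction of the whole stratum under the
#'   gene's zygosity mode), `zygosity` (`"dominant"`/`"recessive"`). Optional
#'   `n_syn` synonymous variants per gene (default 2) and `ptv_frac`, the
#'   fraction of the gene's qualifying variants that are protein-truncating
#'   (default 0.5; the rest are missense), and `max_maf`, a ceiling on any
#'   single variant's allele frequency (excess probability is redistributed
#'   over the rarer variants; keeps every qualifying variant below a model's
#'   MAF ceiling, as in the emulated gene where the most frequent truncating
#'   variant has MAF 0.35%).
#' @param carrier_freq_by_ancestry Optional gene x ancestry matrix overriding
#'   `genes$carrier_freq` per stratum.
#' @param binary_phenotypes Named list: per phenotype, `prevalence` and
#'   `logor` (named vector of per-gene carrier log odds ratios).
#' @param quantitative_phenotypes Named list: per phenotype, `beta` (named
#'   per-gene vector, SD units).
#' @param haplotype `NULL`, or a list with `freq` (allele frequency of the tag
#'   variant), `chrom`, `pos`, `logor` (marginal log-OR of haplotype carriage,
#'   applied to every binary phenotype), `beta` (SD units, every quantitative
#'   phenotype), `interaction_logor` and `interaction_beta` (named per-gene
#'   vectors added in haplotype carriers).
#' @param comphet_cis_frac Fraction of two-variant heterozygous females whose
#'   variants are simulated in cis (no second-copy effect in the phenotype
#'   model, probing the phase-blind compound-het coding). Default 0.
#' @param call_metrics Simulate per-call DP/GQ/AD matrices (default TRUE;
#'   disable for large calibration runs).
#' @param missing_rate Per-call missingness (default 0).
#' @param n_pcs Number of principal-component covariates (default 5).
#' @return Validated list with class `"sim_config"`.
#' @export
sim_config <- function(n = 10000,
                       ancestry_props = c(EUR = 1),
                       female_frac = 0.5,
                       age_range = c(40, 70),
                       genes = data.frame(
                         gene = c("GENE_XR", "GENE_NULL"),
                         chrom = c("X", "7"),
                         n_variants = c(40L, 6L),
                         carrier_freq = c(0.0177, 0.01),
                         zygosity = c("recessive", "dominant"),
                         max_maf = c(0.0035, NA),
                         stringsAsFactors = FALSE),
                       carrier_freq_by_ancestry = NULL,
                       binary_phenotypes = list(
                         diabetes = list(prevalence = 0.085,
                                         logor = c(GENE_XR = log(0.70)))),
                       quantitative_phenotypes = list(
                         hba1c = list(beta = c(GENE_XR = -0.14))),
                       haplotype = NULL,
                       comphet_cis_frac = 0,
                       call_metrics = TRUE,
                       missing_rate = 0,
                       n_pcs = 5) {
  stopifnot(n >= 1, abs(sum(ancestry_props) - 1) < 1e-8,
            female_frac >= 0, female_frac <= 1)
  if (!"n_syn" %in% names(genes)) genes$n_syn <- 2L
  if (!"ptv_frac" %in% names(genes)) genes$ptv_frac <- 0.5
  if (!"max_maf" %in% names(genes)) genes$max_maf <- NA_real_
  known <- genes$gene
  for (ph in names(binary_phenotypes)) {
    bad <- setdiff(names(binary_phenotypes[[ph]]$logor), known)
    if (length(bad)) stop("effect on unknown gene: ", paste(bad, collapse = ", "))
  }
  for (ph in names(quantitative_phenotypes)) {
    bad <- setdiff(names(quantitative_phenotypes[[ph]]$beta), known)
    if (length(bad)) stop("effect on unknown gene: ", paste(bad, collapse = ", "))
  }
  if (!is.null(haplotype)) {
    haplotype <- utils::modifyList(
      list(tag = "HAP_TAG", chrom = "17", pos = 7041768L, freq = 0.30,
           logor = 0, beta = 0, interaction_logor = numeric(),
           interaction_beta = numeric()), haplotype)
    bad <- setdiff(c(names(haplotype$interaction_logor),
                     names(haplotype$interaction_beta)), known)
    if (length(bad)) stop("effect on unknown gene: ", paste(bad, collapse = ", "))
  }
  structure(list(n = n, ancestry_props = ancestry_props,
                 female_frac = female_frac, age_range = age_range,
                 genes = genes,
                 carrier_freq_by_ancestry = carrier_freq_by_ancestry,
                 binary_phenotypes = binary_phenotypes,
                 quantitative_phenotypes = quantitative_phenotypes,
                 haplotype = haplotype, comphet_cis_frac = comphet_cis_frac,
                 call_metrics = call_metrics, missing_rate = missing_rate,
                 n_pcs = n_pcs),
            class = "sim_config")
}

# Cap per-variant allele frequencies at max_maf, redistributing the excess
# over the uncapped variants (water-filling); returns assignment weights.
.cap_spectrum <- function(w, q, cap) {
  if (is.na(cap)) return(w)
  qi <- w * q
  if (length(qi) * cap < q)
    stop("max_maf * n_variants below the required cumulative allele frequency")
  repeat {
    over <- qi > cap
    if (!any(over)) break
    excess <- sum(qi[over] - cap)
    qi[over] <- cap
    free <- !over & qi < cap
    if (!any(free)) break
    qi[free] <- qi[free] + excess * qi[free] / sum(qi[free])
  }
  qi / sum(qi)
}

# Solve the per-stratum cumulative QV allele frequency from a target carrier
# fraction under the gene's zygosity mode. m = male fraction of the stratum.
.solve_allele_freq <- function(target, zygosity, x_linked, m) {
  f <- function(q) {
    if (zygosity == "dominant") {
      if (x_linked) m * q + (1 - m) * (1 - (1 - q)^2) else 1 - (1 - q)^2
    } else {
      if (x_linked) m * q + (1 - m) * q^2 else q^2
    }
  }
  stats::uniroot(function(q) f(q) - target, c(1e-10, 0.999),
                 tol = 1e-12)$root
}

#' Generate a synthetic exome cohort
#'
#' Draws samples, variants, genotypes and phenotypes under a [sim_config()],
#' and returns the truth table of generative parameters for recovery tests.
#' Randomness is fully determined by `seed` (per-component substreams are
#' derived from it).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list with class `"sim_cohort"`: `samples` (sample table with
#'   covariates and phenotypes), `variants` (annotation table), `genotypes`
#'   (a [genotype_matrix()]), `truth` (list: `genes`, `haplotype`, `seed`),
#'   and `hap_phase` (two-column phased tag haplotypes, or NULL).
#' @export
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)

  ## samples ----------------------------------------------------------------
  set.seed(.sub_seed(seed, 1L))
  n <- config$n
  ancestry <- sample(rep(names(config$ancestry_props),
                         times = round(config$ancestry_props * n))[seq_len(n)])
  sex <- ifelse(stats::runif(n) < config$female_frac, "female", "male")
  age <- round(stats::runif(n, config$age_range[1], config$age_range[2]), 1)
  pcs <- matrix(stats::rnorm(n * config$n_pcs), n)
  # crude ancestry separation on the leading components
  anc_idx <- as.integer(factor(ancestry))
  pcs[, 1] <- pcs[, 1] + 4 * (anc_idx - 1)
  if (config$n_pcs >= 2) pcs[, 2] <- pcs[, 2] + 2 * (anc_idx %% 2)
  colnames(pcs) <- paste0("PC", seq_len(config$n_pcs))
  samples <- data.frame(sample_id = sprintf("S%06d", seq_len(n)),
                        sex = sex, age = age, ancestry = ancestry,
                        bmi = round(stats::rnorm(n, 27, 4.5), 2),
                        antihtn = as.integer(stats::runif(n) < 0.2),
                        stringsAsFactors = FALSE)
  samples <- cbind(samples, as.data.frame(pcs))
  male <- sex == "male"

  ## variants & genotypes ---------------------------------------------------
  set.seed(.sub_seed(seed, 2L))
  genes <- config$genes
  strata <- split(seq_len(n), ancestry)
  var_rows <- list()
  dosage_cols <- list()
  carrier_truth <- matrix(FALSE, n, nrow(genes),
                          dimnames = list(samples$sample_id, genes$gene))
  qv_freq <- list()

  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    x_linked <- g$chrom %in% c("X", "chrX")
    nv <- g$n_variants
    w <- (1 / seq_len(nv)^1.5); w <- w / sum(w)   # skewed allelic spectrum
    gene_dosage <- matrix(0L, n, nv)
    cap <- g$max_maf
    for (st in names(strata)) {
      idx <- strata[[st]]
      m <- mean(male[idx])
      target <- if (!is.null(config$carrier_freq_by_ancestry))
        config$carrier_freq_by_ancestry[g$gene, st] else g$carrier_freq
      q <- .solve_allele_freq(target, g$zygosity, x_linked, m)
      wq <- .cap_spectrum(w, q, cap)   # per-variant assignment weights
      if (target * length(idx) < 1)
        warning("gene ", g$gene, ", stratum ", st,
                ": expected carrier count below 1")
      copies <- if (x_linked) ifelse(male[idx], 1L, 2L) else 2L
      k <- stats::rbinom(length(idx), copies, q)
      has <- which(k > 0)
      if (length(has)) {
        owner <- rep(idx[has], k[has])
        allele <- sample.int(nv, length(owner), replace = TRUE, prob = wq)
        gene_dosage <- gene_dosage +
          matrix(tabulate((allele - 1L) * n + owner, nbins = n * nv), n)
      }
      if (x_linked) {
        hemi <- idx[male[idx]]
        gene_dosage[hemi, ] <- gene_dosage[hemi, ] * 2L  # hemizygous coded 2
      }
      qv_freq[[paste(g$gene, st, sep = ".")]] <-
        data.frame(gene = g$gene, ancestry = st, target_carrier_freq = target,
                   allele_freq = q, stringsAsFactors = FALSE)
    }
    # truth carrier status under the gene's zygosity mode
    ct <- carrier_status(
      `dimnames<-`(gene_dosage, list(samples$sample_id, paste0("v", seq_len(nv)))),
      g$zygosity, male = male, x_linked = x_linked, pos = seq_len(nv))
    if (g$zygosity == "recessive") {
      ch <- which(!is.na(attr(ct, "basis")) & attr(ct, "basis") == "compound_het")
      u <- stats::runif(length(ch))   # drawn regardless, keeps streams aligned
      if (config$comphet_cis_frac > 0) {
        ct[ch[u < config$comphet_cis_frac]] <- FALSE  # cis: no second-copy effect
      }
    }
    carrier_truth[, gi] <- as.logical(ct)

    # realized internal MAFs; external MAFs = internal with multiplicative noise
    copies_per_sample <- if (x_linked) ifelse(male, 1, 2) else rep(2, n)
    total_alleles <- sum(copies_per_sample)
    allele_counts <- gene_dosage
    if (x_linked) allele_counts[male, ] <- allele_counts[male, , drop = FALSE] / 2
    alt_alleles <- colSums(allele_counts)
    maf_int <- pmin(alt_alleles / total_alleles, 0.5)
    maf_ext <- pmin(maf_int * exp(stats::rnorm(nv, 0, 0.2)), 0.5)

    is_ptv <- stats::runif(nv) < g$ptv_frac
    csq <- ifelse(is_ptv, sample(c("stop_gained", "frameshift_variant"), nv,
                                 replace = TRUE),
                  "missense_variant")
    pos0 <- 1e6 + gi * 1e5   # disjoint per-gene windows keep keys unique
    vr <- data.frame(
      chrom = g$chrom, pos = pos0 + sort(sample.int(5e4, nv)),
      ref = sample(c("A", "C", "G", "T"), nv, replace = TRUE),
      gene = g$gene, consequence = csq, stringsAsFactors = FALSE)
    vr$alt <- vapply(vr$ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
    vr$maf_internal <- maf_int
    vr$maf_external <- maf_ext
    vr$ext_observed <- maf_ext * 250000 >= 1
    vr$maf_external[!vr$ext_observed] <- 0
    vr$revel_score <- ifelse(csq == "missense_variant",
                             round(stats::runif(nv), 3), NA_real_)
    vr$mtr_percentile <- ifelse(csq == "missense_variant",
                                round(stats::runif(nv, 0, 100), 1), NA_real_)
    var_rows[[length(var_rows) + 1L]] <- vr
    dosage_cols[[length(dosage_cols) + 1L]] <- gene_dosage

    # synonymous companions (negative-control model content)
    if (g$n_syn > 0) {
      sf <- stats::runif(g$n_syn, 0.0005, 0.004)
      syn_dos <- sapply(sf, function(q) {
        if (x_linked) {
          k <- stats::rbinom(n, ifelse(male, 1L, 2L), q)
          ifelse(male, k * 2L, k)
        } else stats::rbinom(n, 2L, q)
      })
      syn_dos <- matrix(as.integer(syn_dos), n)
      sv <- data.frame(
        chrom = g$chrom, pos = pos0 + 5e4 + sort(sample.int(1e4, g$n_syn)),
        ref = sample(c("A", "C", "G", "T"), g$n_syn, replace = TRUE),
        gene = g$gene, consequence = "synonymous_variant",
        stringsAsFactors = FALSE)
      sv$alt <- vapply(sv$ref, function(r)
        sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
      sv$maf_internal <- pmin(colSums(syn_dos) / (2 * n), 0.5)
      sv$maf_external <- pmin(sv$maf_internal * exp(stats::rnorm(g$n_syn, 0, 0.2)), 0.5)
      sv$ext_observed <- TRUE
      sv$revel_score <- NA_real_
      sv$mtr_percentile <- NA_real_
      var_rows[[length(var_rows) + 1L]] <- sv
      dosage_cols[[length(dosage_cols) + 1L]] <- syn_dos
    }
  }

  ## haplotype tag ----------------------------------------------------------
  set.seed(.sub_seed(seed, 3L))
  hap <- config$haplotype
  hap_phase <- NULL
  hap_carrier <- rep(FALSE, n)
  if (!is.null(hap)) {
    h1 <- as.integer(stats::runif(n) < hap$freq)
    h2 <- as.integer(stats::runif(n) < hap$freq)
    hap_phase <- cbind(h1 = h1, h2 = h2)
    hap_dos <- h1 + h2
    hap_carrier <- hap_dos >= 1
    vr <- data.frame(chrom = hap$chrom, pos = hap$pos, ref = "G",
                     gene = hap$tag, consequence = "missense_variant",
                     stringsAsFactors = FALSE)
    vr$alt <- "T"
    vr$maf_internal <- pmin(mean(hap_dos) / 2, 0.5)
    vr$maf_external <- vr$maf_internal
    vr$ext_observed <- TRUE
    vr$revel_score <- 0.2
    vr$mtr_percentile <- 80
    var_rows[[length(var_rows) + 1L]] <- vr
    dosage_cols[[length(dosage_cols) + 1L]] <- matrix(as.integer(hap_dos), n)
  }

  variants <- do.call(rbind, var_rows)
  nv_all <- nrow(variants)
  variants$fs <- round(stats::runif(nv_all, 0, 20), 2)
  variants$mq <- round(stats::runif(nv_all, 55, 60), 1)
  variants$qual <- round(stats::runif(nv_all, 500, 5000), 0)
  variants$rprs <- round(stats::rnorm(nv_all, 0, 0.5), 3)
  variants$mqrs <- round(stats::rnorm(nv_all, 0, 0.5), 3)
  variants$filter_status <- "PASS"
  variants$ext_coverage_frac <- round(stats::runif(nv_all, 0.8, 1), 3)
  variants$ext_z <- round(stats::rnorm(nv_all, 0.5, 0.5), 3)
  variants$ext_mq <- round(stats::runif(nv_all, 50, 60), 1)
  variants$ext_pass_frac <- round(stats::runif(nv_all, 0.9, 1), 3)
  variants$ccds <- TRUE
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = "-")
  if (anyDuplicated(key)) stop("internal error: duplicate variant keys")
  rownames(variants) <- NULL

  dosage <- do.call(cbind, dosage_cols)
  dimnames(dosage) <- list(samples$sample_id, key)
  if (config$missing_rate > 0) {
    dosage[stats::runif(length(dosage)) < config$missing_rate] <- NA_integer_
  }

  ## phenotypes -------------------------------------------------------------
  set.seed(.sub_seed(seed, 4L))
  age_c <- (samples$age - mean(config$age_range)) / 10
  for (ph in names(config$binary_phenotypes)) {
    spec <- config$binary_phenotypes[[ph]]
    eta <- 0.3 * male + 0.35 * age_c
    for (g in names(spec$logor)) eta <- eta + spec$logor[[g]] * carrier_truth[, g]
    if (!is.null(hap)) {
      eta <- eta + hap$logor * hap_carrier
      for (g in names(hap$interaction_logor))
        eta <- eta + hap$interaction_logor[[g]] * carrier_truth[, g] * hap_carrier
    }
    b0 <- stats::uniroot(function(b) mean(stats::plogis(b + eta)) - spec$prevalence,
                         c(-25, 25), tol = 1e-10)$root
    samples[[ph]] <- stats::rbinom(n, 1, stats::plogis(b0 + eta))
  }
  for (ph in names(config$quantitative_phenotypes)) {
    spec <- config$quantitative_phenotypes[[ph]]
    mu <- 0.1 * male + 0.1 * age_c
    for (g in names(spec$beta)) mu <- mu + spec$beta[[g]] * carrier_truth[, g]
    if (!is.null(hap)) {
      mu <- mu + hap$beta * hap_carrier
      for (g in names(hap$interaction_beta))
        mu <- mu + hap$interaction_beta[[g]] * carrier_truth[, g] * hap_carrier
    }
    samples[[ph]] <- round(mu + stats::rnorm(n), 6)
  }

  ## per-call metrics -------------------------------------------------------
  dp <- gq <- ad <- NULL
  if (config$call_metrics) {
    set.seed(.sub_seed(seed, 5L))
    dp <- matrix(stats::rpois(length(dosage), 45) + 12L, n)
    het <- !is.na(dosage) & dosage == 1
    hom <- !is.na(dosage) & dosage == 2
    ad <- matrix(0L, n, ncol(dosage))
    ad[het] <- stats::rbinom(sum(het), dp[het], 0.5)
    ad[hom] <- stats::rbinom(sum(hom), dp[hom], 0.98)
    gq <- matrix(pmin(99L, stats::rpois(length(dosage), 90)), n)
    dimnames(dp) <- dimnames(gq) <- dimnames(ad) <- dimnames(dosage)
  }

  truth_genes <- genes[, c("gene", "chrom", "zygosity", "carrier_freq")]
  for (ph in names(config$binary_phenotypes)) {
    lo <- config$binary_phenotypes[[ph]]$logor
    truth_genes[[paste0("logor_", ph)]] <-
      ifelse(genes$gene %in% names(lo), lo[genes$gene], 0)
  }
  for (ph in names(config$quantitative_phenotypes)) {
    be <- config$quantitative_phenotypes[[ph]]$beta
    truth_genes[[paste0("beta_", ph)]] <-
      ifelse(genes$gene %in% names(be), be[genes$gene], 0)
  }
  truth_hap <- if (!is.null(hap)) {
    data.frame(tag = hap$tag, freq = hap$freq, logor = hap$logor,
               beta = hap$beta,
               interaction_logor = paste(names(hap$interaction_logor),
                                         unlist(hap$interaction_logor),
                                         sep = "=", collapse = ";"),
               stringsAsFactors = FALSE)
  }

  structure(list(samples = samples, variants = variants,
                 genotypes = genotype_matrix(dosage, dp, gq, ad),
                 truth = list(genes = truth_genes, haplotype = truth_hap,
                              allele_freqs = do.call(rbind, qv_freq),
                              carrier_truth = carrier_truth, seed = seed),
                 hap_phase = hap_phase, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d samples, %d variants, %d gene(s), seed %d\n",
              nrow(x$samples), nrow(x$variants), nrow(x$truth$genes),
              x$truth$seed))
  invisible(x)
}
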