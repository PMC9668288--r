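#' Quality-control threshold profiles
#'
#' Returns the named threshold set used by [apply_genotype_filters()] and
#' [apply_site_filters()]. Two presets exist: `"collapsing"` (gene-level
#' collapsing analysis) and `"exwas"` (variant-level exome-wide association).
#' They share most per-genotype criteria but differ in the heterozygous
#' alt-read fraction window, the external-reference coverage requirement, and
#' the ExWAS-only site missingness / site fail-fraction rules.
#'
#' @param profile `"collapsing"` or `"exwas"`.
#' @param hom_alt_rule How to treat the alternate-read fraction of homozygous
#'   (and hemizygous) alt calls. `"at_least"` (default) requires alt fraction
#'   >= `hom_alt_frac`; `"as_printed"` requires alt fraction <= `hom_alt_frac`,
#'   the literal reading of the published filter list (which fails essentially
#'   all real homozygous calls); `"off"` disables the rule. See the methods
#'   vignette for why both readings are kept.
#' @param ... Named overrides for individual thresholds.
#' @return A list of thresholds with class `"qc_thresholds"`.
#' @examples
#' qc_thresholds("collapsing")$min_dp
#' qc_thresholds("exwas", min_gq = 30)$min_gq
#' @export
qc_thresholds <- function(profile = c("collapsing", "exwas"),
                          hom_alt_rule = c("at_least", "as_printed", "off"),
                          ...) {
  profile <- match.arg(profile)
  hom_alt_rule <- match.arg(hom_alt_rule)
  base <- list(
    min_dp = 10,
    min_gq = 20,
    het_binom_p = 1e-6,
    hom_alt_frac = 0.8,
    hom_alt_rule = hom_alt_rule,
    max_fs_snv = 60,
    max_fs_indel = 200,
    min_mq = 40,
    min_qual = 30,
    min_rprs = -2,
    min_mqrs = -8,
    caller_status = "PASS",
    min_ext_z = -2,
    min_ext_mq = 30
  )
  if (profile == "collapsing") {
    extra <- list(
      het_alt_frac = c(0.25, 0.8),
      min_ext_coverage = 0.25,
      ccds_required = TRUE,
      max_site_missing = NA_real_,
      max_site_fail = NA_real_,
      min_ext_pass_frac = NA_real_
    )
  } else {
    extra <- list(
      het_alt_frac = c(0.2, 1),
      min_ext_coverage = 0.30,
      ccds_required = FALSE,
      max_site_missing = 0.10,
      max_site_fail = 0.05,
      min_ext_pass_frac = 0.5
    )
  }
  thr <- c(base, extra)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(thr))
    if (length(bad)) stop("unknown QC threshold(s): ", paste(bad, collapse = ", "))
    thr[names(dots)] <- dots
  }
  thr$profile <- profile
  structure(thr, class = "qc_thresholds")
}

#' Exact two-sided binomial test for heterozygous allele balance
#'
#' Tests departure of the alternate-read proportion from 0.5 in a heterozygous
#' call. The two-sided p-value is the sum of the probabilities of all outcomes
#' whose probability does not exceed that of the observed count (the
#' conventional minimum-likelihood rule).
#'
#' @param alt_reads Integer vector of alternate-read counts.
#' @param total_reads Integer vector of total read depths (>= 1).
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' binomial_het_test(50, 100)  # 1
#' binomial_het_test(30, 100)  # ~ 6.6e-5
#' @export
binomial_het_test <- function(alt_reads, total_reads) {
  if (length(total_reads) == 1L) total_reads <- rep(total_reads, length(alt_reads))
  stopifnot(length(alt_reads) == length(total_reads))
  if (any(total_reads < 1, na.rm = TRUE)) stop("total_reads must be >= 1")
  if (any(alt_reads > total_reads, na.rm = TRUE)) stop("alt_reads exceeds total_reads")
  if (any(alt_reads < 0, na.rm = TRUE)) stop("alt_reads must be nonnegative")
  vapply(seq_along(alt_reads), function(i) {
    x <- alt_reads[i]; n <- total_reads[i]
    if (is.na(x) || is.na(n)) return(NA_real_)
    d <- stats::dbinom(0:n, n, 0.5)
    # relative-tolerance guard matches the mass-comparison convention
    min(1, sum(d[d <= d[x + 1L] * (1 + 1e-7)]))
  }, numeric(1))
}

# fail-reason vocabulary, in evaluation order (the pass decision is
# order-independent; the order only fixes reason reporting)
.genotype_reasons <- c("coverage", "gq", "het_alt_frac", "het_binom", "hom_alt_frac")

#' Per-genotype quality-control filters
#'
#' Applies the per-call filters of the collapsing / ExWAS frameworks: minimum
#' depth, genotype quality, heterozygous alt-read fraction window, exact
#' binomial allele-balance test, and the homozygous alt-fraction rule. Failing
#' calls are set to missing (`NA`); the site is never removed here.
#'
#' @param geno A `genotype_matrix` (see [genotype_matrix()]) carrying `dosage`,
#'   `dp`, `gq` and `ad` (alt-read count) matrices.
#' @param thresholds A [qc_thresholds()] object.
#' @return A list with `dosage` (filtered copy, failures set to `NA`), `fail`
#'   (logical matrix of failed, previously non-missing calls) and `reasons`
#'   (data frame with `sample`, `variant`, `reason`; one row per failed call
#'   and reason, ordered by the fixed reason vocabulary).
#' @export
apply_genotype_filters <- function(geno, thresholds) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(thresholds, "qc_thresholds"))
  ds <- geno$dosage
  if (is.null(geno$dp)) {
    # metric-free matrix (e.g. a lean simulation): nothing to filter on
    return(list(dosage = ds,
                fail = matrix(FALSE, nrow(ds), ncol(ds), dimnames = dimnames(ds)),
                reasons = data.frame(sample = character(), variant = character(),
                                     reason = character(), stringsAsFactors = FALSE)))
  }
  dp <- geno$dp
  gq <- geno$gq
  ad <- geno$ad
  called <- !is.na(ds)
  het <- called & ds == 1
  hom <- called & ds == 2          # includes hemizygous (coded 2)
  frac <- ad / pmax(dp, 1L)

  fails <- list()
  fails$coverage <- called & (is.na(dp) | dp < thresholds$min_dp)
  fails$gq <- called & (is.na(gq) | gq < thresholds$min_gq)
  lo <- thresholds$het_alt_frac[1]; hi <- thresholds$het_alt_frac[2]
  fails$het_alt_frac <- het & (is.na(frac) | frac < lo | frac > hi)
  bp <- matrix(NA_real_, nrow(ds), ncol(ds))
  if (any(het)) bp[het] <- binomial_het_test(ad[het], pmax(dp[het], 1L))
  fails$het_binom <- het & !is.na(bp) & bp <= thresholds$het_binom_p
  fails$hom_alt_frac <- switch(thresholds$hom_alt_rule,
    at_least = hom & (is.na(frac) | frac < thresholds$hom_alt_frac),
    as_printed = hom & (is.na(frac) | frac > thresholds$hom_alt_frac),
    off = hom & FALSE
  )

  any_fail <- Reduce(`|`, fails)
  out <- ds
  out[any_fail] <- NA_integer_

  reasons <- do.call(rbind, lapply(.genotype_reasons, function(r) {
    idx <- which(fails[[r]], arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(sample = rownames(ds)[idx[, 1]],
               variant = colnames(ds)[idx[, 2]],
               reason = r, stringsAsFactors = FALSE)
  }))
  if (is.null(reasons)) {
    reasons <- data.frame(sample = character(), variant = character(),
                          reason = character(), stringsAsFactors = FALSE)
  }
  list(dosage = out, fail = any_fail, reasons = reasons)
}

#' Per-site quality-control filters
#'
#' Applies the site-level filters to a variant annotation table: strand bias
#' (with separate SNV/indel ceilings), mapping quality, QUAL, rank-sum scores,
#' caller status, external-reference coverage and quality criteria, and (ExWAS
#' profile only) site missingness and fail-fraction rules.
#'
#' @param variants Variant annotation data frame. Required columns: `ref`,
#'   `alt`, `fs`, `mq`, `qual`, `rprs`, `mqrs`, `filter_status`,
#'   `ext_coverage_frac`. Used when present: `ext_observed`, `ext_z`, `ext_mq`,
#'   `ext_pass_frac`, `ccds`, `site_missing_frac`, `site_fail_frac`. When the
#'   external-reference columns are absent those criteria are skipped with a
#'   warning (an annotation table from [generate_cohort()] always has them).
#' @param thresholds A [qc_thresholds()] object.
#' @return A list with `pass` (logical vector) and `reasons` (list of character
#'   vectors of failed criteria per site).
#' @export
apply_site_filters <- function(variants, thresholds) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  need <- c("ref", "alt", "fs", "mq", "qual", "rprs", "mqrs", "filter_status",
            "ext_coverage_frac")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("missing required site metric column(s): ",
                         paste(miss, collapse = ", "))
  n <- nrow(variants)
  is_indel <- nchar(variants$ref) != nchar(variants$alt)
  fs_max <- ifelse(is_indel, thresholds$max_fs_indel, thresholds$max_fs_snv)

  crit <- list(
    fs = variants$fs > fs_max,
    mq = variants$mq < thresholds$min_mq,
    qual = variants$qual < thresholds$min_qual,
    rprs = variants$rprs < thresholds$min_rprs,
    mqrs = variants$mqrs < thresholds$min_mqrs,
    caller_status = variants$filter_status != thresholds$caller_status,
    ext_coverage = variants$ext_coverage_frac < thresholds$min_ext_coverage
  )

  ext_obs <- if ("ext_observed" %in% names(variants)) variants$ext_observed
             else rep(NA, n)
  have_ext <- all(c("ext_observed", "ext_z", "ext_mq") %in% names(variants))
  if (thresholds$profile == "collapsing") {
    if (have_ext) {
      crit$ext_z <- ext_obs & variants$ext_z < thresholds$min_ext_z
      crit$ext_mq <- ext_obs & variants$ext_mq < thresholds$min_ext_mq
    } else {
      warning("external-reference columns absent; skipping external z / MQ criteria")
    }
    if (thresholds$ccds_required) {
      if ("ccds" %in% names(variants)) {
        crit$ccds <- !variants$ccds
      } else {
        warning("ccds column absent; skipping CCDS-transcript criterion")
      }
    }
  } else {
    if (all(c("ext_observed", "ext_pass_frac") %in% names(variants))) {
      crit$ext_pass_frac <- ext_obs & variants$ext_pass_frac < thresholds$min_ext_pass_frac
    } else {
      warning("external-reference columns absent; skipping external pass-fraction criterion")
    }
    if (!is.na(thresholds$max_site_missing)) {
      if (!"site_missing_frac" %in% names(variants))
        stop("missing required site metric column(s): site_missing_frac")
      crit$site_missing <- variants$site_missing_frac >= thresholds$max_site_missing
    }
    if (!is.na(thresholds$max_site_fail)) {
      if (!"site_fail_frac" %in% names(variants))
        stop("missing required site metric column(s): site_fail_frac")
      crit$site_fail <- variants$site_fail_frac >= thresholds$max_site_fail
    }
  }

  crit <- lapply(crit, function(x) { x[is.na(x)] <- TRUE; x })
  fail_mat <- do.call(cbind, crit)
  pass <- !apply(fail_mat, 1, any)
  reasons <- lapply(seq_len(n), function(i) colnames(fail_mat)[fail_mat[i, ]])
  list(pass = pass, reasons = reasons)
}

#' Per-site call statistics from a genotype matrix
#'
#' Computes, per variant, the fraction of samples with a missing call and the
#' fraction whose call failed the per-genotype filters; used by the ExWAS site
#' rules.
#'
#' @param geno A `genotype_matrix`.
#' @param gt_qc Result of [apply_genotype_filters()] on `geno`.
#' @return Data frame with `site_missing_frac` and `site_fail_frac`.
#' @export
site_call_stats <- function(geno, gt_qc) {
  n <- nrow(geno$dosage)
  data.frame(
    site_missing_frac = colSums(is.na(geno$dosage)) / n,
    site_fail_frac = colSums(gt_qc$fail) / n
  )
}
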