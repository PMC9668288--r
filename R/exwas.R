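# Variant-level exome-wide association tests.
#
# Genetic models, with A = alternate allele, B = reference:
#   allelic   - A vs B allele counts (2 alleles per autosomal sample, 1 per
#               hemizygous X male)
#   dominant  - AA + AB vs BB individuals
#   recessive - AA vs AB + BB individuals (X-male hemizygotes count as AA)
#   genotypic - AA vs AB vs BB, quantitative traits only (dosage regression)

.carrier_count <- function(dosage) sum(dosage > 0, na.rm = TRUE)

#' Variant-level binary-trait tests
#'
#' Runs the allelic, dominant and recessive 2x2 exact tests for one variant.
#' Variants carried by fewer than `min_carriers` individuals are skipped, as
#' are monomorphic variants.
#'
#' @param dosage Integer dosage vector (0/1/2, hemizygous X males coded 2).
#' @param is_case Logical case indicator.
#' @param male Logical male indicator (needed for X variants).
#' @param x_linked Is the variant on the X chromosome?
#' @param variant Variant label echoed into results.
#' @param min_carriers Minimum carrier count to test (default 6).
#' @return Data frame with one row per genetic model (columns as
#'   [fisher_burden()] plus `genetic_model`, `n_carriers`, `skipped`,
#'   `skip_reason`).
#' @export
variant_binary_tests <- function(dosage, is_case, male = NULL, x_linked = FALSE,
                                 variant = NA_character_, min_carriers = 6L) {
  nc <- .carrier_count(dosage)
  skip <- function(reason) data.frame(
    variant = variant, genetic_model = c("allelic", "dominant", "recessive"),
    n_carriers = nc, skipped = TRUE, skip_reason = reason,
    or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
    stringsAsFactors = FALSE)
  if (nc == 0) return(skip("monomorphic"))
  if (nc < min_carriers) return(skip("fewer than minimum carriers"))
  ok <- !is.na(dosage) & !is.na(is_case)
  ds <- dosage[ok]; ca <- is_case[ok]
  ml <- if (is.null(male)) rep(FALSE, length(ds)) else male[ok]

  # allele counts: X-male hemizygotes contribute a single allele
  copies <- ifelse(x_linked & ml, 1L, 2L)
  alt <- ifelse(x_linked & ml, as.integer(ds > 0), ds)
  tabs <- list(
    allelic = c(a = sum(alt[ca]), b = sum(alt[!ca]),
                c = sum(copies[ca] - alt[ca]), d = sum(copies[!ca] - alt[!ca])),
    dominant = {
      car <- ds > 0
      c(a = sum(car & ca), b = sum(car & !ca),
        c = sum(!car & ca), d = sum(!car & !ca))
    },
    recessive = {
      car <- ds == 2
      c(a = sum(car & ca), b = sum(car & !ca),
        c = sum(!car & ca), d = sum(!car & !ca))
    }
  )
  do.call(rbind, lapply(names(tabs), function(gm) {
    t <- tabs[[gm]]
    p <- fisher_exact_p(t["a"], t["b"], t["c"], t["d"])
    cc <- if (any(t == 0)) 0.5 else 0
    or <- ((t["a"] + cc) * (t["d"] + cc)) / ((t["b"] + cc) * (t["c"] + cc))
    se <- sqrt(sum(1 / (t + cc)))
    data.frame(variant = variant, genetic_model = gm, n_carriers = nc,
               skipped = FALSE, skip_reason = NA_character_,
               or = unname(or), ci_lo = unname(exp(log(or) - 1.96 * se)),
               ci_hi = unname(exp(log(or) + 1.96 * se)), p = p,
               stringsAsFactors = FALSE)
  }))
}

#' Variant-level quantitative-trait tests
#'
#' Linear regression of a quantitative phenotype on the variant under the
#' genotypic (dosage 0/1/2), dominant and recessive codings, with covariates.
#'
#' @inheritParams variant_binary_tests
#' @param y Inverse-normal-transformed phenotype.
#' @param covariates Covariate data frame (default NULL).
#' @return Data frame, one row per genetic model, columns as
#'   [quantitative_burden()] plus `genetic_model`, `n_carriers`, `skipped`.
#' @export
variant_quantitative_tests <- function(dosage, y, covariates = NULL,
                                       variant = NA_character_,
                                       min_carriers = 6L) {
  nc <- .carrier_count(dosage)
  if (nc < min_carriers) {
    return(data.frame(variant = variant,
                      genetic_model = c("genotypic", "dominant", "recessive"),
                      n_carriers = nc, skipped = TRUE, beta = NA_real_,
                      se = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                      p = NA_real_, stringsAsFactors = FALSE))
  }
  codings <- list(genotypic = dosage, dominant = as.numeric(dosage > 0),
                  recessive = as.numeric(dosage == 2))
  do.call(rbind, lapply(names(codings), function(gm) {
    r <- quantitative_burden(codings[[gm]], y, covariates)
    data.frame(variant = variant, genetic_model = gm, n_carriers = nc,
               skipped = FALSE, beta = r$beta, se = r$se, ci_lo = r$ci_lo,
               ci_hi = r$ci_hi, p = r$p, stringsAsFactors = FALSE)
  }))
}

#' Exome-wide scan over a genotype matrix
#'
#' Applies [variant_binary_tests()] or [variant_quantitative_tests()] to every
#' variant passing the ExWAS QC profile.
#'
#' @param samples Sample data frame (needs `sex` and the phenotype column).
#' @param geno A `genotype_matrix`.
#' @param variants Annotation table aligned with `geno`.
#' @param phenotype A [phenotype_spec()].
#' @param thresholds [qc_thresholds()] applied before testing (default the
#'   `"exwas"` profile); NULL skips QC.
#' @param min_carriers Minimum carrier rule (default 6).
#' @return Data frame of per-variant x genetic-model results.
#' @export
exwas_scan <- function(samples, geno, variants, phenotype,
                       thresholds = qc_thresholds("exwas"), min_carriers = 6L) {
  if (!is.null(thresholds)) {
    gq <- apply_genotype_filters(geno, thresholds)
    sq <- apply_site_filters(cbind(variants, site_call_stats(geno, gq)), thresholds)
    ds <- gq$dosage
    ds[, !sq$pass] <- NA_integer_
  } else ds <- geno$dosage
  male <- samples$sex == "male"
  is_x <- variants$chrom %in% c("X", "chrX")
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = "-")
  if (phenotype$type == "quantitative") {
    yv <- int_transform(samples[[phenotype$name]])
    covs <- samples[, phenotype$covariates, drop = FALSE]
    if ("sex" %in% names(covs)) covs$sex <- as.numeric(covs$sex == "male")
  }
  do.call(rbind, lapply(seq_len(ncol(ds)), function(j) {
    if (phenotype$type == "binary") {
      variant_binary_tests(ds[, j], samples[[phenotype$name]] == 1, male,
                           x_linked = is_x[j], variant = key[j],
                           min_carriers = min_carriers)
    } else {
      variant_quantitative_tests(ds[, j], yv, covs, variant = key[j],
                                 min_carriers = min_carriers)
    }
  }))
}
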