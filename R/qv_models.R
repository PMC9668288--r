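#' Consequence-class term sets
#'
#' The SnpEff-style consequence vocabulary defining each variant class used by
#' the qualifying-variant models. PTV terms are a strict subset of the
#' nonsynonymous terms; synonymous and nonsynonymous sets are disjoint.
#'
#' @return Named list of character vectors: `ptv`, `missense`,
#'   `nonsynonymous`, `synonymous`.
#' @export
consequence_classes <- function() {
  ptv <- c("exon_loss_variant", "frameshift_variant", "start_lost",
           "stop_gained", "stop_lost", "splice_acceptor_variant",
           "splice_donor_variant", "gene_fusion", "bidirectional_gene_fusion",
           "rare_amino_acid_variant", "transcript_ablation")
  missense <- c("missense_variant_splice_region_variant", "missense_variant")
  nonsyn <- c(ptv,
              "conservative_inframe_deletion", "conservative_inframe_insertion",
              "disruptive_inframe_insertion", "disruptive_inframe_deletion",
              missense, "protein_altering_variant")
  list(ptv = ptv, missense = missense, nonsynonymous = nonsyn,
       synonymous = "synonymous_variant")
}

#' Classify a consequence term
#'
#' Maps a SnpEff-style consequence term to the most specific class it belongs
#' to: `"PTV"` and `"missense"` take precedence over the umbrella
#' `"nonsynonymous"`; unknown terms map to `"other"`.
#'
#' @param term Character vector of consequence terms.
#' @return Character vector over
#'   `c("PTV", "missense", "nonsynonymous", "synonymous", "other")`.
#' @examples
#' classify_consequence(c("stop_gained", "synonymous_variant", "intron_variant"))
#' @export
classify_consequence <- function(term) {
  cc <- consequence_classes()
  out <- rep("other", length(term))
  out[term %in% cc$nonsynonymous] <- "nonsynonymous"
  out[term %in% cc$missense] <- "missense"
  out[term %in% cc$ptv] <- "PTV"
  out[term %in% cc$synonymous] <- "synonymous"
  out
}

.qv_model <- function(name, classes, maf_internal_max, maf_external_max,
                      require_ext_absent = FALSE, revel_min = NA_real_,
                      mtr_percentile_max = NA_real_,
                      zygosity = c("dominant", "recessive")) {
  list(name = name, classes = classes,
       maf_internal_max = maf_internal_max, maf_external_max = maf_external_max,
       require_ext_absent = require_ext_absent, revel_min = revel_min,
       mtr_percentile_max = mtr_percentile_max, zygosity = match.arg(zygosity))
}

#' Qualifying-variant model registry
#'
#' Returns the registry of collapsing models: 10 nonsynonymous models (9
#' dominant + 1 recessive) plus a synonymous empirical negative control. The
#' recessive model admits nonsynonymous variants with internal and external
#' MAF < 1%; the dominant-model frequency/score ceilings are package
#' conventions (the published per-model parameters live in supplementary
#' material), documented here and freely overridable via `models`.
#'
#' Model fields: `classes` (allowed consequence classes, where
#' `"nonsynonymous"` subsumes PTV and missense), strict MAF ceilings
#' (`maf_internal_max`, `maf_external_max`), `require_ext_absent` (variant must
#' be unobserved in the external reference), optional `revel_min` and
#' `mtr_percentile_max` score conditions (applied to missense variants), and
#' `zygosity`.
#'
#' @param models Optional list of model specs (as built internally) replacing
#'   the defaults, or a data frame with one row per model and the fields above
#'   (`classes` as comma-separated string).
#' @return Named list of model specs with class `"qv_registry"`.
#' @examples
#' names(qv_model_registry())
#' @export
qv_model_registry <- function(models = NULL) {
  if (is.null(models)) {
    models <- list(
      .qv_model("syn", "synonymous", 0.005, 0.005),
      .qv_model("flexnonsyn", "nonsynonymous", 0.001, 0.001),
      .qv_model("flexnonsynmtr", "nonsynonymous", 0.001, 0.001,
                mtr_percentile_max = 50),
      .qv_model("flexdmg", c("PTV", "missense"), 0.005, 0.005, revel_min = 0.5),
      .qv_model("ptv", "PTV", 0.001, 0.001),
      .qv_model("ptv5pcnt", "PTV", 0.05, 0.05),
      .qv_model("ptvraredmg", c("PTV", "missense"), 0.0005, 0.0005,
                revel_min = 0.5),
      .qv_model("raredmg", "missense", 0.0005, 0.0005, revel_min = 0.5),
      .qv_model("UR", "nonsynonymous", 0.0005, 1, require_ext_absent = TRUE),
      .qv_model("URmtr", "missense", 0.0005, 1, require_ext_absent = TRUE,
                mtr_percentile_max = 50),
      .qv_model("rec", "nonsynonymous", 0.01, 0.01, zygosity = "recessive")
    )
  } else if (is.data.frame(models)) {
    models <- lapply(seq_len(nrow(models)), function(i) {
      r <- models[i, ]
      .qv_model(r$name, strsplit(r$classes, ",\\s*")[[1]],
                r$maf_internal_max, r$maf_external_max,
                isTRUE(r$require_ext_absent),
                if ("revel_min" %in% names(r)) r$revel_min else NA_real_,
                if ("mtr_percentile_max" %in% names(r)) r$mtr_percentile_max else NA_real_,
                r$zygosity)
    })
  }
  nm <- vapply(models, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate model name(s): ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  known <- c("PTV", "missense", "nonsynonymous", "synonymous")
  for (m in models) {
    bad <- setdiff(m$classes, known)
    if (length(bad)) stop("model '", m$name, "': unknown class ", bad[1])
    if (any(c(m$maf_internal_max, m$maf_external_max) < 0) ||
        any(c(m$maf_internal_max, m$maf_external_max) > 1))
      stop("model '", m$name, "': MAF ceilings must lie in [0, 1]")
  }
  names(models) <- nm
  structure(models, class = "qv_registry")
}

#' Decide qualifying-variant status under a model
#'
#' A variant qualifies when its consequence class is admitted by the model, its
#' internal and external MAFs are strictly below the ceilings, it satisfies the
#' external-absence requirement if any, and its REVEL / MTR-percentile scores
#' meet the model's conditions (score conditions bind missense variants; PTVs
#' pass them unconditionally). Variants are assumed to have passed QC.
#'
#' @param variants Variant annotation data frame with columns `consequence`,
#'   `maf_internal`, `maf_external`, and optionally `revel_score`,
#'   `mtr_percentile`, `ext_observed`.
#' @param model A model spec from [qv_model_registry()], or a model name looked
#'   up in `registry`.
#' @param registry Registry used when `model` is a name.
#' @return A list: `qualifies` (logical vector) and `first_fail` (character
#'   vector naming the first failed criterion, `NA` where qualifying).
#' @examples
#' v <- data.frame(consequence = "stop_gained", maf_internal = 0.005,
#'                 maf_external = 0.005)
#' qv_qualifies(v, "rec")$qualifies
#' @export
qv_qualifies <- function(variants, model, registry = qv_model_registry()) {
  if (is.character(model)) {
    if (!model %in% names(registry)) stop("model '", model, "' absent from registry")
    model <- registry[[model]]
  }
  n <- nrow(variants)
  cls <- classify_consequence(variants$consequence)
  allowed <- model$classes
  if ("nonsynonymous" %in% allowed) allowed <- union(allowed, c("PTV", "missense"))
  fail <- rep(NA_character_, n)

  chk <- function(fail, bad, reason) ifelse(is.na(fail) & bad, reason, fail)
  fail <- chk(fail, !cls %in% allowed, "class")
  fail <- chk(fail, !(variants$maf_internal < model$maf_internal_max), "maf_internal")
  fail <- chk(fail, !(variants$maf_external < model$maf_external_max), "maf_external")
  if (model$require_ext_absent) {
    obs <- if ("ext_observed" %in% names(variants)) variants$ext_observed
           else variants$maf_external > 0
    fail <- chk(fail, obs, "ext_observed")
  }
  is_mis <- cls == "missense"
  if (!is.na(model$revel_min)) {
    rv <- if ("revel_score" %in% names(variants)) variants$revel_score else NA_real_
    fail <- chk(fail, is_mis & !(!is.na(rv) & rv >= model$revel_min), "revel")
  }
  if (!is.na(model$mtr_percentile_max)) {
    mt <- if ("mtr_percentile" %in% names(variants)) variants$mtr_percentile else NA_real_
    fail <- chk(fail, is_mis & !(!is.na(mt) & mt <= model$mtr_percentile_max), "mtr")
  }
  list(qualifies = is.na(fail), first_fail = fail)
}

#' Serialize a model registry for provenance headers
#'
#' @param registry A [qv_model_registry()] object.
#' @return Data frame, one row per model, with `classes` comma-joined; suitable
#'   for echoing into results-file headers and for round-tripping back through
#'   `qv_model_registry(models = )`.
#' @export
registry_table <- function(registry = qv_model_registry()) {
  do.call(rbind, lapply(registry, function(m) {
    data.frame(name = m$name, classes = paste(m$classes, collapse = ","),
               maf_internal_max = m$maf_internal_max,
               maf_external_max = m$maf_external_max,
               require_ext_absent = m$require_ext_absent,
               revel_min = m$revel_min, mtr_percentile_max = m$mtr_percentile_max,
               zygosity = m$zygosity, stringsAsFactors = FALSE)
  }))
}
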