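# End-to-end orchestration: simulate-or-load -> QC -> qualifying variants ->
# collapsing -> (optional) ExWAS -> per-stratum meta-analysis, with a run
# manifest capturing inputs, checksums, registry, thresholds, seed and row
# counts.

#' Run the full analysis pipeline
#'
#' Sequences the stages over a simulated or loaded cohort. Stages are logged;
#' re-running with the same inputs, configuration and seed reproduces
#' identical outputs.
#'
#' @param sim_cfg A [sim_config()] (used when `input_prefix` is NULL).
#' @param input_prefix Path prefix of a cohort written by [write_cohort()];
#'   overrides simulation.
#' @param phenotypes List of [phenotype_spec()]; defaults to every binary and
#'   quantitative phenotype found in the configuration or phenotype table.
#' @param registry Model registry.
#' @param models Model names to run.
#' @param profile QC profile name for the collapsing stage.
#' @param run_exwas Also run the variant-level scan (default FALSE).
#' @param meta_by Optional stratification column (e.g. `"ancestry"`): binary
#'   phenotypes are additionally tested per stratum and combined with
#'   [cmh_test()].
#' @param out_dir Optional directory: results and the manifest are written as
#'   TSV/JSON.
#' @param seed Integer seed (simulation and sex matching).
#' @return List: `burden` (collapsing results), `lambda`, `exwas`, `meta`,
#'   `manifest`, and the `cohort` used.
#' @export
run_pipeline <- function(sim_cfg = sim_config(), input_prefix = NULL,
                         phenotypes = NULL, registry = qv_model_registry(),
                         models = names(registry), profile = "collapsing",
                         run_exwas = FALSE, meta_by = NULL, out_dir = NULL,
                         seed = 1L) {
  t0 <- Sys.time()
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  inputs <- list()
  if (is.null(input_prefix)) {
    say("stage simulate: n=%d", sim_cfg$n)
    cohort <- generate_cohort(sim_cfg, seed)
  } else {
    say("stage load: %s", input_prefix)
    cohort <- read_cohort(input_prefix)
    fls <- paste0(input_prefix, c(".vcf", ".annotations.tsv", ".phenotypes.tsv"))
    inputs <- as.list(tools::md5sum(fls))
  }
  samples <- cohort$samples; variants <- cohort$variants
  geno <- cohort$genotypes

  if (is.null(phenotypes)) {
    if (!is.null(cohort$config)) {
      phenotypes <- c(
        lapply(names(cohort$config$binary_phenotypes), phenotype_spec,
               type = "binary"),
        lapply(names(cohort$config$quantitative_phenotypes), phenotype_spec,
               type = "quantitative"))
    } else stop("phenotypes must be given when loading a cohort from disk")
  }
  for (ph in phenotypes) {
    if (!ph$name %in% names(samples))
      stop("stage collapse failed: phenotype column missing: ", ph$name)
  }

  thr <- qc_thresholds(profile)
  say("stage qc: profile=%s", profile)
  gt_qc <- apply_genotype_filters(geno, thr)
  site_qc <- apply_site_filters(cbind(variants, site_call_stats(geno, gt_qc)), thr)
  ds <- gt_qc$dosage
  ds[, !site_qc$pass] <- NA_integer_
  geno_qc <- genotype_matrix(ds, geno$dp, geno$gq, geno$ad)
  say("stage qc: %d/%d sites pass, %d genotype calls failed",
      sum(site_qc$pass), length(site_qc$pass), sum(gt_qc$fail))

  say("stage collapse: %d model(s), %d phenotype(s)", length(models),
      length(phenotypes))
  burden <- run_collapsing(samples, geno_qc, variants, phenotypes,
                           registry = registry, models = models, seed = seed)

  exwas <- NULL
  if (run_exwas) {
    say("stage exwas")
    exwas <- do.call(rbind, lapply(phenotypes, function(ph)
      cbind(phenotype = ph$name,
            exwas_scan(samples, geno, variants, ph))))
  }

  meta <- NULL
  if (!is.null(meta_by)) {
    say("stage meta: stratified by %s", meta_by)
    strata_lab <- samples[[meta_by]]
    bin <- Filter(function(p) p$type == "binary", phenotypes)
    meta <- do.call(rbind, lapply(bin, function(ph) {
      y <- samples[[ph$name]] == 1
      do.call(rbind, lapply(models, function(mod) {
        qv <- qv_qualifies(variants, mod, registry)$qualifies
        cm <- build_carrier_matrix(geno_qc, variants,
                                   stats::setNames(list(qv), mod),
                                   samples$sex == "male", registry)[[mod]]
        do.call(rbind, lapply(colnames(cm), function(g) {
          tabs <- lapply(split(seq_len(nrow(samples)), strata_lab), function(i)
            matrix(c(sum(cm[i, g] & y[i]), sum(!cm[i, g] & y[i]),
                     sum(cm[i, g] & !y[i]), sum(!cm[i, g] & !y[i])), 2))
          ok <- vapply(tabs, function(t) all(rowSums(t) > 0) &&
                         all(colSums(t) > 0), logical(1))
          if (!any(ok)) return(NULL)
          r <- cmh_test(tabs[ok])
          data.frame(phenotype = ph$name, model = mod, gene = g,
                     or = r$or, ci_lo = r$ci_lo, ci_hi = r$ci_hi,
                     chisq = r$chisq, p = r$p, n_strata = r$n_strata,
                     stringsAsFactors = FALSE)
        }))
      }))
    }))
  }

  manifest <- list(
    version = as.character(utils::packageVersion("rvburden")),
    seed = seed,
    profile = profile,
    models = models,
    registry = registry_table(registry),
    inputs = inputs,
    rows = list(samples = nrow(samples), variants = nrow(variants),
                burden = nrow(burden),
                exwas = if (is.null(exwas)) 0L else nrow(exwas),
                meta = if (is.null(meta)) 0L else nrow(meta)),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    log = log_lines)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    .write_tsv(burden, file.path(out_dir, "burden.tsv"))
    .write_tsv(attr(burden, "lambda"), file.path(out_dir, "lambda.tsv"))
    if (!is.null(exwas)) .write_tsv(exwas, file.path(out_dir, "exwas.tsv"))
    if (!is.null(meta)) .write_tsv(meta, file.path(out_dir, "meta.tsv"))
    .write_tsv(qq_data(burden$p[!is.na(burden$p)]),
               file.path(out_dir, "qq.tsv"))
    mf <- manifest; mf$log <- NULL
    jsonlite::write_json(mf, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }

  list(burden = burden, lambda = attr(burden, "lambda"), exwas = exwas,
       meta = meta, manifest = manifest, cohort = cohort)
}
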