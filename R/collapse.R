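#' Exact two-sided p-value for a 2x2 table
#'
#' Conditional (hypergeometric) exact test: the two-sided p-value sums the
#' probabilities of all tables with the observed margins whose probability does
#' not exceed that of the observed table (minimum-likelihood rule, the
#' convention of `stats::fisher.test`).
#'
#' @param a,b,c,d Cell counts: rows are carrier/noncarrier, columns case/control
#'   (`a` = case carriers, `b` = control carriers, `c` = case noncarriers,
#'   `d` = control noncarriers).
#' @return p-value in (0, 1].
#' @export
fisher_exact_p <- function(a, b, c, d) {
  m <- a + b          # carriers
  n <- c + d          # noncarriers
  k <- a + c          # cases
  if (m + n == 0 || k == 0 || k == m + n || m == 0 || n == 0) return(1)
  supp <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(supp, m, n, k)
  min(1, sum(dens[dens <= dens[supp == a] * (1 + 1e-7)]))
}

#' Fisher's exact burden test for a gene
#'
#' Compares the proportion of qualifying-variant carriers between cases and
#' controls with the exact two-sided test. The odds ratio is the
#' cross-product ratio, with the Haldane-Anscombe 0.5 continuity correction
#' applied to every cell iff any cell is zero; the 95% CI is the Woolf log-OR
#' normal approximation on the (possibly corrected) table.
#'
#' @param carrier Logical carrier indicator per sample.
#' @param is_case Logical case indicator per sample.
#' @param gene,model,phenotype Optional labels echoed into the result.
#' @return A one-row data frame (`burden_result`): counts, carrier frequencies,
#'   `or`, `ci_lo`, `ci_hi`, `p`, and `or_defined`.
#' @examples
#' fisher_burden(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
#'               c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))$p  # 0.1
#' @export
fisher_burden <- function(carrier, is_case, gene = NA_character_,
                          model = NA_character_, phenotype = NA_character_) {
  keep <- !is.na(carrier) & !is.na(is_case)
  carrier <- carrier[keep]; is_case <- is_case[keep]
  if (!any(is_case) || all(is_case)) stop("need at least one case and one control")
  a <- sum(carrier & is_case); b <- sum(carrier & !is_case)
  c_ <- sum(!carrier & is_case); d <- sum(!carrier & !is_case)
  or_defined <- any(carrier)
  if (!or_defined) {
    p <- 1; or <- NA_real_; ci <- c(NA_real_, NA_real_)
  } else {
    p <- fisher_exact_p(a, b, c_, d)
    cc <- if (any(c(a, b, c_, d) == 0)) 0.5 else 0
    aa <- a + cc; bb <- b + cc; cc_ <- c_ + cc; dd <- d + cc
    or <- (aa * dd) / (bb * cc_)
    se <- sqrt(1 / aa + 1 / bb + 1 / cc_ + 1 / dd)
    ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  }
  data.frame(gene = gene, model = model, phenotype = phenotype,
             case_carrier = a, control_carrier = b,
             case_noncarrier = c_, control_noncarrier = d,
             f_case = a / (a + c_), f_ctrl = b / (b + d),
             or = or, ci_lo = ci[1], ci_hi = ci[2], p = p,
             or_defined = or_defined, stringsAsFactors = FALSE)
}

#' Rank-based inverse-normal transformation
#'
#' Blom-offset fractional ranks mapped through the standard-normal quantile:
#' `qnorm((rank - 3/8) / (n + 1/4))`. Ties share the average rank; missing
#' values stay missing and do not enter `n`.
#'
#' @param x Numeric vector with at least two distinct non-missing values.
#' @return Numeric vector of scores, same length and order as `x`.
#' @examples
#' round(int_transform(c(1, 2, 3)), 4)
#' @export
int_transform <- function(x) {
  ok <- !is.na(x)
  v <- x[ok]
  if (length(v) < 2) stop("need >= 2 non-missing values")
  if (length(unique(v)) == 1) stop("inverse-normal transform undefined for constant input")
  r <- rank(v, ties.method = "average")
  out <- rep(NA_real_, length(x))
  out[ok] <- stats::qnorm((r - 3 / 8) / (length(v) + 1 / 4))
  out
}

#' Sex-match controls to the case sex composition
#'
#' If the case and control female fractions differ (two-sided Fisher exact
#' p < 0.05), the surplus sex among the controls is randomly down-sampled
#' (seeded) until the fractions agree to within one sample and the test is no
#' longer significant; otherwise controls are returned unchanged.
#'
#' @param case_female Logical vector over cases (TRUE = female).
#' @param control_female Logical vector over controls.
#' @param seed Integer seed making the down-sampling reproducible.
#' @return Integer indices of the retained controls (in input order).
#' @export
sex_match_controls <- function(case_female, control_female, seed = 1L) {
  n_ca <- length(case_female); n_co <- length(control_female)
  f_ca <- sum(case_female); f_co <- sum(control_female)
  if (f_ca == 0 && f_co == 0 || f_ca == n_ca && f_co == n_co) {
    warning("single-sex input; controls returned unchanged")
    return(seq_len(n_co))
  }
  p <- fisher_exact_p(f_ca, f_co, n_ca - f_ca, n_co - f_co)
  if (p >= 0.05) return(seq_len(n_co))
  frac_ca <- f_ca / n_ca
  surplus_female <- (f_co / n_co) > frac_ca
  keep_sex <- which(control_female != surplus_female)   # deficient sex: keep all
  pool <- which(control_female == surplus_female)
  n_keep_sex <- length(keep_sex)
  # target count of the surplus sex so the control fraction matches the cases'
  target <- if (surplus_female) round(frac_ca * n_keep_sex / (1 - frac_ca))
            else round((1 - frac_ca) * n_keep_sex / frac_ca)
  target <- min(length(pool), max(0L, target))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  repeat {
    kept_pool <- sort(sample(pool, target))
    idx <- sort(c(keep_sex, kept_pool))
    f2 <- sum(control_female[idx])
    p2 <- fisher_exact_p(f_ca, f2, n_ca - f_ca, length(idx) - f2)
    if (p2 >= 0.05) return(idx)
    target <- target - 1L  # shave further; terminates at 0
    if (target < 0L) stop("sex matching failed to reach p >= 0.05")
  }
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
}
.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Covariate-adjusted linear burden test
#'
#' Ordinary least-squares regression of an (already inverse-normal-transformed)
#' quantitative phenotype on the carrier indicator plus covariates. The carrier
#' coefficient is the effect in SD units, with a normal-approximation 95% CI
#' and two-sided t-test p-value.
#'
#' @param carrier Logical carrier indicator.
#' @param y Numeric phenotype.
#' @param covariates Data frame of covariates (may be NULL); complete cases
#'   only are analyzed.
#' @param gene,model,phenotype Labels echoed into the result.
#' @return One-row data frame: `n_carrier`, `n_noncarrier`, `beta`, `se`,
#'   `ci_lo`, `ci_hi`, `p`, `estimable`.
#' @export
quantitative_burden <- function(carrier, y, covariates = NULL,
                                gene = NA_character_, model = NA_character_,
                                phenotype = NA_character_) {
  df <- data.frame(.y = y, .carrier = as.numeric(carrier))
  if (!is.null(covariates)) df <- cbind(df, covariates)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n_car <- sum(df$.carrier == 1)
  base <- data.frame(gene = gene, model = model, phenotype = phenotype,
                     n_carrier = n_car, n_noncarrier = nrow(df) - n_car,
                     beta = NA_real_, se = NA_real_, ci_lo = NA_real_,
                     ci_hi = NA_real_, p = NA_real_, estimable = FALSE,
                     stringsAsFactors = FALSE)
  if (n_car == 0) return(base)
  fit <- stats::lm(.y ~ ., data = df)
  if (any(is.na(stats::coef(fit)))) {
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear covariate(s): ", paste(dropped, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  est <- sm[".carrier", ]
  base$beta <- est[["Estimate"]]; base$se <- est[["Std. Error"]]
  base$ci_lo <- base$beta - stats::qnorm(0.975) * base$se
  base$ci_hi <- base$beta + stats::qnorm(0.975) * base$se
  base$p <- est[["Pr(>|t|)"]]
  base$estimable <- TRUE
  base
}

#' Run the gene-level collapsing analysis
#'
#' For each requested model, computes qualifying variants, builds the carrier
#' matrix, and tests each gene against each phenotype: binary phenotypes via
#' Fisher's exact test on sex-matched controls, quantitative phenotypes via
#' linear regression on inverse-normal-transformed values with the phenotype's
#' covariates. Per model x phenotype, the genomic inflation factor lambda of
#' the resulting p-values is reported.
#'
#' @param samples Sample data frame: `sample_id`, `sex` ("male"/"female"),
#'   `age`, phenotype columns, covariate columns.
#' @param geno A `genotype_matrix` (apply QC first, or pass `thresholds`).
#' @param variants Variant annotation table aligned with `geno`.
#' @param phenotypes List of phenotype specs from [phenotype_spec()].
#' @param registry Model registry; `models` selects a subset by name.
#' @param models Character vector of model names to run.
#' @param thresholds Optional [qc_thresholds()]; when given, genotype and site
#'   filters are applied before collapsing.
#' @param sex_match Match controls by sex for binary phenotypes (default TRUE).
#' @param seed Seed for the sex-matching down-sampling.
#' @return Data frame of `burden_result` rows (column `negative_control` flags
#'   the synonymous model, `significant` flags p < 1e-8), with attribute
#'   `lambda` (data frame per model x phenotype) and attribute `registry`.
#' @export
run_collapsing <- function(samples, geno, variants, phenotypes,
                           registry = qv_model_registry(),
                           models = names(registry), thresholds = NULL,
                           sex_match = TRUE, seed = 1L) {
  stopifnot(all(models %in% names(registry)))
  if (!identical(samples$sample_id, rownames(geno$dosage)))
    stop("sample present in genotypes but absent from cohort (id mismatch)")
  if (!is.null(thresholds)) {
    gq <- apply_genotype_filters(geno, thresholds)
    sq <- apply_site_filters(cbind(variants, site_call_stats(geno, gq)), thresholds)
    ds <- gq$dosage
    ds[, !sq$pass] <- NA_integer_
    geno <- genotype_matrix(ds, geno$dp, geno$gq, geno$ad)
  }
  male <- samples$sex == "male"
  qv_sets <- lapply(stats::setNames(models, models), function(m)
    qv_qualifies(variants, m, registry)$qualifies)
  cmat <- build_carrier_matrix(geno, variants, qv_sets, male, registry)

  rows <- list(); lam <- list()
  for (mod in models) {
    for (ph in phenotypes) {
      res <- lapply(colnames(cmat[[mod]]), function(g) {
        carrier <- cmat[[mod]][, g]
        if (ph$type == "binary") {
          y <- samples[[ph$name]] == 1
          idx_ca <- which(y)
          idx_co <- which(!y)
          if (sex_match) {
            keep <- sex_match_controls(!male[idx_ca], !male[idx_co], seed = seed)
            idx_co <- idx_co[keep]
          }
          idx <- c(idx_ca, idx_co)
          fisher_burden(carrier[idx], y[idx], gene = g, model = mod,
                        phenotype = ph$name)
        } else {
          yv <- int_transform(samples[[ph$name]])
          covs <- samples[, ph$covariates, drop = FALSE]
          if ("sex" %in% names(covs)) covs$sex <- as.numeric(covs$sex == "male")
          quantitative_burden(carrier, yv, covs, gene = g, model = mod,
                              phenotype = ph$name)
        }
      })
      res <- do.call(rbind, res)
      lam[[length(lam) + 1L]] <- data.frame(model = mod, phenotype = ph$name,
                                            lambda = genomic_lambda(res$p[!is.na(res$p)]))
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- .rbind_fill(rows)
  out$significant <- !is.na(out$p) & out$p < 1e-8
  out$negative_control <- vapply(out$model, function(m)
    identical(registry[[m]]$classes, "synonymous"), logical(1))
  attr(out, "lambda") <- do.call(rbind, lam)
  attr(out, "registry") <- registry_table(registry)
  out
}

# rbind data frames with differing columns (binary vs quantitative results),
# filling absentees with NA
.rbind_fill <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  cols <- unique(unlist(lapply(lst, names)))
  do.call(rbind, lapply(lst, function(d) {
    for (cl in setdiff(cols, names(d))) d[[cl]] <- NA
    d[, cols, drop = FALSE]
  }))
}

#' Phenotype specification
#'
#' @param name Column name in the sample table.
#' @param type `"binary"` or `"quantitative"`.
#' @param covariates Covariate column names for quantitative models (default
#'   age and sex; add a medication indicator for blood-pressure traits, BMI
#'   when configured).
#' @param sex_restrict Optional `"male"`/`"female"` restriction.
#' @return A list with class `"phenotype_spec"`.
#' @export
phenotype_spec <- function(name, type = c("binary", "quantitative"),
                           covariates = c("age", "sex"), sex_restrict = NULL) {
  structure(list(name = name, type = match.arg(type), covariates = covariates,
                 sex_restrict = sex_restrict), class = "phenotype_spec")
}
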