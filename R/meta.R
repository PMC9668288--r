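#' Cochran-Mantel-Haenszel stratified 2x2xN test
#'
#' Combines per-stratum 2x2 carrier-by-case tables into a Mantel-Haenszel
#' common odds ratio with the CMH chi-squared test (1 df, no continuity
#' correction) and a Robins-Breslow-Greenland variance 95% CI on the log odds
#' ratio.
#'
#' @param strata A list of 2x2 matrices (rows carrier/noncarrier, columns
#'   case/control), or a 2x2xN array. Strata with an empty margin contribute
#'   nothing and are dropped with a message.
#' @param correct Apply the 0.5 continuity correction to the CMH statistic
#'   (default FALSE; matters at rare-carrier scale).
#' @return A list (`meta_result`): `or`, `ci_lo`, `ci_hi`, `chisq`, `df`, `p`,
#'   `stratum_or`, `n_strata`.
#' @examples
#' s <- matrix(c(10, 5, 90, 95), 2, byrow = TRUE)
#' cmh_test(list(s, s))$or  # 2.111..., the single-table OR
#' @export
cmh_test <- function(strata, correct = FALSE) {
  if (is.array(strata) && length(dim(strata)) == 3)
    strata <- lapply(seq_len(dim(strata)[3]), function(i) strata[, , i])
  stopifnot(length(strata) >= 1)
  ok <- vapply(strata, function(t) {
    t <- as.matrix(t)
    all(t >= 0) && all(rowSums(t) > 0) && all(colSums(t) > 0)
  }, logical(1))
  if (!any(ok)) stop("all strata degenerate (empty margin)")
  if (!all(ok)) message(sum(!ok), " degenerate stratum/strata dropped")
  strata <- strata[ok]

  a <- vapply(strata, function(t) t[1, 1], numeric(1))
  b <- vapply(strata, function(t) t[1, 2], numeric(1))
  c_ <- vapply(strata, function(t) t[2, 1], numeric(1))
  d <- vapply(strata, function(t) t[2, 2], numeric(1))
  n <- a + b + c_ + d

  or_mh <- sum(a * d / n) / sum(b * c_ / n)
  # CMH score statistic: sum over strata of (a - E[a]) with variance
  # r1*r2*c1*c2 / (n^2 (n-1))
  ea <- (a + b) * (a + c_) / n
  va <- (a + b) * (c_ + d) * (a + c_) * (b + d) / (n^2 * (n - 1))
  dev <- abs(sum(a) - sum(ea)) - if (correct) 0.5 else 0
  chisq <- max(0, dev)^2 / sum(va)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)

  # Robins-Breslow-Greenland variance of log(or_mh)
  P <- (a + d) / n; Q <- (b + c_) / n
  R <- a * d / n;  S <- b * c_ / n
  sr <- sum(R); ss <- sum(S)
  var_log <- sum(P * R) / (2 * sr^2) + sum(P * S + Q * R) / (2 * sr * ss) +
    sum(Q * S) / (2 * ss^2)
  ci <- exp(log(or_mh) + c(-1, 1) * stats::qnorm(0.975) * sqrt(var_log))

  structure(list(or = or_mh, ci_lo = ci[1], ci_hi = ci[2], chisq = chisq,
                 df = 1L, p = p, stratum_or = (a * d) / (b * c_),
                 n_strata = length(strata)),
            class = "meta_result")
}

#' Chi-squared heterogeneity test between two estimates
#'
#' Cochran's Q for two log-scale estimates (log odds ratios or betas) with
#' standard errors: `Q = (b1 - b2)^2 / (se1^2 + se2^2)`, referred to
#' chi-squared with 1 df.
#'
#' @param b1,b2 Estimates on a common (log) scale.
#' @param se1,se2 Positive standard errors.
#' @return List with `Q`, `df`, `p`.
#' @examples
#' heterogeneity_test(log(0.45), se_from_ci(0.28, 0.69),
#'                    log(1.11), se_from_ci(0.86, 1.40))
#' @export
heterogeneity_test <- function(b1, se1, b2, se2) {
  if (se1 <= 0 || se2 <= 0) stop("standard errors must be positive")
  q <- (b1 - b2)^2 / (se1^2 + se2^2)
  list(Q = q, df = 1L, p = stats::pchisq(q, 1, lower.tail = FALSE))
}

#' Back-derive a log-scale standard error from a printed 95% CI
#'
#' `(log(upper) - log(lower)) / (2 * 1.96)`; useful when only ratio-scale
#' confidence limits are reported.
#'
#' @param lower,upper Ratio-scale 95% confidence limits.
#' @return Standard error of the log estimate.
#' @export
se_from_ci <- function(lower, upper) (log(upper) - log(lower)) / (2 * stats::qnorm(0.975))

#' Genomic inflation factor lambda
#'
#' Median of the chi-squared(1) quantiles of the observed p-values divided by
#' the chi-squared(1) median (~0.4549). Lambda near 1 indicates calibrated
#' test statistics.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Lambda (scalar).
#' @examples
#' genomic_lambda(rep(0.5, 200))  # 1
#' @export
genomic_lambda <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) < 100) warning("fewer than 100 p-values; lambda is noisy")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

#' Pooled pan-ancestry quantitative burden test
#'
#' Single linear model over the pooled cohort with categorical ancestry and
#' the top five principal components as covariates in addition to the
#' phenotype's own covariates (age, sex by default).
#'
#' @param carrier Logical carrier indicator.
#' @param y Inverse-normal-transformed phenotype.
#' @param samples Sample data frame with `ancestry`, `PC1`..`PC5` and the
#'   covariate columns.
#' @param covariates Additional covariate column names (default age + sex).
#' @param n_pcs Number of principal components (default 5).
#' @param ... Passed to [quantitative_burden()].
#' @return A `burden_result` row.
#' @export
pan_ancestry_quantitative <- function(carrier, y, samples,
                                      covariates = c("age", "sex"),
                                      n_pcs = 5, ...) {
  pcs <- paste0("PC", seq_len(n_pcs))
  miss <- setdiff(c("ancestry", pcs), names(samples))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  cov <- samples[, c(covariates, pcs), drop = FALSE]
  if ("sex" %in% names(cov)) cov$sex <- as.numeric(cov$sex == "male")
  anc <- factor(samples$ancestry)
  if (nlevels(anc) > 1) {
    dm <- stats::model.matrix(~ anc)[, -1, drop = FALSE]
    cov <- cbind(cov, as.data.frame(dm))
  }
  # flag (but keep) strata without carrier variance
  tab <- tapply(carrier, anc, function(x) stats::var(as.numeric(x)))
  if (any(tab == 0, na.rm = TRUE))
    message("stratum/strata without carrier variance retained: ",
            paste(names(tab)[which(tab == 0)], collapse = ", "))
  quantitative_burden(carrier, y, cov, ...)
}

#' QQ-plot data for a p-value vector
#'
#' @param p P-values.
#' @return Data frame of expected and observed -log10 p, sorted.
#' @export
qq_data <- function(p) {
  p <- sort(p[!is.na(p)])
  n <- length(p)
  data.frame(expected = -log10((seq_len(n) - 0.5) / n), observed = -log10(p))
}
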