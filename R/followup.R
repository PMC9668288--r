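# Secondary analyses: conditional joint regression, leave-variants-out
# collapsing, dominant single-variant logistic models, risk-haplotype
# stratification with an effect-modification test, and pairwise LD.

#' Conditional joint regression on several carrier indicators
#'
#' Fits one logistic (binary outcome) or linear (quantitative outcome) model
#' containing all carrier indicators simultaneously plus covariates, so each
#' estimate is conditional on the others.
#'
#' @param indicators Named list or data frame of carrier indicators (0/1 or
#'   logical); names label the output rows.
#' @param outcome Binary (0/1 or logical) or numeric outcome.
#' @param covariates Optional covariate data frame.
#' @param family `"logistic"` or `"linear"`.
#' @return Data frame, one row per indicator: `estimate` (log-OR or beta),
#'   `se`, `or` (logistic only), `ci_lo`, `ci_hi`, `p`, `separation` flag.
#' @export
conditional_joint_regression <- function(indicators, outcome, covariates = NULL,
                                         family = c("logistic", "linear")) {
  family <- match.arg(family)
  ind <- as.data.frame(lapply(indicators, as.numeric))
  if (any(colSums(ind) == 0)) stop("indicator without carriers")
  for (i in seq_len(ncol(ind))) for (j in seq_len(ncol(ind))) {
    if (i < j && isTRUE(all(ind[[i]] == ind[[j]])))
      stop("identical indicators: ", names(ind)[i], ", ", names(ind)[j])
  }
  df <- data.frame(.y = as.numeric(outcome))
  df <- cbind(df, ind)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  fit <- if (family == "logistic") {
    stats::glm(.y ~ ., data = df, family = stats::binomial())
  } else stats::lm(.y ~ ., data = df)
  cf <- stats::coef(fit)
  if (any(is.na(cf))) stop("collinear predictors: ",
                           paste(names(cf)[is.na(cf)], collapse = ", "))
  sm <- summary(fit)$coefficients
  nm <- make.names(names(ind))
  out <- data.frame(indicator = names(ind), estimate = sm[nm, 1],
                    se = sm[nm, 2], stringsAsFactors = FALSE)
  # complete separation shows up as runaway coefficients with huge SEs
  out$separation <- abs(out$estimate) > 10 & out$se > 10
  out$ci_lo <- out$estimate - 1.96 * out$se
  out$ci_hi <- out$estimate + 1.96 * out$se
  out$p <- sm[nm, 4]
  if (family == "logistic") {
    out$or <- exp(out$estimate)
    out$or_lo <- exp(out$ci_lo); out$or_hi <- exp(out$ci_hi)
  }
  rownames(out) <- NULL
  out
}

#' Collapsing analysis with variants left out
#'
#' Re-runs the gene's burden test on the qualifying-variant set minus an
#' exclusion list (e.g. the two most frequent PTVs), leaving everything else
#' identical to the standard analysis.
#'
#' @param samples,geno,variants As in [run_collapsing()].
#' @param gene Gene symbol.
#' @param exclude Character keys `chrom-pos-ref-alt` of variants to exclude;
#'   must belong to the gene's QV set.
#' @param model Model name.
#' @param phenotype A [phenotype_spec()].
#' @param registry Model registry.
#' @param ... Passed to [run_collapsing()] (e.g. `sex_match`, `seed`).
#' @return A `burden_result` row with attribute `excluded`; if the exclusion
#'   empties the QV set, a flagged row with no test.
#' @export
leave_out_collapsing <- function(samples, geno, variants, gene, exclude,
                                 model, phenotype,
                                 registry = qv_model_registry(), ...) {
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = "-")
  qv <- qv_qualifies(variants, model, registry)$qualifies & variants$gene == gene
  bad <- setdiff(exclude, key[qv])
  if (length(bad)) stop("excluded variant(s) not in the gene's QV set: ",
                        paste(bad, collapse = ", "))
  keep <- !(key %in% exclude)
  if (!any(qv & keep)) {
    out <- data.frame(gene = gene, model = model, phenotype = phenotype$name,
                      p = NA_real_, empty_qv_set = TRUE)
    attr(out, "excluded") <- exclude
    return(out)
  }
  v2 <- variants[keep, , drop = FALSE]
  g2 <- genotype_matrix(geno$dosage[, keep, drop = FALSE],
                        geno$dp[, keep, drop = FALSE],
                        geno$gq[, keep, drop = FALSE],
                        geno$ad[, keep, drop = FALSE])
  res <- run_collapsing(samples, g2, v2, list(phenotype), registry,
                        models = model, ...)
  out <- res[res$gene == gene, , drop = FALSE]
  attr(out, "excluded") <- exclude
  out
}

#' Dominant single-variant logistic model
#'
#' Logistic regression of a binary outcome on the carrier indicator
#' (dosage >= 1) of a single variant, with covariates (age and sex by
#' default in the calling analyses).
#'
#' @param dosage Dosage vector (0/1/2).
#' @param outcome Binary outcome.
#' @param covariates Covariate data frame.
#' @return One-row data frame: `or`, `ci_lo`, `ci_hi`, `p`, `n_carriers`.
#' @export
dominant_snp_model <- function(dosage, outcome, covariates = NULL) {
  nc <- sum(dosage > 0, na.rm = TRUE)
  if (nc == 0 || all(dosage > 0, na.rm = TRUE)) {
    return(data.frame(or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                      p = NA_real_, n_carriers = nc, monomorphic = TRUE))
  }
  r <- conditional_joint_regression(list(carrier = as.numeric(dosage > 0)),
                                    outcome, covariates, family = "logistic")
  data.frame(or = r$or, ci_lo = r$or_lo, ci_hi = r$or_hi, p = r$p,
             n_carriers = nc, monomorphic = FALSE)
}

#' Stratified analysis with an effect-modification test
#'
#' Fits the carrier-effect model separately in carriers and noncarriers of a
#' modifier (e.g. a common risk haplotype tag), then compares the two
#' log-scale estimates with the chi-squared heterogeneity test.
#'
#' @param carrier Exposure carrier indicator.
#' @param modifier Logical modifier-carrier indicator defining the strata.
#' @param outcome Binary or numeric outcome.
#' @param covariates Covariate data frame.
#' @param family `"logistic"` or `"linear"`.
#' @return List (`stratified_effect`): `strata` data frame (one row per
#'   modifier stratum with estimate/OR, CI, p) and `heterogeneity`
#'   (`Q`, `df`, `p`, or NULL when a stratum has no carriers).
#' @export
stratified_effect_modification <- function(carrier, modifier, outcome,
                                           covariates = NULL,
                                           family = c("logistic", "linear")) {
  family <- match.arg(family)
  if (!any(modifier) || all(modifier)) stop("both modifier strata must be non-empty")
  fit1 <- function(idx, label) {
    if (!any(carrier[idx])) {
      return(data.frame(stratum = label, estimate = NA_real_, se = NA_real_,
                        p = NA_real_, n = length(idx),
                        n_carriers = 0L, stringsAsFactors = FALSE))
    }
    cv <- if (is.null(covariates)) NULL else covariates[idx, , drop = FALSE]
    r <- conditional_joint_regression(list(carrier = carrier[idx]),
                                      outcome[idx], cv, family = family)
    data.frame(stratum = label, estimate = r$estimate, se = r$se, p = r$p,
               n = length(idx), n_carriers = sum(carrier[idx]),
               stringsAsFactors = FALSE)
  }
  st <- rbind(fit1(which(!modifier), "modifier_noncarrier"),
              fit1(which(modifier), "modifier_carrier"))
  st$ci_lo <- st$estimate - 1.96 * st$se
  st$ci_hi <- st$estimate + 1.96 * st$se
  if (family == "logistic") st$or <- exp(st$estimate)
  het <- if (any(is.na(st$estimate))) NULL else
    heterogeneity_test(st$estimate[1], st$se[1], st$estimate[2], st$se[2])
  structure(list(strata = st, heterogeneity = het), class = "stratified_effect")
}

#' Pairwise linkage disequilibrium statistics
#'
#' From phased haplotypes the haplotype frequencies are counted directly; from
#' unphased genotypes they are estimated by an EM algorithm (maximum
#' likelihood under random mating, started at linkage equilibrium). Either way
#' D = p(AB) - p(A)p(B), D' = |D| / Dmax, and r^2 = D^2 / (p(A)q(A)p(B)q(B)).
#'
#' @param x Either a 2-column matrix of phased alt-allele indicators (one row
#'   per haplotype), or with `phased = FALSE` a 2-column matrix of unphased
#'   dosages (0/1/2, one row per individual).
#' @param phased Are the rows haplotypes?
#' @param max_iter,tol EM controls (defaults 1000 iterations, log-likelihood
#'   change < 1e-10).
#' @return List (`ld_result`): `D`, `Dprime`, `r2`, `hap_freq` (AB, Ab, aB,
#'   ab), `method`, and `loglik`/`iterations` for EM.
#' @examples
#' h <- cbind(rep(c(1, 1, 0, 0), c(40, 10, 10, 40)),
#'            rep(c(1, 0, 1, 0), c(40, 10, 10, 40)))
#' ld_stats(h)$Dprime  # 0.6
#' @export
ld_stats <- function(x, phased = TRUE, max_iter = 1000L, tol = 1e-10) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == 2)
  if (phased) {
    pAB <- mean(x[, 1] == 1 & x[, 2] == 1)
    pAb <- mean(x[, 1] == 1 & x[, 2] == 0)
    paB <- mean(x[, 1] == 0 & x[, 2] == 1)
    pab <- 1 - pAB - pAb - paB
    hf <- c(AB = pAB, Ab = pAb, aB = paB, ab = pab)
    method <- "phased"; ll <- NA_real_; it <- NA_integer_
  } else {
    em <- .ld_em(x[, 1], x[, 2], max_iter, tol)
    hf <- em$hap_freq; method <- "em"; ll <- em$loglik; it <- em$iterations
  }
  pA <- hf["AB"] + hf["Ab"]; pB <- hf["AB"] + hf["aB"]
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) stop("monomorphic variant")
  pA <- unname(pA); pB <- unname(pB)
  D <- unname(hf["AB"] - pA * pB)
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  structure(list(D = D, Dprime = abs(D) / dmax,
                 r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)),
                 hap_freq = hf, method = method, loglik = ll, iterations = it),
            class = "ld_result")
}

# EM over the nine unphased genotype classes; only the double heterozygote is
# phase-ambiguous.
.ld_em <- function(g1, g2, max_iter, tol) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n2 <- 2 * length(g1)
  n_dh <- sum(g1 == 1 & g2 == 1)
  # fixed haplotype contributions from the eight phase-unambiguous classes
  cAB <- cAb <- caB <- cab <- 0
  for (cls in list(c(0, 0), c(0, 1), c(0, 2), c(1, 0), c(1, 2),
                   c(2, 0), c(2, 1), c(2, 2))) {
    cnt <- sum(g1 == cls[1] & g2 == cls[2])
    if (!cnt) next
    nAB <- min(cls[1], cls[2])
    nAb <- cls[1] - nAB
    naB <- cls[2] - nAB
    nab <- 2 - nAB - nAb - naB
    cAB <- cAB + cnt * nAB; cAb <- cAb + cnt * nAb
    caB <- caB + cnt * naB; cab <- cab + cnt * nab
  }
  pA <- mean(g1) / 2; pB <- mean(g2) / 2
  p <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))  # linkage-equilibrium start
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    denom <- unname(p["AB"] * p["ab"] + p["Ab"] * p["aB"])
    w <- if (denom > 0) unname(p["AB"] * p["ab"]) / denom else 0.5
    p <- c(AB = cAB + n_dh * w, Ab = cAb + n_dh * (1 - w),
           aB = caB + n_dh * (1 - w), ab = cab + n_dh * w) / n2
    ll <- cAB * log(pmax(p["AB"], 1e-300)) + cAb * log(pmax(p["Ab"], 1e-300)) +
      caB * log(pmax(p["aB"], 1e-300)) + cab * log(pmax(p["ab"], 1e-300)) +
      n_dh * log(pmax(2 * (p["AB"] * p["ab"] + p["Ab"] * p["aB"]), 1e-300))
    if (abs(ll - ll_old) < tol) {
      return(list(hap_freq = p, loglik = unname(ll), iterations = it))
    }
    ll_old <- ll
  }
  stop("EM failed to converge after ", max_iter,
       " iterations (final log-likelihood ", signif(ll_old, 6), ")")
}
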