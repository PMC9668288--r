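# Conditional joint regression, leave-out collapsing, stratified effect
# modification, LD statistics.

test_that("joint estimates match marginals for non-overlapping indicators", {
  set.seed(61)
  n <- 5000
  i1 <- runif(n) < 0.02
  i2 <- !i1 & runif(n) < 0.02       # zero carrier overlap
  eta <- -1.8 + log(0.4) * i1 + log(2.0) * i2
  y <- rbinom(n, 1, plogis(eta))
  joint <- conditional_joint_regression(list(v1 = i1, v2 = i2), y)
  m1 <- conditional_joint_regression(list(v1 = i1), y)
  m2 <- conditional_joint_regression(list(v2 = i2), y)
  expect_equal(joint$estimate[1], m1$estimate, tolerance = 0.05)
  expect_equal(joint$estimate[2], m2$estimate, tolerance = 0.05)
  # single indicator equals the plain glm fit exactly
  fit <- glm(y ~ i1, family = binomial)
  expect_equal(m1$estimate, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(m1$p, summary(fit)$coefficients[2, 4], tolerance = 1e-10)
})

test_that("degenerate indicator sets are rejected or flagged", {
  set.seed(62)
  i1 <- runif(500) < 0.05
  y <- rbinom(500, 1, 0.2)
  expect_error(conditional_joint_regression(list(a = i1, b = i1), y),
               "identical")
  expect_error(conditional_joint_regression(list(a = rep(FALSE, 500)), y),
               "without carriers")
  # complete separation is flagged, not silently returned
  ys <- as.numeric(i1)
  r <- conditional_joint_regression(list(a = i1), ys)
  expect_true(r$separation)
})

test_that("leave-out collapsing: identity and single-variant equivalence", {
  cfg <- null_cfg(n = 1200, n_genes = 2, carrier_freq = 0.05)
  sim <- generate_cohort(cfg, seed = 13)
  ph <- phenotype_spec("status", "binary")
  key <- paste(sim$variants$chrom, sim$variants$pos, sim$variants$ref,
               sim$variants$alt, sep = "-")
  qv <- qv_qualifies(sim$variants, "ptv5pcnt")$qualifies
  g1keys <- key[sim$variants$gene == "NG001" & qv]
  full <- run_collapsing(sim$samples, sim$genotypes, sim$variants, list(ph),
                         models = "ptv5pcnt", sex_match = FALSE)
  base <- full[full$gene == "NG001", ]
  # excluding nothing reproduces the standard result
  r0 <- leave_out_collapsing(sim$samples, sim$genotypes, sim$variants, "NG001",
                             character(0), "ptv5pcnt", ph, sex_match = FALSE)
  expect_equal(r0$p, base$p)
  expect_equal(r0$case_carrier, base$case_carrier)
  # excluding all but one equals the single-variant dominant exact test
  keep <- g1keys[1]
  r1 <- leave_out_collapsing(sim$samples, sim$genotypes, sim$variants, "NG001",
                             setdiff(g1keys, keep), "ptv5pcnt", ph,
                             sex_match = FALSE)
  j <- which(key == keep)
  sv <- variant_binary_tests(sim$genotypes$dosage[, j],
                             sim$samples$status == 1, min_carriers = 1L)
  expect_equal(r1$p, sv$p[sv$genetic_model == "dominant"], tolerance = 1e-12)
  # excluded variants must belong to the QV set
  expect_error(leave_out_collapsing(sim$samples, sim$genotypes, sim$variants,
                                    "NG001", "9-1-A-T", "ptv5pcnt", ph),
               "not in the gene's QV set")
  # exclusion that empties the set is flagged without a test
  r_all <- leave_out_collapsing(sim$samples, sim$genotypes, sim$variants,
                                "NG001", g1keys, "ptv5pcnt", ph)
  expect_true(r_all$empty_qv_set)
  expect_true(is.na(r_all$p))
})

test_that("dominant SNP model approaches the unadjusted OR at large n", {
  set.seed(67)
  n <- 30000
  ds <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, plogis(-1.5 + log(1.4) * (ds > 0)))
  r <- dominant_snp_model(ds, y)
  t <- table(ds > 0, y)
  or_2x2 <- (t[2, 2] * t[1, 1]) / (t[2, 1] * t[1, 2])
  expect_equal(round(r$or, 2), round(or_2x2, 2))
  expect_true(dominant_snp_model(rep(0L, 100), rbinom(100, 1, 0.5))$monomorphic)
})

test_that("stratified effect modification is internally consistent", {
  set.seed(71)
  n <- 20000
  mod <- runif(n) < 0.5
  carrier <- runif(n) < 0.05
  eta <- -1.5 + ifelse(mod, log(1.1), log(0.45)) * carrier
  y <- rbinom(n, 1, plogis(eta))
  covs <- data.frame(age = rnorm(n, 55, 8))
  r <- stratified_effect_modification(carrier, mod, y, covs)
  expect_equal(r$strata$stratum, c("modifier_noncarrier", "modifier_carrier"))
  h <- heterogeneity_test(r$strata$estimate[1], r$strata$se[1],
                          r$strata$estimate[2], r$strata$se[2])
  expect_equal(r$heterogeneity$Q, h$Q)          # internal consistency
  # swapping stratum labels flips the order but not Q
  r2 <- stratified_effect_modification(carrier, !mod, y, covs)
  expect_equal(r2$heterogeneity$Q, r$heterogeneity$Q, tolerance = 1e-10)
  # a stratum with no carriers skips heterogeneity
  r3 <- stratified_effect_modification(carrier & !mod, mod, y, covs)
  expect_null(r3$heterogeneity)
  expect_error(stratified_effect_modification(carrier, rep(TRUE, n), y),
               "non-empty")
})

test_that("identical effects in both strata give a null heterogeneity test", {
  set.seed(73)
  n <- 8000
  mod <- runif(n) < 0.5
  carrier <- runif(n) < 0.1
  y <- rbinom(n, 1, plogis(-1 + log(0.6) * carrier))
  r <- stratified_effect_modification(carrier, mod, y)
  expect_gt(r$heterogeneity$p, 0.001)
})

test_that("LD closed form reproduces the fixed haplotype-count example", {
  h <- cbind(rep(c(1, 1, 0, 0), c(40, 10, 10, 40)),
             rep(c(1, 0, 1, 0), c(40, 10, 10, 40)))
  r <- ld_stats(h)
  expect_equal(r$D, 0.15, tolerance = 1e-12)
  expect_equal(r$Dprime, 0.6, tolerance = 1e-12)
  expect_equal(r$r2, 0.36, tolerance = 1e-12)
  # perfectly co-inherited pair
  h2 <- cbind(rep(c(1, 0), c(30, 70)), rep(c(1, 0), c(30, 70)))
  r2 <- ld_stats(h2)
  expect_equal(r2$Dprime, 1)
  expect_equal(r2$r2, 1)
})

test_that("EM haplotype frequencies converge to the phased closed form", {
  set.seed(79)
  n <- 10000
  # correlated haplotypes: draw pairs with D' ~ 0.8
  hap_freqs <- c(AB = 0.25, Ab = 0.05, aB = 0.1, ab = 0.6)
  draw <- function() sample(names(hap_freqs), 2 * n, TRUE, prob = hap_freqs)
  h1 <- draw()[1:n]; h2 <- draw()[1:n]
  a1 <- (h1 %in% c("AB", "Ab")) + (h2 %in% c("AB", "Ab"))
  b1 <- (h1 %in% c("AB", "aB")) + (h2 %in% c("AB", "aB"))
  phased <- ld_stats(cbind(c(h1 %in% c("AB", "Ab"), h2 %in% c("AB", "Ab")),
                           c(h1 %in% c("AB", "aB"), h2 %in% c("AB", "aB"))))
  em <- ld_stats(cbind(a1, b1), phased = FALSE)
  expect_equal(em$method, "em")
  expect_lt(max(abs(em$hap_freq - phased$hap_freq)), 0.01)
  expect_equal(em$r2, phased$r2, tolerance = 0.02)
  # independent variants: D' and r2 near zero
  g1 <- rbinom(5000, 2, 0.3); g2 <- rbinom(5000, 2, 0.4)
  ind <- ld_stats(cbind(g1, g2), phased = FALSE)
  expect_lt(ind$r2, 0.01)
})
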