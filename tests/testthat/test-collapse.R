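# Carrier coding, Fisher burden test, inverse-normal transform, sex matching,
# quantitative burden, run_collapsing.

test_that("fisher_exact_p matches enumeration and fisher.test", {
  # margins (3,3)/(3,3): only a=0 and a=3 have mass <= that of a=3 (1/20 each)
  expect_equal(fisher_exact_p(3, 0, 0, 3), 0.1, tolerance = 1e-12)
  set.seed(11)
  for (i in 1:60) {
    t <- matrix(rpois(4, 8), 2)
    expect_equal(fisher_exact_p(t[1, 1], t[1, 2], t[2, 1], t[2, 2]),
                 fisher.test(t)$p.value, tolerance = 1e-10)
  }
})

test_that("fisher_burden reports counts, OR, Haldane correction and CI", {
  carrier <- c(rep(TRUE, 3), rep(FALSE, 3))
  is_case <- c(rep(TRUE, 3), rep(FALSE, 3))
  r <- fisher_burden(carrier, is_case)
  expect_equal(r$p, 0.1, tolerance = 1e-12)
  expect_equal(c(r$case_carrier, r$control_carrier,
                 r$case_noncarrier, r$control_noncarrier), c(3, 0, 0, 3))
  # zero cells: Haldane-Anscombe on all four cells
  expect_equal(r$or, (3.5 * 3.5) / (0.5 * 0.5))
  expect_true(r$ci_lo < r$or && r$or < r$ci_hi)
  # symmetric table: OR 1, p 1
  r2 <- fisher_burden(rep(c(TRUE, FALSE), 10), rep(c(TRUE, TRUE, FALSE, FALSE), 5))
  expect_equal(r2$or, 1)
  expect_equal(r2$p, 1)
  # no carriers anywhere: p = 1, OR undefined
  r3 <- fisher_burden(rep(FALSE, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(r3$p, 1)
  expect_false(r3$or_defined)
  expect_error(fisher_burden(carrier, rep(TRUE, 6)), "case and one control")
})

test_that("Table-1-style carrier frequencies imply the printed odds ratio", {
  # 1.25% case vs 1.77% control carriers at large n reproduce OR 0.70
  n_case <- 40000; n_ctrl <- 360000
  a <- round(0.0125 * n_case); b <- round(0.0177 * n_ctrl)
  carrier <- rep(c(TRUE, FALSE, TRUE, FALSE),
                 c(a, n_case - a, b, n_ctrl - b))
  is_case <- rep(c(TRUE, FALSE), c(n_case, n_ctrl))
  r <- fisher_burden(carrier, is_case)
  expect_equal(round(r$or, 2), 0.70)
})

test_that("int_transform produces Blom scores with tie and NA handling", {
  expect_equal(round(int_transform(c(1, 2, 3)), 4), c(-0.8694, 0, 0.8694))
  x <- c(5, 1, NA, 3, 3, 9)
  s <- int_transform(x)
  expect_true(is.na(s[3]))
  expect_equal(s[4], s[5])                      # ties share the average rank
  # rank symmetry: tie-free input has mean and skewness zero
  set.seed(101)
  s2 <- int_transform(rnorm(501))
  expect_equal(mean(s2), 0, tolerance = 1e-6 * 501)
  expect_equal(mean(s2^3), 0, tolerance = 1e-6 * 501)
  set.seed(3)
  y <- rexp(50)
  expect_equal(order(int_transform(y)), order(y))   # rank preservation
  expect_error(int_transform(rep(2, 5)), "constant")
  expect_error(int_transform(c(1, NA)), ">= 2")
})

test_that("sex matching triggers on imbalance and is deterministic", {
  # identical fractions: unchanged
  expect_equal(sex_match_controls(rep(c(TRUE, FALSE), 50), rep(c(TRUE, FALSE), 50)),
               1:100)
  # 40% female cases vs 60% female controls at n=1000: Fisher p < 0.05
  case_f <- rep(c(TRUE, FALSE), c(400, 600))
  ctrl_f <- rep(c(TRUE, FALSE), c(600, 400))
  expect_lt(fisher.test(matrix(c(400, 600, 600, 400), 2))$p.value, 0.05)
  idx <- sex_match_controls(case_f, ctrl_f, seed = 9)
  kept_f <- sum(ctrl_f[idx])
  frac <- kept_f / length(idx)
  expect_lt(abs(frac - 0.4), 1 / length(idx) + 1e-9)   # within one sample
  p_after <- fisher.test(matrix(c(400, kept_f, 600, length(idx) - kept_f), 2))$p.value
  expect_gte(p_after, 0.05)
  expect_identical(idx, sex_match_controls(case_f, ctrl_f, seed = 9))
  expect_warning(sex_match_controls(rep(TRUE, 10), rep(TRUE, 10)), "single-sex")
})

test_that("recessive carrier calls equal a brute-force genotype scan", {
  set.seed(21)
  for (i in 1:25) {
    n <- 40; nv <- 6
    ds <- matrix(sample(c(0L, 0L, 0L, 1L, 2L, NA), n * nv, TRUE), n, nv,
                 dimnames = list(sprintf("S%02d", 1:n), sprintf("v%d", 1:nv)))
    male <- sample(c(TRUE, FALSE), n, TRUE)
    x_linked <- i %% 2 == 0
    pos <- sample(1:4, nv, TRUE)  # deliberate same-position collisions
    if (x_linked) ds[male, ] <- ds[male, ] - (ds[male, ] == 1L)  # males 0/2 on X
    st <- carrier_status(ds, "recessive", male = male, x_linked = x_linked,
                         pos = pos)
    expect_equal(unname(as.logical(st)), brute_recessive(ds, male, x_linked, pos))
    dom <- carrier_status(ds, "dominant")
    expect_equal(unname(dom),
                 unname(apply(ds, 1, function(d) sum(d > 0, na.rm = TRUE) >= 1)))
  }
})

test_that("carrier basis distinguishes hom, hemizygous and compound het", {
  ds <- rbind(S1 = c(1L, 1L, 0L),   # female, two distinct hets -> compound het
              S2 = c(2L, 0L, 0L),   # male on X -> hemizygous
              S3 = c(0L, 1L, 0L),   # single het -> noncarrier
              S4 = c(2L, 0L, 0L))   # female -> homozygous
  colnames(ds) <- paste0("v", 1:3)
  male <- c(FALSE, TRUE, FALSE, FALSE)
  st <- carrier_status(ds, "recessive", male = male, x_linked = TRUE, pos = 1:3)
  expect_equal(unname(as.logical(st)), c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(unname(attr(st, "basis")),
               c("compound_het", "hemizygous", NA, "homozygous"))
  # the single-het female is still a dominant carrier
  expect_true(carrier_status(ds, "dominant")[3])
  # two hets at the same position do not make a compound het
  st2 <- carrier_status(ds[1, , drop = FALSE], "recessive", male = FALSE,
                        x_linked = FALSE, pos = c(1, 1, 2))
  expect_false(as.logical(st2))
})

test_that("quantitative burden obeys Frisch-Waugh and flags degenerate input", {
  set.seed(31)
  n <- 400
  carrier <- runif(n) < 0.1
  covs <- data.frame(age = rnorm(n, 55, 8))
  y <- -0.3 * carrier + 0.02 * covs$age + rnorm(n)
  r1 <- quantitative_burden(carrier, y, covs)
  # adding a covariate orthogonalized against carrier leaves beta unchanged
  z <- rnorm(n)
  z_orth <- residuals(lm(z ~ carrier + age, data = cbind(covs, carrier = carrier)))
  r2 <- quantitative_burden(carrier, y, cbind(covs, z = z_orth))
  expect_equal(r1$beta, r2$beta, tolerance = 1e-8)
  # explicit residual-regression oracle for the adjusted coefficient
  beta_fw <- coef(lm(residuals(lm(y ~ age, covs)) ~
                       residuals(lm(as.numeric(carrier) ~ age, covs))))[2]
  expect_equal(r1$beta, unname(beta_fw), tolerance = 1e-10)
  r0 <- quantitative_burden(rep(FALSE, n), y, covs)
  expect_false(r0$estimable)
  expect_error(quantitative_burden(carrier, y,
                                   cbind(covs, dup = covs$age)), "collinear")
})

test_that("run_collapsing returns a labelled, deterministic result table", {
  cfg <- null_cfg(n = 1500, n_genes = 6)
  sim <- generate_cohort(cfg, seed = 2)
  ph <- list(phenotype_spec("status", "binary"))
  r1 <- suppressWarnings(run_collapsing(sim$samples, sim$genotypes, sim$variants,
                                        ph, models = c("ptv5pcnt", "syn"),
                                        sex_match = FALSE, seed = 3))
  r2 <- suppressWarnings(run_collapsing(sim$samples, sim$genotypes, sim$variants,
                                        ph, models = c("ptv5pcnt", "syn"),
                                        sex_match = FALSE, seed = 3))
  expect_identical(r1, r2)
  expect_true(all(r1$negative_control[r1$model == "syn"]))
  expect_false(any(r1$negative_control[r1$model == "ptv5pcnt"]))
  expect_s3_class(attr(r1, "lambda"), "data.frame")
  expect_true(all(c("model", "phenotype", "lambda") %in%
                    names(attr(r1, "lambda"))))
  expect_equal(attr(r1, "registry"), registry_table())
  # dominant carrier count identity: gene carriers = samples with >= 1 QV allele
  qv <- qv_qualifies(sim$variants, "ptv5pcnt")$qualifies
  g1 <- sim$variants$gene == "NG001" & qv
  n_car <- sum(rowSums(sim$genotypes$dosage[, g1, drop = FALSE] > 0,
                       na.rm = TRUE) >= 1)
  row1 <- r1[r1$gene == "NG001" & r1$model == "ptv5pcnt", ]
  expect_equal(row1$case_carrier + row1$control_carrier, n_car)
})
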