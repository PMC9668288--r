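# Synthetic cohort generator: determinism, carrier-frequency targeting,
# Hardy-Weinberg structure, null behaviour, config validation.

test_that("generation is deterministic given the seed", {
  cfg <- null_cfg(n = 500, n_genes = 3)
  s1 <- generate_cohort(cfg, seed = 4)
  s2 <- generate_cohort(cfg, seed = 4)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$genotypes$dosage, s2$genotypes$dosage)
  s3 <- generate_cohort(cfg, seed = 5)
  expect_false(identical(s1$genotypes$dosage, s3$genotypes$dosage))
})

test_that("X-linked recessive carrier frequency hits the configured target", {
  genes <- data.frame(gene = "GX", chrom = "X", n_variants = 40L,
                      carrier_freq = 0.0177, zygosity = "recessive",
                      n_syn = 0L, max_maf = 0.0035)
  cfg <- sim_config(n = 50000, genes = genes,
                    binary_phenotypes = list(
                      diabetes = list(prevalence = 0.085,
                                      logor = c(GX = log(0.70)))),
                    quantitative_phenotypes = list(), call_metrics = FALSE)
  sim <- generate_cohort(cfg, seed = 90)
  ctrl <- sim$samples$diabetes == 0
  f <- mean(sim$truth$carrier_truth[ctrl, "GX"])
  sd3 <- 3 * sqrt(0.0177 * (1 - 0.0177) / sum(ctrl))
  expect_lt(abs(f - 0.0177), sd3)
  # males carry only 0/2 dosage on X
  male <- sim$samples$sex == "male"
  expect_true(all(sim$genotypes$dosage[male, ] %in% c(0L, 2L)))
})

test_that("autosomal genotypes sit at Hardy-Weinberg proportions", {
  # aggregate a chi-squared goodness-of-fit over seeds; scaled down from the
  # 100-seed aggregate for runtime, same acceptance level (0.001)
  genes <- data.frame(gene = "GA", chrom = "3", n_variants = 1L,
                      carrier_freq = 0.19, zygosity = "dominant", n_syn = 0L)
  cfg <- sim_config(n = 4000, genes = genes,
                    binary_phenotypes = list(y = list(prevalence = 0.1,
                                                      logor = c())),
                    quantitative_phenotypes = list(), call_metrics = FALSE)
  chisq <- 0; df <- 0
  for (s in 1:20) {
    sim <- generate_cohort(cfg, seed = 300 + s)
    d <- sim$genotypes$dosage[, 1]
    q <- mean(d) / 2
    exp_counts <- length(d) * c((1 - q)^2, 2 * q * (1 - q), q^2)
    obs <- tabulate(d + 1L, 3)
    chisq <- chisq + sum((obs - exp_counts)^2 / exp_counts)
    df <- df + 2
  }
  expect_gt(pchisq(chisq, df, lower.tail = FALSE), 0.001)
})

test_that("with zero effects, carrier frequencies differ only by noise", {
  cfg <- null_cfg(n = 6000, n_genes = 40, carrier_freq = 0.03)
  sim <- generate_cohort(cfg, seed = 15)
  y <- sim$samples$status == 1
  fc <- colMeans(sim$truth$carrier_truth[y, ])
  fn <- colMeans(sim$truth$carrier_truth[!y, ])
  # standardized differences approximately standard normal
  se <- sqrt(0.03 * 0.97 * (1 / sum(y) + 1 / sum(!y)))
  z <- (fc - fn) / se
  expect_lt(abs(mean(z)), 0.6)
  expect_lt(max(abs(z)), 5)
})

test_that("config validation and the low-carrier warning fire", {
  expect_error(sim_config(binary_phenotypes = list(
    d = list(prevalence = 0.1, logor = c(NOPE = 1)))), "unknown gene")
  genes <- data.frame(gene = "G1", chrom = "1", n_variants = 2L,
                      carrier_freq = 1e-5, zygosity = "dominant", n_syn = 0L)
  cfg <- sim_config(n = 500, genes = genes,
                    binary_phenotypes = list(y = list(prevalence = 0.1,
                                                      logor = c())),
                    quantitative_phenotypes = list(), call_metrics = FALSE)
  expect_warning(generate_cohort(cfg, seed = 1), "below 1")
})

test_that("binary prevalence matches the configured target", {
  cfg <- null_cfg(n = 20000, n_genes = 2)
  sim <- generate_cohort(cfg, seed = 33)
  expect_lt(abs(mean(sim$samples$status) - 0.1),
            3 * sqrt(0.1 * 0.9 / 20000) + 0.005)
})

test_that("haplotype interaction abolishes the gene effect in carriers", {
  genes <- data.frame(gene = "GR", chrom = "X", n_variants = 20L,
                      carrier_freq = 0.008, zygosity = "recessive",
                      n_syn = 0L, max_maf = 0.004)
  cfg <- sim_config(
    n = 60000, genes = genes,
    binary_phenotypes = list(diabetes = list(
      prevalence = 0.15, logor = c(GR = log(0.45)))),
    quantitative_phenotypes = list(),
    haplotype = list(freq = 0.30, logor = log(1.37),
                     interaction_logor = c(GR = log(1.11 / 0.45))),
    call_metrics = FALSE)
  sim <- generate_cohort(cfg, seed = 77)
  hap <- sim$genotypes$dosage[, ncol(sim$genotypes$dosage)] >= 1
  expect_lt(abs(mean(hap) - (1 - 0.7^2)), 0.01)
  carrier <- sim$truth$carrier_truth[, "GR"]
  y <- sim$samples$diabetes
  covs <- data.frame(age = sim$samples$age,
                     male = as.numeric(sim$samples$sex == "male"))
  r <- stratified_effect_modification(carrier, hap, y, covs)
  # protective in haplotype noncarriers, near-null in carriers
  expect_lt(r$strata$estimate[1], log(0.8))
  expect_gt(r$strata$estimate[2], log(0.7))
  # phased tag haplotypes are retained for LD truth
  expect_equal(dim(sim$hap_phase), c(60000L, 2L))
  expect_equal(as.integer(rowSums(sim$hap_phase)),
               unname(sim$genotypes$dosage[, ncol(sim$genotypes$dosage)]))
})

test_that("compound-het cis simulation removes truth carriers, not genotypes", {
  genes <- data.frame(gene = "GC", chrom = "5", n_variants = 10L,
                      carrier_freq = 0.04, zygosity = "recessive", n_syn = 0L)
  cfg0 <- sim_config(n = 20000, genes = genes,
                     binary_phenotypes = list(y = list(prevalence = 0.1, logor = c())),
                     quantitative_phenotypes = list(), call_metrics = FALSE,
                     comphet_cis_frac = 0)
  cfg1 <- cfg0; cfg1$comphet_cis_frac <- 1
  s0 <- generate_cohort(cfg0, seed = 21)
  s1 <- generate_cohort(cfg1, seed = 21)
  expect_identical(s0$genotypes$dosage, s1$genotypes$dosage)
  expect_lt(sum(s1$truth$carrier_truth), sum(s0$truth$carrier_truth))
  # genotype-based recessive coding is phase-blind: it still calls them
  st <- carrier_status(s1$genotypes$dosage[, 1:10], "recessive",
                       male = s1$samples$sex == "male", x_linked = FALSE,
                       pos = 1:10)
  expect_gt(sum(st), sum(s1$truth$carrier_truth))
})

test_that("truth table records effects, targets and the seed", {
  cfg <- sim_config(n = 200, call_metrics = FALSE)
  sim <- suppressWarnings(generate_cohort(cfg, seed = 19))
  tg <- sim$truth$genes
  expect_equal(tg$logor_diabetes[tg$gene == "GENE_XR"], log(0.70))
  expect_equal(tg$beta_hba1c[tg$gene == "GENE_XR"], -0.14)
  expect_equal(tg$logor_diabetes[tg$gene == "GENE_NULL"], 0)
  expect_equal(sim$truth$seed, 19)
  expect_true(all(c("gene", "ancestry", "target_carrier_freq", "allele_freq")
                  %in% names(sim$truth$allele_freqs)))
})
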