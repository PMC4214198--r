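test_that("cohort configuration validates its inputs and counts individuals", {
  cfg <- cohort_config()
  expect_equal(cfg$n_individuals, 222L)
  expect_error(cohort_config(n_mz_pairs = -1), "non-negative")
  expect_error(cohort_config(mafs = c(0.2, 1.2), n_snps = 2), "mafs")
  expect_error(cohort_config(sex_ratio = 1.5), "sex_ratio")
})

test_that("MZ co-twins carry identical genotypes at every SNP", {
  cfg <- cohort_config(n_mz_pairs = 10, n_dz_pairs = 5, n_os_dz_pairs = 0,
                       n_unpaired_twins = 0, n_singletons = 5, n_snps = 40,
                       seed = 11)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  for (f in unique(co$family_id[co$zygosity == "MZ"])) {
    idx <- which(co$family_id == f)
    expect_identical(sim$genotypes[idx[1], ], sim$genotypes[idx[2], ])
  }
})

test_that("DZ within-pair dosage correlation is 0.5 under Mendelian transmission", {
  cfg <- cohort_config(n_mz_pairs = 0, n_dz_pairs = 10000, n_os_dz_pairs = 0,
                       n_unpaired_twins = 0, n_singletons = 0, n_snps = 1,
                       mafs = 0.3, seed = 21)
  G <- simulate_genotypes(cfg)
  g <- G[, 1]
  odd <- seq(1, length(g), by = 2)
  expect_equal(cor(g[odd], g[odd + 1]), 0.5, tolerance = 0.02 / 0.5)
})

test_that("singleton genotypes reproduce the configured allele frequency", {
  cfg <- cohort_config(n_mz_pairs = 0, n_dz_pairs = 0, n_os_dz_pairs = 0,
                       n_unpaired_twins = 0, n_singletons = 10000, n_snps = 1,
                       mafs = 0.2, seed = 31)
  G <- simulate_genotypes(cfg)
  expect_equal(mean(G[, 1]) / 2, 0.2, tolerance = 0.01 / 0.2)
})

test_that("family-level covariates are shared and ages stay in the study window", {
  cfg <- cohort_config(seed = 41)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  pair_fams <- names(which(table(co$family_id) == 2))
  for (f in pair_fams[1:10]) {
    idx <- which(co$family_id == f)
    expect_equal(co$maternal_age[idx[1]], co$maternal_age[idx[2]])
    expect_identical(co$income[idx[1]], co$income[idx[2]])
    expect_equal(co$age_months[idx[1]], co$age_months[idx[2]])
  }
  expect_true(all(co$age_months >= 2.70 & co$age_months <= 4.80))
  expect_true(all(co$apgar5 == round(co$apgar5) & co$apgar5 >= 0 & co$apgar5 <= 10))
  expect_true(all(co$transferrin > 0))
})

test_that("transferrin is right-skewed as a log-normal covariate should be", {
  cfg <- cohort_config(n_mz_pairs = 0, n_dz_pairs = 0, n_os_dz_pairs = 0,
                       n_unpaired_twins = 0, n_singletons = 10000, n_snps = 0,
                       seed = 51)
  tv <- simulate_covariates(cfg)$transferrin
  skew <- mean((tv - mean(tv))^3) / sd(tv)^3
  expect_gt(skew, 0)
  expect_equal(mean(tv), 0.88, tolerance = 0.05)
})

test_that("phenotype twin correlations follow the ACE variance composition", {
  tot <- 1
  mk <- function(zyg, n_pairs, a2, c2, seed) {
    cfg <- cohort_config(n_mz_pairs = if (zyg == "MZ") n_pairs else 0,
                         n_dz_pairs = if (zyg == "DZ") n_pairs else 0,
                         n_os_dz_pairs = 0, n_unpaired_twins = 0,
                         n_singletons = 0, n_snps = 0, seed = seed)
    ff <- minitwin:::make_family_frame(cfg)
    m <- phenotype_model(mu = 40, sigma2_A = a2 * tot, sigma2_C = c2 * tot,
                         sigma2_E = (1 - a2 - c2) * tot, beta_cov = NULL,
                         beta_cov_male = NULL, detection_limit = 1e-12)
    y <- simulate_phenotype(ff, NULL, m, seed = seed)
    odd <- seq(1, length(y), by = 2)
    cor(y[odd], y[odd + 1])
  }
  ## pure noise: no twin resemblance
  expect_equal(mk("MZ", 20000, 0, 0, 61), 0, tolerance = 0.02)
  ## a2 = 0.3, c2 = 0.4: r_MZ = 0.7, r_DZ = 0.55
  expect_equal(mk("MZ", 10000, 0.3, 0.4, 62), 0.7, tolerance = 0.03 / 0.7)
  expect_equal(mk("DZ", 10000, 0.3, 0.4, 63), 0.55, tolerance = 0.03 / 0.55)
})

test_that("the generator is bit-reproducible under a fixed seed", {
  cfg <- cohort_config(n_mz_pairs = 3, n_dz_pairs = 3, n_os_dz_pairs = 1,
                       n_unpaired_twins = 1, n_singletons = 5, n_snps = 12,
                       seed = 71)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$genotypes, s2$genotypes)
})

test_that("SNP effects and detection-limit coding enter the phenotype", {
  cfg <- cohort_config(n_mz_pairs = 0, n_dz_pairs = 0, n_os_dz_pairs = 0,
                       n_unpaired_twins = 0, n_singletons = 4000, n_snps = 1,
                       mafs = 0.4, seed = 81)
  ff <- minitwin:::make_family_frame(cfg)
  G <- simulate_genotypes(cfg, ff)
  m <- phenotype_model(mu = 40, sigma2_A = 0, sigma2_C = 0, sigma2_E = 1,
                       beta_snp = c(snp0001 = 6), beta_cov = NULL,
                       beta_cov_male = NULL)
  y <- simulate_phenotype(ff, G, m, seed = 81)
  fitb <- coef(lm(y ~ G[, 1]))[2]
  expect_equal(unname(fitb), 6, tolerance = 0.02)
  ## detection limit floors to exactly zero
  m2 <- phenotype_model(mu = 0.5, sigma2_A = 0, sigma2_C = 0, sigma2_E = 1e-6,
                        beta_cov = NULL, beta_cov_male = NULL,
                        detection_limit = 1)
  y2 <- simulate_phenotype(ff, NULL, m2, seed = 82)
  expect_true(all(y2 == 0))
})

test_that("dimension mismatch between cohort and genotypes is rejected", {
  cfg <- cohort_config(n_mz_pairs = 2, n_dz_pairs = 0, n_os_dz_pairs = 0,
                       n_unpaired_twins = 0, n_singletons = 2, n_snps = 3,
                       seed = 91)
  sim <- simulate_cohort(cfg)
  expect_error(
    simulate_phenotype(sim$cohort[-1, ], sim$genotypes, phenotype_model()),
    "mismatch")
})
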