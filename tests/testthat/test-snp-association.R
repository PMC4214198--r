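test_that("a dosage collinear with the null design carries no information", {
  set.seed(1)
  n <- 60
  x <- rnorm(n)
  X0 <- cbind(1, x)
  res <- lrt_snp(rnorm(n), 2 * x, X0, rep(1:30, each = 2))
  expect_equal(res$lr, 0)
  expect_equal(res$pval, 1)
  expect_true(is.na(res$beta_hat))
})

test_that("a noiseless additive signal returns its exact effect size", {
  set.seed(2)
  g <- rbinom(50, 2, 0.4)
  res <- lrt_snp(3 * g, g, matrix(1, 50, 1), 1:50)
  expect_equal(res$beta_hat, 3, tolerance = 1e-8)
  expect_lt(res$pval, 1e-10)
})

test_that("the null LRT follows chi-square(1) and Wald p-values agree", {
  set.seed(3)
  fam <- rep(1:40, each = 2)
  X0 <- matrix(1, 80, 1)
  lrs <- pv_diff <- numeric(400)
  for (r in 1:400) {
    g <- rbinom(80, 2, 0.3)
    y <- rep(rnorm(40, sd = 0.8), each = 2) + rnorm(80)
    res <- lrt_snp(y, g, X0, fam)
    lrs[r] <- res$lr
    full <- fit_mixed_model(y, cbind(X0, g = g), fam)
    pv_diff[r] <- abs(log10(res$pval) - log10(full$pval["g"]))
  }
  ks <- suppressWarnings(stats::ks.test(lrs, function(q) pchisq(q, 1)))
  expect_gt(ks$p.value, 0.01)
  expect_lt(median(pv_diff), 0.25)   # asymptotic agreement at modest n
  expect_true(all(lrs >= 0))
})

test_that("BH adjustment equals the step-up oracle and p.adjust on random inputs", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(c(1, 1)), c(1, 1))
  expect_equal(fdr_adjust(0.2), 0.2)
  set.seed(4)
  for (r in 1:20) {
    m <- sample(1:1000, 1)
    p <- runif(m)^sample(1:3, 1)
    expect_equal(fdr_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(fdr_adjust(c(0.1, NaN)), "NaN")
  expect_error(fdr_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("the association scan is complete, ordered and order-invariant", {
  sim <- simulate_cohort(cohort_config(n_mz_pairs = 5, n_dz_pairs = 5,
                                       n_os_dz_pairs = 0, n_unpaired_twins = 0,
                                       n_singletons = 60, n_snps = 25,
                                       seed = 5))
  co <- sim$cohort
  G <- sim$genotypes
  G[, 3] <- 0L                                    # monomorphic: skipped
  scan <- association_scan(co, G, sex = "M", subset = "full")
  expect_equal(nrow(scan) + length(attr(scan, "skipped")), ncol(G))
  expect_named(attr(scan, "skipped"), "snp0003")
  expect_true(!is.unsorted(scan$pval))
  expect_true(all(scan$pval_bh >= scan$pval - 1e-12))
  ## permuting the SNP panel leaves per-SNP results unchanged
  perm <- sample(ncol(G))
  Gp <- G[, perm]
  scan_p <- association_scan(co, Gp, sex = "M", subset = "full")
  m <- merge(as.data.frame(scan), as.data.frame(scan_p), by = "snp")
  expect_equal(m$pval.x, m$pval.y, tolerance = 1e-10)
})

test_that("the sensitivity subset drops the transferrin covariate and its rows", {
  sim <- simulate_cohort(cohort_config(n_mz_pairs = 8, n_dz_pairs = 8,
                                       n_os_dz_pairs = 0, n_unpaired_twins = 0,
                                       n_singletons = 120, n_snps = 10,
                                       seed = 6))
  co <- sim$cohort
  scan <- association_scan(co, sim$genotypes, sex = "F",
                           subset = "low_transferrin")
  n_expected <- sum(co$sex == "F" & co$transferrin < 0.5)
  expect_true(all(scan$n_used <= n_expected))
})

test_that("a strongly causal SNP is detected at cohort-scale n", {
  cfg <- cohort_config(n_snps = 40, seed = 7)
  ff <- minitwin:::make_family_frame(cfg)
  G <- simulate_genotypes(cfg, ff)
  cov <- simulate_covariates(cfg, ff)
  co <- cbind(ff, cov)
  m <- phenotype_model(beta_snp = c(snp0010 = 8), beta_cov = NULL,
                       beta_cov_male = NULL)
  co$phenotype <- simulate_phenotype(co, G, m, seed = 7)
  scan <- association_scan(co, G, sex = "M", subset = "full")
  expect_equal(scan$snp[1], "snp0010")
  expect_true(scan$significant[1])
})

test_that("effect-size concordance is 1 on self-comparison and ~0 for noise", {
  sim <- simulate_cohort(cohort_config(n_mz_pairs = 5, n_dz_pairs = 5,
                                       n_os_dz_pairs = 0, n_unpaired_twins = 0,
                                       n_singletons = 50, n_snps = 8, seed = 8))
  scan <- association_scan(sim$cohort, sim$genotypes, sex = "M",
                           subset = "full")
  self <- effect_size_concordance(scan, scan)
  expect_equal(self$correlation, 1)
  set.seed(9)
  t1 <- data.frame(snp = paste0("s", 1:500), beta_hat = rnorm(500))
  t2 <- data.frame(snp = paste0("s", 1:500), beta_hat = rnorm(500))
  expect_lt(abs(effect_size_concordance(t1, t2)$correlation), 0.1)
  expect_warning(
    out <- effect_size_concordance(t1[1:2, ], t2[1:2, ]), "fewer than 3")
  expect_true(is.na(out$correlation))
})
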