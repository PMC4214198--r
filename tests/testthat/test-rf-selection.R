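## Planted-signal testbed: one SNP explaining a fixed share of the residual
## variance among pure-noise SNPs.
planted_panel <- function(n = 200, p = 60, share = 0.3, seed = 1) {
  set.seed(seed)
  G <- matrix(rbinom(n * p, 2, 0.3), n, p)
  colnames(G) <- sprintf("s%03d", seq_len(p))
  g <- G[, 7]
  sig_g <- var(g)
  beta <- 1
  noise_var <- sig_g * (1 - share) / share
  y <- beta * g + rnorm(n, sd = sqrt(noise_var))
  list(y = y, G = G, causal = "s007")
}

test_that("one twin per complete pair is retained, deterministically", {
  sim <- simulate_cohort(cohort_config(n_mz_pairs = 27, n_dz_pairs = 0,
                                       n_os_dz_pairs = 0, n_unpaired_twins = 0,
                                       n_singletons = 54, n_snps = 0,
                                       seed = 4))
  one <- select_one_twin_per_pair(sim$cohort, seed = 9)
  expect_equal(nrow(one), 27 + 54)
  expect_false(any(duplicated(one$family_id)))
  one2 <- select_one_twin_per_pair(sim$cohort, seed = 9)
  expect_identical(one$individual_id, one2$individual_id)
})

test_that("residualization is an orthogonal projection, column-wise on matrices", {
  set.seed(5)
  n <- 80
  C <- matrix(rnorm(n * 3), n, 3)
  y <- rnorm(n)
  r <- residualize(y, C)
  expect_lt(max(abs(crossprod(cbind(1, C), r))), 1e-8)
  ## a linear combination of covariates residualizes to ~0
  expect_lt(max(abs(residualize(drop(C %*% c(1, -2, 3)) + 5, C))), 1e-10)
  ## a target orthogonal to the covariates is untouched
  y_orth <- residualize(y, C)
  expect_equal(residualize(y_orth, C), y_orth, tolerance = 1e-10)
  M <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("m", 1:4)))
  R <- residualize(M, C)
  expect_equal(dim(R), dim(M))
  expect_lt(max(abs(crossprod(cbind(1, C), R))), 1e-8)
  expect_error(residualize(y, cbind(C, C[, 1])), "rank")
})

test_that("a planted strong SNP tops the importance ranking reproducibly", {
  pp <- planted_panel(seed = 6)
  cfg <- rf_config(ntree = 500, base_seed = 11)
  top1 <- vapply(1:10, function(r) {
    imp <- rf_importance(pp$y, pp$G, cfg, run_seed = 100 + r)
    names(which.max(imp))
  }, character(1))
  expect_gte(mean(top1 == pp$causal), 0.95)
  i1 <- rf_importance(pp$y, pp$G, cfg, run_seed = 3)
  i2 <- rf_importance(pp$y, pp$G, cfg, run_seed = 3)
  expect_identical(i1, i2)
  expect_error(rf_importance(rep(1, 10), pp$G[1:10, ], cfg), "constant")
})

test_that("pure-noise importance is centred near zero", {
  set.seed(7)
  n <- 150; p <- 40
  G <- matrix(rbinom(n * p, 2, 0.3), n, p,
              dimnames = list(NULL, paste0("s", 1:p)))
  imp <- rf_importance(rnorm(n), G, rf_config(ntree = 500), run_seed = 2)
  expect_lt(abs(mean(imp)), 2 * sd(imp) / sqrt(p))
})

test_that("stability selection intersects per-run top lists correctly", {
  pp <- planted_panel(seed = 8)
  cfg <- rf_config(n_runs = 8, top_k = 10, ntree = 400, base_seed = 21)
  st <- stability_selection(pp$y, pp$G, cfg)
  expect_true(pp$causal %in% st$intersection)
  for (lst in st$top_lists)
    expect_true(all(st$intersection %in% lst))
  expect_true(all(st$counts[st$intersection] == cfg$n_runs))
  expect_true(all(st$counts <= cfg$n_runs))
  ## n_runs = 1: intersection is exactly that run's list
  st1 <- stability_selection(pp$y, pp$G, rf_config(n_runs = 1, top_k = 10,
                                                   ntree = 400,
                                                   base_seed = 21))
  expect_setequal(st1$intersection, st1$top_lists[[1]])
  expect_error(stability_selection(pp$y, pp$G,
                                   rf_config(top_k = 1000)), "top_k")
})

test_that("the planted SNP survives across distinct base seeds", {
  pp <- planted_panel(seed = 9)
  for (bs in c(1, 500, 9000)) {
    st <- stability_selection(pp$y, pp$G,
                              rf_config(n_runs = 5, top_k = 10, ntree = 400,
                                        base_seed = bs))
    expect_true(pp$causal %in% st$intersection)
  }
})

test_that("the mtry comparison reports all four rules with similar errors", {
  pp <- planted_panel(seed = 10)
  cmp <- mtry_error_comparison(pp$y, pp$G, rf_config(ntree = 400,
                                                     base_seed = 31))
  expect_equal(cmp$rule, c("p/3", "2p/3", "0.5p/3", "p"))
  expect_equal(cmp$mtry, c(20, 40, 10, 60))
  expect_true(all(is.finite(cmp$oob_mse)))
  ## "highly similar" error rates on a planted-signal panel
  expect_lt(max(cmp$oob_mse) / min(cmp$oob_mse), 1.2)
})
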