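test_that("penalty limits: lambda 0 keeps everything, lambda Inf only the fixed set", {
  prob <- sim_selection_problem(n_fam = 60, p_noise = 6, seed = 11)
  sel0 <- adaptive_lasso_select(prob$y, prob$X, prob$fam, prob$always_in,
                                lambda_grid = c(0))
  expect_setequal(sel0$selected, colnames(prob$X))
  sel_inf <- adaptive_lasso_select(prob$y, prob$X, prob$fam, prob$always_in,
                                   lambda_grid = c(1e9))
  expect_setequal(sel_inf$selected, prob$always_in)
})

test_that("the coordinate-descent solution matches glmnet at fixed lambda", {
  skip_if_not_installed("glmnet")
  prob <- sim_selection_problem(n_fam = 80, p_noise = 10, seed = 12)
  init <- fgls_initial(prob$y, prob$X, prob$fam)
  wh <- whiten_family(prob$y, prob$X, prob$fam, init$theta)
  unpen <- colnames(prob$X) %in% prob$always_in
  w <- ifelse(unpen, 0, 1 / abs(init$beta))
  for (lam in c(0.05, 0.2, 0.8)) {
    mine <- minitwin:::cd_lasso_path(wh$X, wh$y, w, lam)[, 1]
    gn <- glmnet::glmnet(wh$X, wh$y, alpha = 1, standardize = FALSE,
                         intercept = FALSE, penalty.factor = w,
                         lambda = lam * mean(w), thresh = 1e-12)
    expect_equal(unname(mine), unname(as.vector(gn$beta)), tolerance = 1e-4)
  }
})

test_that("BIC-tuned selection recovers a strong single covariate", {
  hits <- 0L
  n_rep <- 30L
  for (r in seq_len(n_rep)) {
    prob <- sim_selection_problem(n_fam = 110, p_noise = 20, beta_true = 5,
                                  seed = 100 + r)
    sel <- adaptive_lasso_select(prob$y, prob$X, prob$fam, prob$always_in)
    if (setequal(sel$selected, c(prob$always_in, prob$true_cov)))
      hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("support size is monotone along the lambda path on orthogonal designs", {
  set.seed(13)
  n <- 120
  X <- qr.Q(qr(matrix(rnorm(n * 8), n, 8))) * sqrt(n)   # orthogonal columns
  colnames(X) <- paste0("v", 1:8)
  y <- drop(X %*% c(3, 2, 1.5, 1, 0.5, 0, 0, 0)) + rnorm(n)
  sel <- adaptive_lasso_select(y - mean(y), X, seq_len(n), always_in = character(0))
  sizes <- colSums(sel$coef_path != 0)
  expect_true(all(diff(sizes) >= 0))        # grid runs from large to small lambda
})

test_that("zeroed initial coefficients get a capped weight and can still enter", {
  prob <- sim_selection_problem(n_fam = 60, p_noise = 4, seed = 14)
  init <- fgls_initial(prob$y, prob$X, prob$fam)
  ## simulate a degenerate initial estimate by direct call with tiny weights
  w <- rep(1, ncol(prob$X))
  sel <- adaptive_lasso_select(prob$y, prob$X, prob$fam, prob$always_in,
                               weight_cap = 10)
  expect_true(all(sel$weights[!names(sel$weights) %in% prob$always_in] <= 10))
})

test_that("cluster bootstrap counts are deterministic and fix the always-in set", {
  prob <- sim_selection_problem(n_fam = 50, p_noise = 5, seed = 15)
  b1 <- bootstrap_stability(prob$y, prob$X, prob$fam, prob$always_in,
                            B = 20, base_seed = 42)
  b2 <- bootstrap_stability(prob$y, prob$X, prob$fam, prob$always_in,
                            B = 20, base_seed = 42)
  expect_identical(b1$counts, b2$counts)
  expect_true(all(b1$counts[prob$always_in] == b1$B_effective))
  expect_true(all(b1$counts <= b1$B))
})

test_that("pure-noise covariates are selected in well under half the replicates", {
  ## a single dataset can carry a chance association that the bootstrap then
  ## reselects persistently, so the null calibration pools bootstrap counts
  ## over independent datasets (total B = 200)
  pooled <- NULL
  for (d in 1:4) {
    prob <- sim_selection_problem(n_fam = 110, p_noise = 8, beta_true = 0,
                                  seed = 160 + d)
    bt <- bootstrap_stability(prob$y, prob$X, prob$fam, prob$always_in,
                              B = 50, base_seed = 7)
    pooled <- if (is.null(pooled)) bt$counts else pooled + bt$counts
  }
  noise_names <- setdiff(names(pooled), c("fix1", "fix2"))
  expect_true(all(pooled[noise_names] < 100))
})

test_that("post-selection inference applies the full-model Bonferroni threshold", {
  prob <- sim_selection_problem(n_fam = 100, p_noise = 10, beta_true = 5,
                                seed = 17)
  sel <- adaptive_lasso_select(prob$y, prob$X, prob$fam, prob$always_in)
  post <- post_selection_model(prob$y, prob$X[, sel$selected, drop = FALSE],
                               prob$fam, m_total = 29)
  expect_equal(signif(post$threshold, 2), 0.0017)
  expect_true(post$table$significant[post$table$predictor == prob$true_cov])
  expect_true(all(post$table$r2 >= 0))
  expect_gte(post$R2, max(post$table$r2) - 1e-10)
  ## single-predictor threshold equals alpha
  p1 <- post_selection_model(prob$y, prob$X[, prob$true_cov, drop = FALSE],
                             prob$fam, m_total = 1)
  expect_equal(p1$threshold, 0.05)
  expect_error(post_selection_model(prob$y,
                                    prob$X[, character(0), drop = FALSE],
                                    prob$fam, 29), "empty")
})
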