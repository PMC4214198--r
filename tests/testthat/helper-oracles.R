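## Independent oracles used across the suite. Each is a deliberately
## different route to the quantity it checks (recurrence instead of closed
## form, brute force instead of vectorized code, closed-form algebra
## instead of numerical optimization).

## Exact HWE p-value by the heterozygote-count recurrence: probabilities
## are built multiplicatively from the ratio P(h+2)/P(h), not from
## log-factorials.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_rare <- 2 * min(n_AA, n_aa) + n_Aa
  n_common <- 2 * n - n_rare
  hets <- seq(n_rare %% 2, min(n_rare, n_common), by = 2)
  pr <- numeric(length(hets))
  pr[1] <- 1
  for (i in seq_along(hets)[-1]) {
    h <- hets[i - 1]
    ## P(h+2)/P(h) = 4 * hom_rare * hom_common / ((h+2)*(h+1))
    pr[i] <- pr[i - 1] * 4 * ((n_rare - h) / 2) * ((n_common - h) / 2) /
      ((h + 2) * (h + 1))
  }
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

## Benjamini-Hochberg step-up from its definition: adjusted p_(i) =
## min over j >= i of m * p_(j) / j, mapped back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

## Closed-form GLS for balanced families of size 2 with known intraclass
## correlation rho: V_i = sigma2 [[1, rho], [rho, 1]] per family.
balanced_gls_oracle <- function(y, X, fam, rho) {
  n <- length(y)
  V <- matrix(0, n, n)
  for (i in unique(fam)) {
    idx <- which(fam == i)
    V[idx, idx] <- rho
  }
  diag(V) <- 1
  Vi <- solve(V)
  solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
}

## Twin-pair phenotype simulator used as the parameter-recovery testbed:
## bivariate-normal additive deviates with zygosity correlation, shared
## family deviate, independent error.
sim_twin_pairs <- function(n_mz, n_dz, sigma2_A, sigma2_C, sigma2_E,
                           mu = 40, seed = 1) {
  set.seed(seed)
  n_pairs <- n_mz + n_dz
  zyg_pair <- c(rep("MZ", n_mz), rep("DZ", n_dz))
  r <- ifelse(zyg_pair == "MZ", 1, 0.5)
  z1 <- rnorm(n_pairs); z2 <- rnorm(n_pairs)
  a1 <- sqrt(sigma2_A) * z1
  a2 <- sqrt(sigma2_A) * (r * z1 + sqrt(1 - r^2) * z2)
  cd <- sqrt(sigma2_C) * rnorm(n_pairs)
  y1 <- mu + a1 + cd + rnorm(n_pairs, sd = sqrt(sigma2_E))
  y2 <- mu + a2 + cd + rnorm(n_pairs, sd = sqrt(sigma2_E))
  data.frame(
    y = as.vector(rbind(y1, y2)),
    family_id = rep(seq_len(n_pairs), each = 2),
    zygosity = rep(zyg_pair, each = 2))
}

## A small standardized clustered regression problem for selection tests.
sim_selection_problem <- function(n_fam = 110, p_noise = 20, beta_true = 5,
                                  sigma2_fam = 0.4, seed = 1) {
  set.seed(seed)
  n <- 2 * n_fam
  fam <- rep(seq_len(n_fam), each = 2)
  p <- p_noise + 3
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- c("fix1", "fix2", "true1", paste0("noise", seq_len(p_noise)))
  y <- 0.5 * X[, "fix1"] + beta_true * X[, "true1"] +
    rep(rnorm(n_fam, sd = sqrt(sigma2_fam)), each = 2) + rnorm(n)
  std <- standardize_and_center(as.data.frame(X), y)
  list(y = std$y, X = std$X, fam = fam,
       always_in = c("fix1", "fix2"), true_cov = "true1")
}
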