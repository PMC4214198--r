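## Twin-structured Monte-Carlo power surface for the single-SNP
## likelihood-ratio scan over MAF x effect-size grids.

#' Power simulation configuration
#'
#' Defaults mirror the study's power assessment: the real cohort's family
#' composition (27 MZ, 27 + 2 DZ pairs, 2 unpaired twins, 108 singletons),
#' variance components at the male estimates (a2 = 0, c2 = 0.627 of a
#' phenotype SD of 13.4 pg/ml), significance level 0.05/500, and 10,000
#' replicates per scenario in the full setting (`n_reps` defaults to a desk
#' scale of 1,000; the full setting is one argument change).
#'
#' @param maf_grid minor-allele frequencies to simulate.
#' @param beta_grid per-allele effects, pg/ml per allele.
#' @param alpha per-test significance level.
#' @param n_reps Monte-Carlo replicates per grid cell.
#' @param cohort a [cohort_config()] describing the simulated cohort
#'   structure (SNP panel fields are ignored; one SNP is simulated).
#' @param mu,sigma2_A,sigma2_C,sigma2_E phenotype model for the generative
#'   ACE background.
#' @param detection_limit assay floor applied to simulated phenotypes.
#' @param nuisance_covariates logical; include the generator's transferrin
#'   covariate effect and adjust for it in the fitted models (off by
#'   default: the power model is the marginal SNP test).
#' @param base_seed integer; row `i`, replicate `r` uses seed
#'   `base_seed + (i-1) * n_reps + r`, giving common random numbers across
#'   effect sizes within a MAF row.
#' @return list of class `power_config`.
#' @export
power_config <- function(maf_grid = c(0.1, 0.3, 0.5),
                         beta_grid = c(0, 3, 6, 9),
                         alpha = 0.05 / 500, n_reps = 1000L,
                         cohort = cohort_config(n_snps = 1L),
                         mu = 40, sigma2_A = 0, sigma2_C = 112.6,
                         sigma2_E = 67.0, detection_limit = 1.0,
                         nuisance_covariates = FALSE, base_seed = 1L) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (n_reps < 1) stop("n_reps must be >= 1")
  structure(list(maf_grid = maf_grid, beta_grid = beta_grid, alpha = alpha,
                 n_reps = as.integer(n_reps), cohort = cohort, mu = mu,
                 sigma2_A = sigma2_A, sigma2_C = sigma2_C,
                 sigma2_E = sigma2_E, detection_limit = detection_limit,
                 nuisance_covariates = nuisance_covariates,
                 base_seed = as.integer(base_seed)),
            class = "power_config")
}

## One replicate's rejection verdicts for a vector of betas at one MAF.
## Genotypes and ACE noise are simulated once and reused across betas
## (common random numbers), so power is monotone in |beta| by construction.
power_one_rep <- function(maf, betas, config, seed) {
  cc <- config$cohort
  cc$n_snps <- 1L
  cc$mafs <- maf
  cc$seed <- seed
  ff <- make_family_frame(cc, seed = seed)
  G <- simulate_genotypes(cc, ff, seed = seed + 1L)
  g <- G[, 1L]
  set.seed(seed + 2L)
  model <- phenotype_model(mu = config$mu, sigma2_A = config$sigma2_A,
                           sigma2_C = config$sigma2_C,
                           sigma2_E = config$sigma2_E,
                           beta_cov = NULL, beta_cov_male = NULL,
                           detection_limit = config$detection_limit)
  cohort <- ff
  if (config$nuisance_covariates) {
    cohort <- cbind(ff, simulate_covariates(cc, ff, seed = seed + 3L))
    model$beta_cov <- c(log10_transferrin = 17.4)
  }
  base <- simulate_phenotype(cohort, NULL, model, seed = seed + 2L)
  X_null <- if (config$nuisance_covariates)
    cbind(1, log10_transferrin = log10(cohort$transferrin))
  else matrix(1, nrow(ff), 1)
  gc_ <- g - 2 * maf
  vapply(betas, function(b) {
    y <- code_below_detection(pmax(base + b * gc_, 0), config$detection_limit)
    t <- lrt_snp(y, g, X_null, ff$family_id)
    t$pval < config$alpha
  }, logical(1))
}

#' Estimate power at one (MAF, beta) scenario
#'
#' Monte-Carlo rejection fraction of the single-SNP likelihood-ratio test
#' at level `alpha`: each replicate simulates genotypes and an ACE
#' phenotype with per-allele effect `beta` on a cohort with the study's
#' family composition, then tests the SNP.
#'
#' @param maf minor-allele frequency of the simulated SNP.
#' @param beta per-allele effect, pg/ml.
#' @param config a [power_config()].
#' @param row_offset internal seed offset used by [power_grid()].
#' @return list with `power`, `mc_se` and `n_reps`.
#' @export
simulate_power <- function(maf, beta, config = power_config(),
                           row_offset = 0L) {
  rej <- vapply(seq_len(config$n_reps), function(r) {
    power_one_rep(maf, beta, config,
                  seed = config$base_seed + row_offset + 4L * r)
  }, logical(length(beta)))
  rej <- matrix(rej, nrow = length(beta))
  pw <- rowMeans(rej)
  list(power = pw, mc_se = sqrt(pw * (1 - pw) / config$n_reps),
       n_reps = config$n_reps)
}

#' Power surface over the MAF x effect-size grid
#'
#' Evaluates [simulate_power()] on every grid cell. Within a MAF row, all
#' effect sizes share replicate seeds (common random numbers), so estimated
#' power is non-decreasing in the effect size; rows use disjoint seed
#' ranges.
#'
#' @param config a [power_config()].
#' @return data.frame of class `power_grid` with columns `maf`, `beta`,
#'   `power`, `mc_se`, `n_reps`.
#' @export
power_grid <- function(config = power_config()) {
  if (!length(config$maf_grid) || !length(config$beta_grid))
    stop("empty grid")
  rows <- lapply(seq_along(config$maf_grid), function(i) {
    pw <- simulate_power(config$maf_grid[i], config$beta_grid, config,
                         row_offset = (i - 1L) * 4L * config$n_reps)
    data.frame(maf = config$maf_grid[i], beta = config$beta_grid,
               power = pw$power, mc_se = pw$mc_se, n_reps = pw$n_reps)
  })
  structure(do.call(rbind, rows), class = c("power_grid", "data.frame"),
            alpha = config$alpha)
}

#' @export
print.power_grid <- function(x, ...) {
  cat(sprintf("Monte-Carlo power grid (alpha = %.2g, %d reps/cell)\n",
              attr(x, "alpha"), x$n_reps[1]))
  print.data.frame(transform(x, power = round(power, 3),
                             mc_se = signif(mc_se, 2)), row.names = FALSE)
  invisible(x)
}

#' @export
plot.power_grid <- function(x, ...) {
  mafs <- sort(unique(x$maf))
  betas <- sort(unique(x$beta))
  m <- sapply(mafs, function(f) x$power[x$maf == f][order(x$beta[x$maf == f])])
  matplot(betas, m, type = "b", pch = 19, lty = 1,
          xlab = "per-allele effect (pg/ml)", ylab = "power", ylim = c(0, 1),
          ...)
  legend("bottomright", legend = sprintf("MAF %.2f", mafs), col = seq_along(mafs),
         lty = 1, pch = 19, bty = "n")
  invisible(x)
}
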