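## Twin resemblance: per-group intraclass correlations and the ACE variance
## decomposition with non-negativity constraints and one-tailed boundary
## tests.

## Complete same-sex pairs of a cohort, as a two-column index matrix.
complete_pairs <- function(cohort) {
  idx <- split(seq_len(nrow(cohort)), cohort$family_id)
  idx <- idx[vapply(idx, length, integer(1)) == 2L]
  if (!length(idx)) return(matrix(integer(0), 0, 2))
  do.call(rbind, idx)
}

#' Intraclass correlations by zygosity-sex group
#'
#' One-way ANOVA intraclass correlation, ICC(1), of the (optionally
#' covariate-adjusted) phenotype within complete same-sex twin pairs,
#' estimated separately for the MZM, DZM, MZF and DZF groups, with exact-F
#' 95% confidence intervals. Opposite-sex pairs and unpaired twins are
#' excluded; a group with fewer than 2 complete pairs is reported as
#' unavailable (`NA`) rather than as an estimate.
#'
#' @param cohort cohort data.frame with `phenotype`, `family_id`,
#'   `zygosity`, `sex` and covariate columns.
#' @param covariates character vector of covariate columns to adjust the
#'   phenotype for (by OLS residualization over the whole cohort;
#'   `"log10_transferrin"` is understood as log10 of the `transferrin`
#'   column), or `NULL` for raw ICCs.
#' @param conf_level confidence level of the exact-F interval.
#' @return data.frame of class `icc_result` with columns `group`,
#'   `n_pairs`, `icc`, `ci_low`, `ci_high`.
#' @export
icc_by_group <- function(cohort, covariates = NULL, conf_level = 0.95) {
  y <- cohort$phenotype
  if (!is.null(covariates) && length(covariates)) {
    Xc <- covariate_block(cohort, covariates)
    y <- lm.fit(cbind(1, Xc), y)$residuals
  }
  groups <- list(MZM = c("MZ", "M"), DZM = c("DZ", "M"),
                 MZF = c("MZ", "F"), DZF = c("DZ", "F"))
  alpha <- 1 - conf_level
  rows <- lapply(names(groups), function(g) {
    zyg <- groups[[g]][1]; sx <- groups[[g]][2]
    sub <- cohort$zygosity == zyg & cohort$sex == sx
    sub_cohort <- cohort[sub, , drop = FALSE]
    pr <- complete_pairs(sub_cohort)
    ## same-sex requirement is implied by the stratum, but guard anyway
    if (nrow(pr) < 2L)
      return(data.frame(group = g, n_pairs = nrow(pr), icc = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_))
    ysub <- y[sub]
    y1 <- ysub[pr[, 1]]; y2 <- ysub[pr[, 2]]
    k <- 2; np <- nrow(pr)
    gm <- mean(c(y1, y2))
    pm <- (y1 + y2) / 2
    msb <- k * sum((pm - gm)^2) / (np - 1)
    msw <- sum((y1 - pm)^2 + (y2 - pm)^2) / np
    icc <- (msb - msw) / (msb + (k - 1) * msw)
    f_obs <- msb / msw
    fl <- f_obs / qf(1 - alpha / 2, np - 1, np)
    fu <- f_obs * qf(1 - alpha / 2, np, np - 1)
    data.frame(group = g, n_pairs = np, icc = icc,
               ci_low = (fl - 1) / (fl + 1), ci_high = (fu - 1) / (fu + 1))
  })
  structure(do.call(rbind, rows), class = c("icc_result", "data.frame"))
}

#' @export
print.icc_result <- function(x, ...) {
  cat("Intraclass correlations by zygosity-sex group (ICC(1), exact-F CI)\n")
  print.data.frame(transform(x, icc = round(icc, 3),
                             ci_low = round(ci_low, 3),
                             ci_high = round(ci_high, 3)), row.names = FALSE)
  invisible(x)
}

#' @export
plot.icc_result <- function(x, ...) {
  bp <- barplot(x$icc, names.arg = x$group, ylim = c(-0.2, 1),
                ylab = "intraclass correlation", ...)
  ok <- !is.na(x$icc)
  if (any(ok))
    arrows(bp[ok], x$ci_low[ok], bp[ok], x$ci_high[ok], angle = 90,
           code = 3, length = 0.06)
  abline(h = 0, lty = 3)
  invisible(x)
}

## Named covariate columns as a numeric matrix; "log10_transferrin" maps to
## log10 of the transferrin column.
covariate_block <- function(cohort, covariates) {
  cols <- lapply(covariates, function(nm) {
    if (nm == "log10_transferrin") log10_transferrin(cohort$transferrin)
    else {
      v <- cohort[[nm]]
      if (is.null(v)) stop("unknown covariate: ", nm)
      if (is.factor(v) || is.character(v)) as.numeric(factor(v)) else as.numeric(v)
    }
  })
  m <- do.call(cbind, cols)
  colnames(m) <- covariates
  m
}

## ACE likelihood machinery. Pairs share cov = k*sA + sC (k = 1 MZ, 0.5 DZ);
## every individual has variance sA + sC + sE. Beta is profiled by GLS, and
## because the 2x2 covariance is constant within a zygosity group the
## likelihood reduces to group-level sufficient statistics, making each
## evaluation O(p^2).
ace_suffstats <- function(y, X, pairs_mz, pairs_dz, singles) {
  grp <- function(pr) {
    i <- pr[, 1]; j <- pr[, 2]
    X1 <- X[i, , drop = FALSE]; X2 <- X[j, , drop = FALSE]
    y1 <- y[i]; y2 <- y[j]
    list(m = nrow(pr),
         Sxx = crossprod(X1) + crossprod(X2),
         Sxx12 = crossprod(X1, X2) + crossprod(X2, X1),
         Sxy = crossprod(X1, y1) + crossprod(X2, y2),
         Sxy12 = crossprod(X1, y2) + crossprod(X2, y1),
         Syy = sum(y1^2) + sum(y2^2), Syy12 = 2 * sum(y1 * y2))
  }
  Xs <- X[singles, , drop = FALSE]; ys <- y[singles]
  list(mz = grp(pairs_mz), dz = grp(pairs_dz),
       s = list(m = length(singles), Sxx = crossprod(Xs),
                Sxy = crossprod(Xs, ys), Syy = sum(ys^2)),
       n = length(y), p = ncol(X))
}

ace_loglik <- function(par, ss) {
  sA <- par[1]; sC <- par[2]; sE <- par[3]
  v <- sA + sC + sE
  if (v <= 0) return(-1e10)
  covs <- c(mz = sA + sC, dz = 0.5 * sA + sC)
  dets <- v^2 - covs^2
  if (any(dets <= 0)) return(-1e10)
  a <- v / dets; b <- -covs / dets          # 2x2 inverse entries
  M <- a[["mz"]] * ss$mz$Sxx + b[["mz"]] * ss$mz$Sxx12 +
    a[["dz"]] * ss$dz$Sxx + b[["dz"]] * ss$dz$Sxx12 + ss$s$Sxx / v
  mv <- a[["mz"]] * ss$mz$Sxy + b[["mz"]] * ss$mz$Sxy12 +
    a[["dz"]] * ss$dz$Sxy + b[["dz"]] * ss$dz$Sxy12 + ss$s$Sxy / v
  yy <- a[["mz"]] * ss$mz$Syy + b[["mz"]] * ss$mz$Syy12 +
    a[["dz"]] * ss$dz$Syy + b[["dz"]] * ss$dz$Syy12 + ss$s$Syy / v
  beta <- tryCatch(solve(M, mv), error = function(e) NULL)
  if (is.null(beta)) return(-1e10)
  quad <- yy - sum(beta * mv)
  logdet <- ss$mz$m * log(dets[["mz"]]) + ss$dz$m * log(dets[["dz"]]) +
    ss$s$m * log(v)
  ll <- -0.5 * (ss$n * log(2 * pi) + logdet + quad)
  attr(ll, "beta") <- drop(beta)
  ll
}

ace_optimize <- function(ss, var_y, fix_A = FALSE, fix_C = FALSE) {
  starts <- list(c(1, 1, 1) / 3, c(0.1, 0.1, 0.8), c(0.1, 0.6, 0.3))
  best <- NULL
  for (s0 in starts) {
    par0 <- s0 * var_y
    if (fix_A) par0[1] <- 0
    if (fix_C) par0[2] <- 0
    free <- c(!fix_A, !fix_C, TRUE)
    fn <- function(pfree) {
      par <- numeric(3)
      par[free] <- pfree
      -as.numeric(ace_loglik(par, ss))
    }
    opt <- optim(par0[free], fn, method = "L-BFGS-B",
                 lower = rep(0, sum(free)) + c(rep(0, sum(free) - 1), 1e-8),
                 control = list(maxit = 500))
    par <- numeric(3); par[free] <- opt$par
    ll <- -opt$value
    if (is.null(best) || ll > best$ll + 1e-9 ||
        (abs(ll - best$ll) <= 1e-9 && par[1] < best$par[1]))
      best <- list(par = par, ll = ll, conv = opt$convergence)
  }
  best
}

#' ACE variance decomposition from twin pairs
#'
#' Maximizes the Gaussian likelihood of the twin model in which each pair's
#' phenotype covariance is `k * sigma2_A + sigma2_C` (k = 1 for MZ, 0.5 for
#' DZ) and every individual's variance is `sigma2_A + sigma2_C + sigma2_E`,
#' under the constraint that all three components are non-negative.
#' Covariates enter as fixed effects (profiled by GLS); singletons and
#' unpaired twins contribute to the fixed effects and total variance as
#' families of size one. One-tailed p-values for `sigma2_A > 0` and
#' `sigma2_C > 0` come from likelihood-ratio tests against the boundary
#' null with the 50:50 chi-square mixture reference
#' (`0.5 chi2_0 + 0.5 chi2_1`); a one-sided Wald z p-value is also reported
#' for comparability.
#'
#' @param phenotype numeric phenotype vector.
#' @param covariates numeric matrix of fixed-effect covariates (an intercept
#'   is added internally), or `NULL`.
#' @param family_ids family identifiers.
#' @param zygosity per-individual `"MZ"` / `"DZ"` / `"singleton"` codes.
#' @return object of class `ace_fit`: `sigma2` (named A/C/E vector),
#'   `proportions` (a2/c2/e2), `p_A`, `p_C` (boundary LRT), `p_A_wald`,
#'   `p_C_wald`, `loglik`, `beta`, `boundary`, `n_pairs_mz`, `n_pairs_dz`,
#'   `n_singletons`.
#' @export
fit_ace <- function(phenotype, covariates = NULL, family_ids, zygosity) {
  y <- phenotype
  n <- length(y)
  X <- if (is.null(covariates)) matrix(1, n, 1) else cbind(1, as.matrix(covariates))
  colnames(X)[1] <- "(Intercept)"
  fam <- factor(family_ids, levels = unique(family_ids))
  idx <- split(seq_len(n), fam)
  sizes <- vapply(idx, length, integer(1))
  if (any(sizes > 2)) stop("families larger than 2 are not supported")
  pair_list <- idx[sizes == 2L]
  zyg_of <- vapply(pair_list, function(i) zygosity[i[1]], character(1))
  pairs_mz <- do.call(rbind, c(pair_list[zyg_of == "MZ"], list(matrix(integer(0), 0, 2))))
  pairs_dz <- do.call(rbind, c(pair_list[zyg_of == "DZ"], list(matrix(integer(0), 0, 2))))
  singles <- unlist(idx[sizes == 1L], use.names = FALSE)
  if (nrow(pairs_mz) < 2L || nrow(pairs_dz) < 2L)
    stop("both MZ and DZ pairs are required to identify A and C")

  ss <- ace_suffstats(y, X, pairs_mz, pairs_dz, singles)
  vy <- var(lm.fit(X, y)$residuals)
  full <- ace_optimize(ss, vy)
  no_a <- ace_optimize(ss, vy, fix_A = TRUE)
  no_c <- ace_optimize(ss, vy, fix_C = TRUE)

  mix_p <- function(lr) if (lr <= 1e-8) 1 else 0.5 * pchisq(lr, 1, lower.tail = FALSE)
  lr_A <- max(0, 2 * (full$ll - no_a$ll))
  lr_C <- max(0, 2 * (full$ll - no_c$ll))

  ## one-sided Wald from the numeric Hessian at the optimum (NA on boundary)
  wald_p <- function(comp) {
    if (full$par[comp] <= 1e-8) return(NA_real_)
    H <- tryCatch(optimHess(full$par, function(p) -as.numeric(ace_loglik(p, ss))),
                  error = function(e) NULL)
    if (is.null(H)) return(NA_real_)
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(V) || V[comp, comp] <= 0) return(NA_real_)
    pnorm(full$par[comp] / sqrt(V[comp, comp]), lower.tail = FALSE)
  }

  sig <- setNames(full$par, c("A", "C", "E"))
  tot <- sum(sig)
  ll_full <- as.numeric(ace_loglik(full$par, ss))
  structure(list(
    sigma2 = sig, proportions = sig / tot,
    p_A = mix_p(lr_A), p_C = mix_p(lr_C),
    lr_A = lr_A, lr_C = lr_C,
    p_A_wald = wald_p(1), p_C_wald = wald_p(2),
    loglik = full$ll, beta = attr(ace_loglik(full$par, ss), "beta"),
    boundary = sig <= 1e-8, convergence = full$conv,
    n_pairs_mz = nrow(pairs_mz), n_pairs_dz = nrow(pairs_dz),
    n_singletons = length(singles), n = n
  ), class = "ace_fit")
}

#' @export
print.ace_fit <- function(x, ...) {
  cat("ACE variance decomposition (constrained ML)\n")
  cat(sprintf("  %d MZ pairs, %d DZ pairs, %d size-1 families; logLik %.3f\n",
              x$n_pairs_mz, x$n_pairs_dz, x$n_singletons, x$loglik))
  tab <- data.frame(component = c("A", "C", "E"),
                    variance = round(unname(x$sigma2), 3),
                    `explained (%)` = round(100 * unname(x$proportions), 1),
                    `one-tailed p` = c(signif(x$p_A, 3), signif(x$p_C, 3), NA),
                    check.names = FALSE)
  print(tab, row.names = FALSE)
  if (any(x$boundary))
    cat("  note: component(s) at the zero boundary:",
        paste(names(x$sigma2)[x$boundary], collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.ace_fit <- function(object, ...) object$beta

#' @export
logLik.ace_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$beta) + 3L, nobs = object$n,
            class = "logLik")
}

#' @export
summary.ace_fit <- function(object, ...) object
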