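## Family random-intercept linear mixed model, fit by maximum likelihood via
## a profiled 1-D search over the variance ratio theta = sigma2_family /
## sigma2_resid. The same block structure supplies the FGLS initial
## estimator and the whitening transform used by the adaptive Lasso.

## Sufficient statistics reused across likelihood evaluations.
fam_stats <- function(y, X, family_ids) {
  fam <- factor(family_ids, levels = unique(family_ids))
  fi <- as.integer(fam)
  sizes <- tabulate(fi)
  list(fi = fi, sizes = sizes, n = length(y), p = ncol(X),
       XtX = crossprod(X), Xty = crossprod(X, y), yty = sum(y^2),
       S = rowsum(X, fi), sy = rowsum(y, fi))
}

## Profile log-likelihood pieces at a given theta >= 0. Returns the GLS
## beta, profiled sigma2_resid and the ML log-likelihood.
profile_theta <- function(st, theta) {
  w <- theta / (1 + theta * st$sizes)
  A <- st$XtX - crossprod(st$S, w * st$S)
  b <- st$Xty - crossprod(st$S, w * st$sy)
  beta <- solve(A, b)
  rs <- st$sy - st$S %*% beta
  quad <- st$yty - 2 * sum(beta * st$Xty) +
    sum(beta * (st$XtX %*% beta)) - sum(w * rs^2)
  quad <- max(quad, 1e-300)
  s2e <- quad / st$n
  ll <- -0.5 * (st$n * log(2 * pi) + st$n * log(s2e) +
                  sum(log1p(theta * st$sizes)) + st$n)
  list(beta = drop(beta), s2e = s2e, ll = ll, A = A, w = w)
}

#' Fit a family random-intercept linear mixed model (ML)
#'
#' Fits `y = X beta + u_family + e` with `u ~ N(0, sigma2_family)` and
#' `e ~ N(0, sigma2_resid)` by maximum likelihood, profiling out `beta` and
#' the residual variance and maximizing a one-dimensional likelihood in the
#' variance ratio. Twins enter as repeated measures of their family;
#' singleton families are plain independent observations (with all families
#' of size one the fit coincides with ordinary least squares).
#'
#' @param y numeric response.
#' @param X design matrix (include an intercept column if wanted); must be
#'   full column rank.
#' @param family_ids family identifier per observation.
#' @return an object of class `famlmm` with components `coefficients`,
#'   `se`, `zval`, `pval` (Wald, normal reference), `sigma2_family`,
#'   `sigma2_resid`, `theta`, `loglik`, `vcov`, `fitted`, `residuals`.
#' @examples
#' set.seed(1)
#' fam <- rep(1:30, each = 2)
#' x <- rnorm(60)
#' y <- 1 + 2 * x + rnorm(30)[fam] + rnorm(60)
#' fit <- fit_mixed_model(y, cbind(1, x), fam)
#' coef(fit)
#' @export
fit_mixed_model <- function(y, X, family_ids) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)) - 1L)
  if (length(y) != nrow(X) || length(family_ids) != nrow(X))
    stop("y, X and family_ids must have matching lengths")
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    drop_cols <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  st <- fam_stats(y, X, family_ids)
  obj <- function(lt) -profile_theta(st, exp(lt))$ll
  opt <- optimize(obj, c(-15, 15), tol = 1e-9)
  theta_hat <- exp(opt$minimum)
  ## prefer the boundary when clustering adds (numerically) nothing
  theta <- if (profile_theta(st, 0)$ll >= profile_theta(st, theta_hat)$ll - 1e-7)
    0 else theta_hat
  pr <- profile_theta(st, theta)
  vc <- pr$s2e * solve(pr$A)
  se <- sqrt(diag(vc))
  beta <- pr$beta
  names(beta) <- colnames(X)
  zval <- beta / se
  fitted <- drop(X %*% beta)
  structure(list(
    coefficients = beta, se = setNames(se, colnames(X)),
    zval = zval, pval = 2 * pnorm(-abs(zval)),
    sigma2_family = theta * pr$s2e, sigma2_resid = pr$s2e, theta = theta,
    loglik = pr$ll, vcov = vc, n = st$n,
    n_families = length(unique(family_ids)),
    fitted = fitted, residuals = y - fitted,
    family_ids = family_ids
  ), class = "famlmm")
}

#' @export
print.famlmm <- function(x, ...) {
  cat("Family random-intercept mixed model (ML)\n")
  cat(sprintf("  n = %d in %d families; sigma2_family = %.4g, sigma2_resid = %.4g\n",
              x$n, x$n_families, x$sigma2_family, x$sigma2_resid))
  cat(sprintf("  log-likelihood = %.4f\n", x$loglik))
  print(round(cbind(Estimate = x$coefficients, `Std.Err` = x$se,
                    z = x$zval, `p` = x$pval), 4))
  invisible(x)
}

#' @export
summary.famlmm <- function(object, ...) {
  object
}

#' @export
coef.famlmm <- function(object, ...) object$coefficients

#' @export
logLik.famlmm <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 2L,
            nobs = object$n, class = "logLik")
}

#' @export
vcov.famlmm <- function(object, ...) object$vcov

#' @export
residuals.famlmm <- function(object, ...) object$residuals

#' @export
fitted.famlmm <- function(object, ...) object$fitted

#' @export
predict.famlmm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  drop(as.matrix(newdata) %*% object$coefficients)
}

#' Feasible GLS initial estimator
#'
#' Two-stage moment-based estimator for the family-clustered linear model:
#' ordinary least squares, then method-of-moments estimates of the family
#' and residual variances from the OLS residuals (within-family residual
#' cross-products), then one GLS step under the implied block covariance.
#' A negative moment estimate of the family variance is truncated at 0 and
#' flagged. The result seeds the adaptive-Lasso penalty weights.
#'
#' @inheritParams fit_mixed_model
#' @return list with `beta`, `sigma2_family`, `sigma2_resid`, `theta` and
#'   logical `truncated`.
#' @export
fgls_initial <- function(y, X, family_ids) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  ols <- lm.fit(X, y)
  r <- ols$residuals
  fam <- factor(family_ids, levels = unique(family_ids))
  fi <- as.integer(fam)
  sizes <- tabulate(fi)
  rs <- rowsum(r, fi)
  r2s <- rowsum(r^2, fi)
  npairs2 <- sizes * (sizes - 1)            # ordered within-family pairs
  cross <- sum(rs^2 - r2s)                  # sum over j != k of r_j r_k
  s2f_raw <- if (sum(npairs2) > 0) cross / sum(npairs2) else 0
  truncated <- s2f_raw < 0
  s2f <- max(s2f_raw, 0)
  s2tot <- sum(r^2) / (length(y) - ncol(X))
  s2e <- max(s2tot - s2f, 1e-10)
  theta <- s2f / s2e
  st <- fam_stats(y, X, family_ids)
  pr <- profile_theta(st, theta)
  beta <- pr$beta
  names(beta) <- colnames(X)
  list(beta = beta, sigma2_family = s2f, sigma2_resid = s2e, theta = theta,
       truncated = truncated)
}

#' Whiten observations by the inverse square root of the family block
#' covariance
#'
#' Applies `(I + theta * J)^(-1/2)` family-block-wise (J the all-ones
#' matrix), so that whitened observations are homoscedastic and uncorrelated
#' under the estimated family covariance. The overall residual-variance
#' scale is left untouched (it does not affect penalized selection or BIC
#' ranking).
#'
#' @param y response vector.
#' @param X design matrix.
#' @param family_ids family identifiers.
#' @param theta ratio `sigma2_family / sigma2_resid` (>= 0).
#' @return list with whitened `y` and `X`.
#' @export
whiten_family <- function(y, X, family_ids, theta) {
  X <- as.matrix(X)
  fam <- factor(family_ids, levels = unique(family_ids))
  fi <- as.integer(fam)
  sizes <- tabulate(fi)
  d <- (1 / sqrt(1 + theta * sizes) - 1) / sizes   # per-family J coefficient
  Sy <- rowsum(y, fi)
  SX <- rowsum(X, fi)
  yw <- y + d[fi] * Sy[fi]
  Xw <- X + d[fi] * SX[fi, , drop = FALSE]
  list(y = yw, X = Xw)
}
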