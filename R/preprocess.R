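## Deterministic phenotype/covariate transformations applied before every
## analysis stage: detection-limit coding, log10 transferrin, saliva-to-serum
## conversion, design standardization, sensitivity subsetting, sex strata.

#' Code assay values below the detection limit as 0
#'
#' Salivary testosterone concentrations that the assay cannot distinguish
#' from zero (strictly below `limit`) are coded as 0 pg/ml; all other values
#' are unchanged.
#'
#' @param values numeric vector of concentrations, pg/ml; must be >= 0.
#' @param limit detection limit, pg/ml (> 0).
#' @return vector of the same length with sub-limit values set to 0.
#' @examples
#' code_below_detection(c(0.5, 12), limit = 1)
#' @export
code_below_detection <- function(values, limit = 1.0) {
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("values must be finite numeric")
  if (any(values < 0)) stop("negative concentrations are not valid")
  if (!is.finite(limit) || limit <= 0) stop("limit must be > 0")
  values[values < limit] <- 0
  values
}

#' Base-10 logarithm of salivary transferrin
#'
#' Transferrin is strongly right-skewed; analyses adjust for its base-10
#' logarithm rather than the raw concentration.
#'
#' @param values transferrin concentrations, mg/dl, strictly positive.
#' @return log10-transformed vector.
#' @export
log10_transferrin <- function(values) {
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("values must be finite numeric")
  if (any(values <= 0))
    stop("transferrin must be strictly positive to take log10; found value <= 0")
  log10(values)
}

#' Convert salivary testosterone to an estimated serum level
#'
#' Applies the sex-specific Salimetrics adult calibration lines mapping
#' salivary testosterone (pg/ml) to total serum testosterone (ng/ml):
#' males `0.2421 + 0.0496 x`, females `0.1415 + 0.0055 x`.
#'
#' @param x salivary testosterone, pg/ml (>= 0); recycled against `sex`.
#' @param sex character vector of `"M"`/`"F"` codes.
#' @param coeffs list with elements `M` and `F`, each `c(intercept, slope)`.
#' @return estimated total serum testosterone, ng/ml.
#' @examples
#' saliva_to_serum(40.39, "M")  # ~2.25 ng/ml
#' saliva_to_serum(39.70, "F")  # ~0.36 ng/ml
#' @export
saliva_to_serum <- function(x, sex,
                            coeffs = list(M = c(0.2421, 0.0496),
                                          F = c(0.1415, 0.0055))) {
  if (any(!is.finite(x)) || any(x < 0)) stop("x must be finite and >= 0")
  sex <- as.character(sex)
  if (!all(sex %in% names(coeffs)))
    stop("unknown sex code: ", paste(setdiff(sex, names(coeffs)), collapse = ", "))
  k <- rep_len(sex, max(length(x), length(sex)))
  x <- rep_len(x, length(k))
  ic <- vapply(coeffs, `[`, numeric(1), 1L)
  sl <- vapply(coeffs, `[`, numeric(1), 2L)
  unname(ic[k] + sl[k] * x)
}

#' Standardize a covariate design and centre the response
#'
#' Expands categorical covariates to reference-coded indicator columns (the
#' first factor level is the reference; an explicit `"Missing"` level stays a
#' level, never a dropped row), then scales every column to mean 0 / SD 1 and
#' centres the response. The transformation parameters are returned so the
#' mapping can be inverted exactly.
#'
#' @param X data.frame (or numeric matrix) of covariates.
#' @param y numeric response (salivary testosterone), pg/ml.
#' @return list of class `std_design` with elements `X` (standardized
#'   matrix), `y` (centred response), `centers`, `scales`, `y_center` and
#'   `n_predictors`.
#' @export
standardize_and_center <- function(X, y) {
  if (length(y) != nrow(as.data.frame(X))) stop("X and y sizes differ")
  if (is.data.frame(X)) {
    Xm <- model.matrix(~ ., data = X)[, -1L, drop = FALSE]
  } else {
    Xm <- as.matrix(X)
    if (is.null(colnames(Xm))) colnames(Xm) <- paste0("x", seq_len(ncol(Xm)))
  }
  scales <- apply(Xm, 2, sd)
  if (any(scales == 0))
    stop("zero-variance covariate column(s): ",
         paste(colnames(Xm)[scales == 0], collapse = ", "))
  centers <- colMeans(Xm)
  Xs <- sweep(sweep(Xm, 2, centers), 2, scales, "/")
  structure(list(X = Xs, y = y - mean(y), centers = centers, scales = scales,
                 y_center = mean(y), n_predictors = ncol(Xs)),
            class = "std_design")
}

#' Invert a standardized design
#'
#' @param design a `std_design` from [standardize_and_center()].
#' @return list with the original-scale design matrix `X` and response `y`.
#' @export
unstandardize <- function(design) {
  stopifnot(inherits(design, "std_design"))
  X <- sweep(sweep(design$X, 2, design$scales, "*"), 2, design$centers, "+")
  list(X = X, y = design$y + design$y_center)
}

#' @export
print.std_design <- function(x, ...) {
  cat(sprintf("Standardized design: %d observations x %d predictors\n",
              nrow(x$X), x$n_predictors))
  invisible(x)
}

#' Sensitivity subset: infants with low salivary transferrin
#'
#' Retains infants whose transferrin is strictly below `cutoff` mg/dl (the
#' blood-contamination sensitivity subset) and refreshes family-structure
#' metadata: a pair whose co-twin is excluded is flagged as incomplete.
#'
#' @param cohort cohort data.frame with `transferrin`, `family_id` and
#'   `complete_pair` columns.
#' @param cutoff transferrin cutoff, mg/dl (default 0.50).
#' @return the filtered cohort data.frame.
#' @export
subset_low_transferrin <- function(cohort, cutoff = 0.50) {
  if (!is.finite(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  keep <- cohort$transferrin < cutoff
  out <- cohort[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("no infants below the transferrin cutoff")
  if ("complete_pair" %in% names(out)) {
    sizes <- table(out$family_id)
    out$complete_pair <- out$complete_pair &
      as.vector(sizes[out$family_id]) == 2L
  }
  rownames(out) <- NULL
  out
}

#' Split a cohort into male and female strata
#'
#' All analyses are run separately by sex. Members of opposite-sex DZ pairs
#' fall into their own sex stratum (where they are effectively unpaired).
#' Rows with missing sex are dropped with a warning.
#'
#' @param cohort cohort data.frame with a `sex` column of `"M"`/`"F"`.
#' @return named list with elements `M` and `F`.
#' @export
stratify_by_sex <- function(cohort) {
  bad <- is.na(cohort$sex) | !(cohort$sex %in% c("M", "F"))
  if (any(bad)) {
    warning(sum(bad), " row(s) with missing/unknown sex dropped: ",
            paste(head(cohort$individual_id[bad]), collapse = ", "))
    cohort <- cohort[!bad, , drop = FALSE]
  }
  list(M = cohort[cohort$sex == "M", , drop = FALSE],
       F = cohort[cohort$sex == "F", , drop = FALSE])
}
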