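## Residualized random-forest variable-importance stability selection:
## repeated seeded forests, per-run top-k importance lists, and their
## intersection. Forests cannot treat twins as repeated measures, so one
## twin per pair is dropped first.

#' Keep one randomly chosen twin per complete pair
#'
#' Random forests assume independent rows, so exactly one member of every
#' complete twin pair is retained (seeded uniform choice); singletons and
#' unpaired twins are kept as they stand.
#'
#' @param cohort cohort data.frame with `family_id`.
#' @param seed seed for the per-pair choice.
#' @return the reduced cohort; retained row indices of the input in
#'   `attr(, "kept_rows")`.
#' @export
select_one_twin_per_pair <- function(cohort, seed = 1L) {
  set.seed(seed)
  idx <- split(seq_len(nrow(cohort)),
               factor(cohort$family_id, levels = unique(cohort$family_id)))
  kept <- sort(unlist(lapply(idx, function(i)
    if (length(i) == 1L) i else sample(i, 1L)), use.names = FALSE))
  out <- cohort[kept, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "kept_rows") <- kept
  out
}

#' OLS residualization of a response or dosage matrix
#'
#' Removes covariate effects before the forest: ordinary-least-squares
#' residuals of the target on the covariates (plus intercept), column-wise
#' when the target is a matrix of SNP dosages. The residuals are orthogonal
#' to every covariate column.
#'
#' @param target numeric vector, or matrix with variables in columns.
#' @param covariates numeric covariate matrix; must be full column rank.
#' @return residuals with the shape of `target`.
#' @export
residualize <- function(target, covariates) {
  X <- cbind(1, as.matrix(covariates))
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is rank deficient")
  qrX <- qr(X)
  if (is.matrix(target)) {
    out <- qr.resid(qrX, target)
    dimnames(out) <- dimnames(target)
    out
  } else drop(qr.resid(qrX, target))
}

#' Random-forest configuration for stability selection
#'
#' @param n_runs number of seeded forest runs (study setting: 50).
#' @param top_k size of each run's high-importance list (study setting: 30).
#' @param ntree trees per forest (study setting: 2000).
#' @param mtry_rule one of `"p/3"` (default, as recommended for regression
#'   forests), `"2p/3"`, `"0.5p/3"`, `"p"`; fractional values are rounded
#'   up.
#' @param min_node_size regression default 5.
#' @param base_seed run `i` uses seed `base_seed + i`.
#' @return list of class `rf_config`.
#' @export
rf_config <- function(n_runs = 50L, top_k = 30L, ntree = 2000L,
                      mtry_rule = c("p/3", "2p/3", "0.5p/3", "p"),
                      min_node_size = 5L, base_seed = 1L) {
  stopifnot(n_runs >= 1, top_k >= 1, ntree >= 1)
  structure(list(n_runs = as.integer(n_runs), top_k = as.integer(top_k),
                 ntree = as.integer(ntree), mtry_rule = match.arg(mtry_rule),
                 min_node_size = as.integer(min_node_size),
                 base_seed = as.integer(base_seed)),
            class = "rf_config")
}

mtry_from_rule <- function(rule, p) {
  m <- switch(rule, "p/3" = p / 3, "2p/3" = 2 * p / 3,
              "0.5p/3" = 0.5 * p / 3, "p" = p,
              stop("unknown mtry rule: ", rule))
  max(1L, min(p, as.integer(ceiling(m))))
}

#' Permutation importance from one seeded regression forest
#'
#' Fits a regression random forest on residualized dosages and returns the
#' permutation importance (mean out-of-bag MSE increase) per SNP, which is
#' deterministic under `run_seed`.
#'
#' @param y_res residualized phenotype.
#' @param G_res residualized dosage matrix (>= 2 SNPs).
#' @param config an [rf_config()].
#' @param run_seed integer seed for this run.
#' @return numeric importance vector named by SNP, with the forest's
#'   out-of-bag MSE in `attr(, "oob_mse")`.
#' @export
rf_importance <- function(y_res, G_res, config = rf_config(), run_seed = 1L) {
  if (ncol(G_res) < 2L) stop("at least 2 SNPs are required")
  if (sd(y_res) == 0) stop("constant response after residualization")
  dat <- as.data.frame(G_res)
  fit <- ranger::ranger(x = dat, y = y_res,
                        num.trees = config$ntree,
                        mtry = mtry_from_rule(config$mtry_rule, ncol(G_res)),
                        min.node.size = config$min_node_size,
                        importance = "permutation",
                        seed = run_seed, num.threads = 1L,
                        verbose = FALSE)
  imp <- fit$variable.importance
  attr(imp, "oob_mse") <- fit$prediction.error
  imp
}

#' Stability selection across seeded forest runs
#'
#' Runs [rf_importance()] `n_runs` times with seeds `base_seed + run`,
#' records each run's `top_k` SNPs by importance (ties broken by panel
#' order), and returns the intersection of all lists together with per-SNP
#' appearance counts.
#'
#' @inheritParams rf_importance
#' @param config an [rf_config()].
#' @return object of class `rf_stability`: `intersection` (SNPs in every
#'   run's list), `counts` (appearances per SNP in 0..n_runs), `top_lists`
#'   (list of per-run top-k character vectors), `oob_mse` per run and the
#'   `config`.
#' @export
stability_selection <- function(y_res, G_res, config = rf_config()) {
  snps <- colnames(G_res)
  if (is.null(snps)) snps <- colnames(G_res) <- paste0("snp", seq_len(ncol(G_res)))
  if (config$top_k > length(snps)) stop("top_k exceeds the number of SNPs")
  top_lists <- vector("list", config$n_runs)
  oob <- numeric(config$n_runs)
  for (i in seq_len(config$n_runs)) {
    imp <- rf_importance(y_res, G_res, config, run_seed = config$base_seed + i)
    oob[i] <- attr(imp, "oob_mse")
    ord <- order(-imp, seq_along(imp))          # ties -> panel order
    top_lists[[i]] <- snps[ord[seq_len(config$top_k)]]
  }
  counts <- table(factor(unlist(top_lists), levels = snps))
  counts <- setNames(as.integer(counts), snps)
  intersection <- snps[counts == config$n_runs]
  structure(list(intersection = intersection, counts = counts,
                 top_lists = top_lists, oob_mse = oob, config = config),
            class = "rf_stability")
}

#' @export
print.rf_stability <- function(x, ...) {
  cat(sprintf(
    "RF stability selection: %d runs x top-%d of %d SNPs (ntree %d, mtry %s)\n",
    x$config$n_runs, x$config$top_k, length(x$counts), x$config$ntree,
    x$config$mtry_rule))
  cat(sprintf("  intersection (%d SNPs): %s\n", length(x$intersection),
              if (length(x$intersection))
                paste(x$intersection, collapse = ", ") else "(empty)"))
  invisible(x)
}

#' Out-of-bag error across mtry rules
#'
#' Fits one seeded forest per mtry rule (`p/3`, `2p/3`, `0.5p/3`, `p`) and
#' reports the out-of-bag mean-squared errors side by side.
#'
#' @inheritParams rf_importance
#' @return data.frame with columns `rule`, `mtry`, `oob_mse`.
#' @export
mtry_error_comparison <- function(y_res, G_res, config = rf_config()) {
  if (ncol(G_res) < 4L) stop("at least 4 SNPs are required")
  rules <- c("p/3", "2p/3", "0.5p/3", "p")
  rows <- lapply(rules, function(r) {
    cfg <- config
    cfg$mtry_rule <- r
    imp <- rf_importance(y_res, G_res, cfg, run_seed = config$base_seed)
    data.frame(rule = r, mtry = mtry_from_rule(r, ncol(G_res)),
               oob_mse = attr(imp, "oob_mse"))
  })
  do.call(rbind, rows)
}
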