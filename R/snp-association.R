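## Candidate-SNP association: per-SNP mixed-model likelihood-ratio tests,
## FDR adjustment and full-vs-sensitivity-subset effect concordance.

#' Single-SNP likelihood-ratio test in the family mixed model
#'
#' Fits the family random-intercept model by ML with and without the SNP
#' dosage and forms `lr = 2 (loglik_full - loglik_null)` with a chi-square
#' (1 df) reference; the SNP enters as an additive fixed effect, so no
#' boundary correction applies. A dosage that is (numerically) collinear
#' with the null design carries no information: the test returns `lr = 0`,
#' `pval = 1` and `beta_hat = NA`. Tiny negative `lr` values from finite
#' optimizer tolerance are clipped at 0.
#'
#' @param y phenotype vector.
#' @param g additive dosage vector (0/1/2, possibly residualized).
#' @param X_null null-model design matrix (intercept plus covariates/PCs).
#' @param family_ids family identifiers.
#' @return list with `beta_hat`, `lr`, `pval`, `n_used`.
#' @export
lrt_snp <- function(y, g, X_null, family_ids) {
  X_null <- as.matrix(X_null)
  ## information check: residual variation of g given the null design
  g_res <- lm.fit(X_null, g)$residuals
  if (sd(g_res) < 1e-10 * max(sd(g), 1))
    return(list(beta_hat = NA_real_, lr = 0, pval = 1, n_used = length(y),
                reason = "collinear"))
  null_fit <- fit_mixed_model(y, X_null, family_ids)
  Xf <- cbind(X_null, g = g)
  full_fit <- fit_mixed_model(y, Xf, family_ids)
  lr <- max(0, 2 * (full_fit$loglik - null_fit$loglik))
  list(beta_hat = unname(coef(full_fit)["g"]), lr = lr,
       pval = pchisq(lr, 1, lower.tail = FALSE), n_used = length(y),
       reason = NA_character_)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement, capped at 1.
#'
#' @param pvals numeric p-values in \[0, 1\]; `NaN` is rejected.
#' @return adjusted p-values in the input order.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03))
#' @export
fdr_adjust <- function(pvals) {
  if (any(is.nan(pvals))) stop("NaN p-values are not valid")
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Per-SNP association scan of a cohort stratum
#'
#' Runs [lrt_snp()] for every SNP of a QC-passed dosage panel within one sex
#' stratum, on either the full sample or the low-transferrin sensitivity
#' subset. Covariates follow the study design: log10 transferrin (dropped in
#' the sensitivity subset, which it defines), age, 5-min APGAR (males only),
#' and the supplied genotype PCs. Individuals with a missing dosage are
#' dropped for that SNP only (`n_used` records the count); monomorphic SNPs
#' in the analysis subset are skipped with a reason, never aborting the
#' scan. P-values are FDR-adjusted by Benjamini-Hochberg and the table is
#' sorted by raw p-value.
#'
#' @param cohort cohort data.frame.
#' @param G dosage matrix aligned row-wise with `cohort`.
#' @param sex `"M"` or `"F"` stratum to analyse.
#' @param subset `"full"` or `"low_transferrin"`.
#' @param pcs matrix of genotype PC scores aligned with `cohort` rows, or
#'   `NULL`.
#' @param transferrin_cutoff sensitivity cutoff, mg/dl.
#' @param fdr_level significance level on adjusted p-values.
#' @return data.frame of class `assoc_scan` with columns `snp`, `beta_hat`,
#'   `lr`, `pval`, `pval_bh`, `maf`, `n_used`, `significant`; skipped SNPs
#'   and their reasons in `attr(, "skipped")`.
#' @export
association_scan <- function(cohort, G, sex = c("M", "F"),
                             subset = c("full", "low_transferrin"),
                             pcs = NULL, transferrin_cutoff = 0.50,
                             fdr_level = 0.05) {
  sex <- match.arg(sex)
  subset <- match.arg(subset)
  keep <- cohort$sex == sex
  if (subset == "low_transferrin")
    keep <- keep & cohort$transferrin < transferrin_cutoff
  rows <- which(keep)
  if (!length(rows)) stop("empty analysis stratum")
  co <- cohort[rows, , drop = FALSE]
  Gs <- G[rows, , drop = FALSE]
  pcs_s <- if (!is.null(pcs)) as.matrix(pcs)[rows, , drop = FALSE] else NULL

  cov_names <- c(if (subset == "full") "log10_transferrin", "age_months",
                 if (sex == "M") "apgar5")
  Xc <- covariate_block(co, cov_names)
  X_null <- cbind(`(Intercept)` = 1, Xc, pcs_s)
  y <- co$phenotype
  fam <- co$family_id

  res <- vector("list", ncol(Gs))
  skipped <- character(0)
  for (j in seq_len(ncol(Gs))) {
    gj <- Gs[, j]
    ok <- !is.na(gj)
    if (sum(ok) < ncol(X_null) + 2L || var(gj[ok]) == 0) {
      skipped[colnames(Gs)[j]] <- if (sum(ok) && var(gj[ok]) == 0)
        "monomorphic" else "insufficient data"
      next
    }
    f <- mean(gj[ok]) / 2
    t <- lrt_snp(y[ok], gj[ok], X_null[ok, , drop = FALSE], fam[ok])
    res[[j]] <- data.frame(snp = colnames(Gs)[j], beta_hat = t$beta_hat,
                           lr = t$lr, pval = t$pval, maf = min(f, 1 - f),
                           n_used = sum(ok))
  }
  tab <- do.call(rbind, res)
  if (is.null(tab)) stop("no testable SNPs in this stratum")
  tab$pval_bh <- fdr_adjust(tab$pval)
  tab$significant <- tab$pval_bh < fdr_level
  tab <- tab[order(tab$pval), c("snp", "beta_hat", "lr", "pval", "pval_bh",
                                "maf", "n_used", "significant")]
  rownames(tab) <- NULL
  structure(tab, class = c("assoc_scan", "data.frame"),
            skipped = skipped, sex = sex, subset = subset)
}

#' @export
print.assoc_scan <- function(x, n = 10L, ...) {
  cat(sprintf("Association scan (%s, %s sample): %d SNPs tested, %d skipped, %d significant at FDR\n",
              attr(x, "sex"), attr(x, "subset"), nrow(x),
              length(attr(x, "skipped")), sum(x$significant)))
  print.data.frame(head(transform(x, beta_hat = round(beta_hat, 3),
                                  lr = round(lr, 3), pval = signif(pval, 3),
                                  pval_bh = signif(pval_bh, 3),
                                  maf = round(maf, 3)), n),
                   row.names = FALSE)
  invisible(x)
}

#' Concordance of effect sizes between two scans
#'
#' Pearson correlation of per-SNP effect estimates between two association
#' tables (typically the full sample and the low-transferrin sensitivity
#' subset), joined on SNP identifier.
#'
#' @param table_full,table_subset `assoc_scan` tables.
#' @return list with `correlation`, `n_shared` and the joined data.frame.
#' @export
effect_size_concordance <- function(table_full, table_subset) {
  merged <- merge(as.data.frame(table_full)[, c("snp", "beta_hat")],
                  as.data.frame(table_subset)[, c("snp", "beta_hat")],
                  by = "snp", suffixes = c("_full", "_subset"))
  merged <- merged[is.finite(merged$beta_hat_full) &
                     is.finite(merged$beta_hat_subset), ]
  if (nrow(merged) < 3L) {
    warning("fewer than 3 shared SNPs; concordance unavailable")
    return(list(correlation = NA_real_, n_shared = nrow(merged),
                data = merged))
  }
  list(correlation = cor(merged$beta_hat_full, merged$beta_hat_subset),
       n_shared = nrow(merged), data = merged)
}
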