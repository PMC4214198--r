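## SNP-level quality control (MAF, exact HWE, call rate, LD pruning) and
## population-structure principal components. Frequency-based statistics
## are computed on a one-per-family "founder proxy" subset, because twins
## violate the independence assumptions of both the MAF and the HWE test.

## Seeded choice of one individual per family.
founder_subset <- function(family_ids, seed = 1L) {
  set.seed(seed)
  idx <- split(seq_along(family_ids), factor(family_ids, levels = unique(family_ids)))
  sort(vapply(idx, function(i) if (length(i) == 1L) i else sample(i, 1L),
              integer(1)))
}

snp_attrs <- function(G) {
  list(mafs = attr(G, "mafs"), chrom = attr(G, "chrom"),
       positions = attr(G, "positions"))
}

subset_snps <- function(G, keep) {
  at <- snp_attrs(G)
  out <- G[, keep, drop = FALSE]
  attr(out, "mafs") <- at$mafs[keep]
  attr(out, "chrom") <- at$chrom[keep]
  attr(out, "positions") <- at$positions[keep]
  class(out) <- class(G)
  out
}

## Folded allele frequency per SNP on the given rows (non-missing dosages).
folded_maf <- function(G, rows = seq_len(nrow(G))) {
  f <- colMeans(G[rows, , drop = FALSE], na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Filter SNPs by minor-allele frequency
#'
#' Removes SNPs whose folded MAF, computed on one randomly chosen member
#' per family (to avoid twin double-counting), is strictly below
#' `threshold`; a SNP at exactly the threshold is retained.
#'
#' @param G genotype matrix (individuals x SNPs, dosages 0/1/2 or `NA`).
#' @param family_ids family identifiers for the rows of `G`.
#' @param threshold MAF threshold in (0, 0.5\] (default 0.05).
#' @param seed seed for the one-per-family choice.
#' @return the filtered genotype matrix; removed SNP names in
#'   `attr(, "removed")`.
#' @export
maf_filter <- function(G, family_ids, threshold = 0.05, seed = 1L) {
  if (!is.finite(threshold) || threshold <= 0 || threshold > 0.5)
    stop("threshold must lie in (0, 0.5]")
  maf <- folded_maf(G, founder_subset(family_ids, seed))
  keep <- !is.na(maf) & maf >= threshold
  out <- subset_snps(G, keep)
  attr(out, "removed") <- colnames(G)[!keep]
  out
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditioning on the observed allele counts: the
#' p-value is the total probability of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count
#' (computed in closed form from log factorials). Stable in the far tail,
#' unlike the chi-square approximation.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total > 0).
#' @return exact p-value; `NA` with a warning when the total is 0.
#' @examples
#' hwe_test(25, 50, 25)   # counts at the HWE expectation
#' hwe_test(50, 0, 50)    # extreme departure, p << 1e-8
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) { warning("no genotyped individuals; HWE undefined"); return(NA_real_) }
  n_rare <- 2 * min(n_AA, n_aa) + n_Aa
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  n_common <- 2 * n - n_rare
  lp <- hets * log(2) + lfactorial(n) + lfactorial(n_rare) +
    lfactorial(n_common) - lfactorial((n_rare - hets) / 2) -
    lfactorial(hets) - lfactorial((n_common - hets) / 2) - lfactorial(2 * n)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

#' Filter SNPs by exact HWE p-value
#'
#' Computes the exact HWE test on the one-per-family subset and removes
#' SNPs with `p < p_threshold` (default 1e-8). SNPs with no genotyped
#' founders are flagged and removed.
#'
#' @inheritParams maf_filter
#' @param p_threshold removal threshold on the exact p-value.
#' @return filtered genotype matrix with `attr(, "removed")` and
#'   `attr(, "hwe_p")` (p-values for all input SNPs).
#' @export
hwe_filter <- function(G, family_ids, p_threshold = 1e-8, seed = 1L) {
  rows <- founder_subset(family_ids, seed)
  pv <- apply(G[rows, , drop = FALSE], 2, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    hwe_test(sum(g == 0), sum(g == 1), sum(g == 2))
  })
  keep <- !is.na(pv) & pv >= p_threshold
  out <- subset_snps(G, keep)
  attr(out, "removed") <- colnames(G)[!keep]
  attr(out, "hwe_p") <- pv
  out
}

#' Filter SNPs by genotype call rate
#'
#' Removes SNPs whose fraction of non-missing dosages is strictly below
#' `threshold` (default 0.95).
#'
#' @param G genotype matrix.
#' @param threshold call-rate threshold in (0, 1\].
#' @return filtered genotype matrix with `attr(, "removed")`.
#' @export
call_rate_filter <- function(G, threshold = 0.95) {
  if (!is.finite(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  rate <- colMeans(!is.na(G))
  keep <- rate >= threshold
  out <- subset_snps(G, keep)
  attr(out, "removed") <- colnames(G)[!keep]
  out
}

#' Greedy window-based LD pruning
#'
#' Scans SNPs left to right in panel order with windows of `window_size`
#' SNPs advancing by `step`; within each window, for every pair with
#' squared dosage correlation above `r2_threshold`, the later SNP is
#' dropped. Missing dosages are mean-imputed for the correlation only.
#'
#' @param G genotype matrix.
#' @param r2_threshold squared-correlation threshold (default 0.2).
#' @param window_size window width in SNPs (>= 2, default 50).
#' @param step window advance in SNPs (default 5).
#' @return pruned genotype matrix with `attr(, "removed")`.
#' @export
ld_prune <- function(G, r2_threshold = 0.2, window_size = 50L, step = 5L) {
  if (window_size < 2) stop("window_size must be >= 2")
  p <- ncol(G)
  M <- impute_colmeans(G)
  keep <- rep(TRUE, p)
  sds <- apply(M, 2, sd)
  for (s in seq(1L, max(1L, p - 1L), by = step)) {
    win <- s:min(s + window_size - 1L, p)
    act <- win[keep[win] & sds[win] > 0]
    if (length(act) < 2L) next
    for (ii in seq_len(length(act) - 1L)) {
      i <- act[ii]
      if (!keep[i]) next
      for (j in act[(ii + 1L):length(act)]) {
        if (!keep[j]) next
        if (cor(M[, i], M[, j])^2 > r2_threshold) keep[j] <- FALSE
      }
    }
  }
  out <- subset_snps(G, keep)
  attr(out, "removed") <- colnames(G)[!keep]
  out
}

impute_colmeans <- function(G) {
  M <- unclass(G)[, , drop = FALSE]
  storage.mode(M) <- "double"
  if (anyNA(M)) {
    cm <- colMeans(M, na.rm = TRUE)
    nas <- which(is.na(M), arr.ind = TRUE)
    M[nas] <- cm[nas[, 2]]
  }
  M
}

#' Genotype principal components for population structure
#'
#' Column-standardized dosage PCA: loadings are fit by singular-value
#' decomposition on one randomly chosen member per family (twins share
#' their co-twin's ancestry, so relatives would distort the axes), and
#' scores are projected for all individuals. Missing dosages are
#' mean-imputed for this computation only. Each loading vector is oriented
#' so its largest-magnitude entry is positive, making outputs reproducible.
#'
#' @param G genotype matrix.
#' @param family_ids family identifiers for the rows of `G`.
#' @param k number of components (default 3).
#' @param unrelated_only fit loadings on the one-per-family subset (default
#'   `TRUE`).
#' @param seed seed for the one-per-family choice.
#' @return object of class `geno_pca`: `scores` (individuals x k),
#'   `loadings`, `var_explained` (fractions of total standardized variance,
#'   non-increasing), `k`.
#' @export
genotype_pca <- function(G, family_ids, k = 3L, unrelated_only = TRUE,
                         seed = 1L) {
  M <- impute_colmeans(G)
  rows <- if (unrelated_only) founder_subset(family_ids, seed) else seq_len(nrow(M))
  ctr <- colMeans(M[rows, , drop = FALSE])
  scl <- apply(M[rows, , drop = FALSE], 2, sd)
  ok <- scl > 0
  if (sum(ok) < k) stop("k exceeds the rank of the centered dosage matrix")
  Z <- sweep(sweep(M[, ok, drop = FALSE], 2, ctr[ok]), 2, scl[ok], "/")
  sv <- svd(Z[rows, , drop = FALSE], nu = 0, nv = min(k, sum(ok)))
  if (length(sv$d) < k || sv$d[k] <= sqrt(.Machine$double.eps))
    stop("k exceeds the rank of the centered dosage matrix")
  load <- sv$v[, seq_len(k), drop = FALSE]
  ## sign convention: largest-magnitude loading entry positive
  for (j in seq_len(k)) {
    m <- which.max(abs(load[, j]))
    if (load[m, j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- colnames(G)[ok]
  colnames(load) <- paste0("PC", seq_len(k))
  scores <- Z %*% load
  rownames(scores) <- rownames(G)
  ev <- (sv$d^2) / (length(rows) - 1)
  ve <- ev[seq_len(k)] / sum(ok)      # fractions of total standardized variance
  structure(list(scores = scores, loadings = load,
                 var_explained = ve, k = k, n_fit = length(rows)),
            class = "geno_pca")
}

#' @export
print.geno_pca <- function(x, ...) {
  cat(sprintf("Genotype PCA: %d components fit on %d unrelated individuals\n",
              x$k, x$n_fit))
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "),
      sprintf(" (first %d: %.1f%%)\n", x$k, 100 * sum(x$var_explained)))
  invisible(x)
}

#' Full SNP quality-control pass
#'
#' Applies the study's QC chain in order -- call rate >= 95%, folded
#' MAF >= 0.05, exact HWE p >= 1e-8 -- and returns the filtered panel plus
#' a per-SNP report.
#'
#' @param G genotype matrix.
#' @param family_ids family identifiers.
#' @param maf_threshold,call_rate_threshold,hwe_threshold filter settings.
#' @param seed seed for one-per-family subsetting.
#' @return list of class `qc_result` with `genotypes` (filtered matrix) and
#'   `report` (data.frame: snp, maf, call_rate, hwe_p, verdict).
#' @export
genotype_qc <- function(G, family_ids, maf_threshold = 0.05,
                        call_rate_threshold = 0.95, hwe_threshold = 1e-8,
                        seed = 1L) {
  rows <- founder_subset(family_ids, seed)
  maf <- folded_maf(G, rows)
  rate <- colMeans(!is.na(G))
  pv <- apply(G[rows, , drop = FALSE], 2, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    hwe_test(sum(g == 0), sum(g == 1), sum(g == 2))
  })
  verdict <- ifelse(rate < call_rate_threshold, "low_call_rate",
             ifelse(is.na(maf) | maf < maf_threshold, "low_maf",
             ifelse(is.na(pv) | pv < hwe_threshold, "hwe_fail", "pass")))
  report <- data.frame(snp = colnames(G), maf = maf, call_rate = rate,
                       hwe_p = pv, verdict = verdict, row.names = NULL)
  out <- subset_snps(G, verdict == "pass")
  structure(list(genotypes = out, report = report), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("SNP QC: %d of %d SNPs pass\n", ncol(x$genotypes),
              nrow(x$report)))
  print(table(x$report$verdict))
  invisible(x)
}
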