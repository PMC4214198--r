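make_panel <- function(n = 60, p = 30, mafs = NULL, seed = 1,
                       missing_rate = 0) {
  cfg <- cohort_config(n_mz_pairs = 0, n_dz_pairs = 0, n_os_dz_pairs = 0,
                       n_unpaired_twins = 0, n_singletons = n, n_snps = p,
                       mafs = mafs, missing_rate = missing_rate, seed = seed)
  simulate_genotypes(cfg)
}

test_that("MAF filter removes below-threshold SNPs with a strict inequality", {
  G <- matrix(c(rep(0L, 99), 1L,          # maf 0.005 -> removed
                rep(0L, 100),             # monomorphic -> removed
                rep(c(0L, 1L), 50),       # maf 0.25 -> kept
                rep(0L, 90), rep(1L, 10)  # maf 0.05 exactly -> kept
  ), 100, 4)
  colnames(G) <- paste0("s", 1:4)
  rownames(G) <- paste0("i", 1:100)
  attr(G, "mafs") <- rep(NA_real_, 4); attr(G, "chrom") <- rep("1", 4)
  attr(G, "positions") <- 1:4
  out <- maf_filter(G, family_ids = seq_len(100), threshold = 0.05)
  expect_setequal(colnames(out), c("s3", "s4"))
  expect_setequal(attr(out, "removed"), c("s1", "s2"))
})

test_that("MAF is computed on one member per family (no twin double-counting)", {
  ## two MZ families whose duplicated rows would inflate the rare allele
  G <- rbind(c(1L), c(1L), c(0L), c(0L), matrix(0L, 16, 1))
  colnames(G) <- "s1"
  fam <- c(1, 1, 2, 2, 3:18)
  out <- maf_filter(G, fam, threshold = 0.05, seed = 2)
  ## founder subset has 18 members, 0 or 1 carrying the allele; the full
  ## matrix would count the MZ copy twice
  maf_founder <- minitwin:::folded_maf(G, minitwin:::founder_subset(fam, 2))
  expect_lte(maf_founder, 1 / 36 + 1e-12)
})

test_that("exact HWE test matches the enumeration oracle and hits the tails", {
  expect_gt(hwe_test(25, 50, 25), 0.9)           # at HWE expectation
  expect_lt(hwe_test(50, 0, 50), 1e-8)           # gross departure
  set.seed(7)
  for (i in 1:50) {
    n <- sample(5:200, 1)
    nAA <- sample(0:n, 1)
    nAa <- sample(0:(n - nAA), 1)
    naa <- n - nAA - nAa
    expect_equal(hwe_test(nAA, nAa, naa), hwe_oracle(nAA, nAa, naa),
                 tolerance = 1e-10)
  }
  expect_error(hwe_test(-1, 2, 3), "non-negative")
  expect_warning(p <- hwe_test(0, 0, 0), "undefined")
  expect_true(is.na(p))
})

test_that("call-rate filter agrees with direct recomputation", {
  G <- make_panel(n = 200, p = 300, seed = 5, missing_rate = 0.04)
  out <- call_rate_filter(G, 0.95)
  keep_direct <- colMeans(!is.na(G)) >= 0.95
  expect_setequal(colnames(out), colnames(G)[keep_direct])
  ## complete SNPs always survive; a 94% SNP never does
  G2 <- make_panel(n = 100, p = 2, seed = 6)
  G2[1:6, 2] <- NA                              # call rate 0.94
  expect_setequal(colnames(call_rate_filter(G2, 0.95)), colnames(G2)[1])
})

test_that("LD pruning drops duplicated columns and keeps independent ones", {
  G <- make_panel(n = 300, p = 6, seed = 8)
  Gd <- cbind(G, dup = G[, 3])
  attr(Gd, "mafs") <- c(attr(G, "mafs"), attr(G, "mafs")[3])
  attr(Gd, "chrom") <- rep("1", 7); attr(Gd, "positions") <- 1:7
  out <- ld_prune(Gd, r2_threshold = 0.5, window_size = 10)
  expect_false("dup" %in% colnames(out))
  expect_true(all(colnames(G) %in% colnames(out)))
  ## 3-SNP toy against exhaustive pairwise r^2
  set.seed(9)
  g1 <- rbinom(500, 2, 0.4)
  g2 <- g1; flip <- sample(500, 20); g2[flip] <- rbinom(20, 2, 0.4)  # r2 ~ 1
  g3 <- rbinom(500, 2, 0.4)
  T3 <- cbind(a = g1, b = g2, c = g3)
  attr(T3, "mafs") <- rep(0.4, 3); attr(T3, "chrom") <- rep("1", 3)
  attr(T3, "positions") <- 1:3
  r2_ab <- cor(g1, g2)^2
  out3 <- ld_prune(T3, r2_threshold = 0.2, window_size = 3)
  expect_identical(colnames(out3),
                   if (r2_ab > 0.2) c("a", "c") else c("a", "b", "c"))
})

test_that("genotype PCA separates ancestry clusters and projects twins identically", {
  set.seed(10)
  p <- 80
  f1 <- runif(p, 0.05, 0.5)
  f2 <- pmin(0.95, pmax(0.05, f1 + sample(c(-1, 1), p, TRUE) * 0.4))
  A <- sapply(seq_len(p), function(j) rbinom(60, 2, f1[j]))
  B <- sapply(seq_len(p), function(j) rbinom(60, 2, f2[j]))
  G <- rbind(A, B)
  ## add one MZ pair duplicating row 1
  G <- rbind(G, G[1, ])
  rownames(G) <- paste0("i", seq_len(nrow(G)))
  colnames(G) <- paste0("s", seq_len(p))
  fam <- c(seq_len(120), 1L)           # last row is row 1's co-twin
  pca <- genotype_pca(G, fam, k = 3, seed = 3)
  s1 <- pca$scores[1:60, 1]; s2 <- pca$scores[61:120, 1]
  expect_true(min(s1) > max(s2) || min(s2) > max(s1))  # zero overlap
  expect_equal(pca$scores[121, ], pca$scores[1, ], ignore_attr = TRUE)
  expect_true(all(diff(pca$var_explained) <= 1e-12))
  expect_lte(sum(pca$var_explained), 1)
  ## scores invariant (up to sign) under SNP column permutation
  perm <- sample(p)
  Gp <- G[, perm]
  attr(Gp, "mafs") <- NULL
  pca_p <- genotype_pca(Gp, fam, k = 3, seed = 3)
  for (j in 1:3)
    expect_equal(abs(cor(pca$scores[, j], pca_p$scores[, j])), 1,
                 tolerance = 1e-8)
  expect_error(genotype_pca(G[, 1:2], fam, k = 5), "rank")
})

test_that("the combined QC pass reports per-SNP verdicts consistently", {
  G <- make_panel(n = 150, p = 60, seed = 12, missing_rate = 0.02)
  ## plant a low-MAF SNP and an HWE-violating SNP
  G[, 1] <- 0L; G[1, 1] <- 1L
  G[, 2] <- rep(c(0L, 2L), length.out = 150)      # no heterozygotes
  qc <- genotype_qc(G, family_ids = seq_len(150))
  expect_equal(qc$report$verdict[1], "low_maf")
  expect_equal(qc$report$verdict[2], "hwe_fail")
  expect_equal(ncol(qc$genotypes), sum(qc$report$verdict == "pass"))
  ## filters commute with row permutation of individuals
  perm <- sample(150)
  qc_p <- genotype_qc(G[perm, ], family_ids = seq_len(150)[perm])
  expect_setequal(colnames(qc_p$genotypes), colnames(qc$genotypes))
})
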