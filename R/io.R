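## Delimited-text serialization of cohorts and genotype panels, a minimal
## VCF export, and the reproducibility manifest.

#' Write / read a cohort table as tab-delimited text
#'
#' One row per infant with a fixed header (IDs, family structure, phenotype
#' and covariates). Factors are written as their labels and restored as
#' character columns plus re-levelled factors on read.
#'
#' @param cohort cohort data.frame.
#' @param file path to the `.tsv` file.
#' @return `write_cohort` returns `file` invisibly; `read_cohort` the
#'   cohort data.frame.
#' @export
write_cohort <- function(cohort, file) {
  write.table(cohort, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  factor_levels <- list(
    nicu_stay = c("No", "Yes"), csection = c("No", "Yes"),
    maternal_ethnicity = c("White", "Black", "Asian", "Other"),
    paternal_ethnicity = c("White", "Black", "Asian", "Other"),
    maternal_psych = c("No", "Yes"), paternal_psych = c("No", "Yes"),
    income = c("Low", "Middle", "High", "Missing"),
    maternal_smoking = c("No", "Yes"),
    gestation_number = c("Singleton", "Twin"))
  for (nm in intersect(names(factor_levels), names(df)))
    df[[nm]] <- factor(df[[nm]], levels = factor_levels[[nm]])
  df
}

#' Write / read an additive-dosage matrix as delimited text
#'
#' Individuals in rows (first column `individual_id`), SNPs in columns;
#' missing dosages are written as `NA`. SNP metadata (MAF, chromosome,
#' position) travels in a sibling `<file>.snps.tsv` table.
#'
#' @param G genotype matrix with SNP attributes.
#' @param file path to the dosage `.tsv` file.
#' @return `write_dosages` returns `file` invisibly; `read_dosages` a
#'   `genotype_matrix`.
#' @export
write_dosages <- function(G, file) {
  df <- data.frame(individual_id = rownames(G), unclass(G),
                   check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(snp = colnames(G), maf = attr(G, "mafs"),
                     chrom = attr(G, "chrom"), pos = attr(G, "positions"))
  write.table(meta, paste0(file, ".snps.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname write_dosages
#' @export
read_dosages <- function(file) {
  df <- read.delim(file, check.names = FALSE)
  G <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(G) <- "integer"
  rownames(G) <- df$individual_id
  meta_file <- paste0(file, ".snps.tsv")
  if (file.exists(meta_file)) {
    meta <- read.delim(meta_file)
    attr(G, "mafs") <- meta$maf
    attr(G, "chrom") <- as.character(meta$chrom)
    attr(G, "positions") <- meta$pos
  }
  class(G) <- c("genotype_matrix", class(G))
  G
}

#' Export genotypes as a minimal VCF
#'
#' Writes a VCFv4.2 file carrying only the GT field (unphased diploid
#' genotypes; missing dosages as `./.`), one sample per individual. The
#' alternate allele is the minor allele counted by the dosage.
#'
#' @param G genotype matrix.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_vcf <- function(G, file) {
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  chrom <- attr(G, "chrom")
  pos <- attr(G, "positions")
  if (is.null(chrom)) chrom <- rep("1", ncol(G))
  if (is.null(pos)) pos <- seq_len(ncol(G))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(G)), collapse = "\t")), con)
  for (j in seq_len(ncol(G))) {
    g <- G[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    writeLines(paste(c(chrom[j], pos[j], colnames(G)[j], "A", "G", ".",
                       "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(file)
}

#' Read additive dosages from a VCF
#'
#' Parses the GT field of a VCF (via the vcfR package) into an additive
#' dosage matrix, individuals in rows.
#'
#' @param file VCF path.
#' @return a `genotype_matrix` of dosages with SNP positions attached.
#' @export
read_vcf_genotypes <- function(file) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the vcfR package is required to read VCF files")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- function(x) {
    ifelse(x %in% c("0/0", "0|0"), 0L,
           ifelse(x %in% c("0/1", "1/0", "0|1", "1|0"), 1L,
                  ifelse(x %in% c("1/1", "1|1"), 2L, NA_integer_)))
  }
  G <- t(apply(gt, 1, alleles))
  G <- t(G)  # individuals x SNPs
  dimnames(G) <- list(colnames(gt), rownames(gt))
  attr(G, "chrom") <- as.character(v@fix[, "CHROM"])
  attr(G, "positions") <- as.integer(v@fix[, "POS"])
  attr(G, "mafs") <- pmin(colMeans(G, na.rm = TRUE) / 2,
                          1 - colMeans(G, na.rm = TRUE) / 2)
  class(G) <- c("genotype_matrix", class(G))
  G
}

#' Write a reproducibility manifest
#'
#' Records the configuration snapshot, seeds, per-stage notes and MD5
#' digests of every output file as JSON, so a rerun with identical inputs
#' can be verified byte for byte.
#'
#' @param path output JSON path.
#' @param config configuration snapshot (list).
#' @param seeds named list/vector of stage seeds.
#' @param files character vector of output files to digest.
#' @param stages per-stage notes (list), optional.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, config, seeds, files, stages = list()) {
  manifest <- list(
    package_version = as.character(packageVersion("minitwin")),
    config = config, seeds = as.list(seeds),
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))),
    stages = stages)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
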