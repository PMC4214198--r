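## End-to-end orchestration: one configuration, fixed stage seeds, a run
## manifest with file digests, and the fixture generator used by the tests.

#' Pipeline configuration
#'
#' Single structured configuration driving [run_pipeline()]. Stage seeds
#' derive from `master_seed` plus fixed offsets (generator 0, QC 10, lasso
#' bootstrap 20, power 30, RF 40), all recorded in the manifest.
#'
#' @param cohort a [cohort_config()]; its `seed` is overwritten by
#'   `master_seed`.
#' @param model a [phenotype_model()].
#' @param master_seed integer master seed.
#' @param n_bootstrap cluster-bootstrap replicates for the selection stage.
#' @param n_pcs genotype PCs carried as covariates.
#' @param run_power,run_rf logical stage toggles (the heavier stages).
#' @param power a [power_config()] (its `base_seed` is overwritten).
#' @param rf an [rf_config()] (its `base_seed` is overwritten).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            model = phenotype_model(),
                            master_seed = 1L, n_bootstrap = 100L,
                            n_pcs = 3L, run_power = FALSE, run_rf = TRUE,
                            power = power_config(n_reps = 200L),
                            rf = rf_config(n_runs = 10L, ntree = 500L)) {
  cohort$seed <- as.integer(master_seed)
  power$base_seed <- as.integer(master_seed + 30L)
  rf$base_seed <- as.integer(master_seed + 40L)
  structure(list(cohort = cohort, model = model,
                 master_seed = as.integer(master_seed),
                 n_bootstrap = as.integer(n_bootstrap),
                 n_pcs = as.integer(n_pcs),
                 run_power = run_power, run_rf = run_rf,
                 power = power, rf = rf),
            class = "pipeline_config")
}

#' Covariate design of the environmental-selection stage
#'
#' Assembles the selection-stage covariate table: the 16 demographic and
#' medical-history variables plus the two always-in columns (log10
#' transferrin and age). Covariates constant within the given cohort
#' stratum are dropped (recorded in `attr(, "dropped_constant")`);
#' categorical expansion to reference-coded indicators happens downstream
#' in [standardize_and_center()].
#'
#' @param cohort cohort data.frame (typically one sex stratum).
#' @return data.frame of covariates ready for [standardize_and_center()].
#' @export
selection_design <- function(cohort) {
  covs <- cohort[, c("birth_weight", "gestational_age", "apgar5",
                     "nicu_stay", "csection", "maternal_ethnicity",
                     "paternal_ethnicity", "maternal_age", "paternal_age",
                     "maternal_education", "paternal_education",
                     "maternal_psych", "paternal_psych", "income",
                     "maternal_smoking", "gestation_number"), drop = FALSE]
  covs <- droplevels(covs)
  ## a covariate constant in this stratum carries no information; drop it
  ok <- vapply(covs, function(v)
    if (is.factor(v)) nlevels(v) >= 2L else sd(v) > 0, logical(1))
  covs <- covs[, ok, drop = FALSE]
  fixed <- data.frame(log10_transferrin = log10_transferrin(cohort$transferrin),
                      age_months = cohort$age_months)
  out <- cbind(fixed, covs)
  attr(out, "dropped_constant") <- names(ok)[!ok]
  out
}

#' Run the analysis pipeline end to end
#'
#' Executes the stages in study order on a simulated cohort: generation,
#' preprocessing, SNP QC and PCA, per-sex adaptive-Lasso covariate
#' selection with bootstrap and post-selection inference, ICC/ACE
#' heritability, per-sex association scans (full and low-transferrin
#' subsets) with effect concordance, and optionally the power grid and RF
#' stability selection. All tables are written as delimited text under
#' `out_dir` and digested into `manifest.json`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @return list of class `pipeline_result` with the per-stage objects and
#'   the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  out_files <- character(0)
  emit <- function(df, name) {
    f <- file.path(out_dir, name)
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    out_files <<- c(out_files, f)
    f
  }

  ## --- synthetic data -----------------------------------------------------
  sim <- simulate_cohort(config$cohort, config$model)
  cohort <- sim$cohort
  G <- sim$genotypes
  f <- file.path(out_dir, "cohort.tsv")
  write_cohort(cohort, f); out_files <- c(out_files, f)
  stages$synthetic_data <- list(n_individuals = nrow(cohort),
                                n_snps = if (is.null(G)) 0L else ncol(G))

  ## --- genotype QC + PCs --------------------------------------------------
  pcs <- NULL
  if (!is.null(G) && ncol(G) > 0) {
    qc <- genotype_qc(G, cohort$family_id, seed = config$master_seed + 10L)
    Gq <- qc$genotypes
    emit(qc$report, "qc_report.tsv")
    f <- file.path(out_dir, "dosages.tsv")
    write_dosages(Gq, f); out_files <- c(out_files, f, paste0(f, ".snps.tsv"))
    pca <- genotype_pca(Gq, cohort$family_id, k = config$n_pcs,
                        seed = config$master_seed + 10L)
    pcs <- pca$scores
    emit(data.frame(individual_id = cohort$individual_id, pcs), "pc_scores.tsv")
    stages$genotype_qc <- list(n_pass = ncol(Gq),
                               var_explained = pca$var_explained)
  } else {
    Gq <- NULL
    stages$genotype_qc <- list(skipped = "no SNPs in configuration")
  }

  ## --- covariate selection per sex ---------------------------------------
  strata <- stratify_by_sex(cohort)
  selection <- list()
  for (sx in c("M", "F")) {
    co <- strata[[sx]]
    des <- selection_design(co)
    std <- standardize_and_center(des, co$phenotype)
    always <- c("log10_transferrin", "age_months")
    sel <- adaptive_lasso_select(std$y, std$X, co$family_id, always)
    boot <- bootstrap_stability(std$y, std$X, co$family_id, always,
                                B = config$n_bootstrap,
                                base_seed = config$master_seed + 20L)
    post <- post_selection_model(std$y,
                                 std$X[, sel$selected, drop = FALSE],
                                 co$family_id, m_total = std$n_predictors)
    emit(data.frame(covariate = names(boot$counts),
                    selected = names(boot$counts) %in% sel$selected,
                    bootstrap_count = unname(boot$counts)),
         sprintf("selection_%s.tsv", sx))
    emit(post$table, sprintf("post_selection_%s.tsv", sx))
    selection[[sx]] <- list(selection = sel, bootstrap = boot, post = post,
                            n_predictors = std$n_predictors)
  }
  stages$covariate_selection <- lapply(selection, function(s)
    list(selected = s$selection$selected, n_predictors = s$n_predictors))

  ## --- heritability -------------------------------------------------------
  icc <- icc_by_group(cohort, covariates = c("log10_transferrin", "age_months"))
  emit(as.data.frame(icc), "icc.tsv")
  heritability <- list(icc = icc)
  ace <- list()
  for (sx in c("M", "F")) {
    co <- strata[[sx]]
    covs <- covariate_block(co, c("log10_transferrin", "age_months",
                                  if (sx == "M") "apgar5"))
    fit <- tryCatch(fit_ace(co$phenotype, covs, co$family_id, co$zygosity),
                    error = function(e) e$message)
    ace[[sx]] <- fit
    if (inherits(fit, "ace_fit"))
      emit(data.frame(component = c("A", "C", "E"),
                      variance = unname(fit$sigma2),
                      explained_pct = 100 * unname(fit$proportions),
                      p_one_tailed = c(fit$p_A, fit$p_C, NA)),
           sprintf("ace_%s.tsv", sx))
  }
  heritability$ace <- ace
  stages$heritability <- list(groups = icc$group, n_pairs = icc$n_pairs)

  ## --- association scans --------------------------------------------------
  assoc <- list()
  if (!is.null(Gq) && ncol(Gq) > 0) {
    for (sx in c("M", "F")) {
      full <- association_scan(cohort, Gq, sex = sx, subset = "full",
                               pcs = pcs)
      sub <- tryCatch(association_scan(cohort, Gq, sex = sx,
                                       subset = "low_transferrin", pcs = pcs),
                      error = function(e) NULL)
      conc <- if (!is.null(sub)) effect_size_concordance(full, sub) else NULL
      emit(as.data.frame(full), sprintf("assoc_%s_full.tsv", sx))
      if (!is.null(sub)) emit(as.data.frame(sub), sprintf("assoc_%s_low.tsv", sx))
      assoc[[sx]] <- list(full = full, low_transferrin = sub,
                          concordance = conc)
    }
    stages$snp_association <- lapply(assoc, function(a)
      list(n_tested = nrow(a$full),
           concordance = if (!is.null(a$concordance)) a$concordance$correlation
                         else NA))
  } else stages$snp_association <- list(skipped = "no SNPs after QC")

  ## --- power (optional) ---------------------------------------------------
  power <- NULL
  if (config$run_power) {
    power <- power_grid(config$power)
    emit(as.data.frame(power), "power.tsv")
    stages$power <- list(cells = nrow(power))
  } else stages$power <- list(skipped = "disabled")

  ## --- random forest (optional) -------------------------------------------
  rf <- list()
  if (config$run_rf && !is.null(Gq) && ncol(Gq) >= max(4L, config$rf$top_k)) {
    for (sx in c("M", "F")) {
      co_idx <- which(cohort$sex == sx)
      co <- cohort[co_idx, , drop = FALSE]
      one <- select_one_twin_per_pair(co, seed = config$master_seed + 40L)
      rows <- co_idx[attr(one, "kept_rows")]
      covs <- cbind(covariate_block(cohort[rows, ],
                                    c("log10_transferrin", "age_months",
                                      if (sx == "M") "apgar5")),
                    if (!is.null(pcs)) pcs[rows, , drop = FALSE])
      y_res <- residualize(cohort$phenotype[rows], covs)
      G_res <- residualize(impute_colmeans(Gq)[rows, , drop = FALSE], covs)
      stab <- stability_selection(y_res, G_res, config$rf)
      emit(data.frame(snp = names(stab$counts),
                      appearances = unname(stab$counts),
                      in_intersection = names(stab$counts) %in% stab$intersection),
           sprintf("rf_stability_%s.tsv", sx))
      rf[[sx]] <- stab
    }
    stages$rf_selection <- lapply(rf, function(s)
      list(intersection = s$intersection))
  } else stages$rf_selection <- list(skipped = "disabled or panel too small")

  manifest <- write_manifest(
    file.path(out_dir, "manifest.json"),
    config = list(master_seed = config$master_seed,
                  n_individuals = config$cohort$n_individuals,
                  n_snps = config$cohort$n_snps,
                  n_bootstrap = config$n_bootstrap),
    seeds = list(master = config$master_seed,
                 generator = config$master_seed,
                 qc = config$master_seed + 10L,
                 bootstrap = config$master_seed + 20L,
                 power = config$master_seed + 30L,
                 rf = config$master_seed + 40L),
    files = out_files, stages = stages)

  structure(list(cohort = cohort, genotypes = Gq, pcs = pcs,
                 selection = selection, heritability = heritability,
                 association = assoc, power = power, rf = rf,
                 manifest = manifest, out_dir = out_dir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run:", x$out_dir, "\n")
  cat("  stages:", paste(names(x$manifest$stages), collapse = ", "), "\n")
  cat("  outputs:", length(x$manifest$files), "files (digests in manifest.json)\n")
  invisible(x)
}

#' Generate on-disk fixtures
#'
#' Writes a complete simulated dataset (cohort table, dosage matrix, VCF,
#' manifest) for tests and examples. `"tiny"` is a 10-family / 20-SNP
#' dataset that generates in well under a second; `"study_scale"` matches
#' the study cohort structure (222 infants: 27 MZ pairs, 27 same-sex plus 2
#' opposite-sex DZ pairs, 2 unpaired twins, 108 singletons) with a 500-SNP
#' panel.
#'
#' @param profile `"tiny"` or `"study_scale"`.
#' @param dir output directory.
#' @param seed master seed.
#' @return invisible list with the cohort, genotypes and file paths.
#' @export
make_fixtures <- function(profile = c("tiny", "study_scale"),
                          dir = tempfile("fixtures"), seed = 1L) {
  profile <- match.arg(profile)
  cfg <- switch(profile,
    tiny = cohort_config(n_mz_pairs = 3, n_dz_pairs = 3, n_os_dz_pairs = 0,
                         n_unpaired_twins = 0, n_singletons = 4,
                         n_snps = 20, seed = seed),
    study_scale = cohort_config(seed = seed))
  sim <- simulate_cohort(cfg)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cohort = file.path(dir, "cohort.tsv"),
             dosages = file.path(dir, "dosages.tsv"),
             vcf = file.path(dir, "genotypes.vcf"))
  write_cohort(sim$cohort, paths["cohort"])
  write_dosages(sim$genotypes, paths["dosages"])
  write_vcf(sim$genotypes, paths["vcf"])
  write_manifest(file.path(dir, "manifest.json"),
                 config = list(profile = profile, seed = seed,
                               n_individuals = cfg$n_individuals,
                               n_snps = cfg$n_snps),
                 seeds = list(master = seed),
                 files = c(paths, paste0(paths["dosages"], ".snps.tsv")))
  invisible(list(cohort = sim$cohort, genotypes = sim$genotypes,
                 config = cfg, paths = paths, dir = dir))
}
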