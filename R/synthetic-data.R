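## Synthetic twin-cohort generator: family structure, Mendelian genotypes,
## Table-1-style covariates and an ACE phenotype model.

#' Cohort structure configuration
#'
#' Describes the family composition, sex ratio and SNP panel of a simulated
#' cohort. The defaults reproduce the structure of the study cohort: 222
#' infants comprising 27 monozygotic (MZ) pairs, 27 same-sex dizygotic (DZ)
#' pairs, 2 opposite-sex DZ pairs, 2 unpaired twins and 108 singletons, with
#' 119 males expected out of 222.
#'
#' @param n_mz_pairs number of MZ twin pairs (same sex by construction).
#' @param n_dz_pairs number of same-sex DZ twin pairs.
#' @param n_os_dz_pairs number of opposite-sex DZ twin pairs.
#' @param n_unpaired_twins twins whose co-twin is absent; they retain a
#'   family ID with a single member, exercising degenerate-family handling.
#' @param n_singletons number of singleton infants.
#' @param sex_ratio probability that an individual (or same-sex pair) is male.
#' @param n_snps number of biallelic SNPs in the panel.
#' @param mafs vector of minor-allele frequencies in (0, 1), recycled or
#'   truncated to `n_snps`; default draws them uniformly on \[0.05, 0.5\]
#'   under `seed`.
#' @param missing_rate per-genotype missingness probability (default 0).
#' @param seed integer seed governing every random draw derived from this
#'   configuration.
#' @return an object of class `cohort_config` (a list).
#' @examples
#' cfg <- cohort_config(n_mz_pairs = 2, n_dz_pairs = 2, n_os_dz_pairs = 0,
#'                      n_unpaired_twins = 0, n_singletons = 4, n_snps = 10)
#' cfg$n_individuals
#' @export
cohort_config <- function(n_mz_pairs = 27, n_dz_pairs = 27, n_os_dz_pairs = 2,
                          n_unpaired_twins = 2, n_singletons = 108,
                          sex_ratio = 119 / 222, n_snps = 500, mafs = NULL,
                          missing_rate = 0, seed = 1L) {
  counts <- c(n_mz_pairs, n_dz_pairs, n_os_dz_pairs, n_unpaired_twins,
              n_singletons, n_snps)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (!is.finite(sex_ratio) || sex_ratio < 0 || sex_ratio > 1)
    stop("sex_ratio must lie in [0, 1]")
  if (!is.finite(missing_rate) || missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (is.null(mafs)) {
    if (n_snps > 0) {
      set.seed(seed)
      mafs <- runif(n_snps, 0.05, 0.5)
    } else mafs <- numeric(0)
  } else {
    if (any(!is.finite(mafs)) || any(mafs <= 0) || any(mafs >= 1))
      stop("mafs must be finite allele frequencies in (0, 1)")
    mafs <- rep_len(mafs, n_snps)
  }
  n_individuals <- 2L * (n_mz_pairs + n_dz_pairs + n_os_dz_pairs) +
    n_unpaired_twins + n_singletons
  structure(list(
    n_mz_pairs = as.integer(n_mz_pairs),
    n_dz_pairs = as.integer(n_dz_pairs),
    n_os_dz_pairs = as.integer(n_os_dz_pairs),
    n_unpaired_twins = as.integer(n_unpaired_twins),
    n_singletons = as.integer(n_singletons),
    n_individuals = as.integer(n_individuals),
    sex_ratio = sex_ratio, n_snps = as.integer(n_snps), mafs = mafs,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Cohort configuration:", x$n_individuals, "individuals\n")
  cat(sprintf("  %d MZ pairs, %d same-sex DZ pairs, %d opposite-sex DZ pairs,\n",
              x$n_mz_pairs, x$n_dz_pairs, x$n_os_dz_pairs))
  cat(sprintf("  %d unpaired twins, %d singletons; sex ratio %.3f\n",
              x$n_unpaired_twins, x$n_singletons, x$sex_ratio))
  cat(sprintf("  %d SNPs (MAF %.3f-%.3f), seed %d\n",
              x$n_snps, if (x$n_snps) min(x$mafs) else NA,
              if (x$n_snps) max(x$mafs) else NA, x$seed))
  invisible(x)
}

#' Phenotype generative model
#'
#' Parameters of the ACE generative model for the salivary testosterone
#' phenotype (pg/ml): additive-genetic deviates correlated 1 within MZ pairs
#' and 0.5 within DZ pairs, a shared-environment deviate common to a family,
#' and independent unique error. Covariate and per-SNP effects are added on
#' centred covariate scales so that `mu` remains the phenotype mean. Values
#' below the assay detection limit are coded as 0 pg/ml.
#'
#' Defaults place the phenotype at mean 40 pg/ml with SD ~13.4 and the
#' variance split a2 = 0, c2 = 0.627, e2 = 0.373 estimated for males in the
#' study cohort.
#'
#' @param mu phenotype mean, pg/ml.
#' @param sigma2_A,sigma2_C,sigma2_E additive-genetic, shared-environment and
#'   unique-error variances (pg/ml squared), each >= 0.
#' @param beta_snp named vector of per-allele SNP effects (pg/ml per allele);
#'   names are SNP IDs, or an unnamed vector recycled over the panel.
#' @param beta_cov named vector of covariate effects applied to both sexes;
#'   recognised names are cohort covariate columns (continuous covariates are
#'   centred at their generative means before multiplication).
#' @param beta_cov_male named vector of additional male-only covariate
#'   effects (e.g. the 5-min APGAR effect observed in males).
#' @param detection_limit assay detection limit, pg/ml; simulated values
#'   strictly below it are coded as 0.
#' @return an object of class `phenotype_model` (a list).
#' @export
phenotype_model <- function(mu = 40, sigma2_A = 0, sigma2_C = 112.6,
                            sigma2_E = 67.0, beta_snp = NULL,
                            beta_cov = c(log10_transferrin = 17.4),
                            beta_cov_male = c(apgar5 = -5.3),
                            detection_limit = 1.0) {
  if (any(!is.finite(c(sigma2_A, sigma2_C, sigma2_E))) ||
      any(c(sigma2_A, sigma2_C, sigma2_E) < 0))
    stop("variance components must be finite and >= 0")
  structure(list(mu = mu, sigma2_A = sigma2_A, sigma2_C = sigma2_C,
                 sigma2_E = sigma2_E, beta_snp = beta_snp,
                 beta_cov = beta_cov, beta_cov_male = beta_cov_male,
                 detection_limit = detection_limit),
            class = "phenotype_model")
}

#' @export
print.phenotype_model <- function(x, ...) {
  tot <- x$sigma2_A + x$sigma2_C + x$sigma2_E
  cat(sprintf("ACE phenotype model: mu = %.2f pg/ml, total SD = %.2f\n",
              x$mu, sqrt(tot)))
  cat(sprintf("  a2 = %.3f, c2 = %.3f, e2 = %.3f; detection limit %.2f pg/ml\n",
              x$sigma2_A / tot, x$sigma2_C / tot, x$sigma2_E / tot,
              x$detection_limit))
  invisible(x)
}

## Family skeleton: one row per individual with IDs, zygosity and sex.
## Deterministic given the config seed (offset 101).
make_family_frame <- function(config, seed = config$seed + 101L) {
  set.seed(seed)
  draw_sex <- function(n) ifelse(runif(n) < config$sex_ratio, "M", "F")
  n_mz <- config$n_mz_pairs; n_dz <- config$n_dz_pairs
  n_os <- config$n_os_dz_pairs; n_up <- config$n_unpaired_twins
  n_sg <- config$n_singletons
  ## family-level draws in a fixed order, then expanded to members
  pair_sex_mz <- draw_sex(n_mz)
  pair_sex_dz <- draw_sex(n_dz)
  os_first_male <- runif(n_os) < 0.5
  sex_up <- draw_sex(n_up)
  sex_sg <- draw_sex(n_sg)
  fam_sizes <- c(rep(2L, n_mz + n_dz + n_os), rep(1L, n_up + n_sg))
  n_fam <- length(fam_sizes)
  fam_id <- sprintf("fam%04d", rep(seq_len(n_fam), fam_sizes))
  zyg_fam <- c(rep("MZ", n_mz), rep("DZ", n_dz + n_os + n_up),
               rep("singleton", n_sg))
  sex <- c(rep(pair_sex_mz, each = 2), rep(pair_sex_dz, each = 2),
           as.vector(rbind(ifelse(os_first_male, "M", "F"),
                           ifelse(os_first_male, "F", "M"))),
           sex_up, sex_sg)
  out <- data.frame(
    individual_id = sprintf("ind%04d", seq_along(sex)),
    family_id = fam_id,
    zygosity = rep(zyg_fam, fam_sizes),
    sex = sex,
    complete_pair = rep(fam_sizes == 2L, fam_sizes),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate an additive-dosage genotype panel
#'
#' Generates dosages in \{0, 1, 2\} for every individual in the cohort.
#' MZ co-twins receive identical genotype rows. DZ co-twins are produced by
#' simulating two parental genotypes per family under Hardy-Weinberg
#' proportions and transmitting one uniformly chosen allele per parent per
#' child, which yields an expected within-pair dosage correlation of 0.5.
#' Singletons and unpaired twins are drawn directly from Hardy-Weinberg
#' proportions at each SNP's minor-allele frequency.
#'
#' @param config a [cohort_config()].
#' @param family_frame optional family skeleton (as produced internally);
#'   regenerated from `config` when omitted.
#' @param seed random seed (default derived from the config seed).
#' @return an integer matrix (individuals x SNPs) of class `genotype_matrix`
#'   with `dimnames`, plus attributes `mafs`, `positions` and `chrom`.
#' @examples
#' cfg <- cohort_config(n_mz_pairs = 1, n_dz_pairs = 1, n_os_dz_pairs = 0,
#'                      n_unpaired_twins = 0, n_singletons = 2, n_snps = 5)
#' G <- simulate_genotypes(cfg)
#' dim(G)
#' @export
simulate_genotypes <- function(config, family_frame = NULL,
                               seed = config$seed + 1L) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(family_frame)) family_frame <- make_family_frame(config)
  p <- config$n_snps
  mafs <- config$mafs
  n <- nrow(family_frame)
  set.seed(seed)
  G <- matrix(NA_integer_, n, p)
  hw_draw <- function(k) {
    ## k independent HWE genotypes at each of the p SNPs: k x p matrix
    matrix(rbinom(k * p, 2L, rep(mafs, each = k)), k, p)
  }
  fams <- split(seq_len(n), family_frame$family_id)
  for (idx in fams) {
    if (length(idx) == 1L) {
      G[idx, ] <- hw_draw(1L)
    } else {
      zyg <- family_frame$zygosity[idx[1L]]
      if (zyg == "MZ") {
        g <- hw_draw(1L)
        G[idx[1L], ] <- g
        G[idx[2L], ] <- g
      } else {
        par_g <- hw_draw(2L)                       # two parents
        for (child in idx) {
          ## one allele transmitted per parent: Bernoulli(g/2) per SNP
          a1 <- rbinom(p, 1L, par_g[1L, ] / 2)
          a2 <- rbinom(p, 1L, par_g[2L, ] / 2)
          G[child, ] <- a1 + a2
        }
      }
    }
  }
  if (config$missing_rate > 0) {
    miss <- matrix(runif(n * p) < config$missing_rate, n, p)
    G[miss] <- NA_integer_
  }
  dimnames(G) <- list(family_frame$individual_id,
                      sprintf("snp%04d", seq_len(p)))
  attr(G, "mafs") <- mafs
  attr(G, "chrom") <- rep("1", p)
  attr(G, "positions") <- 100000L * seq_len(p)
  class(G) <- c("genotype_matrix", class(G))
  G
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d individuals x %d SNPs, %.2f%% missing\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

## Generative marginals for the Table-1-style covariates; continuous
## covariates are centred at these means before phenotype effects apply.
covariate_centers <- c(log10_transferrin = -0.45 / log(10),
                       age_months = 3.34, apgar5 = 8.7,
                       birth_weight = 2900, gestational_age = 37.5,
                       maternal_age = 30, paternal_age = 32,
                       maternal_education = 15.7, paternal_education = 15.4)

#' Simulate demographic and medical-history covariates
#'
#' Draws the covariate block of the cohort table: salivary transferrin
#' (log-normal, mg/dl, right-skewed, mean ~0.88), age at saliva sampling
#' (months, restricted to \[2.70, 4.80\]), 5-min APGAR score (integer,
#' concentrated in 7-10, mean ~8.7), birth weight, gestational age, NICU
#' stay, delivery method, parental demographics, household income (with an
#' explicit "Missing" level) and maternal smoking. Shared-environment
#' covariates (parental variables, income, smoking, delivery method,
#' gestational age) are identical within a family; individual-level
#' covariates (transferrin, age, APGAR, birth weight, NICU) vary by infant.
#'
#' @inheritParams simulate_genotypes
#' @return a data.frame with one row per individual.
#' @export
simulate_covariates <- function(config, family_frame = NULL,
                                seed = config$seed + 2L) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(family_frame)) family_frame <- make_family_frame(config)
  set.seed(seed)
  n <- nrow(family_frame)
  fam <- factor(family_frame$family_id, levels = unique(family_frame$family_id))
  nf <- nlevels(fam)
  fi <- as.integer(fam)

  rtrunc_norm <- function(n, mean, sd, lo, hi) {
    x <- rnorm(n, mean, sd)
    while (any(bad <- x < lo | x > hi)) x[bad] <- rnorm(sum(bad), mean, sd)
    x
  }
  ## family-level draws, broadcast to members
  fam_draw <- function(gen) gen(nf)[fi]

  transferrin <- exp(rnorm(n, -0.45, 0.8))         # mg/dl, right-skewed
  age <- rtrunc_norm(nf, 3.34, 0.36, 2.70, 4.80)[fi]  # co-twins share a visit
  apgar <- sample(6:10, n, replace = TRUE,
                  prob = c(0.01, 0.06, 0.25, 0.55, 0.13))
  birth_weight <- rtrunc_norm(n, 2900, 650, 500, 5500)
  gestational_age <- fam_draw(function(k) rtrunc_norm(k, 37.5, 2.6, 26, 42))
  nicu <- factor(ifelse(runif(n) < 0.17, "Yes", "No"), levels = c("No", "Yes"))
  csection <- fam_draw(function(k)
    factor(ifelse(runif(k) < 0.48, "Yes", "No"), levels = c("No", "Yes")))
  eth_levels <- c("White", "Black", "Asian", "Other")
  maternal_ethnicity <- fam_draw(function(k)
    factor(sample(eth_levels, k, TRUE, prob = c(0.77, 0.20, 0.02, 0.01)),
           levels = eth_levels))
  paternal_ethnicity <- fam_draw(function(k)
    factor(sample(eth_levels, k, TRUE, prob = c(0.75, 0.20, 0.04, 0.01)),
           levels = eth_levels))
  maternal_age <- fam_draw(function(k) rtrunc_norm(k, 30, 5.7, 16, 48))
  paternal_age <- fam_draw(function(k) rtrunc_norm(k, 32, 6.0, 16, 60))
  maternal_education <- fam_draw(function(k) rtrunc_norm(k, 15.7, 3.1, 6, 24))
  paternal_education <- fam_draw(function(k) rtrunc_norm(k, 15.4, 3.1, 6, 24))
  maternal_psych <- fam_draw(function(k)
    factor(ifelse(runif(k) < 0.21, "Yes", "No"), levels = c("No", "Yes")))
  paternal_psych <- fam_draw(function(k)
    factor(ifelse(runif(k) < 0.11, "Yes", "No"), levels = c("No", "Yes")))
  income_levels <- c("Low", "Middle", "High", "Missing")
  income <- fam_draw(function(k)
    factor(sample(income_levels, k, TRUE, prob = c(0.29, 0.38, 0.31, 0.02)),
           levels = income_levels))
  maternal_smoking <- fam_draw(function(k)
    factor(ifelse(runif(k) < 0.10, "Yes", "No"), levels = c("No", "Yes")))
  gestation_number <- factor(
    ifelse(family_frame$zygosity == "singleton", "Singleton", "Twin"),
    levels = c("Singleton", "Twin"))

  data.frame(transferrin = transferrin, age_months = age, apgar5 = apgar,
             birth_weight = birth_weight, gestational_age = gestational_age,
             nicu_stay = nicu, csection = csection,
             maternal_ethnicity = maternal_ethnicity,
             paternal_ethnicity = paternal_ethnicity,
             maternal_age = maternal_age, paternal_age = paternal_age,
             maternal_education = maternal_education,
             paternal_education = paternal_education,
             maternal_psych = maternal_psych, paternal_psych = paternal_psych,
             income = income, maternal_smoking = maternal_smoking,
             gestation_number = gestation_number,
             stringsAsFactors = FALSE)
}

#' Simulate the ACE phenotype
#'
#' Builds the phenotype as
#' `mu + X beta_cov + G beta_snp + a + c + e`, where `a` is an
#' additive-genetic deviate with within-pair correlation 1 (MZ), 0.5 (DZ) and
#' 0 between unrelated individuals (simulated as bivariate normal per pair),
#' `c` is shared within a family, and `e` is independent. Continuous
#' covariates are centred at their generative means before effects apply, so
#' `mu` is the phenotype mean. Values strictly below the detection limit are
#' coded as 0 pg/ml.
#'
#' @param cohort a cohort data.frame (family skeleton plus covariates), as
#'   built by [simulate_cohort()].
#' @param genotypes a `genotype_matrix` aligned row-wise with `cohort`, or
#'   `NULL` when `model$beta_snp` is empty.
#' @param model a [phenotype_model()].
#' @param seed random seed.
#' @return numeric phenotype vector, pg/ml.
#' @export
simulate_phenotype <- function(cohort, genotypes, model, seed = 1L) {
  stopifnot(inherits(model, "phenotype_model"))
  n <- nrow(cohort)
  if (!is.null(genotypes) && nrow(genotypes) != n)
    stop("cohort and genotypes have mismatched dimensions")
  set.seed(seed)
  sA <- model$sigma2_A; sC <- model$sigma2_C; sE <- model$sigma2_E

  fam <- factor(cohort$family_id, levels = unique(cohort$family_id))
  fi <- as.integer(fam)
  nf <- nlevels(fam)
  ## shared environment: one deviate per family
  c_dev <- (sqrt(sC) * rnorm(nf))[fi]
  ## additive genetic: bivariate normal per pair with zygosity correlation
  first_of_fam <- !duplicated(fi)
  second_of_fam <- duplicated(fi)
  z1 <- rnorm(nf)                             # one per family
  z2 <- rnorm(n)                              # per-individual innovation
  a_dev <- numeric(n)
  a_dev[first_of_fam] <- sqrt(sA) * z1
  r <- ifelse(cohort$zygosity[second_of_fam] == "MZ", 1, 0.5)
  a_dev[second_of_fam] <- sqrt(sA) *
    (r * z1[fi[second_of_fam]] + sqrt(1 - r^2) * z2[second_of_fam])
  e_dev <- sqrt(sE) * rnorm(n)

  eff <- rep(model$mu, n)
  apply_betas <- function(eff, betas, rows) {
    for (nm in names(betas)) {
      v <- if (nm == "log10_transferrin") log10(cohort$transferrin) else cohort[[nm]]
      if (is.null(v)) stop("unknown covariate in beta_cov: ", nm)
      ctr <- if (nm %in% names(covariate_centers)) covariate_centers[[nm]] else mean(v)
      eff[rows] <- eff[rows] + betas[[nm]] * (v[rows] - ctr)
    }
    eff
  }
  eff <- apply_betas(eff, model$beta_cov, seq_len(n))
  if (length(model$beta_cov_male))
    eff <- apply_betas(eff, model$beta_cov_male, which(cohort$sex == "M"))
  if (!is.null(model$beta_snp) && length(model$beta_snp) && !is.null(genotypes)) {
    bs <- model$beta_snp
    if (is.null(names(bs))) {
      bs <- rep_len(bs, ncol(genotypes))
      names(bs) <- colnames(genotypes)
    }
    Gsub <- genotypes[, names(bs), drop = FALSE]
    Gsub[is.na(Gsub)] <- 0
    ## centre dosages at 2*MAF so mu stays the phenotype mean
    m2 <- 2 * attr(genotypes, "mafs")[match(names(bs), colnames(genotypes))]
    eff <- eff + as.vector(sweep(Gsub, 2, m2) %*% bs)
  }
  y <- eff + a_dev + c_dev + e_dev
  code_below_detection(pmax(y, 0), model$detection_limit)
}

#' Simulate a complete twin cohort
#'
#' Convenience wrapper tying the generator together: family skeleton,
#' genotypes, covariates and phenotype, all driven by the configuration seed.
#'
#' @param config a [cohort_config()].
#' @param model a [phenotype_model()].
#' @return a list of class `twin_cohort` with elements `cohort` (data.frame,
#'   one row per infant), `genotypes` (`genotype_matrix` or `NULL`), `config`
#'   and `model`.
#' @examples
#' sim <- simulate_cohort(cohort_config(n_mz_pairs = 3, n_dz_pairs = 3,
#'                                      n_os_dz_pairs = 0, n_unpaired_twins = 0,
#'                                      n_singletons = 4, n_snps = 8))
#' head(sim$cohort)
#' @export
simulate_cohort <- function(config = cohort_config(),
                            model = phenotype_model()) {
  ff <- make_family_frame(config)
  G <- if (config$n_snps > 0) simulate_genotypes(config, ff) else NULL
  cov <- simulate_covariates(config, ff)
  cohort <- cbind(ff, cov, stringsAsFactors = FALSE)
  cohort$phenotype <- simulate_phenotype(cohort, G, model,
                                         seed = config$seed + 3L)
  structure(list(cohort = cohort, genotypes = G, config = config,
                 model = model), class = "twin_cohort")
}

#' @export
print.twin_cohort <- function(x, ...) {
  cat(sprintf("Simulated twin cohort: %d infants (%d M, %d F), %d families\n",
              nrow(x$cohort), sum(x$cohort$sex == "M"),
              sum(x$cohort$sex == "F"),
              length(unique(x$cohort$family_id))))
  cat(sprintf("  phenotype mean %.2f pg/ml (SD %.2f); %s SNPs\n",
              mean(x$cohort$phenotype), sd(x$cohort$phenotype),
              if (is.null(x$genotypes)) "no" else ncol(x$genotypes)))
  invisible(x)
}
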