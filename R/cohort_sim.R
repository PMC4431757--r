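#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the marginal structure of a Japanese
#' population-based obesity cohort of adults aged 40-84: baseline BMI mean
#' 23.4 (SD 3.1, observed range 15.0-35.5 kg/m2), physical-activity
#' expenditure mean 36.2 (SD 5.8) METs-h/day, caloric intake mean 2,257
#' (SD 673) kcal/day, a 29-locus weighted genetic predisposition score with
#' mean near 26, a men:women ratio of 726:894, 5-7 year follow-up with
#' yearly BMI drift mean -0.02 (SD 0.22), and roughly two-thirds follow-up
#' completion.
#'
#' Baseline BMI is generated from an additive structural model
#' \deqn{BMI_i = b_0 + b_{sex} 1[woman_i] + b_{age} age_i + \gamma GPS_i +
#'       \delta_{int} intake_i + \delta_{exp} expenditure_i + \epsilon_i,}
#' \eqn{\epsilon \sim N(0, \sigma)}, truncated to \code{bmi_bounds} by
#' resampling.  Genotypes are drawn per locus as Binomial(2, f) under
#' Hardy-Weinberg equilibrium, where f is the effect-allele frequency.
#'
#' @param n_subjects cohort size (default 1620).
#' @param seed RNG seed; every draw in [simulate_cohort()] flows from it.
#' @param L number of SNP loci in the genetic score (default 29).
#' @param effect_allele_freq per-locus effect-allele frequencies in (0, 1);
#'   \code{NULL} (default) draws them once from U(0.2, 0.7).  The effect
#'   (BMI-increasing) allele need not be the minor allele.
#' @param beta per-locus GWAS effect sizes; \code{NULL} draws U(0.05, 0.35).
#' @param age_range inclusive integer age bounds (discrete uniform).
#' @param sex_ratio men:women counts used as sampling weights.
#' @param intake_mean,intake_sd,intake_min intake distribution, kcal/day,
#'   normal truncated below at \code{intake_min}.
#' @param expenditure_mean,expenditure_sd,expenditure_min expenditure
#'   distribution, METs-h/day, truncated below.
#' @param b0,b_sex,b_age,gamma_gps,delta_intake,delta_expenditure,sigma_noise
#'   structural coefficients of the BMI model (units: kg/m2 per unit of each
#'   covariate; \code{sigma_noise >= 0}).
#' @param bmi_bounds truncation interval for generated BMI, kg/m2.
#' @param followup_fraction fraction of subjects completing follow-up.
#' @param followup_interval min/max of the uniform follow-up interval, years.
#' @param drift_mean,drift_sd yearly BMI drift distribution, kg/m2/year.
#' @param drift_gps,drift_efficiency optional structural dependence of the
#'   drift mean on the (centred) genetic score / efficiency score, for power
#'   studies; both default to 0 (pure-noise drift).
#' @return list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_subjects = 1620L,
                       seed = 20150514L,
                       L = 29L,
                       effect_allele_freq = NULL,
                       beta = NULL,
                       age_range = c(40L, 84L),
                       sex_ratio = c(men = 726, women = 894),
                       intake_mean = 2257, intake_sd = 673, intake_min = 300,
                       expenditure_mean = 36.2, expenditure_sd = 5.8,
                       expenditure_min = 20,
                       b0 = 19.2, b_sex = -0.4, b_age = 0.02,
                       gamma_gps = 0.06, delta_intake = 0.002,
                       delta_expenditure = -0.08, sigma_noise = 2.6,
                       bmi_bounds = c(15, 36),
                       followup_fraction = 1079 / 1620,
                       followup_interval = c(5, 7),
                       drift_mean = -0.02, drift_sd = 0.22,
                       drift_gps = 0, drift_efficiency = 0) {
  cfg <- list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
              L = as.integer(L), effect_allele_freq = effect_allele_freq,
              beta = beta, age_range = as.integer(age_range),
              sex_ratio = sex_ratio,
              intake_mean = intake_mean, intake_sd = intake_sd,
              intake_min = intake_min,
              expenditure_mean = expenditure_mean,
              expenditure_sd = expenditure_sd,
              expenditure_min = expenditure_min,
              b0 = b0, b_sex = b_sex, b_age = b_age, gamma_gps = gamma_gps,
              delta_intake = delta_intake,
              delta_expenditure = delta_expenditure,
              sigma_noise = sigma_noise, bmi_bounds = bmi_bounds,
              followup_fraction = followup_fraction,
              followup_interval = followup_interval,
              drift_mean = drift_mean, drift_sd = drift_sd,
              drift_gps = drift_gps, drift_efficiency = drift_efficiency)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_subjects < 0L) stop("n_subjects must be >= 0")
  if (cfg$L < 1L) stop("at least one locus is required")
  if (cfg$sigma_noise < 0) stop("sigma_noise must be >= 0")
  if (cfg$drift_sd < 0) stop("drift_sd must be >= 0")
  if (!is.null(cfg$effect_allele_freq)) {
    f <- cfg$effect_allele_freq
    if (length(f) != cfg$L || any(f <= 0 | f >= 1)) {
      stop("effect_allele_freq must be length L with values in (0, 1)")
    }
  }
  if (!is.null(cfg$beta) &&
      (length(cfg$beta) != cfg$L || any(cfg$beta <= 0))) {
    stop("beta must be length L and strictly positive")
  }
  if (cfg$intake_min <= 0 || cfg$expenditure_min <= 0) {
    stop("truncation bounds must be positive")
  }
  if (cfg$followup_fraction < 0 || cfg$followup_fraction > 1) {
    stop("followup_fraction must be in [0, 1]")
  }
  if (diff(cfg$bmi_bounds) <= 0 || cfg$bmi_bounds[1L] <= 0) {
    stop("bmi_bounds must be an increasing positive interval")
  }
  invisible(cfg)
}

# normal draw truncated below (and optionally above) by resampling
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf, max_iter = 1000L) {
  x <- stats::rnorm(n, mean, sd)
  for (i in seq_len(max_iter)) {
    bad <- x < lower | x > upper
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lower), upper)
}

#' Simulate a baseline cohort with genotypes and genetic scores
#'
#' Draws demographics, diet/exercise, Hardy-Weinberg genotypes, the
#' weighted genetic predisposition score, and structural-model BMI as
#' configured in [sim_config()].  Identical configurations (including seed)
#' produce identical output.
#'
#' @param config a [sim_config()].
#' @return list of class \code{"cohort_sim"} with elements
#'   \describe{
#'     \item{cohort}{data frame: subject_id, age, sex, bmi_baseline,
#'       energy_intake_kcal, energy_expenditure_mets_h, gps}
#'     \item{genotypes}{a [genotype_matrix()] (subjects x L)}
#'     \item{weights}{a [snp_weight_set()]}
#'     \item{truth}{all generating parameters, frequencies and weights}
#'   }
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_subjects; L <- config$L

  freq <- config$effect_allele_freq
  if (is.null(freq)) freq <- stats::runif(L, 0.2, 0.7)
  beta <- config$beta
  if (is.null(beta)) beta <- stats::runif(L, 0.05, 0.35)
  snp_ids <- sprintf("rs%05d", seq_len(L))
  bases <- c("A", "C", "G", "T")
  eff_allele <- sample(bases, L, replace = TRUE)
  other_allele <- vapply(eff_allele,
                         function(b) sample(setdiff(bases, b), 1L), "")
  eff_is_ref <- stats::runif(L) < 0.5
  weights <- snp_weight_set(snp_ids, eff_allele, beta)

  if (n == 0L) {
    cohort <- data.frame(subject_id = character(0), age = integer(0),
                         sex = character(0), bmi_baseline = numeric(0),
                         energy_intake_kcal = numeric(0),
                         energy_expenditure_mets_h = numeric(0),
                         gps = numeric(0), stringsAsFactors = FALSE)
    geno <- genotype_matrix(matrix(numeric(0), 0L, L,
                                   dimnames = list(NULL, snp_ids)),
                            maf = pmin(freq, 1 - freq),
                            call_rate = rep(1, L))
    return(structure(list(cohort = cohort, genotypes = geno,
                          weights = weights,
                          truth = sim_truth(config, freq, beta, eff_is_ref,
                                            other_allele)),
                     class = "cohort_sim"))
  }

  age <- sample(seq(config$age_range[1L], config$age_range[2L]), n,
                replace = TRUE)
  sex <- sample(c("man", "woman"), n, replace = TRUE,
                prob = config$sex_ratio / sum(config$sex_ratio))
  intake <- rtruncnorm(n, config$intake_mean, config$intake_sd,
                       lower = config$intake_min)
  expenditure <- rtruncnorm(n, config$expenditure_mean, config$expenditure_sd,
                            lower = config$expenditure_min)

  dos <- vapply(freq, function(f) stats::rbinom(n, 2L, f), numeric(n))
  if (n == 1L) dos <- matrix(dos, nrow = 1L)
  colnames(dos) <- snp_ids
  geno <- genotype_matrix(dos, maf = pmin(freq, 1 - freq),
                          call_rate = rep(1, L))
  gps <- compute_gps(geno, weights)

  mu <- config$b0 + config$b_sex * (sex == "woman") + config$b_age * age +
    config$gamma_gps * gps + config$delta_intake * intake +
    config$delta_expenditure * expenditure
  # per-subject truncation by resampling the noise term
  if (config$sigma_noise > 0) {
    bmi <- mu + stats::rnorm(n, 0, config$sigma_noise)
    for (i in seq_len(1000L)) {
      bad <- bmi < config$bmi_bounds[1L] | bmi > config$bmi_bounds[2L]
      if (!any(bad)) break
      bmi[bad] <- mu[bad] + stats::rnorm(sum(bad), 0, config$sigma_noise)
    }
    bmi <- pmin(pmax(bmi, config$bmi_bounds[1L]), config$bmi_bounds[2L])
  } else {
    bmi <- pmin(pmax(mu, config$bmi_bounds[1L]), config$bmi_bounds[2L])
  }

  cohort <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    age = age, sex = sex, bmi_baseline = bmi,
    energy_intake_kcal = intake,
    energy_expenditure_mets_h = expenditure,
    gps = gps, stringsAsFactors = FALSE
  )
  rownames(dos) <- cohort$subject_id
  geno <- genotype_matrix(dos, maf = pmin(freq, 1 - freq),
                          call_rate = rep(1, L))
  structure(list(cohort = cohort, genotypes = geno, weights = weights,
                 truth = sim_truth(config, freq, beta, eff_is_ref,
                                   other_allele)),
            class = "cohort_sim")
}

sim_truth <- function(config, freq, beta, eff_is_ref, other_allele) {
  c(unclass(config)[c("n_subjects", "seed", "L", "b0", "b_sex", "b_age",
                      "gamma_gps", "delta_intake", "delta_expenditure",
                      "sigma_noise", "followup_fraction", "drift_mean",
                      "drift_sd", "drift_gps", "drift_efficiency")],
    list(effect_allele_freq = freq, beta = beta,
         effect_allele_is_ref = eff_is_ref, other_allele = other_allele))
}

#' Add follow-up BMI to a simulated cohort
#'
#' Assigns each completer a follow-up interval drawn uniformly from
#' \code{followup_interval} years and a yearly BMI drift
#' \eqn{N(\mu_d, \sigma_d)} where \eqn{\mu_d} may optionally depend on the
#' centred genetic and efficiency scores; the remaining subjects (attrition)
#' get NA follow-up fields.  Seeded from \code{config$seed + 1} so baseline
#' and follow-up generation are independently reproducible.
#'
#' @param cohort baseline cohort data frame (from [simulate_cohort()]; an
#'   \code{efficiency} column is required only when
#'   \code{drift_efficiency != 0}).
#' @param config the same [sim_config()] used at baseline.
#' @return the cohort with columns \code{bmi_followup},
#'   \code{followup_years} appended.
#' @export
simulate_followup <- function(cohort, config = sim_config()) {
  validate_sim_config(config)
  n <- nrow(cohort)
  set.seed(config$seed + 1L)
  if (n == 0L) {
    cohort$bmi_followup <- numeric(0)
    cohort$followup_years <- numeric(0)
    return(cohort)
  }
  n_fu <- round(config$followup_fraction * n)
  completer <- rep(FALSE, n)
  completer[sample.int(n, n_fu)] <- TRUE

  mu_d <- rep(config$drift_mean, n)
  if (config$drift_gps != 0) {
    mu_d <- mu_d + config$drift_gps * (cohort$gps - mean(cohort$gps))
  }
  if (config$drift_efficiency != 0) {
    if (is.null(cohort$efficiency)) {
      stop("drift_efficiency != 0 requires an efficiency column")
    }
    mu_d <- mu_d + config$drift_efficiency *
      (cohort$efficiency - mean(cohort$efficiency))
  }
  interval <- stats::runif(n, config$followup_interval[1L],
                           config$followup_interval[2L])
  drift <- stats::rnorm(n, mu_d, config$drift_sd)
  cohort$bmi_followup <- ifelse(completer,
                                cohort$bmi_baseline + drift * interval,
                                NA_real_)
  cohort$followup_years <- ifelse(completer, interval, NA_real_)
  cohort
}

#' Write simulator artifacts to disk
#'
#' Serialises the cohort CSV, SNP-weights TSV, dosage CSV, and the truth
#' record (JSON) into \code{dir}, the same formats the analysis functions
#' read back.
#'
#' @param sim a \code{"cohort_sim"} from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_cohort_artifacts <- function(sim, dir) {
  stopifnot(inherits(sim, "cohort_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cohort  = file.path(dir, "cohort.csv"),
             weights = file.path(dir, "weights.tsv"),
             dosages = file.path(dir, "dosages.csv"),
             truth   = file.path(dir, "truth.json"))
  write_cohort_csv(sim$cohort, paths["cohort"])
  write_snp_weights(sim$weights, paths["weights"])
  dos <- as.data.frame(unclass(sim$genotypes))
  dos <- cbind(subject_id = rownames(dos), dos)
  utils::write.csv(dos, paths["dosages"], row.names = FALSE, quote = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE,
                         digits = NA)
  } else {
    dput(sim$truth, file = paths["truth"])
  }
  invisible(paths)
}

#' Write a minimal VCF for a genotype matrix
#'
#' Emits a VCF 4.2 with GT-only records for integer dosages (0/0, 0/1,
#' 1/1; NA becomes ./.), one biallelic record per SNP.  Allele orientation
#' follows \code{effect_is_ref}: where TRUE the effect allele is written as
#' REF (so readers must flip the ALT count), otherwise as ALT.
#'
#' @param genotypes a [genotype_matrix()] of integer effect-allele dosages.
#' @param weights the matching [snp_weight_set()].
#' @param path output path.
#' @param effect_is_ref logical, length L (default all FALSE).
#' @param other_allele the non-effect allele per SNP (default: any base
#'   different from the effect allele).
#' @return \code{path}, invisibly.
#' @export
write_minimal_vcf <- function(genotypes, weights, path,
                              effect_is_ref = rep(FALSE, nrow(weights)),
                              other_allele = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(weights, "snp_weight_set"))
  A <- unclass(genotypes)[, weights$snp_id, drop = FALSE]
  if (any(A[!is.na(A)] != round(A[!is.na(A)]))) {
    stop("write_minimal_vcf supports integer dosages only (GT hard calls)")
  }
  L <- nrow(weights)
  if (is.null(other_allele)) {
    other_allele <- vapply(weights$effect_allele,
                           function(b) setdiff(c("A", "C", "G", "T"), b)[1L], "")
  }
  gt_string <- function(alt_dose) {
    ifelse(is.na(alt_dose), "./.",
           c("0/0", "0/1", "1/1")[alt_dose + 1L])
  }
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(A)), collapse = "\t"))
  for (l in seq_len(L)) {
    eff_dose <- A[, l]
    alt_dose <- if (effect_is_ref[l]) 2L - eff_dose else eff_dose
    ref <- if (effect_is_ref[l]) weights$effect_allele[l] else other_allele[l]
    alt <- if (effect_is_ref[l]) other_allele[l] else weights$effect_allele[l]
    lines <- c(lines,
               paste(c("1", as.character(1000L + l), weights$snp_id[l], ref,
                       alt, ".", "PASS", ".", "GT", gt_string(alt_dose)),
                     collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
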