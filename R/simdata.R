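#' Configuration for the synthetic lipidomics study generator
#'
#' Defines a two-class untargeted LC-MS plasma study with the run
#' structure the pipeline assumes: pooled study-QC (SQC) injections, a
#' seven-concentration SQC dilution series with replicates at the start
#' and end of the run, long-term reference (LTR) injections interleaved
#' every ten study samples, multiplicative injection-order drift, and
#' planted class-discriminating and age-associated features.
#'
#' Coefficients of variation are given on the natural intensity scale and
#' converted exactly to log-normal sigma via `sqrt(log(1 + cv^2))`.
#'
#' @param n_per_class Study samples per class (bacterial and viral).
#' @param n_features Total number of metabolic features.
#' @param n_discriminatory Number of planted class-effect features (half
#'   up in bacterial, half up in viral).
#' @param effect_size Standardized mean log-intensity shift between the
#'   classes for planted features (units of total log SD).
#' @param n_age_assoc Number of planted age-associated features.
#' @param age_effect_size Standardized log-intensity difference between
#'   samples above vs below the median age for age-associated features.
#' @param tech_cv Technical coefficient of variation of replicate
#'   injections (fraction).
#' @param bio_cv Biological coefficient of variation of study samples
#'   (fraction); must exceed `tech_cv`.
#' @param n_sqc Number of undiluted SQC injections.
#' @param n_ltr Number of LTR injections.
#' @param dilution_factors Ordered vector of 7 relative SQC
#'   concentrations.
#' @param dilution_replicates Replicate injections per concentration (one
#'   block at the start and one at the end of the run when 2).
#' @param drift_slope Multiplicative log-intensity drift per injection.
#' @param frac_noise_features Fraction of features that are
#'   non-dilution-responsive artifacts (background ions).
#' @param missing_rate Fraction of intensity cells set missing; default 0
#'   (a filtered feature table is complete).
#' @param seed Integer random seed; fixed seed gives bit-identical output.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_per_class = 20,
                       n_features = 4000,
                       n_discriminatory = 40,
                       effect_size = 1.0,
                       n_age_assoc = 5,
                       age_effect_size = 1.0,
                       tech_cv = 0.05,
                       bio_cv = 0.35,
                       n_sqc = 8,
                       n_ltr = 4,
                       dilution_factors = 2^-(0:6),
                       dilution_replicates = 2,
                       drift_slope = 5e-4,
                       frac_noise_features = 0.1,
                       missing_rate = 0,
                       seed = 1) {
  cfg <- list(n_per_class = n_per_class, n_features = n_features,
              n_discriminatory = n_discriminatory, effect_size = effect_size,
              n_age_assoc = n_age_assoc, age_effect_size = age_effect_size,
              tech_cv = tech_cv, bio_cv = bio_cv, n_sqc = n_sqc,
              n_ltr = n_ltr, dilution_factors = dilution_factors,
              dilution_replicates = dilution_replicates,
              drift_slope = drift_slope,
              frac_noise_features = frac_noise_features,
              missing_rate = missing_rate, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    rlang::abort(sprintf("invalid sim_config field '%s': %s", field, why),
                 class = "lipidsig_error")
  }
  count1 <- function(field, x, min = 1) {
    if (length(x) != 1 || !is.finite(x) || x < min || x != round(x)) {
      bad(field, sprintf("must be a single integer >= %d", min))
    }
  }
  count1("n_per_class", cfg$n_per_class, 2)
  count1("n_features", cfg$n_features)
  count1("n_discriminatory", cfg$n_discriminatory, 0)
  count1("n_age_assoc", cfg$n_age_assoc, 0)
  count1("n_sqc", cfg$n_sqc, 0)
  count1("n_ltr", cfg$n_ltr, 0)
  count1("dilution_replicates", cfg$dilution_replicates)
  count1("seed", cfg$seed, 0)
  if (!is.finite(cfg$tech_cv) || cfg$tech_cv <= 0) {
    bad("tech_cv", "must be > 0")
  }
  if (!is.finite(cfg$bio_cv) || cfg$bio_cv <= cfg$tech_cv) {
    bad("bio_cv", "must exceed tech_cv")
  }
  if (length(cfg$dilution_factors) != 7 ||
      any(!is.finite(cfg$dilution_factors) | cfg$dilution_factors <= 0)) {
    bad("dilution_factors", "must be 7 strictly positive concentrations")
  }
  if (!is.finite(cfg$effect_size) || cfg$effect_size < 0) {
    bad("effect_size", "must be >= 0")
  }
  if (!is.finite(cfg$age_effect_size) || cfg$age_effect_size < 0) {
    bad("age_effect_size", "must be >= 0")
  }
  if (!is.finite(cfg$drift_slope)) bad("drift_slope", "must be finite")
  if (cfg$frac_noise_features < 0 || cfg$frac_noise_features >= 1) {
    bad("frac_noise_features", "must be in [0, 1)")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    bad("missing_rate", "must be in [0, 1)")
  }
  n_noise <- round(cfg$frac_noise_features * cfg$n_features)
  if (cfg$n_discriminatory + cfg$n_age_assoc + n_noise > cfg$n_features) {
    bad("n_features",
        "too small to hold disjoint discriminatory, age and noise sets")
  }
  invisible(cfg)
}

cv_to_sdlog <- function(cv) sqrt(log1p(cv^2))

#' Simulate a two-class lipidomics study with ground truth
#'
#' Generates a [feature_table()] following a multiplicative (log-normal)
#' intensity model: per-feature base abundances are drawn log-normally
#' across features; a study sample's intensity is base level times a
#' class effect (planted features only, on the log scale), a log-linear
#' age effect (planted age features), biological log-normal noise,
#' injection-order drift, and technical log-normal noise. SQC injections
#' measure the per-feature pooled mean of the study samples with
#' technical noise only; dilution-series injections scale that pooled
#' level by the dilution factor for dilution-responsive features and stay
#' constant for artifact (noise) features; LTR injections measure an
#' independent pooled plasma level. Ages are drawn log-uniformly on 1-102
#' months (median near 9-10 months) and sex is Bernoulli(0.5).
#'
#' @param config A [sim_config()].
#' @return A list with elements `table` (a [feature_table()]) and `truth`
#'   (class `sim_truth`: tibble `discriminatory` with `feature_id` and
#'   `direction`, plus `age_assoc_ids` and `noise_ids`).
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_study_impl(config))
}

simulate_study_impl <- function(cfg) {
  n_study <- 2 * cfg$n_per_class
  p <- cfg$n_features
  feature_id <- sprintf("F%04d", seq_len(p))

  sd_tech <- cv_to_sdlog(cfg$tech_cv)
  sd_bio <- cv_to_sdlog(cfg$bio_cv)
  sd_total <- sqrt(sd_tech^2 + sd_bio^2)

  n_noise <- round(cfg$frac_noise_features * p)
  ids <- sample.int(p, cfg$n_discriminatory + cfg$n_age_assoc + n_noise)
  disc_idx <- ids[seq_len(cfg$n_discriminatory)]
  age_idx <- ids[cfg$n_discriminatory + seq_len(cfg$n_age_assoc)]
  noise_idx <- ids[cfg$n_discriminatory + cfg$n_age_assoc + seq_len(n_noise)]

  # class effect: +delta/2 in bacterial, -delta/2 in viral (log scale)
  delta <- cfg$effect_size * sd_total
  sign_j <- numeric(p)
  if (cfg$n_discriminatory > 0) {
    sign_j[disc_idx] <- rep(c(1, -1), length.out = cfg$n_discriminatory)
  }

  base_mu <- stats::rnorm(p, mean = 11, sd = 1.5)

  # study covariates
  class <- rep(c("bacterial", "viral"), each = cfg$n_per_class)
  age <- exp(stats::runif(n_study, log(1), log(102)))
  sex <- ifelse(stats::rbinom(n_study, 1, 0.5) == 1, "M", "F")
  # age slope so that the above/below-median log-mean difference equals
  # age_effect_size * sd_total (log-age is uniform, so the half-means
  # differ by half the log-age range)
  la <- log(age) - mean(c(log(1), log(102)))
  half_gap <- (log(102) - log(1)) / 4
  beta_age <- numeric(p)
  beta_age[age_idx] <- (cfg$age_effect_size * sd_total) / (2 * half_gap)

  ybac <- as.numeric(class == "bacterial") # 1 bacterial, 0 viral
  class_shift <- outer(ybac - 0.5, sign_j * delta)     # n_study x p
  age_shift <- outer(la, beta_age)
  bio_noise <- matrix(stats::rnorm(n_study * p, 0, sd_bio), n_study, p)
  log_bio <- matrix(base_mu, n_study, p, byrow = TRUE) +
    class_shift + age_shift + bio_noise   # biological level, pre-acquisition

  pooled <- colMeans(exp(log_bio))        # physical pooling of all samples
  ltr_level <- exp(base_mu + stats::rnorm(p, 0, sd_bio)) # external pool

  # injection sequence: dilution block 1, then per 10 study samples
  # [SQC, 5 study, LTR, 5 study], spare SQC/LTR appended, dilution block 2+
  n_dil_levels <- length(cfg$dilution_factors)
  study_order <- sample.int(n_study)      # acquisition order of study samples
  seq_roles <- character(0); seq_which <- integer(0); seq_dil <- numeric(0)
  push <- function(role, which = NA_integer_, dil = NA_real_) {
    seq_roles <<- c(seq_roles, role)
    seq_which <<- c(seq_which, which)
    seq_dil <<- c(seq_dil, dil)
  }
  dil_block <- function(rep_no) {
    for (l in seq_len(n_dil_levels)) {
      push("dilution", which = (rep_no - 1L) * n_dil_levels + l,
           dil = cfg$dilution_factors[l])
    }
  }
  first_blocks <- ceiling(cfg$dilution_replicates / 2)
  for (r in seq_len(first_blocks)) dil_block(r)
  sqc_used <- 0L; ltr_used <- 0L; si <- 0L
  while (si < n_study) {
    if (sqc_used < cfg$n_sqc) { sqc_used <- sqc_used + 1L; push("sqc", sqc_used) }
    for (k in seq_len(min(5L, n_study - si))) { si <- si + 1L; push("study", study_order[si]) }
    if (ltr_used < cfg$n_ltr) { ltr_used <- ltr_used + 1L; push("ltr", ltr_used) }
    for (k in seq_len(min(5L, n_study - si))) { si <- si + 1L; push("study", study_order[si]) }
  }
  while (sqc_used < cfg$n_sqc) { sqc_used <- sqc_used + 1L; push("sqc", sqc_used) }
  while (ltr_used < cfg$n_ltr) { ltr_used <- ltr_used + 1L; push("ltr", ltr_used) }
  for (r in seq_len(cfg$dilution_replicates - first_blocks)) {
    dil_block(first_blocks + r)
  }

  n_total <- length(seq_roles)
  order_idx <- seq_len(n_total)
  drift <- cfg$drift_slope * order_idx

  log_level <- matrix(NA_real_, n_total, p)
  is_resp <- rep(TRUE, p); is_resp[noise_idx] <- FALSE
  for (i in order_idx) {
    log_level[i, ] <- switch(
      seq_roles[i],
      study = log_bio[seq_which[i], ],
      sqc = log(pooled),
      ltr = log(ltr_level),
      dilution = ifelse(is_resp, log(pooled * seq_dil[i]), log(pooled))
    )
  }
  tech_noise <- matrix(stats::rnorm(n_total * p, 0, sd_tech), n_total, p)
  intensities <- exp(log_level + drift + tech_noise)
  if (cfg$missing_rate > 0) {
    drop <- stats::runif(length(intensities)) < cfg$missing_rate
    intensities[drop] <- 0
  }

  sample_id <- character(n_total)
  for (i in order_idx) {
    sample_id[i] <- switch(
      seq_roles[i],
      study = sprintf("S%02d", seq_which[i]),
      sqc = sprintf("SQC%02d", seq_which[i]),
      ltr = sprintf("LTR%02d", seq_which[i]),
      dilution = sprintf("DIL%02d", seq_which[i])
    )
  }
  samples <- tibble::tibble(
    sample_id = sample_id,
    role = seq_roles,
    class = ifelse(seq_roles == "study", class[seq_which], NA_character_),
    injection_order = order_idx,
    dilution_factor = seq_dil,
    age_months = ifelse(seq_roles == "study", age[seq_which], NA_real_),
    sex = ifelse(seq_roles == "study", sex[seq_which], NA_character_)
  )
  features <- tibble::tibble(
    feature_id = feature_id,
    mz = round(stats::runif(p, 100, 1100), 4),
    rt_min = round(stats::runif(p, 0.5, 12), 2),
    annotation = "unannotated",
    annotation_level = 4
  )

  truth <- structure(list(
    discriminatory = tibble::tibble(
      feature_id = feature_id[disc_idx],
      direction = ifelse(sign_j[disc_idx] > 0, "up_in_bacterial",
                         "up_in_viral")
    ),
    age_assoc_ids = feature_id[age_idx],
    noise_ids = feature_id[noise_idx]
  ), class = "sim_truth")

  list(table = feature_table(intensities, samples, features), truth = truth)
}

#' Write a simulated study to disk as plain-text fixture files
#'
#' Writes `intensities.csv` (first column `sample_id`), `samples.csv`,
#' `features.csv` and `truth.json` into `dir`. [read_study()] round-trips
#' the three CSVs exactly.
#'
#' @param table A [feature_table()].
#' @param truth The matching `sim_truth` object (or `NULL` to skip).
#' @param dir Output directory, created if needed.
#' @return Invisibly, `dir`.
#' @export
write_fixture <- function(table, truth, dir) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$intensities) == 0 || ncol(table$intensities) == 0) {
    rlang::abort("refusing to write an empty feature table",
                 class = "lipidsig_error")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ints <- tibble::as_tibble(table$intensities)
  ints <- dplyr::bind_cols(
    tibble::tibble(sample_id = table$samples$sample_id), ints)
  readr::write_csv(ints, file.path(dir, "intensities.csv"), progress = FALSE)
  readr::write_csv(table$samples, file.path(dir, "samples.csv"),
                   progress = FALSE)
  readr::write_csv(table$features, file.path(dir, "features.csv"),
                   progress = FALSE)
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(discriminatory = truth$discriminatory,
           age_assoc_ids = truth$age_assoc_ids,
           noise_ids = truth$noise_ids),
      file.path(dir, "truth.json"), auto_unbox = FALSE, digits = NA)
  }
  invisible(dir)
}

#' Read the ground-truth labels written by [write_fixture()]
#'
#' @param path Path to `truth.json`.
#' @return A `sim_truth` object.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    discriminatory = tibble::as_tibble(x$discriminatory),
    age_assoc_ids = as.character(x$age_assoc_ids),
    noise_ids = as.character(x$noise_ids)
  ), class = "sim_truth")
}
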