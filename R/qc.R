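#' QC configuration
#'
#' Thresholds for the feature-retention filters and the PCA-based sample
#' outlier flagging.
#'
#' @param cv_threshold Retain a feature only if its relative coefficient
#'   of variation (sd/mean of raw intensity) across undiluted SQC
#'   injections is strictly below this fraction.
#' @param dilution_r_threshold Retain a feature only if its Pearson
#'   correlation between raw intensity and relative concentration across
#'   the SQC dilution series is strictly above this value.
#' @param dilution_method `"pearson"` (default) or `"spearman"`.
#' @param outlier_alpha Significance level of the Hotelling-T2 outlier
#'   flag.
#' @param n_pca_components Score-space dimension for the outlier test.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(cv_threshold = 0.15, dilution_r_threshold = 0.9,
                      dilution_method = c("pearson", "spearman"),
                      outlier_alpha = 0.05, n_pca_components = 2) {
  dilution_method <- match.arg(dilution_method)
  if (!is.finite(cv_threshold) || cv_threshold <= 0) {
    rlang::abort("cv_threshold must be > 0", class = "lipidsig_error")
  }
  if (!is.finite(dilution_r_threshold) || dilution_r_threshold >= 1) {
    rlang::abort("dilution_r_threshold must be < 1", class = "lipidsig_error")
  }
  if (outlier_alpha <= 0 || outlier_alpha >= 1) {
    rlang::abort("outlier_alpha must be in (0,1)", class = "lipidsig_error")
  }
  if (n_pca_components < 1) {
    rlang::abort("n_pca_components must be >= 1", class = "lipidsig_error")
  }
  structure(list(cv_threshold = cv_threshold,
                 dilution_r_threshold = dilution_r_threshold,
                 dilution_method = dilution_method,
                 outlier_alpha = outlier_alpha,
                 n_pca_components = n_pca_components),
            class = "qc_config")
}

#' Pooled-QC coefficient-of-variation filter
#'
#' Per-feature CV (sd/mean) of raw intensities across the undiluted SQC
#' injections; a feature is retained only when CV is strictly below the
#' threshold. Computed on raw, pre-log intensities, the standard
#' pooled-QC practice.
#'
#' @param table A raw-scale [feature_table()] containing at least 3
#'   samples with `role == "sqc"`.
#' @param threshold CV retention threshold (fraction).
#' @return A tibble with `feature_id`, `sqc_cv`, `cv_pass`.
#' @export
sqc_cv_filter <- function(table, threshold = 0.15) {
  stopifnot(inherits(table, "feature_table"))
  if (table$log_transformed) {
    rlang::abort("QC filters operate on raw intensities; apply before log_transform",
                 class = "lipidsig_error")
  }
  sqc <- table$intensities[table$samples$role == "sqc", , drop = FALSE]
  if (nrow(sqc) < 3) {
    rlang::abort("need at least 3 undiluted SQC samples for the CV filter",
                 class = "lipidsig_error")
  }
  m <- colMeans(sqc)
  s <- apply(sqc, 2, stats::sd)
  cv <- unname(ifelse(m == 0, NA_real_, s / m))
  tibble::tibble(feature_id = table$features$feature_id,
                 sqc_cv = cv,
                 cv_pass = !is.na(cv) & cv < threshold)
}

#' Dilution-series linearity filter
#'
#' Per-feature correlation between raw intensity and relative
#' concentration across all dilution-series injections; a feature is
#' retained only when the coefficient is strictly above the threshold.
#' Features constant across the series (undefined correlation) are
#' dropped.
#'
#' @param table A raw-scale [feature_table()] containing dilution samples
#'   at >= 3 distinct factors.
#' @param threshold Correlation retention threshold.
#' @param method `"pearson"` or `"spearman"`.
#' @return A tibble with `feature_id`, `dilution_r`, `dilution_pass`.
#' @export
dilution_filter <- function(table, threshold = 0.9,
                            method = c("pearson", "spearman")) {
  stopifnot(inherits(table, "feature_table"))
  method <- match.arg(method)
  if (table$log_transformed) {
    rlang::abort("QC filters operate on raw intensities; apply before log_transform",
                 class = "lipidsig_error")
  }
  idx <- table$samples$role == "dilution"
  d <- table$samples$dilution_factor[idx]
  if (length(unique(d)) < 3) {
    rlang::abort("need dilution samples at >= 3 distinct factors",
                 class = "lipidsig_error")
  }
  x <- table$intensities[idx, , drop = FALSE]
  r <- suppressWarnings(
    as.numeric(stats::cor(x, d, method = method))
  )
  tibble::tibble(feature_id = table$features$feature_id,
                 dilution_r = r,
                 dilution_pass = !is.na(r) & r > threshold)
}

#' Apply the QC feature filters
#'
#' Combines the SQC CV filter and the dilution-series correlation filter
#' (a feature is retained only if it passes both), flags sample outliers
#' by Hotelling T2 in PCA score space of the study samples, and returns
#' the table restricted to study samples and retained features together
#' with the full report. Filters are computed on QC-role samples only;
#' study-sample values never influence retention. Outlier flags are
#' advisory: removal is an explicit downstream step.
#'
#' @param table A raw-scale [feature_table()].
#' @param config A [qc_config()].
#' @return A list with `table` (filtered, study samples only) and
#'   `report` (class `qc_report`: `features` tibble with `sqc_cv`,
#'   `dilution_r`, `retained`, `drop_reason`; `samples` tibble with
#'   `hotelling_t2`, `outlier`).
#' @export
apply_qc <- function(table, config = qc_config()) {
  stopifnot(inherits(table, "feature_table"), inherits(config, "qc_config"))
  cvr <- sqc_cv_filter(table, config$cv_threshold)
  dlr <- dilution_filter(table, config$dilution_r_threshold,
                         config$dilution_method)
  features <- dplyr::mutate(
    dplyr::inner_join(cvr, dlr, by = "feature_id"),
    retained = .data$cv_pass & .data$dilution_pass,
    drop_reason = dplyr::case_when(
      .data$cv_pass & .data$dilution_pass ~ "none",
      !.data$cv_pass & !.data$dilution_pass ~ "both",
      !.data$cv_pass ~ "cv",
      TRUE ~ "dilution"
    )
  )
  if (!any(features$retained)) {
    rlang::abort("no features retained by the QC filters",
                 class = "lipidsig_error")
  }
  out <- ft_subset(ft_study(table), features = which(features$retained))
  samples <- flag_outliers(out, config)
  report <- structure(list(features = features, samples = samples,
                           config = config),
                      class = "qc_report")
  list(table = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d/%d features retained; %d sample(s) flagged\n",
              sum(x$features$retained), nrow(x$features),
              sum(x$samples$outlier)))
  invisible(x)
}

#' Flag sample outliers by Hotelling T2 in PCA score space
#'
#' Pareto-scaled PCA on log intensities of the given samples; T2 on the
#' first `n_pca_components` scores is compared with the F-distribution
#' critical value at `outlier_alpha`. This formalizes the visual
#' PCA-outlier inspection of routine metabolomics practice; flags are
#' advisory, removal requires explicit confirmation.
#'
#' @param table A [feature_table()] (raw or log scale; raw is logged
#'   internally with pseudocount 1).
#' @param config A [qc_config()].
#' @return A tibble with `sample_id`, `hotelling_t2`, `t2_critical`,
#'   `outlier`.
#' @export
flag_outliers <- function(table, config = qc_config()) {
  stopifnot(inherits(table, "feature_table"))
  k <- config$n_pca_components
  n <- nrow(table$intensities)
  if (n <= k + 1) {
    rlang::abort("too few samples for the Hotelling-T2 outlier test",
                 class = "lipidsig_error")
  }
  x <- if (table$log_transformed) table$intensities
       else log(table$intensities + 1)
  keep <- apply(x, 2, stats::sd) > 0
  pca <- fit_pca(pareto_scale(x[, keep, drop = FALSE]), k = k)
  sc <- pca$scores
  v <- colSums(sc^2) / (n - 1)
  t2 <- rowSums(sweep(sc^2, 2, v, "/"))
  crit <- k * (n^2 - 1) / (n * (n - k)) *
    stats::qf(1 - config$outlier_alpha, k, n - k)
  tibble::tibble(sample_id = table$samples$sample_id,
                 hotelling_t2 = t2,
                 t2_critical = crit,
                 outlier = t2 > crit)
}
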