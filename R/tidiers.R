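#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the per-feature terms of an OPLS-DA model
#'
#' @param x An `opls_model`.
#' @param ... Unused.
#' @return A tibble with `feature_id`, predictive `weight` and `loading`.
#' @export
tidy.opls_model <- function(x, ...) {
  tibble::tibble(feature_id = x$feature_ids,
                 weight = x$predictive_weights,
                 loading = x$predictive_loadings)
}

#' One-row model summary of an OPLS-DA fit
#'
#' @param x An `opls_model`.
#' @param ... Unused.
#' @return A one-row tibble with `r2x_cum`, `r2y_cum`, `q2_cum`,
#'   `n_ortho`.
#' @export
glance.opls_model <- function(x, ...) {
  tibble::tibble(r2x_cum = x$r2x_cum, r2y_cum = x$r2y_cum,
                 q2_cum = x$q2_cum, n_ortho = x$n_ortho)
}

#' Tidy an FS-PLS model's selection path
#'
#' @param x An `fspls_model`.
#' @param ... Unused.
#' @return The `selected` tibble with the final joint coefficient joined.
#' @export
tidy.fspls_model <- function(x, ...) {
  dplyr::mutate(x$selected,
                coefficient = unname(
                  x$final_coefficients[x$selected$feature_id]))
}

#' One-row summary of an FS-PLS model
#'
#' @param x An `fspls_model`.
#' @param ... Unused.
#' @return A one-row tibble with `n_selected`, `stop_reason`, `p_thresh`.
#' @export
glance.fspls_model <- function(x, ...) {
  tibble::tibble(n_selected = nrow(x$selected), stop_reason = x$stop_reason,
                 p_thresh = x$config$p_thresh)
}

#' Tidy a ROC result into its curve points
#'
#' @param x A `roc_result`.
#' @param ... Unused.
#' @return The ROC points tibble.
#' @export
tidy.roc_result <- function(x, ...) x$points

#' One-row summary of a ROC result
#'
#' @param x A `roc_result`.
#' @param ... Unused.
#' @return A one-row tibble with `auc`, `ci_lower`, `ci_upper`, `n_boot`.
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, ci_lower = x$ci_lower, ci_upper = x$ci_upper,
                 n_boot = x$n_boot)
}

#' Tidy a QC report (per-feature verdicts)
#'
#' @param x A `qc_report`.
#' @param ... Unused.
#' @return The per-feature tibble.
#' @export
tidy.qc_report <- function(x, ...) x$features

#' One-row summary of a QC report
#'
#' @param x A `qc_report`.
#' @param ... Unused.
#' @return A one-row tibble of retention counts and flagged samples.
#' @export
glance.qc_report <- function(x, ...) {
  tibble::tibble(n_features = nrow(x$features),
                 n_retained = sum(x$features$retained),
                 n_dropped_cv = sum(x$features$drop_reason == "cv"),
                 n_dropped_dilution = sum(x$features$drop_reason == "dilution"),
                 n_dropped_both = sum(x$features$drop_reason == "both"),
                 n_outlier_flags = sum(x$samples$outlier))
}

#' Tidy a PCA model (scores)
#'
#' @param x A `pca_model`.
#' @param ... Unused.
#' @return A tibble with `sample_id` and one column per component.
#' @export
tidy.pca_model <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(x$scores)),
                   tibble::as_tibble(x$scores))
}
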