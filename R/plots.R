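#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' PCA scores plot
#'
#' @param object A `pca_model`.
#' @param colour Optional vector (length = samples) mapped to point
#'   colour, e.g. sample role or class.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pca_model <- function(object, colour = NULL, ...) {
  d <- tidy(object)
  ev <- object$explained_variance_fraction
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if (!is.null(colour)) {
    d$colour <- colour
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                         colour = .data$colour)) +
      ggplot2::labs(colour = NULL)
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * ev[2]),
                  title = "PCA scores")
}

#' OPLS-DA scores plot (predictive vs first orthogonal component)
#'
#' @param object An `opls_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.opls_model <- function(object, ...) {
  d <- tibble::tibble(
    t_predictive = object$predictive_scores,
    t_orthogonal = if (object$n_ortho > 0) object$orthogonal_scores[, 1]
                   else 0,
    class = ifelse(object$y == 1, "bacterial", "viral"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_predictive,
                                  y = .data$t_orthogonal,
                                  colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "predictive score t[1]",
                  y = if (object$n_ortho > 0) "orthogonal score t[o1]"
                      else "",
                  title = sprintf(
                    "OPLS-DA scores (R2X %.2f, R2Y %.2f)",
                    object$r2x_cum, object$r2y_cum))
}

#' S-plot
#'
#' Modelled covariance (`p1`) against correlation with the predictive
#' score (`pcorr`), shortlisted features highlighted.
#'
#' @param object An `splot` tibble from [s_plot()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.splot <- function(object, ...) {
  cutoff <- attr(object, "cutoff")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$p1, y = .data$pcorr,
                                       colour = .data$shortlisted)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-cutoff, cutoff), linetype = 2) +
    ggplot2::labs(x = "p[1] (modelled covariance)",
                  y = "p(corr) (correlation with t[1])", title = "S-plot")
}

#' ROC curve plot
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_result <- function(object, ...) {
  lab <- sprintf("AUC = %.3f", object$auc)
  if (!is.na(object$ci_lower)) {
    lab <- sprintf("%s (95%% CI %.2f-%.2f)", lab, object$ci_lower,
                   object$ci_upper)
  }
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = 1 - .data$specificity,
                               y = .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity", title = lab)
}

#' Disease-risk-score boxplots by class
#'
#' @param object A `drs_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.drs_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$class, y = .data$drs)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "disease risk score",
                  title = "DRS by class")
}
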