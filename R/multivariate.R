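#' Pareto-scale a matrix
#'
#' Columnwise `(x - mean) / sqrt(sd)`: the metabolomics-standard
#' compromise between mean-centering and unit-variance scaling, applied
#' before PCA and OPLS-DA.
#'
#' @param x Numeric matrix (samples x features) with column names.
#' @param scaling One of `"pareto"` (default), `"uv"` (unit variance) or
#'   `"none"` (centering only).
#' @return A `scaled_matrix`: list with `values`, `column_means`,
#'   `column_sds`, `scaling`.
#' @export
pareto_scale <- function(x, scaling = c("pareto", "uv", "none")) {
  scaling <- match.arg(scaling)
  x <- as.matrix(x)
  mu <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    offenders <- colnames(x)[sds == 0]
    if (is.null(offenders)) offenders <- which(sds == 0)
    rlang::abort(sprintf("zero-variance column(s): %s",
                         paste(offenders, collapse = ", ")),
                 class = "lipidsig_error")
  }
  div <- switch(scaling, pareto = sqrt(sds), uv = sds, none = rep(1, ncol(x)))
  values <- sweep(sweep(x, 2, mu, "-"), 2, div, "/")
  structure(list(values = values, column_means = mu, column_sds = sds,
                 scaling = scaling),
            class = "scaled_matrix")
}

#' Invert a scaled matrix back to the original space
#'
#' @param scaled A `scaled_matrix` from [pareto_scale()].
#' @return The reconstructed input matrix.
#' @export
unscale <- function(scaled) {
  stopifnot(inherits(scaled, "scaled_matrix"))
  div <- switch(scaled$scaling,
                pareto = sqrt(scaled$column_sds),
                uv = scaled$column_sds,
                none = rep(1, ncol(scaled$values)))
  sweep(sweep(scaled$values, 2, div, "*"), 2, scaled$column_means, "+")
}

as_scaled_values <- function(scaled) {
  if (inherits(scaled, "scaled_matrix")) scaled$values else as.matrix(scaled)
}

#' Principal component analysis by truncated SVD
#'
#' @param scaled A `scaled_matrix` (or an already-centered matrix).
#' @param k Number of components; at most `min(n_samples - 1, n_features)`.
#' @return A `pca_model` with `scores` (samples x k), `loadings`
#'   (features x k, orthonormal) and `explained_variance_fraction`.
#' @export
fit_pca <- function(scaled, k = 2) {
  x <- as_scaled_values(scaled)
  kmax <- min(nrow(x) - 1, ncol(x))
  if (k < 1 || k > kmax) {
    rlang::abort(sprintf("k must be in 1..%d", kmax), class = "lipidsig_error")
  }
  sv <- svd(x, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  rownames(scores) <- rownames(x)
  loadings <- sv$v
  rownames(loadings) <- colnames(x)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_fraction = sv$d[seq_len(k)]^2 / sum(x^2),
                 total_ss = sum(x^2)),
            class = "pca_model")
}

#' Fit an OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis: one
#' class-predictive component plus `n_ortho` class-orthogonal components,
#' via the O-PLS deflation scheme. For each orthogonal component the PLS
#' weight `w` is computed from the current matrix, the part of the
#' loading orthogonal to `w` is extracted and its variation removed from
#' `X`; the final predictive component is fit on the deflated matrix. The
#' predictive score is oriented so that larger values mean more
#' bacterial-like (y: bacterial = 1).
#'
#' @param scaled A `scaled_matrix` (typically pareto-scaled log
#'   intensities of the study samples) or a numeric matrix.
#' @param y Class labels (bacterial/viral strings or 0/1, bacterial = 1).
#' @param n_ortho Number of orthogonal components (>= 0). With
#'   `n_ortho = 0` the model reduces to single-component PLS-DA.
#' @return An `opls_model` with predictive scores/weights/loadings,
#'   orthogonal scores/loadings, `r2x_cum`, `r2y_cum` and (once
#'   [cross_validated_q2()] has been run, as `fit_oplsda()` does via
#'   [permutation_test()] or directly) `q2_cum`.
#' @export
fit_oplsda <- function(scaled, y, n_ortho = 1) {
  x <- as_scaled_values(scaled)
  y <- encode_class(y)
  if (length(y) != nrow(x)) {
    rlang::abort("length(y) must match nrow(X)", class = "lipidsig_error")
  }
  if (n_ortho < 0 || n_ortho != round(n_ortho)) {
    rlang::abort("n_ortho must be a non-negative integer",
                 class = "lipidsig_error")
  }
  x_center <- colMeans(x)
  X <- sweep(x, 2, x_center, "-")
  y_mean <- mean(y)
  yc <- y - y_mean
  ssx <- sum(X^2)
  ssy <- sum(yc^2)

  W_o <- P_o <- NULL
  T_o <- NULL
  r2x_ortho <- numeric(0)
  Xd <- X
  for (k in seq_len(n_ortho)) {
    w <- crossprod(Xd, yc)
    w <- w / sqrt(sum(w^2))
    t <- Xd %*% w
    p <- crossprod(Xd, t) / sum(t^2)
    w_o <- p - as.numeric(crossprod(w, p)) * w
    if (sum(w_o^2) < 1e-12 * sum(p^2)) {
      rlang::abort(sprintf("n_ortho = %d too large for the rank of X", n_ortho),
                   class = "lipidsig_error")
    }
    w_o <- w_o / sqrt(sum(w_o^2))
    t_o <- Xd %*% w_o
    p_o <- crossprod(Xd, t_o) / sum(t_o^2)
    Xd <- Xd - t_o %*% t(p_o)
    W_o <- cbind(W_o, w_o)
    P_o <- cbind(P_o, p_o)
    T_o <- cbind(T_o, t_o)
    r2x_ortho <- c(r2x_ortho, sum(t_o^2) * sum(p_o^2) / ssx)
  }
  w_p <- crossprod(Xd, yc)
  wnorm <- sqrt(sum(w_p^2))
  if (wnorm < 1e-300) {
    rlang::abort("X carries no covariance with y; cannot fit",
                 class = "lipidsig_error")
  }
  w_p <- w_p / wnorm
  t_p <- Xd %*% w_p
  p_p <- crossprod(Xd, t_p) / sum(t_p^2)
  q <- sum(yc * t_p) / sum(t_p^2)
  if (q < 0) { # orient: higher predictive score = more bacterial-like
    w_p <- -w_p; t_p <- -t_p; p_p <- -p_p; q <- -q
  }
  r2y <- q^2 * sum(t_p^2) / ssy
  r2x_pred <- sum(t_p^2) * sum(p_p^2) / ssx

  structure(list(
    predictive_scores = as.numeric(t_p),
    predictive_loadings = as.numeric(p_p),
    predictive_weights = as.numeric(w_p),
    orthogonal_scores = T_o,
    orthogonal_loadings = P_o,
    orthogonal_weights = W_o,
    y_loading = q,
    y_mean = y_mean,
    x_center = x_center,
    feature_ids = colnames(x),
    sample_ids = rownames(x),
    n_ortho = n_ortho,
    r2x_cum = r2x_pred + sum(r2x_ortho),
    r2x_predictive = r2x_pred,
    r2x_orthogonal = r2x_ortho,
    r2y_cum = r2y,
    q2_cum = NA_real_,
    y = y
  ), class = "opls_model")
}

#' Predict from an OPLS-DA model
#'
#' Applies the orthogonal signal filter learned at fit time, then the
#' predictive component. New data must be on the same (scaled) axes as
#' the training matrix.
#'
#' @param object An `opls_model`.
#' @param newdata Matrix on the training scale (samples x features).
#' @param ... Unused.
#' @return A tibble with `score` (predictive score) and `y_hat`
#'   (continuous class prediction; threshold at 0.5 for a hard call).
#' @export
predict.opls_model <- function(object, newdata, ...) {
  X <- sweep(as_scaled_values(newdata), 2, object$x_center, "-")
  if (object$n_ortho > 0) {
    for (k in seq_len(object$n_ortho)) {
      t_o <- X %*% object$orthogonal_weights[, k]
      X <- X - t_o %*% t(object$orthogonal_loadings[, k])
    }
  }
  t_p <- as.numeric(X %*% object$predictive_weights)
  tibble::tibble(score = t_p, y_hat = object$y_mean + object$y_loading * t_p)
}

# Stratified fold assignment driven by one global permutation, so a
# sample's fold depends only on the class partition (not on which class
# is coded 1): the permutation p-value is exactly invariant to swapping
# the bacterial/viral labelling convention.
stratified_folds <- function(y, n_folds, seed = 1) {
  if (n_folds < 2) {
    rlang::abort("n_folds must be >= 2", class = "lipidsig_error")
  }
  perm <- withr::with_seed(seed, sample.int(length(y)))
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- perm[y[perm] == cls]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Cross-validated Q2 of an OPLS-DA model
#'
#' `Q2 = 1 - PRESS / SSY` over stratified folds (7 by default, the SIMCA
#' convention): each fold's samples are predicted by a model fit on the
#' remaining folds, and squared prediction errors are accumulated against
#' the total (grand-mean-centered) y sum of squares.
#'
#' @inheritParams fit_oplsda
#' @param n_folds Number of cross-validation folds.
#' @param seed Seed controlling the fold assignment (deterministic).
#' @param return_scores If `TRUE`, also return the held-out predictive
#'   scores per sample (the cross-validated scores plot).
#' @return The Q2 value, or a list `(q2, cv_scores)` when
#'   `return_scores = TRUE`.
#' @export
cross_validated_q2 <- function(scaled, y, n_ortho = 1, n_folds = 7,
                               seed = 1, return_scores = FALSE) {
  x <- as_scaled_values(scaled)
  y <- encode_class(y)
  fold <- stratified_folds(y, n_folds, seed)
  press <- 0
  cv_scores <- numeric(length(y))
  for (f in sort(unique(fold))) {
    test <- fold == f
    if (!any(test)) next
    fit <- fit_oplsda(x[!test, , drop = FALSE], y[!test], n_ortho)
    pr <- predict(fit, x[test, , drop = FALSE])
    press <- press + sum((y[test] - pr$y_hat)^2)
    cv_scores[test] <- pr$score
  }
  q2 <- 1 - press / sum((y - mean(y))^2)
  if (return_scores) list(q2 = q2, cv_scores = cv_scores) else q2
}

#' Label-permutation test of an OPLS-DA model's Q2
#'
#' Refits the model and its cross-validated Q2 under `n_perm` random
#' permutations of class membership and compares the observed Q2 with the
#' permuted distribution. The p-value uses the add-one estimator
#' `p = (1 + #\{Q2_perm >= Q2_obs\}) / (1 + n_perm)`, which is never zero.
#' A model is declared valid when the observed Q2 is positive and
#' `p < 0.05`.
#'
#' @inheritParams cross_validated_q2
#' @param n_perm Number of permutations (999 mirrors common practice).
#' @param seed Seed for both the folds and the permutations.
#' @return A `permutation_result`: list with `observed_q2`, `permuted_q2`,
#'   `p_value`, `valid`.
#' @export
permutation_test <- function(scaled, y, n_ortho = 1, n_perm = 999,
                             seed = 1, n_folds = 7) {
  if (n_perm < 1) {
    rlang::abort("n_perm must be >= 1", class = "lipidsig_error")
  }
  x <- as_scaled_values(scaled)
  y <- encode_class(y)
  observed <- cross_validated_q2(x, y, n_ortho, n_folds, seed = seed)
  permuted <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      yp <- sample(y)
      cross_validated_q2(x, yp, n_ortho, n_folds,
                         seed = seed + b)
    }, numeric(1))
  })
  p <- (1 + sum(permuted >= observed)) / (1 + n_perm)
  structure(list(observed_q2 = observed, permuted_q2 = permuted,
                 p_value = p, n_perm = n_perm,
                 valid = observed > 0 && p < 0.05),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Q2 = %.3f, permutation p = %.4g (%d permutations) -> %s\n",
              x$observed_q2, x$p_value, x$n_perm,
              if (x$valid) "valid" else "NOT valid"))
  invisible(x)
}

#' S-plot of an OPLS-DA model
#'
#' For every feature, the modelled covariance with the predictive score
#' (`p1`, the predictive loading axis) and the correlation with the
#' predictive score (`pcorr`). Features with `|p1| >= cutoff` are
#' shortlisted as candidate class discriminators; the direction follows
#' the sign of `p1` under the bacterial = 1 orientation.
#'
#' @param model An `opls_model`.
#' @param scaled The `scaled_matrix` (or matrix) the model was fit on.
#' @param cutoff Shortlist threshold on `|p1|`.
#' @return A tibble of class `splot` with columns `feature_id`, `p1`,
#'   `pcorr`, `shortlisted`, `direction`.
#' @export
s_plot <- function(model, scaled, cutoff = 0.05) {
  stopifnot(inherits(model, "opls_model"))
  X <- sweep(as_scaled_values(scaled), 2, model$x_center, "-")
  t_p <- model$predictive_scores
  p1 <- as.numeric(crossprod(X, t_p) / sum(t_p^2))
  sx <- unname(sqrt(colSums(X^2)))
  st <- sqrt(sum(t_p^2))
  pcorr <- as.numeric(crossprod(X, t_p)) / (sx * st)
  pcorr[sx == 0] <- 0
  ids <- colnames(X)
  if (is.null(ids)) ids <- sprintf("V%d", seq_along(p1))
  out <- tibble::tibble(
    feature_id = ids, p1 = p1, pcorr = pcorr,
    shortlisted = abs(p1) >= cutoff,
    direction = ifelse(p1 >= 0, "up_in_bacterial", "up_in_viral")
  )
  attr(out, "cutoff") <- cutoff
  class(out) <- c("splot", class(out))
  out
}
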