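#' Two-group differential abundance with FDR control
#'
#' Per-feature two-group linear-model t-test on log abundances with
#' Benjamini-Hochberg adjustment across features. Used to screen a
#' shortlist for covariate (age/sex) associations before signature
#' selection: with a handful of features and ~40 samples the plain pooled
#' t-test is the default; empirical-Bayes variance moderation (via limma)
#' is available behind `moderated = TRUE`.
#'
#' @param table A log-scale [feature_table()] (study samples are used).
#' @param grouping One of `"class"`, `"sex"`, `"age_median_split"`
#'   (samples above vs below the median age).
#' @param features Optional feature ids restricting the test (e.g. the
#'   S-plot shortlist); BH adjustment is across the tested features.
#' @param moderated Use limma's moderated t-statistics instead.
#' @return A tibble with `feature_id`, `estimate` (group log-difference,
#'   first level minus second), `t_statistic`, `p_value`,
#'   `fdr_adjusted_p`, plus a `grouping` attribute.
#' @export
diff_abundance <- function(table,
                           grouping = c("class", "sex", "age_median_split"),
                           features = NULL, moderated = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  grouping <- match.arg(grouping)
  tab <- ft_study(table)
  x <- tab$intensities
  if (!tab$log_transformed) x <- log(x + 1)
  if (!is.null(features)) {
    x <- x[, features, drop = FALSE]
  }
  g <- switch(grouping,
              class = tab$samples$class == "bacterial",
              sex = tab$samples$sex == "M",
              age_median_split = tab$samples$age_months >
                stats::median(tab$samples$age_months))
  if (anyNA(g)) {
    rlang::abort(sprintf("missing metadata for grouping '%s'", grouping),
                 class = "lipidsig_error")
  }
  n1 <- sum(g); n0 <- sum(!g)
  if (n1 < 2 || n0 < 2) {
    rlang::abort("each group needs at least 2 samples",
                 class = "lipidsig_error")
  }
  if (moderated) {
    if (!requireNamespace("limma", quietly = TRUE)) {
      rlang::abort("moderated = TRUE requires the limma package",
                   class = "lipidsig_error")
    }
    design <- cbind(intercept = 1, group = as.numeric(g))
    fit <- limma::eBayes(limma::lmFit(t(x), design))
    est <- fit$coefficients[, "group"]
    tstat <- fit$t[, "group"]
    p <- fit$p.value[, "group"]
  } else {
    m1 <- colMeans(x[g, , drop = FALSE])
    m0 <- colMeans(x[!g, , drop = FALSE])
    v1 <- apply(x[g, , drop = FALSE], 2, stats::var)
    v0 <- apply(x[!g, , drop = FALSE], 2, stats::var)
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    est <- m1 - m0
    tstat <- ifelse(se == 0, 0, est / se)
    p <- 2 * stats::pt(-abs(tstat), df = n1 + n0 - 2)
    p[se == 0 & est == 0] <- 1
  }
  out <- tibble::tibble(
    feature_id = colnames(x),
    estimate = unname(est),
    t_statistic = unname(tstat),
    p_value = unname(p),
    fdr_adjusted_p = stats::p.adjust(unname(p), method = "BH")
  )
  attr(out, "grouping") <- grouping
  out
}

#' FS-PLS configuration
#'
#' @param p_thresh Stopping p-value: selection stops before adding a
#'   feature whose univariate (deflated) p-value exceeds this.
#' @param max_features Safety cap on signature size.
#' @param model_family `"logistic"` (binary class, default) or
#'   `"linear"`.
#' @param seed Seed (recorded for provenance; the algorithm itself is
#'   deterministic).
#' @return A list of class `fspls_config`.
#' @export
fspls_config <- function(p_thresh = 0.01, max_features = 10,
                         model_family = c("logistic", "linear"), seed = 1) {
  model_family <- match.arg(model_family)
  if (!is.finite(p_thresh) || p_thresh <= 0 || p_thresh >= 1) {
    rlang::abort("p_thresh must be in (0,1)", class = "lipidsig_error")
  }
  if (max_features < 1) {
    rlang::abort("max_features must be >= 1", class = "lipidsig_error")
  }
  structure(list(p_thresh = p_thresh, max_features = max_features,
                 model_family = model_family, seed = seed),
            class = "fspls_config")
}

# Firth-penalized logistic regression (Newton iteration on the modified
# score); used when an ordinary ML fit separates perfectly, which happens
# routinely on small-n omics shortlists.
firth_logistic <- function(X, y, offset = NULL, max_iter = 50, tol = 1e-8) {
  X <- cbind(1, X)
  if (is.null(offset)) offset <- rep(0, nrow(X))
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- offset + as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    XtW <- t(X * w)
    info <- XtW %*% X
    info_inv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(info_inv)) break
    h <- rowSums((X %*% info_inv) * (X * w))
    U <- as.numeric(t(X) %*% (y - mu + h * (0.5 - mu)))
    step <- as.numeric(info_inv %*% U)
    # step-halving for stability
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- offset + as.numeric(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  w <- mu * (1 - mu)
  info <- t(X * w) %*% X
  se <- sqrt(diag(solve(info)))
  ll <- sum(y * eta - log1p(exp(eta))) + 0.5 * determinant(info)$modulus
  list(coef = beta, se = se, loglik = as.numeric(ll))
}

# One univariate fit of y on x given the current model's linear
# predictor as an offset (selection acts on the residual variation of
# the response); returns the slope p-value, log-likelihood, coefficient,
# and whether the Firth fallback was used.
univariate_fit <- function(x, y, family, eta = NULL) {
  if (stats::sd(x) < 1e-10) {
    return(list(p = 1, loglik = -Inf, coef = 0, firth = FALSE,
                degenerate = TRUE))
  }
  if (is.null(eta)) eta <- rep(0, length(y))
  if (family == "linear") {
    yr <- y - eta
    fit <- stats::lm(yr ~ x)
    sm <- summary(fit)$coefficients
    return(list(p = sm["x", 4], loglik = as.numeric(stats::logLik(fit)),
                coef = sm["x", 1], firth = FALSE, degenerate = FALSE))
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, offset = eta, family = stats::binomial()),
    warning = function(w) {
      separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!separated && fit$converged && abs(stats::coef(fit)[2]) < 15) {
    sm <- summary(fit)$coefficients
    return(list(p = sm["x", 4], loglik = as.numeric(stats::logLik(fit)),
                coef = sm["x", 1], firth = FALSE, degenerate = FALSE))
  }
  ff <- firth_logistic(matrix(x, ncol = 1), y, offset = eta)
  z <- ff$coef[2] / ff$se[2]
  list(p = 2 * stats::pnorm(-abs(z)), loglik = ff$loglik, coef = ff$coef[2],
       firth = TRUE, degenerate = FALSE)
}

# Joint model of y on the selected (standardized, original-scale)
# columns; Firth fallback on separation. Supplies the reported final
# coefficients and the linear predictor offset for later steps.
joint_fit <- function(Xf, y, ids, family) {
  colnames(Xf) <- ids
  if (family == "linear") {
    fit <- stats::lm(y ~ Xf)
    coefs <- stats::setNames(stats::coef(fit), c("(Intercept)", ids))
    return(list(coef = coefs, eta = unname(stats::fitted(fit)),
                firth = FALSE))
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ Xf, family = stats::binomial()),
    warning = function(w) { separated <<- TRUE; invokeRestart("muffleWarning") })
  if (!separated && fit$converged && all(abs(stats::coef(fit)[-1]) < 15)) {
    return(list(coef = stats::setNames(stats::coef(fit),
                                       c("(Intercept)", ids)),
                eta = unname(fit$linear.predictors), firth = FALSE))
  }
  ff <- firth_logistic(Xf, y)
  coefs <- stats::setNames(ff$coef, c("(Intercept)", ids))
  list(coef = coefs, eta = as.numeric(cbind(1, Xf) %*% ff$coef),
       firth = TRUE)
}

#' Forward-selection PLS (FS-PLS) sparse signature selection
#'
#' Iteratively (1) fits one univariate regression per remaining feature
#' (logistic maximum likelihood with a Wald test by default), taking the
#' current model's linear predictor as an offset so that selection acts
#' on the residual variation of the response, (2) selects
#' the feature with the smallest p-value (ties broken by larger maximized
#' log-likelihood, then column order), (3) stops before adding if that
#' p-value exceeds `p_thresh` or the cap is reached, and (4) projects the
#' selected column's variation out of all remaining columns (the rank-1
#' SVD projection `X <- X - s (s'X) / (s's)`), so later selections act on
#' residual variation and the signature features are mutually
#' uncorrelated. A final joint model of y on the originally-scaled
#' selected columns provides the reported coefficients. Perfectly
#' separating univariate fits fall back to Firth-penalized likelihood,
#' recorded per step.
#'
#' @param X Numeric matrix (samples x candidate features, typically the
#'   shortlisted log abundances); columns are standardized internally.
#' @param y Class labels (bacterial/viral or 0/1; bacterial = 1). For
#'   `model_family = "linear"`, any numeric response.
#' @param config An [fspls_config()].
#' @return An `fspls_model`: `selected` tibble (`feature_id`,
#'   `step_p_value`, `step_loglik`, `firth`), `final_coefficients` (named,
#'   incl. intercept), `deflation_record`, `stop_reason`, plus the
#'   standardization used.
#' @export
fspls_select <- function(X, y, config = fspls_config()) {
  stopifnot(inherits(config, "fspls_config"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  y <- if (config$model_family == "logistic") encode_class(y) else as.numeric(y)
  if (config$model_family == "logistic" && length(unique(y)) < 2) {
    rlang::abort("both classes must be present", class = "lipidsig_error")
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  Xd <- Xs
  remaining <- seq_len(ncol(X))
  selected <- integer(0)
  steps <- list()
  record <- list()
  stop_reason <- "exhausted"
  eta <- NULL # linear predictor of the current model (offset at each step)
  joint <- NULL
  while (length(remaining) > 0) {
    fits <- lapply(remaining, function(j) univariate_fit(Xd[, j], y,
                                                         config$model_family,
                                                         eta))
    p <- vapply(fits, `[[`, numeric(1), "p")
    ll <- vapply(fits, `[[`, numeric(1), "loglik")
    # smallest p, tie-break larger loglik, then column order
    best <- order(p, -ll)[1]
    if (fits[[best]]$degenerate || p[best] > config$p_thresh) {
      stop_reason <- "p_thresh"
      break
    }
    j <- remaining[best]
    selected <- c(selected, j)
    steps[[length(steps) + 1]] <- tibble::tibble(
      feature_id = colnames(X)[j],
      step_p_value = p[best],
      step_loglik = ll[best],
      firth = fits[[best]]$firth
    )
    s <- Xd[, j]
    proj <- crossprod(s, Xd) / sum(s^2)
    record[[length(record) + 1]] <- list(feature_id = colnames(X)[j],
                                         projection = as.numeric(proj),
                                         firth = fits[[best]]$firth)
    Xd <- Xd - s %*% proj
    remaining <- setdiff(remaining, j)
    joint <- joint_fit(Xs[, selected, drop = FALSE], y,
                       colnames(X)[selected], config$model_family)
    eta <- joint$eta
    if (length(selected) >= config$max_features) {
      stop_reason <- "max_features"
      break
    }
  }
  sel_tbl <- if (length(steps)) dplyr::bind_rows(steps) else
    tibble::tibble(feature_id = character(), step_p_value = numeric(),
                   step_loglik = numeric(), firth = logical())
  final <- if (is.null(joint)) {
    c(`(Intercept)` = if (config$model_family == "logistic")
      stats::qlogis(mean(y)) else mean(y))
  } else {
    joint$coef
  }
  structure(list(selected = sel_tbl,
                 final_coefficients = final,
                 deflation_record = record,
                 stop_reason = stop_reason,
                 center = ctr, scale = scl,
                 config = config),
            class = "fspls_model")
}

#' @export
print.fspls_model <- function(x, ...) {
  cat(sprintf("<fspls_model> %d feature(s) selected (stop: %s)\n",
              nrow(x$selected), x$stop_reason))
  if (nrow(x$selected) > 0) print(x$selected)
  invisible(x)
}

#' Extract the signature from an FS-PLS model
#'
#' @param model An `fspls_model` with at least one selected feature.
#' @return A tibble of class `signature` with `feature_id`, `direction`
#'   (by sign of the final joint coefficient, bacterial = 1 orientation)
#'   and `weight`.
#' @export
signature_of <- function(model) {
  stopifnot(inherits(model, "fspls_model"))
  if (nrow(model$selected) == 0) {
    rlang::abort("empty signature: no features were selected",
                 class = "lipidsig_error")
  }
  coefs <- unname(model$final_coefficients[model$selected$feature_id])
  out <- tibble::tibble(
    feature_id = model$selected$feature_id,
    direction = ifelse(coefs >= 0, "up_in_bacterial", "up_in_viral"),
    weight = coefs
  )
  class(out) <- c("signature", class(out))
  out
}

#' Covariate-robustness check of the FS-PLS signature
#'
#' Runs FS-PLS on the full shortlist and again after removing the
#' features the covariate screen called significant (FDR < `alpha`), and
#' reports whether the two selected feature sets are identical.
#'
#' @param X Shortlisted log-abundance matrix (samples x features).
#' @param y Class labels.
#' @param covariate_screen A [diff_abundance()] result (or a row-bound
#'   combination over several groupings) computed on the same shortlist.
#' @param config An [fspls_config()].
#' @param alpha FDR significance level of the screen.
#' @return A list with `full` and `screened` (`fspls_model`s),
#'   `removed_features`, and `agreement` (identical selected sets).
#' @export
robustness_check <- function(X, y, covariate_screen,
                             config = fspls_config(), alpha = 0.05) {
  hits <- unique(covariate_screen$feature_id[
    covariate_screen$fdr_adjusted_p < alpha])
  keep <- setdiff(colnames(X), hits)
  if (length(keep) == 0) {
    rlang::abort("screen removed every shortlisted feature",
                 class = "lipidsig_error")
  }
  full <- fspls_select(X, y, config)
  screened <- fspls_select(X[, keep, drop = FALSE], y, config)
  list(full = full, screened = screened,
       removed_features = hits,
       agreement = setequal(full$selected$feature_id,
                            screened$selected$feature_id))
}
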