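#' Disease risk score (DRS)
#'
#' Collapses the signature's abundances into one scalar per study sample:
#' the sum of per-feature z-scored log abundances over up-in-bacterial
#' features minus the same sum over up-in-viral features. Z-scoring is
#' per feature across the study samples, so the score is invariant to
#' per-feature affine rescaling of the raw abundances; higher DRS means
#' more bacterial-like. The FS-PLS linear predictor (signature weights
#' applied to the z-scores) is emitted alongside for comparison.
#'
#' @param table A [feature_table()] (log scale preferred; raw intensities
#'   are logged internally with pseudocount 1). Only study samples are
#'   scored.
#' @param signature A [signature_of()] tibble (non-empty).
#' @return A `drs_result`: tibble with `sample_id`, `class`, `drs`,
#'   `linear_predictor`, plus a `summary` attribute of per-class median
#'   and IQR.
#' @export
disease_risk_score <- function(table, signature) {
  stopifnot(inherits(table, "feature_table"))
  if (!inherits(signature, "signature") || nrow(signature) == 0) {
    rlang::abort("signature must be a non-empty signature tibble",
                 class = "lipidsig_error")
  }
  tab <- ft_study(table)
  missing <- setdiff(signature$feature_id, tab$features$feature_id)
  if (length(missing) > 0) {
    rlang::abort(sprintf("signature feature(s) absent from table: %s",
                         paste(missing, collapse = ", ")),
                 class = "lipidsig_error")
  }
  x <- tab$intensities[, signature$feature_id, drop = FALSE]
  if (!tab$log_transformed) x <- log(x + 1)
  z <- scale(x)
  sgn <- ifelse(signature$direction == "up_in_bacterial", 1, -1)
  drs <- as.numeric(z %*% sgn)
  lp <- as.numeric(z %*% signature$weight)
  out <- tibble::tibble(sample_id = tab$samples$sample_id,
                        class = tab$samples$class,
                        drs = drs, linear_predictor = lp)
  attr(out, "summary") <- dplyr::summarise(
    dplyr::group_by(out, .data$class),
    median = stats::median(.data$drs),
    iqr = stats::IQR(.data$drs), .groups = "drop")
  class(out) <- c("drs_result", class(out))
  out
}

# Tie-aware rank AUC: probability a random bacterial sample scores above
# a random viral one, half credit for ties (Mann-Whitney concordance).
auc_rank <- function(scores, y01) {
  n1 <- sum(y01 == 1)
  n0 <- sum(y01 == 0)
  r <- rank(scores)
  (sum(r[y01 == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and AUC
#'
#' AUC by concordant-pair counting with half credit for ties (exactly the
#' Mann-Whitney concordance probability), plus the full ROC point set.
#'
#' @param scores Per-sample real scores (higher = more bacterial-like).
#' @param y Class labels (bacterial/viral or 0/1; bacterial = 1 is the
#'   positive class).
#' @return A `roc_result`: list with `points` tibble (`threshold`,
#'   `sensitivity`, `specificity`), `auc`, `n_pos`, `n_neg`;
#'   `ci_lower`/`ci_upper` are `NA` until [bootstrap_ci()].
#' @export
roc_auc <- function(scores, y) {
  y01 <- encode_class(y)
  if (length(scores) != length(y01)) {
    rlang::abort("scores and y must have equal length",
                 class = "lipidsig_error")
  }
  if (length(unique(y01)) < 2) {
    rlang::abort("both classes must be present", class = "lipidsig_error")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(thr, function(t) mean(scores[y01 == 1] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[y01 == 0] < t), numeric(1))
  points <- tibble::tibble(
    threshold = c(Inf, thr, -Inf),
    sensitivity = c(0, sens, 1),
    specificity = c(1, spec, 0)
  )
  structure(list(points = points, auc = auc_rank(scores, y01),
                 n_pos = sum(y01 == 1), n_neg = sum(y01 == 0),
                 ci_lower = NA_real_, ci_upper = NA_real_,
                 n_boot = 0L, seed = NA_integer_),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  ci <- if (is.na(x$ci_lower)) "" else
    sprintf(" (95%% CI %.3f-%.3f, %d bootstrap iterations)",
            x$ci_lower, x$ci_upper, x$n_boot)
  cat(sprintf("AUC = %.3f%s [%d pos, %d neg]\n", x$auc, ci, x$n_pos, x$n_neg))
  invisible(x)
}

#' Stratified percentile bootstrap CI for the AUC
#'
#' Resamples within each class (so no draw can lose a class), recomputes
#' the AUC `n_boot` times and takes the 2.5/97.5 percentiles.
#' Deterministic given the seed.
#'
#' @inheritParams roc_auc
#' @param n_boot Number of bootstrap iterations.
#' @param seed Random seed.
#' @return A `roc_result` with `ci_lower`/`ci_upper` filled in and the
#'   bootstrap AUC draws in `boot_aucs`.
#' @export
bootstrap_ci <- function(scores, y, n_boot = 500, seed = 1) {
  if (n_boot < 1) {
    rlang::abort("n_boot must be >= 1", class = "lipidsig_error")
  }
  y01 <- encode_class(y)
  res <- roc_auc(scores, y01)
  i1 <- which(y01 == 1); i0 <- which(y01 == 0)
  boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(i1, length(i1), replace = TRUE),
               sample(i0, length(i0), replace = TRUE))
      auc_rank(scores[idx], y01[idx])
    }, numeric(1))
  })
  qs <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  res$ci_lower <- qs[1]
  res$ci_upper <- qs[2]
  res$n_boot <- as.integer(n_boot)
  res$seed <- seed
  res$boot_aucs <- boot
  res
}

#' Rank shortlisted features by single-feature AUC
#'
#' Per-feature ROC analysis with the AUC folded to >= 0.5
#' (direction-agnostic; the orientation actually used is recorded),
#' sorted descending. AUC is invariant to monotone transforms, so raw vs
#' log abundance is immaterial.
#'
#' @param table A [feature_table()] (study samples are used).
#' @param shortlist Character vector of feature ids to rank.
#' @param n_boot Bootstrap iterations for per-feature CIs (0 to skip).
#' @param seed Random seed for the bootstrap.
#' @return A tibble with `feature_id`, `auc`, `orientation`
#'   (`"up_in_bacterial"`/`"up_in_viral"`), `ci_lower`, `ci_upper`,
#'   sorted by decreasing AUC.
#' @export
rank_single_features <- function(table, shortlist, n_boot = 500, seed = 1) {
  stopifnot(inherits(table, "feature_table"))
  if (length(shortlist) == 0) {
    rlang::abort("shortlist is empty", class = "lipidsig_error")
  }
  tab <- ft_study(table)
  y <- class_vector(tab)
  x <- tab$intensities[, shortlist, drop = FALSE]
  rows <- purrr::map(seq_along(shortlist), function(j) {
    a <- auc_rank(x[, j], y)
    flip <- a < 0.5
    sc <- if (flip) -x[, j] else x[, j]
    if (n_boot > 0) {
      r <- bootstrap_ci(sc, y, n_boot = n_boot, seed = seed + j)
      lo <- r$ci_lower; hi <- r$ci_upper
    } else {
      lo <- NA_real_; hi <- NA_real_
    }
    tibble::tibble(feature_id = shortlist[j],
                   auc = if (flip) 1 - a else a,
                   orientation = if (flip) "up_in_viral" else "up_in_bacterial",
                   ci_lower = lo, ci_upper = hi)
  })
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$auc))
}
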