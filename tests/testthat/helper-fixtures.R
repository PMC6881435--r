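# Shared fixtures and independent oracles for the test suite.

# A scaled-down study: same design as the defaults, fewer features, so
# module tests stay fast. Planted sets remain disjoint.
small_sim <- function(seed = 1, ...) {
  simulate_study(sim_config(n_features = 300, n_discriminatory = 12,
                            n_age_assoc = 4, seed = seed, ...))
}

# Minimal hand-built feature table: explicit SQC/dilution/study values,
# used for arithmetic-level QC checks.
tiny_table <- function(sqc = rbind(c(100, 90, 50),
                                   c(100, 100, 100),
                                   c(100, 110, 150)),
                       dil_factors = c(1, 0.5, 0.25),
                       dil = NULL) {
  if (is.null(dil)) dil <- outer(dil_factors, c(100, 100, 100))
  study <- matrix(rep(c(80, 95, 120), each = 4), nrow = 4)
  ints <- rbind(study, sqc, dil)
  n <- nrow(ints)
  samples <- tibble::tibble(
    sample_id = sprintf("X%02d", seq_len(n)),
    role = c(rep("study", 4), rep("sqc", nrow(sqc)),
             rep("dilution", nrow(dil))),
    class = c("bacterial", "bacterial", "viral", "viral",
              rep(NA, nrow(sqc) + nrow(dil))),
    injection_order = seq_len(n),
    dilution_factor = c(rep(NA, 4 + nrow(sqc)), dil_factors),
    age_months = c(3, 10, 24, 60, rep(NA, nrow(sqc) + nrow(dil))),
    sex = c("M", "F", "M", "F", rep(NA, nrow(sqc) + nrow(dil)))
  )
  features <- tibble::tibble(
    feature_id = c("f1", "f2", "f3"), mz = c(200, 300, 400),
    rt_min = c(1, 2, 3), annotation = "unannotated", annotation_level = 4)
  feature_table(ints, samples, features)
}

# Exhaustive concordant-pair AUC oracle (half credit for ties).
oracle_auc <- function(scores, y01) {
  pos <- scores[y01 == 1]
  neg <- scores[y01 == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

# Independent single-component PLS1 oracle: weight from the SVD of the
# cross-covariance, then least-squares y-loading; returns predictions
# for new rows.
oracle_pls1_predict <- function(Xtrain, ytrain, Xnew) {
  xc <- colMeans(Xtrain)
  Xc <- sweep(Xtrain, 2, xc, "-")
  yc <- ytrain - mean(ytrain)
  w <- svd(crossprod(Xc, matrix(yc)))$u[, 1]
  t <- Xc %*% w
  q <- sum(yc * t) / sum(t^2)
  # orient as the package does: higher score = class 1
  if (q < 0) { w <- -w; t <- -t; q <- -q }
  tnew <- sweep(Xnew, 2, xc, "-") %*% w
  mean(ytrain) + q * as.numeric(tnew)
}

# Dense eigendecomposition PCA oracle on the covariance matrix.
oracle_pca <- function(Xc, k) {
  ev <- eigen(stats::cov(Xc), symmetric = TRUE)
  scores <- Xc %*% ev$vectors[, seq_len(k), drop = FALSE]
  list(scores = scores,
       explained = ev$values[seq_len(k)] * (nrow(Xc) - 1) / sum(Xc^2))
}
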