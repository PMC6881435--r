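test_that("pareto scaling is (x - mean)/sqrt(sd) and inverts exactly", {
  m <- cbind(a = c(1, 2, 3), b = c(2, 4, 9))
  sc <- pareto_scale(m)
  expect_equal(sc$values[, "a"], c(-1, 0, 1))
  expect_equal(unname(colMeans(sc$values)), c(0, 0))
  expect_equal(unscale(sc), m, tolerance = 1e-10)

  bad <- cbind(a = c(1, 2, 3), flat = c(5, 5, 5))
  expect_error(pareto_scale(bad), "flat")

  x <- withr::with_seed(1, matrix(stats::rexp(60, 0.01), 12, 5))
  colnames(x) <- letters[1:5]
  expect_lt(max(abs(colMeans(pareto_scale(x)$values))), 1e-10)
  expect_equal(unscale(pareto_scale(x)), x, tolerance = 1e-10)
})

test_that("PCA matches a dense eigendecomposition oracle", {
  x <- withr::with_seed(2, matrix(stats::rnorm(20 * 50), 20, 50))
  colnames(x) <- sprintf("v%02d", 1:50)
  sc <- pareto_scale(x)
  k <- 5
  pca <- fit_pca(sc, k)
  ora <- oracle_pca(sc$values, k)
  for (j in seq_len(k)) {
    expect_equal(abs(stats::cor(pca$scores[, j], ora$scores[, j])), 1,
                 tolerance = 1e-8)
    expect_equal(sd(pca$scores[, j]), sd(ora$scores[, j]), tolerance = 1e-8)
  }
  expect_equal(pca$explained_variance_fraction, ora$explained,
               tolerance = 1e-8)
  expect_equal(crossprod(pca$loadings), diag(k), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pca$explained_variance_fraction) <= 1e-12))
})

test_that("rank identities: rank-1 input and full-rank reconstruction", {
  u <- 1:8; v <- c(2, -1, 3)
  x <- outer(u, v) + 0 # rank 1, nonzero column sds
  colnames(x) <- c("a", "b", "c")
  xc <- sweep(x, 2, colMeans(x))
  pca <- fit_pca(xc, 2)
  expect_equal(pca$explained_variance_fraction[1], 1, tolerance = 1e-12)

  y <- withr::with_seed(3, matrix(stats::rnorm(10 * 6), 10, 6))
  yc <- sweep(y, 2, colMeans(y))
  full <- fit_pca(yc, 6)
  expect_equal(full$scores %*% t(full$loadings), yc, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("on simulated runs, SQC injections cluster tighter than study samples", {
  sim <- small_sim(seed = 13)
  keep <- sim$table$samples$role %in% c("study", "sqc")
  tab <- ft_subset(sim$table, samples = which(keep))
  pca <- fit_pca(pareto_scale(log(tab$intensities + 1)), 2)
  d <- as.matrix(stats::dist(pca$scores))
  sqc <- tab$samples$role == "sqc"
  mean_pair <- function(idx) mean(d[idx, idx][upper.tri(d[idx, idx])])
  expect_lt(mean_pair(sqc), mean_pair(!sqc))
})

test_that("OPLS-DA recovers a planted predictive direction", {
  y <- rep(c(1, 0), each = 15)
  x <- withr::with_seed(4, cbind(sig = y * 2 + stats::rnorm(30, 0, 0.1),
                                 matrix(stats::rnorm(30 * 60), 30, 60)))
  colnames(x) <- c("sig", sprintf("n%02d", 1:60))
  m <- fit_oplsda(pareto_scale(x), y, n_ortho = 1)
  expect_gt(stats::cor(m$predictive_scores, y), 0.95)
  expect_gt(abs(m$predictive_weights[1]), max(abs(m$predictive_weights[-1])))
})

test_that("predictive scores are orthogonal to every orthogonal score", {
  x <- withr::with_seed(5, matrix(stats::rnorm(24 * 40), 24, 40))
  colnames(x) <- sprintf("v%02d", 1:40)
  y <- rep(c(1, 0), 12)
  for (no in 1:3) {
    m <- fit_oplsda(pareto_scale(x), y, n_ortho = no)
    for (k in seq_len(no)) {
      expect_lt(abs(sum(m$predictive_scores * m$orthogonal_scores[, k])),
                1e-8)
    }
  }
})

test_that("n_ortho = 0 reduces to the single-component PLS-DA oracle", {
  for (s in 1:5) {
    x <- withr::with_seed(s, matrix(stats::rnorm(20 * 50), 20, 50))
    colnames(x) <- sprintf("v%02d", 1:50)
    y <- rep(c(1, 0), 10)
    sc <- pareto_scale(x)
    m <- fit_oplsda(sc, y, n_ortho = 0)
    pred <- predict(m, sc$values)
    expect_equal(pred$y_hat, oracle_pls1_predict(sc$values, y, sc$values),
                 tolerance = 1e-8)
  }
})

test_that("modelled plus residual X variance equals the total", {
  x <- withr::with_seed(6, matrix(stats::rnorm(30 * 25), 30, 25))
  colnames(x) <- sprintf("v%02d", 1:25)
  y <- rep(c(1, 0), 15)
  sc <- pareto_scale(x)
  m <- fit_oplsda(sc, y, n_ortho = 2)
  X <- sweep(sc$values, 2, m$x_center)
  Xres <- X - m$predictive_scores %*% t(m$predictive_loadings)
  for (k in 1:2) {
    Xres <- Xres - m$orthogonal_scores[, k] %*% t(m$orthogonal_loadings[, k])
  }
  expect_equal(m$r2x_cum + sum(Xres^2) / sum(X^2), 1, tolerance = 1e-8)
  expect_true(m$r2y_cum >= 0 && m$r2y_cum <= 1)
})

test_that("Q2 behaves across signal, null and bound cases", {
  # dominant informative feature: near-perfect prediction
  y <- rep(c(1, 0), each = 20)
  x <- withr::with_seed(7, cbind(y * 4 + stats::rnorm(40, 0, 0.05),
                                 matrix(stats::rnorm(40 * 10, 0, 0.05),
                                        40, 10)))
  colnames(x) <- sprintf("v%02d", 1:11)
  expect_gt(cross_validated_q2(pareto_scale(x), y, 1, 7, seed = 1), 0.9)

  # y independent of X: Q2 typically negative, never above 1
  q2s <- vapply(1:40, function(s) {
    xn <- withr::with_seed(s, matrix(stats::rnorm(40 * 50), 40, 50))
    cross_validated_q2(pareto_scale(xn), y, 1, 7, seed = s)
  }, numeric(1))
  expect_lt(stats::median(q2s), 0)
  expect_true(all(q2s <= 1))
})

test_that("permutation p has the add-one floor and labelling-swap invariance", {
  y <- rep(c(1, 0), each = 15)
  x <- withr::with_seed(8, cbind(y * 3 + stats::rnorm(30, 0, 0.2),
                                 matrix(stats::rnorm(30 * 20), 30, 20)))
  colnames(x) <- sprintf("v%02d", 1:21)
  sc <- pareto_scale(x)
  pr <- permutation_test(sc, y, 1, n_perm = 39, seed = 5)
  expect_equal(pr$p_value, 1 / 40) # observed beats all permutations
  expect_true(pr$valid)
  expect_length(pr$permuted_q2, 39)

  swapped <- permutation_test(sc, 1 - y, 1, n_perm = 39, seed = 5)
  expect_equal(swapped$p_value, pr$p_value)
  expect_equal(swapped$observed_q2, pr$observed_q2, tolerance = 1e-10)

  # identity permutation reproduces the observed Q2
  expect_equal(pr$observed_q2,
               cross_validated_q2(sc, y, 1, 7, seed = 5), tolerance = 1e-12)
})

test_that("S-plot axes have their defining identities", {
  y <- rep(c(1, 0), each = 12)
  x <- withr::with_seed(9, cbind(y + stats::rnorm(24, 0, 0.4),
                                 matrix(stats::rnorm(24 * 15), 24, 15)))
  colnames(x) <- sprintf("v%02d", 1:16)
  sc <- pareto_scale(x)
  m <- fit_oplsda(sc, y, 1)
  # a column equal to the predictive score: pcorr exactly 1
  x2 <- sc$values
  x2[, 5] <- m$predictive_scores + m$x_center[5]
  sp <- s_plot(m, x2, cutoff = 0.05)
  expect_equal(sp$pcorr[5], 1, tolerance = 1e-10)
  # a column orthogonal to the predictive score: p1 ~ 0, not shortlisted
  t_p <- m$predictive_scores
  ortho <- stats::residuals(stats::lm(stats::rnorm(24) ~ t_p))
  x3 <- sc$values
  x3[, 6] <- ortho * 1e-3 + m$x_center[6]
  sp3 <- s_plot(m, x3, cutoff = 0.05)
  expect_lt(abs(sp3$p1[6]), 1e-10)
  expect_false(sp3$shortlisted[6])
  expect_true(all(sp3$pcorr >= -1 & sp3$pcorr <= 1))
  expect_true(all(sp3$shortlisted == (abs(sp3$p1) >= 0.05)))
})

test_that("the S-plot shortlist is precise for planted discriminators", {
  sim <- simulate_study(sim_config(seed = 31))
  qc <- apply_qc(sim$table)
  tab <- log_transform(qc$table)
  sc <- pareto_scale(tab$intensities)
  y <- class_vector(tab)
  m <- fit_oplsda(sc, y, 1)
  sp <- s_plot(m, sc, 0.05)
  truth <- sim$truth$discriminatory
  hits <- sp[sp$shortlisted, ]
  expect_gt(mean(hits$feature_id %in% truth$feature_id), 0.6)
  # planted features dominate the covariance axis
  planted <- sp$feature_id %in% truth$feature_id
  expect_gt(stats::median(abs(sp$p1[planted])),
            stats::quantile(abs(sp$p1[!planted]), 0.99))
  # directions of true positives match the planted signs
  tp <- dplyr::inner_join(hits, truth, by = "feature_id")
  expect_true(all(tp$direction.x == tp$direction.y))
})
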