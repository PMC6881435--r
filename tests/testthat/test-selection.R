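test_that("differential abundance: exact null and BH identities", {
  half <- withr::with_seed(1, matrix(exp(stats::rnorm(20 * 30, 8, 0.4)),
                                     20, 30))
  x <- rbind(half, half) # the two groups hold identical values
  colnames(x) <- sprintf("g%02d", 1:30)
  samples <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:40), role = "study",
    class = rep(c("bacterial", "viral"), each = 20),
    injection_order = 1:40, dilution_factor = NA_real_,
    age_months = rep(c(3, 50), 20), sex = rep(c("M", "F"), 20))
  features <- tibble::tibble(feature_id = colnames(x), mz = 1:30, rt_min = 1,
                             annotation = "unannotated", annotation_level = 4)
  tab <- log_transform(feature_table(x, samples, features), 1)
  da <- diff_abundance(tab, "class")
  expect_equal(da$estimate, rep(0, 30))
  expect_equal(da$t_statistic, rep(0, 30))
  expect_equal(da$p_value, rep(1, 30))
  # equal raw p across features: BH leaves them unchanged
  expect_equal(da$fdr_adjusted_p, da$p_value)
  expect_true(all(da$fdr_adjusted_p >= da$p_value))
})

test_that("moderated and plain screens agree on strong signals", {
  sim <- small_sim(seed = 17, age_effect_size = 2)
  tab <- log_transform(ft_study(sim$table))
  plain <- diff_abundance(tab, "age_median_split")
  mod <- diff_abundance(tab, "age_median_split", moderated = TRUE)
  top_plain <- plain$feature_id[plain$fdr_adjusted_p < 0.05]
  top_mod <- mod$feature_id[mod$fdr_adjusted_p < 0.05]
  expect_gt(length(intersect(top_plain, top_mod)) /
              max(1, length(union(top_plain, top_mod))), 0.5)
  expect_gt(stats::cor(plain$t_statistic, mod$t_statistic), 0.98)
})

test_that("planted age-associated features are recovered at FDR 0.05", {
  hits <- vapply(1:10, function(s) {
    sim <- small_sim(seed = 100 + s, age_effect_size = 1.5)
    tab <- log_transform(ft_study(sim$table))
    da <- diff_abundance(tab, "age_median_split")
    sig <- da$feature_id[da$fdr_adjusted_p < 0.05]
    mean(sim$truth$age_assoc_ids %in% sig)
  }, numeric(1))
  expect_gte(stats::median(hits), 0.75)
})

test_that("a logistic step reproduces the 2x2-table log odds ratio", {
  # balanced binary y, binary feature: closed-form MLE from the table
  y <- rep(c(1, 0), each = 20)
  x <- c(rep(1, 15), rep(0, 5), rep(1, 8), rep(0, 12))
  fit <- lipidsig:::univariate_fit(x, y, "logistic")
  lor <- log((15 * 12) / (5 * 8))
  expect_equal(fit$coef, lor, tolerance = 1e-6)
  expect_false(fit$firth)
})

test_that("FS-PLS selects a duplicated informative column exactly once", {
  y <- rep(c(1, 0), length.out = 39)
  x <- withr::with_seed(1, matrix(stats::rnorm(39 * 10), 39, 10))
  x[, 1] <- y + stats::rnorm(39, 0, 0.5)
  x[, 2] <- x[, 1]
  colnames(x) <- sprintf("V%d", 1:10)
  m <- fspls_select(x, y, fspls_config(p_thresh = 0.5, max_features = 10))
  expect_equal(sum(c("V1", "V2") %in% m$selected$feature_id), 1)
  # the duplicate's deflated column is numerically zero after selection
  first <- intersect(c("V1", "V2"), m$selected$feature_id)[1]
  xs <- scale(x)
  s <- xs[, first]
  xd <- xs - s %*% (crossprod(s, xs) / sum(s^2))
  dup <- setdiff(c("V1", "V2"), first)
  expect_lt(max(abs(xd[, dup])), 1e-10)
})

test_that("FS-PLS with max_features = 1 equals the best univariate fit", {
  y <- rep(c(1, 0), length.out = 30)
  x <- withr::with_seed(2, matrix(stats::rnorm(30 * 12), 30, 12))
  x[, 4] <- y * 1.2 + stats::rnorm(30, 0, 0.8)
  colnames(x) <- sprintf("V%d", 1:12)
  m <- fspls_select(x, y, fspls_config(p_thresh = 0.99, max_features = 1))
  # oracle: exhaustive univariate logistic fits on standardized columns
  xs <- scale(x)
  ps <- vapply(1:12, function(j) {
    summary(stats::glm(y ~ xs[, j],
                       family = stats::binomial()))$coefficients[2, 4]
  }, numeric(1))
  expect_equal(m$selected$feature_id, colnames(x)[which.min(ps)])
  expect_equal(m$selected$step_p_value, min(ps), tolerance = 1e-8)
})

test_that("selection is invariant to column permutation", {
  y <- rep(c(1, 0), length.out = 39)
  x <- withr::with_seed(3, {
    x <- matrix(stats::rnorm(39 * 15), 39, 15)
    x[, c(2, 9)] <- x[, c(2, 9)] + outer(y, c(1.6, 1.6))
    x
  })
  colnames(x) <- sprintf("V%d", 1:15)
  m1 <- fspls_select(x, y, fspls_config())
  perm <- withr::with_seed(4, sample(15))
  m2 <- fspls_select(x[, perm], y, fspls_config())
  expect_setequal(m1$selected$feature_id, m2$selected$feature_id)
})

test_that("deflation makes selected and remaining columns orthogonal", {
  y <- rep(c(1, 0), length.out = 39)
  x <- withr::with_seed(5, {
    x <- matrix(stats::rnorm(39 * 10), 39, 10)
    x[, 1:2] <- x[, 1:2] + outer(y, c(2, 2))
    x
  })
  colnames(x) <- sprintf("V%d", 1:10)
  m <- fspls_select(x, y, fspls_config(p_thresh = 0.2, max_features = 3))
  expect_gte(nrow(m$selected), 2)
  # replay the recorded deflations: the deflated basis is orthogonal
  xs <- sweep(sweep(x, 2, m$center), 2, m$scale, "/")
  basis <- list()
  xd <- xs
  for (step in m$deflation_record) {
    s <- xd[, step$feature_id]
    basis[[step$feature_id]] <- s
    xd <- xd - s %*% (crossprod(s, xd) / sum(s^2))
  }
  b <- do.call(cbind, basis)
  off <- crossprod(b) - diag(diag(crossprod(b)))
  expect_lt(max(abs(off)), 1e-8)
  # every remaining deflated column is orthogonal to the selected basis
  rem <- setdiff(colnames(x), m$selected$feature_id)
  expect_lt(max(abs(crossprod(b, xd[, rem]))), 1e-8)
})

test_that("pure noise yields an empty signature at a stringent threshold", {
  y <- rep(c(1, 0), length.out = 39)
  empty <- vapply(1:50, function(s) {
    x <- withr::with_seed(s, matrix(stats::rnorm(39 * 28), 39, 28))
    nrow(fspls_select(x, y, fspls_config(p_thresh = 1e-4))$selected) == 0
  }, logical(1))
  expect_gte(mean(empty), 0.95)
})

test_that("perfect separation falls back to penalized likelihood", {
  y <- rep(c(1, 0), each = 10)
  x <- cbind(sep = y * 10 - 5 + stats::rnorm(20, 0, 0.01),
             withr::with_seed(6, matrix(stats::rnorm(20 * 3), 20, 3)))
  colnames(x) <- c("sep", "a", "b", "c")
  m <- fspls_select(x, y, fspls_config(p_thresh = 0.05))
  expect_true("sep" %in% m$selected$feature_id)
  expect_true(m$selected$firth[m$selected$feature_id == "sep"])
  expect_true(all(is.finite(m$final_coefficients)))
})

test_that("robustness check responds to the covariate screen", {
  y <- rep(c(1, 0), length.out = 39)
  x <- withr::with_seed(7, {
    x <- matrix(stats::rnorm(39 * 12), 39, 12)
    x[, c(1, 5)] <- x[, c(1, 5)] + outer(y, c(2, 2))
    x
  })
  colnames(x) <- sprintf("V%d", 1:12)
  none <- tibble::tibble(feature_id = colnames(x),
                         fdr_adjusted_p = rep(1, 12))
  r0 <- robustness_check(x, y, none, fspls_config(p_thresh = 0.2))
  expect_true(r0$agreement)
  expect_identical(r0$full$selected$feature_id,
                   r0$screened$selected$feature_id)

  # force removal of a selected feature: signatures must differ
  hit <- r0$full$selected$feature_id[1]
  forced <- dplyr::mutate(none,
                          fdr_adjusted_p = ifelse(.data$feature_id == hit,
                                                  0.001, 1))
  r1 <- robustness_check(x, y, forced, fspls_config(p_thresh = 0.2))
  expect_false(r1$agreement)
  expect_false(hit %in% r1$screened$selected$feature_id)
  expect_error(robustness_check(x, y,
                                dplyr::mutate(none, fdr_adjusted_p = 0),
                                fspls_config()),
               "every")
})

test_that("signatures carry directions consistent with the coefficients", {
  y <- rep(c(1, 0), length.out = 40)
  x <- withr::with_seed(8, {
    x <- matrix(stats::rnorm(40 * 8), 40, 8)
    x[, 1] <- x[, 1] + y * 1.8      # up in bacterial
    x[, 2] <- x[, 2] - y * 1.8      # up in viral
    x
  })
  colnames(x) <- sprintf("V%d", 1:8)
  m <- fspls_select(x, y, fspls_config(p_thresh = 0.05))
  sig <- signature_of(m)
  expect_equal(sig$direction[sig$feature_id == "V1"], "up_in_bacterial")
  expect_equal(sig$direction[sig$feature_id == "V2"], "up_in_viral")
  m0 <- fspls_select(withr::with_seed(9, matrix(stats::rnorm(40 * 5), 40, 5)),
                     y, fspls_config(p_thresh = 1e-6))
  expect_error(signature_of(m0), "empty")
})
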