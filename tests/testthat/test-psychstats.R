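test_that("learning index is the relative threshold change", {
  expect_equal(learning_index(2, 2), 0)
  expect_equal(learning_index(4, 2), -0.5)
  for (c in c(0.1, 3, 42))
    expect_equal(learning_index(c * 4, c * 2), -0.5) # scale invariance
  expect_error(learning_index(0, 1), "positive")
  expect_error(learning_index(-2, 1), "positive")
})

test_that("exclusion rule drops weak learners at the configured criterion", {
  subj <- data.frame(subject_id = c("a", "b", "c"),
                     randomization = c("phase", "phase", "contrast"),
                     li_training = c(-0.35, -0.10, -0.25))
  ex <- apply_exclusions(subj)
  expect_equal(ex$retained$subject_id, c("a", "c"))
  expect_equal(ex$excluded$subject_id, "b")
  # robustness-check variant: stricter criterion
  ex30 <- apply_exclusions(subj, criterion_li = -0.30)
  expect_equal(ex30$retained$subject_id, "a")
})

test_that("power-law fit recovers noise-free parameters", {
  b <- 1:20
  y <- 2 * b^(-0.5) + 0.5
  fit <- power_law_fit(b, y)
  expect_true(fit$converged)
  expect_equal(fit$a, 2, tolerance = 1e-4)
  expect_equal(fit$beta, 0.5, tolerance = 1e-4)
  expect_equal(fit$c, 0.5, tolerance = 1e-4)
  expect_lt(fit$residual, 1e-3)

  flat <- power_law_fit(b, rep(1.7, 20))
  expect_lt(abs(flat$beta) * flat$a, 0.02) # no decay component

  two <- power_law_fit(b, 3 * b^(-0.8), three_param = FALSE)
  expect_equal(two$beta, 0.8, tolerance = 1e-4)
  expect_equal(two$c, 0)
})

test_that("power law beats a linear fit on a simulated staircase learner", {
  set.seed(31)
  b <- 1:20
  truth <- 1.0 + 2.5 * b^(-0.7)
  thr <- vapply(truth, function(a) {
    blk <- run_block(observer_function(observer_model(a)))
    block_threshold(blk$staircases)$threshold_deg
  }, numeric(1))
  fit <- power_law_fit(b, thr)
  lin <- lm(thr ~ b)
  expect_lt(fit$residual^2, sum(residuals(lin)^2))
})

test_that("welch test matches direction, zero cases and effect size", {
  w <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w$t, 0)
  expect_equal(w$cohens_d, 0)
  w2 <- welch_t(c(1, 2, 3), c(2, 3, 4)) # a - b < 0
  expect_lt(w2$t, 0)
  expect_lt(w2$cohens_d, 0)
  expect_error(welch_t(rep(1, 3), rep(2, 3)), "variance")
})

test_that("welch p agrees with an exact permutation oracle on toy data", {
  a <- c(4.1, 5.0, 6.2, 5.5, 4.8, 5.9)
  b <- c(6.0, 6.8, 7.1, 5.7, 6.5, 7.4)
  w <- welch_t(a, b)
  pool <- c(a, b)
  idx <- utils::combn(12, 6)
  tobs <- abs(w$t)
  tperm <- apply(idx, 2, function(i) {
    abs(welch_t(pool[i], pool[-i])$t)
  })
  p_perm <- mean(tperm >= tobs - 1e-12)
  expect_lt(abs(w$p - p_perm), 0.05)
})

test_that("pearson test follows the closed form and flags r = 1", {
  # construct a sample with exactly r = 0.71 at n = 13
  set.seed(8)
  x <- rnorm(13)
  e <- residuals(lm(rnorm(13) ~ x))
  y <- 0.71 * scale(x)[, 1] + sqrt(1 - 0.71^2) * scale(e)[, 1]
  res <- pearson_r_test(x, y)
  expect_equal(res$r, 0.71, tolerance = 1e-10)
  expect_equal(res$df, 11)
  # the closed form gives 3.344 here, not the commonly misquoted rounding
  expect_equal(res$t, 0.71 * sqrt(11) / sqrt(1 - 0.71^2), tolerance = 1e-10)
  expect_equal(res$t, 3.344, tolerance = 0.01)
  expect_equal(res$p, 2 * pt(-res$t, 11))

  expect_warning(perfect <- pearson_r_test(1:5, 2 * (1:5)), "infinite")
  expect_equal(perfect$p, 0)
  expect_error(pearson_r_test(rep(1, 5), 1:5), "zero-variance")
  expect_error(pearson_r_test(1:3, 1:3), "n >= 4")
})

test_that("null correlations concentrate near zero in large samples", {
  set.seed(9)
  res <- pearson_r_test(rnorm(2000), rnorm(2000))
  expect_lt(abs(res$r), 0.05)
})

test_that("fisher z comparison is symmetric and antisymmetric as expected", {
  same <- compare_independent_correlations(0.4, 20, 0.4, 25, sided = "one")
  expect_equal(same$z_stat, 0)
  expect_equal(same$cohens_q, 0)
  expect_equal(same$p_value, 0.5)

  ab <- compare_independent_correlations(0.7, 15, 0.2, 18, sided = "two")
  ba <- compare_independent_correlations(0.2, 18, 0.7, 15, sided = "two")
  expect_equal(ab$z_stat, -ba$z_stat)
  expect_equal(ab$cohens_q, ba$cohens_q)
  expect_equal(ab$p_value, ba$p_value)

  expect_error(compare_independent_correlations(1, 10, 0.5, 10), "< 1")
  expect_error(compare_independent_correlations(0.5, 3, 0.5, 10), "n > 3")
})

test_that("partial eta squared is monotone in F and bounded", {
  expect_equal(partial_eta_sq(0, 3, 100), 0)
  f <- seq(0, 50, by = 0.5)
  e <- partial_eta_sq(f, 2, 60)
  expect_true(all(diff(e) > 0))
  expect_true(all(e >= 0 & e < 1))
  expect_error(partial_eta_sq(-1, 1, 10), "nonnegative")
})
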