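test_that("ordinary least squares matches the hand-computed line", {
  exact <- fit_calibration(data.frame(concentration_nM = c(0, 1, 2),
                                      normalized = c(1, 3, 5)))
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(exact$r_squared, 1)

  f <- fit_calibration(data.frame(concentration_nM = c(0, 1, 2),
                                  normalized = c(0, 1, 1)))
  expect_equal(f$slope, 0.5)
  expect_equal(f$intercept, 1 / 6)
  expect_equal(f$r_squared, 0.75)
  expect_equal(f$pearson_r, sqrt(0.75), tolerance = 1e-12)
})

test_that("calibration design and rejects are validated", {
  expect_error(fit_calibration(data.frame(concentration_nM = c(0, 0, 0),
                                          normalized = c(1, 2, 3))),
               class = "lfa_design_error")
  m <- data.frame(concentration_nM = c(0, 0, 1, 2),
                  normalized = c(NA, 1, 3, 5))
  f <- fit_calibration(m)
  expect_equal(nrow(f$rejects), 1)
  expect_equal(f$n_points, 3)
  expect_equal(f$slope, 2)
})

test_that("replicate statistics use sample SD and Student-t intervals", {
  s <- replicate_stats(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$ci_low, 2 - qt(0.975, 2) / sqrt(3))
  expect_equal(s$ci_high, 2 + qt(0.975, 2) / sqrt(3))
  expect_equal(c(s$ci_low, s$ci_high), c(-0.484, 4.484), tolerance = 1e-3)

  z <- replicate_stats(c(5, 5, 5, 5))
  expect_equal(z$sd, 0)
  expect_equal(c(z$ci_low, z$ci_high), c(5, 5))

  one <- replicate_stats(7)
  expect_equal(one$mean, 7)
  expect_true(is.na(one$sd))
  expect_error(replicate_stats(numeric(0)), class = "lfa_invalid_input")
})

test_that("per-concentration statistics nest the group means", {
  m <- data.frame(concentration_nM = rep(c(0, 10), each = 3),
                  normalized = c(1, 2, 3, 4, 5, 6))
  f <- fit_calibration(m)
  pc <- f$per_concentration
  expect_equal(pc$mean, c(2, 5))
  expect_equal(pc$sd, c(1, 1))
  expect_true(all(pc$ci_low <= pc$mean & pc$mean <= pc$ci_high))
})

test_that("inverse prediction solves the line and flags below-range values", {
  f <- toy_fit()
  expect_equal(as.numeric(predict_concentration(f, 5)), 2)
  expect_equal(as.numeric(predict_concentration(f, 1)), 0)
  below <- predict_concentration(f, 0.5)
  expect_equal(as.numeric(below), -0.25)
  expect_true(attr(below, "below_range"))

  flat <- fit_calibration(data.frame(concentration_nM = c(0, 1, 2),
                                     normalized = c(1, 1, 1)))
  expect_error(predict_concentration(flat, 1),
               class = "lfa_noninvertible_model")
})

test_that("pearson_vs_predicted squared equals R^2 for simple OLS", {
  f <- fit_calibration(data.frame(concentration_nM = c(0, 1, 2),
                                  normalized = c(0, 1, 1)))
  expect_equal(pearson_vs_predicted(f), sqrt(0.75), tolerance = 1e-12)
  expect_equal(pearson_vs_predicted(toy_fit()), 1)

  const <- data.frame(concentration_nM = c(0, 1, 2),
                      normalized = c(2, 2, 2))
  fc <- fit_calibration(const)
  expect_error(pearson_vs_predicted(fc), class = "lfa_undefined_correlation")
})

test_that("fits are scale-equivariant in the ratio", {
  set.seed(11)
  m <- data.frame(concentration_nM = rep(c(0, 1, 20, 40, 60, 80, 100), 5))
  m$normalized <- 0.5 + 0.02 * m$concentration_nM + rnorm(nrow(m), 0, 0.01)
  f1 <- fit_calibration(m)
  k <- 3.7
  m2 <- m; m2$normalized <- k * m$normalized
  f2 <- fit_calibration(m2)
  expect_equal(f2$slope, k * f1$slope)
  expect_equal(f2$intercept, k * f1$intercept)
  expect_equal(f2$r_squared, f1$r_squared)
  l1 <- limits_method1(m$normalized[m$concentration_nM == 0], f1)
  l2 <- limits_method1(m2$normalized[m2$concentration_nM == 0], f2)
  expect_equal(l2$lod_intensity, k * l1$lod_intensity)
  expect_equal(l2$lod_nM, l1$lod_nM)
  expect_equal(l2$loq_nM, l1$loq_nM)
})

test_that("slope recovery is unbiased at the calibration design", {
  # ratio-level simulation at the assay design, 200 seeds
  design <- rep(c(0, 1, 20, 40, 60, 80, 100), each = 5)
  slopes <- vapply(1:200, function(s) {
    set.seed(s)
    m <- data.frame(concentration_nM = design,
                    normalized = 0.5 + 0.02 * design +
                      rnorm(length(design), 0, 0.01))
    fit_calibration(m)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.02) / 0.02, 0.05)
})
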