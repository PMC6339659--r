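test_that("profile extraction averages the central ROI per flow position", {
  img <- as_strip_image(matrix(0.5, 3, 3), signal = TRUE)
  p <- extract_profile(img)
  expect_equal(p$values, rep(0.5, 3))
  expect_equal(p$positions_px, 0:2)

  ramp <- as_strip_image(matrix(rep((0:9) / 10, 5), 10, 5), signal = TRUE)
  expect_equal(extract_profile(ramp, lane_geometry())$values, (0:9) / 10)

  narrow <- as_strip_image(matrix(0.5, 10, 2), signal = TRUE)
  expect_error(extract_profile(narrow), class = "lfa_invalid_geometry")
})

test_that("baseline correction removes band-free backgrounds", {
  # linear ramp, no bands
  p <- as_profile(0.1 + 0.001 * (0:99))
  expect_true(all(correct_baseline(p, "flank_linear")$corrected <= 1e-9))
  # constant background
  pc <- correct_baseline(as_profile(rep(0.2, 100)), "flank_linear")
  expect_equal(pc$corrected, rep(0, 100))
  expect_equal(pc$baseline, rep(0.2, 100), tolerance = 1e-12)
  # rolling_min handles the constant case too
  expect_true(all(correct_baseline(as_profile(rep(0.2, 100)),
                                   "rolling_min", 31)$corrected <= 1e-12))
  expect_error(correct_baseline(p, "rolling_min", window_px = 2),
               class = "lfa_parameter_error")
})

test_that("a Gaussian band on a ramp is recovered to within 5%", {
  x <- 0:119
  band <- 0.3 * exp(-(x - 60)^2 / (2 * 4^2))
  p <- correct_baseline(as_profile(0.1 + 0.002 * x + band), "flank_linear")
  expect_equal(max(p$corrected), 0.3, tolerance = 0.05)
  expect_equal(which.max(p$corrected) - 1, 60)
})

test_that("band detection finds the analytic peak positions exactly", {
  s <- generate_strip(synthetic_strip_spec())  # bands at 40 and 90 px
  prof <- correct_baseline(extract_profile(to_signal_channel(s$image)),
                           "flank_linear")
  b <- detect_bands(prof, lane_geometry(), px_per_mm = 10)
  expect_equal(b$tl$center_px, 40)
  expect_equal(b$cl$center_px, 90)
  expect_lt(b$tl$center_px, b$cl$center_px)
  expect_true(all(c(b$tl$corrected_intensity, b$cl$corrected_intensity) >= 0))
  # windows are half-open 1.5-band-width (15 px) intervals around the centers
  expect_equal(diff(unname(b$tl$window_px)), 16)
  expect_equal(mean(unname(b$tl$window_px)), 40)
})

test_that("band detection fails informatively on flat or one-line strips", {
  flat <- correct_baseline(as_profile(rep(0, 120)), "flank_linear")
  expect_error(detect_bands(flat, lane_geometry(), 10),
               class = "lfa_band_not_found")

  only_cl <- generate_strip(synthetic_strip_spec(band_amplitudes = c(0, 0.3)))
  expect_error(
    suppressMessages(quantify_strip(only_cl$image)),
    regexp = "test line \\(tl\\)", class = "lfa_band_not_found")

  prof <- correct_baseline(as_profile(rep(0, 120)), "flank_linear")
  expect_error(detect_bands(prof, lane_geometry(), px_per_mm = NA),
               class = "lfa_parameter_error")
  expect_error(detect_bands(extract_profile(as_strip_image(
    matrix(0.5, 120, 30), signal = TRUE)), lane_geometry(), 10),
    class = "lfa_invalid_input")
})

test_that("band detection is translation-equivariant", {
  for (shift_mm in c(-1, 0.5, 1.5)) {
    s <- generate_strip(synthetic_strip_spec(
      band_centers_mm = c(4, 9) + shift_mm))
    prof <- correct_baseline(extract_profile(to_signal_channel(s$image)),
                             "flank_linear")
    b <- detect_bands(prof, lane_geometry(), 10)
    expect_equal(b$tl$center_px, 40 + 10 * shift_mm, tolerance = 1e-9)
    expect_equal(b$cl$center_px, 90 + 10 * shift_mm, tolerance = 1e-9)
  }
})

test_that("quantified ratios match the generator's analytic areas", {
  # tl area twice cl area -> normalized (cl/tl) = 0.5
  s <- generate_strip(synthetic_strip_spec(band_amplitudes = c(0.4, 0.2)))
  m <- suppressMessages(quantify_strip(s$image))
  expect_equal(m$normalized, 0.5, tolerance = 0.02)
  expect_equal(m$standardized, 2, tolerance = 0.02 * 4)
  expect_equal(m$normalized * m$standardized, 1)
})

test_that("intensity ratios are invariant to joint amplitude scaling and exposure", {
  base <- generate_strip(synthetic_strip_spec(band_amplitudes = c(0.4, 0.2)))
  m0 <- suppressMessages(quantify_strip(base$image))
  for (k in c(0.5, 1.5)) {
    sk <- generate_strip(synthetic_strip_spec(
      band_amplitudes = k * c(0.4, 0.2)))
    mk <- suppressMessages(quantify_strip(sk$image))
    expect_equal(mk$normalized, m0$normalized, tolerance = 0.01)
  }
  # global exposure drop: pixel lightness x 0.9
  dim_img <- base$image
  dim_img$pixels <- dim_img$pixels * 0.9
  m_dim <- suppressMessages(quantify_strip(dim_img))
  expect_equal(m_dim$normalized / m0$normalized, 1, tolerance = 0.03)
})

test_that("normalized ratio increases with concentration on a noiseless series", {
  cs <- generate_calibration_set(calibration_scenario(
    replicates = 1, ratio_noise_sd = 0, seed = 3))
  m <- quantify_set(cs)
  ord <- order(m$concentration_nM)
  expect_true(all(diff(m$normalized[ord]) >= 0))
})

test_that("saturated strips are flagged but still measured", {
  spec <- synthetic_strip_spec(band_amplitudes = c(0.5, 0.25),
                               background = c(0, 0))
  s <- generate_strip(spec)  # background darkness 0 -> lightness exactly 1
  m <- suppressMessages(quantify_strip(s$image))
  expect_match(m$flags, "saturated")
  expect_equal(m$normalized, 0.5, tolerance = 0.02)
})
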