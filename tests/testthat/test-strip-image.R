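test_that("8-bit and 16-bit images load scaled to [0,1]", {
  f8 <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(1, 5, 10), f8)
  img <- load_strip_image(f8, source_label = "test")
  expect_true(all(img$pixels == 1))
  expect_identical(img$channels, 1L)
  expect_equal(dim(img$pixels), c(5, 10))

  skip_if_not_installed("tiff")
  f16 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(1, 5, 10), f16, bits.per.sample = 16)
  img16 <- load_strip_image(f16)
  expect_true(all(img16$pixels == 1))
})

test_that("load errors on missing or corrupt files", {
  expect_error(load_strip_image(tempfile(fileext = ".png")),
               class = "lfa_decode_error")
  f <- withr::local_tempfile(fileext = ".png")
  writeLines("not a png", f)
  expect_error(load_strip_image(f), class = "lfa_decode_error")
})

test_that("lossless write/load round trip is within 8-bit quantization", {
  s <- generate_strip(synthetic_strip_spec(noise_sd = 0.01, seed = 7))
  f <- withr::local_tempfile(fileext = ".png")
  write_strip_image(s$image, f)
  back <- load_strip_image(f)
  expect_lt(max(abs(back$pixels - s$image$pixels)), 1 / 255 + 1e-12)
  # idempotence: a second round trip changes nothing further
  f2 <- withr::local_tempfile(fileext = ".png")
  write_strip_image(back, f2)
  expect_identical(load_strip_image(f2)$pixels, back$pixels)
})

test_that("signal channel extraction inverts polarity per policy", {
  px <- array(0, dim = c(1, 3, 3))
  px[1, 1, ] <- c(1, 1, 1)          # white membrane
  px[1, 2, ] <- c(0, 0, 0)          # black
  px[1, 3, ] <- c(0.9, 0.3, 0.35)   # red AuNP band
  img <- as_strip_image(px)
  g <- to_signal_channel(img, "green")
  expect_equal(as.numeric(g$pixels), c(0, 1, 0.7))
  expect_equal(as.numeric(to_signal_channel(img, "red")$pixels[1, 2]), 1)
  expect_error(to_signal_channel(img, "alpha"), class = "lfa_config_error")
  # polarity inversion is an involution
  expect_equal(1 - (1 - px[1, , 2]), px[1, , 2])
})

test_that("grayscale input passes through the same inversion", {
  img <- as_strip_image(matrix(c(0, 0.25, 1), 1, 3))
  expect_equal(as.numeric(to_signal_channel(img, "green")$pixels),
               c(1, 0.75, 0))
})

test_that("canonicalization honors hints and flips cl-upstream strips", {
  s <- generate_strip(synthetic_strip_spec(band_amplitudes = c(0.2, 0.5)))
  sig <- to_signal_channel(s$image)
  same <- canonicalize_orientation(sig, flow_direction_hint = "tl_first")
  expect_identical(same$pixels, sig$pixels)

  # control (stronger) band upstream at 40 px: auto must flip
  rev_s <- generate_strip(synthetic_strip_spec(band_amplitudes = c(0.5, 0.2)))
  sig_r <- to_signal_channel(rev_s$image)
  fixed <- canonicalize_orientation(sig_r, flow_direction_hint = "auto")
  prof <- correct_baseline(extract_profile(fixed), "flank_linear")
  b <- detect_bands(prof, lane_geometry(), 10)
  expect_equal(b$tl$center_px, 120 - 1 - 90)
  expect_equal(b$cl$center_px, 120 - 1 - 40)
  expect_gt(b$cl$corrected_intensity, b$tl$corrected_intensity)

  # idempotent under auto
  again <- canonicalize_orientation(fixed, flow_direction_hint = "auto")
  expect_identical(again$pixels, fixed$pixels)
})

test_that("ambiguous orientation is refused rather than guessed", {
  sq <- as_strip_image(matrix(0.5, 50, 50), signal = TRUE)
  expect_error(canonicalize_orientation(sq, flow_direction_hint = "auto"),
               class = "lfa_orientation_ambiguous")
  # equal bands: amplitude rule cannot decide
  eq <- generate_strip(synthetic_strip_spec(band_amplitudes = c(0.3, 0.3)))
  expect_error(canonicalize_orientation(to_signal_channel(eq$image),
                                        flow_direction_hint = "auto"),
               class = "lfa_orientation_ambiguous")
  # featureless rectangle: bands not found
  flat <- as_strip_image(matrix(0.9, 100, 30), signal = TRUE)
  expect_error(canonicalize_orientation(flat, flow_direction_hint = "auto"),
               class = "lfa_orientation_ambiguous")
})

test_that("px_per_mm is estimated from the detected line spacing", {
  s <- generate_strip(synthetic_strip_spec(band_amplitudes = c(0.2, 0.5)))
  sig <- to_signal_channel(s$image)
  sig$px_per_mm <- NA_real_
  canon <- canonicalize_orientation(sig, flow_direction_hint = "tl_first")
  expect_equal(canon$px_per_mm, 10, tolerance = 0.05)
})
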