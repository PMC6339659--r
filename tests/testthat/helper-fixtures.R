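# Shared fixtures built in code.

# Quantify every strip of a generated calibration set (in memory, quietly).
quantify_set <- function(cs, ...) {
  rows <- lapply(seq_along(cs$strips), function(i)
    as.data.frame(suppressMessages(quantify_strip(
      cs$strips[[i]]$image,
      concentration_nM = cs$sample_sheet$concentration_nM[i],
      replicate = cs$sample_sheet$replicate[i], ...))))
  do.call(rbind, rows)
}

# Bare strip_image around a pixel array (bypasses file IO).
as_strip_image <- function(pixels, px_per_mm = NA_real_, signal = FALSE) {
  lfaquant:::new_strip_image(pixels, px_per_mm = px_per_mm, signal = signal)
}

# Signal profile ready for band detection, from a darkness vector.
as_profile <- function(darkness, width_px = 9) {
  img <- as_strip_image(matrix(1 - darkness, nrow = length(darkness),
                               ncol = width_px))
  extract_profile(to_signal_channel(img), lane_geometry())
}

# Toy calibration fit with slope 2, intercept 1 (exact line).
toy_fit <- function() {
  fit_calibration(data.frame(concentration_nM = c(0, 1, 2),
                             normalized = c(1, 3, 5)))
}
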