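#' Specification of a synthetic LFA strip image
#'
#' Describes a simulated strip: two Gaussian absorbance bands on a light
#' membrane with an optional linear background gradient and i.i.d. Gaussian
#' pixel noise. The defaults mirror the physical strips this package
#' targets: lines 5 mm apart (at 4 mm and 9 mm along a 12 mm crop),
#' 10 px/mm resolution, 0.4 mm band sigma.
#'
#' @param length_px,width_px Image size; flow runs along `length_px`.
#' @param px_per_mm Resolution.
#' @param band_centers_mm Test- and control-line centers in mm from the
#'   upstream edge (tl first).
#' @param band_sigma_mm Gaussian band sigma in mm.
#' @param band_amplitudes Peak darkness of (tl, cl), each in `[0, 1]`.
#' @param background `c(offset, slope_per_px)` of the linear darkness
#'   background.
#' @param noise_sd SD of the Gaussian pixel noise (darkness units).
#' @param seed RNG seed; identical spec + seed gives bit-identical images.
#' @param rgb If `TRUE`, render 3-channel pixels with red/pink bands (gold
#'   nanoparticle color); the green channel carries the full signal.
#' @return A `synthetic_strip_spec`.
#' @export
synthetic_strip_spec <- function(length_px = 120, width_px = 30,
                                 px_per_mm = 10,
                                 band_centers_mm = c(4, 9),
                                 band_sigma_mm = 0.4,
                                 band_amplitudes = c(0.3, 0.3),
                                 background = c(offset = 0.1,
                                                slope_per_px = 0),
                                 noise_sd = 0, seed = 1L, rgb = FALSE) {
  spec <- structure(list(length_px = as.integer(length_px),
                         width_px = as.integer(width_px),
                         px_per_mm = px_per_mm,
                         band_centers_mm = band_centers_mm,
                         band_sigma_mm = band_sigma_mm,
                         band_amplitudes = band_amplitudes,
                         background = unname(background),
                         noise_sd = noise_sd, seed = as.integer(seed),
                         rgb = isTRUE(rgb)),
                    class = "synthetic_strip_spec")
  prof <- analytic_profile(spec)
  if (max(prof) > 1 + 1e-12)
    stop_lfa("lfa_generation_error",
             "band amplitudes plus background exceed 1 (max darkness %.3f)",
             max(prof))
  if (any(band_amplitudes < 0 | band_amplitudes > 1))
    stop_lfa("lfa_generation_error", "band amplitudes must lie in [0, 1]")
  if (noise_sd < 0)
    stop_lfa("lfa_generation_error", "noise_sd must be >= 0")
  spec
}

# Noiseless darkness profile along the flow axis (0-based positions).
analytic_profile <- function(spec) {
  x <- seq_len(spec$length_px) - 1
  mu <- spec$band_centers_mm * spec$px_per_mm
  sig <- spec$band_sigma_mm * spec$px_per_mm
  d <- spec$background[1] + spec$background[2] * x
  for (k in 1:2)
    d <- d + spec$band_amplitudes[k] * exp(-(x - mu[k])^2 / (2 * sig^2))
  d
}

#' Generate a synthetic strip image with ground truth
#'
#' The darkness signal at flow position x is
#' `offset + slope * x + sum_k A_k * exp(-(x - mu_k)^2 / (2 sigma^2))`,
#' replicated across the strip width, with optional i.i.d. Gaussian pixel
#' noise added and pixels clipped to `[0, 1]`. Pixels store lightness
#' (`1 - darkness`), so the image looks like a real strip: light membrane,
#' dark bands. The manifest records the exact band centers (px), the
#' analytic band areas `A_k * sigma_px * sqrt(2 * pi)`, and the noiseless
#' profile, giving every downstream test an exact oracle.
#'
#' @param spec A [synthetic_strip_spec()].
#' @return List with `image` (a `strip_image`) and `manifest` (list:
#'   `centers_px`, `band_areas`, `profile`, `spec`).
#' @export
generate_strip <- function(spec) {
  stopifnot(inherits(spec, "synthetic_strip_spec"))
  prof <- analytic_profile(spec)
  dark <- matrix(prof, nrow = spec$length_px, ncol = spec$width_px)
  px <- if (spec$rgb) {
    # gold-nanoparticle bands are red/pink: signal strongest in green
    arr <- array(0, dim = c(spec$length_px, spec$width_px, 3))
    arr[, , 1] <- 1 - 0.25 * dark
    arr[, , 2] <- 1 - dark
    arr[, , 3] <- 1 - 0.85 * dark
    arr
  } else {
    1 - dark
  }
  if (spec$noise_sd > 0) {
    px <- with_local_seed(spec$seed,
                          px + array(rnorm(length(px), 0, spec$noise_sd),
                                     dim = dim(px)))
  }
  px[px < 0] <- 0
  px[px > 1] <- 1
  sig_px <- spec$band_sigma_mm * spec$px_per_mm
  list(image = new_strip_image(px, px_per_mm = spec$px_per_mm,
                               source_label = "synthetic"),
       manifest = list(centers_px = spec$band_centers_mm * spec$px_per_mm,
                       band_areas = spec$band_amplitudes * sig_px *
                         sqrt(2 * pi),
                       profile = prof,
                       spec = spec))
}

#' Scenario for a simulated calibration experiment
#'
#' Defines the ground-truth calibration line for the normalized (cl/tl)
#' ratio and the experimental design. Defaults follow the digoxigenin
#' calibration experiment this package targets: 0, 1, 20, 40, 60, 80,
#' 100 nM measured in five repetitions. The default true line
#' (`beta0 = 0.5`, `beta1 = 0.02` per nM) keeps both band amplitudes well
#' inside `(0, 1)` across the whole design, and the default ratio noise
#' (SD 0.01) matches tight replicate agreement on a benchtop imager.
#'
#' @param concentrations_nM Design concentrations.
#' @param replicates Repetitions per concentration.
#' @param true_beta0,true_beta1 Intercept and slope of the true
#'   normalized-ratio line.
#' @param ratio_noise_sd SD of Gaussian noise added to the target ratio of
#'   each strip.
#' @param pixel_noise_sd SD of per-pixel image noise; 0 (default) keeps the
#'   image-level ground truth exact.
#' @param amplitude_total Summed band amplitude budget `A_ref`; each strip
#'   uses `A_cl = A_ref r / (1 + r)`, `A_tl = A_ref / (1 + r)` so the
#'   analytic cl/tl area ratio equals the target ratio `r` exactly.
#' @param device_label Device tag written to the sample sheet.
#' @param seed Scenario seed.
#' @return A `calibration_scenario`.
#' @export
calibration_scenario <- function(concentrations_nM = c(0, 1, 20, 40, 60,
                                                       80, 100),
                                 replicates = 5,
                                 true_beta0 = 0.5, true_beta1 = 0.02,
                                 ratio_noise_sd = 0.01,
                                 pixel_noise_sd = 0,
                                 amplitude_total = 0.8,
                                 device_label = "synthetic", seed = 1L) {
  r <- true_beta0 + true_beta1 * concentrations_nM
  if (any(r <= 0))
    stop_lfa("lfa_scenario_error",
             "true line gives non-positive ratio at %.3g nM",
             concentrations_nM[which(r <= 0)[1]])
  if (amplitude_total <= 0 || amplitude_total > 1)
    stop_lfa("lfa_scenario_error", "amplitude_total must be in (0, 1]")
  structure(list(concentrations_nM = concentrations_nM,
                 replicates = as.integer(replicates),
                 true_beta0 = true_beta0, true_beta1 = true_beta1,
                 ratio_noise_sd = ratio_noise_sd,
                 pixel_noise_sd = pixel_noise_sd,
                 amplitude_total = amplitude_total,
                 device_label = device_label, seed = as.integer(seed)),
            class = "calibration_scenario")
}

#' Generate a full synthetic calibration image set
#'
#' For every concentration and replicate, draws a target ratio
#' `r = beta0 + beta1 * c + eps`, `eps ~ N(0, ratio_noise_sd^2)`, sets the
#' band amplitudes so that the analytic cl/tl area ratio equals `r`
#' exactly, and renders the strip. Optionally writes PNG images, the
#' sample sheet and the truth record to a directory.
#'
#' @param scn A [calibration_scenario()].
#' @param dir Optional output directory; if given, images are written as
#'   lossless PNG and `sample_sheet.csv` / `truth.csv` are created.
#' @return List with `strips` (list of [generate_strip()] results),
#'   `sample_sheet` (data frame: `image_path`, `concentration_nM`,
#'   `replicate`, `device`) and `truth` (data frame with the target ratio
#'   and band amplitudes per strip).
#' @export
generate_calibration_set <- function(scn, dir = NULL) {
  stopifnot(inherits(scn, "calibration_scenario"))
  design <- expand.grid(replicate = seq_len(scn$replicates),
                        concentration_nM = scn$concentrations_nM)
  design <- design[, c("concentration_nM", "replicate")]
  n <- nrow(design)
  drawn <- with_local_seed(scn$seed, {
    eps <- rnorm(n, 0, scn$ratio_noise_sd)
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    list(eps = eps, seeds = seeds)
  })
  r <- scn$true_beta0 + scn$true_beta1 * design$concentration_nM + drawn$eps
  if (any(r <= 0))
    stop_lfa("lfa_scenario_error",
             "drawn target ratio <= 0 (%.4f); lower ratio_noise_sd", min(r))
  A_cl <- scn$amplitude_total * r / (1 + r)
  A_tl <- scn$amplitude_total / (1 + r)
  strips <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- synthetic_strip_spec(band_amplitudes = c(A_tl[i], A_cl[i]),
                                 noise_sd = scn$pixel_noise_sd,
                                 seed = drawn$seeds[i])
    strips[[i]] <- generate_strip(spec)
  }
  ids <- sprintf("strip_c%03g_r%d", design$concentration_nM,
                 design$replicate)
  sheet <- data.frame(image_path = paste0(ids, ".png"),
                      concentration_nM = design$concentration_nM,
                      replicate = design$replicate,
                      device = scn$device_label,
                      stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = ids,
                      concentration_nM = design$concentration_nM,
                      replicate = design$replicate,
                      true_ratio = r, A_tl = A_tl, A_cl = A_cl,
                      tl_center_px = 40, cl_center_px = 90,
                      stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    sheet$image_path <- file.path(dir, sheet$image_path)
    for (i in seq_len(n))
      write_strip_image(strips[[i]]$image, sheet$image_path[i])
    write.csv(sheet, file.path(dir, "sample_sheet.csv"), row.names = FALSE)
    write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  list(strips = strips, sample_sheet = sheet, truth = truth)
}
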