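#' Lane geometry of an LFA strip
#'
#' Physical layout parameters of the printed strip used as priors for band
#' detection and integration. The digoxigenin strips this package was
#' developed for have the test and control lines 5 mm apart.
#'
#' @param line_spacing_mm Expected distance between the test-line and
#'   control-line centers, in mm. Default 5.
#' @param band_width_mm Nominal printed line width in mm. Default 1.
#' @param roi_width_fraction Central fraction of the strip width averaged
#'   when extracting the flow-axis profile; flanks are excluded because
#'   strip edges carry cutting artefacts. Default 0.6.
#'
#' @return An object of class `lane_geometry`.
#' @export
#' @examples
#' lane_geometry()
lane_geometry <- function(line_spacing_mm = 5, band_width_mm = 1,
                          roi_width_fraction = 0.6) {
  if (!is.numeric(line_spacing_mm) || line_spacing_mm <= 0)
    stop_lfa("lfa_parameter_error", "line_spacing_mm must be > 0")
  if (!is.numeric(band_width_mm) || band_width_mm <= 0)
    stop_lfa("lfa_parameter_error", "band_width_mm must be > 0")
  if (roi_width_fraction <= 0 || roi_width_fraction > 1)
    stop_lfa("lfa_parameter_error", "roi_width_fraction must be in (0, 1]")
  structure(list(line_spacing_mm = line_spacing_mm,
                 band_width_mm = band_width_mm,
                 roi_width_fraction = roi_width_fraction),
            class = "lane_geometry")
}

new_strip_image <- function(pixels, px_per_mm = NA_real_,
                            source_label = "", signal = FALSE,
                            flags = character()) {
  d <- dim(pixels)
  channels <- if (length(d) == 3) d[3] else 1L
  structure(list(pixels = pixels,
                 height_px = d[1], width_px = d[2],
                 channels = channels,
                 flow_axis = 1L,
                 px_per_mm = px_per_mm,
                 source_label = source_label,
                 signal = signal,
                 flags = flags),
            class = "strip_image")
}

#' @export
print.strip_image <- function(x, ...) {
  cat(sprintf("<strip_image> %d x %d px, %d channel(s), %s, px/mm = %s%s\n",
              x$height_px, x$width_px, x$channels,
              if (isTRUE(x$signal)) "signal (darkness)" else "raw",
              if (is.na(x$px_per_mm)) "unknown" else format(x$px_per_mm),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Load a strip photograph
#'
#' Reads a JPEG, PNG or TIFF photograph of a single LFA strip and returns a
#' raster with pixel values scaled to `[0, 1]` (8-bit inputs divided by 255,
#' 16-bit by 65535). The raster is stored rows-by-columns with the first
#' array axis vertical in the photograph.
#'
#' @param path Path to the image file.
#' @param source_label Free-text provenance label, e.g. `"iPhone5S"` or
#'   `"Imager"`. Stored with the image and propagated to measurements.
#' @param px_per_mm Image resolution if known; `NA` (default) means unknown,
#'   in which case it is later estimated from the detected line spacing.
#'
#' @return A `strip_image` with all pixel values in `[0, 1]`.
#' @seealso [to_signal_channel()], [canonicalize_orientation()]
#' @export
load_strip_image <- function(path, source_label = "", px_per_mm = NA_real_) {
  if (!file.exists(path))
    stop_lfa("lfa_decode_error", "image file not found: %s", path)
  img <- tryCatch(suppressWarnings(EBImage::readImage(path)),
                  error = function(e)
                    stop_lfa("lfa_decode_error",
                             "cannot decode image %s: %s", path,
                             conditionMessage(e)))
  px <- EBImage::imageData(img)
  d <- dim(px)
  if (length(d) == 3 && d[3] > 3) px <- px[, , 1:3, drop = FALSE]  # drop alpha
  # EBImage stores x (width) first; transpose to rows = image y
  px <- if (length(dim(px)) == 3) aperm(px, c(2, 1, 3)) else t(px)
  if (any(dim(px)[1:2] == 0))
    stop_lfa("lfa_invalid_input", "zero-area image: %s", path)
  px[px < 0] <- 0
  px[px > 1] <- 1
  new_strip_image(px, px_per_mm = px_per_mm, source_label = source_label)
}

#' Write a strip image to disk
#'
#' PNG output is lossless 8-bit (16-bit with `bits = 16`); JPEG output uses
#' the given quality and introduces compression noise, which the synthetic
#' module exploits to emulate smartphone artefacts.
#'
#' @param img A `strip_image`.
#' @param path Output path; extension selects the format (`.png`, `.jpg`).
#' @param quality JPEG quality (ignored for PNG). Default 85.
#' @return `path`, invisibly.
#' @export
write_strip_image <- function(img, path, quality = 85) {
  stopifnot(inherits(img, "strip_image"))
  px <- img$pixels
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(px, target = path)
  } else if (ext %in% c("jpg", "jpeg")) {
    eb <- EBImage::Image(if (img$channels == 3) aperm(px, c(2, 1, 3)) else t(px),
                         colormode = if (img$channels == 3) "Color" else "Grayscale")
    EBImage::writeImage(eb, path, quality = quality)
  } else {
    stop_lfa("lfa_config_error", "unsupported output format: .%s", ext)
  }
  invisible(path)
}

#' Reduce a photograph to a single signal (darkness) channel
#'
#' Collapses an RGB image to one channel and inverts the polarity so that
#' colored bands become positive peaks: `signal = 1 - channel_value`. Gold
#' nanoparticle bands are red/pink, so the green channel carries the largest
#' absorbance contrast and is the default policy; `luminance` (Rec. 709
#' weights) is the fallback for grayscale imagers.
#'
#' @param img A `strip_image` with 1 or 3 channels.
#' @param policy One of `"green"`, `"luminance"`, `"red"`, `"blue"`.
#' @return A single-channel `strip_image` with `signal = TRUE` (darkness
#'   polarity: white membrane maps to 0, saturated band to 1).
#' @export
to_signal_channel <- function(img, policy = c("green", "luminance",
                                              "red", "blue")) {
  stopifnot(inherits(img, "strip_image"))
  policy <- tryCatch(match.arg(policy),
                     error = function(e)
                       stop_lfa("lfa_config_error",
                                "unknown channel policy: %s",
                                paste(policy, collapse = "/")))
  px <- img$pixels
  ch <- if (img$channels == 1) {
    px
  } else {
    v <- switch(policy,
                red = px[, , 1],
                green = px[, , 2],
                blue = px[, , 3],
                luminance = 0.2126 * px[, , 1] + 0.7152 * px[, , 2] +
                  0.0722 * px[, , 3])
    dim(v) <- dim(px)[1:2]  # keep matrix shape for 1-row images
    v
  }
  out <- new_strip_image(1 - ch, px_per_mm = img$px_per_mm,
                         source_label = img$source_label, signal = TRUE,
                         flags = img$flags)
  out
}

# Locate the two strongest candidate bands on a signal image's profile.
# Returns NULL when fewer than two peaks exist.
find_band_candidates <- function(img, geom) {
  prof <- extract_profile(img, geom)
  # small fixed smoothing window; resolution may still be unknown here
  prof <- correct_baseline(prof, method = "flank_linear")
  pk <- find_peaks(smooth_ma(prof$corrected, 5))
  if (nrow(pk) < 2) return(NULL)
  pk[order(-pk$prominence), ][1:2, ]
}

#' Put a strip image into canonical orientation
#'
#' Canonical orientation has the capillary-flow axis along the first array
#' axis with the test line upstream (lower index) of the control line. The
#' flow axis is taken as the longer image axis. With `hint = "auto"` the
#' band layout is inferred from the image: the more prominent band is
#' assumed to be the control line (the control captures probe regardless of
#' analyte level), and the image is flipped if that band is upstream. With
#' an explicit hint no content-based guessing occurs.
#'
#' @param img Single-channel signal `strip_image` (see
#'   [to_signal_channel()]).
#' @param geom A [lane_geometry()].
#' @param flow_direction_hint `"auto"`, `"tl_first"` (image already
#'   canonical along its longer axis) or `"cl_first"` (control line
#'   upstream; image is flipped).
#' @return A canonical `strip_image`; `px_per_mm` is filled in from the
#'   detected band separation when previously unknown.
#' @export
canonicalize_orientation <- function(img, geom = lane_geometry(),
                                     flow_direction_hint = c("auto",
                                                             "tl_first",
                                                             "cl_first")) {
  stopifnot(inherits(img, "strip_image"))
  hint <- match.arg(flow_direction_hint)
  if (!isTRUE(img$signal) || img$channels != 1)
    stop_lfa("lfa_invalid_input",
             "canonicalize_orientation requires a single-channel signal image")
  d <- dim(img$pixels)
  if (d[1] == d[2])
    stop_lfa("lfa_orientation_ambiguous",
             paste("square image: flow axis indeterminate; crop the strip",
                   "so the flow axis is the longer side"))
  if (d[2] > d[1]) img$pixels <- t(img$pixels)
  img <- new_strip_image(img$pixels, px_per_mm = img$px_per_mm,
                         source_label = img$source_label, signal = TRUE,
                         flags = img$flags)

  flip <- switch(hint, tl_first = FALSE, cl_first = TRUE, auto = {
    cand <- find_band_candidates(img, geom)
    if (is.null(cand))
      stop_lfa("lfa_orientation_ambiguous",
               paste("bands not found; cannot infer orientation --",
                     "pass flow_direction_hint = 'tl_first' or 'cl_first'"))
    hi <- cand[which.max(cand$prominence), ]
    lo <- cand[which.min(cand$prominence), ]
    if (abs(hi$prominence - lo$prominence) <
        0.05 * max(hi$prominence, lo$prominence))
      stop_lfa("lfa_orientation_ambiguous",
               paste("band intensities equal within tolerance; orientation",
                     "indeterminate -- pass an explicit flow_direction_hint"))
    # stronger band = control line; flip if it sits upstream
    hi$position < lo$position
  })
  if (flip) img$pixels <- img$pixels[rev(seq_len(nrow(img$pixels))), ,
                                     drop = FALSE]
  if (is.na(img$px_per_mm)) {
    cand <- find_band_candidates(img, geom)
    if (!is.null(cand))
      img$px_per_mm <- abs(diff(cand$position)) / geom$line_spacing_mm
  }
  img
}
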