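# Moving average with reflected boundaries; w is forced odd.
smooth_ma <- function(x, w) {
  w <- max(1L, as.integer(round(w)))
  if (w %% 2 == 0) w <- w + 1L
  if (w == 1L || length(x) < 3) return(x)
  h <- (w - 1L) %/% 2L
  h <- min(h, length(x) - 1L)
  xp <- c(x[(h + 1):2], x, x[(length(x) - 1):(length(x) - h)])
  as.numeric(stats::filter(xp, rep(1 / (2 * h + 1), 2 * h + 1),
                           sides = 2))[(h + 1):(h + length(x))]
}

# Local maxima with topographic prominence. Positions are 0-based to match
# profile coordinates. A peak's prominence is its height above the higher of
# the two lowest points separating it from higher ground (or the range edge).
find_peaks <- function(x) {
  n <- length(x)
  idx <- which(diff(sign(diff(x))) < 0) + 1L  # strict rise then fall/plateau
  if (n >= 3) {
    # include plateau peaks: first index of any flat top higher than both sides
    r <- rle(x)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (starts[k] > 1 && ends[k] < n &&
          r$values[k] > x[starts[k] - 1] && r$values[k] > x[ends[k] + 1])
        idx <- c(idx, starts[k])
    }
    idx <- sort(unique(idx))
  }
  if (!length(idx))
    return(data.frame(position = numeric(0), height = numeric(0),
                      prominence = numeric(0)))
  prom <- vapply(idx, function(i) {
    left <- if (i > 1) x[1:(i - 1)] else numeric(0)
    right <- if (i < n) x[(i + 1):n] else numeric(0)
    lmin <- {
      seg <- left
      higher <- which(seg > x[i])
      if (length(higher)) min(seg[(max(higher)):length(seg)]) else
        if (length(seg)) min(seg) else x[i]
    }
    rmin <- {
      seg <- right
      higher <- which(seg > x[i])
      if (length(higher)) min(seg[1:(min(higher))]) else
        if (length(seg)) min(seg) else x[i]
    }
    x[i] - max(lmin, rmin)
  }, numeric(1))
  data.frame(position = idx - 1, height = x[idx], prominence = prom)
}

#' Extract the flow-axis intensity profile of a strip
#'
#' Averages the signal over the central `roi_width_fraction` of the strip
#' width at every flow position, yielding a 1-D darkness profile whose peaks
#' are the printed lines.
#'
#' @param img Canonical single-channel signal `strip_image`.
#' @param geom A [lane_geometry()].
#' @return An `intensity_profile` with fields `values` (row means),
#'   `positions_px` (0-based), and empty `baseline`/`corrected` until
#'   [correct_baseline()] is applied.
#' @export
extract_profile <- function(img, geom = lane_geometry()) {
  stopifnot(inherits(img, "strip_image"))
  px <- img$pixels
  if (length(dim(px)) != 2)
    stop_lfa("lfa_invalid_input", "extract_profile needs a single-channel image")
  w <- ncol(px)
  keep <- max(3L, as.integer(round(w * geom$roi_width_fraction)))
  if (w < 3)
    stop_lfa("lfa_invalid_geometry",
             "image only %d px wide after ROI trim; need >= 3", w)
  lo <- (w - keep) %/% 2 + 1L
  cols <- lo:min(w, lo + keep - 1L)
  structure(list(values = rowMeans(px[, cols, drop = FALSE]),
                 positions_px = seq_len(nrow(px)) - 1,
                 roi_cols = cols,
                 baseline = NULL, corrected = NULL),
            class = "intensity_profile")
}

# Iteratively clipped linear fit: an OLS line is fitted, values above the
# line are clipped to it, and the fit is repeated until it stabilises on the
# band-free flanks and the inter-band valley floor.
baseline_flank_linear <- function(y, x) {
  yw <- y
  fit_prev <- rep(Inf, length(y))
  for (i in 1:60) {
    cf <- stats::coef(stats::lm.fit(cbind(1, x), yw))
    fit <- cf[1] + cf[2] * x
    if (max(abs(fit - fit_prev)) < 1e-12) break
    fit_prev <- fit
    yw <- pmin(yw, fit)
  }
  fit
}

baseline_rolling_min <- function(y, w) {
  n <- length(y)
  h <- (max(3L, as.integer(w)) - 1L) %/% 2L
  mins <- vapply(seq_len(n), function(i)
    min(y[max(1, i - h):min(n, i + h)]), numeric(1))
  smooth_ma(mins, w)
}

#' Baseline-correct an intensity profile
#'
#' Estimates the band-free background of the profile and subtracts it.
#' `flank_linear` (default) fits a straight line through the band-free
#' flanks and the inter-band valley by iteratively clipping points above the
#' fit; it assumes the membrane background varies at most linearly along the
#' strip. `rolling_min` uses a smoothed rolling minimum and tolerates curved
#' backgrounds, at the cost of shaving broad bands; its `window_px` must be
#' at least three band widths.
#'
#' @param p An `intensity_profile` from [extract_profile()].
#' @param method `"flank_linear"` or `"rolling_min"`.
#' @param window_px Rolling-minimum window in px (ignored by
#'   `flank_linear`).
#' @return The profile with `baseline` populated and `corrected` set to
#'   `pmax(values - baseline, 0)`.
#' @export
correct_baseline <- function(p, method = c("flank_linear", "rolling_min"),
                             window_px = 31) {
  stopifnot(inherits(p, "intensity_profile"))
  method <- match.arg(method)
  if (window_px < 3)
    stop_lfa("lfa_parameter_error", "window_px must be >= 3 (got %s)",
             format(window_px))
  p$baseline <- switch(method,
                       flank_linear = baseline_flank_linear(p$values,
                                                            p$positions_px),
                       rolling_min = baseline_rolling_min(p$values, window_px))
  p$corrected <- pmax(p$values - p$baseline, 0)
  p$residual <- p$values - p$baseline
  p
}

#' Detect the test and control lines on a corrected profile
#'
#' Smooths the corrected profile with a moving average one band width wide,
#' finds local maxima with their topographic prominences, and among all
#' candidate peak pairs whose separation is within 25% of the expected
#' line spacing selects the pair maximizing summed prominence. The upstream
#' peak is labelled `tl`, the downstream one `cl`. Integration windows span
#' 1.5 band widths centred on each peak, as half-open 0-based pixel
#' intervals clipped to the profile.
#'
#' @param p Baseline-corrected `intensity_profile`.
#' @param geom A [lane_geometry()].
#' @param px_per_mm Image resolution in px/mm (used to convert the spacing
#'   and width priors to pixels).
#' @return A list with elements `tl` and `cl`, each a `band_call` with
#'   fields `label`, `center_px`, `window_px` (`c(start, stop)`, half-open),
#'   `raw_area` and `corrected_intensity`.
#' @export
detect_bands <- function(p, geom = lane_geometry(), px_per_mm) {
  stopifnot(inherits(p, "intensity_profile"))
  if (is.null(p$corrected))
    stop_lfa("lfa_invalid_input",
             "profile must be baseline-corrected before band detection")
  if (!is.numeric(px_per_mm) || is.na(px_per_mm) || px_per_mm <= 0)
    stop_lfa("lfa_parameter_error", "px_per_mm must be a positive number")
  bw_px <- geom$band_width_mm * px_per_mm
  spacing_px <- geom$line_spacing_mm * px_per_mm
  sm <- smooth_ma(p$corrected, bw_px)
  pk <- find_peaks(sm)
  pk <- pk[pk$prominence > 0, , drop = FALSE]
  if (nrow(pk) < 2) {
    missing <- if (nrow(pk) == 1) {
      # name the absent line by where it would have to sit
      up <- pk$position - spacing_px >= min(p$positions_px)
      down <- pk$position + spacing_px <= max(p$positions_px)
      if (down && !up) "control line (cl)"
      else if (up && !down) "test line (tl)"
      else "test line (tl) or control line (cl)"
    } else "both test line (tl) and control line (cl)"
    stop_lfa("lfa_band_not_found", "band not found: %s missing (%d peak(s) detected)",
             missing, nrow(pk))
  }
  pairs <- which(outer(pk$position, pk$position,
                       function(a, b) abs(b - a - spacing_px) <=
                         0.25 * spacing_px & b > a),
                 arr.ind = TRUE)
  if (!nrow(pairs)) {
    stop_lfa("lfa_band_not_found",
             paste("band not found: no peak pair within 25%% of the expected",
                   "%.1f px line spacing"), spacing_px)
  }
  score <- pk$prominence[pairs[, 1]] + pk$prominence[pairs[, 2]]
  best <- max(score)
  ties <- which(abs(score - best) <= 1e-9)
  if (length(ties) > 1)
    stop_lfa("lfa_ambiguous_bands",
             "%d candidate band pairs tie in prominence; cannot disambiguate",
             length(ties))
  i <- pairs[ties, 1]; j <- pairs[ties, 2]
  up <- min(pk$position[i], pk$position[j])
  dn <- max(pk$position[i], pk$position[j])
  band_call <- function(label, center) {
    half <- 1.5 * bw_px / 2
    start <- max(0, round(center - half))
    stop_ <- min(length(p$values), round(center + half))
    sel <- (p$positions_px >= start) & (p$positions_px < stop_)
    structure(list(label = label, center_px = center,
                   window_px = c(start = start, stop = stop_),
                   raw_area = sum(p$values[sel]),
                   corrected_intensity = max(0, sum(p$residual[sel]))),
              class = "band_call")
  }
  list(tl = band_call("tl", up), cl = band_call("cl", dn))
}

# Estimate px/mm from the two most prominent peaks of a corrected profile.
estimate_px_per_mm <- function(p, geom) {
  pk <- find_peaks(smooth_ma(p$corrected, 5))
  pk <- pk[pk$prominence > 0, , drop = FALSE]
  if (nrow(pk) < 2)
    stop_lfa("lfa_band_not_found",
             "cannot estimate resolution: fewer than two bands visible")
  pk <- pk[order(-pk$prominence), ][1:2, ]
  abs(diff(pk$position)) / geom$line_spacing_mm
}

#' Quantify one strip image
#'
#' Full single-strip densitometry: channel reduction, orientation
#' canonicalization, profile extraction, baseline correction, band
#' detection, and window integration. The band quantity is the integrated
#' background-corrected area (not peak height), which is robust to the
#' focus differences between smartphone and benchtop imagers.
#'
#' If more than 1% of ROI pixels are saturated (exactly 0 or 1 before
#' inversion) the measurement is flagged `"saturated"` but still computed.
#' A zero test-line intensity leaves `normalized` undefined (`NA`) and
#' flags the measurement.
#'
#' @param img A `strip_image` (raw RGB/gray, or an already canonical signal
#'   image).
#' @param geom A [lane_geometry()].
#' @param channel Channel policy for [to_signal_channel()].
#' @param baseline_method,baseline_window_px Passed to
#'   [correct_baseline()].
#' @param flow_direction_hint Passed to [canonicalize_orientation()].
#'   Batch pipelines photograph strips in a fixed template, so the default
#'   is the explicit `"tl_first"`; use `"auto"` for ad-hoc single images
#'   with unequal bands.
#' @param sample_id,device,concentration_nM,replicate Metadata copied into
#'   the measurement.
#' @return A `strip_measurement`: one-row data.frame with columns
#'   `sample_id, device, concentration_nM, replicate, tl, cl, normalized,
#'   standardized, flags` plus attributes `bands` (the two band calls) and
#'   `profile`.
#' @export
quantify_strip <- function(img, geom = lane_geometry(),
                           channel = "green",
                           baseline_method = "flank_linear",
                           baseline_window_px = 31,
                           flow_direction_hint = "tl_first",
                           sample_id = NA_character_,
                           device = NA_character_,
                           concentration_nM = NA_real_,
                           replicate = NA_integer_) {
  stopifnot(inherits(img, "strip_image"))
  flags <- character()
  raw <- img$pixels
  sat <- mean(raw == 0 | raw == 1)
  if (sat > 0.01) flags <- c(flags, "saturated")
  if (!isTRUE(img$signal)) img <- to_signal_channel(img, channel)
  img <- canonicalize_orientation(img, geom, flow_direction_hint)
  prof <- extract_profile(img, geom)
  prof <- correct_baseline(prof, baseline_method, baseline_window_px)
  ppm <- img$px_per_mm
  if (is.na(ppm)) ppm <- estimate_px_per_mm(prof, geom)
  bands <- detect_bands(prof, geom, ppm)
  tl <- bands$tl$corrected_intensity
  cl <- bands$cl$corrected_intensity
  normalized <- if (tl > 0) cl / tl else NA_real_
  standardized <- if (cl > 0) tl / cl else NA_real_
  if (tl <= 0) flags <- c(flags, "tl_zero")
  if (cl <= 0) flags <- c(flags, "cl_zero")
  dev_label <- if (is.na(device) && nzchar(img$source_label))
    img$source_label else device
  m <- data.frame(sample_id = sample_id, device = dev_label,
                  concentration_nM = concentration_nM,
                  replicate = replicate,
                  tl = tl, cl = cl,
                  normalized = normalized, standardized = standardized,
                  flags = paste(flags, collapse = ";"),
                  stringsAsFactors = FALSE)
  attr(m, "bands") <- bands
  attr(m, "profile") <- prof
  attr(m, "px_per_mm") <- ppm
  class(m) <- c("strip_measurement", class(m))
  m
}
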