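new_detection_limits <- function(method, fit, lob_i, lod_i, loq_i) {
  to_nM <- function(v) if (is.na(v)) NA_real_
  else as.numeric(predict_concentration(fit, v))
  structure(list(method = method,
                 scale_note = paste(
                   "limits computed on the", fit$mode,
                   "intensity-ratio scale and converted to nmol/L through",
                   "the inverse fitted calibration line"),
                 lob_intensity = lob_i, lod_intensity = lod_i,
                 loq_intensity = loq_i,
                 lob_nM = to_nM(lob_i), lod_nM = to_nM(lod_i),
                 loq_nM = to_nM(loq_i)),
            class = "detection_limits")
}

#' @export
print.detection_limits <- function(x, ...) {
  cat(sprintf("<detection_limits> method %d\n", x$method))
  tab <- rbind(intensity = c(x$lob_intensity, x$lod_intensity, x$loq_intensity),
               `nmol/L` = c(x$lob_nM, x$lod_nM, x$loq_nM))
  colnames(tab) <- c("LOB", "LOD", "LOQ")
  print(signif(tab, 5))
  invisible(x)
}

#' Detection limits, method 1 (blank statistics only)
#'
#' \deqn{LOD = \bar{x}_{blank} + 3\,s_{blank}, \qquad
#'       LOQ = \bar{x}_{blank} + 10\,s_{blank}}
#'
#' computed on the intensity-ratio scale and converted to nmol/L with the
#' inverse calibration line. No limit of blank is defined by this method.
#'
#' @param blank_ratios Ratios (normalized or standardized, matching the
#'   fit's mode) measured at 0 nM; at least two.
#' @param fit A `calibration_fit` used for the concentration conversion.
#' @return A `detection_limits` object (fields `lob_*` are `NA`).
#' @export
#' @examples
#' f <- fit_calibration(data.frame(concentration_nM = c(0, 1, 2),
#'                                 normalized = c(1, 3, 5)))
#' limits_method1(c(1, 2, 3), f)
limits_method1 <- function(blank_ratios, fit) {
  blank_ratios <- blank_ratios[!is.na(blank_ratios)]
  if (length(blank_ratios) < 2)
    stop_lfa("lfa_insufficient_blanks",
             "method 1 needs >= 2 blank (0 nM) measurements (got %d)",
             length(blank_ratios))
  m <- mean(blank_ratios); s <- stats::sd(blank_ratios)
  new_detection_limits(1L, fit,
                       lob_i = NA_real_,
                       lod_i = m + 3 * s,
                       loq_i = m + 10 * s)
}

#' Detection limits, method 2 (limit-of-blank route)
#'
#' \deqn{LOB = \bar{x}_{blank} + 1.645\,s_{blank}}
#' \deqn{LOD = LOB + 1.645\,s_{1\,nM}}
#' \deqn{LOQ = \bar{x}_{blank} + 10\,s_{blank}}
#'
#' The LOD builds on the spread of the lowest non-blank calibrator (1 nM),
#' following the standard clinical-chemistry LOB/LOD construction with
#' one-sided 95% z = 1.645. All three are converted to nmol/L with the
#' inverse calibration line.
#'
#' @param blank_ratios Ratios at 0 nM (>= 2 values).
#' @param one_nM_ratios Ratios at the 1 nM calibrator (>= 2 values).
#' @param fit A `calibration_fit`.
#' @return A `detection_limits` object.
#' @export
limits_method2 <- function(blank_ratios, one_nM_ratios, fit) {
  blank_ratios <- blank_ratios[!is.na(blank_ratios)]
  one_nM_ratios <- one_nM_ratios[!is.na(one_nM_ratios)]
  if (length(blank_ratios) < 2)
    stop_lfa("lfa_insufficient_blanks",
             "method 2 needs >= 2 blank (0 nM) measurements (got %d)",
             length(blank_ratios))
  if (length(one_nM_ratios) < 2)
    stop_lfa("lfa_method2_unavailable",
             paste("method 2 needs >= 2 measurements of the 1 nM calibrator",
                   "(got %d); include a 1 nM group or use method 1"),
             length(one_nM_ratios))
  m <- mean(blank_ratios); s <- stats::sd(blank_ratios)
  lob <- m + 1.645 * s
  new_detection_limits(2L, fit,
                       lob_i = lob,
                       lod_i = lob + 1.645 * stats::sd(one_nM_ratios),
                       loq_i = m + 10 * s)
}

#' Compute both detection-limit methods from a measurement table
#'
#' Convenience wrapper extracting the 0 nM (and, for method 2, the 1 nM)
#' ratio groups from a measurement data frame.
#'
#' @param measurements Measurement data frame (columns `concentration_nM`
#'   and the fit's ratio column).
#' @param fit A `calibration_fit`.
#' @param methods Integer vector, subset of `c(1, 2)`.
#' @return Named list of `detection_limits` (`method1`, `method2`); a
#'   method whose prerequisites are missing is returned as the error
#'   condition object instead, so batch reports can state why.
#' @export
compute_limits <- function(measurements, fit, methods = c(1, 2)) {
  ratios <- function(conc)
    measurements[[fit$mode]][measurements$concentration_nM == conc]
  out <- list()
  if (1 %in% methods)
    out$method1 <- tryCatch(limits_method1(ratios(0), fit),
                            lfaquant_error = function(e) e)
  if (2 %in% methods)
    out$method2 <- tryCatch(limits_method2(ratios(0), ratios(1), fit),
                            lfaquant_error = function(e) e)
  out
}
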