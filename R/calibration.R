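#' Replicate mean, SD and confidence interval
#'
#' Summary statistics used for the per-concentration replicate groups:
#' sample standard deviation (n - 1 denominator) and a Student-t confidence
#' interval `mean +/- t(1 - alpha/2, n - 1) * sd / sqrt(n)`.
#'
#' @param values Numeric vector of replicate measurements.
#' @param confidence Confidence level, default 0.95.
#' @return Named list `mean`, `sd`, `ci_low`, `ci_high`, `n`. With a single
#'   value the SD and CI are `NA`.
#' @export
#' @examples
#' replicate_stats(c(1, 2, 3))
replicate_stats <- function(values, confidence = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0)
    stop_lfa("lfa_invalid_input", "replicate_stats: empty input")
  m <- mean(values)
  if (n == 1)
    return(list(mean = m, sd = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, n = 1L))
  s <- stats::sd(values)
  half <- stats::qt(1 - (1 - confidence) / 2, df = n - 1) * s / sqrt(n)
  list(mean = m, sd = s, ci_low = m - half, ci_high = m + half, n = n)
}

#' Fit a linear calibration model of intensity ratio vs concentration
#'
#' Ordinary least squares of the chosen band-intensity ratio on analyte
#' concentration, fitted on the individual replicates (not on
#' per-concentration means). The normalized ratio cl/tl increases with
#' analyte concentration in the competitive format (the test line fades);
#' the standardized ratio tl/cl is the supported reciprocal response.
#'
#' @param measurements Data frame of strip measurements with columns
#'   `concentration_nM` and the ratio column named by `mode`
#'   (the measurement CSV layout; see [quantify_strip()]).
#' @param mode `"normalized"` (cl/tl, default) or `"standardized"` (tl/cl).
#' @param confidence Confidence level for the replicate CIs and the slope
#'   CI. Default 0.95.
#' @return A `calibration_fit` with slope, intercept, `r_squared`,
#'   `pearson_r` (observed vs predicted ratios), slope CI, the per
#'   concentration replicate statistics, the rows rejected for undefined
#'   ratios, and the underlying `lm` fit.
#' @export
fit_calibration <- function(measurements,
                            mode = c("normalized", "standardized"),
                            confidence = 0.95) {
  mode <- match.arg(mode)
  if (!all(c("concentration_nM", mode) %in% names(measurements)))
    stop_lfa("lfa_invalid_input",
             "measurements need columns 'concentration_nM' and '%s'", mode)
  y <- measurements[[mode]]
  x <- measurements$concentration_nM
  bad <- !is.finite(y) | !is.finite(x)
  rejects <- measurements[bad, , drop = FALSE]
  x <- x[!bad]; y <- y[!bad]
  if (length(unique(x)) < 2)
    stop_lfa("lfa_design_error",
             "need >= 2 distinct concentrations to fit a calibration line (got %d)",
             length(unique(x)))
  fit <- stats::lm(y ~ x)
  # exact-line inputs (zero residual) trip a spurious precision warning
  quiet_perfect_fit <- function(expr)
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  sm <- quiet_perfect_fit(summary(fit))
  cf <- stats::coef(fit)
  ci <- quiet_perfect_fit(stats::confint(fit, level = confidence))
  per <- lapply(split(y, x), replicate_stats, confidence = confidence)
  per_df <- data.frame(concentration_nM = as.numeric(names(per)),
                       mean = vapply(per, `[[`, numeric(1), "mean"),
                       sd = vapply(per, `[[`, numeric(1), "sd"),
                       ci_low = vapply(per, `[[`, numeric(1), "ci_low"),
                       ci_high = vapply(per, `[[`, numeric(1), "ci_high"),
                       n = vapply(per, `[[`, integer(1), "n"),
                       row.names = NULL)
  per_df <- per_df[order(per_df$concentration_nM), ]
  structure(list(mode = mode,
                 slope = unname(cf[2]), intercept = unname(cf[1]),
                 slope_se = sm$coefficients[2, 2],
                 slope_ci = unname(ci[2, ]),
                 intercept_ci = unname(ci[1, ]),
                 r_squared = sm$r.squared,
                 pearson_r = if (stats::sd(y) == 0 ||
                                 stats::sd(stats::fitted(fit)) == 0)
                   NA_real_ else stats::cor(y, stats::fitted(fit)),
                 n_points = length(y),
                 per_concentration = per_df,
                 rejects = rejects,
                 confidence = confidence,
                 model = fit,
                 data = data.frame(concentration_nM = x, ratio = y)),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> %s ratio ~ concentration (n = %d)\n  slope     %.6g per nM  [%.6g, %.6g]\n  intercept %.6g\n  R^2 = %.4f, Pearson r(obs, pred) = %.4f\n",
    x$mode, x$n_points, x$slope, x$slope_ci[1], x$slope_ci[2],
    x$intercept, x$r_squared, x$pearson_r))
  invisible(x)
}

#' Inverse-predict concentration from a ratio
#'
#' Solves the fitted line for concentration: `(ratio - intercept) / slope`.
#' Negative concentrations are returned as-is with a `below_range`
#' attribute flagging them, so that a limit slightly below the blank maps
#' transparently rather than being censored.
#'
#' @param fit A `calibration_fit`.
#' @param ratio Numeric vector of ratios.
#' @return Numeric vector of concentrations (nM) with logical attribute
#'   `below_range`.
#' @export
predict_concentration <- function(fit, ratio) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (!is.finite(fit$slope) || abs(fit$slope) < 1e-12 * max(1, abs(fit$intercept)))
    stop_lfa("lfa_noninvertible_model",
             "calibration slope is zero; model cannot be inverted")
  conc <- (ratio - fit$intercept) / fit$slope
  attr(conc, "below_range") <- conc < 0
  conc
}

#' Pearson correlation of observed ratios with model predictions
#'
#' @param fit A `calibration_fit`.
#' @param measurements Optional data frame of measurements (defaults to the
#'   data the fit was made on); needs `concentration_nM` and the fit's
#'   ratio column.
#' @return Pearson r between observed and predicted ratios. For a simple
#'   OLS fit evaluated on its own data this equals `sqrt(r_squared)`.
#' @export
pearson_vs_predicted <- function(fit, measurements = NULL) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (is.null(measurements)) {
    obs <- fit$data$ratio
    conc <- fit$data$concentration_nM
  } else {
    obs <- measurements[[fit$mode]]
    conc <- measurements$concentration_nM
    keep <- is.finite(obs) & is.finite(conc)
    obs <- obs[keep]; conc <- conc[keep]
  }
  if (length(obs) < 3)
    stop_lfa("lfa_invalid_input",
             "need >= 3 measurements for a correlation (got %d)", length(obs))
  pred <- fit$intercept + fit$slope * conc
  if (stats::sd(obs) == 0 || stats::sd(pred) == 0)
    stop_lfa("lfa_undefined_correlation",
             "zero variance in observed or predicted ratios")
  stats::cor(obs, pred)
}
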