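md_table <- function(df, digits = 5) {
  fmt <- function(v) if (is.numeric(v)) signif(v, digits) else v
  df <- as.data.frame(lapply(df, fmt))
  lines <- c(paste0("| ", paste(names(df), collapse = " | "), " |"),
             paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"))
  for (i in seq_len(nrow(df)))
    lines <- c(lines, paste0("| ", paste(unlist(df[i, ]), collapse = " | "),
                             " |"))
  lines
}

#' Plot a calibration fit
#'
#' Scatter of per-strip ratios vs concentration with the fitted line and
#' per-concentration error bars (replicate SD), matching the standard
#' presentation of LFA calibration curves.
#'
#' @param fit A `calibration_fit`.
#' @param ... Passed to `plot()`.
#' @export
plot_calibration <- function(fit, ...) {
  d <- fit$data
  plot(d$concentration_nM, d$ratio,
       xlab = "concentration [nmol/L]",
       ylab = paste(fit$mode, "intensity",
                    if (fit$mode == "normalized") "(cl/tl)" else "(tl/cl)"),
       main = sprintf("%s calibration: R^2 = %.3f", fit$mode,
                      fit$r_squared),
       pch = 19, col = "#00000088", ...)
  abline(fit$intercept, fit$slope, col = "firebrick", lwd = 2)
  pc <- fit$per_concentration
  ok <- !is.na(pc$sd) & pc$sd > 0
  if (any(ok))
    suppressWarnings(arrows(pc$concentration_nM[ok],
                            pc$mean[ok] - pc$sd[ok],
                            pc$concentration_nM[ok],
                            pc$mean[ok] + pc$sd[ok],
                            angle = 90, code = 3, length = 0.04))
  invisible(fit)
}

report_body <- function(report) {
  cfg <- report$config
  lines <- c("# LFA strip analysis report", "",
             paste0("generated: ", report$timestamp),
             paste0("software: lfaquant ", report$version), "",
             "## Inputs", "",
             paste0("- ", report$inventory), "",
             "## Settings", "")
  show <- cfg[!vapply(cfg, is.null, logical(1))]
  for (nm in names(show))
    lines <- c(lines, sprintf("- %s: %s", nm,
                              paste(format(show[[nm]]), collapse = ", ")))
  lines <- c(lines, "", "## Per-strip measurements", "",
             md_table(report$measurements), "")
  if (nrow(report$rejects))
    lines <- c(lines, "## Rejected strips", "", md_table(report$rejects), "")
  for (md in names(report$fits)) {
    f <- report$fits[[md]]
    lines <- c(lines, sprintf("## Calibration fit (%s)", md), "",
               md_table(data.frame(mode = f$mode, slope = f$slope,
                                   intercept = f$intercept,
                                   r_squared = f$r_squared,
                                   pearson_r = f$pearson_r,
                                   n = f$n_points)), "",
               "Per-concentration replicate statistics:", "",
               md_table(f$per_concentration), "")
    lim <- report$limits[[md]]
    lines <- c(lines, sprintf("## Detection limits (%s)", md), "")
    for (nm in names(lim)) {
      if (inherits(lim[[nm]], "detection_limits")) {
        l <- lim[[nm]]
        lines <- c(lines,
                   sprintf("Method %d (%s):", l$method, l$scale_note), "",
                   md_table(data.frame(
                     scale = c("intensity", "nM"),
                     LOB = c(l$lob_intensity, l$lob_nM),
                     LOD = c(l$lod_intensity, l$lod_nM),
                     LOQ = c(l$loq_intensity, l$loq_nM))), "")
      } else {
        lines <- c(lines, sprintf("Method %s unavailable: %s",
                                  sub("method", "", nm),
                                  conditionMessage(lim[[nm]])), "")
      }
    }
  }
  lines
}

#' Render the analysis report
#'
#' Writes a self-contained report into a fresh per-run subdirectory of
#' `out_dir` (`run-<id>/report.md` or `report.html` plus the calibration
#' plot). The run id in the path means a new report never overwrites a
#' previous one. Two runs on identical inputs and configuration produce
#' reports that differ only in the timestamp line.
#'
#' @param report An `analysis_report` from [run_pipeline()].
#' @param format `"markdown"` or `"html"`.
#' @param out_dir Output directory.
#' @return Path of the written report file.
#' @export
render_report <- function(report, format = c("markdown", "html"),
                          out_dir = ".") {
  stopifnot(inherits(report, "analysis_report"))
  format <- match.arg(format)
  base_id <- format(Sys.time(), "run-%Y%m%dT%H%M%S")
  run_dir <- file.path(out_dir, base_id)
  k <- 1
  while (dir.exists(run_dir)) {
    k <- k + 1
    run_dir <- file.path(out_dir, sprintf("%s-%d", base_id, k))
  }
  dir.create(run_dir, recursive = TRUE)
  plot_paths <- character()
  for (md in names(report$fits)) {
    p <- file.path(run_dir, paste0("calibration_", md, ".png"))
    grDevices::png(p, width = 720, height = 480)
    plot_calibration(report$fits[[md]])
    grDevices::dev.off()
    plot_paths[md] <- p
  }
  body <- report_body(report)
  for (md in names(plot_paths))
    body <- c(body, sprintf("![calibration plot (%s)](%s)", md,
                            basename(plot_paths[md])), "")
  if (format == "markdown") {
    path <- file.path(run_dir, "report.md")
    writeLines(body, path)
  } else {
    path <- file.path(run_dir, "report.html")
    imgs <- vapply(plot_paths, function(p)
      sprintf('<img src="data:image/png;base64,%s" alt="calibration plot"/>',
              gsub("[\r\n]", "", jsonlite::base64_enc(
                readBin(p, "raw", file.info(p)$size)))),
      character(1))
    body <- body[!grepl("^!\\[calibration plot", body)]
    writeLines(c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
                 "<title>LFA strip analysis report</title></head><body>",
                 "<pre>", body, "</pre>", imgs, "</body></html>"),
               path)
  }
  path
}
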