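#' Pipeline run configuration
#'
#' Every field has a default, so an empty configuration is runnable on a
#' directory of images plus a sample sheet.
#'
#' @param mode Ratio to calibrate on: `"normalized"` (cl/tl),
#'   `"standardized"` (tl/cl) or `"both"`.
#' @param channel Channel policy (see [to_signal_channel()]).
#' @param baseline_method,baseline_window_mm Baseline algorithm and
#'   rolling-minimum window (mm, converted to px per image).
#' @param line_spacing_mm,band_width_mm,roi_width_fraction Geometry
#'   overrides (see [lane_geometry()]).
#' @param flow_direction_hint Orientation hint (see
#'   [canonicalize_orientation()]).
#' @param limits_methods Which detection-limit methods to run.
#' @param sample_sheet Path to the sample-sheet CSV (columns `image_path`,
#'   `concentration_nM`, `replicate`, `device`).
#' @param measurements_csv Path to a pre-extracted measurement CSV (e.g.
#'   ImageJ output reshaped to the measurement layout); bypasses imaging.
#' @param out_dir Output directory for CSVs and the report.
#' @param px_per_mm Image resolution if known; `NA` = estimate per image.
#' @param seed Seed for simulation subcommands.
#' @param format Report format, `"markdown"` or `"html"`.
#' @return A `run_config`.
#' @export
run_config <- function(mode = "normalized",
                       channel = "green",
                       baseline_method = "flank_linear",
                       baseline_window_mm = 3,
                       line_spacing_mm = 5, band_width_mm = 1,
                       roi_width_fraction = 0.6,
                       flow_direction_hint = "tl_first",
                       limits_methods = c(1, 2),
                       sample_sheet = NULL, measurements_csv = NULL,
                       out_dir = ".", px_per_mm = NA_real_,
                       seed = 1L, format = "markdown") {
  if (!mode %in% c("normalized", "standardized", "both"))
    stop_lfa("lfa_config_error", "unknown mode: %s", mode)
  if (!format %in% c("markdown", "html"))
    stop_lfa("lfa_config_error", "unknown report format: %s", format)
  structure(list(mode = mode, channel = channel,
                 baseline_method = baseline_method,
                 baseline_window_mm = baseline_window_mm,
                 line_spacing_mm = line_spacing_mm,
                 band_width_mm = band_width_mm,
                 roi_width_fraction = roi_width_fraction,
                 flow_direction_hint = flow_direction_hint,
                 limits_methods = limits_methods,
                 sample_sheet = sample_sheet,
                 measurements_csv = measurements_csv,
                 out_dir = out_dir, px_per_mm = px_per_mm,
                 seed = as.integer(seed), format = format),
            class = "run_config")
}

#' Read / write the measurement CSV
#'
#' Layout: `sample_id, device, concentration_nM, replicate, tl, cl,
#' normalized, standardized, flags` (UTF-8, header required). This is both
#' the pipeline's output and an accepted input, so band intensities
#' extracted with other tools (e.g. ImageJ) can enter the calibration
#' stage directly. Missing `normalized`/`standardized` columns are filled
#' from `cl/tl` when the raw intensities are present.
#'
#' @param path CSV path.
#' @return Data frame in measurement layout.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path))
    stop_lfa("lfa_usage_error", "measurement CSV not found: %s", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("concentration_nM")
  if (!all(need %in% names(m)))
    stop_lfa("lfa_invalid_input",
             "measurement CSV lacks required column(s): %s",
             paste(setdiff(need, names(m)), collapse = ", "))
  if (all(c("tl", "cl") %in% names(m))) {
    if (is.null(m$normalized))
      m$normalized <- ifelse(m$tl > 0, m$cl / m$tl, NA_real_)
    if (is.null(m$standardized))
      m$standardized <- ifelse(m$cl > 0, m$tl / m$cl, NA_real_)
  }
  for (col in c("sample_id", "device", "flags"))
    if (is.null(m[[col]])) m[[col]] <- NA_character_
  if (is.null(m$replicate)) m$replicate <- NA_integer_
  m
}

#' @rdname read_measurements
#' @param measurements Data frame in measurement layout.
#' @export
write_measurements <- function(measurements, path) {
  cols <- c("sample_id", "device", "concentration_nM", "replicate",
            "tl", "cl", "normalized", "standardized", "flags")
  keep <- intersect(cols, names(measurements))
  utils::write.csv(measurements[, keep, drop = FALSE], path,
                   row.names = FALSE)
  invisible(path)
}

limits_as_table <- function(limits_list, mode) {
  rows <- list()
  for (nm in names(limits_list)) {
    lim <- limits_list[[nm]]
    if (inherits(lim, "detection_limits")) {
      rows[[length(rows) + 1]] <- data.frame(
        mode = mode, method = lim$method, scale = "intensity",
        lob = lim$lob_intensity, lod = lim$lod_intensity,
        loq = lim$loq_intensity)
      rows[[length(rows) + 1]] <- data.frame(
        mode = mode, method = lim$method, scale = "nM",
        lob = lim$lob_nM, lod = lim$lod_nM, loq = lim$loq_nM)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Run the full batch analysis pipeline
#'
#' Quantifies every strip listed in the sample sheet (or ingests a
#' measurement CSV directly), fits the calibration model(s), computes the
#' requested detection-limit methods, writes the result CSVs and renders
#' the analysis report. Per-strip failures are logged to the rejects table
#' and excluded; they never abort the batch.
#'
#' @param cfg A [run_config()].
#' @param strips Optional list of in-memory `strip_image`s (or
#'   [generate_strip()] results) aligned with the sample-sheet rows;
#'   bypasses file loading, used mainly with synthetic data.
#' @param sheet Optional in-memory sample-sheet data frame (overrides
#'   `cfg$sample_sheet`).
#' @param render Render the report file (default `TRUE`).
#' @return An `analysis_report` (list: `measurements`, `fits`, `limits`,
#'   `rejects`, `config`, `inventory`, `version`, `timestamp`, and the
#'   output `paths`).
#' @export
run_pipeline <- function(cfg = run_config(), strips = NULL, sheet = NULL,
                         render = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  geom <- lane_geometry(cfg$line_spacing_mm, cfg$band_width_mm,
                        cfg$roi_width_fraction)
  rejects <- data.frame(sample_id = character(), error = character(),
                        stringsAsFactors = FALSE)
  inventory <- character()

  if (!is.null(cfg$measurements_csv)) {
    measurements <- read_measurements(cfg$measurements_csv)
    inventory <- cfg$measurements_csv
  } else {
    if (is.null(sheet)) {
      if (is.null(cfg$sample_sheet))
        stop_lfa("lfa_usage_error",
                 "no input: provide sample_sheet (+ images) or measurements_csv")
      if (!file.exists(cfg$sample_sheet))
        stop_lfa("lfa_usage_error", "sample sheet not found: %s",
                 cfg$sample_sheet)
      sheet <- utils::read.csv(cfg$sample_sheet, stringsAsFactors = FALSE)
    }
    if (!all(c("image_path", "concentration_nM") %in% names(sheet)))
      stop_lfa("lfa_usage_error",
               "sample sheet needs columns image_path and concentration_nM")
    if (any(!is.na(sheet$concentration_nM) & sheet$concentration_nM < 0))
      stop_lfa("lfa_usage_error", "concentrations must be nonnegative")
    inventory <- sheet$image_path
    window_px <- function(ppm)
      max(3, round(cfg$baseline_window_mm * if (is.na(ppm)) 10 else ppm))
    rows <- vector("list", nrow(sheet))
    for (i in seq_len(nrow(sheet))) {
      res <- tryCatch({
        img <- if (!is.null(strips)) {
          s <- strips[[i]]
          if (is.list(s) && !inherits(s, "strip_image")) s$image else s
        } else {
          load_strip_image(sheet$image_path[i],
                           px_per_mm = cfg$px_per_mm)
        }
        quantify_strip(img, geom, channel = cfg$channel,
                       baseline_method = cfg$baseline_method,
                       baseline_window_px = window_px(img$px_per_mm),
                       flow_direction_hint = cfg$flow_direction_hint,
                       sample_id = basename(as.character(sheet$image_path[i])),
                       device = if (!is.null(sheet$device)) sheet$device[i]
                       else NA_character_,
                       concentration_nM = sheet$concentration_nM[i],
                       replicate = if (!is.null(sheet$replicate))
                         sheet$replicate[i] else NA_integer_)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        message(sprintf("[lfaquant] strip %s FAILED: %s",
                        sheet$image_path[i], conditionMessage(res)))
        rejects <- rbind(rejects,
                         data.frame(sample_id = as.character(sheet$image_path[i]),
                                    error = conditionMessage(res)))
      } else {
        message(sprintf("[lfaquant] strip %s ok: tl=%.3f cl=%.3f",
                        sheet$image_path[i], res$tl, res$cl))
        rows[[i]] <- as.data.frame(res)
      }
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows))
      stop_lfa("lfa_batch_error",
               "all %d strips failed:\n%s", nrow(sheet),
               paste(sprintf("  %s: %s", rejects$sample_id, rejects$error),
                     collapse = "\n"))
    measurements <- do.call(rbind, rows)
  }

  modes <- if (cfg$mode == "both") c("normalized", "standardized")
  else cfg$mode
  fits <- list()
  limits <- list()
  for (md in modes) {
    fits[[md]] <- fit_calibration(measurements, md)
    limits[[md]] <- compute_limits(measurements, fits[[md]],
                                   cfg$limits_methods)
  }

  report <- structure(list(inventory = inventory,
                           config = cfg,
                           measurements = measurements,
                           fits = fits, limits = limits,
                           rejects = rejects,
                           version = as.character(utils::packageVersion("lfaquant")),
                           timestamp = format(Sys.time(),
                                              "%Y-%m-%dT%H:%M:%S%z")),
                      class = "analysis_report")

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(measurements = file.path(cfg$out_dir, "measurements.csv"),
                fit = file.path(cfg$out_dir, "fit_summary.csv"),
                limits = file.path(cfg$out_dir, "limits.csv"),
                rejects = file.path(cfg$out_dir, "rejects.csv"))
  write_measurements(measurements, paths$measurements)
  fit_tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(mode = f$mode, slope = f$slope, intercept = f$intercept,
               r_squared = f$r_squared, pearson_r = f$pearson_r,
               n = f$n_points)))
  utils::write.csv(fit_tab, paths$fit, row.names = FALSE)
  lim_tab <- do.call(rbind, Filter(Negate(is.null),
                                   lapply(names(limits), function(md)
                                     limits_as_table(limits[[md]], md))))
  if (!is.null(lim_tab))
    utils::write.csv(lim_tab, paths$limits, row.names = FALSE)
  if (nrow(rejects)) utils::write.csv(rejects, paths$rejects,
                                      row.names = FALSE)
  if (render)
    paths$report <- render_report(report, cfg$format, cfg$out_dir)
  report$paths <- paths
  report
}
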