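#' Run configuration for the end-to-end pipeline
#'
#' Bundles everything one analysis run needs: either a preset name (the
#' synthetic route) or an input stack path, the ROI ladder, the fit
#' configuration, the half-time matching grids, the output directory and
#' the master seed. A single top-level seed deterministically derives the
#' per-stage seeds. The resolved configuration is written beside the
#' outputs of every run for provenance.
#'
#' @param preset Preset name (see [make_preset()]), or `NULL` when
#'   supplying `input`.
#' @param input Path to a multi-page TIFF stack, or `NULL` when supplying
#'   `preset`. Exactly one of the two must be given.
#' @param output_dir Output directory (created if missing).
#' @param roi Named list for the ROI ladder: `source` (pixel coords),
#'   `start`, `stop`, `step`, `band_width` (um). Optional when a sidecar
#'   provides geometry or the preset route is used.
#' @param fit A [fit_config()].
#' @param D_grid,t0_grid Half-time matching grids.
#' @param seed Master integer seed.
#' @param frame_interval,pixel_size Stack calibration (used when the input
#'   TIFF has no sidecar).
#' @return An object of class `run_config`.
#' @export
run_config <- function(preset = NULL, input = NULL, output_dir = ".",
                       roi = NULL, fit = fit_config(),
                       D_grid = c(4, 10),
                       t0_grid = c(300, 450, 600, 1200, 1800),
                       seed = 1L, frame_interval = NULL, pixel_size = NULL) {
  if (is.null(preset) == is.null(input))
    stop("supply exactly one of 'preset' or 'input'")
  stopifnot(inherits(fit, "fit_config"))
  structure(list(preset = preset, input = input, output_dir = output_dir,
                 roi = roi, fit = fit, D_grid = D_grid, t0_grid = t0_grid,
                 seed = as.integer(seed), frame_interval = frame_interval,
                 pixel_size = pixel_size),
            class = "run_config")
}

.stage_seed <- function(config, stage) {
  # deterministic per-stage seed derived from the master seed
  offsets <- c(simulate = 101L, noise = 211L, analyze = 307L, qc = 401L)
  (config$seed * 7919L + offsets[[stage]]) %% .Machine$integer.max
}

.write_resolved_config <- function(config, dir) {
  cfg <- unclass(config)
  cfg$fit <- unclass(cfg$fit)
  jsonlite::write_json(cfg, file.path(dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Simulate a preset acquisition and write it to disk
#'
#' Renders the preset's two-channel stack into the configured output
#' directory as TIFF + ground-truth sidecar JSON, plus the noise-free
#' reference traces as CSV.
#'
#' @param config A [run_config()] with a `preset`.
#' @param geom Optional [stack_geometry()]; a default centered-source
#'   geometry sized to cover the preset's ROI ladder is used otherwise.
#' @return Invisibly, a list with the written paths.
#' @export
cmd_simulate <- function(config, geom = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$preset)) stop("cmd_simulate requires a preset")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  preset <- make_preset(config$preset,
                        noise = noise_spec(seed = .stage_seed(config, "noise")))
  if (is.null(geom)) {
    px <- 1.375
    half <- ceiling((max(preset$roi_distances) + 15) / px)
    side <- 2L * half + 1L
    geom <- stack_geometry(side, side, pixel_size = px,
                           source = c(half, half))
  }
  rendered <- render_stack(preset, geom)
  stack_path <- file.path(config$output_dir,
                          paste0(config$preset, "_stack.tif"))
  truth <- list(preset = preset$name, D_um2_s = preset$D, t0_s = preset$t0,
                B = preset$B, seed = preset$noise$seed,
                source_px = as.vector(geom$source),
                roi_distances_um = preset$roi_distances)
  sidecar <- write_stack(rendered, stack_path, truth = truth)
  traces_path <- file.path(config$output_dir,
                           paste0(config$preset, "_traces.csv"))
  write_traces_csv(simulate_traces(preset, noise_free = TRUE), traces_path)
  .write_resolved_config(config, config$output_dir)
  invisible(list(stack = stack_path, sidecar = sidecar,
                 traces = traces_path, geom = geom))
}

#' Run the full analysis on a stack or preset
#'
#' Pipeline: extract ROI traces (or simulate them for a preset), smooth,
#' global shared-D fit, half-time trend, grid-matched delay estimate.
#' Writes the fit report JSON, the trend CSV + JSON, the trace CSV, and
#' the resolved configuration into `output_dir`. Deterministic given the
#' config.
#'
#' @param config A [run_config()].
#' @param t0_fixed Fixed delay passed to the fit; defaults to the preset's
#'   delay (preset route) or `config$fit$t0_s`.
#' @return A list with `fit` ([fit_global()] result), `trend`
#'   ([build_trend()] result), `t0_est` ([estimate_t0()] result), and the
#'   written paths.
#' @export
cmd_analyze <- function(config, t0_fixed = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "extract"
  result <- tryCatch({
    if (!is.null(config$preset)) {
      preset <- make_preset(config$preset,
                            noise = noise_spec(seed = .stage_seed(config,
                                                                  "noise")))
      traces <- simulate_traces(preset)
      if (is.null(t0_fixed)) t0_fixed <- preset$t0
    } else {
      stack <- read_stack(config$input,
                          frame_interval = config$frame_interval,
                          pixel_size = config$pixel_size)
      roi <- config$roi
      if (is.null(roi))
        stop("analyzing a stack requires 'roi' ladder parameters")
      rois <- build_roi_ladder(stack, roi$source, roi$start, roi$stop,
                               roi$step, roi$band_width %||% roi$step)
      traces <- extract_traces(stack, rois)
    }
    cfg <- config$fit
    if (!is.null(t0_fixed)) cfg$t0_s <- t0_fixed
    stage <- "smooth"
    smoothed <- lapply(traces, smooth_trace, cfg = cfg)
    stage <- "global_fit"
    fit <- fit_global(smoothed, cfg)
    stage <- "half_time"
    trend <- build_trend(smoothed)
    t0_est <- estimate_t0(trend, config$D_grid, config$t0_grid)
    list(traces = smoothed, fit = fit, trend = trend, t0_est = t0_est)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  paths <- list(
    traces = file.path(config$output_dir, "traces.csv"),
    fit = file.path(config$output_dir, "fit_report.json"),
    trend_csv = file.path(config$output_dir, "halftime_trend.csv"),
    trend_json = file.path(config$output_dir, "halftime_analysis.json"))
  write_traces_csv(result$traces, paths$traces)
  fit_report(result$fit, result$traces, json_path = paths$fit)
  utils::write.csv(result$trend$points, paths$trend_csv, row.names = FALSE)
  jsonlite::write_json(
    list(slope_s_per_um = result$trend$slope,
         intercept_s = result$trend$intercept,
         v_hat_um_s = result$trend$v_hat,
         v_points_um_s = result$trend$v_points,
         Dv_hat_um2_s = result$trend$Dv_hat,
         t0_hat_s = result$t0_est$t0_hat,
         D_at_min = result$t0_est$D_at_min,
         sse_table = result$t0_est$sse_table),
    paths$trend_json, auto_unbox = TRUE, digits = NA, null = "null")
  .write_resolved_config(config, config$output_dir)
  c(result, list(paths = paths))
}

#' Run the optics quality-control analyses
#'
#' Runs the light-sheet thickness and/or PSF estimators on calibration
#' images (or on freshly generated synthetic fixtures when no paths are
#' given) and writes a QC JSON report.
#'
#' @param config A [run_config()] (used for `output_dir` and seed).
#' @param sheet_path,beads_path Optional single-page TIFF paths; when
#'   `NULL` a synthetic fixture at the default ground truth is analyzed.
#' @param pixel_size_sheet,pixel_size_beads Pixel pitches for supplied
#'   images, um/pixel.
#' @return Invisibly, a list with the two reports and the JSON path.
#' @export
cmd_optics_qc <- function(config, sheet_path = NULL, beads_path = NULL,
                          pixel_size_sheet = 1.375,
                          pixel_size_beads = 0.55) {
  stopifnot(inherits(config, "run_config") || is.null(config))
  out_dir <- if (is.null(config)) "." else config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  read_img <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img
  }
  sheet <- if (is.null(sheet_path)) {
    fx <- make_calibration_fixture("sheet")
    sheet_thickness(fx$image, fx$pixel_size)
  } else sheet_thickness(read_img(sheet_path), pixel_size_sheet)
  beads <- if (is.null(beads_path)) {
    fx <- make_calibration_fixture("beads")
    psf_from_beads(fx$image, fx$pixel_size)
  } else psf_from_beads(read_img(beads_path), pixel_size_beads)
  path <- file.path(out_dir, "optics_qc.json")
  jsonlite::write_json(
    list(sheet = list(mean_fwhm_um = sheet$mean_fwhm,
                      sd_fwhm_um = sheet$sd_fwhm,
                      n_lines = sheet$n_lines),
         psf = list(mean_fwhm_um = beads$mean_fwhm,
                    sd_fwhm_um = beads$sd_fwhm,
                    n_beads = beads$n_beads)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(list(sheet = sheet, psf = beads, path = path))
}
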