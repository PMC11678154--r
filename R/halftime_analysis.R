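#' Half time of a measured trace
#'
#' The first observation time at which the trace falls to half its initial
#' value, with linear interpolation between the bracketing frames. The
#' "initial value" is the value at the first recorded frame (default) or
#' the maximum over an early window, for traces that rise before decaying.
#'
#' @param trace An [intensity_trace()] (typically smoothed first).
#' @param initial `"first"` (value at the first frame) or `"early_max"`
#'   (maximum over the first `early_window` frames; the crossing search
#'   starts at the maximum).
#' @param early_window Number of frames defining the early window.
#' @return The half time tau_1/2, s, on the observation clock relative to
#'   the first frame.
#' @export
measure_half_time <- function(trace, initial = c("first", "early_max"),
                              early_window = 11L) {
  stopifnot(inherits(trace, "intensity_trace"))
  initial <- match.arg(initial)
  y <- trace$values; t <- trace$times
  if (initial == "first") {
    y0 <- y[1]; start <- 1L
  } else {
    w <- min(early_window, length(y))
    start <- which.max(y[seq_len(w)])
    y0 <- y[start]
  }
  if (y0 <= 0) stop("trace '", trace$label, "' has nonpositive initial value")
  target <- y0 / 2
  below <- which(y <= target & seq_along(y) > start)
  if (length(below) == 0L)
    stop("trace '", trace$label,
         "' never falls to half its initial value within the record")
  k <- below[1]
  # linear interpolation between the last frame above and the first at/below
  frac <- (y[k - 1] - target) / (y[k - 1] - y[k])
  (t[k - 1] + frac * (t[k] - t[k - 1])) - t[1]
}

#' Half-time-versus-distance trend
#'
#' Measures tau_1/2 for each trace, fits the ordinary-least-squares line
#' `tau_1/2 = slope * R0 + intercept` (the relation is linear but not a
#' direct proportionality: the intercept, about `3 t0`, is retained), and
#' derives the wavefront speed `v_hat = 1/slope`, the per-point speeds
#' `R0/tau`, and the corrected diffusion estimate `Dv_hat` via
#' [solve_Dv()] at the reference point `R0 = v_hat * tau_ref`.
#'
#' ROIs whose traces never halve within the recorded window are dropped
#' with a warning (they carry no half-time information); at least 3 valid
#' points are required.
#'
#' @param traces List of [intensity_trace()] objects.
#' @param initial,early_window Passed to [measure_half_time()].
#' @param tau_ref Reference half time, s, at which `Dv_hat` is evaluated.
#' @param fc An [f_correction()].
#' @return An object of class `half_time_trend` with fields `points`
#'   (data frame `R0_um`, `tau_half_s`), `slope`, `slope_se`, `intercept`,
#'   `intercept_se`, `v_hat`, `v_points` (per-point `R0/tau`), `Dv_hat`,
#'   `tau_ref`, `dropped` (labels of non-crossing ROIs).
#' @export
build_trend <- function(traces, initial = c("first", "early_max"),
                        early_window = 11L, tau_ref = 700,
                        fc = f_correction()) {
  stopifnot(is.list(traces), length(traces) >= 1L)
  initial <- match.arg(initial)
  R0 <- numeric(0); tau <- numeric(0); dropped <- character(0)
  for (tr in traces) {
    th <- tryCatch(measure_half_time(tr, initial, early_window),
                   error = function(e) NA_real_)
    if (is.na(th)) dropped <- c(dropped, tr$label)
    else { R0 <- c(R0, tr$distance); tau <- c(tau, th) }
  }
  if (length(dropped))
    warning("ROIs without a half-value crossing dropped from the trend: ",
            paste(dropped, collapse = ", "))
  if (length(R0) < 3L)
    stop("build_trend needs >= 3 ROIs with a measurable half time (got ",
         length(R0), ")")
  ord <- order(R0)
  R0 <- R0[ord]; tau <- tau[ord]
  fit <- stats::lm(tau ~ R0)
  # noise-free data fits exactly; silence summary()'s perfect-fit caveat
  co <- suppressWarnings(summary(fit)$coefficients)
  slope <- co["R0", "Estimate"]
  if (slope <= 0)
    warning("nonpositive tau-half slope: not consistent with outward diffusion")
  v_hat <- if (slope > 0) 1 / slope else NA_real_
  Dv_hat <- if (is.finite(v_hat)) {
    tryCatch(solve_Dv(v_hat * tau_ref, tau_ref, fc),
             error = function(e) { warning(conditionMessage(e)); NA_real_ })
  } else NA_real_
  structure(list(points = data.frame(R0_um = R0, tau_half_s = tau),
                 slope = slope, slope_se = co["R0", "Std. Error"],
                 intercept = co["(Intercept)", "Estimate"],
                 intercept_se = co["(Intercept)", "Std. Error"],
                 v_hat = v_hat, v_points = R0 / tau,
                 Dv_hat = Dv_hat, tau_ref = tau_ref,
                 dropped = dropped, fc = fc),
            class = "half_time_trend")
}

#' @export
print.half_time_trend <- function(x, ...) {
  cat(sprintf("Half-time trend over %d ROIs (%d dropped)\n",
              nrow(x$points), length(x$dropped)))
  cat(sprintf("  tau_1/2 = %.4g * R0 + %.4g s (SEs %.2g, %.2g)\n",
              x$slope, x$intercept, x$slope_se, x$intercept_se))
  cat(sprintf("  v_hat = %.4g um/s, Dv_hat = %.4g um^2/s (tau_ref = %g s)\n",
              x$v_hat, x$Dv_hat, x$tau_ref))
  invisible(x)
}

#' Simulated half-time curve
#'
#' The model half time at each distance of `R0_grid` for given `(D, t0)` —
#' the same operator later compared against data, guaranteeing
#' self-consistency of the matching in [estimate_t0()].
#'
#' @param D Diffusion coefficient, um^2/s, > 0.
#' @param t0 Delay, s, > 0.
#' @param R0_grid Distances, um.
#' @param t_max If finite, distances whose half time exceeds `t_max`
#'   (i.e. would not be observable in a record of that length) get `NA`.
#' @return A data frame `R0_um`, `tau_half_s`.
#' @export
simulate_trend <- function(D, t0, R0_grid, t_max = Inf) {
  params <- diffusion_params(D, t0, 1)
  tau <- half_time(params, R0_grid)
  if (is.finite(t_max)) tau[tau > t_max] <- NA_real_
  data.frame(R0_um = R0_grid, tau_half_s = tau)
}

#' Estimate the injection-to-observation delay by curve matching
#'
#' Compares the measured half-time points against simulated
#' tau-half-versus-distance curves over a `(D, t0)` candidate grid and
#' returns the `t0` of the best-matching curve (sum of squared errors at
#' the measured distances; ties broken toward smaller `t0`). The default
#' grids span the physiologically plausible delays and effective
#' diffusivities of the embryo experiments.
#'
#' @param trend A [build_trend()] result.
#' @param D_grid Candidate diffusion coefficients, um^2/s.
#' @param t0_grid Candidate delays, s.
#' @return A list with `t0_hat` (s), `D_at_min` (the candidate D of the
#'   winning curve), and `sse_table` (data frame `D`, `t0`, `sse`).
#' @export
#' @examples
#' tr <- simulate_traces(make_preset("control_embryo"), noise_free = TRUE)
#' est <- estimate_t0(build_trend(tr))
#' est$t0_hat
estimate_t0 <- function(trend, D_grid = c(4, 10),
                        t0_grid = c(300, 450, 600, 1200, 1800)) {
  stopifnot(inherits(trend, "half_time_trend"),
            length(D_grid) >= 1L, length(t0_grid) >= 1L)
  R0 <- trend$points$R0_um
  tau <- trend$points$tau_half_s
  grid <- expand.grid(D = D_grid, t0 = t0_grid)
  grid$sse <- vapply(seq_len(nrow(grid)), function(i) {
    sim <- tryCatch(
      simulate_trend(grid$D[i], grid$t0[i], R0)$tau_half_s,
      error = function(e) rep(NA_real_, length(R0)))
    if (any(!is.finite(sim))) return(Inf)
    sum((sim - tau)^2)
  }, numeric(1))
  if (all(!is.finite(grid$sse)))
    stop("estimate_t0: all candidate simulations failed")
  ord <- order(grid$sse, grid$t0)   # ties toward smaller t0
  best <- grid[ord[1], ]
  list(t0_hat = best$t0, D_at_min = best$D, sse_table = grid)
}

#' Plot a half-time trend in the simulated-curve style
#'
#' Measured points, the dotted best-fit line, and solid/dashed simulated
#' curves for each `(D, t0)` candidate pair.
#'
#' @param trend A [build_trend()] result.
#' @param D_grid,t0_grid Candidate curves to overlay.
#' @param path Optional PNG path; if `NULL`, plots to the active device.
#' @return Invisibly, `trend`.
#' @export
plot_trend <- function(trend, D_grid = c(4, 10),
                       t0_grid = c(300, 450, 600, 1200, 1800), path = NULL) {
  stopifnot(inherits(trend, "half_time_trend"))
  if (!is.null(path)) {
    grDevices::png(path, width = 700, height = 500)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  R0g <- seq(0, max(trend$points$R0_um) * 1.1, length.out = 50)
  plot(trend$points$R0_um, trend$points$tau_half_s,
       xlab = "R0 (um)", ylab = expression(tau[1/2] ~ "(s)"),
       pch = 15, ylim = c(0, max(trend$points$tau_half_s) * 1.3))
  graphics::abline(trend$intercept, trend$slope, lty = 3)
  for (D in D_grid) for (t0 in t0_grid) {
    sim <- simulate_trend(D, t0, R0g)
    graphics::lines(sim$R0_um, sim$tau_half_s,
                    lty = if (D == D_grid[1]) 2 else 1,
                    col = "grey40")
  }
  invisible(trend)
}
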