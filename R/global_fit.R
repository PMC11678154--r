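#' Configuration for smoothing and global fitting
#'
#' @param sg_window Savitzky--Golay window, odd number of frames,
#'   `> sg_order`.
#' @param sg_order Savitzky--Golay polynomial order.
#' @param t0_s Injection-to-observation delay: a fixed value in seconds, or
#'   the string `"free"` to estimate it (bounded to `[0, 3600]` s).
#' @param D_bounds Search interval for the shared diffusion coefficient,
#'   um^2/s; lower bound must be > 0.
#' @param baseline If `TRUE`, fit an additive per-trace offset alongside
#'   the amplitude.
#' @param mask_before_s Discard frames earlier than this observation time
#'   (e.g. to exclude a pressure-ramp transient), s.
#' @param n_starts Number of log-spaced sub-intervals of `D_bounds`
#'   searched independently (multi-start).
#' @param max_iter,tol Optimizer budget and relative tolerance.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(sg_window = 11, sg_order = 3, t0_s = 0,
                       D_bounds = c(0.01, 100), baseline = FALSE,
                       mask_before_s = 0, n_starts = 5,
                       max_iter = 200, tol = 1e-10) {
  stopifnot(sg_window %% 2 == 1, sg_window > sg_order, sg_order >= 0)
  stopifnot(length(D_bounds) == 2L, D_bounds[1] > 0,
            D_bounds[2] > D_bounds[1])
  if (!(identical(t0_s, "free") ||
        (is.numeric(t0_s) && length(t0_s) == 1L && t0_s >= 0)))
    stop("'t0_s' must be a nonnegative number or \"free\"")
  structure(list(sg_window = as.integer(sg_window),
                 sg_order = as.integer(sg_order), t0_s = t0_s,
                 D_bounds = D_bounds, baseline = isTRUE(baseline),
                 mask_before_s = mask_before_s,
                 n_starts = as.integer(n_starts),
                 max_iter = as.integer(max_iter), tol = tol),
            class = "fit_config")
}

#' Savitzky--Golay smoothing of a trace
#'
#' Least-squares local-polynomial smoothing with the configured window and
#' order; times are unchanged. Endpoints are handled by fitting the
#' polynomial over the first/last full window and evaluating off-center
#' (no reflection padding), so polynomials up to the filter order pass
#' through unchanged everywhere.
#'
#' @param trace An [intensity_trace()], at least `sg_window` frames long.
#' @param cfg A [fit_config()] (only `sg_window`/`sg_order` are used).
#' @return The smoothed [intensity_trace()].
#' @export
smooth_trace <- function(trace, cfg = fit_config()) {
  stopifnot(inherits(trace, "intensity_trace"), inherits(cfg, "fit_config"))
  if (length(trace$values) < cfg$sg_window)
    stop("trace '", trace$label, "' is shorter than the smoothing window")
  trace$values <- as.numeric(
    signal::sgolayfilt(trace$values, p = cfg$sg_order, n = cfg$sg_window))
  trace
}

# Model shape with unit amplitude: 1/sqrt(pi D u) exp(-x^2/(4 D u)), u = t + t0.
.fit_shape <- function(D, t0, x, t) {
  u <- t + t0
  1 / sqrt(pi * D * u) * exp(-x^2 / (4 * D * u))
}

# Profiled residual sum of squares: per-trace amplitude (and optional
# baseline) solved linearly for a candidate (D, t0).
.profiled_rss <- function(D, t0, tr_data, baseline) {
  rss <- 0
  for (td in tr_data) {
    g <- .fit_shape(D, t0, td$x, td$t)
    if (any(!is.finite(g))) return(sqrt(.Machine$double.xmax))
    gg <- sum(g * g)
    if (gg < .Machine$double.xmin) {
      # shape underflowed to zero (D far too small for this distance):
      # the best amplitude is 0 and the trace is pure residual
      rss <- rss + sum(td$y^2)
    } else if (baseline) {
      fit <- stats::lm.fit(cbind(g, 1), td$y)
      rss <- rss + sum(fit$residuals^2)
    } else {
      B <- sum(td$y * g) / gg
      rss <- rss + sum((td$y - B * g)^2)
    }
  }
  rss
}

.profiled_coefs <- function(D, t0, tr_data, baseline) {
  t(vapply(tr_data, function(td) {
    g <- .fit_shape(D, t0, td$x, td$t)
    if (baseline) {
      co <- stats::lm.fit(cbind(g, 1), td$y)$coefficients
      c(B = unname(co[1]), c0 = unname(co[2]))
    } else {
      c(B = sum(td$y * g) / sum(g * g), c0 = 0)
    }
  }, c(B = 0, c0 = 0)))
}

#' Global shared-D fit of the delayed point-source model
#'
#' Fits all traces simultaneously to
#' `B_i / sqrt(pi D (t + t0)) exp(-R0_i^2 / (4 D (t + t0)))`
#' by least squares, with the diffusion coefficient `D` shared across
#' traces and one free amplitude `B_i` (plus optional baseline) per trace.
#' ROI distances `R0_i` are taken from the trace metadata and never fitted.
#' The delay `t0` is either fixed (default) or estimated.
#'
#' Amplitudes enter the model linearly and are profiled out, reducing the
#' search to `D` alone (or `(D, t0)`); the profiled objective is minimized
#' over `n_starts` log-spaced sub-intervals of `D_bounds` and the best
#' optimum kept. Standard errors come from the Jacobian of the full
#' residual vector at the optimum.
#'
#' @param traces A list of at least two [intensity_trace()] objects with
#'   distinct distances.
#' @param cfg A [fit_config()]; `cfg$t0_s` is the fixed delay or `"free"`.
#' @return An object of class `global_fit_result` with elements `D_hat`,
#'   `D_se`, `t0_used`, `t0_se` (`NA` when fixed), `B_hat`, `B_se`,
#'   `baseline_hat`, `rss`, `r_squared` (per trace), `distances`,
#'   `converged`, `at_bound`, `n_obs`.
#' @export
#' @examples
#' tr <- simulate_traces(make_preset("control_embryo"), noise_free = TRUE)
#' fit <- fit_global(tr, fit_config(t0_s = 320))
#' fit$D_hat
fit_global <- function(traces, cfg = fit_config()) {
  stopifnot(is.list(traces), inherits(cfg, "fit_config"))
  traces <- Filter(function(tr) inherits(tr, "intensity_trace"), traces)
  if (length(traces) < 2L)
    stop("fit_global needs at least 2 traces")
  dists <- vapply(traces, `[[`, numeric(1), "distance")
  if (length(unique(dists)) < 2L)
    stop("fit_global needs traces at >= 2 distinct distances")
  tr_data <- lapply(traces, function(tr) {
    keep <- tr$times >= cfg$mask_before_s
    if (sum(keep) < 3L)
      stop("trace '", tr$label, "' has too few frames after masking")
    list(x = tr$distance, t = tr$times[keep], y = tr$values[keep],
         label = tr$label)
  })
  free_t0 <- identical(cfg$t0_s, "free")
  lb <- log10(cfg$D_bounds)

  edges <- seq(lb[1], lb[2], length.out = cfg$n_starts + 1L)
  best <- NULL
  for (i in seq_len(cfg$n_starts)) {
    cand <- if (free_t0) {
      o <- stats::optim(c(mean(edges[i:(i + 1)]), 300),
                        function(p) .profiled_rss(10^p[1], p[2], tr_data,
                                                  cfg$baseline),
                        method = "L-BFGS-B",
                        lower = c(lb[1], 1e-3), upper = c(lb[2], 3600),
                        control = list(maxit = cfg$max_iter,
                                       factr = cfg$tol / .Machine$double.eps))
      list(logD = o$par[1], t0 = o$par[2], rss = o$value,
           conv = o$convergence == 0)
    } else {
      o <- stats::optimize(function(ld) .profiled_rss(10^ld, cfg$t0_s,
                                                      tr_data, cfg$baseline),
                           lower = edges[i], upper = edges[i + 1L],
                           tol = cfg$tol)
      list(logD = o$minimum, t0 = cfg$t0_s, rss = o$objective, conv = TRUE)
    }
    if (is.null(best) || cand$rss < best$rss) best <- cand
  }
  # polish across the full interval around the best start
  if (!free_t0) {
    o <- stats::optimize(function(ld) .profiled_rss(10^ld, cfg$t0_s,
                                                    tr_data, cfg$baseline),
                         lower = max(lb[1], best$logD - 0.3),
                         upper = min(lb[2], best$logD + 0.3), tol = cfg$tol)
    if (o$objective <= best$rss)
      best <- list(logD = o$minimum, t0 = cfg$t0_s, rss = o$objective,
                   conv = TRUE)
  }
  D_hat <- 10^best$logD
  t0_hat <- best$t0
  at_bound <- min(abs(best$logD - lb)) < 1e-6 ||
    (free_t0 && (t0_hat <= 1e-9 || t0_hat >= 3600 - 1e-9))
  if (at_bound)
    warning("fitted D (or t0) sits at a search bound; result flagged")

  coefs <- .profiled_coefs(D_hat, t0_hat, tr_data, cfg$baseline)
  B_hat <- coefs[, "B"]
  base_hat <- coefs[, "c0"]
  labels <- vapply(tr_data, `[[`, "", "label")
  names(B_hat) <- names(base_hat) <- labels

  se <- .fit_standard_errors(D_hat, t0_hat, B_hat, base_hat, tr_data,
                             cfg$baseline, free_t0, best$rss)
  r2 <- vapply(seq_along(tr_data), function(i) {
    td <- tr_data[[i]]
    pred <- B_hat[i] * .fit_shape(D_hat, t0_hat, td$x, td$t) + base_hat[i]
    1 - sum((td$y - pred)^2) / max(sum((td$y - mean(td$y))^2),
                                   .Machine$double.eps)
  }, numeric(1))
  names(r2) <- labels

  structure(list(D_hat = D_hat, D_se = se$D_se,
                 t0_used = t0_hat, t0_free = free_t0,
                 t0_se = if (free_t0) se$t0_se else NA_real_,
                 B_hat = B_hat, B_se = se$B_se,
                 baseline_hat = if (cfg$baseline) base_hat else NULL,
                 rss = best$rss, r_squared = r2,
                 distances = dists, n_obs = sum(lengths(lapply(tr_data,
                                                               `[[`, "t"))),
                 converged = best$conv, at_bound = at_bound, cfg = cfg),
            class = "global_fit_result")
}

# Standard errors from the numeric Jacobian of the stacked residual vector
# with respect to (D [, t0], B_1..B_n [, c_1..c_n]).
.fit_standard_errors <- function(D, t0, B, base, tr_data, baseline,
                                 free_t0, rss) {
  theta <- c(D, if (free_t0) t0, B, if (baseline) base)
  resid_vec <- function(th) {
    Dv <- th[1]
    off <- 1
    t0v <- if (free_t0) { off <- 2; th[2] } else t0
    n <- length(tr_data)
    Bv <- th[(off + 1):(off + n)]
    cv <- if (baseline) th[(off + n + 1):(off + 2 * n)] else rep(0, n)
    unlist(lapply(seq_len(n), function(i) {
      td <- tr_data[[i]]
      td$y - (Bv[i] * .fit_shape(Dv, t0v, td$x, td$t) + cv[i])
    }))
  }
  r0 <- resid_vec(theta)
  p <- length(theta); N <- length(r0)
  J <- matrix(0, N, p)
  h <- pmax(abs(theta), 1e-4) * 1e-6
  for (j in seq_len(p)) {
    tp <- theta; tm <- theta
    tp[j] <- tp[j] + h[j]; tm[j] <- tm[j] - h[j]
    J[, j] <- (resid_vec(tp) - resid_vec(tm)) / (2 * h[j])
  }
  sigma2 <- rss / max(N - p, 1)
  cov <- tryCatch(sigma2 * solve(crossprod(J)),
                  error = function(e) matrix(NA_real_, p, p))
  ses <- sqrt(pmax(diag(cov), 0))
  off <- if (free_t0) 2L else 1L
  list(D_se = ses[1],
       t0_se = if (free_t0) ses[2] else NA_real_,
       B_se = stats::setNames(ses[(off + 1):(off + length(tr_data))],
                              vapply(tr_data, `[[`, "", "label")))
}

#' @export
print.global_fit_result <- function(x, ...) {
  cat(sprintf("Global diffusion fit over %d traces (%d points)\n",
              length(x$B_hat), x$n_obs))
  cat(sprintf("  D_hat = %.4g +/- %.2g um^2/s%s\n", x$D_hat, x$D_se,
              if (x$at_bound) "  [AT BOUND]" else ""))
  cat(sprintf("  t0 %s = %.4g s%s\n",
              if (x$t0_free) "(fitted)" else "(fixed)", x$t0_used,
              if (x$t0_free) sprintf(" +/- %.2g", x$t0_se) else ""))
  cat(sprintf("  RSS = %.4g, median per-trace R^2 = %.4f\n",
              x$rss, stats::median(x$r_squared)))
  invisible(x)
}

#' Serialize a global fit (and optionally plot it)
#'
#' Writes the fit summary as JSON and, optionally, a per-ROI
#' data-plus-fitted-curves figure (one curve per distance).
#'
#' @param result A [fit_global()] result.
#' @param traces The traces that were fitted (needed for the figure).
#' @param json_path Optional path for the JSON report.
#' @param plot_path Optional path for a PNG figure.
#' @return The report as a named list, invisibly.
#' @export
fit_report <- function(result, traces = NULL, json_path = NULL,
                       plot_path = NULL) {
  stopifnot(inherits(result, "global_fit_result"))
  rep <- list(D_hat_um2_s = result$D_hat, D_se = result$D_se,
              t0_s = result$t0_used, t0_free = result$t0_free,
              t0_se = result$t0_se,
              B_hat = as.list(result$B_hat),
              baseline_hat = if (!is.null(result$baseline_hat))
                as.list(result$baseline_hat),
              rss = result$rss, r_squared = as.list(result$r_squared),
              distances_um = result$distances,
              converged = result$converged, at_bound = result$at_bound)
  if (!is.null(json_path))
    jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (!is.null(plot_path) && !is.null(traces)) {
    grDevices::png(plot_path, width = 800, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    cols <- grDevices::hcl.colors(length(traces), "viridis")
    ylim <- range(unlist(lapply(traces, `[[`, "values")))
    plot(NULL, xlim = range(traces[[1]]$times), ylim = ylim,
         xlab = "time (s)", ylab = "intensity (a.u.)",
         main = sprintf("Global fit: D = %.3g um^2/s", result$D_hat))
    for (i in seq_along(traces)) {
      tr <- traces[[i]]
      graphics::points(tr$times, tr$values, col = cols[i], pch = 16,
                       cex = 0.3)
      pred <- result$B_hat[[tr$label]] *
        .fit_shape(result$D_hat, result$t0_used, tr$distance, tr$times)
      if (!is.null(result$baseline_hat))
        pred <- pred + result$baseline_hat[[tr$label]]
      graphics::lines(tr$times, pred, col = cols[i], lwd = 2)
    }
  }
  invisible(rep)
}
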