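#' Parameters of the delayed point-source diffusion model
#'
#' Bundles the three parameters of the one-dimensional Gaussian solution of
#' Fick's second law on a semi-infinite bar with a delayed observation clock:
#' the diffusion coefficient `D`, the injection-to-observation delay `t0`,
#' and the source amplitude `B` (the conserved half-line mass, in
#' intensity x um).
#'
#' The model describes a fixed quantity of fluorescent tracer released at
#' the origin at injection time; recording starts `t0` seconds later, so the
#' concentration at distance `x` and observation time `t` is
#' \deqn{C(x, t) = \frac{B}{\sqrt{\pi D (t + t_0)}}
#'       \exp\!\left(-\frac{x^2}{4 D (t + t_0)}\right).}
#'
#' @param D Diffusion coefficient, um^2/s. Must be > 0.
#' @param t0 Delay between injection and the first recorded frame, s.
#'   Must be >= 0; `t0 = 0` means observation starts at injection (the
#'   agarose point-injection case).
#' @param B Source amplitude (half-line mass), intensity a.u. x um. Must
#'   be > 0.
#' @return An object of class `diffusion_params`.
#' @seealso [dye_concentration()], [half_time()], [peak_time()]
#' @export
#' @examples
#' p <- diffusion_params(D = 12, t0 = 320)
#' dye_concentration(p, x = 30, t = 0)
diffusion_params <- function(D, t0 = 0, B = 1) {
  stopifnot(is.numeric(D), length(D) == 1L, is.finite(D),
            is.numeric(t0), length(t0) == 1L, is.finite(t0),
            is.numeric(B), length(B) == 1L, is.finite(B))
  if (D <= 0) stop("'D' must be > 0 (got ", D, ")")
  if (t0 < 0) stop("'t0' must be >= 0 (got ", t0, ")")
  if (B <= 0) stop("'B' must be > 0 (got ", B, ")")
  structure(list(D = D, t0 = t0, B = B), class = "diffusion_params")
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat(sprintf("Diffusion parameters: D = %g um^2/s, t0 = %g s, B = %g\n",
              x$D, x$t0, x$B))
  invisible(x)
}

#' Empirical half-time correction polynomial
#'
#' The quadratic correction factor f(D) relating the mean-squared
#' displacement, the half time and the diffusion coefficient in the
#' wavefront analysis: `f(D) = c2 D^2 + c1 D + c0`. With the default
#' coefficients f(D) is close to 4 over the supported range
#' 1 <= D <= 20 um^2/s.
#'
#' @param c2,c1,c0 Polynomial coefficients (dimensionless).
#' @return An object of class `f_correction`.
#' @seealso [f_of_D()], [solve_Dv()]
#' @export
f_correction <- function(c2 = 0.013, c1 = -0.51, c0 = 8.14) {
  stopifnot(is.numeric(c2), is.numeric(c1), is.numeric(c0))
  structure(list(c2 = c2, c1 = c1, c0 = c0), class = "f_correction")
}

#' Evaluate the correction polynomial f(D)
#'
#' @param D Diffusion coefficient(s), um^2/s. Values outside the supported
#'   range 1--20 um^2/s trigger a warning (the polynomial was calibrated
#'   there).
#' @param fc An [f_correction()] object.
#' @return f(D), dimensionless; vectorized over `D`.
#' @export
#' @examples
#' f_of_D(12)  # 3.892
f_of_D <- function(D, fc = f_correction()) {
  stopifnot(inherits(fc, "f_correction"), is.numeric(D))
  if (any(D < 1 | D > 20))
    warning("f(D) evaluated outside its supported range 1 <= D <= 20 um^2/s")
  fc$c2 * D^2 + fc$c1 * D + fc$c0
}

#' Concentration of the delayed point-source diffusion model
#'
#' Evaluates \eqn{C(x,t) = B / \sqrt{\pi D (t+t_0)} \exp(-x^2 / (4 D (t+t_0)))},
#' the Gaussian solution of the 1-D diffusion equation on a half line with
#' total mass `B` and the observation clock shifted by `t0`.
#'
#' @param params A [diffusion_params()] object.
#' @param x Distance(s) from the source, um, >= 0.
#' @param t Observation time(s), s, >= 0. `x` and `t` are recycled to a
#'   common length.
#' @return Concentration in intensity units, strictly positive.
#' @export
dye_concentration <- function(params, x, t) {
  stopifnot(inherits(params, "diffusion_params"), is.numeric(x), is.numeric(t))
  if (any(x < 0)) stop("distance 'x' must be >= 0")
  if (any(t < 0)) stop("time 't' must be >= 0")
  u <- t + params$t0
  if (any(u == 0))
    stop("singular time: t + t0 = 0 (the model diverges at the injection instant)")
  params$B / sqrt(pi * params$D * u) * exp(-x^2 / (4 * params$D * u))
}

#' Time of peak concentration at a fixed distance
#'
#' On the injection clock the concentration at distance `x` peaks at
#' `x^2 / (2 D)`; on the observation (recording) clock the peak is at
#' `max(0, x^2/(2D) - t0)` — traces whose peak predates the first recorded
#' frame are monotonically decaying in the recorded window.
#'
#' @inheritParams dye_concentration
#' @param observed If `TRUE`, return the peak time on the observation clock
#'   (clamped at 0); otherwise on the injection clock.
#' @return Peak time(s), s.
#' @export
peak_time <- function(params, x, observed = FALSE) {
  stopifnot(inherits(params, "diffusion_params"), is.numeric(x))
  if (any(x < 0)) stop("distance 'x' must be >= 0")
  tm <- x^2 / (2 * params$D)
  if (observed) pmax(0, tm - params$t0) else tm
}

#' Half time of the modelled trace
#'
#' The time (observation clock) at which the concentration at distance `x`
#' first falls to half its value at the start of recording. Requires
#' `t0 > 0` so that the initial value is finite. At `x = 0` the half time
#' is exactly `3 t0` (the `1/sqrt(t + t0)` prefactor halves at
#' `t + t0 = 4 t0`). The root of
#' `log(u/t0)/2 + a/u - a/t0 = log(2)` with `u = t + t0`, `a = x^2/(4D)`
#' is bracketed on the decaying branch (`u >= max(t0, 2a)`) and solved with
#' [stats::uniroot()] to relative tolerance 1e-10.
#'
#' @inheritParams dye_concentration
#' @return Half time(s) tau_1/2, s; vectorized over `x`.
#' @export
#' @examples
#' p <- diffusion_params(D = 12, t0 = 320)
#' half_time(p, x = c(0, 30, 60))
half_time <- function(params, x) {
  stopifnot(inherits(params, "diffusion_params"), is.numeric(x))
  if (params$t0 <= 0)
    stop("half_time requires t0 > 0: the initial value is undefined at t0 = 0")
  if (any(x < 0)) stop("distance 'x' must be >= 0")
  t0 <- params$t0
  vapply(x, function(xi) {
    a <- xi^2 / (4 * params$D)
    if (a == 0) return(3 * t0)
    g <- function(u) 0.5 * log(u / t0) + a / u - a / t0 - log(2)
    lo <- max(t0, 2 * a)     # decaying branch starts at the peak u = 2a
    hi <- max(4 * t0, 2 * lo)
    while (g(hi) < 0) {
      hi <- hi * 4
      if (hi > 1e12) stop("half_time failed to bracket the crossing (x = ",
                          xi, ", D = ", params$D, ", t0 = ", t0, ")")
    }
    r <- stats::uniroot(g, lower = lo, upper = hi, tol = 1e-10 * t0)
    r$root - t0
  }, numeric(1))
}

#' Wave speed from distance and half time
#'
#' Heuristic speed of the concentration wavefront, `v = R0 / tau_half`.
#'
#' @param R0 Distance from the source, um, >= 0.
#' @param tau_half Half time, s, > 0.
#' @return Speed, um/s; vectorized.
#' @export
wave_speed <- function(R0, tau_half) {
  stopifnot(is.numeric(R0), is.numeric(tau_half))
  if (any(tau_half <= 0)) stop("'tau_half' must be > 0")
  if (any(R0 < 0)) stop("'R0' must be >= 0")
  R0 / tau_half
}

#' Diffusion coefficient from the half-time wavefront relation
#'
#' Inverts the generalized mean-squared-displacement relation between the
#' observation distance, the half time and the diffusion coefficient. Under
#' the default (quotient) reading this solves
#' `R0^2 = 4 D tau_half / f(D)` for `D`; the alternative product reading
#' `R0^2 = 4 D tau_half f(D)` is available via `reading = "product"`.
#' The quotient form reproduces the expected order of magnitude for
#' physiological half times (f(D) is ~4 on 1--20 um^2/s, so
#' `D ~ R0^2 f / (4 tau)`).
#'
#' The quotient-side function `D / f(D)` is increasing only up to
#' `D = sqrt(c0/c2)` (about 25 um^2/s for the default polynomial); the root
#' is searched on the increasing branch of the bracket.
#'
#' @param R0 Distance, um, > 0.
#' @param tau_half Half time, s, > 0.
#' @param fc An [f_correction()] object.
#' @param reading `"quotient"` (default) or `"product"` form of the relation.
#' @param bracket Search interval for D, um^2/s.
#' @return The diffusion coefficient `Dv`, um^2/s.
#' @export
#' @examples
#' solve_Dv(R0 = 70, tau_half = 700)  # about 8.4 um^2/s
solve_Dv <- function(R0, tau_half, fc = f_correction(),
                     reading = c("quotient", "product"),
                     bracket = c(0.01, 100)) {
  reading <- match.arg(reading)
  stopifnot(is.numeric(R0), length(R0) == 1L,
            is.numeric(tau_half), length(tau_half) == 1L)
  if (tau_half <= 0) stop("'tau_half' must be > 0")
  if (R0 < 0) stop("'R0' must be >= 0")
  if (R0 == 0) return(0)
  fD <- function(D) fc$c2 * D^2 + fc$c1 * D + fc$c0
  g <- if (reading == "quotient") {
    function(D) 4 * D * tau_half / fD(D) - R0^2
  } else {
    function(D) 4 * D * tau_half * fD(D) - R0^2
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (reading == "quotient" && fc$c2 > 0) {
    turn <- sqrt(fc$c0 / fc$c2)  # D/f(D) increases only up to here
    hi <- min(hi, turn)
  }
  if (g(lo) * g(hi) > 0)
    stop("solve_Dv: no sign change in bracket [", lo, ", ", hi,
         "] um^2/s; the measured (R0, tau_half) pair is outside the model range")
  stats::uniroot(g, lower = lo, upper = hi, tol = 1e-12)$root
}
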