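# Gaussian + constant-offset fit of a 1-D profile.
# Returns list(A, mu, sigma, c, snr, ok). x in pixels (or um), y intensity.
.fit_gaussian1d <- function(x, y) {
  c0 <- min(y); A0 <- max(y) - c0
  if (A0 <= 0) return(list(ok = FALSE))
  mu0 <- x[which.max(y)]
  w <- pmax(y - c0, 0)
  s0 <- sqrt(sum(w * (x - mu0)^2) / sum(w))
  if (!is.finite(s0) || s0 <= 0) s0 <- diff(range(x)) / 10
  fit <- tryCatch(suppressWarnings(
    stats::nls(y ~ cc + A * exp(-(x - mu)^2 / (2 * s^2)),
               start = list(cc = c0, A = A0, mu = mu0, s = s0),
               algorithm = "port",
               lower = list(cc = -Inf, A = 0, mu = min(x), s = 1e-6),
               upper = list(cc = Inf, A = Inf, mu = max(x),
                            s = diff(range(x))),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) return(list(ok = FALSE))
  co <- stats::coef(fit)
  resid_sd <- stats::sd(stats::residuals(fit))
  snr <- if (resid_sd > 0) co[["A"]] / resid_sd else Inf
  list(A = co[["A"]], mu = co[["mu"]], sigma = co[["s"]], c = co[["cc"]],
       snr = snr, ok = is.finite(co[["s"]]) && co[["s"]] > 0 && co[["A"]] > 0)
}

# Radial Gaussian + offset fit: center fixed at r = 0 (r is a radius).
.fit_gaussian_radial <- function(r, y) {
  c0 <- min(y); A0 <- max(y) - c0
  if (A0 <= 0) return(list(ok = FALSE))
  w <- pmax(y - c0, 0)
  s0 <- sqrt(sum(w * r^2) / (2 * sum(w)))
  if (!is.finite(s0) || s0 <= 0) s0 <- max(r) / 5
  fit <- tryCatch(suppressWarnings(
    stats::nls(y ~ cc + A * exp(-r^2 / (2 * s^2)),
               start = list(cc = c0, A = A0, s = s0),
               algorithm = "port",
               lower = list(cc = -Inf, A = 0, s = 1e-6),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) return(list(ok = FALSE))
  co <- stats::coef(fit)
  list(A = co[["A"]], sigma = co[["s"]], c = co[["cc"]],
       ok = is.finite(co[["s"]]) && co[["s"]] > 0 && co[["A"]] > 0)
}

.FWHM_FACTOR <- 2 * sqrt(2 * log(2))  # 2.3548: FWHM of a Gaussian per sigma

#' Light-sheet thickness from a mirror calibration image
#'
#' In a light-sheet calibration image (a 45-degree mirror reflecting the
#' sheet onto the camera), every image row is a cross-section of the beam.
#' Each row is fitted to a Gaussian plus constant offset; the full width at
#' half maximum `2 sqrt(2 ln 2) sigma * pixel_size` of each accepted row is
#' collected and summarized as mean +/- sd. Rows whose fit fails or whose
#' fitted amplitude-to-residual ratio falls below `min_snr` are excluded
#' (and counted).
#'
#' @param image 2-D intensity matrix (rows orthogonal to the sheet).
#' @param pixel_size Pixel pitch, um/pixel.
#' @param min_snr Minimum amplitude / residual-sd ratio for a row to count.
#' @return An object of class `sheet_profile_report`: list with
#'   `per_line_fwhm` (um), `mean_fwhm`, `sd_fwhm`, `n_lines`,
#'   `n_rejected`.
#' @export
sheet_thickness <- function(image, pixel_size, min_snr = 3) {
  stopifnot(is.matrix(image), pixel_size > 0)
  x <- seq_len(ncol(image))
  fwhm <- numeric(0); rejected <- 0L
  for (i in seq_len(nrow(image))) {
    f <- .fit_gaussian1d(x, image[i, ])
    if (isTRUE(f$ok) && f$snr >= min_snr) {
      fwhm <- c(fwhm, .FWHM_FACTOR * f$sigma * pixel_size)
    } else rejected <- rejected + 1L
  }
  if (length(fwhm) == 0L)
    stop("no image line passed the Gaussian-fit quality gate")
  structure(list(per_line_fwhm = fwhm,
                 mean_fwhm = mean(fwhm),
                 sd_fwhm = if (length(fwhm) > 1) stats::sd(fwhm) else 0,
                 n_lines = length(fwhm), n_rejected = rejected),
            class = "sheet_profile_report")
}

#' @export
print.sheet_profile_report <- function(x, ...) {
  cat(sprintf("Light-sheet thickness: FWHM = %.3g +/- %.2g um over %d lines (%d rejected)\n",
              x$mean_fwhm, x$sd_fwhm, x$n_lines, x$n_rejected))
  invisible(x)
}

#' Lateral PSF from a bead-field image
#'
#' Detects isolated sub-resolution beads as local intensity maxima, gates
#' out aggregates and overlaps by integrated spot intensity (spots outside
#' `gate_band` of the median integrated intensity are discarded), radially
#' dissects each accepted spot around its centroid, fits the radial
#' profile to a Gaussian plus offset, and reports the FWHM statistics.
#' Bead-size deconvolution is not applied (for beads much smaller than the
#' PSF the broadening bias is below a few percent).
#'
#' @param image 2-D intensity matrix.
#' @param pixel_size Pixel pitch, um/pixel.
#' @param bead_diameter Physical bead diameter, um (recorded in the
#'   report; not deconvolved).
#' @param window Half-size of the fitting window around each spot, px; by
#'   default chosen from the image density.
#' @param gate_band Relative band around the median integrated intensity
#'   inside which a spot counts as a singleton (default keeps
#'   0.6--1.4x median).
#' @param threshold_frac Detection threshold as a fraction of the image
#'   dynamic range above background.
#' @return An object of class `psf_report`: list with `per_bead_fwhm`
#'   (um), `mean_fwhm`, `sd_fwhm`, `n_beads`, `n_rejected`,
#'   `bead_diameter`.
#' @export
psf_from_beads <- function(image, pixel_size, bead_diameter = 1,
                           window = NULL, gate_band = 0.4,
                           threshold_frac = 0.3) {
  stopifnot(is.matrix(image), pixel_size > 0)
  bg <- stats::median(image)
  peak <- max(image)
  if (peak <= bg) stop("image has no spots above background")
  thr <- bg + threshold_frac * (peak - bg)
  H <- nrow(image); W <- ncol(image)
  # local maxima strictly above the 8 neighbours and above threshold
  cand <- which(image > thr, arr.ind = TRUE)
  cand <- cand[cand[, 1] > 1 & cand[, 1] < H &
               cand[, 2] > 1 & cand[, 2] < W, , drop = FALSE]
  is_max <- vapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1]; cc <- cand[i, 2]
    v <- image[r, cc]
    nb <- image[(r - 1):(r + 1), (cc - 1):(cc + 1)]
    v >= max(nb) && sum(nb == v) == 1L
  }, TRUE)
  peaks <- cand[is_max, , drop = FALSE]
  if (nrow(peaks) == 0L) stop("no spots detected")
  if (is.null(window)) {
    # typical spot extent from the brightest one
    window <- 7L
  }
  win <- as.integer(window)
  keep <- peaks[, 1] > win & peaks[, 1] <= H - win &
          peaks[, 2] > win & peaks[, 2] <= W - win
  peaks <- peaks[keep, , drop = FALSE]
  if (nrow(peaks) == 0L) stop("no spots clear of the image border")
  integ <- vapply(seq_len(nrow(peaks)), function(i) {
    r <- peaks[i, 1]; cc <- peaks[i, 2]
    sum(image[(r - win):(r + win), (cc - win):(cc + win)] - bg)
  }, numeric(1))
  med <- stats::median(integ)
  singleton <- abs(integ - med) <= gate_band * med
  n_rejected <- sum(!singleton)
  peaks <- peaks[singleton, , drop = FALSE]
  if (nrow(peaks) == 0L) stop("no singleton spots after intensity gating")
  off <- seq(-win, win)
  fwhm <- numeric(0)
  for (i in seq_len(nrow(peaks))) {
    r <- peaks[i, 1]; cc <- peaks[i, 2]
    sub <- image[r + off, cc + off] - bg
    w <- pmax(sub, 0)
    cy <- sum(w * matrix(off, length(off), length(off))) / sum(w)
    cx <- sum(w * matrix(off, length(off), length(off), byrow = TRUE)) / sum(w)
    rr <- sqrt(outer(off - cy, off - cx, function(a, b) a^2 + b^2))
    f <- .fit_gaussian_radial(as.vector(rr), as.vector(sub))
    if (isTRUE(f$ok))
      fwhm <- c(fwhm, .FWHM_FACTOR * f$sigma * pixel_size)
  }
  if (length(fwhm) == 0L) stop("no spot produced a valid Gaussian fit")
  structure(list(per_bead_fwhm = fwhm, mean_fwhm = mean(fwhm),
                 sd_fwhm = if (length(fwhm) > 1) stats::sd(fwhm) else 0,
                 n_beads = length(fwhm), n_rejected = n_rejected,
                 bead_diameter = bead_diameter),
            class = "psf_report")
}

#' @export
print.psf_report <- function(x, ...) {
  cat(sprintf("Lateral PSF: FWHM = %.3g +/- %.2g um over %d beads (%d gated out)\n",
              x$mean_fwhm, x$sd_fwhm, x$n_beads, x$n_rejected))
  invisible(x)
}

#' Synthetic calibration images
#'
#' Seeded generator for the two calibration-image kinds the QC operations
#' consume: a mirror image of the light sheet (`"sheet"`: every row a
#' Gaussian beam cross-section of known FWHM) and a bead field
#' (`"beads"`: isolated Gaussian spots of known FWHM on a jittered grid).
#'
#' @param kind `"sheet"` or `"beads"`.
#' @param fwhm Ground-truth FWHM, um; defaults to 7.8 (sheet) or 3.2
#'   (beads).
#' @param pixel_size Pixel pitch, um/pixel; defaults to 1.375 (sheet,
#'   binned camera) or 0.55 (beads, unbinned-equivalent sampling).
#' @param noise A [noise_spec()] or `NULL` for a noise-free image.
#' @param n_spots Number of beads (beads kind).
#' @param amplitude,offset Peak amplitude and constant background, a.u.
#' @param dims Image size `c(rows, cols)`; defaults depend on `kind`.
#' @return A list with `image` (matrix), `pixel_size`, `fwhm` (the ground
#'   truth), `kind`, and for beads `n_spots`.
#' @export
#' @examples
#' fx <- make_calibration_fixture("sheet")
#' rep <- sheet_thickness(fx$image, fx$pixel_size)
#' rep$mean_fwhm
make_calibration_fixture <- function(kind = c("sheet", "beads"),
                                     fwhm = NULL, pixel_size = NULL,
                                     noise = NULL, n_spots = 100L,
                                     amplitude = 200, offset = 10,
                                     dims = NULL) {
  kind <- match.arg(kind)
  if (is.null(fwhm)) fwhm <- if (kind == "sheet") 7.8 else 3.2
  stopifnot(fwhm > 0)
  if (is.null(pixel_size)) pixel_size <- if (kind == "sheet") 1.375 else 0.55
  sigma_px <- fwhm / .FWHM_FACTOR / pixel_size
  img <- if (kind == "sheet") {
    if (is.null(dims)) dims <- c(64L, 129L)
    center <- (dims[2] + 1) / 2
    profile <- offset + amplitude *
      exp(-(seq_len(dims[2]) - center)^2 / (2 * sigma_px^2))
    matrix(profile, dims[1], dims[2], byrow = TRUE)
  } else {
    side <- ceiling(sqrt(n_spots))
    spacing <- max(8 * sigma_px, 16)
    if (is.null(dims))
      dims <- rep(ceiling(side * spacing + 4 * spacing), 2L)
    m <- matrix(offset, dims[1], dims[2])
    seed <- if (is.null(noise)) 42L else noise$seed
    centers <- withr::with_seed(seed, {
      g <- expand.grid(i = seq_len(side), j = seq_len(side))[seq_len(n_spots), ]
      cbind(2 * spacing + (g$i - 0.5) * spacing +
              stats::runif(n_spots, -1, 1),
            2 * spacing + (g$j - 0.5) * spacing +
              stats::runif(n_spots, -1, 1))
    })
    half <- ceiling(5 * sigma_px)
    for (s in seq_len(n_spots)) {
      r0 <- round(centers[s, 1]); c0 <- round(centers[s, 2])
      rr <- max(1, r0 - half):min(dims[1], r0 + half)
      cc <- max(1, c0 - half):min(dims[2], c0 + half)
      m[rr, cc] <- m[rr, cc] + amplitude *
        exp(-(outer((rr - centers[s, 1])^2, (cc - centers[s, 2])^2, "+")) /
              (2 * sigma_px^2))
    }
    m
  }
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_spec"))
    img <- withr::with_seed(noise$seed, .add_noise(img, noise))
  }
  out <- list(image = img, pixel_size = pixel_size, fwhm = fwhm, kind = kind)
  if (kind == "beads") out$n_spots <- n_spots
  out
}
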