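#' Camera-noise specification
#'
#' Additive Gaussian read noise plus signal-proportional (shot-like)
#' variance: the sampled value at clean signal `s` is
#' `s + N(0, sqrt(read_sigma^2 + shot_scale * max(s, 0)))`.
#'
#' @param read_sigma Read-noise standard deviation, a.u., >= 0.
#' @param shot_scale Signal-proportional variance factor, a.u., >= 0.
#' @param seed Integer RNG seed; a fixed seed makes output bit-reproducible.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(read_sigma = 2, shot_scale = 0.05, seed = 1L) {
  stopifnot(read_sigma >= 0, shot_scale >= 0,
            is.numeric(seed), length(seed) == 1L)
  structure(list(read_sigma = read_sigma, shot_scale = shot_scale,
                 seed = as.integer(seed)), class = "noise_spec")
}

#' Pressure-ramp specification
#'
#' Near the injection site, the pressure transient pushes dye through the
#' medium at a limiting speed, producing an early linear rise of the
#' fluorescence that saturates after `ramp_duration` and fades with
#' distance. Modelled as an additive contribution
#' `ramp_rate * min(t_inj, ramp_duration)` for pixels/ROIs within
#' `ramp_radius` of the source (`t_inj` on the injection clock).
#'
#' @param ramp_rate Intensity rise rate, a.u./s, >= 0.
#' @param ramp_duration Saturation time, s, >= 0.
#' @param ramp_radius Distance from the source within which the ramp
#'   applies, um, >= 0.
#' @return An object of class `pressure_spec`.
#' @export
pressure_spec <- function(ramp_rate = 1, ramp_duration = 10, ramp_radius = 10) {
  stopifnot(ramp_rate >= 0, ramp_duration >= 0, ramp_radius >= 0)
  structure(list(ramp_rate = ramp_rate, ramp_duration = ramp_duration,
                 ramp_radius = ramp_radius), class = "pressure_spec")
}

.preset_registry <- function() {
  agarose_rois <- seq(30, 200, by = 10)
  embryo_rois  <- seq(10, 40, by = 5)
  list(
    agarose_1pct      = list(D = 18.1, t0 = 0,   roi_distances = agarose_rois),
    agarose_2pct      = list(D = 8.9,  t0 = 0,   roi_distances = agarose_rois),
    agarose_5pct      = list(D = 2.6,  t0 = 0,   roi_distances = agarose_rois),
    control_embryo    = list(D = 12,   t0 = 320, roi_distances = embryo_rois),
    xenograft_embryo  = list(D = 1.0,  t0 = 600, roi_distances = embryo_rois),
    xenograft_variant_a = list(D = 1.9,  t0 = 600, roi_distances = embryo_rois),
    xenograft_variant_b = list(D = 0.82, t0 = 600, roi_distances = embryo_rois)
  )
}

#' Named experimental presets for the synthetic generator
#'
#' Each preset encodes one of the experimental conditions the analysis was
#' designed for:
#' \describe{
#'   \item{`agarose_1pct`, `agarose_2pct`, `agarose_5pct`}{point injection of
#'     rhodamine-labelled dextran into agarose gel; D = 18.1 / 8.9 / 2.6
#'     um^2/s, observation starts at injection (t0 = 0), ROIs 30--200 um
#'     from the injection point at 10 um steps.}
#'   \item{`control_embryo`}{tracer diffusing out of the subintestinal vein
#'     (SIV) plexus of a control zebrafish embryo; D = 12 um^2/s,
#'     t0 = 320 s, ROIs 10--40 um from the SIV at 5 um steps.}
#'   \item{`xenograft_embryo`}{tumour-xenografted embryo; D = 1.0 um^2/s,
#'     t0 = 600 s, same ROI ladder.}
#'   \item{`xenograft_variant_a`, `xenograft_variant_b`}{individual
#'     xenografted embryos at the extremes of the observed variability;
#'     D = 1.9 and 0.82 um^2/s, t0 = 600 s.}
#' }
#' All presets acquire 720 frames every 5 s. For t0 = 0 presets the first
#' recorded frame is taken one frame interval after injection (the model is
#' singular at the injection instant).
#'
#' @param name Preset name (see Details).
#' @param noise A [noise_spec()]; defaults to the standard camera model.
#' @param pressure A [pressure_spec()] or `NULL` (default: ramp disabled).
#' @return An object of class `spim_preset`: a list with fields `name`,
#'   `D`, `t0`, `B`, `roi_distances`, `frame_interval`, `n_frames`,
#'   `noise`, `pressure`. Fields may be modified before simulation.
#' @export
#' @examples
#' p <- make_preset("control_embryo")
#' p$D
make_preset <- function(name, noise = noise_spec(), pressure = NULL) {
  reg <- .preset_registry()
  if (!is.character(name) || length(name) != 1L || !name %in% names(reg))
    stop("unknown preset '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  if (!is.null(pressure)) stopifnot(inherits(pressure, "pressure_spec"))
  stopifnot(inherits(noise, "noise_spec"))
  e <- reg[[name]]
  # amplitude set so the first recorded frame at the source is ~1000 a.u.,
  # giving the high trace SNR of a typical dye-channel acquisition
  B0 <- 1000 * sqrt(pi * e$D * max(e$t0, 5))
  structure(list(name = name, D = e$D, t0 = e$t0, B = B0,
                 roi_distances = e$roi_distances,
                 frame_interval = 5, n_frames = 720L,
                 noise = noise, pressure = pressure),
            class = "spim_preset")
}

#' @export
print.spim_preset <- function(x, ...) {
  cat(sprintf(paste0("SPIM preset '%s': D = %g um^2/s, t0 = %g s, ",
                     "%d ROIs (%g-%g um), %d frames every %g s\n"),
              x$name, x$D, x$t0, length(x$roi_distances),
              min(x$roi_distances), max(x$roi_distances),
              x$n_frames, x$frame_interval))
  invisible(x)
}

.validate_preset <- function(p) {
  stopifnot(inherits(p, "spim_preset"))
  if (p$n_frames < 2L) stop("preset needs n_frames >= 2")
  if (p$frame_interval <= 0) stop("frame_interval must be > 0")
  d <- p$roi_distances
  if (any(d < 0) || any(diff(d) <= 0))
    stop("roi_distances must be >= 0 and strictly increasing")
  invisible(p)
}

# Observation-clock frame times. For t0 = 0 the model is singular at the
# injection instant, so recording starts one frame interval later.
.preset_times <- function(p) {
  k <- seq_len(p$n_frames) - 1
  if (p$t0 == 0) (k + 1) * p$frame_interval else k * p$frame_interval
}

.ramp_contribution <- function(pressure, distance, t_injection) {
  if (is.null(pressure) || distance > pressure$ramp_radius) return(0)
  pressure$ramp_rate * pmin(t_injection, pressure$ramp_duration)
}

.add_noise <- function(clean, noise) {
  sd <- sqrt(noise$read_sigma^2 + noise$shot_scale * pmax(clean, 0))
  clean + stats::rnorm(length(clean), 0, sd)
}

#' Simulate intensity traces for a preset
#'
#' Realizes the delayed point-source model at each of the preset's ROI
#' distances, sampled at the preset's frame cadence, with optional pressure
#' ramp and camera noise. Noise-free traces equal the model exactly.
#'
#' @param preset A [make_preset()] object (fields may have been modified).
#' @param noise_free If `TRUE`, return the exact model values.
#' @return A list of [intensity_trace()] objects, one per ROI distance.
#' @export
#' @examples
#' tr <- simulate_traces(make_preset("control_embryo"), noise_free = TRUE)
#' tr[[1]]
simulate_traces <- function(preset, noise_free = FALSE) {
  .validate_preset(preset)
  params <- diffusion_params(preset$D, preset$t0, preset$B)
  times <- .preset_times(preset)
  make_one <- function(x) {
    clean <- dye_concentration(params, x, times) +
      .ramp_contribution(preset$pressure, x, times + preset$t0)
    intensity_trace(times, clean, x)
  }
  traces <- lapply(preset$roi_distances, make_one)
  if (!noise_free) {
    traces <- withr::with_seed(preset$noise$seed, lapply(traces, function(tr) {
      tr$values <- .add_noise(tr$values, preset$noise)
      tr
    }))
  }
  traces
}

#' Synthetic acquisition geometry
#'
#' Describes the camera frame into which a stack is rendered: image size,
#' physical pixel pitch, the source set (injection point or vessel segment)
#' in pixel coordinates, and an optional binary vessel mask for the static
#' (EGFP-like) channel. Pixel coordinates are 0-based `(x, y)` with the
#' origin at the top-left pixel center.
#'
#' @param width,height Frame size in pixels.
#' @param pixel_size Physical pixel pitch, um/pixel (default 1.375: an
#'   880 um field of view over 640 binned pixels).
#' @param source Either a length-2 numeric `(x, y)` point or a 2x2 matrix
#'   `rbind(c(x1, y1), c(x2, y2))` for a segment source.
#' @param vessel_mask Optional `height x width` binary matrix; default is a
#'   2-pixel-wide neighbourhood of the source.
#' @return An object of class `stack_geometry`.
#' @export
stack_geometry <- function(width, height, pixel_size = 1.375, source,
                           vessel_mask = NULL) {
  stopifnot(width >= 1, height >= 1, pixel_size > 0)
  src <- .as_source(source)
  xs <- src[, 1]; ys <- src[, 2]
  if (any(xs < 0 | xs > width - 1 | ys < 0 | ys > height - 1))
    stop("source lies outside the image bounds")
  if (is.null(vessel_mask)) {
    dpx <- .distance_map(height, width, 1, src)  # in pixels
    vessel_mask <- dpx <= 2
  }
  stopifnot(is.matrix(vessel_mask), nrow(vessel_mask) == height,
            ncol(vessel_mask) == width)
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size = pixel_size, source = src,
                 vessel_mask = vessel_mask),
            class = "stack_geometry")
}

.as_source <- function(source) {
  if (is.numeric(source) && is.null(dim(source)) && length(source) == 2L)
    return(matrix(source, nrow = 1, dimnames = list(NULL, c("x", "y"))))
  if (is.matrix(source) && ncol(source) == 2L && nrow(source) %in% 1:2)
    return(source)
  stop("'source' must be a (x, y) point or a 2-row segment matrix")
}

# Per-pixel Euclidean distance (in um) from the source point or segment.
# Pixel (row i, col j), 1-based in R, has coordinates x = j-1, y = i-1.
.distance_map <- function(height, width, pixel_size, src) {
  px <- matrix(rep(seq_len(width) - 1, each = height), height, width)
  py <- matrix(rep(seq_len(height) - 1, times = width), height, width)
  if (nrow(src) == 1L) {
    d <- sqrt((px - src[1, 1])^2 + (py - src[1, 2])^2)
  } else {
    a <- src[1, ]; b <- src[2, ]
    ab <- b - a
    len2 <- sum(ab^2)
    tt <- if (len2 == 0) matrix(0, height, width) else
      pmin(1, pmax(0, ((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / len2))
    d <- sqrt((px - (a[1] + tt * ab[1]))^2 + (py - (a[2] + tt * ab[2]))^2)
  }
  d * pixel_size
}

#' Render a two-channel synthetic SPIM acquisition
#'
#' Produces a time-lapse dye-channel stack whose pixel values follow the
#' delayed point-source model at each pixel's Euclidean distance from the
#' source, plus a static vessel (EGFP-like) channel. The mean over a narrow
#' annular ROI band reproduces [simulate_traces()] at the band's nominal
#' distance.
#'
#' @param preset A [make_preset()] object.
#' @param geom A [stack_geometry()].
#' @param noise_free If `TRUE`, omit camera noise.
#' @param vessel_intensity Constant intensity of the vessel channel.
#' @return A list with components `dye` (an [image_stack()]) and `vessel`
#'   (a matrix).
#' @export
render_stack <- function(preset, geom, noise_free = FALSE,
                         vessel_intensity = 100) {
  .validate_preset(preset)
  stopifnot(inherits(geom, "stack_geometry"))
  params <- diffusion_params(preset$D, preset$t0, preset$B)
  times <- .preset_times(preset)
  dmap <- .distance_map(geom$height, geom$width, geom$pixel_size, geom$source)
  frames <- array(0, dim = c(geom$height, geom$width, length(times)))
  ramp_mask <- if (is.null(preset$pressure)) NULL else
    dmap <= preset$pressure$ramp_radius
  for (k in seq_along(times)) {
    fr <- dye_concentration(params, dmap, times[k])
    dim(fr) <- dim(dmap)
    if (!is.null(ramp_mask)) {
      t_inj <- times[k] + preset$t0
      fr[ramp_mask] <- fr[ramp_mask] +
        preset$pressure$ramp_rate * min(t_inj, preset$pressure$ramp_duration)
    }
    frames[, , k] <- fr
  }
  if (!noise_free) {
    frames <- withr::with_seed(preset$noise$seed, {
      sd <- sqrt(preset$noise$read_sigma^2 +
                 preset$noise$shot_scale * pmax(frames, 0))
      frames + stats::rnorm(length(frames), 0, sd)
    })
  }
  dye <- image_stack(frames, frame_interval = preset$frame_interval,
                     pixel_size = geom$pixel_size,
                     origin_time = times[1], clip_negative = TRUE)
  list(dye = dye, vessel = geom$vessel_mask * vessel_intensity)
}

#' Write a rendered stack to disk
#'
#' Writes the dye channel as a multi-page 32-bit-float TIFF (one page per
#' time point), the vessel channel as a single-page TIFF, and a sidecar
#' JSON with the intensity scale (pages are normalized to `[0, 1]`), frame
#' interval, pixel size, origin time, and any ground-truth metadata
#' supplied.
#'
#' @param rendered The list returned by [render_stack()], or an
#'   [image_stack()] alone.
#' @param path Output path for the dye-channel TIFF; the vessel channel (if
#'   present) goes to `<path base>_vessel.tif` and the sidecar to
#'   `<path>.json`.
#' @param truth Optional named list of ground-truth values recorded in the
#'   sidecar (e.g. preset parameters, seed).
#' @return Invisibly, the sidecar path.
#' @export
write_stack <- function(rendered, path, truth = NULL) {
  stack <- if (inherits(rendered, "image_stack")) rendered else rendered$dye
  scale <- max(stack$frames, 1e-12)
  pages <- lapply(seq_len(dim(stack$frames)[3]),
                  function(k) stack$frames[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  vessel_path <- NULL
  if (!inherits(rendered, "image_stack") && !is.null(rendered$vessel)) {
    vessel_path <- sub("(\\.tiff?)?$", "_vessel.tif", path)[1]
    vscale <- max(rendered$vessel, 1e-12)
    tiff::writeTIFF(rendered$vessel / vscale, vessel_path,
                    bits.per.sample = 32L)
  }
  sidecar <- paste0(path, ".json")
  meta <- list(intensity_scale = scale,
               frame_interval_s = stack$frame_interval,
               pixel_size_um = stack$pixel_size,
               origin_time_s = stack$origin_time,
               n_frames = dim(stack$frames)[3],
               vessel_path = vessel_path,
               truth = truth)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(sidecar)
}
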