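#' Time-lapse image stack with physical calibration
#'
#' A stack of equally spaced 2-D frames with the physical pixel pitch and
#' the frame interval attached. Frames are stored `height x width x T`
#' (frame index along the third dimension). `origin_time` is the
#' observation-clock time of the first frame (frame k, 0-based, is at
#' `origin_time + k * frame_interval`).
#'
#' @param frames A `H x W x T` numeric array or a single `H x W` matrix.
#' @param frame_interval Frame spacing, s, > 0.
#' @param pixel_size Pixel pitch, um/pixel, > 0.
#' @param origin_time Observation-clock time of the first frame, s.
#' @param clip_negative If `TRUE`, clamp slightly negative (noise) values
#'   to 0 instead of failing the non-negativity invariant.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, frame_interval, pixel_size,
                        origin_time = 0, clip_negative = FALSE) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (any(!is.finite(frames))) stop("all stack intensities must be finite")
  if (clip_negative) frames[frames < 0] <- 0
  if (any(frames < 0)) stop("stack intensities must be >= 0")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(frames = frames, frame_interval = frame_interval,
                 pixel_size = pixel_size, origin_time = origin_time),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(paste0("Image stack: %d frames of %d x %d px ",
                     "(%g um/px), dt = %g s, t = [%g, %g] s\n"),
              d[3], d[1], d[2], x$pixel_size, x$frame_interval,
              x$origin_time, x$origin_time + (d[3] - 1) * x$frame_interval))
  invisible(x)
}

#' Read a multi-page TIFF time-lapse stack
#'
#' Pages are taken in file order as successive time points. If a sidecar
#' JSON written by [write_stack()] sits next to the file, its intensity
#' scale and calibration fill in any metadata not supplied explicitly.
#'
#' @param path Path to a (multi-page) TIFF.
#' @param frame_interval Frame spacing, s; overrides the sidecar.
#' @param pixel_size Pixel pitch, um/pixel; overrides the sidecar.
#' @param origin_time Time of the first frame, s; overrides the sidecar.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, frame_interval = NULL, pixel_size = NULL,
                       origin_time = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) paste(dim(p)[1:2], collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop("ragged TIFF: pages have differing shapes (",
         paste(unique(shapes), collapse = ", "), ")")
  scale <- 1
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    scale <- meta$intensity_scale %||% 1
    frame_interval <- frame_interval %||% meta$frame_interval_s
    pixel_size <- pixel_size %||% meta$pixel_size_um
    origin_time <- origin_time %||% meta$origin_time_s
  }
  if (is.null(frame_interval))
    stop("frame_interval not given and no sidecar found")
  if (is.null(pixel_size)) stop("pixel_size not given and no sidecar found")
  frames <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]  # first channel only
    frames[, , k] <- pg * scale
  }
  image_stack(frames, frame_interval, pixel_size,
              origin_time %||% 0, clip_negative = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Re-bin a stack by pixel summation
#'
#' Sums each `factor x factor` pixel block (hardware-binning semantics, so
#' total intensity over the retained region is preserved); trailing rows or
#' columns not divisible by `factor` are dropped; the pixel pitch grows by
#' `factor`.
#'
#' @param stack An [image_stack()].
#' @param factor Integer binning factor, >= 1.
#' @return The re-binned [image_stack()].
#' @export
rebin <- function(stack, factor) {
  stopifnot(inherits(stack, "image_stack"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("'factor' must be an integer >= 1")
  if (factor == 1L) return(stack)
  d <- dim(stack$frames)
  H <- (d[1] %/% factor) * factor
  W <- (d[2] %/% factor) * factor
  if (H == 0 || W == 0) stop("binning factor larger than the image")
  out <- array(0, dim = c(H %/% factor, W %/% factor, d[3]))
  for (k in seq_len(d[3])) {
    fr <- stack$frames[seq_len(H), seq_len(W), k]
    # sum over factor x factor blocks via two reshapes
    m <- rowsum(fr, rep(seq_len(H %/% factor), each = factor))
    m <- t(rowsum(t(m), rep(seq_len(W %/% factor), each = factor)))
    out[, , k] <- m
  }
  image_stack(out, stack$frame_interval, stack$pixel_size * factor,
              stack$origin_time)
}

#' Region-of-interest specification
#'
#' An ROI is a fixed pixel set with a nominal physical distance from the
#' dye source. `roi_spec()` wraps an explicit logical mask; `roi_rect()`
#' builds a rectangular ROI from 0-based inclusive pixel bounds.
#'
#' @param mask Logical `H x W` matrix selecting the ROI pixels.
#' @param nominal_distance Distance from the source, um, >= 0.
#' @param label ROI label.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(mask, nominal_distance,
                     label = sprintf("d%g", nominal_distance)) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("ROI '", label, "' selects no pixels")
  if (nominal_distance < 0) stop("nominal_distance must be >= 0")
  structure(list(mask = mask, nominal_distance = nominal_distance,
                 label = as.character(label)), class = "roi_spec")
}

#' @rdname roi_spec
#' @param x0,x1,y0,y1 Inclusive pixel bounds, 0-based (`x` = column,
#'   `y` = row).
#' @param width,height Frame size in pixels.
#' @export
roi_rect <- function(x0, x1, y0, y1, width, height, nominal_distance,
                     label = sprintf("d%g", nominal_distance)) {
  stopifnot(0 <= x0, x0 <= x1, x1 <= width - 1,
            0 <= y0, y0 <= y1, y1 <= height - 1)
  mask <- matrix(FALSE, height, width)
  mask[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)] <- TRUE
  roi_spec(mask, nominal_distance, label)
}

#' Build a ladder of annular distance-band ROIs
#'
#' Creates ROIs at nominal distances `start, start + step, ..., <= stop`
#' from the source; each ROI is the set of pixels whose Euclidean distance
#' from the source lies in `[d - band_width/2, d + band_width/2)`. Bands
#' are pairwise disjoint whenever `band_width <= step`.
#'
#' @param stack An [image_stack()] (provides frame size and pixel pitch).
#' @param source Source point `(x, y)` or 2-row segment matrix, 0-based
#'   pixel coordinates.
#' @param start,stop,step Ladder of nominal distances, um; `0 <= start <
#'   stop`, `step > 0`.
#' @param band_width Radial width of each band, um (default `step`).
#' @return A list of [roi_spec()] objects.
#' @export
build_roi_ladder <- function(stack, source, start, stop, step,
                             band_width = step) {
  stopifnot(inherits(stack, "image_stack"))
  if (!(start >= 0 && start < stop)) stop("need 0 <= start < stop")
  if (step <= 0) stop("'step' must be > 0")
  if (band_width <= 0) stop("'band_width' must be > 0")
  d <- dim(stack$frames)
  src <- .as_source(source)
  if (any(src[, 1] < 0 | src[, 1] > d[2] - 1 |
          src[, 2] < 0 | src[, 2] > d[1] - 1))
    stop("source lies outside the image bounds")
  dmap <- .distance_map(d[1], d[2], stack$pixel_size, src)
  lapply(seq(start, stop, by = step), function(dist) {
    mask <- dmap >= dist - band_width / 2 & dmap < dist + band_width / 2
    if (!any(mask))
      stop("ROI band at ", dist, " um contains no pixels")
    roi_spec(mask, dist)
  })
}

#' Extract mean-intensity traces from a stack
#'
#' For each ROI, the trace value at frame k is the mean intensity over the
#' ROI's pixels, minus (when a background ROI is given) the mean over the
#' background ROI at the same frame. Times are
#' `origin_time + k * frame_interval`.
#'
#' @param stack An [image_stack()].
#' @param rois A list of [roi_spec()] objects (or a single one).
#' @param background Optional background [roi_spec()].
#' @return A list of [intensity_trace()] objects.
#' @export
extract_traces <- function(stack, rois, background = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (inherits(rois, "roi_spec")) rois <- list(rois)
  stopifnot(length(rois) >= 1L,
            all(vapply(rois, inherits, TRUE, "roi_spec")))
  d <- dim(stack$frames)
  for (r in rois)
    if (!identical(dim(r$mask), d[1:2]))
      stop("ROI '", r$label, "' does not match the frame size")
  bg <- NULL
  if (!is.null(background)) {
    stopifnot(inherits(background, "roi_spec"))
    if (!identical(dim(background$mask), d[1:2]))
      stop("background ROI does not match the frame size")
    overlap <- vapply(rois, function(r) any(r$mask & background$mask), TRUE)
    if (any(overlap))
      warning("background ROI overlaps signal ROI(s): ",
              paste(vapply(rois[overlap], `[[`, "", "label"), collapse = ", "))
    bg <- vapply(seq_len(d[3]), function(k)
      mean(stack$frames[, , k][background$mask]), numeric(1))
  }
  times <- stack$origin_time + (seq_len(d[3]) - 1) * stack$frame_interval
  lapply(rois, function(r) {
    v <- vapply(seq_len(d[3]), function(k)
      mean(stack$frames[, , k][r$mask]), numeric(1))
    if (!is.null(bg)) v <- v - bg
    intensity_trace(times, v, r$nominal_distance, r$label)
  })
}
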