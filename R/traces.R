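#' Intensity trace at a fixed distance from the source
#'
#' A fluorescence-vs-time record for one region of interest (ROI), annotated
#' with the ROI's nominal distance from the dye source. This is the common
#' currency between the synthetic generator, the stack extractor, the global
#' fit and the half-time analysis.
#'
#' @param times Observation times, s, strictly increasing.
#' @param values Mean ROI intensities, a.u., finite.
#' @param distance Nominal distance of the ROI from the source, um, >= 0.
#' @param label ROI label (default derived from the distance).
#' @return An object of class `intensity_trace`.
#' @export
intensity_trace <- function(times, values, distance,
                            label = sprintf("d%g", distance)) {
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values), length(times) >= 1L)
  if (any(!is.finite(values))) stop("trace values must be finite")
  if (any(diff(times) <= 0)) stop("trace times must be strictly increasing")
  if (!is.numeric(distance) || length(distance) != 1L || distance < 0)
    stop("'distance' must be a single number >= 0")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 distance = as.numeric(distance), label = as.character(label)),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("Intensity trace '%s': %d frames, t = [%g, %g] s, R0 = %g um\n",
              x$label, length(x$times), x$times[1],
              x$times[length(x$times)], x$distance))
  invisible(x)
}

#' @export
as.data.frame.intensity_trace <- function(x, ...) {
  data.frame(time_s = x$times, value = x$values,
             distance_um = x$distance, roi_label = x$label,
             stringsAsFactors = FALSE)
}

#' Convert a list of traces to / from long-format tables
#'
#' `traces_to_df()` stacks traces into one long data frame with columns
#' `time_s`, `value`, `distance_um`, `roi_label`; `df_to_traces()` inverts
#' it. `write_traces_csv()` and `read_traces_csv()` are thin CSV wrappers
#' around the same layout.
#'
#' @param traces A list of [intensity_trace()] objects.
#' @return `traces_to_df()`: a data frame; `df_to_traces()`: a list of
#'   traces.
#' @export
traces_to_df <- function(traces) {
  stopifnot(is.list(traces), length(traces) >= 1L)
  do.call(rbind, lapply(traces, as.data.frame))
}

#' @rdname traces_to_df
#' @param df A data frame with columns `time_s`, `value`, `distance_um`,
#'   `roi_label`.
#' @export
df_to_traces <- function(df) {
  stopifnot(all(c("time_s", "value", "distance_um", "roi_label") %in% names(df)))
  lapply(split(df, df$roi_label, drop = TRUE), function(d) {
    d <- d[order(d$time_s), ]
    intensity_trace(d$time_s, d$value, d$distance_um[1], d$roi_label[1])
  })
}

#' @rdname traces_to_df
#' @param path File path.
#' @export
write_traces_csv <- function(traces, path) {
  utils::write.csv(traces_to_df(traces), path, row.names = FALSE)
  invisible(path)
}

#' @rdname traces_to_df
#' @export
read_traces_csv <- function(path) {
  df_to_traces(utils::read.csv(path, stringsAsFactors = FALSE))
}
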