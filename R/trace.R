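#' Per-frame ocular trace
#'
#' An `ocular_trace` is the per-frame, per-eye time series extracted from a
#' one-eye video (or simulated directly): palpebral fissure length (eyelid
#' aperture, pixels), pupil diameter (pixels), pupil centroid (pixels) and a
#' validity flag that is `FALSE` wherever the pupil is not visible (e.g.
#' during eye closure). Frames are 0-based and contiguous.
#'
#' @param frame integer vector of 0-based contiguous frame indices.
#' @param fissure_length numeric, eyelid aperture per frame, pixels, >= 0.
#' @param pupil_diameter numeric, pixels; `NA` where the pupil is invisible.
#' @param pupil_x,pupil_y numeric centroid coordinates, pixels; `NA` where
#'   invalid.
#' @param valid logical; must be `FALSE` wherever `pupil_diameter` is `NA`.
#' @param eye `"left"` or `"right"`.
#' @param frame_rate frames per second, > 0.
#' @return a data frame of class `ocular_trace` with attributes `eye` and
#'   `frame_rate`.
#' @export
ocular_trace <- function(frame, fissure_length, pupil_diameter,
                         pupil_x, pupil_y, valid,
                         eye = c("left", "right"), frame_rate = 30) {
  eye <- match.arg(eye)
  n <- length(frame)
  stopifnot(frame_rate > 0, n >= 1)
  if (!identical(as.integer(frame), seq_len(n) - 1L + as.integer(frame[1])))
    stop("frames must be contiguous")
  lens <- vapply(list(fissure_length, pupil_diameter, pupil_x, pupil_y, valid),
                 length, integer(1))
  if (any(lens != n)) stop("all per-frame arrays must have equal length")
  if (any(fissure_length < 0, na.rm = TRUE)) stop("fissure_length must be >= 0")
  valid <- as.logical(valid) & !is.na(pupil_diameter)
  out <- data.frame(frame = as.integer(frame),
                    fissure_length = as.numeric(fissure_length),
                    pupil_diameter = as.numeric(pupil_diameter),
                    pupil_x = as.numeric(pupil_x),
                    pupil_y = as.numeric(pupil_y),
                    valid = valid)
  structure(out, eye = eye, frame_rate = as.numeric(frame_rate),
            class = c("ocular_trace", "data.frame"))
}

#' @export
print.ocular_trace <- function(x, ...) {
  cat(sprintf("<ocular_trace> eye=%s  %d frames @ %g fps  (%.1f s), %d invalid\n",
              attr(x, "eye"), nrow(x), attr(x, "frame_rate"),
              nrow(x) / attr(x, "frame_rate"), sum(!x$valid)))
  invisible(x)
}

frame_rate_of <- function(trace) attr(trace, "frame_rate")

# Restrict a trace to original frame numbers in [start, end) (half-open).
trim_trace <- function(trace, start, end) {
  keep <- trace$frame >= start & trace$frame < end
  out <- trace[keep, , drop = FALSE]
  attributes(out)$eye <- attr(trace, "eye")
  attributes(out)$frame_rate <- attr(trace, "frame_rate")
  class(out) <- class(trace)
  out
}

#' Read and write trace CSV files
#'
#' The on-disk schema has one row per frame and eye with columns
#' `frame, eye, fissure_length_px, pupil_diameter_px, pupil_x_px, pupil_y_px,
#' valid`. Missing pupil values are empty cells.
#'
#' @param traces a single `ocular_trace` or a list of them (e.g. both eyes).
#' @param path file path.
#' @param frame_rate frames per second recorded in the file? The frame rate
#'   is not stored in the CSV; pass it to `read_trace_csv()`.
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   returns a named list of `ocular_trace` objects, one per eye present.
#' @export
write_trace_csv <- function(traces, path) {
  if (inherits(traces, "ocular_trace")) traces <- list(traces)
  rows <- lapply(traces, function(tr) {
    data.frame(frame = tr$frame, eye = attr(tr, "eye"),
               fissure_length_px = tr$fissure_length,
               pupil_diameter_px = tr$pupil_diameter,
               pupil_x_px = tr$pupil_x, pupil_y_px = tr$pupil_y,
               valid = tr$valid)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path, frame_rate = 30) {
  df <- utils::read.csv(path)
  need <- c("frame", "eye", "fissure_length_px", "pupil_diameter_px",
            "pupil_x_px", "pupil_y_px", "valid")
  if (!all(need %in% names(df))) stop("trace CSV missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  out <- lapply(split(df, df$eye), function(d) {
    d <- d[order(d$frame), ]
    ocular_trace(d$frame, d$fissure_length_px, d$pupil_diameter_px,
                 d$pupil_x_px, d$pupil_y_px, as.logical(d$valid),
                 eye = d$eye[1], frame_rate = frame_rate)
  })
  out[order(names(out))]
}
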