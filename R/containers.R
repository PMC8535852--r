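# Core data containers (S3).

#' Paw trajectory
#'
#' Raw pixel coordinates of one forepaw per video frame, as exported from a
#' markerless pose tracker.
#'
#' @param x_raw,y_raw Numeric vectors of pixel coordinates (equal length).
#' @param frame_rate Video frame rate in Hz (default 71.5).
#' @param paw `"left"` or `"right"`.
#' @return Object of class `paw_trajectory`.
#' @export
paw_trajectory <- function(x_raw, y_raw, frame_rate = video_frame_rate(),
                           paw = c("left", "right")) {
  paw <- match.arg(paw)
  if (length(x_raw) != length(y_raw))
    stop("x_raw and y_raw must have equal length")
  if (!is.finite(frame_rate) || frame_rate <= 0)
    stop("frame_rate must be positive")
  structure(list(x_raw = as.numeric(x_raw), y_raw = as.numeric(y_raw),
                 frame_rate = frame_rate, paw = paw),
            class = "paw_trajectory")
}

#' @export
print.paw_trajectory <- function(x, ...) {
  cat("paw_trajectory (", x$paw, "): ", length(x$x_raw), " frames @ ",
      x$frame_rate, " Hz\n", sep = "")
  invisible(x)
}

#' Calcium trace matrix
#'
#' Neurons-by-frames matrix of fractional fluorescence change (dF/F), with
#' per-neuron layer labels and centroid pixel coordinates.
#'
#' @param dff Numeric matrix, neurons x frames.
#' @param frame_rate Imaging frame rate in Hz.  Values outside [5, 10] Hz
#'   trigger a warning (this rig acquires ~6-7 frames/s per layer).
#' @param layer Optional character vector per neuron (e.g. "L2/3", "L5a").
#' @param centroid Optional numeric matrix (neurons x 2) of (x, y) pixels.
#' @param pixel_size Microns per pixel (default 1).
#' @return Object of class `trace_matrix`.
#' @export
trace_matrix <- function(dff, frame_rate = imaging_frame_rate(),
                         layer = NULL, centroid = NULL, pixel_size = 1) {
  dff <- as.matrix(dff)
  if (any(!is.finite(dff))) stop("dff must be finite (no missing frames)")
  if (frame_rate < 5 || frame_rate > 10)
    warning("frame_rate ", signif(frame_rate, 4),
            " Hz is outside the 5-10 Hz range typical of this acquisition")
  if (!is.null(layer) && length(layer) != nrow(dff))
    stop("layer must have one label per neuron")
  if (!is.null(centroid)) {
    centroid <- as.matrix(centroid)
    if (nrow(centroid) != nrow(dff) || ncol(centroid) != 2L)
      stop("centroid must be a neurons x 2 matrix of (x, y) pixels")
  }
  structure(list(dff = dff, frame_rate = frame_rate, layer = layer,
                 centroid = centroid, pixel_size = pixel_size),
            class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat("trace_matrix: ", nrow(x$dff), " neurons x ", ncol(x$dff),
      " frames @ ", signif(x$frame_rate, 4), " Hz\n", sep = "")
  if (!is.null(x$layer)) {
    tab <- table(x$layer)
    cat("  layers:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Event raster
#'
#' Binary neurons-by-frames matrix marking event onsets, plus a record of
#' the detection parameters that produced it.
#'
#' @param events Logical or 0/1 matrix, neurons x frames.
#' @param frame_rate Imaging frame rate in Hz.
#' @param params Named list recording how events were produced.
#' @return Object of class `event_raster`.
#' @export
event_raster <- function(events, frame_rate = imaging_frame_rate(),
                         params = list()) {
  events <- as.matrix(events) != 0
  structure(list(events = events, frame_rate = frame_rate, params = params),
            class = "event_raster")
}

#' @export
print.event_raster <- function(x, ...) {
  cat("event_raster: ", nrow(x$events), " neurons x ", ncol(x$events),
      " frames, ", sum(x$events), " events\n", sep = "")
  invisible(x)
}

# internal: pull a plain numeric series out of the flexible trace inputs
as_series <- function(x) {
  if (inherits(x, "centered_trace")) return(x$d)
  if (is.numeric(x)) return(as.numeric(x))
  stop("expected a numeric vector or centered_trace")
}
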