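# Forelimb kinematics: paw centering, smoothing, stride detection,
# interlimb coordination.

#' Center a paw coordinate series
#'
#' Converts raw pixel coordinates to millimetres relative to the median paw
#' position: d_new = alpha * (median(d_raw) - d_raw).  With the camera
#' geometry used here, raw pixel values decrease as the paw moves forward,
#' so forward positions come out positive.
#'
#' @param d_raw Numeric vector of raw pixel coordinates, or a
#'   `paw_trajectory` (both axes are centered).
#' @param alpha Millimetres per pixel (> 0).
#' @param frame_rate Sampling rate in Hz (taken from the trajectory if one
#'   is supplied).
#' @return A `centered_trace` (list: `d` in mm, `alpha`, `d_median` in px,
#'   `frame_rate`), or for a `paw_trajectory` a list with elements `x` and
#'   `y`, each a `centered_trace`.
#' @examples
#' ct <- center_paw(c(1, 2, 3), alpha = 1)
#' ct$d                                    # 1 0 -1 (median 2)
#' @export
center_paw <- function(d_raw, alpha, frame_rate = video_frame_rate()) {
  if (!is.finite(alpha) || alpha <= 0) stop("`alpha` must be positive (mm/px)")
  if (inherits(d_raw, "paw_trajectory")) {
    return(list(x = center_paw(d_raw$x_raw, alpha, d_raw$frame_rate),
                y = center_paw(d_raw$y_raw, alpha, d_raw$frame_rate)))
  }
  d_raw <- as.numeric(d_raw)
  if (length(d_raw) == 0L) stop("empty coordinate series")
  med <- stats::median(d_raw)
  structure(list(d = alpha * (med - d_raw), alpha = alpha, d_median = med,
                 frame_rate = frame_rate),
            class = "centered_trace")
}

#' Zero-phase Butterworth smoothing
#'
#' Low-pass Butterworth filter (order 2 by default) applied forward and
#' backward (`signal::filtfilt`), so the output has no phase lag.  Phase
#' neutrality matters here because a filter-induced lag between the two paw
#' traces would bias the coordination index.
#'
#' @param series Numeric vector or `centered_trace`.
#' @param order Filter order (default 2).
#' @param cutoff Cutoff as a fraction of the Nyquist frequency, in (0, 1).
#' @return Smoothed series, same class as the input.
#' @export
smooth_trace <- function(series, order = 2, cutoff = 0.1) {
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= 1)
    stop("`cutoff` must lie strictly between 0 and 1 (fraction of Nyquist)")
  v <- as_series(series)
  n <- length(v)
  if (n <= 3 * (order + 1))
    stop("series too short for order-", order, " zero-phase filtering")
  bf <- signal::butter(order, cutoff, type = "low")
  # odd-reflection padding and demeaning suppress start/end transients, so
  # a constant series passes through unchanged (DC gain 1)
  pad <- min(n - 1L, as.integer(ceiling(3 / cutoff)))
  mu <- mean(v)
  vp <- c(2 * v[1] - v[seq(pad + 1L, 2L)],
          v,
          2 * v[n] - v[seq(n - 1L, n - pad)]) - mu
  out <- signal::filtfilt(bf, vp)[pad + seq_len(n)] + mu
  if (inherits(series, "centered_trace")) {
    series$d <- out
    series
  } else out
}

# Local maxima of v with prominence and separation constraints.
# Prominence of a peak: height above the higher of the two deepest valleys
# separating it from taller terrain (or the series edge).
find_peaks <- function(v, min_prominence = 0, min_separation = 1) {
  n <- length(v)
  if (n < 3L) return(integer())
  d <- diff(v)
  cand <- which(d[-(n - 1L)] > 0 & d[-1L] <= 0) + 1L   # rise then fall/plateau
  if (length(cand) == 0L) return(integer())
  prom <- vapply(cand, function(p) {
    higher_l <- which(v[seq_len(p - 1L)] > v[p])
    lo <- if (length(higher_l)) max(higher_l) + 1L else 1L
    left_min <- min(v[lo:p])
    higher_r <- which(v[(p + 1L):n] > v[p])
    hi <- if (length(higher_r)) p + min(higher_r) - 1L else n
    right_min <- min(v[p:hi])
    v[p] - max(left_min, right_min)
  }, numeric(1))
  keep <- cand[prom >= min_prominence & prom > 0]
  if (length(keep) <= 1L || min_separation <= 1L) return(sort(keep))
  # enforce separation, tallest first
  ord <- keep[order(v[keep], decreasing = TRUE)]
  sel <- integer()
  for (p in ord) {
    if (all(abs(sel - p) >= min_separation)) sel <- c(sel, p)
  }
  sort(sel)
}

#' Detect strides from centered paw traces
#'
#' A stride is the rising phase of a spike in the horizontal trace (x, from
#' a local trough to the next local peak) that co-occurs with a complete
#' spike (a prominent local maximum) in the vertical trace (y).  Stride
#' length is x(peak) - x(trough) in millimetres.
#'
#' Detection thresholds default to scale-free values: minimum spike
#' prominence is half the interquartile range of each trace, and minimum
#' peak separation is 0.1 s of frames.  Both are robust to baseline drift
#' and to uniform rescaling of the traces.
#'
#' @param x,y `centered_trace` objects (or numeric vectors) for the
#'   horizontal and vertical paw coordinates, same length and frame rate.
#' @param min_prominence Minimum spike prominence in mm; `NULL` for the
#'   IQR-based default.
#' @param min_separation_s Minimum separation between spikes in seconds.
#' @param frame_rate Required if `x` is a plain numeric vector.
#' @return A `stride_set`: data.frame with columns `start_frame` (x trough),
#'   `peak_frame` (x peak, used for block assignment), `end_frame`,
#'   `length_mm`; class `stride_set`.
#' @export
detect_strides <- function(x, y, min_prominence = NULL,
                           min_separation_s = 0.1, frame_rate = NULL) {
  if (is.null(frame_rate)) {
    frame_rate <- if (inherits(x, "centered_trace")) x$frame_rate else
      stop("supply `frame_rate` when x is a plain numeric vector")
  }
  xv <- as_series(x); yv <- as_series(y)
  if (length(xv) != length(yv)) stop("x and y traces must have equal length")
  sep <- max(1L, as.integer(round(min_separation_s * frame_rate)))
  # scale-free default: half the IQR; for zero-inflated traces whose IQR
  # collapses to 0, fall back to a quarter of the range
  auto_prom <- function(v) {
    p <- 0.5 * stats::IQR(v)
    if (p <= 0) p <- 0.25 * diff(range(v))
    p
  }
  prom_x <- if (is.null(min_prominence)) auto_prom(xv) else min_prominence
  prom_y <- if (is.null(min_prominence)) auto_prom(yv) else min_prominence
  empty <- data.frame(start_frame = integer(), peak_frame = integer(),
                      end_frame = integer(), length_mm = numeric())
  if (prom_x <= 0 || prom_y <= 0)          # flat traces
    return(structure(empty, class = c("stride_set", "data.frame")))
  ypk <- find_peaks(yv, prom_y, sep)
  xpk <- find_peaks(xv, prom_x, sep)
  xtr <- find_peaks(-xv, prom_x, sep)
  if (!length(ypk) || !length(xpk) || !length(xtr))
    return(structure(empty, class = c("stride_set", "data.frame")))
  out <- vector("list", length(xpk))
  last_used <- 0L
  for (i in seq_along(xpk)) {
    p <- xpk[i]
    tr <- xtr[xtr < p & xtr > last_used]
    if (!length(tr)) next
    tr <- max(tr)
    if (!any(ypk >= tr & ypk <= p)) next   # rising x must carry a y spike
    out[[i]] <- data.frame(start_frame = tr, peak_frame = p, end_frame = p,
                           length_mm = xv[p] - xv[tr])
    last_used <- p
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) res <- empty
  structure(res, class = c("stride_set", "data.frame"), frame_rate = frame_rate)
}

#' Per-block stride counts and mean lengths
#'
#' Strides are assigned to speed blocks by the frame of their x-peak.
#' Blocks with no strides report `NA` mean length.
#'
#' @param strides A `stride_set`.
#' @param profile A `speed_profile`.
#' @param frame_rate Video frame rate in Hz (defaults to the rate recorded
#'   in the stride set).
#' @return data.frame with columns `block`, `speed`, `n_strides`,
#'   `mean_length_mm`.
#' @export
block_stride_stats <- function(strides, profile,
                               frame_rate = attr(strides, "frame_rate")) {
  if (is.null(frame_rate)) stop("frame_rate unavailable; pass it explicitly")
  bl <- profile$blocks
  t_peak <- (strides$peak_frame - 1) / frame_rate
  if (nrow(strides) && (any(t_peak < 0) || any(t_peak >= profile$total_s)))
    stop("stride frames extend beyond the profile duration")
  idx <- findInterval(t_peak, bl$start_s)
  data.frame(
    block = bl$block, speed = bl$speed,
    n_strides = vapply(bl$block, function(b) sum(idx == b), integer(1)),
    mean_length_mm = vapply(bl$block, function(b) {
      v <- strides$length_mm[idx == b]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1)))
}

#' Percent change between two values
#'
#' Convention: (later - earlier) / earlier * 100.
#' @param earlier,later Numeric values (e.g. stride counts at two speeds).
#' @export
percent_change <- function(earlier, later) (later - earlier) / earlier * 100

#' Interlimb coordination index
#'
#' The negative of the Pearson correlation coefficient between the two
#' forepaw horizontal location traces, conventionally computed over the
#' 2-min 60 mm/s block.  +1 is perfect alternation (anti-phase), -1 is
#' perfect in-phase movement.
#'
#' @param left,right `centered_trace` objects or numeric vectors (horizontal
#'   paw location).
#' @param block Optional integer vector of frame indices restricting the
#'   computation (e.g. from [speed_block_frames()]).
#' @return Coordination index in [-1, 1].
#' @export
coordination_index <- function(left, right, block = NULL) {
  lv <- as_series(left); rv <- as_series(right)
  if (length(lv) != length(rv)) stop("paw traces must have equal length")
  if (!is.null(block)) { lv <- lv[block]; rv <- rv[block] }
  if (stats::sd(lv) == 0 || stats::sd(rv) == 0)
    stop("coordination index undefined: a paw trace has zero variance in the block")
  -stats::cor(lv, rv)
}
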