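# Fluorescence transient (event) detection and event-rate summaries.

#' Detect fluorescence transients (events)
#'
#' A transparent threshold detector: per neuron, the baseline is a running
#' median; an event onset is marked wherever the baseline-subtracted trace
#' crosses `k_mad` times its median absolute deviation upward and stays
#' above it for at least `min_duration_frames`.  Within one above-threshold
#' excursion, additional onsets are marked at frames whose one-frame
#' increment exceeds `k_mad` times the MAD of the differenced trace, so
#' transients stacked on the decaying tail of a predecessor are counted
#' separately.  Onsets, not active frames, are what the rate analyses
#' count.
#'
#' Event rasters produced elsewhere (e.g. by deconvolution) can be supplied
#' to the downstream analyses directly via [event_raster()].
#'
#' @param traces A `trace_matrix`.
#' @param k_mad Threshold multiplier (default 2.5).
#' @param min_duration_frames Minimum above-threshold duration (default 2).
#' @param baseline_window_s Running-median window, s (default 30).
#' @return An `event_raster`.  The detector is invariant to adding a
#'   constant to any trace.
#' @export
detect_events <- function(traces, k_mad = 2.5, min_duration_frames = 2,
                          baseline_window_s = 30) {
  stopifnot(inherits(traces, "trace_matrix"))
  x <- traces$dff
  n_frames <- ncol(x)
  k_base <- min(n_frames, as.integer(round(baseline_window_s * traces$frame_rate)))
  if (k_base %% 2L == 0L) k_base <- k_base - 1L
  k_base <- max(k_base, 1L)
  ev <- matrix(FALSE, nrow(x), n_frames)
  for (i in seq_len(nrow(x))) {
    resid <- x[i, ] - stats::runmed(x[i, ], k_base)
    thr <- k_mad * stats::mad(resid)
    above <- resid > thr
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- r$values & r$lengths >= min_duration_frames
    onsets <- starts[ok]
    # re-trigger on sharp upward jumps inside an excursion
    jump_thr <- k_mad * stats::mad(diff(resid))
    if (jump_thr > 0 && length(onsets)) {
      in_run <- rep(ok, r$lengths)
      jumps <- which(c(FALSE, diff(resid) > jump_thr) & in_run)
      onsets <- sort(union(onsets, setdiff(jumps, onsets)))
      onsets <- onsets[c(TRUE, diff(onsets) > 1L)]   # merge adjacent marks
    }
    ev[i, onsets] <- TRUE
  }
  event_raster(ev, traces$frame_rate,
               params = list(method = "mad-threshold", k_mad = k_mad,
                             min_duration_frames = min_duration_frames,
                             baseline_window_s = baseline_window_s,
                             counts = "onsets"))
}

#' Per-neuron, per-block event rates
#'
#' Rate = event count in block / block duration.  Rest pools the speed-0
#' blocks, running pools all nonzero-speed blocks (counts over pooled time).
#'
#' @param raster An `event_raster`.
#' @param profile A `speed_profile`.
#' @return List: `rates` (neurons x blocks matrix, events/s, columns named
#'   by speed), `blocks` (the profile block table), `rest`, `running`
#'   (per-neuron pooled rates).
#' @export
block_event_rate <- function(raster, profile) {
  stopifnot(inherits(raster, "event_raster"))
  fb <- profile_frame_blocks(profile, raster$frame_rate, ncol(raster$events))
  if (any(lengths(fb) == 0L)) stop("a profile block contains no frames")
  if (max(unlist(fb)) > ncol(raster$events))
    stop("raster shorter than the profile")
  counts <- vapply(fb, function(idx) rowSums(raster$events[, idx, drop = FALSE]),
                   numeric(nrow(raster$events)))
  counts <- matrix(counts, nrow = nrow(raster$events))
  rates <- counts / profile$block_duration_s
  colnames(rates) <- paste0("speed_", profile$blocks$speed)
  rest_b <- which(profile$blocks$speed == 0)
  run_b <- which(profile$blocks$speed > 0)
  pooled <- function(bs) if (length(bs) == 0L) rep(NA_real_, nrow(rates)) else
    rowSums(counts[, bs, drop = FALSE]) / (length(bs) * profile$block_duration_s)
  list(rates = rates, blocks = profile$blocks,
       rest = pooled(rest_b), running = pooled(run_b))
}

#' Width of the event-rate distribution
#'
#' Full width at half maximum of the (lightly smoothed) histogram of
#' per-neuron event rates.  The histogram counts are smoothed with a
#' 3-bin moving average, the modal bin located, and the half-height
#' crossings on either side found by linear interpolation between bin
#' centres.  If the smoothed histogram has several peaks above half the
#' modal height the result describes the highest peak and the return value
#' carries `attr(, "multimodal") = TRUE`.
#'
#' @param rates Numeric vector of per-neuron rates (>= 10 values).
#' @param bin_width Histogram bin width (default: Freedman-Diaconis).
#' @return FWHM in the units of `rates`; for a degenerate (all-equal)
#'   input, one bin width.
#' @export
rate_distribution_width <- function(rates, bin_width = NULL) {
  rates <- rates[is.finite(rates)]
  if (length(rates) < 10L) stop("need at least 10 neurons for a rate histogram")
  if (is.null(bin_width)) {
    bin_width <- 2 * stats::IQR(rates) / length(rates)^(1 / 3)
    if (bin_width <= 0) bin_width <- max(diff(range(rates)) / 25, 1e-6)
  }
  if (diff(range(rates)) == 0) return(bin_width)       # degenerate: one bin
  breaks <- seq(min(rates) - bin_width, max(rates) + bin_width, by = bin_width)
  if (breaks[length(breaks)] < max(rates)) breaks <- c(breaks, breaks[length(breaks)] + bin_width)
  h <- graphics::hist(rates, breaks = breaks, plot = FALSE)
  counts <- h$counts
  # 3-bin moving average, edges padded with zero
  sm <- (c(0, counts[-length(counts)]) + counts + c(counts[-1], 0)) / 3
  mode_i <- which.max(sm)
  half <- sm[mode_i] / 2
  mids <- h$mids
  cross <- function(side) {
    if (side == "left") {
      below <- which(sm[seq_len(mode_i)] <= half)
      if (!length(below)) return(mids[1] - bin_width / 2)
      i <- max(below)                                   # last bin <= half
      mids[i] + (half - sm[i]) / (sm[i + 1] - sm[i]) * bin_width
    } else {
      below <- which(sm[mode_i:length(sm)] <= half)
      if (!length(below)) return(mids[length(mids)] + bin_width / 2)
      i <- mode_i + min(below) - 1L                     # first bin <= half
      mids[i - 1] + (sm[i - 1] - half) / (sm[i - 1] - sm[i]) * bin_width
    }
  }
  fwhm <- cross("right") - cross("left")
  n_peaks <- sum(diff(sign(diff(c(-Inf, sm, -Inf)))) == -2 & sm > half)
  attr(fwhm, "multimodal") <- n_peaks > 1L
  fwhm
}

#' Peri-transition event-rate change
#'
#' For each speed transition t, per-neuron event rates over the `pre_s`
#' seconds before ([t - pre_s, t)) and the `post_s` seconds after
#' ([t, t + post_s)).  A neuron is transition-associated at t if its post
#' rate strictly exceeds its pre rate (ties count as not associated).
#' Transitions whose windows do not fit inside the recording are skipped
#' with a message.
#'
#' @param raster An `event_raster`.
#' @param profile A `speed_profile`.
#' @param post_s Post-transition window, s (default 10).
#' @param pre_s Pre-transition window, s (default 5).
#' @return List: `pre`, `post` (neurons x transitions rate matrices,
#'   columns named by transition time), `associated` (logical matrix
#'   post > pre), `transitions` (times used).
#' @export
transition_rate_change <- function(raster, profile, post_s = 10, pre_s = 5) {
  stopifnot(inherits(raster, "event_raster"))
  fr <- raster$frame_rate
  n_frames <- ncol(raster$events)
  tt <- (seq_len(n_frames) - 1) / fr
  times <- transition_times(profile)
  usable <- times - pre_s >= 0 & times + post_s <= n_frames / fr
  if (any(!usable))
    message("skipping ", sum(!usable), " transition(s) too close to the recording edge")
  times <- times[usable]
  pre <- post <- matrix(NA_real_, nrow(raster$events), length(times))
  for (j in seq_along(times)) {
    t0 <- times[j]
    pre[, j] <- rowSums(raster$events[, tt >= t0 - pre_s & tt < t0, drop = FALSE]) / pre_s
    post[, j] <- rowSums(raster$events[, tt >= t0 & tt < t0 + post_s, drop = FALSE]) / post_s
  }
  colnames(pre) <- colnames(post) <- paste0("t", times)
  list(pre = pre, post = post, associated = post > pre, transitions = times)
}
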