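# Speed profile: the experiment clock shared by every analysis stage.

#' Construct a wheel speed profile
#'
#' A speed profile is an ordered sequence of constant-speed blocks.  The
#' standard session holds each speed for 2 min: the ascending session runs
#' 0, 15, 30, 45, 60 mm/s and ends with a 2-min rest; the descending session
#' starts at rest, jumps to 60 mm/s and steps down by 15 mm/s.  A transition
#' is a boundary between consecutive blocks whose speeds differ.
#'
#' @param speeds Numeric vector of block speeds in mm/s (nonnegative).
#' @param block_duration_s Duration of each block in seconds (default 120).
#' @return An object of class `speed_profile`: a list with `blocks`
#'   (data.frame: block, speed, start_s, end_s), `transitions`
#'   (data.frame: time_s, from, to), `block_duration_s` and `total_s`.
#' @examples
#' p <- speed_profile()           # ascending default: 6 blocks, 5 transitions
#' nrow(p$transitions)
#' @export
speed_profile <- function(speeds = c(0, 15, 30, 45, 60, 0),
                          block_duration_s = 120) {
  if (length(speeds) == 0L) stop("`speeds` must contain at least one block speed")
  if (any(!is.finite(speeds)) || any(speeds < 0))
    stop("wheel speeds must be finite and nonnegative (mm/s)")
  if (!is.finite(block_duration_s) || block_duration_s <= 0)
    stop("`block_duration_s` must be positive")
  n <- length(speeds)
  start_s <- (seq_len(n) - 1) * block_duration_s
  blocks <- data.frame(block = seq_len(n), speed = as.numeric(speeds),
                       start_s = start_s, end_s = start_s + block_duration_s)
  change <- which(diff(speeds) != 0)
  transitions <- data.frame(time_s = blocks$end_s[change],
                            from = speeds[change], to = speeds[change + 1L])
  structure(list(blocks = blocks, transitions = transitions,
                 block_duration_s = block_duration_s,
                 total_s = n * block_duration_s),
            class = "speed_profile")
}

#' @rdname speed_profile
#' @export
ascending_profile <- function(block_duration_s = 120)
  speed_profile(c(0, 15, 30, 45, 60, 0), block_duration_s)

#' @rdname speed_profile
#' @export
descending_profile <- function(block_duration_s = 120)
  speed_profile(c(0, 60, 45, 30, 15, 0), block_duration_s)

#' @export
print.speed_profile <- function(x, ...) {
  cat("speed_profile:", nrow(x$blocks), "blocks of", x$block_duration_s,
      "s (", x$total_s, "s total ),", nrow(x$transitions), "transitions\n")
  cat("  speeds (mm/s):", paste(x$blocks$speed, collapse = " -> "), "\n")
  invisible(x)
}

#' Transition times of a speed profile
#'
#' @param profile A `speed_profile`.
#' @param increasing_only If `TRUE`, keep only speed-increasing transitions
#'   (four in the ascending session, one in the descending session).
#' @return Numeric vector of transition times in seconds.
#' @export
transition_times <- function(profile, increasing_only = FALSE) {
  tr <- profile$transitions
  if (increasing_only) tr <- tr[tr$to > tr$from, , drop = FALSE]
  tr$time_s
}

#' Frames belonging to each block of a profile
#'
#' Frame f (1-based) covers time (f-1)/frame_rate; a frame belongs to the
#' block whose half-open interval [start_s, end_s) contains that time.
#'
#' @param profile A `speed_profile`.
#' @param frame_rate Sampling rate in Hz.
#' @param n_frames Total frames available; defaults to the number spanned by
#'   the profile.
#' @return List of integer frame-index vectors, one per block.
#' @export
profile_frame_blocks <- function(profile, frame_rate, n_frames = NULL) {
  if (is.null(n_frames)) n_frames <- frames_per_session(profile, frame_rate)
  tt <- (seq_len(n_frames) - 1) / frame_rate
  lapply(seq_len(nrow(profile$blocks)), function(b) {
    which(tt >= profile$blocks$start_s[b] & tt < profile$blocks$end_s[b])
  })
}

#' Frames of the first block at a given speed
#'
#' Convenience selector, e.g. the 2-min 60 mm/s block used for the
#' coordination index.
#' @inheritParams profile_frame_blocks
#' @param speed Block speed to select (mm/s).
#' @export
speed_block_frames <- function(profile, speed, frame_rate, n_frames = NULL) {
  b <- which(profile$blocks$speed == speed)
  if (length(b) == 0L) stop("no block at speed ", speed, " mm/s in this profile")
  profile_frame_blocks(profile, frame_rate, n_frames)[[b[1L]]]
}

#' Number of frames spanned by a profile at a given sampling rate
#' @inheritParams profile_frame_blocks
#' @export
frames_per_session <- function(profile, frame_rate)
  as.integer(round(profile$total_s * frame_rate))

# Default rates: behaviour video at 71.5 Hz; two-photon imaging at
# 4630 frames / 720 s per layer.
#' Default sampling rates
#'
#' The behaviour camera runs at 71.5 Hz; two-photon imaging acquires 4630
#' frames per layer over the 12-min session (~6.4 Hz).
#' @name default_rates
#' @export
video_frame_rate <- function() 71.5

#' @rdname default_rates
#' @export
imaging_frame_rate <- function() 4630 / 720
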