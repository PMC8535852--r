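# Identification of transition-active neurons: similarity statistic and
# permutation null.

#' Build the speed-transition indicator vector
#'
#' s_t = 1 on the frames within `window_s` seconds after each speed
#' transition, 0 elsewhere; overlapping windows are merged.  "Within
#' `window_s` of a transition" is read as the window *following* the
#' transition, consistent with the post-transition rate analyses; set
#' `symmetric = TRUE` for a window on both sides.
#'
#' @param profile A `speed_profile`.
#' @param frame_rate Imaging frame rate, Hz.
#' @param window_s Window length, s (default 15).
#' @param n_frames Total frames (defaults to the profile span).
#' @param symmetric Include `window_s` before each transition as well.
#' @return Object of class `transition_vector`: list with `s` (0/1 integer
#'   vector), `frame_rate`, `window_s`, `transition_frames`.
#' @export
build_transition_vector <- function(profile, frame_rate = imaging_frame_rate(),
                                    window_s = 15, n_frames = NULL,
                                    symmetric = FALSE) {
  if (frame_rate <= 0) stop("frame_rate must be positive")
  if (is.null(n_frames)) n_frames <- frames_per_session(profile, frame_rate)
  times <- transition_times(profile)
  s <- integer(n_frames)
  w <- as.integer(round(window_s * frame_rate))
  tf <- integer(0)
  for (t0 in times) {
    f0 <- as.integer(floor(t0 * frame_rate)) + 1L
    tf <- c(tf, f0)
    lo <- if (symmetric) max(1L, f0 - w) else f0
    hi <- min(n_frames, f0 + w - 1L)
    if (lo <= hi) s[lo:hi] <- 1L
  }
  structure(list(s = s, frame_rate = frame_rate, window_s = window_s,
                 transition_frames = tf),
            class = "transition_vector")
}

#' Transition similarity statistic
#'
#' The normalised inner product 2 (s . c) / (|s|^2 + |c|^2) between a
#' neuron's calcium trace c (dF/F, clipped at zero) and the transition
#' vector s.  The value lies in [0, 1]: 1 exactly when c equals s
#' elementwise, 0 exactly when the two vectors have zero inner product.
#' The statistic is symmetric in its two arguments.
#'
#' @param c_k Numeric trace (negative values are clipped to 0).
#' @param s A `transition_vector` or numeric vector.
#' @return Similarity in [0, 1].
#' @examples
#' similarity(c(2, 0, 0), c(1, 1, 0))   # 2*2 / (2 + 4) = 2/3
#' @export
similarity <- function(c_k, s) {
  sv <- if (inherits(s, "transition_vector")) s$s else as.numeric(s)
  cv <- pmax(as.numeric(c_k), 0)
  if (length(cv) != length(sv)) stop("trace and transition vector lengths differ")
  denom <- sum(sv^2) + sum(cv^2)
  if (denom == 0) stop("similarity undefined: both vectors are identically zero")
  2 * sum(sv * cv) / denom
}

# Draw n sets of onsets for circular windows of lengths L (frames) such
# that the repositioned windows are pairwise disjoint on a ring of size T.
# Rejection sampling; returns an m x n integer matrix.
draw_disjoint_onsets <- function(T, L, n) {
  m <- length(L)
  if (sum(L) > T) stop("transition windows exceed the recording length")
  if (m == 1L) return(matrix(sample.int(T, n, replace = TRUE), 1L, n))
  out <- matrix(NA_integer_, m, n)
  filled <- 0L
  while (filled < n) {
    k <- max(64L, as.integer(ceiling((n - filled) * 1.8)))
    tau <- matrix(sample.int(T, m * k, replace = TRUE), m, k)
    ok <- apply(tau, 2L, function(tv) {
      o <- order(tv)
      ts <- tv[o]; ls <- L[o]
      all(diff(ts) >= ls[-m]) && (ts[1L] + T - ts[m] >= ls[m])
    })
    nk <- min(sum(ok), n - filled)
    if (nk > 0) {
      out[, filled + seq_len(nk)] <- tau[, which(ok)[seq_len(nk)], drop = FALSE]
      filled <- filled + nk
    }
  }
  out
}

#' Permutation null for the similarity statistic
#'
#' Repositions the transition windows at uniformly random onsets (window
#' count and lengths preserved; circular wrap; windows kept disjoint so
#' |s|^2 is invariant) and records the similarity of the trace with each
#' shuffled vector.  `mode = "elementwise"` instead permutes the entries of
#' s freely, which destroys the window structure and gives a much easier
#' null; it is exposed for comparison only.
#'
#' @param c_k Numeric trace (clipped at 0 internally).
#' @param s A `transition_vector`.
#' @param n_shuffles Number of shuffles (default 5000).
#' @param seed Integer seed; fixed seed gives an identical sample vector.
#' @param mode `"window"` (default) or `"elementwise"`.
#' @return Numeric vector of `n_shuffles` null similarities.
#' @export
permutation_null <- function(c_k, s, n_shuffles = 5000, seed = 1L,
                             mode = c("window", "elementwise")) {
  mode <- match.arg(mode)
  stopifnot(inherits(s, "transition_vector"), n_shuffles >= 1)
  sv <- s$s
  T <- length(sv)
  cv <- pmax(as.numeric(c_k), 0)
  if (length(cv) != T) stop("trace and transition vector lengths differ")
  S2 <- sum(sv)
  C2 <- sum(cv^2)
  if (S2 + C2 == 0) stop("similarity undefined: both vectors are identically zero")
  if (S2 == 0) return(rep(0, n_shuffles))
  r <- rle(sv)
  L <- r$lengths[r$values == 1L]
  if (max(L) > T) stop("a transition window is longer than the recording")
  withr::with_seed(seed, {
    if (mode == "elementwise") {
      vapply(seq_len(n_shuffles), function(i)
        2 * sum(cv[sample.int(T, S2)]) / (S2 + C2), numeric(1))
    } else {
      # circular rolling sums of cv for each distinct window length
      ext <- c(cv, cv[seq_len(max(L) - 1L)])
      cs <- c(0, cumsum(ext))
      W <- lapply(stats::setNames(nm = sort(unique(L))), function(l)
        cs[seq_len(T) + l] - cs[seq_len(T)])
      tau <- draw_disjoint_onsets(T, L, n_shuffles)
      dots <- numeric(n_shuffles)
      for (j in seq_along(L))
        dots <- dots + W[[as.character(L[j])]][tau[j, ]]
      2 * dots / (S2 + C2)
    }
  })
}

#' Classify transition-active neurons
#'
#' A neuron is transition-active if the similarity between its trace and
#' the transition vector exceeds the given empirical percentile of its own
#' permutation null (per-neuron null; no pooling across neurons, no
#' multiple-testing correction beyond the percentile rule).
#'
#' @param traces A `trace_matrix`.
#' @param profile A `speed_profile`.
#' @param percentile Percentile of the null distribution (default 99.95).
#' @param n_shuffles Shuffles per neuron (default 5000).
#' @param seed Integer seed; neuron k uses seed + k, so per-neuron results
#'   are reproducible in isolation and independent of evaluation order.
#' @param window_s Post-transition window, s.
#' @param mode Shuffle mode, see [permutation_null()].
#' @return data.frame: `neuron`, `similarity`, `threshold` (null
#'   percentile), `active`.
#' @export
classify_transition_active <- function(traces, profile, percentile = 99.95,
                                       n_shuffles = 5000, seed = 1L,
                                       window_s = 15,
                                       mode = c("window", "elementwise")) {
  mode <- match.arg(mode)
  stopifnot(inherits(traces, "trace_matrix"))
  if (percentile < 0 || percentile > 100)
    stop("`percentile` must lie in [0, 100]")
  tv <- build_transition_vector(profile, traces$frame_rate, window_s,
                                n_frames = ncol(traces$dff))
  n <- nrow(traces$dff)
  out <- data.frame(neuron = seq_len(n), similarity = NA_real_,
                    threshold = NA_real_, active = NA)
  for (k in seq_len(n)) {
    ck <- traces$dff[k, ]
    obs <- similarity(ck, tv)
    null <- permutation_null(ck, tv, n_shuffles, seed = seed + k, mode = mode)
    thr <- stats::quantile(null, percentile / 100, names = FALSE)
    out$similarity[k] <- obs
    out$threshold[k] <- thr
    out$active[k] <- obs > thr
  }
  attr(out, "params") <- list(percentile = percentile, n_shuffles = n_shuffles,
                              window_s = window_s, mode = mode, seed = seed)
  out
}
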