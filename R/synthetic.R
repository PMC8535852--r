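# Synthetic-data generators.  Every generator is a pure function of its
# seed and plants ground truth that the downstream stage can recover.

#' Generate forepaw trajectories with planted strides
#'
#' Within each running block the paw cycles sinusoidally: the horizontal
#' trace is a sine whose rising phase (trough to peak) is one stride, and
#' the vertical trace is the positive lobe of the corresponding cosine, so
#' every stride carries a complete vertical spike whose peak sits in the
#' middle of the rising horizontal phase.  The right paw is the same cycle
#' shifted by a phase offset chosen so that the expected coordination index
#' equals `coordination`: offset acos(-coordination), i.e. anti-phase for
#' coordination 1.
#'
#' @param profile A `speed_profile`.
#' @param strides_per_block Integer: strides planted in each running block
#'   (scalar, applied to every nonzero-speed block, or a vector with one
#'   count per block; rest blocks must be 0).
#' @param stride_length_mm Planted stride length (peak-to-trough horizontal
#'   excursion), mm.
#' @param lift_height_mm Amplitude of the vertical spike, mm.
#' @param coordination Target coordination index in [-1, 1].
#' @param noise_sd Gaussian observation noise on both coordinates, mm.
#' @param frame_rate Video frame rate, Hz (default 71.5).
#' @param alpha Millimetres per pixel used to convert to raw pixels.
#' @param seed Integer seed; identical seeds give identical outputs.
#' @return List with `left`, `right` (`paw_trajectory` objects) and `truth`
#'   (list: `stride_times` data.frame(paw, frame), `counts_per_block`,
#'   `stride_length_mm`, `coordination`).
#' @export
gen_paw_trajectories <- function(profile = ascending_profile(),
                                 strides_per_block = 10,
                                 stride_length_mm = 4,
                                 lift_height_mm = 8,
                                 coordination = 1,
                                 noise_sd = 0,
                                 frame_rate = video_frame_rate(),
                                 alpha = 0.1,
                                 seed = 1L) {
  if (coordination < -1 || coordination > 1)
    stop("`coordination` must lie in [-1, 1]")
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative")
  nb <- nrow(profile$blocks)
  counts <- if (length(strides_per_block) == 1L) {
    ifelse(profile$blocks$speed > 0, strides_per_block, 0L)
  } else {
    if (length(strides_per_block) != nb)
      stop("strides_per_block must be scalar or one count per block")
    strides_per_block
  }
  if (any(counts < 0) || any(counts != round(counts)))
    stop("stride counts must be nonnegative integers")
  n_frames <- frames_per_session(profile, frame_rate)
  tt <- (seq_len(n_frames) - 1) / frame_rate
  A <- stride_length_mm / 2
  phi <- acos(max(-1, min(1, -coordination)))
  lx <- ly <- rx <- ry <- numeric(n_frames)
  truth_rows <- list()
  for (b in seq_len(nb)) {
    nsb <- counts[b]
    if (nsb == 0) next
    s0 <- profile$blocks$start_s[b]; dur <- profile$block_duration_s
    idx <- which(tt >= s0 & tt < s0 + dur)
    # phase -pi/2 at block start: each block begins at a trough, so every
    # planted stride has a detectable rising phase
    th <- 2 * pi * nsb * (tt[idx] - s0) / dur - pi / 2
    lx[idx] <- A * sin(th)
    ly[idx] <- lift_height_mm * pmax(0, cos(th))
    rx[idx] <- A * sin(th - phi)
    ry[idx] <- lift_height_mm * pmax(0, cos(th - phi))
    period <- dur / nsb
    k <- seq_len(nsb) - 1
    lt <- s0 + (k + 0.5) * period                        # x-peak times, left
    rt <- s0 + ((k + 0.5 + phi / (2 * pi)) %% nsb) * period
    truth_rows[[b]] <- data.frame(
      paw = rep(c("left", "right"), each = nsb), block = b,
      frame = as.integer(floor(c(lt, rt) * frame_rate) + 1))
  }
  noise <- withr::with_seed(seed, matrix(stats::rnorm(4L * n_frames,
                                                      sd = noise_sd),
                                         ncol = 4L))
  # raw pixels: d_new = alpha*(median - raw) => raw = center - d/alpha
  cx <- 200; cy <- 150
  mk <- function(dx, dy, nz, paw)
    paw_trajectory(cx - (dx + noise[, nz[1]]) / alpha,
                   cy - (dy + noise[, nz[2]]) / alpha,
                   frame_rate, paw)
  truth <- do.call(rbind, truth_rows[!vapply(truth_rows, is.null, logical(1))])
  if (is.null(truth))
    truth <- data.frame(paw = character(), block = integer(), frame = integer())
  list(left = mk(lx, ly, c(1, 2), "left"),
       right = mk(rx, ry, c(3, 4), "right"),
       truth = list(stride_times = truth[order(truth$paw, truth$frame), ],
                    counts_per_block = counts,
                    stride_length_mm = stride_length_mm,
                    coordination = coordination, alpha = alpha))
}

# ---------------------------------------------------------------------------
# Coupled-network trace generator

#' Coupling matrices for network simulation
#'
#' `chain_coupling` builds an n-node chain; `random_coupling_graph` draws a
#' symmetric Bernoulli graph with the given edge density, all edges at the
#' same coupling strength.
#'
#' @param n Number of neurons.
#' @param coupling Coupling strength on each edge.
#' @param density Edge probability.
#' @param seed Integer seed.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
chain_coupling <- function(n, coupling = 0.8) {
  C <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) C[i, i + 1L] <- C[i + 1L, i] <- coupling
  C
}

#' @rdname chain_coupling
#' @export
random_coupling_graph <- function(n, density = 0.1, coupling = 0.3, seed = 1L) {
  withr::with_seed(seed, {
    C <- matrix(0, n, n)
    up <- upper.tri(C)
    C[up] <- coupling * (stats::runif(sum(up)) < density)
    C + t(C)
  })
}

# union-find: is the nonzero pattern of C a forest (no cycles)?
is_forest <- function(C) {
  n <- nrow(C)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  e <- which(upper.tri(C) & C != 0, arr.ind = TRUE)
  for (k in seq_len(nrow(e))) {
    a <- find(e[k, 1]); b <- find(e[k, 2])
    if (a == b) return(FALSE)
    parent[a] <- b
  }
  TRUE
}

#' Population covariance implied by a coupling graph
#'
#' For a forest (acyclic) graph the couplings are taken as the marginal
#' correlations of adjacent neurons and the covariance is the Gaussian
#' Markov-tree correlation matrix: Sigma_ij is the product of couplings
#' along the unique path between i and j.  Non-adjacent pairs then have
#' exactly zero partial correlation, and on a chain the marginal
#' correlation of the two ends is the product of the link correlations.
#'
#' For a graph with cycles the precision matrix P = I - C is used; if it is
#' not positive definite it is shifted by a multiple of the identity (and
#' renormalised to unit diagonal), which preserves the zero pattern - the
#' planted edges stay the only nonzero partial correlations, at a reduced
#' common magnitude.
#'
#' @param C Symmetric coupling matrix, zero diagonal, |couplings| < 1.
#' @return Correlation matrix (positive definite).
#' @export
coupling_covariance <- function(C) {
  C <- as.matrix(C)
  if (!isSymmetric(unname(C))) stop("coupling matrix must be symmetric")
  if (any(diag(C) != 0)) stop("coupling matrix must have zero diagonal")
  n <- nrow(C)
  if (all(C == 0)) return(diag(n))
  if (any(abs(C) >= 1)) stop("couplings must have magnitude < 1")
  if (is_forest(C)) {
    # path products via BFS from every node
    S <- diag(n)
    for (root in seq_len(n)) {
      visited <- rep(FALSE, n); visited[root] <- TRUE
      frontier <- root
      while (length(frontier)) {
        nxt <- integer()
        for (u in frontier) {
          nbr <- which(C[u, ] != 0 & !visited)
          S[root, nbr] <- S[root, u] * C[u, nbr]
          visited[nbr] <- TRUE
          nxt <- c(nxt, nbr)
        }
        frontier <- nxt
      }
    }
    return((S + t(S)) / 2)
  }
  P <- diag(n) - C
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  floor_ev <- 0.05
  if (min(ev) < floor_ev) P <- P + (floor_ev - min(ev)) * diag(n)
  d <- sqrt(diag(P))
  P <- P / (d %o% d)
  S <- solve(P)
  d <- sqrt(diag(S))
  S / (d %o% d)
}

#' Generate calcium-like traces from a planted coupling graph
#'
#' Latent activity is a stationary zero-mean Gaussian process whose
#' instantaneous covariance is [coupling_covariance()] of the graph; it is
#' convolved with a single-exponential calcium kernel (time constant
#' `kernel_tau`, variance-normalised so the stationary variance stays 1)
#' and corrupted with white observation noise.  The kernel acts identically
#' on every neuron, so the cross-neuron correlation structure of the latent
#' process is preserved in the traces.
#'
#' @param graph Symmetric coupling matrix (see [chain_coupling()],
#'   [random_coupling_graph()]).
#' @param frames Number of frames to simulate.
#' @param frame_rate Imaging frame rate, Hz.
#' @param kernel_tau Calcium decay time constant, s (0 disables smoothing).
#' @param noise_sd Observation noise SD (dF/F units).
#' @param layer Optional layer labels per neuron.
#' @param centroid Optional neurons x 2 centroid matrix; if `NULL` and
#'   `field_px` is given, centroids are drawn uniformly over the field.
#' @param field_px Field size for random centroids (default `NULL`: none).
#' @param pixel_size Microns per pixel for the trace matrix.
#' @param seed Integer seed.
#' @return List with `traces` (a `trace_matrix`) and `truth` (list:
#'   `coupling`, `sigma` the analytic latent covariance).
#' @export
gen_network_traces <- function(graph, frames, frame_rate = imaging_frame_rate(),
                               kernel_tau = 0.6, noise_sd = 0.05,
                               layer = NULL, centroid = NULL, field_px = NULL,
                               pixel_size = 1, seed = 1L) {
  C <- as.matrix(graph)
  n <- nrow(C)
  if (frames < n)
    warning("frames < n_neurons: downstream covariance will be ill-conditioned")
  Sigma <- coupling_covariance(C)
  R <- chol(Sigma)
  a <- if (kernel_tau > 0) exp(-1 / (kernel_tau * frame_rate)) else 0
  sim <- withr::with_seed(seed, {
    U <- matrix(stats::rnorm(frames * n), frames, n) %*% R
    if (a > 0) {
      U <- apply(U * sqrt(1 - a^2), 2, function(u)
        as.numeric(stats::filter(u, a, method = "recursive")))
    }
    U <- U + matrix(stats::rnorm(frames * n, sd = noise_sd), frames, n)
    cen <- centroid
    if (is.null(cen) && !is.null(field_px))
      cen <- matrix(stats::runif(2 * n, 1, field_px), n, 2,
                    dimnames = list(NULL, c("x", "y")))
    list(dff = t(U), centroid = cen)
  })
  tm <- suppressWarnings(trace_matrix(sim$dff, frame_rate, layer,
                                      sim$centroid, pixel_size))
  list(traces = tm, truth = list(coupling = C, sigma = Sigma))
}

# ---------------------------------------------------------------------------

#' Generate traces with planted speed-transition responders
#'
#' Non-responders emit events as a homogeneous Bernoulli process at
#' `baseline_rate`; responders multiply that rate by `effect_rate_gain`
#' inside the `window_s`-second window following every speed transition.
#' Events (amplitude 1) are convolved with an exponential calcium kernel
#' and observation noise is added.
#'
#' @param profile A `speed_profile`.
#' @param n_neurons Number of neurons.
#' @param responder_fraction Fraction of neurons that are responders, [0,1].
#' @param effect_rate_gain Multiplicative rate gain inside windows (>= 1).
#' @param baseline_rate Baseline event rate, events/s.
#' @param frame_rate Imaging frame rate, Hz.
#' @param window_s Post-transition window, s (default 15).
#' @param kernel_tau Calcium decay constant, s.
#' @param noise_sd Observation noise SD.
#' @param seed Integer seed.
#' @return List with `traces` (`trace_matrix`), `raster` (`event_raster`
#'   of the planted events) and `truth` (list: `responder` logical vector,
#'   `baseline_rate`, `effect_rate_gain`).
#' @export
gen_transition_responders <- function(profile = ascending_profile(),
                                      n_neurons = 100,
                                      responder_fraction = 0.2,
                                      effect_rate_gain = 4,
                                      baseline_rate = 0.1,
                                      frame_rate = imaging_frame_rate(),
                                      window_s = 15,
                                      kernel_tau = 0.6,
                                      noise_sd = 0.05,
                                      seed = 1L) {
  if (responder_fraction < 0 || responder_fraction > 1)
    stop("`responder_fraction` must lie in [0, 1]")
  if (effect_rate_gain < 1) stop("`effect_rate_gain` must be >= 1")
  tv <- build_transition_vector(profile, frame_rate, window_s)
  n_frames <- length(tv$s)
  a <- if (kernel_tau > 0) exp(-1 / (kernel_tau * frame_rate)) else 0
  out <- withr::with_seed(seed, {
    responder <- rep(FALSE, n_neurons)
    n_resp <- round(responder_fraction * n_neurons)
    if (n_resp > 0) responder[sample.int(n_neurons, n_resp)] <- TRUE
    p <- matrix(baseline_rate / frame_rate, n_neurons, n_frames)
    p[responder, tv$s == 1] <- p[responder, tv$s == 1] * effect_rate_gain
    ev <- matrix(stats::runif(n_neurons * n_frames), n_neurons, n_frames) < p
    dff <- t(apply(ev, 1, function(e)
      as.numeric(stats::filter(as.numeric(e), a, method = "recursive"))))
    dff <- dff + matrix(stats::rnorm(n_neurons * n_frames, sd = noise_sd),
                        n_neurons, n_frames)
    list(ev = ev, dff = dff, responder = responder)
  })
  list(traces = trace_matrix(out$dff, frame_rate),
       raster = event_raster(out$ev, frame_rate,
                             params = list(source = "planted")),
       truth = list(responder = out$responder,
                    baseline_rate = baseline_rate,
                    effect_rate_gain = effect_rate_gain,
                    window_s = window_s))
}

# ---------------------------------------------------------------------------

#' Generate multi-day ROI tables with planted field-of-view shifts
#'
#' Day-1 centroids are drawn uniformly over the field with a minimum
#' spacing of 2 px, avoiding a border wide enough that shifted neurons stay
#' inside the field.  Each later day applies a planted integer shift, adds
#' per-neuron jitter uniform in [-jitter_px, jitter_px] per axis (bounded,
#' so jitter within the matching tolerance guarantees a candidate within
#' tolerance), and drops each neuron independently with
#' probability `dropout` (day 1, the registration reference, keeps all
#' neurons).  Per-day ROI ids are freshly assigned in a shuffled order so
#' that identity is only recoverable through matching.
#'
#' @param n_neurons Number of neurons.
#' @param n_days Number of days (>= 1).
#' @param field_px Field side in pixels (default 512).
#' @param max_shift_px Maximum |shift| per axis, px (must fit the
#'   registration search window).
#' @param jitter_px Per-neuron centroid jitter bound, px (uniform per axis).
#' @param dropout Per-day dropout probability on days >= 2.
#' @param min_spacing_px Minimum centroid spacing on day 1 (default 2).
#' @param seed Integer seed.
#' @return List with `rois` (list of per-day data.frames: id, x_px, y_px),
#'   `truth` (list: `day_shifts` data.frame(day, dx, dy), `identity_map`
#'   n_neurons x n_days matrix of per-day ids, NA where dropped,
#'   `centroids_day1`).
#' @export
gen_roi_sessions <- function(n_neurons = 100, n_days = 5, field_px = 512,
                             max_shift_px = 10, jitter_px = 1, dropout = 0.1,
                             min_spacing_px = 2, seed = 1L) {
  margin <- max_shift_px + 12
  if (2 * margin >= field_px) stop("field too small for the requested shift margin")
  usable <- field_px - 2 * margin
  if (n_neurons > (usable / min_spacing_px + 1)^2)
    stop("could not place ", n_neurons, " neurons at >= ", min_spacing_px,
         " px spacing in this field")
  withr::with_seed(seed, {
    xy <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(xy) < n_neurons) {
      cand <- stats::runif(2, margin, field_px - margin)
      if (nrow(xy) == 0 ||
          min(sqrt(colSums((t(xy) - cand)^2))) >= min_spacing_px)
        xy <- rbind(xy, cand)
      tries <- tries + 1L
      if (tries > 200L * n_neurons)
        stop("could not place ", n_neurons,
             " neurons at >= ", min_spacing_px, " px spacing in this field")
    }
    colnames(xy) <- c("x", "y")
    shifts <- data.frame(day = seq_len(n_days), dx = 0L, dy = 0L)
    if (n_days > 1) {
      shifts$dx[-1] <- sample.int(2 * max_shift_px + 1, n_days - 1,
                                  replace = TRUE) - max_shift_px - 1L
      shifts$dy[-1] <- sample.int(2 * max_shift_px + 1, n_days - 1,
                                  replace = TRUE) - max_shift_px - 1L
    }
    identity_map <- matrix(NA_integer_, n_neurons, n_days)
    rois <- vector("list", n_days)
    for (d in seq_len(n_days)) {
      present <- if (d == 1) rep(TRUE, n_neurons) else
        stats::runif(n_neurons) >= dropout
      jit <- if (d == 1) matrix(0, n_neurons, 2) else
        matrix(stats::runif(2 * n_neurons, -jitter_px, jitter_px),
               n_neurons, 2)
      px <- xy[present, 1] + shifts$dx[d] + jit[present, 1]
      py <- xy[present, 2] + shifts$dy[d] + jit[present, 2]
      ord <- sample.int(sum(present))
      ids <- seq_len(sum(present))
      rois[[d]] <- data.frame(id = ids, x_px = px[ord], y_px = py[ord])
      identity_map[which(present)[ord], d] <- ids
    }
    list(rois = rois,
         truth = list(day_shifts = shifts, identity_map = identity_map,
                      centroids_day1 = xy))
  })
}
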