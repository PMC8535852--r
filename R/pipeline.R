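# Orchestration: configuration, seed fan-out, end-to-end run on synthetic
# or file inputs.

#' Pipeline configuration
#'
#' Collects every stage parameter with defaults matching the experimental
#' protocol (2-min blocks, 15-s transition window, 5000 shuffles, 99.95th
#' percentile, 5-px rendering SD, 5-px matching tolerance, search
#' half-width 40) and validates ranges before any stage runs.
#'
#' @param profile A `speed_profile`.
#' @param alpha Millimetres per pixel for paw centering.
#' @param cutoff Butterworth cutoff (fraction of Nyquist).
#' @param k_mad Event-detection threshold multiplier.
#' @param window_s Transition window, s.
#' @param percentile Permutation-test percentile (0-100].
#' @param n_shuffles Permutation shuffles.
#' @param lambda DCC shrinkage.
#' @param ws Registration search half-width, px.
#' @param tol_px Identity-matching tolerance, px.
#' @param seed Master seed; each stage derives its own seed as
#'   `seed + 1000 * stage_index`, so stage-level reruns reproduce in
#'   isolation.
#' @param n_neurons,n_days,frames Synthetic input sizes used when the
#'   pipeline simulates its inputs.
#' @param out_dir Optional output directory for report tables + manifest.
#' @return A validated `run_config` list.
#' @export
run_config <- function(profile = ascending_profile(),
                       alpha = 0.1, cutoff = 0.1, k_mad = 2.5,
                       window_s = 15, percentile = 99.95, n_shuffles = 5000,
                       lambda = 0.05, ws = 40, tol_px = 5, seed = 1L,
                       n_neurons = 40, n_days = 4, frames = 2000,
                       out_dir = NULL) {
  stopifnot(inherits(profile, "speed_profile"))
  if (percentile <= 0 || percentile > 100)
    stop("invalid config: `percentile` must lie in (0, 100]")
  if (cutoff <= 0 || cutoff >= 1)
    stop("invalid config: `cutoff` must lie in (0, 1)")
  if (lambda < 0 || lambda > 1) stop("invalid config: `lambda` in [0, 1]")
  if (ws < 0 || tol_px < 0) stop("invalid config: ws and tol_px must be >= 0")
  if (n_shuffles < 1) stop("invalid config: n_shuffles must be >= 1")
  structure(list(profile = profile, alpha = alpha, cutoff = cutoff,
                 k_mad = k_mad, window_s = window_s, percentile = percentile,
                 n_shuffles = n_shuffles, lambda = lambda, ws = ws,
                 tol_px = tol_px, seed = as.integer(seed),
                 n_neurons = n_neurons, n_days = n_days, frames = frames,
                 out_dir = out_dir),
            class = "run_config")
}

stage_seed <- function(config, stage_index) config$seed + 1000L * stage_index

#' Run the full analysis pipeline on synthetic inputs
#'
#' Generates a synthetic session (paw trajectories, responder traces, a
#' coupled network, multi-day ROI maps), then executes every stage:
#' kinematics (centering, smoothing, stride detection, block stats,
#' coordination), calcium events (detection, block rates, peri-transition
#' change), transition-responder classification, connectivity (Pearson,
#' DCC, strong pairs, proximity ratio), cross-day registration, and pair
#' persistence.  With identical config and seed the result is identical;
#' no stage mutates its inputs.  If `config$out_dir` is set, per-stage
#' tables and a JSON run manifest (parameters, seed, package version) are
#' written there.
#'
#' @param config A `run_config`.
#' @param paws Optional list(left, right) of `paw_trajectory` to analyse
#'   instead of simulating.
#' @param traces Optional `trace_matrix` for the event/transition stages.
#' @return Named list of per-stage results, plus `truth` for simulated
#'   inputs and the `manifest`.
#' @export
run_pipeline <- function(config = run_config(), paws = NULL, traces = NULL) {
  stopifnot(inherits(config, "run_config"))
  pr <- config$profile
  res <- list()

  # stage 1: inputs
  sim_paws <- is.null(paws)
  if (sim_paws) {
    pg <- gen_paw_trajectories(pr, strides_per_block = 10, coordination = 0.8,
                               noise_sd = 0.2, seed = stage_seed(config, 1L))
    paws <- pg[c("left", "right")]
    res$truth_paws <- pg$truth
  }
  if (is.null(traces)) {
    tg <- gen_transition_responders(pr, n_neurons = config$n_neurons,
                                    responder_fraction = 0.2,
                                    effect_rate_gain = 4,
                                    seed = stage_seed(config, 2L))
    traces <- tg$traces
    res$truth_responders <- tg$truth
  }

  # stage 2: kinematics
  fr_v <- paws$left$frame_rate
  cl <- center_paw(paws$left, config$alpha)
  cr <- center_paw(paws$right, config$alpha)
  sx <- smooth_trace(cl$x, cutoff = config$cutoff)
  sy <- smooth_trace(cl$y, cutoff = config$cutoff)
  strides <- detect_strides(sx, sy)
  res$stride_stats <- block_stride_stats(strides, pr, fr_v)
  res$strides <- strides
  run_blk <- speed_block_frames(pr, max(pr$blocks$speed), fr_v,
                                length(cl$x$d))
  res$coordination <- coordination_index(
    smooth_trace(cl$x, cutoff = config$cutoff),
    smooth_trace(cr$x, cutoff = config$cutoff), run_blk)

  # stage 3: events
  raster <- detect_events(traces, k_mad = config$k_mad)
  res$raster <- raster
  res$block_rates <- block_event_rate(raster, pr)
  res$rate_width <- tryCatch(rate_distribution_width(res$block_rates$running),
                             error = function(e) NA_real_)
  res$transition_change <- transition_rate_change(raster, pr)

  # stage 4: transition responders
  res$transition_active <- classify_transition_active(
    traces, pr, percentile = config$percentile,
    n_shuffles = config$n_shuffles, seed = stage_seed(config, 4L),
    window_s = config$window_s)

  # stage 5: connectivity on a planted coupled network
  net <- gen_network_traces(
    random_coupling_graph(config$n_neurons, density = 0.1, coupling = 0.3,
                          seed = stage_seed(config, 5L)),
    frames = config$frames, field_px = 512, seed = stage_seed(config, 5L))
  r_mat <- pearson_matrix(net$traces)
  d_mat <- dcc_matrix(net$traces, lambda = config$lambda)
  res$pairs <- pair_records(r_mat, d_mat, net$traces$centroid,
                            net$traces$pixel_size)
  res$strong_pairs <- strong_pairs(r_mat)
  res$proximity <- tryCatch(
    proximity_ratio(res$pairs$dcc, res$pairs$distance_um),
    error = function(e) NULL)
  res$edge_auc <- edge_recovery_auc(d_mat, net$truth$coupling)
  res$truth_network <- net$truth

  # stage 6: registration
  roi <- gen_roi_sessions(config$n_neurons, config$n_days,
                          max_shift_px = min(10, config$ws),
                          seed = stage_seed(config, 6L))
  res$registration <- track_across_days(roi$rois, ws = config$ws,
                                        tol_px = config$tol_px)
  res$truth_rois <- roi$truth

  # stage 7: persistence of directly-correlated pairs across days
  day_mats <- lapply(seq_len(config$n_days), function(d)
    dcc_matrix(gen_network_traces(net$truth$coupling, frames = config$frames,
                                  seed = stage_seed(config, 7L) + d)$traces,
               lambda = config$lambda))
  sets <- detected_pairs_per_day(day_mats)
  res$persistence <- persistence_histogram(sets, config$n_days)
  res$persistence_kurtosis <- tryCatch(
    suppressWarnings(histogram_kurtosis(res$persistence)),
    error = function(e) NA_real_)

  res$manifest <- list(package = "wheelnet",
                       version = as.character(utils::packageVersion("wheelnet")),
                       seed = config$seed,
                       parameters = config[setdiff(names(config),
                                                   c("profile", "out_dir"))],
                       profile_speeds = pr$blocks$speed,
                       block_duration_s = pr$block_duration_s)

  if (!is.null(config$out_dir)) write_report(res, config)
  res
}

write_report <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  data.table::fwrite(res$stride_stats, p("stride_stats.csv"))
  data.table::fwrite(as.data.frame(res$strides), p("strides.csv"))
  data.table::fwrite(as.data.frame(res$block_rates$rates), p("block_rates.csv"))
  data.table::fwrite(res$transition_active, p("transition_active.csv"))
  data.table::fwrite(res$pairs, p("pair_records.csv"))
  data.table::fwrite(res$registration$shifts, p("registration_shifts.csv"))
  data.table::fwrite(data.frame(days = seq_along(res$persistence$fraction),
                                fraction = res$persistence$fraction),
                     p("persistence_histogram.csv"))
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(config$out_dir)
}
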