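test_that("generators are pure functions of their seed", {
  p <- ascending_profile()
  a <- gen_paw_trajectories(p, noise_sd = 0.5, seed = 7)
  b <- gen_paw_trajectories(p, noise_sd = 0.5, seed = 7)
  expect_identical(a, b)
  n1 <- gen_network_traces(chain_coupling(4, 0.5), frames = 200, seed = 3)
  n2 <- gen_network_traces(chain_coupling(4, 0.5), frames = 200, seed = 3)
  expect_identical(n1$traces$dff, n2$traces$dff)
  r1 <- gen_roi_sessions(30, 3, seed = 9)
  r2 <- gen_roi_sessions(30, 3, seed = 9)
  expect_identical(r1, r2)
  t1 <- gen_transition_responders(p, n_neurons = 10, seed = 5)
  t2 <- gen_transition_responders(p, n_neurons = 10, seed = 5)
  expect_identical(t1$traces$dff, t2$traces$dff)
})

test_that("paw generator plants the requested strides", {
  p <- ascending_profile()
  g <- gen_paw_trajectories(p, strides_per_block = 10, noise_sd = 0, seed = 1)
  expect_equal(g$truth$counts_per_block, c(0, 10, 10, 10, 10, 0))
  left <- g$truth$stride_times[g$truth$stride_times$paw == "left", ]
  expect_equal(nrow(left), 40)
  expect_equal(unname(table(left$block)), rep(10L, 4), ignore_attr = TRUE)
  expect_error(gen_paw_trajectories(p, strides_per_block = -1), "nonnegative")
  expect_error(gen_paw_trajectories(p, noise_sd = -1), "nonnegative")
  expect_error(gen_paw_trajectories(p, coordination = 1.5), "\\[-1, 1\\]")
})

test_that("planted coordination is realised by the paw pair", {
  p <- ascending_profile()
  blk <- speed_block_frames(p, 60, video_frame_rate())
  ci <- function(g) {
    cl <- center_paw(g$left, 0.1); cr <- center_paw(g$right, 0.1)
    coordination_index(cl$x, cr$x, blk)
  }
  expect_equal(ci(gen_paw_trajectories(p, coordination = 1, noise_sd = 0)),
               1, tolerance = 1e-9)
  expect_equal(ci(gen_paw_trajectories(p, coordination = -1, noise_sd = 0)),
               -1, tolerance = 1e-9)
  expect_equal(ci(gen_paw_trajectories(p, coordination = 0.5, noise_sd = 0)),
               0.5, tolerance = 1e-6)
  # coordination 0 with noise: unbiased around 0 over seeds
  vals <- vapply(1:20, function(s)
    ci(gen_paw_trajectories(p, coordination = 0, noise_sd = 1, seed = s)),
    numeric(1))
  expect_lt(abs(mean(vals)), 0.1)
})

test_that("coupling covariance honours the planted graph", {
  # chain closed form: adjacent correlation = coupling, ends = product
  S <- coupling_covariance(chain_coupling(3, 0.8))
  expect_equal(S[1, 2], 0.8)
  expect_equal(S[1, 3], 0.64)
  # partial correlation of the non-adjacent pair is exactly zero
  P <- solve(S)
  expect_equal(-P[1, 3] / sqrt(P[1, 1] * P[3, 3]), 0, tolerance = 1e-12)
  # cyclic graph: positive definite, zero pattern preserved
  C <- matrix(0, 4, 4)
  C[1, 2] <- C[2, 3] <- C[3, 4] <- C[4, 1] <- C[1, 3] <- 0.4
  C <- C + t(C)
  S4 <- coupling_covariance(C)
  expect_true(all(eigen(S4, symmetric = TRUE, only.values = TRUE)$values > 0))
  P4 <- solve(S4)
  expect_equal(P4[2, 4], 0, tolerance = 1e-10)   # non-edge stays non-edge
  expect_error(coupling_covariance(chain_coupling(3, 1.2)), "magnitude")
  expect_error(coupling_covariance(matrix(1, 2, 2)), "diagonal")
})

test_that("uncoupled neurons decorrelate and sample covariance converges", {
  n0 <- gen_network_traces(matrix(0, 15, 15), frames = 4000, seed = 2)
  r <- pearson_matrix(n0$traces)
  expect_lt(mean(abs(r[upper.tri(r)])), 0.05)
  # Frobenius error of the sample correlation decreases with frames
  C <- chain_coupling(5, 0.6)
  S <- coupling_covariance(C)
  err <- vapply(c(250, 1000, 4000), function(f) {
    g <- gen_network_traces(C, frames = f, noise_sd = 0, seed = 11)
    norm(stats::cor(t(g$traces$dff)) - S, "F")
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_warning(gen_network_traces(matrix(0, 10, 10), frames = 5, seed = 1),
                 "ill-conditioned")
})

test_that("responder generator plants labels and rates as requested", {
  p <- ascending_profile()
  g0 <- gen_transition_responders(p, n_neurons = 50, responder_fraction = 0,
                                  seed = 1)
  expect_false(any(g0$truth$responder))
  g <- gen_transition_responders(p, n_neurons = 200, responder_fraction = 0.2,
                                 effect_rate_gain = 4, baseline_rate = 0.1,
                                 seed = 2)
  expect_equal(sum(g$truth$responder), 40)
  # realised event rate of responders inside windows ~ 4x baseline
  tv <- build_transition_vector(p, g$raster$frame_rate)
  inw <- tv$s == 1
  rate_in <- sum(g$raster$events[g$truth$responder, inw]) /
    (sum(g$truth$responder) * sum(inw) / g$raster$frame_rate)
  expect_equal(rate_in, 0.4, tolerance = 0.15)
  expect_error(gen_transition_responders(p, responder_fraction = 2), "\\[0, 1\\]")
  expect_error(gen_transition_responders(p, effect_rate_gain = 0.5), ">= 1")
})

test_that("ROI sessions plant shifts, jitter bounds and dropout", {
  r0 <- gen_roi_sessions(40, 3, max_shift_px = 0, jitter_px = 0, dropout = 0,
                         seed = 4)
  # identical per-day tables up to id shuffling
  for (d in 2:3) {
    m <- r0$truth$identity_map
    expect_equal(r0$rois[[d]]$x_px[m[, d]], r0$rois[[1]]$x_px[m[, 1]])
  }
  r <- gen_roi_sessions(200, 4, max_shift_px = 8, jitter_px = 1,
                        dropout = 0.5, seed = 5)
  expect_true(all(abs(r$truth$day_shifts[, c("dx", "dy")]) <= 8))
  n_per_day <- vapply(r$rois[-1], nrow, integer(1))
  expect_true(all(n_per_day > 60) && all(n_per_day < 140))  # ~Binomial(200,.5)
  expect_error(gen_roi_sessions(1e6, 2, field_px = 64, max_shift_px = 1),
               "could not place|field too small")
})
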