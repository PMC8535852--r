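test_that("paw centering matches the definition d_new = alpha (median - raw)", {
  ct <- center_paw(c(1, 2, 3), alpha = 1)
  expect_equal(ct$d, c(1, 0, -1))
  expect_equal(ct$d_median, 2)
  # direct substitution: alpha 0.1, median 200, raw 150 -> 5 mm
  raw <- c(rep(200, 9), 150)
  expect_equal(center_paw(raw, alpha = 0.1)$d[10], 5)
  expect_equal(center_paw(raw, alpha = 0.1)$d[1], 0)   # raw at median -> 0
  # all-constant series centers to zeros
  expect_equal(center_paw(rep(7, 5), alpha = 2)$d, rep(0, 5))
  expect_error(center_paw(1:3, alpha = 0), "positive")
})

test_that("zero-phase Butterworth smoothing preserves DC and kills high frequencies", {
  expect_equal(smooth_trace(rep(3.5, 100), cutoff = 0.2), rep(3.5, 100),
               tolerance = 1e-8)
  # sinusoid at 10x the cutoff frequency is attenuated below 5 %
  fr <- 100; cutoff <- 0.04                       # 2 Hz cutoff
  t <- seq(0, 20, by = 1 / fr)
  hi <- sin(2 * pi * 20 * t)                      # 20 Hz
  out <- smooth_trace(hi, cutoff = cutoff)
  mid <- seq(200, length(t) - 200)
  expect_lt(max(abs(out[mid])), 0.05)
  # a sinusoid well below cutoff passes essentially unchanged
  lo <- sin(2 * pi * 0.2 * t)
  expect_equal(smooth_trace(lo, cutoff = cutoff)[mid], lo[mid],
               tolerance = 0.01)
  expect_error(smooth_trace(1:100, cutoff = 1.5), "between 0 and 1")
  expect_error(smooth_trace(1:5, cutoff = 0.2), "too short")
})

test_that("stride detection recovers planted spikes exactly at zero noise", {
  expect_equal(nrow(detect_strides(rep(0, 500), rep(0, 500),
                                   frame_rate = 71.5)), 0)
  # one planted spike pair: full x-spike whose rising phase carries a y-spike
  th <- seq(-pi / 2, 3 * pi / 2, length.out = 60)
  x <- c(rep(0, 50), 2 * sin(th), rep(0, 50))
  y <- c(rep(0, 50), 8 * pmax(0, cos(th)), rep(0, 50))
  st <- detect_strides(x, y, frame_rate = 71.5)
  expect_equal(nrow(st), 1)
  expect_equal(st$length_mm, 4, tolerance = 1e-2)   # sampling discretisation

  p <- ascending_profile()
  g <- gen_paw_trajectories(p, strides_per_block = 10, stride_length_mm = 4,
                            noise_sd = 0, seed = 1)
  cl <- center_paw(g$left, 0.1)
  st <- detect_strides(cl$x, cl$y)
  bs <- block_stride_stats(st, p)
  expect_equal(bs$n_strides, g$truth$counts_per_block)
  expect_equal(bs$mean_length_mm[bs$speed > 0], rep(4, 4), tolerance = 1e-3)
  expect_true(all(is.na(bs$mean_length_mm[bs$speed == 0])))
  expect_equal(sort(st$peak_frame),
               sort(g$truth$stride_times$frame[
                 g$truth$stride_times$paw == "left"]))
})

test_that("stride detection is invariant to offsets; lengths scale with alpha", {
  p <- speed_profile(c(0, 60, 0), block_duration_s = 30)
  g <- gen_paw_trajectories(p, strides_per_block = c(0, 10, 0),
                            noise_sd = 0, seed = 2)
  cl <- center_paw(g$left, 0.1)
  st0 <- detect_strides(cl$x, cl$y)
  sh <- function(v, k) structure(list(d = v$d + k, alpha = v$alpha,
                                      d_median = v$d_median,
                                      frame_rate = v$frame_rate),
                                 class = "centered_trace")
  st1 <- detect_strides(sh(cl$x, 12), sh(cl$y, -3))
  expect_equal(st1$peak_frame, st0$peak_frame)
  expect_equal(st1$length_mm, st0$length_mm)
  cl2 <- center_paw(g$left, 0.2)                       # doubled alpha
  st2 <- detect_strides(cl2$x, cl2$y)
  expect_equal(nrow(st2), nrow(st0))
  expect_equal(st2$length_mm, 2 * st0$length_mm, tolerance = 1e-9)
})

test_that("running-block stride counts are robust to noise at 10% of spike amplitude", {
  p <- speed_profile(c(0, 60, 0), block_duration_s = 30)
  planted <- 10
  errs <- vapply(1:20, function(s) {
    g <- gen_paw_trajectories(p, strides_per_block = c(0, planted, 0),
                              stride_length_mm = 4, lift_height_mm = 8,
                              noise_sd = 0.8, seed = s)
    cl <- center_paw(g$left, 0.1)
    sx <- smooth_trace(cl$x, cutoff = 0.05)
    sy <- smooth_trace(cl$y, cutoff = 0.05)
    bs <- block_stride_stats(detect_strides(sx, sy), p)
    abs(bs$n_strides[2] - planted)
  }, numeric(1))
  expect_lte(mean(errs) / planted, 0.02)
})

test_that("percent change uses the (later - earlier)/earlier convention", {
  expect_equal(percent_change(271.8, 475.7), 75.0184, tolerance = 1e-4)
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(200, 100), -50)
})

test_that("coordination index endpoints, bounds and antisymmetry", {
  x <- sin(seq(0, 20 * pi, length.out = 1000))
  expect_equal(coordination_index(x, -x), 1)
  expect_equal(coordination_index(x, x), -1)
  expect_equal(coordination_index(x, -x), -coordination_index(x, x))
  set.seed(3)
  vals <- replicate(20, coordination_index(rnorm(500), rnorm(500)))
  expect_true(all(vals >= -1 & vals <= 1))
  expect_lt(abs(mean(vals)), 0.1)
  expect_error(coordination_index(rep(1, 10), rnorm(10)), "zero variance")
})
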