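test_that("event detector: degenerate traces and a single planted transient", {
  fr <- imaging_frame_rate()
  flat <- trace_matrix(matrix(0.3, 2, 600), fr)
  expect_equal(sum(detect_events(flat)$events), 0)
  # one transient, 5x any plausible threshold
  x <- rep(0, 600)
  x[300:310] <- 5 * exp(-(0:10) / 4)
  tm <- trace_matrix(rbind(x, 0), fr)
  ra <- detect_events(tm)
  expect_equal(sum(ra$events[1, ]), 1)
  expect_equal(which(ra$events[1, ]), 300)
  expect_equal(sum(ra$events[2, ]), 0)
  # invariance to adding a constant
  ra2 <- detect_events(trace_matrix(rbind(x + 10, 10), fr))
  expect_identical(ra2$events, ra$events)
})

test_that("detector recovers planted events with high precision and recall", {
  p <- ascending_profile()
  prec <- rec <- numeric(10)
  for (s in 1:10) {
    g <- gen_transition_responders(p, n_neurons = 12, responder_fraction = 0,
                                   baseline_rate = 0.1, noise_sd = 0.1,
                                   seed = s)
    det <- detect_events(g$traces)
    n_match <- n_true <- n_det <- 0
    for (i in seq_len(nrow(det$events))) {
      tf <- which(g$raster$events[i, ]); df <- which(det$events[i, ])
      n_match <- n_match + match_onsets(tf, df)
      n_true <- n_true + length(tf); n_det <- n_det + length(df)
    }
    rec[s] <- n_match / n_true; prec[s] <- n_match / n_det
  }
  expect_gte(mean(rec), 0.95)
  expect_gte(mean(prec), 0.95)
})

test_that("block event rates: arithmetic, pooling and calibration", {
  p <- ascending_profile()
  fr <- imaging_frame_rate()
  n_f <- frames_per_session(p, fr)
  ev <- matrix(FALSE, 2, n_f)
  blk2 <- profile_frame_blocks(p, fr)[[2]]
  ev[1, blk2[seq_len(12)]] <- TRUE          # 12 events in one 120-s block
  br <- block_event_rate(event_raster(ev, fr), p)
  expect_equal(unname(br$rates[1, 2]), 0.1)
  expect_equal(unname(br$rates[2, ]), rep(0, 6))      # empty raster row
  expect_equal(br$rest[1], 0)
  expect_equal(br$running[1], 12 / 480)
  # homogeneous process: block rates near the planted rate
  g <- gen_transition_responders(p, n_neurons = 400, responder_fraction = 0,
                                 baseline_rate = 0.1, seed = 3)
  br2 <- block_event_rate(g$raster, p)
  expect_equal(mean(br2$rates), 0.1, tolerance = 0.02)
})

test_that("rate-distribution width behaves like a FWHM", {
  set.seed(5)
  rates <- rnorm(1e4, 0.2, 0.05)
  w <- rate_distribution_width(rates)
  expect_equal(as.numeric(w), 2.355 * 0.05, tolerance = 0.1 * 2.355 * 0.05)
  # scale equivariance
  w2 <- rate_distribution_width(2 * rates)
  expect_equal(as.numeric(w2), 2 * as.numeric(w), tolerance = 1e-9)
  # degenerate: all identical -> one bin width
  expect_equal(rate_distribution_width(rep(0.2, 50), bin_width = 0.01), 0.01)
  # multimodal flag on a clearly bimodal sample
  bim <- c(rnorm(5e3, 0.1, 0.01), rnorm(5e3, 0.5, 0.01))
  expect_true(attr(rate_distribution_width(bim), "multimodal"))
  expect_error(rate_distribution_width(1:5), "at least 10")
})

test_that("peri-transition rate change flags responders, not homogeneous cells", {
  p <- ascending_profile()
  fr <- imaging_frame_rate()
  # zero events -> nothing associated
  empty <- event_raster(matrix(FALSE, 3, frames_per_session(p, fr)), fr)
  tc0 <- transition_rate_change(empty, p)
  expect_false(any(tc0$associated))
  expect_equal(dim(tc0$pre), c(3, 5))
  # homogeneous process: the associated fraction matches the closed-form
  # P(post > 2 pre) for independent Bernoulli-frame counts (ties, counted
  # as not associated, pull it below 1/2)
  g <- gen_transition_responders(p, n_neurons = 600, responder_fraction = 0,
                                 baseline_rate = 0.3, seed = 8)
  tc <- transition_rate_change(g$raster, p)
  pf <- 0.3 / fr
  n_pre <- round(5 * fr); n_post <- round(10 * fr)
  p_assoc <- sum(dbinom(0:n_pre, n_pre, pf) *
                   (1 - pbinom(2 * (0:n_pre), n_post, pf)))
  expect_lt(p_assoc, 0.5)
  expect_lt(abs(mean(tc$associated) - p_assoc), 0.04)
  # planted gain-4 responders at 0.2 ev/s: post > pre almost surely
  gr <- gen_transition_responders(p, n_neurons = 100, responder_fraction = 1,
                                  effect_rate_gain = 4, baseline_rate = 0.2,
                                  seed = 9)
  tcr <- transition_rate_change(gr$raster, p)
  expect_gte(mean(rowMeans(tcr$associated) > 0.5), 0.95)
})
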