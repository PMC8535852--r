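test_that("Pearson matrix basics and error handling", {
  set.seed(2)
  x <- matrix(rnorm(4 * 500), 4, 500)
  x[2, ] <- x[1, ]                                    # duplicated trace
  r <- pearson_matrix(x)
  expect_equal(r[1, 2], 1)
  expect_true(isSymmetric(r))
  expect_equal(diag(r), rep(1, 4), ignore_attr = TRUE)
  # independent noise decorrelates
  y <- matrix(rnorm(20 * 4000), 20, 4000)
  ry <- pearson_matrix(y)
  expect_lt(mean(abs(ry[upper.tri(ry)])), 0.05)
  x[3, ] <- 2
  expect_error(pearson_matrix(x), "zero-variance")
  expect_error(pearson_matrix(y[, 1:2]), "at least 3 frames")
})

test_that("strong-pair rule: mean + 2 SD with strict inequality", {
  m_eq <- matrix(0.3, 10, 10)                         # all values equal
  expect_equal(nrow(strong_pairs(m_eq)), 0)
  # one standout among 100 values
  n <- 15                                             # C(15,2) = 105 pairs
  m <- matrix(0, n, n)
  m[1, 2] <- m[2, 1] <- 1
  sp <- strong_pairs(m)
  expect_equal(nrow(sp), 1)
  expect_equal(c(sp$i, sp$j), c(1, 2))
  vals <- m[upper.tri(m)]
  expect_equal(attr(sp, "threshold"), mean(vals) + 2 * sd(vals))
  # Gaussian values: selected fraction near the +2 sigma tail (~2.3 %)
  set.seed(7)
  n <- 150                                            # ~1.1e4 pairs
  g <- matrix(0, n, n)
  g[upper.tri(g)] <- rnorm(sum(upper.tri(g)))
  g <- g + t(g)
  frac <- nrow(strong_pairs(g)) / sum(upper.tri(g))
  expect_equal(frac, 0.023, tolerance = 0.35)
})

test_that("DCC separates direct from indirect coupling on a chain", {
  net <- gen_network_traces(chain_coupling(3, 0.8), frames = 4000, seed = 7)
  r <- pearson_matrix(net$traces)
  d <- dcc_matrix(net$traces, lambda = 0)
  expect_equal(r[1, 3], 0.64, tolerance = 0.1)        # indirect survives in r
  expect_lt(abs(d[1, 3]), 0.1)                        # but not in DCC
  expect_gt(d[1, 2], 5 * abs(d[1, 3]))
  expect_gt(d[2, 3], 5 * abs(d[1, 3]))
  # 4-node chain: both skip-one pairs conditionally independent
  net4 <- gen_network_traces(chain_coupling(4, 0.7), frames = 4000, seed = 8)
  d4 <- dcc_matrix(net4$traces, lambda = 0)
  expect_lt(max(abs(c(d4[1, 3], d4[2, 4], d4[1, 4]))), 0.1)
  r4 <- pearson_matrix(net4$traces)
  expect_equal(r4[1, 3], 0.49, tolerance = 0.1)       # 0.7^2 along the path
})

test_that("DCC: affine invariance, shrinkage limit, independence", {
  net <- gen_network_traces(chain_coupling(5, 0.5), frames = 1500, seed = 3)
  d1 <- dcc_matrix(net$traces, lambda = 0.05)
  scaled <- net$traces
  scl <- seq(0.2, 5, length.out = 5)
  scaled$dff <- scaled$dff * scl + 7                  # per-neuron affine map
  expect_equal(dcc_matrix(scaled, lambda = 0.05), d1, tolerance = 1e-9)
  expect_equal(max(abs(dcc_matrix(net$traces, lambda = 1))), 0)
  # diagonal truth: all DCC near zero
  n0 <- gen_network_traces(matrix(0, 15, 15), frames = 4000, seed = 5)
  d0 <- dcc_matrix(n0$traces)
  expect_lt(mean(abs(d0[upper.tri(d0)])), 0.05)
  # singular covariance without shrinkage is an instructive error
  few <- matrix(rnorm(20 * 10), 20, 10)
  expect_error(dcc_matrix(few, lambda = 0), "lambda")
})

test_that("|DCC| ranking recovers planted edges (and the AUC oracle agrees)", {
  aucs <- vapply(1:3, function(s) {
    C <- random_coupling_graph(50, density = 0.1, coupling = 0.3, seed = s)
    net <- gen_network_traces(C, frames = 4000, seed = s + 50)
    d <- dcc_matrix(net$traces)
    a <- edge_recovery_auc(d, C)
    up <- upper.tri(d)
    expect_equal(a, brute_auc(abs(d[up]), C[up] != 0), tolerance = 1e-12)
    a
  }, numeric(1))
  expect_gte(mean(aucs), 0.9)
})

test_that("scope masks split pairs by layer", {
  layer <- c("L2/3", "L2/3", "L5a", "L5a")
  within23 <- scope_mask(layer, "L2/3")
  cross <- scope_mask(layer, "cross")
  expect_true(within23[1, 2] && !within23[1, 3] && !within23[3, 4])
  expect_true(cross[1, 3] && !cross[1, 2] && !cross[3, 4])
  expect_false(any(diag(within23)) || any(diag(cross)))
  # every off-diagonal pair is in exactly one within/cross scope
  all_m <- scope_mask(layer, "L2/3") | scope_mask(layer, "L5a") | cross
  expect_equal(all_m, scope_mask(layer, "all"))
})

test_that("proximity ratio measures distance-dependent direct coupling", {
  expect_equal(proximity_ratio(rep(0.2, 50), c(rep(50, 25), rep(150, 25)))$ratio, 1)
  expect_equal(proximity_ratio(c(rep(0.2, 5), rep(0.1, 5)),
                               c(rep(50, 5), rep(150, 5)))$ratio, 2)
  expect_error(proximity_ratio(0.2, 300), "undefined")
  # distance-decaying couplings give ratio > 1; flat couplings give ~1
  set.seed(11)
  n <- 40
  cen <- matrix(runif(2 * n, 0, 250), n, 2)
  D <- as.matrix(dist(cen))
  ratios <- vapply(c(decay = TRUE, flat = FALSE), function(dec) {
    C <- matrix(0, n, n)
    C[upper.tri(C)] <- 0.3 * (if (dec)
      (D[upper.tri(D)] < 100) else (runif(sum(upper.tri(D))) < 0.3))
    C <- C + t(C)
    net <- gen_network_traces(C, frames = 3000, centroid = cen,
                              seed = 17 + dec)
    pr <- pair_records(pearson_matrix(net$traces),
                       dcc_matrix(net$traces), cen, pixel_size = 1)
    proximity_ratio(pr$dcc, pr$distance_um)$ratio
  }, numeric(1))
  expect_gt(ratios["decay"], 1.3)
  expect_equal(unname(ratios["flat"]), 1, tolerance = 0.35)
})
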