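# Independent oracles and small utilities shared by the tests.

# Brute-force ROC AUC by pair counting (independent of the rank formula
# used in the package).
brute_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Greedy onset matching with a frame tolerance; returns number matched.
match_onsets <- function(true_f, det_f, tol = 2) {
  n <- 0L
  det <- det_f
  for (t in true_f) {
    if (!length(det)) break
    d <- abs(det - t)
    if (min(d) <= tol) {
      n <- n + 1L
      det <- det[-which.min(d)]
    }
  }
  n
}

# Identity-matching accuracy of a registration map against planted truth:
# fraction of non-dropped neurons assigned their true per-day id.
identity_accuracy <- function(reg, truth) {
  im <- truth$identity_map
  days <- 2:ncol(im)
  mean(vapply(days, function(d) {
    present <- !is.na(im[, d])
    got <- reg$identity[im[present, 1], d]
    mean(!is.na(got) & got == im[present, d])
  }, numeric(1)))
}

# Translate an image matrix by integer (dx, dy): content moves +dx columns
# (x) and +dy rows (y), zero fill.
translate_image <- function(img, dx, dy) {
  n_r <- nrow(img); n_c <- ncol(img)
  out <- matrix(0, n_r, n_c)
  src_r <- seq_len(n_r) - dy
  src_c <- seq_len(n_c) - dx
  ok_r <- src_r >= 1 & src_r <= n_r
  ok_c <- src_c >= 1 & src_c <= n_c
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

# Closed-form excess kurtosis of the discrete uniform over 1..n.
discrete_uniform_kurtosis <- function(n) -(6 / 5) * (n^2 + 1) / (n^2 - 1)
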