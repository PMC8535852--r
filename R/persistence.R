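# Pair persistence: how many days the same directly-correlated neuron pair
# recurs, and the shape (kurtosis) of the persistence distribution.

#' Directly-correlated pair sets per day
#'
#' For each day's DCC matrix (rows/columns indexed in the shared
#' tracked-neuron id space from the registration map), selects the pairs
#' passing the direct-correlation threshold rule: |DCC| greater than the
#' mean plus two SD of the off-diagonal |DCC| in scope — the same rule used
#' for strong Pearson pairs, applied to magnitudes.
#'
#' @param dcc_by_day List of symmetric DCC matrices, one per day, all the
#'   same dimension (tracked neurons).  Entries involving neurons absent on
#'   a day should be `NA` and are never selected.
#' @param scope Optional logical pair mask (see [scope_mask()]).
#' @return List of data.frames (`i`, `j`) of detected pairs per day.
#' @export
detected_pairs_per_day <- function(dcc_by_day, scope = NULL) {
  lapply(dcc_by_day, function(m) {
    m <- as.matrix(m)
    if (nrow(m) < 2L) stop("a day has fewer than 2 tracked neurons")
    sel <- upper.tri(m) & !is.na(m)
    if (!is.null(scope)) sel <- sel & scope
    vals <- abs(m[sel])
    if (length(vals) < 2L || stats::sd(vals) == 0)
      return(data.frame(i = integer(), j = integer()))
    thr <- mean(vals) + 2 * stats::sd(vals)
    keep <- sel & abs(m) > thr
    idx <- which(keep, arr.ind = TRUE)
    out <- data.frame(i = idx[, 1], j = idx[, 2])
    out[order(out$i, out$j), , drop = FALSE]
  })
}

#' Persistence histogram of detected pairs
#'
#' For every pair detected on at least one day, counts the number of days
#' it was detected, and normalises the counts over 1..n_days to fractions.
#' Pairs never detected are excluded (the histogram describes detected
#' pairs only).
#'
#' @param pair_sets List of per-day pair data.frames (`i`, `j`), e.g. from
#'   [detected_pairs_per_day()].
#' @param n_days Number of days covered (>= 1).
#' @return Object of class `persistence_profile`: list with `counts`
#'   (named integer vector over 1..n_days), `fraction` (sums to 1),
#'   `n_pairs`, `days_per_pair` (integer vector, one entry per pair).
#' @export
persistence_histogram <- function(pair_sets, n_days = length(pair_sets)) {
  if (n_days < 1L) stop("`n_days` must be >= 1")
  keys <- unlist(lapply(pair_sets, function(p) paste(p$i, p$j, sep = "-")))
  if (length(keys) == 0L)
    stop("no pairs detected on any day: persistence profile is empty")
  tab <- table(keys)
  days_per_pair <- as.integer(tab)
  counts <- vapply(seq_len(n_days), function(k) sum(days_per_pair == k),
                   integer(1))
  names(counts) <- seq_len(n_days)
  structure(list(counts = counts, fraction = counts / sum(counts),
                 n_pairs = sum(counts), days_per_pair = days_per_pair),
            class = "persistence_profile")
}

#' @export
print.persistence_profile <- function(x, ...) {
  cat("persistence_profile:", x$n_pairs, "pairs over",
      length(x$counts), "days\n")
  print(x$fraction)
  invisible(x)
}

#' Excess kurtosis of the persistence histogram
#'
#' Fisher (excess) kurtosis of the detection-day distribution, treating
#' the histogram as a weighted sample: with weights w_k on day-counts k,
#' g2 = m4 / m2^2 - 3 computed from the weighted central moments.  A
#' uniform histogram over n counts gives the discrete-uniform value
#' -(6/5)(n^2 + 1)/(n^2 - 1) (about -1.2); heavier concentration at one
#' count with a thin tail gives larger values.
#'
#' @param profile A `persistence_profile` (or a plain nonnegative weight
#'   vector over day-counts 1..n).
#' @return Excess kurtosis (scalar).
#' @export
histogram_kurtosis <- function(profile) {
  w <- if (inherits(profile, "persistence_profile")) profile$fraction else
    profile / sum(profile)
  v <- seq_along(w)
  if (sum(w > 0) < 2L)
    stop("kurtosis undefined for a single-bin persistence distribution")
  if (sum(w > 0) < 4L)
    warning("fewer than 4 distinct day-counts with mass; kurtosis is unstable")
  mu <- sum(w * v)
  m2 <- sum(w * (v - mu)^2)
  m4 <- sum(w * (v - mu)^4)
  m4 / m2^2 - 3
}
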