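# Pairwise functional connectivity: Pearson and maximum-entropy direct
# correlation (partial correlation), strong pairs, proximity bias.

#' Pearson correlation matrix over a frame block
#'
#' Standard zero-lag Pearson correlation between every pair of neuron
#' traces, restricted to `block` frames.  Pearson connectivity mixes direct
#' coupling with shared afferent input; compare [dcc_matrix()].
#' Zero-variance neurons make the correlation undefined and are rejected
#' with an informative error.
#'
#' @param traces A `trace_matrix` (or plain neurons x frames matrix).
#' @param block Optional integer frame indices (default: all frames).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(traces, block = NULL) {
  x <- if (inherits(traces, "trace_matrix")) traces$dff else as.matrix(traces)
  if (!is.null(block)) x <- x[, block, drop = FALSE]
  if (ncol(x) < 3L) stop("block must contain at least 3 frames")
  v <- apply(x, 1, stats::sd)
  if (any(v == 0))
    stop("zero-variance neuron(s) in block: ",
         paste(which(v == 0), collapse = ", "),
         "; exclude them before correlating")
  if (nrow(x) < 2L) stop("need at least 2 neurons")
  stats::cor(t(x))
}

#' Direct correlation (DCC) matrix
#'
#' Maximum-entropy estimate of direct pairwise coupling for continuous
#' data: under the pairwise maximum-entropy (Gaussian) model, the direct
#' correlation between neurons i and j is the partial correlation
#' -P_ij / sqrt(P_ii P_jj), where P is the inverse of the (shrunk) sample
#' covariance.  Shrinkage Sigma <- (1 - lambda) Sigma + lambda diag(Sigma)
#' conditions the inversion when frames are scarce relative to neurons.
#' The estimate is invariant to per-neuron affine rescaling of the traces.
#'
#' @param traces A `trace_matrix` or neurons x frames matrix.
#' @param block Optional frame indices.
#' @param lambda Shrinkage weight in [0, 1] (default 0.05).  At
#'   `lambda = 1` the precision is diagonal and the DCC matrix is zero.
#' @return Symmetric matrix of direct correlation coefficients, zero
#'   diagonal, entries in [-1, 1].
#' @export
dcc_matrix <- function(traces, block = NULL, lambda = 0.05) {
  if (lambda < 0 || lambda > 1) stop("`lambda` must lie in [0, 1]")
  x <- if (inherits(traces, "trace_matrix")) traces$dff else as.matrix(traces)
  if (!is.null(block)) x <- x[, block, drop = FALSE]
  if (ncol(x) <= nrow(x) && lambda == 0)
    stop("fewer frames than neurons: the sample covariance is singular; ",
         "use shrinkage (lambda > 0)")
  S <- stats::cov(t(x))
  if (any(diag(S) == 0))
    stop("zero-variance neuron(s): ", paste(which(diag(S) == 0), collapse = ", "))
  Sh <- (1 - lambda) * S + lambda * diag(diag(S))
  P <- tryCatch(solve(Sh), error = function(e)
    stop("covariance inversion failed (", conditionMessage(e),
         "); increase the shrinkage `lambda`", call. = FALSE))
  d <- sqrt(diag(P))
  D <- -P / (d %o% d)
  diag(D) <- 0
  (D + t(D)) / 2
}

#' Scope mask for neuron pairs
#'
#' Logical matrix marking the pairs belonging to a connectivity scope:
#' within one layer, or across the two layers.
#'
#' @param layer Character vector of per-neuron layer labels.
#' @param scope `"all"`, `"cross"`, or a layer label for within-layer pairs.
#' @return Symmetric logical matrix (diagonal FALSE).
#' @export
scope_mask <- function(layer, scope = "all") {
  n <- length(layer)
  m <- if (identical(scope, "all")) {
    matrix(TRUE, n, n)
  } else if (identical(scope, "cross")) {
    outer(layer, layer, `!=`)
  } else {
    outer(layer == scope, layer == scope, `&`)
  }
  diag(m) <- FALSE
  m
}

#' Strong pairs: mean + 2 SD rule
#'
#' Pairs whose connectivity value strictly exceeds the mean plus two
#' standard deviations of all off-diagonal values in scope.  With
#' `use_abs = TRUE` the rule is applied to |values| (the convention used
#' for direct correlations, whose sign is not thresholded).
#'
#' @param mat Symmetric connectivity matrix (Pearson or DCC).
#' @param scope Optional symmetric logical mask of in-scope pairs (see
#'   [scope_mask()]); default all off-diagonal pairs.
#' @param use_abs Threshold |values| instead of signed values.
#' @return data.frame (`i`, `j`, `value`) of selected pairs, i < j, with
#'   `attr(, "threshold")`.  Zero SD yields an empty set.
#' @export
strong_pairs <- function(mat, scope = NULL, use_abs = FALSE) {
  mat <- as.matrix(mat)
  v <- if (use_abs) abs(mat) else mat
  sel <- upper.tri(mat)
  if (!is.null(scope)) sel <- sel & scope
  vals <- v[sel]
  if (length(vals) < 2L) stop("need at least 2 off-diagonal values in scope")
  thr <- mean(vals) + 2 * stats::sd(vals)
  keep <- sel & v > thr & !is.na(thr)
  if (stats::sd(vals) == 0) keep[] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  out <- data.frame(i = idx[, 1], j = idx[, 2], value = mat[keep])
  out <- out[order(out$i, out$j), ]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Pair records: connectivity and physical distance per neuron pair
#'
#' Combines Pearson and direct correlations with the Euclidean centroid
#' separation (in microns) and strong-pair flags for every in-scope pair.
#'
#' @param r_mat Pearson matrix from [pearson_matrix()].
#' @param dcc_mat DCC matrix from [dcc_matrix()].
#' @param centroid Neurons x 2 matrix of (x, y) pixel centroids.
#' @param pixel_size Microns per pixel.
#' @param layer Optional per-neuron layer labels.
#' @param scope Scope passed to [scope_mask()] when `layer` is given.
#' @return data.frame: `i`, `j`, `scope`, `r`, `dcc`, `distance_um`,
#'   `strong_r`, `strong_dcc`.
#' @export
pair_records <- function(r_mat, dcc_mat, centroid, pixel_size = 1,
                         layer = NULL, scope = "all") {
  n <- nrow(r_mat)
  mask <- if (is.null(layer)) {
    m <- matrix(TRUE, n, n); diag(m) <- FALSE; m
  } else scope_mask(layer, scope)
  sp_r <- strong_pairs(r_mat, mask)
  sp_d <- strong_pairs(dcc_mat, mask, use_abs = TRUE)
  sel <- upper.tri(r_mat) & mask
  idx <- which(sel, arr.ind = TRUE)
  dx <- (centroid[idx[, 1], 1] - centroid[idx[, 2], 1]) * pixel_size
  dy <- (centroid[idx[, 1], 2] - centroid[idx[, 2], 2]) * pixel_size
  key <- function(i, j) paste(i, j)
  data.frame(i = idx[, 1], j = idx[, 2],
             scope = if (is.null(layer)) "all" else scope,
             r = r_mat[sel], dcc = dcc_mat[sel],
             distance_um = sqrt(dx^2 + dy^2),
             strong_r = key(idx[, 1], idx[, 2]) %in% key(sp_r$i, sp_r$j),
             strong_dcc = key(idx[, 1], idx[, 2]) %in% key(sp_d$i, sp_d$j))
}

#' Proximity ratio DCC100 / DCC200
#'
#' Mean |DCC| over pairs closer than `near_max` microns divided by mean
#' |DCC| over pairs between `near_max` and `far_max` microns.  A ratio
#' above 1 indicates proximity bias: physically near pairs are more
#' directly coupled.
#'
#' @param dcc Numeric vector of direct correlations per pair.
#' @param distance_um Pair distances in microns.
#' @param near_max Near-bin upper edge, microns (default 100).
#' @param far_max Far-bin upper edge, microns (default 200).
#' @return List: `ratio`, `dcc_near`, `dcc_far`, `n_near`, `n_far`.
#' @export
proximity_ratio <- function(dcc, distance_um, near_max = 100, far_max = 200) {
  near <- distance_um < near_max
  far <- distance_um >= near_max & distance_um < far_max
  if (!any(near) || !any(far))
    stop("proximity ratio undefined: bin counts near=", sum(near),
         " far=", sum(far))
  dn <- mean(abs(dcc[near])); df <- mean(abs(dcc[far]))
  list(ratio = dn / df, dcc_near = dn, dcc_far = df,
       n_near = sum(near), n_far = sum(far))
}

# rank-based AUC (Mann-Whitney)
rank_auc <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Planted-edge recovery AUC
#'
#' How well ranking neuron pairs by |DCC| recovers the edges of a planted
#' coupling graph: the area under the ROC curve of |DCC| as a score for
#' "pair is a true edge" (Mann-Whitney formulation).
#'
#' @param dcc_mat DCC matrix.
#' @param true_coupling Planted coupling matrix (nonzero = edge).
#' @return AUC in [0, 1].
#' @export
edge_recovery_auc <- function(dcc_mat, true_coupling) {
  up <- upper.tri(dcc_mat)
  rank_auc(abs(dcc_mat[up]), true_coupling[up] != 0)
}
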