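# Cross-day registration: render neuron-distribution images, exhaustive
# integer shift search, identity matching.

#' Render an ROI distribution image
#'
#' Each neuron contributes an isotropic bivariate normal peak centred at
#' its centroid with maximum height `peak_height` and standard deviation
#' `sd_px` (about the radius of a neuron at this magnification), summed on
#' a `field_px` x `field_px` grid — the same size as the raw imaging frame.
#'
#' @param rois data.frame with columns `x_px`, `y_px` (and optionally `id`).
#' @param field_px Image side in pixels (default 512).
#' @param peak_height Peak height per neuron (default 1.0).
#' @param sd_px Peak SD in pixels (default 5).
#' @return `field_px` x `field_px` numeric matrix; rows index y, columns x.
#'   An empty table gives the zero image.
#' @export
render_roi_image <- function(rois, field_px = 512, peak_height = 1.0,
                             sd_px = 5) {
  if (sd_px <= 0) stop("`sd_px` must be positive")
  img <- matrix(0, field_px, field_px)
  if (is.null(rois) || nrow(rois) == 0L) return(img)
  half <- ceiling(4 * sd_px)
  for (k in seq_len(nrow(rois))) {
    x0 <- rois$x_px[k]; y0 <- rois$y_px[k]
    xs <- max(1L, floor(x0 - half)):min(field_px, ceiling(x0 + half))
    ys <- max(1L, floor(y0 - half)):min(field_px, ceiling(y0 + half))
    if (!length(xs) || !length(ys)) next
    gx <- exp(-(xs - x0)^2 / (2 * sd_px^2))
    gy <- exp(-(ys - y0)^2 / (2 * sd_px^2))
    img[ys, xs] <- img[ys, xs] + peak_height * (gy %o% gx)
  }
  img
}

# FFT cross-correlation of B (N x N) with A (n x n) zero-padded:
# returns matrix M where M[i, j] = sum_uv B[u + i - 1, v + j - 1] * A[u, v]
xcorr_valid <- function(B, A, out_rows, out_cols) {
  N1 <- nrow(B); N2 <- ncol(B)
  Ap <- matrix(0, N1, N2)
  Ap[seq_len(nrow(A)), seq_len(ncol(A))] <- A
  cc <- Re(stats::fft(stats::fft(B) * Conj(stats::fft(Ap)),
                      inverse = TRUE)) / (N1 * N2)
  cc[seq_len(out_rows), seq_len(out_cols), drop = FALSE]
}

#' Exhaustive shift search between two ROI images
#'
#' The reference image is padded with a border of `ws` pixels on each side
#' and the Pearson correlation between `image` and the reference window is
#' evaluated at every integer offset in [-ws, ws]^2, giving a
#' (2 ws + 1) x (2 ws + 1) correlation-score matrix (81 x 81 at the default
#' ws = 40).  The offset with the highest score is the estimated
#' field-of-view shift; a well-registered pair yields a sparse score matrix
#' with a single sharp peak (the peak score is returned for QC).  Ties are
#' broken toward the smallest shift magnitude, then lexicographically by
#' (dx, dy).
#'
#' Sign convention: the returned (dx, dy) satisfies
#' image ~= reference translated by +dx columns (x) and +dy rows (y), so
#' subtracting (dx, dy) from the later day's centroids aligns them to the
#' reference.
#'
#' @param ref_image,image Equal-sized square numeric matrices (rows = y).
#' @param ws Search half-width in pixels (default 40).
#' @return List: `dx`, `dy`, `score` (peak correlation), `matrix` (the
#'   score matrix, dimnames = shifts).
#' @export
find_shift <- function(ref_image, image, ws = 40) {
  if (!all(dim(ref_image) == dim(image)))
    stop("images must have identical dimensions")
  n_r <- nrow(image); n_c <- ncol(image)
  if (ws < 0 || ws >= min(n_r, n_c)) stop("`ws` must be in [0, image size)")
  side <- 2L * ws + 1L
  B <- matrix(0, n_r + 2L * ws, n_c + 2L * ws)
  B[ws + seq_len(n_r), ws + seq_len(n_c)] <- ref_image
  ones <- matrix(1, n_r, n_c)
  npix <- n_r * n_c
  sA <- sum(image); ssA <- sum(image^2)
  varA <- ssA - sA^2 / npix
  cross <- xcorr_valid(B, image, side, side)
  s1 <- xcorr_valid(B, ones, side, side)
  s2 <- xcorr_valid(B^2, ones, side, side)
  varB <- pmax(s2 - s1^2 / npix, 0)
  num <- cross - s1 * sA / npix
  den <- sqrt(varB * varA)
  score <- ifelse(den > 0, num / den, NA_real_)
  # offset (i, j) in score corresponds to shift (dy, dx) = ws + 1 - (i, j):
  # window at top-left contains the reference moved down/right by ws.
  shifts <- ws + 1L - seq_len(side)
  dimnames(score) <- list(dy = shifts, dx = shifts)
  best <- which(score == max(score, na.rm = TRUE), arr.ind = TRUE)
  dy <- shifts[best[, 1]]; dx <- shifts[best[, 2]]
  ord <- order(dx^2 + dy^2, dx, dy)
  list(dx = dx[ord[1]], dy = dy[ord[1]],
       score = max(score, na.rm = TRUE), matrix = score)
}

#' Match neuron identities between two days
#'
#' Shift-corrects the later day's centroids and greedily matches each
#' reference neuron to the nearest candidate within `tol_px` pixels
#' (ascending distance; each candidate is consumed at most once; if
#' several candidates fall within tolerance the closest wins).  Reference
#' neurons with no candidate within tolerance are recorded as absent.
#'
#' @param ref_rois,rois data.frames with columns `id`, `x_px`, `y_px`.
#' @param shift List or vector with `dx`, `dy` (from [find_shift()] or
#'   ground truth).
#' @param tol_px Matching tolerance in pixels (default 5, inclusive).
#' @return data.frame: `ref_id`, `matched_id` (NA if absent), `distance_px`.
#' @export
match_neurons <- function(ref_rois, rois, shift = list(dx = 0, dy = 0),
                          tol_px = 5) {
  n_ref <- nrow(ref_rois); n_cand <- nrow(rois)
  out <- data.frame(ref_id = ref_rois$id, matched_id = NA_integer_,
                    distance_px = NA_real_)
  if (n_ref == 0L || n_cand == 0L) return(out)
  cx <- rois$x_px - shift$dx
  cy <- rois$y_px - shift$dy
  D <- sqrt(outer(ref_rois$x_px, cx, `-`)^2 + outer(ref_rois$y_px, cy, `-`)^2)
  cand <- which(D <= tol_px, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(out)
  cand <- cand[order(D[cand]), , drop = FALSE]
  used_ref <- logical(n_ref); used_cand <- logical(n_cand)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used_ref[i] || used_cand[j]) next
    used_ref[i] <- TRUE; used_cand[j] <- TRUE
    out$matched_id[i] <- rois$id[j]
    out$distance_px[i] <- D[i, j]
  }
  out
}

#' Track neurons across days
#'
#' Day 1 is the reference: for every later day the field shift is found by
#' [find_shift()] on rendered ROI images and identities are matched with
#' [match_neurons()].  A neuron's tracked set is the days on which it
#' matched (day 1 always included).
#'
#' @param tables List of per-day ROI data.frames (`id`, `x_px`, `y_px`),
#'   length >= 2.
#' @param ws Shift-search half-width (default 40).
#' @param tol_px Matching tolerance (default 5).
#' @param field_px,sd_px Rendering parameters, see [render_roi_image()].
#' @return Object of class `registration_map`: list with `shifts`
#'   (data.frame day, dx, dy, score), `identity` (reference neurons x days
#'   matrix of per-day ids, NA where absent), `fraction_all_days`.
#' @export
track_across_days <- function(tables, ws = 40, tol_px = 5, field_px = 512,
                              sd_px = 5) {
  if (length(tables) < 2L) stop("need at least 2 days of ROI tables")
  n_days <- length(tables)
  ref <- tables[[1L]]
  ref_img <- render_roi_image(ref, field_px, sd_px = sd_px)
  shifts <- data.frame(day = seq_len(n_days), dx = 0L, dy = 0L, score = 1)
  identity <- matrix(NA_integer_, nrow(ref), n_days)
  identity[, 1L] <- ref$id
  for (d in 2:n_days) {
    img <- render_roi_image(tables[[d]], field_px, sd_px = sd_px)
    sh <- find_shift(ref_img, img, ws)
    shifts$dx[d] <- sh$dx; shifts$dy[d] <- sh$dy; shifts$score[d] <- sh$score
    m <- match_neurons(ref, tables[[d]], sh, tol_px)
    identity[, d] <- m$matched_id
  }
  structure(list(shifts = shifts, identity = identity,
                 fraction_all_days = mean(rowSums(!is.na(identity)) == n_days)),
            class = "registration_map")
}

#' @export
print.registration_map <- function(x, ...) {
  cat("registration_map:", ncol(x$identity), "days,", nrow(x$identity),
      "reference neurons;", round(100 * x$fraction_all_days, 1),
      "% tracked on all days\n")
  invisible(x)
}
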