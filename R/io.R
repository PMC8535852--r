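# Delimited-text readers and writers for the core types.
# Schemas:
#   paw table:   frame, left_x, left_y, right_x, right_y   (pixels)
#   trace table: neuron, layer, x_px, y_px, f1..fT          (dF/F)
#   roi table:   day, id, x_px, y_px
# Each writer emits plain CSV; trace tables carry a JSON sidecar
# (<path>.meta.json) holding frame_rate and pixel_size.

# locate the first non-numeric cell in required columns and report it
check_numeric_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("file ", path, " is missing column(s): ", paste(miss, collapse = ", "))
  for (cl in cols) {
    v <- df[[cl]]
    if (is.numeric(v)) next
    conv <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(conv) & !is.na(v) & v != "NA")
    if (length(bad))
      stop("file ", path, ": non-numeric value '", v[bad[1]],
           "' in column '", cl, "', row ", bad[1])
    df[[cl]] <- conv
  }
  df
}

#' Read and write paw-trajectory tables
#'
#' CSV with columns `frame`, `left_x`, `left_y`, `right_x`, `right_y`
#' (pixel units).  Schema violations are reported with the offending row
#' and column.
#'
#' @param path File path.
#' @param frame_rate Video frame rate, Hz.
#' @return `read_paws`: list with `left` and `right` `paw_trajectory`
#'   objects.
#' @export
read_paws <- function(path, frame_rate = video_frame_rate()) {
  df <- as.data.frame(data.table::fread(path, colClasses = "character"))
  df <- check_numeric_cols(df, c("frame", "left_x", "left_y",
                                 "right_x", "right_y"), path)
  if (is.unsorted(df$frame)) df <- df[order(df$frame), ]
  list(left = paw_trajectory(df$left_x, df$left_y, frame_rate, "left"),
       right = paw_trajectory(df$right_x, df$right_y, frame_rate, "right"))
}

#' @rdname read_paws
#' @param left,right `paw_trajectory` objects of equal length.
#' @export
write_paws <- function(left, right, path) {
  stopifnot(length(left$x_raw) == length(right$x_raw))
  data.table::fwrite(data.frame(frame = seq_along(left$x_raw),
                                left_x = left$x_raw, left_y = left$y_raw,
                                right_x = right$x_raw, right_y = right$y_raw),
                     path)
  invisible(path)
}

#' Read and write calcium trace tables
#'
#' CSV with columns `neuron`, `layer`, `x_px`, `y_px` followed by one
#' column per frame (`f1`..`fT`); frame rate and pixel size travel in a
#' JSON sidecar `<path>.meta.json`.
#'
#' @param path File path.
#' @return `read_traces`: a `trace_matrix`.
#' @export
read_traces <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  fcols <- grep("^f[0-9]+$", names(df), value = TRUE)
  if (!length(fcols)) stop("file ", path, " has no frame columns f1..fT")
  df <- check_numeric_cols(df, c("x_px", "y_px", fcols), path)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else
    list(frame_rate = imaging_frame_rate(), pixel_size = 1)
  dff <- as.matrix(df[, fcols[order(as.integer(sub("^f", "", fcols)))]])
  dimnames(dff) <- NULL
  layer <- if ("layer" %in% names(df) && !all(is.na(df$layer)))
    as.character(df$layer) else NULL
  trace_matrix(dff, as.numeric(meta$frame_rate), layer,
               cbind(x = df$x_px, y = df$y_px),
               as.numeric(meta$pixel_size))
}

#' @rdname read_traces
#' @param traces A `trace_matrix`.
#' @export
write_traces <- function(traces, path) {
  n <- nrow(traces$dff)
  cen <- if (is.null(traces$centroid)) matrix(NA_real_, n, 2) else traces$centroid
  df <- data.frame(neuron = seq_len(n),
                   layer = if (is.null(traces$layer)) NA_character_ else traces$layer,
                   x_px = cen[, 1], y_px = cen[, 2])
  fr <- as.data.frame(traces$dff)
  names(fr) <- paste0("f", seq_len(ncol(traces$dff)))
  data.table::fwrite(cbind(df, fr), path)
  jsonlite::write_json(list(frame_rate = traces$frame_rate,
                            pixel_size = traces$pixel_size),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read and write multi-day ROI tables
#'
#' CSV with columns `day`, `id`, `x_px`, `y_px`.
#'
#' @param path File path.
#' @return `read_rois`: list of per-day data.frames (`id`, `x_px`, `y_px`),
#'   ordered by day.
#' @export
read_rois <- function(path) {
  df <- as.data.frame(data.table::fread(path, colClasses = "character"))
  df <- check_numeric_cols(df, c("day", "id", "x_px", "y_px"), path)
  days <- sort(unique(df$day))
  lapply(days, function(d) {
    sub <- df[df$day == d, c("id", "x_px", "y_px")]
    rownames(sub) <- NULL
    sub
  })
}

#' @rdname read_rois
#' @param rois List of per-day data.frames (`id`, `x_px`, `y_px`).
#' @export
write_rois <- function(rois, path) {
  df <- do.call(rbind, lapply(seq_along(rois), function(d)
    cbind(day = d, rois[[d]])))
  data.table::fwrite(df, path)
  invisible(path)
}
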