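#' ROI-by-time BOLD time series
#'
#' Container for a region-of-interest by frame BOLD matrix together with its
#' sampling interval and identity. All frame indices exposed by the package
#' are 0-based and refer to positions in the original acquisition;
#' `frame_offset` records how many original frames precede column 1 (it is
#' updated by [trim_frames()]), so event frames always map back to scanner
#' time.
#'
#' @param data numeric matrix, one row per ROI, one column per frame (BOLD,
#'   arbitrary units). No missing values.
#' @param tr repetition time in seconds (> 0).
#' @param roi_ids optional character vector of ROI labels.
#' @param subject_id,run_id optional identity labels.
#' @param frame_offset 0-based index of the first retained frame in the
#'   original acquisition.
#' @return an object of class `roi_ts`.
#' @export
roi_timeseries <- function(data, tr, roi_ids = NULL, subject_id = NA_character_,
                           run_id = NA_character_, frame_offset = 0L) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (anyNA(data)) stop("roi_timeseries: data contains missing values")
  if (ncol(data) < 1L) stop("roi_timeseries: at least one frame required")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("roi_timeseries: tr must be a positive scalar (seconds)")
  if (is.null(roi_ids)) roi_ids <- paste0("roi", seq_len(nrow(data)))
  if (length(roi_ids) != nrow(data))
    stop("roi_timeseries: roi_ids length must match row count")
  structure(list(data = data, tr = tr, roi_ids = as.character(roi_ids),
                 subject_id = subject_id, run_id = run_id,
                 frame_offset = as.integer(frame_offset)),
            class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> %d ROIs x %d frames, TR %.3g s", nrow(x$data), ncol(x$data), x$tr))
  if (!is.na(x$subject_id)) cat(sprintf(", subject %s", x$subject_id))
  if (!is.na(x$run_id)) cat(sprintf(", run %s", x$run_id))
  if (x$frame_offset > 0L) cat(sprintf(", frame offset %d", x$frame_offset))
  cat("\n")
  invisible(x)
}

#' @export
dim.roi_ts <- function(x) dim(x$data)

#' Read / write ROI matrices as TSV
#'
#' The on-disk layout is tab-delimited: one row per ROI, first column the ROI
#' label, remaining columns frames with a header row of 0-based frame
#' indices (`f0`, `f1`, ...). A JSON sidecar `<path>.json` carries `tr`,
#' identity and the frame offset; when absent, `tr` must be supplied.
#'
#' @param path file path of the TSV.
#' @param tr repetition time in seconds, used if no sidecar is found.
#' @param subject_id,run_id identity labels, used if no sidecar is found.
#' @return [read_roi_tsv()] returns a [roi_timeseries()]; [write_roi_tsv()]
#'   returns `path` invisibly.
#' @export
read_roi_tsv <- function(path, tr = NULL, subject_id = NA_character_,
                         run_id = NA_character_) {
  if (!file.exists(path)) stop("read_roi_tsv: no such file: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("read_roi_tsv: file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != ncols[1L]))
    stop(sprintf("read_roi_tsv: ragged rows in %s (row %d has %d fields, expected %d)",
                 path, which(ncols != ncols[1L])[1L], ncols[ncols != ncols[1L]][1L], ncols[1L]))
  header <- fields[[1L]]
  body <- fields[-1L]
  roi_ids <- vapply(body, `[`, "", 1L)
  vals <- vapply(body, function(f) {
    v <- suppressWarnings(as.numeric(f[-1L]))
    if (anyNA(v)) stop("read_roi_tsv: non-numeric cell in ROI row '", f[1L], "' of ", path)
    v
  }, numeric(length(header) - 1L))
  mat <- t(vals)
  offset <- suppressWarnings(as.integer(sub("^f", "", header[2L])))
  if (is.na(offset)) offset <- 0L
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  tr <- if (!is.null(meta$tr)) meta$tr else tr
  if (is.null(tr)) stop("read_roi_tsv: tr not given and no sidecar found for ", path)
  roi_timeseries(mat, tr = tr, roi_ids = roi_ids,
                 subject_id = if (!is.null(meta$subject_id)) meta$subject_id else subject_id,
                 run_id = if (!is.null(meta$run_id)) meta$run_id else run_id,
                 frame_offset = if (!is.null(meta$frame_offset)) meta$frame_offset else offset)
}

#' @param ts a [roi_timeseries()] object.
#' @param sidecar write the JSON metadata sidecar (default `TRUE`).
#' @rdname read_roi_tsv
#' @export
write_roi_tsv <- function(ts, path, sidecar = TRUE) {
  stopifnot(inherits(ts, "roi_ts"))
  frames <- seq_len(ncol(ts$data)) - 1L + ts$frame_offset
  header <- paste(c("roi_id", paste0("f", frames)), collapse = "\t")
  rows <- vapply(seq_len(nrow(ts$data)), function(i)
    paste(c(ts$roi_ids[i], format(ts$data[i, ], digits = 17L, scientific = TRUE, trim = TRUE)),
          collapse = "\t"), "")
  writeLines(c(header, rows), path)
  if (sidecar)
    jsonlite::write_json(list(tr = ts$tr, subject_id = ts$subject_id, run_id = ts$run_id,
                              frame_offset = ts$frame_offset),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read / write rigid-body motion parameters
#'
#' Plain whitespace-delimited text with six columns per frame: three
#' translations (mm) followed by three rotations (radians), the layout
#' produced by standard realignment tools.
#'
#' @param path file path.
#' @return [read_motion()] returns a numeric frames x 6 matrix of class
#'   `motion_trace`.
#' @export
read_motion <- function(path) {
  if (!file.exists(path)) stop("read_motion: no such file: ", path)
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 6L) stop("read_motion: expected 6 columns, got ", ncol(m))
  dimnames(m) <- list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz"))
  class(m) <- c("motion_trace", class(m))
  m
}

#' @param motion frames x 6 motion matrix.
#' @rdname read_motion
#' @export
write_motion <- function(motion, path) {
  utils::write.table(format(unclass(motion), digits = 17L, scientific = TRUE, trim = TRUE),
                     path, sep = " ", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a 4-D NIfTI-1 volume as a voxel-by-frame matrix
#'
#' Voxels are flattened in column-major (x fastest) order, the native NIfTI
#' array order, so `matrix <-> volume` round trips are exact. The image
#' header is retained for writing statistical maps back into the same space.
#'
#' @param path NIfTI-1 file (optionally gzipped).
#' @return list with `mat` (voxel x frame matrix), `dim` (spatial dims) and
#'   `ref` (an `RNifti` image to use as a spatial reference).
#' @export
read_nifti4d <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop("read_nifti4d: expected a 4-D NIfTI, got ", length(d), " dims")
  mat <- matrix(as.numeric(img), nrow = prod(d[1:3]), ncol = d[4L])
  list(mat = mat, dim = d[1:3], ref = img)
}

#' Write a voxel statistic vector as a 3-D NIfTI-1 map
#'
#' @param values numeric vector, one value per voxel in the flattened order
#'   used by [read_nifti4d()].
#' @param ref reference image (or the `ref` element of [read_nifti4d()]).
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_nifti_map <- function(values, ref, path) {
  d <- dim(ref)[1:3]
  if (length(values) != prod(d))
    stop("write_nifti_map: value count does not match reference voxel grid")
  arr <- array(as.numeric(values), dim = d)
  RNifti::writeNifti(RNifti::asNifti(arr, reference = ref), path)
  invisible(path)
}

#' Read / write detected events as TSV
#'
#' Columns: `subject_id`, `run_id`, `center_frame`, `window_start`,
#' `window_end` (all frames 0-based in original acquisition time),
#' `explained_variance`, `sub_cluster` (NA when unlabeled), then one column
#' per ROI holding the signed unit TSP loadings.
#'
#' @param events a `ts_events` object (see [detect_ts()]).
#' @param path file path.
#' @export
write_events_tsv <- function(events, path) {
  stopifnot(inherits(events, "ts_events"))
  df <- events$events
  tsp <- t(events$tsp)
  colnames(tsp) <- events$roi_ids
  out <- cbind(data.frame(subject_id = events$subject_id, run_id = events$run_id,
                          center_frame = df$center, window_start = df$start,
                          window_end = df$end, explained_variance = df$explained_variance,
                          sub_cluster = if (is.null(df$sub_cluster)) NA_integer_ else df$sub_cluster),
               as.data.frame(tsp))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  if (!file.exists(path)) stop("read_events_tsv: no such file: ", path)
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
}
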