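#' Calcium time-series stack
#'
#' Container for a single-channel calcium-indicator movie. Frames are stored
#' with time last, i.e. an `H x W x T` array, the natural layout for R's
#' column-major arrays; accessors report `T` first to match the way frame
#' counts are quoted in acquisition protocols.
#'
#' @param data numeric `H x W x T` array (a matrix is promoted to `T = 1`).
#' @param frame_rate_hz acquisition rate, frames per second (> 0).
#' @param pixel_size_um isotropic pixel size in microns (> 0).
#' @param channel channel name, e.g. `"GCaMP6s"`.
#' @return An object of class `ts_stack`.
#' @examples
#' st <- ts_stack(array(0, c(8, 8, 4)), frame_rate_hz = 4)
#' dim(st)
#' @export
ts_stack <- function(data, frame_rate_hz, pixel_size_um = 1, channel = "calcium") {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0)
    stop("frame_rate_hz must be a positive number", call. = FALSE)
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive", call. = FALSE)
  structure(
    list(data = data, frame_rate_hz = frame_rate_hz,
         pixel_size_um = pixel_size_um, channel = channel),
    class = "ts_stack")
}

#' @export
dim.ts_stack <- function(x) dim(x$data)

#' Number of frames in a stack
#' @param x a [ts_stack()].
#' @return integer frame count.
#' @export
n_frames <- function(x) dim(x$data)[3L]

#' @export
print.ts_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ts_stack> %d frames of %d x %d px, %.3g Hz, %.3g um/px [%s]\n",
              d[3], d[1], d[2], x$frame_rate_hz, x$pixel_size_um, x$channel))
  invisible(x)
}

#' Static reference image
#'
#' The cell-fill channel used for segmentation: a single 2-D grayscale
#' image in which every labeled soma is bright regardless of activity.
#'
#' @param data numeric `H x W` matrix, finite and non-negative.
#' @param pixel_size_um isotropic pixel size in microns (> 0).
#' @param channel channel name, e.g. `"mRuby"`.
#' @return An object of class `ref_image`.
#' @export
ref_image <- function(data, pixel_size_um = 1, channel = "cellfill") {
  stopifnot(is.matrix(data), is.numeric(data))
  if (any(!is.finite(data)) || any(data < 0))
    stop("reference image must be finite and non-negative", call. = FALSE)
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive", call. = FALSE)
  structure(list(data = data, pixel_size_um = pixel_size_um, channel = channel),
            class = "ref_image")
}

#' @export
dim.ref_image <- function(x) dim(x$data)

#' @export
print.ref_image <- function(x, ...) {
  cat(sprintf("<ref_image> %d x %d px, %.3g um/px [%s]\n",
              nrow(x$data), ncol(x$data), x$pixel_size_um, x$channel))
  invisible(x)
}

#' Segmented ROI set
#'
#' A labeled segmentation of the reference image. `label_map` holds 0 for
#' background and contiguous integer labels `1..K`; `records` is a tibble
#' with one row per retained ROI (`roi_id`, `size_px`, `eccentricity`,
#' `centroid_row`, `centroid_col`, `touches_border`).
#'
#' @param label_map integer `H x W` matrix.
#' @param records tibble of per-ROI shape records (computed from the map
#'   when omitted).
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(label_map, records = NULL) {
  stopifnot(is.matrix(label_map))
  storage.mode(label_map) <- "integer"
  k <- max(0L, label_map)
  labs <- sort(unique(label_map[label_map > 0L]))
  if (length(labs) && !identical(labs, seq_len(k)))
    stop("labels must be contiguous 1..K", call. = FALSE)
  if (is.null(records)) records <- roi_shape_records(label_map)
  structure(list(label_map = label_map, records = records), class = "roi_set")
}

#' Number of ROIs in a segmentation
#' @param x a [roi_set()].
#' @return integer ROI count.
#' @export
n_rois <- function(x) nrow(x$records)

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROIs on a %d x %d map\n",
              n_rois(x), nrow(x$label_map), ncol(x$label_map)))
  invisible(x)
}

#' Raw per-ROI trace matrix
#'
#' @param values numeric `R x T` matrix of mean soma intensities.
#' @param roi_ids integer vector of length `R`.
#' @param frame_rate_hz frames per second.
#' @return An object of class `trace_matrix`.
#' @export
trace_matrix <- function(values, roi_ids, frame_rate_hz) {
  values <- rbind(values)
  stopifnot(length(roi_ids) == nrow(values), frame_rate_hz > 0)
  structure(list(values = values, roi_ids = as.integer(roi_ids),
                 frame_rate_hz = frame_rate_hz),
            class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<trace_matrix> %d ROIs x %d frames at %.3g Hz\n",
              nrow(x$values), ncol(x$values), x$frame_rate_hz))
  invisible(x)
}

#' Normalized dF/F trace matrix
#'
#' @param values numeric `R x T` matrix of unitless dF/F values (may contain
#'   `NA` where the rolling baseline was 0).
#' @param roi_ids integer vector of length `R`.
#' @param frame_rate_hz frames per second.
#' @param window_frames rolling-baseline window used (>= 2), recorded for
#'   provenance.
#' @return An object of class `dff_matrix`.
#' @export
dff_matrix <- function(values, roi_ids, frame_rate_hz, window_frames = 50L) {
  values <- rbind(values)
  stopifnot(length(roi_ids) == nrow(values), frame_rate_hz > 0,
            window_frames >= 2)
  structure(list(values = values, roi_ids = as.integer(roi_ids),
                 frame_rate_hz = frame_rate_hz,
                 window_frames = as.integer(window_frames)),
            class = "dff_matrix")
}

#' @export
print.dff_matrix <- function(x, ...) {
  cat(sprintf("<dff_matrix> %d ROIs x %d frames at %.3g Hz (window %d)\n",
              nrow(x$values), ncol(x$values), x$frame_rate_hz, x$window_frames))
  invisible(x)
}

#' Long-format view of a trace matrix
#'
#' @param x a [trace_matrix()] or [dff_matrix()].
#' @return A tibble with columns `roi_id`, `frame` (1-based), `time_s`,
#'   `value`.
#' @export
as_trace_tibble <- function(x) {
  stopifnot(inherits(x, c("trace_matrix", "dff_matrix")))
  tt <- ncol(x$values)
  tibble::tibble(
    roi_id = rep(x$roi_ids, each = tt),
    frame = rep(seq_len(tt), times = nrow(x$values)),
    time_s = (rep(seq_len(tt), times = nrow(x$values)) - 1) / x$frame_rate_hz,
    value = as.vector(t(x$values)))
}
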