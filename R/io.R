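#' Write a calcium movie to multi-page TIFF
#'
#' Frames are written as 16-bit grayscale pages. Intensities are stored on
#' the native `[0, 65535]` integer scale (values are rounded and clipped on
#' write), so round trips are lossless for integer-valued data. Acquisition
#' metadata (frame rate, pixel size, channel) goes to a JSON sidecar at
#' `<path>.json`, mirroring the fact that plain TIFF has no standard slot
#' for a frame rate.
#'
#' @param stack a [ts_stack()].
#' @param path output file, conventionally `.tif`.
#' @return `path`, invisibly.
#' @export
save_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ts_stack"))
  pages <- lapply(seq_len(n_frames(stack)), function(t) {
    m <- round(stack$data[, , t])
    m[m < 0] <- 0; m[m > 65535] <- 65535
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(frame_rate_hz = stack$frame_rate_hz,
         pixel_size_um = stack$pixel_size_um,
         channel = stack$channel),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a calcium movie from multi-page TIFF
#'
#' Reads all pages and restores the 16-bit integer intensity scale. Metadata
#' comes from the JSON sidecar written by [save_stack()] when present;
#' explicit arguments override the sidecar. A frame rate must come from one
#' of the two sources.
#'
#' @param path a multi-page TIFF file.
#' @param frame_rate_hz,pixel_size_um,channel overrides for sidecar metadata.
#' @return A [ts_stack()].
#' @export
load_stack <- function(path, frame_rate_hz = NULL, pixel_size_um = NULL,
                       channel = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = FALSE),
                    error = function(e)
                      stop("unsupported or corrupt TIFF: ", path, call. = FALSE))
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) arr[, , t] <- round(pages[[t]] * 65535)
  meta <- read_sidecar(path)
  frame_rate_hz <- frame_rate_hz %||% meta$frame_rate_hz
  if (is.null(frame_rate_hz))
    stop("frame rate missing: no sidecar metadata and no override given",
         call. = FALSE)
  ts_stack(arr, frame_rate_hz,
           pixel_size_um %||% meta$pixel_size_um %||% 1,
           channel %||% meta$channel %||% "calcium")
}

#' Write a reference image to single-page TIFF
#'
#' Same 16-bit convention and JSON sidecar as [save_stack()].
#'
#' @param ref a [ref_image()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_reference <- function(ref, path) {
  stopifnot(inherits(ref, "ref_image"))
  m <- round(ref$data)
  m[m < 0] <- 0; m[m > 65535] <- 65535
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(pixel_size_um = ref$pixel_size_um, channel = ref$channel),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a reference image from TIFF
#'
#' @param path a single-page TIFF file.
#' @param pixel_size_um,channel overrides for sidecar metadata.
#' @return A [ref_image()].
#' @export
load_reference <- function(path, pixel_size_um = NULL, channel = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  m <- tryCatch(tiff::readTIFF(path),
                error = function(e)
                  stop("unsupported or corrupt TIFF: ", path, call. = FALSE))
  if (length(dim(m)) == 3L) m <- m[, , 1L] # drop extra channels
  meta <- read_sidecar(path)
  ref_image(round(m * 65535),
            pixel_size_um %||% meta$pixel_size_um %||% 1,
            channel %||% meta$channel %||% "cellfill")
}

read_sidecar <- function(path) {
  sc <- paste0(path, ".json")
  if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE) else list()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Downsample a reference image to the time-series geometry
#'
#' High-resolution reference images (e.g. 1024 x 1024 at 0.83 um/px) are
#' resized to the calcium time-series geometry (e.g. 256 x 256 at
#' 3.32 um/px) so segmentations can be applied to the movie directly.
#' Bilinear interpolation with anti-aliasing; the pixel size is rescaled by
#' the dimension ratio. The interpolation flavor is recorded in the returned
#' object's `channel`-adjacent attribute `resize_filter`.
#'
#' @param ref a [ref_image()].
#' @param target_h,target_w target dimensions in pixels (positive, no larger
#'   than the source).
#' @return A [ref_image()] of size `target_h x target_w`.
#' @examples
#' r <- ref_image(matrix(100, 64, 64), pixel_size_um = 0.83)
#' downsample_reference(r, 16, 16)$pixel_size_um # 3.32
#' @export
downsample_reference <- function(ref, target_h, target_w) {
  stopifnot(inherits(ref, "ref_image"))
  if (target_h <= 0 || target_w <= 0)
    stop("target dimensions must be positive", call. = FALSE)
  h <- nrow(ref$data); w <- ncol(ref$data)
  if (target_h > h || target_w > w)
    stop("target dimensions exceed the source image", call. = FALSE)
  if (target_h == h && target_w == w) return(ref)
  out <- EBImage::resize(ref$data, w = target_h, h = target_w,
                         filter = "bilinear", antialias = TRUE)
  out <- pmax(as.matrix(out), 0)
  res <- ref_image(out, ref$pixel_size_um * h / target_h, ref$channel)
  attr(res, "resize_filter") <- "bilinear"
  res
}
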