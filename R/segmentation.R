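#' Segmentation configuration
#'
#' Thresholds are expressed as multipliers on the image standard deviation
#' so a single configuration transfers across fields with different
#' absolute intensity scales: minima suppression uses
#' `h = hmin_factor * sd(image)` and region growing stops at
#' `tolerance = grow_tolerance_factor * sd(suppressed image)`. The minimum
#' ROI size defaults to the pixel area of a 5 um-radius disk at the
#' reference image's pixel size.
#'
#' @param hmin_factor multiplier on the image sd for the h-minima depth
#'   (default 2).
#' @param grow_tolerance_factor multiplier on the suppressed image's sd for
#'   the region-growing stop (default 1).
#' @param min_size_px minimum retained ROI area in pixels; `NULL` derives it
#'   from the pixel size as `round(pi * (5 / pixel_size_um)^2)`.
#' @param max_eccentricity retained ROIs must have eccentricity at or below
#'   this (default 0.99; values above indicate a line, i.e. a neurite or
#'   debris).
#' @param exclude_border drop ROIs with any pixel on the image boundary.
#' @param smooth_sigma_px Gaussian sigma for the watershed marker image,
#'   roughly half the expected soma radius.
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(hmin_factor = 2, grow_tolerance_factor = 1,
                                min_size_px = NULL, max_eccentricity = 0.99,
                                exclude_border = TRUE, smooth_sigma_px = 3) {
  stopifnot(hmin_factor > 0, grow_tolerance_factor > 0,
            max_eccentricity >= 0, max_eccentricity <= 1,
            is.null(min_size_px) || min_size_px >= 1, smooth_sigma_px > 0)
  structure(list(hmin_factor = hmin_factor,
                 grow_tolerance_factor = grow_tolerance_factor,
                 min_size_px = min_size_px,
                 max_eccentricity = max_eccentricity,
                 exclude_border = isTRUE(exclude_border),
                 smooth_sigma_px = smooth_sigma_px),
            class = "segmentation_config")
}

#' Suppress shallow regional minima (h-minima transform)
#'
#' Removes every regional minimum whose depth is below `h`, computed as the
#' grayscale reconstruction-by-erosion of `image + h` constrained by
#' `image` (8-connectivity). In a cell-fill image this levels the dim
#' textured background and the thin neurite signal, leaving the bright
#' somata standing for region growing. The output satisfies
#' `input <= output <= input + h`.
#'
#' @param image numeric matrix.
#' @param h minimum depth, intensity units (>= 0); `h = 0` returns the
#'   input unchanged.
#' @return numeric matrix of the same shape.
#' @export
suppress_minima <- function(image, h) {
  stopifnot(is.matrix(image))
  if (!is.numeric(h) || length(h) != 1 || h < 0)
    stop("h must be a single non-negative number", call. = FALSE)
  if (h == 0) return(image)
  # a constant image is one boundary-less plateau: raw reconstruction would
  # lift it uniformly by h, but there is no minimum to suppress
  if (diff(range(image)) == 0) return(image)
  .reconstruct_erode_cpp(image + h, image)
}

#' Grow the background region from the darkest pixel
#'
#' Seeded region growing of the image background: the global-minimum pixel
#' seeds the region (ties broken to the smallest row-major index), and the
#' 4-connected frontier pixel whose intensity is closest to the running
#' region mean is admitted one pixel at a time, the mean updating after
#' every admission, until that smallest difference exceeds `tolerance`. The
#' fully grown region is the background; the returned mask marks its
#' complement — the candidate ROIs.
#'
#' @param image numeric matrix.
#' @param tolerance stopping threshold on `|intensity - region mean|`
#'   (> 0), conventionally the standard deviation of `image`.
#' @return logical matrix, `TRUE` = candidate foreground.
#' @export
region_grow_background <- function(image, tolerance) {
  stopifnot(is.matrix(image), length(image) >= 1)
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop("tolerance must be positive", call. = FALSE)
  !.region_grow_cpp(image, tolerance)
}

#' Split touching somata and label the candidate mask
#'
#' Marker-controlled watershed: the marker image combines the
#' Gaussian-smoothed intensity with the mask's Euclidean distance
#' transform (both min-max normalized inside the mask), its regional
#' maxima seed the labels, and labels are propagated over that map
#' restricted to the mask (EBImage's watershed-by-propagation). The
#' distance-transform term is what separates equally bright somata whose
#' profiles have already merged into a single intensity peak — pure
#' intensity markers cannot split two equal Gaussians closer than twice
#' their sigma, but round cells still pinch the mask at the contact
#' waist. Disjoint blobs come back as plain connected components.
#'
#' @param mask logical matrix of candidate foreground.
#' @param intensity numeric matrix, same shape (typically the
#'   minima-suppressed image).
#' @param smooth_sigma_px Gaussian sigma for the marker image.
#' @return integer label matrix (0 = background) partitioning `mask`.
#' @export
split_and_label <- function(mask, intensity, smooth_sigma_px = 3) {
  stopifnot(is.matrix(mask), all(dim(mask) == dim(intensity)))
  mask <- mask & TRUE
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (!any(mask)) return(lab)
  # clamp the filter support for small images (gblur needs radius < dim)
  rad <- min(2 * ceiling(3 * smooth_sigma_px) + 1,
             (min(dim(mask)) - 1) %/% 2 * 2 - 1)
  sm <- if (rad >= 3)
    as.matrix(EBImage::gblur(intensity, sigma = smooth_sigma_px, radius = rad))
  else intensity
  dm <- as.matrix(EBImage::distmap(mask * 1L))
  norm_in <- function(x) {
    v <- x[mask]
    if (diff(range(v)) == 0) return(ifelse(mask, 1, 0))
    ifelse(mask, (x - min(v)) / diff(range(v)), 0)
  }
  score <- norm_in(sm) + norm_in(dm)
  low <- min(score) - 1
  score_in <- ifelse(mask, score, low)
  # regional maxima of the combined marker image within the mask
  brush <- EBImage::makeBrush(2 * ceiling(smooth_sigma_px) + 1, "disc")
  mx <- as.matrix(EBImage::dilate(score_in, brush))
  peaks <- mask & (score_in >= mx)
  seeds <- EBImage::bwlabel(peaks)
  if (max(seeds) == 0) seeds <- EBImage::bwlabel(mask) # degenerate: flat mask
  lab <- as.matrix(EBImage::propagate(score_in, seeds = seeds, mask = mask))
  storage.mode(lab) <- "integer"
  # relabel contiguously
  labs <- sort(unique(lab[lab > 0L]))
  if (length(labs)) lab[] <- match(lab, labs, nomatch = 0L)
  lab[is.na(lab)] <- 0L
  lab
}

#' Filter ROIs by size, shape and border contact
#'
#' Drops ROIs smaller than `min_size_px`, more eccentric than
#' `max_eccentricity` (eccentricity from the second central moments of the
#' pixel mask: 0 = circle, 1 = line), and — when `exclude_border` — ROIs
#' touching the image boundary. Survivors are relabeled `1..K` in their
#' original label order.
#'
#' @param labels integer label matrix.
#' @param cfg a [segmentation_config()]; its `min_size_px` must be set
#'   (pass `min_size_px` explicitly or derive it via [segment_reference()]).
#' @return A [roi_set()]; the tibble of dropped ROIs with an
#'   `excluded_reason` column is attached as attribute `"excluded"`.
#' @export
filter_rois <- function(labels, cfg = segmentation_config(min_size_px = 30)) {
  stopifnot(is.matrix(labels))
  min_size <- cfg$min_size_px %||% 30
  rec <- roi_shape_records(labels)
  if (!nrow(rec)) {
    rs <- roi_set(matrix(0L, nrow(labels), ncol(labels)), rec)
    attr(rs, "excluded") <- cbind(rec, excluded_reason = character(0))
    return(rs)
  }
  reason <- rep(NA_character_, nrow(rec))
  reason[rec$size_px < min_size] <- "size"
  reason[is.na(reason) & rec$eccentricity > cfg$max_eccentricity] <- "eccentricity"
  if (cfg$exclude_border)
    reason[is.na(reason) & rec$touches_border] <- "border"
  keep <- is.na(reason)
  old_ids <- rec$roi_id[keep]
  new_map <- matrix(0L, nrow(labels), ncol(labels))
  new_map[] <- match(labels, old_ids, nomatch = 0L)
  new_rec <- rec[keep, , drop = FALSE]
  new_rec$roi_id <- seq_along(old_ids)
  rs <- roi_set(new_map, new_rec)
  excl <- rec[!keep, , drop = FALSE]
  excl$excluded_reason <- reason[!keep]
  attr(rs, "excluded") <- excl
  rs
}

#' Segment somata from a cell-fill reference image
#'
#' The full segmentation chain: h-minima suppression with
#' `h = hmin_factor * sd(image)`, background region growing with
#' `tolerance = grow_tolerance_factor * sd(suppressed image)`,
#' marker-controlled watershed splitting of the candidate mask, then
#' size/eccentricity/border filtering. Deterministic for a fixed image and
#' configuration.
#'
#' @param ref a [ref_image()].
#' @param cfg a [segmentation_config()].
#' @return A [roi_set()] (with the dropped-ROI table in attribute
#'   `"excluded"`, see [filter_rois()]).
#' @examples
#' fld <- make_reference_image(field_spec(n_somata = 5, n_neurites = 5,
#'                                        height = 96, width = 96))
#' rois <- segment_reference(fld$ref)
#' n_rois(rois)
#' @export
segment_reference <- function(ref, cfg = segmentation_config()) {
  stopifnot(inherits(ref, "ref_image"), inherits(cfg, "segmentation_config"))
  img <- ref$data
  if (sd(img) == 0)
    return(filter_rois(matrix(0L, nrow(img), ncol(img)), resolve_cfg(cfg, ref)))
  sup <- suppress_minima(img, cfg$hmin_factor * sd(img))
  tol <- cfg$grow_tolerance_factor * sd(sup)
  if (tol <= 0)
    return(filter_rois(matrix(0L, nrow(img), ncol(img)), resolve_cfg(cfg, ref)))
  mask <- region_grow_background(sup, tol)
  lab <- split_and_label(mask, sup, cfg$smooth_sigma_px)
  filter_rois(lab, resolve_cfg(cfg, ref))
}

# fill the pixel-size-derived min_size default
resolve_cfg <- function(cfg, ref) {
  if (is.null(cfg$min_size_px))
    cfg$min_size_px <- max(1, round(pi * (5 / ref$pixel_size_um)^2))
  cfg
}
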