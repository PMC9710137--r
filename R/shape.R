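#' Ellipse-equivalent eccentricity of a pixel set
#'
#' Shape descriptor from the second central moments of the ROI pixel mask:
#' with `l1 >= l2` the eigenvalues of the 2-D covariance of pixel
#' coordinates, eccentricity is `sqrt(1 - l2/l1)` — 0 for a circle,
#' approaching 1 for a line segment. Degenerate ROIs (a single pixel) are
#' assigned 0.
#'
#' @param rows,cols integer pixel coordinates of the ROI.
#' @return eccentricity in `[0, 1]`.
#' @examples
#' # a 1-px wide horizontal line is maximally eccentric
#' roi_eccentricity(rep(1, 60), 1:60)
#' @export
roi_eccentricity <- function(rows, cols) {
  stopifnot(length(rows) == length(cols))
  n <- length(rows)
  if (n < 2L) return(0)
  mu_rr <- mean((rows - mean(rows))^2)
  mu_cc <- mean((cols - mean(cols))^2)
  mu_rc <- mean((rows - mean(rows)) * (cols - mean(cols)))
  tr <- mu_rr + mu_cc
  det <- mu_rr * mu_cc - mu_rc^2
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  if (l1 <= 0) return(0)
  sqrt(max(0, 1 - l2 / l1))
}

#' Per-ROI shape records from a label map
#'
#' @param label_map integer `H x W` matrix, 0 = background.
#' @return A tibble with one row per label: `roi_id`, `size_px`,
#'   `eccentricity`, `centroid_row`, `centroid_col`, `touches_border`.
#' @export
roi_shape_records <- function(label_map) {
  stopifnot(is.matrix(label_map))
  labs <- sort(unique(as.integer(label_map[label_map > 0])))
  if (!length(labs)) {
    return(tibble::tibble(roi_id = integer(), size_px = integer(),
                          eccentricity = double(), centroid_row = double(),
                          centroid_col = double(), touches_border = logical()))
  }
  h <- nrow(label_map); w <- ncol(label_map)
  idx <- which(label_map > 0)
  lab <- as.integer(label_map[idx])
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  by_lab <- split(seq_along(idx), lab)
  recs <- lapply(names(by_lab), function(l) {
    i <- by_lab[[l]]
    r <- rows[i]; c <- cols[i]
    tibble::tibble(
      roi_id = as.integer(l),
      size_px = length(i),
      eccentricity = roi_eccentricity(r, c),
      centroid_row = mean(r),
      centroid_col = mean(c),
      touches_border = any(r == 1L | r == h | c == 1L | c == w))
  })
  out <- do.call(rbind, recs)
  out[order(out$roi_id), , drop = FALSE]
}
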