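# Phase correlation: estimate the rigid translation between two equally
# sized frames from the normalized cross-power spectrum, refined to
# sub-pixel precision by evaluating the correlation surface on a locally
# upsampled DFT grid (matrix-multiply DFT, default 10x).
#
# Returns (dy, dx) such that `b` is approximately `a` translated by
# (dy, dx) (content moved down/right for positive values).
phase_shift <- function(a, b, upsample = 10) {
  stopifnot(all(dim(a) == dim(b)))
  if (sd(a) == 0 || sd(b) == 0) {
    warning("featureless frame in phase correlation; returning zero shift")
    return(c(0, 0))
  }
  # coarse: integer peak of the un-windowed phase correlation (robust to
  # large displacements), then sub-pixel refinement of the residual after
  # shifting b back by the integer estimate, under a Hann window (removes
  # the edge-discontinuity bias that otherwise pulls fractional peaks).
  ip <- -pc_peak(a, b, window = FALSE)
  if (upsample <= 1) return(ip)
  b2 <- if (any(ip != 0)) bilinear_translate(b, -ip[1], -ip[2]) else b
  res <- -pc_peak(a, b2, window = TRUE, upsample = upsample)
  if (any(abs(res) > 1)) res <- c(0, 0) # refinement must stay sub-pixel
  ip + res
}

# location of the phase-correlation peak of (a, b); returns the (possibly
# fractional) peak coordinates, which equal minus the displacement of b
# relative to a
pc_peak <- function(a, b, window = FALSE, upsample = 1) {
  n <- nrow(a); m <- ncol(a)
  if (window) {
    w <- outer(0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1)),
               0.5 - 0.5 * cos(2 * pi * (0:(m - 1)) / (m - 1)))
    a <- (a - mean(a)) * w
    b <- (b - mean(b)) * w
  }
  cps <- fft(a) * Conj(fft(b))
  mag <- Mod(cps)
  # whiten, but floor the magnitude at a relative threshold so spectral
  # components that are numerically zero (smooth, low-texture images) are
  # not amplified into noise phases
  cps <- cps / pmax(mag, 1e-3 * max(mag))
  r <- Re(fft(cps, inverse = TRUE)) / (n * m)
  p <- which.max(r)
  pr <- (p - 1) %% n
  pc <- (p - 1) %/% n
  if (pr > n / 2) pr <- pr - n
  if (pc > m / 2) pc <- pc - m
  if (upsample > 1) {
    # evaluate the correlation surface on a +/-0.8 px grid at 1/upsample
    # steps around the integer peak (grid includes the peak itself, so
    # exact integer shifts stay exact)
    off <- seq(-ceiling(0.8 * upsample), ceiling(0.8 * upsample)) / upsample
    kr <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1)) # signed freqs
    kc <- c(0:floor((m - 1) / 2), -(ceiling((m - 1) / 2):1))
    er <- exp(2i * pi * outer(pr + off, kr) / n)
    ec <- exp(2i * pi * outer(kc, pc + off) / m)
    ru <- Re(er %*% cps %*% ec)
    q <- which(ru == max(ru), arr.ind = TRUE)[1, ]
    pr <- pr + off[q[1]]
    pc <- pc + off[q[2]]
  }
  c(pr, pc)
}

#' Correct rigid drift by frame-to-frame registration
#'
#' Each frame is registered to its predecessor by phase correlation
#' (normalized Fourier cross-power spectrum) with sub-pixel refinement on a
#' 10x upsampled local DFT grid; incremental shifts are composed
#' cumulatively and each frame is resampled once with its composed shift
#' (bilinear warp, out-of-frame pixels filled with the frame median), so
#' interpolation blur is not compounded across steps. Translation-only: the
#' drift this corrects is physical stage/perfusion motion with no rotation
#' component.
#'
#' @param stack a [ts_stack()] with at least 2 frames.
#' @param upsample sub-pixel refinement factor (1 disables refinement).
#' @return A list with `stack` (the registered [ts_stack()], same T/H/W)
#'   and `shifts`, a tibble (`frame`, `dy`, `dx`) of the cumulative
#'   displacement of each frame relative to frame 1 (frame 1 is `(0, 0)`);
#'   the registration applies the negated shift.
#' @export
register_stack <- function(stack, upsample = 10) {
  stopifnot(inherits(stack, "ts_stack"))
  tt <- n_frames(stack)
  if (tt < 2) stop("registration needs at least 2 frames", call. = FALSE)
  inc <- matrix(0, tt, 2)
  for (t in 2:tt)
    inc[t, ] <- phase_shift(stack$data[, , t - 1], stack$data[, , t],
                            upsample = upsample)
  cum <- apply(inc, 2, cumsum)
  out <- stack$data
  for (t in 2:tt) {
    if (any(cum[t, ] != 0))
      out[, , t] <- bilinear_translate(stack$data[, , t],
                                       -cum[t, 1], -cum[t, 2])
  }
  list(stack = ts_stack(out, stack$frame_rate_hz, stack$pixel_size_um,
                        stack$channel),
       shifts = tibble::tibble(frame = seq_len(tt),
                               dy = cum[, 1], dx = cum[, 2]))
}

#' Align a movie to its cell-fill reference image
#'
#' Estimates a single global translation between the movie's temporal mean
#' image and the reference by phase correlation, and applies it to every
#' frame. Run [downsample_reference()] first if the reference was acquired
#' at higher resolution.
#'
#' @param stack a [ts_stack()].
#' @param ref a [ref_image()] with the same H x W as the stack.
#' @return A list with `stack` (aligned) and `shift`, the `(dy, dx)`
#'   displacement of the reference relative to the movie mean (the warp
#'   applied to each frame).
#' @export
align_to_reference <- function(stack, ref) {
  stopifnot(inherits(stack, "ts_stack"), inherits(ref, "ref_image"))
  if (!all(dim(stack$data)[1:2] == dim(ref$data)))
    stop("stack and reference dimensions differ; downsample the reference ",
         "to the time-series geometry first", call. = FALSE)
  mn <- apply(stack$data, c(1, 2), mean)
  sh <- phase_shift(mn, ref$data)
  out <- stack$data
  if (any(sh != 0))
    for (t in seq_len(n_frames(stack)))
      out[, , t] <- bilinear_translate(stack$data[, , t], sh[1], sh[2])
  list(stack = ts_stack(out, stack$frame_rate_hz, stack$pixel_size_um,
                        stack$channel),
       shift = sh)
}

#' Correlation of each frame with the temporal mean image
#'
#' The drift diagnostic: well-registered movies correlate tightly and
#' uniformly with their mean intensity image, drifting ones do not.
#' Zero-variance frames yield `NA` rather than an error.
#'
#' @param stack a [ts_stack()] with at least 2 frames.
#' @return numeric vector of per-frame Pearson correlations in `[-1, 1]`
#'   (or `NA`).
#' @export
frame_mean_correlation <- function(stack) {
  stopifnot(inherits(stack, "ts_stack"))
  tt <- n_frames(stack)
  if (tt < 2) stop("need at least 2 frames", call. = FALSE)
  mn <- as.vector(apply(stack$data, c(1, 2), mean))
  vapply(seq_len(tt), function(t) {
    f <- as.vector(stack$data[, , t])
    if (sd(f) == 0 || sd(mn) == 0) return(NA_real_)
    cor(f, mn)
  }, numeric(1))
}
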