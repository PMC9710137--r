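#' Extract per-ROI mean-intensity traces from a movie
#'
#' Each trace sample is the arithmetic mean of the movie frame over the
#' ROI's pixels.
#'
#' @param stack a [ts_stack()].
#' @param rois a [roi_set()] whose label map matches the stack's H x W.
#' @return A [trace_matrix()] (ROIs x frames) at the stack's frame rate.
#' @export
extract_traces <- function(stack, rois) {
  stopifnot(inherits(stack, "ts_stack"), inherits(rois, "roi_set"))
  d <- dim(stack$data)
  if (!all(d[1:2] == dim(rois$label_map)))
    stop("stack frames and ROI label map have different dimensions",
         call. = FALSE)
  ids <- rois$records$roi_id
  if (!length(ids))
    return(trace_matrix(matrix(0, 0, d[3]), integer(0), stack$frame_rate_hz))
  flat <- stack$data
  dim(flat) <- c(d[1] * d[2], d[3])
  lab <- as.vector(rois$label_map)
  sel <- lab > 0L
  sums <- rowsum(flat[sel, , drop = FALSE], lab[sel], reorder = TRUE)
  dimnames(sums) <- NULL
  npx <- as.vector(table(factor(lab[sel], levels = ids)))
  trace_matrix(sums / npx, ids, stack$frame_rate_hz)
}

#' Normalize traces to dF/F with a rolling baseline
#'
#' For each ROI, the baseline `F0(t)` is the mean of the raw trace over a
#' centered window of `window_frames` frames, truncated at the trace ends,
#' and `dff(t) = (F(t) - F0(t)) / F0(t)`. A centered window avoids the
#' systematic onset lag a trailing window would introduce. Frames where
#' `F0 = 0` become `NA` with a warning (they are treated as sub-threshold
#' by event detection). dF/F is invariant to rescaling a trace by any
#' positive constant.
#'
#' @param traces a [trace_matrix()].
#' @param window_frames rolling window length in frames (>= 2, default 50).
#' @return A [dff_matrix()].
#' @examples
#' tm <- trace_matrix(matrix(c(1, 1, 3, 1, 1), 1), 1L, frame_rate_hz = 4)
#' rolling_dff(tm, 3)$values
#' @export
rolling_dff <- function(traces, window_frames = 50) {
  stopifnot(inherits(traces, "trace_matrix"))
  if (!is.numeric(window_frames) || window_frames < 2)
    stop("window_frames must be at least 2", call. = FALSE)
  w <- as.integer(window_frames)
  tt <- ncol(traces$values)
  left <- floor((w - 1) / 2)
  right <- w - 1L - left
  lo <- pmax(seq_len(tt) - left, 1L)
  hi <- pmin(seq_len(tt) + right, tt)
  vals <- traces$values
  out <- matrix(NA_real_, nrow(vals), tt)
  for (r in seq_len(nrow(vals))) {
    cs <- c(0, cumsum(vals[r, ]))
    f0 <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    z <- f0 == 0
    f0[z] <- NA_real_
    out[r, ] <- (vals[r, ] - f0) / f0
  }
  if (anyNA(out))
    warning("rolling baseline is zero at ", sum(is.na(out)),
            " frame(s); dF/F set to NA there")
  dff_matrix(out, traces$roi_ids, traces$frame_rate_hz, w)
}

#' Resample dF/F traces to the motif frame rate
#'
#' Linear interpolation of every trace onto a uniform grid at
#' `target_rate_hz` spanning the same time interval. The motif library is
#' sampled at 10 frames/s, so traces acquired at other rates are
#' interpolated before event detection; a same-rate call returns the input
#' unchanged. Linear (rather than spline) interpolation is monotone-safe
#' and preserves endpoints and the extrema of monotone traces.
#'
#' @param dff a [dff_matrix()].
#' @param target_rate_hz target frame rate (default 10).
#' @return A [dff_matrix()] at `target_rate_hz`.
#' @export
resample_traces <- function(dff, target_rate_hz = 10) {
  stopifnot(inherits(dff, "dff_matrix"))
  if (!is.numeric(target_rate_hz) || target_rate_hz <= 0)
    stop("target_rate_hz must be positive", call. = FALSE)
  if (target_rate_hz == dff$frame_rate_hz) return(dff)
  tt <- ncol(dff$values)
  src_t <- (seq_len(tt) - 1) / dff$frame_rate_hz
  dst_t <- seq(0, src_t[tt], by = 1 / target_rate_hz)
  out <- matrix(NA_real_, nrow(dff$values), length(dst_t))
  for (r in seq_len(nrow(dff$values))) {
    y <- dff$values[r, ]
    ok <- !is.na(y)
    if (sum(ok) >= 2)
      out[r, ] <- approx(src_t[ok], y[ok], xout = dst_t, rule = 2)$y
    else if (sum(ok) == 1)
      out[r, ] <- y[ok]
  }
  dff_matrix(out, dff$roi_ids, target_rate_hz, dff$window_frames)
}
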