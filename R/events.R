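#' Built-in 23-template motif library
#'
#' Event templates sampled at 10 frames/s with unit peak. Motifs 1-16
#' (origin tag `"fluorosnnap"`) are single transients
#' `k(t) = (1 - exp(-t/rise)) * exp(-t/decay)` over a grid of rise times
#' \{0.1, 0.2\} s, decay times \{0.5, 1, 2, 4\} s and two template durations
#' (`rise + 2*decay` and `rise + 4*decay`). Motifs 17-23 (origin tag
#' `"capture"`) are data-driven shapes: three double transients with
#' inter-peak gaps of \{0.5, 1, 2\} s, one rise-hold-decay plateau, and
#' three slow-onset transients (rise \{0.5, 0.8, 1.2\} s, decay 2.5 s).
#' The library is serializable ([write_motif_library()]) so users can
#' substitute measured template sets.
#'
#' @return A `motif_library`: list with `motifs` (list of 23 numeric
#'   vectors), `origin` (character vector) and `id` (1..23);
#'   `frame_rate_hz` fixed at 10.
#' @export
default_motif_library <- function() {
  fs <- 10
  single <- function(rise, decay, dur) {
    t <- seq(0, dur, by = 1 / fs)
    k <- (1 - exp(-t / rise)) * exp(-t / decay)
    k / max(k)
  }
  motifs <- list()
  for (rise in c(0.1, 0.2))
    for (decay in c(0.5, 1, 2, 4))
      for (mult in c(2, 4))
        motifs[[length(motifs) + 1]] <- single(rise, decay, rise + mult * decay)
  origin <- rep("fluorosnnap", 16)
  # double transients
  for (gap in c(0.5, 1, 2)) {
    dur <- gap + 0.2 + 3 * 1.5
    t <- seq(0, dur, by = 1 / fs)
    k <- transient_kernel(t, 0.2, 1.5) + transient_kernel(t - gap, 0.2, 1.5)
    motifs[[length(motifs) + 1]] <- k / max(k)
  }
  # plateau: fast rise, 2 s hold, slow decay
  t <- seq(0, 0.2 + 1 + 2 + 3 * 1.5, by = 1 / fs)
  k <- ifelse(t <= 1, 1 - exp(-t / 0.2),
              ifelse(t <= 3, 1 - exp(-1 / 0.2), # hold
                     (1 - exp(-1 / 0.2)) * exp(-(t - 3) / 1.5)))
  motifs[[length(motifs) + 1]] <- k / max(k)
  # slow-onset transients
  for (rise in c(0.5, 0.8, 1.2))
    motifs[[length(motifs) + 1]] <- single(rise, 2.5, rise + 3 * 2.5)
  origin <- c(origin, rep("capture", 7))
  structure(list(motifs = motifs, origin = origin,
                 id = seq_along(motifs), frame_rate_hz = fs),
            class = "motif_library")
}

#' @export
print.motif_library <- function(x, ...) {
  cat(sprintf("<motif_library> %d motifs at %g frames/s (%s)\n",
              length(x$motifs), x$frame_rate_hz,
              paste(sprintf("%s: %d", names(table(x$origin)),
                            as.integer(table(x$origin))), collapse = ", ")))
  invisible(x)
}

#' Write a motif library to CSV
#'
#' One motif per column (`motif_1..motif_N`), values at 10 frames/s, short
#' motifs padded with empty cells; origin tags go to a JSON sidecar at
#' `<path>.json`.
#'
#' @param lib a motif library.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_motif_library <- function(lib, path) {
  stopifnot(inherits(lib, "motif_library"))
  len <- max(vapply(lib$motifs, length, 1L))
  m <- vapply(lib$motifs, function(v) c(v, rep(NA_real_, len - length(v))),
              numeric(len))
  colnames(m) <- paste0("motif_", lib$id)
  write.csv(as.data.frame(m), path, row.names = FALSE, na = "")
  jsonlite::write_json(list(origin = lib$origin,
                            frame_rate_hz = lib$frame_rate_hz),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a motif library from CSV
#'
#' @param path CSV written by [write_motif_library()] (or in the same
#'   layout, e.g. a measured template set).
#' @return A `motif_library`.
#' @export
read_motif_library <- function(path) {
  m <- read.csv(path)
  sc <- read_sidecar(path)
  motifs <- lapply(seq_len(ncol(m)), function(j) {
    v <- m[[j]]
    v[!is.na(v)]
  })
  structure(list(motifs = motifs,
                 origin = sc$origin %||% rep("unknown", length(motifs)),
                 id = seq_along(motifs),
                 frame_rate_hz = sc$frame_rate_hz %||% 10),
            class = "motif_library")
}

#' Motif correlation map of one dF/F trace
#'
#' `Ca[m, t]` is the Pearson correlation between motif `m` and the trace
#' window starting at frame `t` with the motif's length, for every `t`
#' where the window fits (remaining columns 0). Columns where the trace is
#' below `height_threshold` (or missing) are then zeroed across all rows —
#' sub-threshold samples represent background and cannot seed events.
#' Zero-variance windows give 0 (an undefined correlation is no match).
#'
#' @param trace numeric dF/F vector at the library's frame rate (at least
#'   as long as the longest motif).
#' @param lib a motif library.
#' @param height_threshold dF/F background level, see
#'   [estimate_height_threshold()].
#' @return A `corr_map`: list with `Ca` (motifs x frames), the threshold,
#'   and the trace.
#' @export
motif_correlation_map <- function(trace, lib, height_threshold = 0) {
  stopifnot(inherits(lib, "motif_library"), is.numeric(trace))
  tt <- length(trace)
  lens <- vapply(lib$motifs, length, 1L)
  if (tt < max(lens))
    stop("trace (", tt, " frames) is shorter than the longest motif (",
         max(lens), " frames)", call. = FALSE)
  x <- trace
  x[is.na(x)] <- 0
  ca <- matrix(0, length(lib$motifs), tt)
  for (mi in seq_along(lib$motifs)) {
    m <- lib$motifs[[mi]]
    l <- lens[mi]
    w <- embed(x, l)[, l:1, drop = FALSE] # row i = window starting at i
    wc <- w - rowMeans(w)
    mc <- m - mean(m)
    den <- sqrt(rowSums(wc^2) * sum(mc^2))
    r <- as.vector(wc %*% mc)
    r <- ifelse(den > 0, r / den, 0)
    ca[mi, seq_len(tt - l + 1)] <- r
  }
  low <- is.na(trace) | trace < height_threshold
  ca[, low] <- 0
  structure(list(Ca = ca, height_threshold = height_threshold, trace = trace),
            class = "corr_map")
}

#' Extract events from a correlation map
#'
#' The column-wise maximum over motifs forms a single row of best
#' correlations; maximal runs of consecutive frames strictly above
#' `corr_threshold` become events. Each event's motif is the row attaining
#' the run's maximum correlation (ties to the lowest motif index).
#'
#' @param cmap a `corr_map` from [motif_correlation_map()].
#' @param corr_threshold correlation threshold in `[0, 1]` (default 0.7).
#' @param frame_rate_hz frame rate of the trace (for the seconds columns).
#' @param roi_id ROI identifier stamped on the rows.
#' @return A tibble: `roi_id`, `onset_frame` (1-based), `duration_frames`,
#'   `onset_time_s`, `duration_s`, `motif_id`, `peak_correlation`. Events
#'   within a ROI are sorted and non-overlapping by construction.
#' @export
detect_events <- function(cmap, corr_threshold = 0.7, frame_rate_hz = 10,
                          roi_id = 1L) {
  stopifnot(inherits(cmap, "corr_map"))
  row <- apply(cmap$Ca, 2, max)
  above <- row > corr_threshold
  if (!any(above)) return(empty_event_table())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  rows <- lapply(keep, function(k) {
    s <- starts[k]; e <- ends[k]
    pk <- s - 1L + which.max(row[s:e])
    tibble::tibble(
      roi_id = as.integer(roi_id),
      onset_frame = s,
      duration_frames = e - s + 1L,
      onset_time_s = (s - 1) / frame_rate_hz,
      duration_s = (e - s + 1L) / frame_rate_hz,
      motif_id = which.max(cmap$Ca[, pk]),
      peak_correlation = row[pk])
  })
  do.call(rbind, rows)
}

empty_event_table <- function() {
  tibble::tibble(roi_id = integer(), onset_frame = integer(),
                 duration_frames = integer(), onset_time_s = double(),
                 duration_s = double(), motif_id = integer(),
                 peak_correlation = double())
}

#' Detect events for every ROI of a dF/F matrix
#'
#' Convenience loop over [motif_correlation_map()] and [detect_events()].
#' The trace matrix must already be at the library's frame rate
#' (see [resample_traces()]).
#'
#' @param dff a [dff_matrix()] at the library frame rate.
#' @param lib a motif library (default [default_motif_library()]).
#' @param corr_threshold correlation threshold (default 0.7).
#' @param height_threshold dF/F background level, a number or `"auto"`
#'   (see [estimate_height_threshold()]).
#' @return An event tibble as in [detect_events()], all ROIs stacked.
#' @export
detect_all_events <- function(dff, lib = default_motif_library(),
                              corr_threshold = 0.7,
                              height_threshold = "auto") {
  stopifnot(inherits(dff, "dff_matrix"))
  if (abs(dff$frame_rate_hz - lib$frame_rate_hz) > 1e-9)
    stop("dF/F frame rate (", dff$frame_rate_hz, ") differs from the motif ",
         "library rate (", lib$frame_rate_hz, "); resample first",
         call. = FALSE)
  ht <- estimate_height_threshold(dff, height_threshold)
  out <- lapply(seq_len(nrow(dff$values)), function(r) {
    cm <- motif_correlation_map(dff$values[r, ], lib, ht)
    detect_events(cm, corr_threshold, dff$frame_rate_hz, dff$roi_ids[r])
  })
  res <- do.call(rbind, out)
  attr(res, "height_threshold") <- ht
  res
}

#' Summaries of motif occurrence
#'
#' @param events an event tibble.
#' @param n_rois total number of ROIs in the field (event-free ROIs get
#'   all-zero percentage rows).
#' @param n_motifs library size (default 23).
#' @return A list with `field_counts` (tibble `motif_id`, `count` over all
#'   motifs) and `roi_percentages` (tibble `roi_id`, `motif_id`, `pct`;
#'   percentages within an active ROI sum to 100).
#' @export
summarize_motifs <- function(events, n_rois, n_motifs = 23) {
  counts <- tabulate(events$motif_id, nbins = n_motifs)
  per_roi <- lapply(seq_len(n_rois), function(r) {
    ev <- events[events$roi_id == r, , drop = FALSE]
    cnt <- tabulate(ev$motif_id, nbins = n_motifs)
    pct <- if (sum(cnt) > 0) 100 * cnt / sum(cnt) else rep(0, n_motifs)
    tibble::tibble(roi_id = r, motif_id = seq_len(n_motifs), pct = pct)
  })
  list(field_counts = tibble::tibble(motif_id = seq_len(n_motifs),
                                     count = counts),
       roi_percentages = do.call(rbind, per_roi))
}

#' Estimate the dF/F background height threshold
#'
#' `mode = "auto"` pools every dF/F sample and returns
#' `median + 3 * 1.4826 * MAD` — a robust upper bound on the noise floor
#' that calcium transients (which are sparse and strongly positive) barely
#' inflate. A numeric `mode` is returned unchanged, which is how a
#' baseline-derived threshold is injected into a drug-treated field of a
#' pharmacology pair.
#'
#' @param dff a [dff_matrix()].
#' @param mode `"auto"` or a fixed dF/F value.
#' @return dF/F threshold (a single number).
#' @export
estimate_height_threshold <- function(dff, mode = "auto") {
  if (is.numeric(mode)) return(mode)
  stopifnot(identical(mode, "auto"), inherits(dff, "dff_matrix"))
  x <- dff$values[!is.na(dff$values)]
  if (!length(x)) stop("all dF/F values are missing", call. = FALSE)
  median(x) + 3 * mad(x)
}
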