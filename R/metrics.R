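#' Per-ROI metric rows (`long_data`)
#'
#' One row per segmented ROI, including event-free ones: event count, mean
#' event duration (in 10 Hz frames and in seconds), ROI pixel volume and
#' eccentricity from the segmentation, and one count column per motif.
#'
#' @param rois a [roi_set()].
#' @param events an event tibble (all `roi_id`s must exist in `rois`).
#' @param name image identifier stamped on every row.
#' @param n_motifs motif library size (default 23).
#' @param frame_rate_hz frame rate the event frames are expressed in
#'   (default 10, the motif rate).
#' @return A tibble: `name`, `roi_id`, `events_ROI`, `avg_width`
#'   (`NA` when `events_ROI = 0`), `avg_width_s`, `volume`, `eccentricity`,
#'   `motif_1..motif_N`. Motif columns sum to `events_ROI` row-wise.
#' @export
build_roi_metrics <- function(rois, events, name = "image", n_motifs = 23,
                              frame_rate_hz = 10) {
  stopifnot(inherits(rois, "roi_set"))
  ids <- rois$records$roi_id
  if (nrow(events) && !all(events$roi_id %in% ids))
    stop("event table references ROIs absent from the segmentation",
         call. = FALSE)
  rows <- lapply(ids, function(r) {
    ev <- events[events$roi_id == r, , drop = FALSE]
    cnt <- tabulate(ev$motif_id, nbins = n_motifs)
    base <- tibble::tibble(
      name = name, roi_id = r, events_ROI = nrow(ev),
      avg_width = if (nrow(ev)) mean(ev$duration_frames) else NA_real_,
      avg_width_s = if (nrow(ev)) mean(ev$duration_frames) / frame_rate_hz
                    else NA_real_,
      volume = rois$records$size_px[rois$records$roi_id == r],
      eccentricity = rois$records$eccentricity[rois$records$roi_id == r])
    cbind(base, motif_count_cols(cnt))
  })
  if (!length(rows)) {
    base <- tibble::tibble(name = character(), roi_id = integer(),
                           events_ROI = integer(), avg_width = double(),
                           avg_width_s = double(), volume = integer(),
                           eccentricity = double())
    return(tibble::as_tibble(cbind(base, motif_count_cols(integer(n_motifs))[0, ])))
  }
  tibble::as_tibble(do.call(rbind, rows))
}

motif_count_cols <- function(counts) {
  setNames(as.data.frame(as.list(as.integer(counts))),
           paste0("motif_", seq_along(counts)))
}

#' Per-image metric row (`man`)
#'
#' Field-level summary: ROI counts, active fraction, synchrony index and
#' cluster count, event rate per ROI per minute, and per-motif totals.
#'
#' @param rois a [roi_set()].
#' @param events an event tibble for the field.
#' @param sync a `synchrony_result`, or `NULL` for fields where synchrony
#'   was not computed (fewer than 2 ROIs).
#' @param duration_s recording length in seconds.
#' @param name image identifier.
#' @param n_motifs motif library size (default 23).
#' @return A one-row tibble: `name`, `num_ROI`, `num_active_ROI`,
#'   `prop_active_ROI`, `corrSYN`, `n_clusters`, `events_per_roi_per_min`,
#'   `motif_1..motif_N`.
#' @export
build_image_metrics <- function(rois, events, sync, duration_s,
                                name = "image", n_motifs = 23) {
  stopifnot(inherits(rois, "roi_set"), duration_s > 0)
  n <- n_rois(rois)
  active <- length(unique(events$roi_id))
  cnt <- tabulate(events$motif_id, nbins = n_motifs)
  base <- tibble::tibble(
    name = name,
    num_ROI = n,
    num_active_ROI = active,
    prop_active_ROI = if (n > 0) active / n else 0,
    corrSYN = if (!is.null(sync)) sync$sync_index else NA_real_,
    n_clusters = if (!is.null(sync)) sync$n_clusters else NA_integer_,
    events_per_roi_per_min = if (n > 0) nrow(events) / n / (duration_s / 60)
                             else 0)
  tibble::as_tibble(cbind(base, motif_count_cols(cnt)))
}

#' Run the full pipeline on one field
#'
#' Executes segment -> (optional register/align) -> trace -> dF/F ->
#' resample -> detect -> synchrony -> metrics on a reference image plus
#' movie, in memory or from TIFF paths. When `out_dir` is given, writes
#' `man.csv`, `long_data.csv`, `events.csv`, `corr_matrix.csv`,
#' `rois.csv`, `traces_dff.csv` and a `run_info.json` recording the
#' resolved parameters and seed.
#'
#' @param ref a [ref_image()] or a TIFF path.
#' @param movie a [ts_stack()] or a TIFF path (sidecar or `frame_rate_hz`
#'   must supply the rate).
#' @param seg_cfg a [segmentation_config()].
#' @param sync_cfg a [synchrony_config()].
#' @param window_frames rolling dF/F window (default 50).
#' @param corr_threshold motif correlation threshold (default 0.7).
#' @param height_threshold `"auto"` or a fixed dF/F value — pass the
#'   baseline field's threshold here when scoring a drug-treated field of
#'   a pharmacology pair.
#' @param register correct frame-to-frame drift before tracing.
#' @param align align the movie to the reference before tracing (requires
#'   matching geometry).
#' @param lib motif library.
#' @param name image identifier used in the output tables.
#' @param out_dir optional output directory for the CSV artifacts.
#' @param frame_rate_hz override for the movie frame rate when loading
#'   from a TIFF without sidecar.
#' @return A list: `man` (one-row tibble), `long_data`, `events`, `rois`,
#'   `dff` (the 10 Hz [dff_matrix()]), `sync`, `height_threshold`.
#' @export
run_pipeline <- function(ref, movie, seg_cfg = segmentation_config(),
                         sync_cfg = synchrony_config(),
                         window_frames = 50, corr_threshold = 0.7,
                         height_threshold = "auto", register = FALSE,
                         align = FALSE, lib = default_motif_library(),
                         name = "image", out_dir = NULL,
                         frame_rate_hz = NULL) {
  if (is.character(ref)) ref <- load_reference(ref)
  if (is.character(movie)) movie <- load_stack(movie, frame_rate_hz = frame_rate_hz)
  stopifnot(inherits(ref, "ref_image"), inherits(movie, "ts_stack"))

  d <- dim(movie$data)
  if (!all(dim(ref$data) == d[1:2]))
    ref <- downsample_reference(ref, d[1], d[2])
  if (register) movie <- register_stack(movie)$stack
  if (align) movie <- align_to_reference(movie, ref)$stack

  rois <- segment_reference(ref, seg_cfg)
  duration_s <- n_frames(movie) / movie$frame_rate_hz
  if (n_rois(rois) == 0) {
    events <- empty_event_table()
    sync <- NULL
    dff10 <- NULL
    ht <- NA_real_
  } else {
    traces <- extract_traces(movie, rois)
    dff <- rolling_dff(traces, window_frames)
    dff10 <- resample_traces(dff, lib$frame_rate_hz)
    ht <- estimate_height_threshold(dff10, height_threshold)
    events <- detect_all_events(dff10, lib, corr_threshold, ht)
    sync <- if (n_rois(rois) >= 2) compute_synchrony(dff10, sync_cfg) else NULL
  }
  n_motifs <- length(lib$motifs)
  man <- build_image_metrics(rois, events, sync, duration_s, name, n_motifs)
  long_data <- build_roi_metrics(rois, events, name, n_motifs,
                                 lib$frame_rate_hz)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.csv(man, file.path(out_dir, "man.csv"), row.names = FALSE)
    write.csv(long_data, file.path(out_dir, "long_data.csv"),
              row.names = FALSE)
    write.csv(events, file.path(out_dir, "events.csv"), row.names = FALSE)
    write.csv(rois$records, file.path(out_dir, "rois.csv"), row.names = FALSE)
    if (!is.null(sync))
      write.csv(as.data.frame(sync$corr_matrix),
                file.path(out_dir, "corr_matrix.csv"), row.names = FALSE)
    if (!is.null(dff10))
      write.csv(as_trace_tibble(dff10),
                file.path(out_dir, "traces_dff.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(name = name, window_frames = window_frames,
           corr_threshold = corr_threshold, height_threshold = ht,
           register = register, align = align,
           n_surrogates = sync_cfg$n_surrogates,
           sync_seed = sync_cfg$rng_seed,
           frame_rate_hz = movie$frame_rate_hz,
           package_version = as.character(utils::packageVersion("catrace"))),
      file.path(out_dir, "run_info.json"), auto_unbox = TRUE, digits = NA)
  }
  list(man = man, long_data = long_data, events = events, rois = rois,
       dff = dff10, sync = sync, height_threshold = ht)
}
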