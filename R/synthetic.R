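#' Specification of a synthetic imaging field
#'
#' Describes the static cell-fill channel of a simulated field: bright round
#' somata and thin neurite-like distractor lines on a dim noisy background.
#' Defaults emulate a 10x confocal field of dissociated cortical neurons at
#' 1 um/px: somata ~6 px in radius at high cell-fill intensity, neurites an
#' order of magnitude dimmer than somata above background.
#'
#' @param height,width field size in pixels.
#' @param n_somata number of somata to place (centers kept at least
#'   `2 * soma_radius_px` apart and `2 * soma_radius_px` from the border).
#' @param soma_radius_px mean soma radius in pixels (half-maximum radius of
#'   the rendered Gaussian profile).
#' @param soma_radius_jitter half-width of the uniform jitter on the radius.
#' @param n_neurites number of straight 1-2 px wide distractor segments.
#' @param background_level,soma_level,neurite_level intensities; somata and
#'   neurites are rendered additively above the background.
#' @param noise_sd additive Gaussian pixel noise, intensity units.
#' @param rng_seed integer seed; every draw the generator makes flows from it.
#' @return A `field_spec` list.
#' @export
field_spec <- function(height = 256, width = 256, n_somata = 30,
                       soma_radius_px = 6, soma_radius_jitter = 0.5,
                       n_neurites = 40, background_level = 20,
                       soma_level = 130, neurite_level = 32,
                       noise_sd = 5, rng_seed = 1L) {
  stopifnot(height >= 8, width >= 8, n_somata >= 0, n_neurites >= 0,
            soma_radius_px > 0, soma_radius_jitter >= 0,
            background_level >= 0, soma_level >= 0, neurite_level >= 0,
            noise_sd >= 0)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_somata = as.integer(n_somata),
                 soma_radius_px = soma_radius_px,
                 soma_radius_jitter = soma_radius_jitter,
                 n_neurites = as.integer(n_neurites),
                 background_level = background_level, soma_level = soma_level,
                 neurite_level = neurite_level, noise_sd = noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "field_spec")
}

#' Specification of synthetic calcium activity
#'
#' Describes the time-varying indicator channel for a field produced by
#' [make_reference_image()]. Transients use a double-exponential kernel
#' `k(t) = (1 - exp(-t/rise)) * exp(-t/decay)` scaled so its peak equals
#' `event_amplitude` in dF/F units — the fast-rise/slow-decay shape of a
#' GCaMP6s event. Defaults match an 8-minute acquisition at 4 Hz.
#'
#' @param frame_rate_hz acquisition rate (> 0).
#' @param duration_s recording length, seconds.
#' @param event_times list of numeric vectors of event onset times in
#'   seconds: one vector per ROI, or (when `sync_blocks` is given) one
#'   vector per block, shared by every ROI in that block.
#' @param kernel_rise_s,kernel_decay_s transient kernel time constants,
#'   seconds (`rise < decay`).
#' @param event_amplitude peak dF/F of a single transient.
#' @param baseline resting soma fluorescence, intensity units.
#' @param noise_sd additive Gaussian pixel noise per frame, intensity units.
#' @param drift_px_per_frame numeric `(dy, dx)`: rigid translation added
#'   cumulatively to every frame (frame t is shifted by `(t-1) * drift`).
#' @param sync_blocks optional named list of ROI-index vectors partitioning
#'   the ROIs into blocks that fire together.
#' @param rng_seed integer seed for the noise draws.
#' @return An `activity_spec` list.
#' @export
activity_spec <- function(frame_rate_hz = 4, duration_s = 480,
                          event_times = list(), kernel_rise_s = 0.2,
                          kernel_decay_s = 1.5, event_amplitude = 1,
                          baseline = 100, noise_sd = 0,
                          drift_px_per_frame = c(0, 0), sync_blocks = NULL,
                          rng_seed = 1L) {
  stopifnot(frame_rate_hz > 0, duration_s > 0,
            kernel_rise_s > 0, kernel_decay_s > kernel_rise_s,
            event_amplitude >= 0, baseline > 0, noise_sd >= 0,
            length(drift_px_per_frame) == 2)
  bad <- vapply(event_times, function(v) any(v < 0 | v >= duration_s), TRUE)
  if (any(bad)) stop("event times must lie in [0, duration_s)", call. = FALSE)
  structure(list(frame_rate_hz = frame_rate_hz, duration_s = duration_s,
                 event_times = event_times, kernel_rise_s = kernel_rise_s,
                 kernel_decay_s = kernel_decay_s,
                 event_amplitude = event_amplitude, baseline = baseline,
                 noise_sd = noise_sd,
                 drift_px_per_frame = as.numeric(drift_px_per_frame),
                 sync_blocks = sync_blocks, rng_seed = as.integer(rng_seed)),
            class = "activity_spec")
}

#' Double-exponential calcium transient kernel
#'
#' `k(t) = (1 - exp(-t/rise)) * exp(-t/decay)` for `t >= 0`, normalized to
#' unit peak. The analytic peak time is `rise * log(1 + decay/rise)`.
#'
#' @param t times in seconds (values < 0 give 0).
#' @param rise_s,decay_s time constants, seconds.
#' @return kernel values, unit peak.
#' @export
transient_kernel <- function(t, rise_s = 0.2, decay_s = 1.5) {
  k <- ifelse(t < 0, 0, (1 - exp(-t / rise_s)) * exp(-t / decay_s))
  tp <- rise_s * log(1 + decay_s / rise_s)
  kp <- (1 - exp(-tp / rise_s)) * exp(-tp / decay_s)
  k / kp
}

#' Render a synthetic reference image with ground truth
#'
#' Somata are filled 2-D Gaussian-profile disks of intensity `soma_level`
#' above the background, with the half-maximum contour at the soma radius;
#' the ground-truth label map marks pixels inside that contour. Neurite
#' distractors are straight 1-2 px wide segments at `neurite_level` above
#' background and never enter the label map. Gaussian noise is added last.
#'
#' @param spec a [field_spec()].
#' @return A list with elements `ref` (a [ref_image()]) and `truth`, a list
#'   holding `soma_centers` (tibble `roi_id`, `row`, `col`, `radius_px`),
#'   `soma_label_map` (integer matrix) and `events` (empty tibble, filled by
#'   [make_movie()]'s companion schedule helpers).
#' @export
make_reference_image <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  set.seed(spec$rng_seed)
  h <- spec$height; w <- spec$width
  img <- matrix(spec$background_level, h, w)
  label <- matrix(0L, h, w)

  margin <- 2 * spec$soma_radius_px
  centers <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  tries <- 0L
  while (nrow(centers) < spec$n_somata) {
    if (tries > 200L * max(1L, spec$n_somata))
      stop("cannot place ", spec$n_somata,
           " somata with separation 2*soma_radius in a ", h, "x", w,
           " field (packing constraint)", call. = FALSE)
    tries <- tries + 1L
    cand <- c(runif(1, 1 + margin, h - margin), runif(1, 1 + margin, w - margin))
    if (nrow(centers) == 0 ||
        all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >= 2 * spec$soma_radius_px)) {
      centers <- rbind(centers, cand)
      radii <- c(radii,
                 spec$soma_radius_px +
                   runif(1, -spec$soma_radius_jitter, spec$soma_radius_jitter))
    }
  }

  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(rep(seq_len(w), each = h), h, w)
  # somata as the pointwise maximum of Gaussian profiles over the
  # background (monolayer cell fill: overlapping cells occlude rather than
  # add, which keeps the half-maximum ground-truth contour exact)
  prof <- matrix(0, h, w)
  for (i in seq_len(nrow(centers))) {
    d2 <- (rr - centers[i, 1])^2 + (cc - centers[i, 2])^2
    sigma <- radii[i] / sqrt(2 * log(2)) # half max at r = radius
    prof <- pmax(prof, spec$soma_level * exp(-d2 / (2 * sigma^2)))
    label[d2 <= radii[i]^2] <- i
  }
  img <- img + prof

  if (spec$n_neurites > 0) {
    for (j in seq_len(spec$n_neurites)) {
      p0 <- c(runif(1, 1, h), runif(1, 1, w))
      ang <- runif(1, 0, pi)
      len <- runif(1, 20, 60)
      wid <- sample(1:2, 1)
      tt <- seq(0, len, by = 0.5)
      pr <- round(p0[1] + tt * sin(ang))
      pc <- round(p0[2] + tt * cos(ang))
      for (o in seq_len(wid) - 1L) {
        ok <- pr + o >= 1 & pr + o <= h & pc >= 1 & pc <= w
        px <- cbind(pr[ok] + o, pc[ok])
        img[px] <- pmax(img[px], spec$background_level + spec$neurite_level)
      }
    }
  }

  if (spec$noise_sd > 0) img <- img + rnorm(h * w, 0, spec$noise_sd)
  img <- pmax(img, 0)

  truth <- list(
    soma_centers = tibble::tibble(
      roi_id = seq_len(nrow(centers)),
      row = centers[, 1], col = centers[, 2], radius_px = radii),
    soma_label_map = label,
    events = tibble::tibble(roi_id = integer(), onset_frame = integer(),
                            duration_frames = integer()))
  list(ref = ref_image(img, pixel_size_um = 1, channel = "cellfill-synthetic"),
       truth = truth)
}

# expand per-block event schedules to per-ROI schedules
expand_event_times <- function(spec, n_rois) {
  if (!is.null(spec$sync_blocks)) {
    if (length(spec$event_times) != length(spec$sync_blocks))
      stop("with sync_blocks, event_times must have one entry per block",
           call. = FALSE)
    out <- vector("list", n_rois)
    for (b in seq_along(spec$sync_blocks))
      for (r in spec$sync_blocks[[b]]) out[[r]] <- spec$event_times[[b]]
    out[vapply(out, is.null, TRUE)] <- list(numeric(0))
    return(out)
  }
  if (length(spec$event_times) == 0)
    return(rep(list(numeric(0)), n_rois))
  if (length(spec$event_times) != n_rois)
    stop("event_times has ", length(spec$event_times),
         " entries for ", n_rois, " ROIs", call. = FALSE)
  spec$event_times
}

#' Ground-truth dF/F trace for one event schedule
#'
#' Sum of unit-peak transient kernels scaled to `event_amplitude`, sampled
#' on the movie's frame grid.
#'
#' @param onsets event onset times, seconds.
#' @param spec an [activity_spec()].
#' @return numeric vector of length `round(frame_rate_hz * duration_s)`.
#' @export
dff_ground_truth <- function(onsets, spec) {
  tt <- (seq_len(round(spec$frame_rate_hz * spec$duration_s)) - 1) /
    spec$frame_rate_hz
  out <- numeric(length(tt))
  for (t0 in onsets)
    out <- out + spec$event_amplitude *
      transient_kernel(tt - t0, spec$kernel_rise_s, spec$kernel_decay_s)
  out
}

#' Render a synthetic calcium movie
#'
#' Soma pixels follow `baseline * (1 + dff(t))` with `dff` the scheduled sum
#' of transients; non-soma pixels sit at a constant photon background of
#' `0.2 * baseline`. Gaussian pixel noise is added per frame, and an
#' optional rigid drift translates frame `t` by `(t-1) * drift_px_per_frame`
#' (bilinear warp, frame-median fill).
#'
#' @param truth ground truth from [make_reference_image()].
#' @param spec an [activity_spec()].
#' @return A list with `stack` (a [ts_stack()]) and `truth`: the input
#'   ground truth with its `events` table filled (`roi_id`, `onset_frame`,
#'   `duration_frames`, 1-based frames at the movie rate) and
#'   `cluster_assignment` when `sync_blocks` were given.
#' @export
make_movie <- function(truth, spec) {
  stopifnot(inherits(spec, "activity_spec"))
  label <- truth$soma_label_map
  n_roi <- max(0L, label)
  times <- expand_event_times(spec, n_roi)
  set.seed(spec$rng_seed)

  h <- nrow(label); w <- ncol(label)
  tt <- round(spec$frame_rate_hz * spec$duration_s)
  movie <- array(0.2 * spec$baseline, c(h, w, tt))
  mview <- matrix(movie, h * w, tt)
  for (r in seq_len(n_roi)) {
    idx <- which(label == r)
    dff <- dff_ground_truth(times[[r]], spec)
    mview[idx, ] <- matrix(spec$baseline * (1 + dff), length(idx), tt,
                           byrow = TRUE)
  }
  if (spec$noise_sd > 0)
    mview <- mview + rnorm(length(mview), 0, spec$noise_sd)
  movie <- array(mview, c(h, w, tt))

  if (any(spec$drift_px_per_frame != 0)) {
    for (t in seq_len(tt)) {
      sh <- (t - 1) * spec$drift_px_per_frame
      if (any(sh != 0))
        movie[, , t] <- bilinear_translate(movie[, , t], sh[1], sh[2])
    }
  }
  movie <- pmax(movie, 0)

  dur_f <- max(1L, round((spec$kernel_rise_s + 2 * spec$kernel_decay_s) *
                           spec$frame_rate_hz))
  ev <- do.call(rbind, lapply(seq_len(n_roi), function(r) {
    if (!length(times[[r]])) return(NULL)
    tibble::tibble(roi_id = r,
                   onset_frame = floor(sort(times[[r]]) * spec$frame_rate_hz) + 1L,
                   duration_frames = dur_f,
                   onset_time_s = sort(times[[r]]))
  }))
  truth$events <- if (is.null(ev))
    tibble::tibble(roi_id = integer(), onset_frame = integer(),
                   duration_frames = integer(), onset_time_s = double())
  else ev
  if (!is.null(spec$sync_blocks)) {
    ca <- integer(n_roi)
    for (b in seq_along(spec$sync_blocks)) ca[spec$sync_blocks[[b]]] <- b
    truth$cluster_assignment <- ca
  }
  list(stack = ts_stack(movie, spec$frame_rate_hz, pixel_size_um = 1,
                        channel = "calcium-synthetic"),
       truth = truth)
}

#' Draw a random event schedule with a refractory gap
#'
#' Event times uniform over the recording conditional on a minimum
#' separation between consecutive onsets — the regime the event detector
#' assumes (non-overlapping transients). Sampled exactly via the
#' order-statistics construction: draw sorted uniforms on the slack
#' interval and add back the mandatory gaps, so schedules from different
#' calls are genuinely independent at any rate the gap allows.
#'
#' @param n_events number of events.
#' @param duration_s recording length, seconds.
#' @param min_gap_s minimum separation between consecutive onsets.
#' @param margin_s dead time kept free at both ends of the recording.
#' @return sorted onset times in seconds.
#' @export
sample_event_times <- function(n_events, duration_s, min_gap_s = 5,
                               margin_s = 5) {
  if (n_events == 0) return(numeric(0))
  slack <- (duration_s - 2 * margin_s) - (n_events - 1) * min_gap_s
  if (slack < 0)
    stop("cannot fit ", n_events, " events with a ", min_gap_s,
         " s gap in ", duration_s, " s", call. = FALSE)
  s <- sort(runif(n_events, 0, slack))
  margin_s + s + (seq_len(n_events) - 1) * min_gap_s
}

#' Write the ground-truthed benchmark fixture set
#'
#' Generates five fixtures exercising the full pipeline — a segmentation
#' field (somata plus neurite distractors), an event-recovery field, a
#' synchrony/cluster field with two blocks of co-active ROIs, a drift field,
#' and a baseline + TTX-analog pair (the TTX field has zero seeded events) —
#' and writes movies/references as TIFF, ground truth as CSV (`*_somata.csv`:
#' roi_id,row,col; `*_events.csv`: roi_id,onset_frame,duration_frames) and a
#' JSON manifest listing every file with its MD5 checksum and seed.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed; each fixture derives its own sub-seed.
#' @param scale duration multiplier in `(0, 1]`; 1 reproduces the full-length
#'   study fixtures, smaller values give quick smoke fixtures.
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
make_benchmark_suite <- function(out_dir, seed = 1L, scale = 1) {
  stopifnot(scale > 0, scale <= 1)
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE))
      stop("cannot create output directory: ", out_dir, call. = FALSE)
  seed <- as.integer(seed)
  fixtures <- list()

  write_truth <- function(prefix, truth) {
    sp <- file.path(out_dir, paste0(prefix, "_somata.csv"))
    write.csv(truth$soma_centers[c("roi_id", "row", "col")], sp,
              row.names = FALSE)
    ep <- file.path(out_dir, paste0(prefix, "_events.csv"))
    write.csv(truth$events[c("roi_id", "onset_frame", "duration_frames")], ep,
              row.names = FALSE)
    c(sp, ep)
  }

  # 1. segmentation field
  fs <- field_spec(rng_seed = seed + 11L)
  seg <- make_reference_image(fs)
  p <- file.path(out_dir, "segmentation_ref.tif")
  save_reference(seg$ref, p)
  fixtures$segmentation <- list(
    files = c(p, write_truth("segmentation", seg$truth)),
    seed = fs$rng_seed, n_somata = fs$n_somata, n_neurites = fs$n_neurites)

  # 2. event-recovery field: 20 ROIs, 8 min at 4 Hz, 2 events/min/ROI
  fs <- field_spec(height = 128, width = 128, n_somata = 20, n_neurites = 0,
                   noise_sd = 0, rng_seed = seed + 23L)
  fld <- make_reference_image(fs)
  dur <- 480 * scale
  set.seed(seed + 24L)
  ev <- lapply(seq_len(20), function(r)
    sample_event_times(max(1, round(2 * dur / 60)), dur))
  asp <- activity_spec(frame_rate_hz = 4, duration_s = dur, event_times = ev,
                       event_amplitude = 1, noise_sd = 0.1 * 100,
                       baseline = 100, rng_seed = seed + 25L)
  mv <- make_movie(fld$truth, asp)
  p <- file.path(out_dir, "events_movie.tif")
  save_stack(mv$stack, p)
  pr <- file.path(out_dir, "events_ref.tif")
  save_reference(fld$ref, pr)
  fixtures$events <- list(
    files = c(p, pr, write_truth("events", mv$truth)),
    seed = fs$rng_seed, frame_rate_hz = 4, duration_s = dur)

  # 3. synchrony field: two blocks of 5 ROIs sharing event times
  fs <- field_spec(height = 96, width = 96, n_somata = 10, n_neurites = 0,
                   noise_sd = 0, rng_seed = seed + 37L)
  fld <- make_reference_image(fs)
  dur <- 300 * scale
  set.seed(seed + 38L)
  blocks <- list(A = 1:5, B = 6:10)
  ev <- lapply(blocks, function(b)
    sample_event_times(max(2, round(10 * dur / 60)), dur, min_gap_s = 2))
  asp <- activity_spec(frame_rate_hz = 10, duration_s = dur, event_times = ev,
                       sync_blocks = blocks, event_amplitude = 2,
                       noise_sd = 0.05 * 100, baseline = 100,
                       rng_seed = seed + 39L)
  mv <- make_movie(fld$truth, asp)
  p <- file.path(out_dir, "sync_movie.tif")
  save_stack(mv$stack, p)
  fixtures$sync <- list(files = c(p, write_truth("sync", mv$truth)),
                        seed = fs$rng_seed, blocks = blocks)

  # 4. drift field: +1 px/frame in x, 20 frames, noise-free
  fs <- field_spec(height = 64, width = 64, n_somata = 6, n_neurites = 0,
                   noise_sd = 0, rng_seed = seed + 41L)
  fld <- make_reference_image(fs)
  asp <- activity_spec(frame_rate_hz = 4, duration_s = 5, event_times = list(),
                       drift_px_per_frame = c(0, 1), noise_sd = 0,
                       rng_seed = seed + 42L)
  mv <- make_movie(fld$truth, asp)
  p <- file.path(out_dir, "drift_movie.tif")
  save_stack(mv$stack, p)
  fixtures$drift <- list(files = c(p, write_truth("drift", mv$truth)),
                         seed = fs$rng_seed, drift_px_per_frame = c(0, 1))

  # 5. baseline + TTX-analog pair (TTX: zero seeded events)
  fs <- field_spec(height = 128, width = 128, n_somata = 15, n_neurites = 0,
                   noise_sd = 0, rng_seed = seed + 53L)
  fld <- make_reference_image(fs)
  dur <- 240 * scale
  set.seed(seed + 54L)
  ev <- lapply(seq_len(15), function(r)
    sample_event_times(max(1, round(2 * dur / 60)), dur))
  base_spec <- activity_spec(frame_rate_hz = 4, duration_s = dur,
                             event_times = ev, noise_sd = 0.1 * 100,
                             baseline = 100, rng_seed = seed + 55L)
  ttx_spec <- activity_spec(frame_rate_hz = 4, duration_s = dur,
                            event_times = list(), noise_sd = 0.1 * 100,
                            baseline = 100, rng_seed = seed + 56L)
  mb <- make_movie(fld$truth, base_spec)
  mt <- make_movie(fld$truth, ttx_spec)
  pb <- file.path(out_dir, "baseline_movie.tif")
  pt <- file.path(out_dir, "ttx_movie.tif")
  save_stack(mb$stack, pb)
  save_stack(mt$stack, pt)
  pr <- file.path(out_dir, "pharm_ref.tif")
  save_reference(fld$ref, pr)
  f1 <- write_truth("baseline", mb$truth)
  f2 <- write_truth("ttx", mt$truth)
  fixtures$pharmacology <- list(files = c(pb, pt, pr, f1, f2),
                                seed = fs$rng_seed)

  all_files <- unlist(lapply(fixtures, `[[`, "files"), use.names = FALSE)
  manifest <- list(
    seed = seed, scale = scale,
    fixtures = lapply(fixtures, function(f) {
      f$checksums <- as.list(tools::md5sum(f$files))
      f$files <- basename(f$files)
      names(f$checksums) <- basename(names(f$checksums))
      f
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
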