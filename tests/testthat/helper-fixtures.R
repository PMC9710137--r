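# Shared synthetic fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (!exists(name, envir = .fx)) assign(name, expr, envir = .fx)
  get(name, envir = .fx)
}

# segmentation study field: 30 somata + 40 neurite distractors, 256x256
fx_seg_field <- function() fx("seg_field", {
  make_reference_image(field_spec(rng_seed = 1L))
})

# event-recovery study field: 20 ROIs, 8 min at 4 Hz, 2 events/min/ROI,
# amplitude 1.0 dF/F, pixel noise 0.1 x baseline
fx_event_recovery <- function() fx("event_recovery", {
  fld <- make_reference_image(field_spec(height = 128, width = 128,
                                         n_somata = 20, n_neurites = 0,
                                         noise_sd = 0, rng_seed = 5L))
  set.seed(100)
  ev <- lapply(1:20, function(r) sample_event_times(16, 480))
  asp <- activity_spec(frame_rate_hz = 4, duration_s = 480, event_times = ev,
                       event_amplitude = 1, baseline = 100, noise_sd = 10,
                       rng_seed = 6L)
  mv <- make_movie(fld$truth, asp)
  rois <- roi_set(fld$truth$soma_label_map)
  dff10 <- resample_traces(rolling_dff(extract_traces(mv$stack, rois), 50), 10)
  list(truth = mv$truth, rois = rois, dff10 = dff10,
       duration_s = 480)
})

# baseline + TTX-analog pair: 15 ROIs, 4 min at 4 Hz; the TTX field has
# zero seeded events and is scored with the baseline-derived threshold
fx_pharm_pair <- function() fx("pharm_pair", {
  fld <- make_reference_image(field_spec(height = 128, width = 128,
                                         n_somata = 15, n_neurites = 0,
                                         noise_sd = 0, rng_seed = 53L))
  set.seed(54)
  ev <- lapply(1:15, function(r) sample_event_times(8, 240))
  rois <- roi_set(fld$truth$soma_label_map)
  dff_of <- function(asp) {
    mv <- make_movie(fld$truth, asp)
    resample_traces(rolling_dff(extract_traces(mv$stack, rois), 50), 10)
  }
  base <- dff_of(activity_spec(frame_rate_hz = 4, duration_s = 240,
                               event_times = ev, event_amplitude = 1,
                               baseline = 100, noise_sd = 10, rng_seed = 55L))
  ttx <- dff_of(activity_spec(frame_rate_hz = 4, duration_s = 240,
                              event_times = list(), event_amplitude = 1,
                              baseline = 100, noise_sd = 10, rng_seed = 56L))
  list(rois = rois, base = base, ttx = ttx, duration_s = 240)
})

# direct dF/F trace fixtures for synchrony: 10 ROIs, 5 min at 10 Hz,
# network bursts at 10/min (amplitude 2 dF/F), trace noise sd 0.1
fx_sync_traces <- function(kind) fx(paste0("sync_", kind), {
  build <- function(schedules, seed) {
    set.seed(seed)
    sp <- activity_spec(frame_rate_hz = 10, duration_s = 300,
                        event_amplitude = 2)
    v <- t(vapply(schedules, function(tt)
      dff_ground_truth(tt, sp) + rnorm(3000, 0, 0.1), numeric(3000)))
    dff_matrix(v, seq_along(schedules), 10)
  }
  switch(kind,
    full = {
      set.seed(11)
      shared <- sample_event_times(50, 300, min_gap_s = 2)
      build(rep(list(shared), 10), seed = 2)
    },
    indep = {
      set.seed(12)
      build(lapply(1:10, function(i) sample_event_times(50, 300, min_gap_s = 2)),
            seed = 4)
    },
    block = {
      set.seed(13)
      tA <- sample_event_times(50, 300, min_gap_s = 2)
      tB <- sample_event_times(50, 300, min_gap_s = 2)
      build(c(rep(list(tA), 5), rep(list(tB), 5)), seed = 6)
    })
})

# drift study field: 6 somata on 64x64, +1 px/frame drift in x, 20 frames
fx_drift_movie <- function() fx("drift_movie", {
  fld <- make_reference_image(field_spec(height = 64, width = 64,
                                         n_somata = 6, n_neurites = 0,
                                         noise_sd = 0, rng_seed = 41L))
  asp <- activity_spec(frame_rate_hz = 4, duration_s = 5,
                       drift_px_per_frame = c(0, 1), noise_sd = 0,
                       rng_seed = 42L)
  list(field = fld, movie = make_movie(fld$truth, asp))
})
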