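make_test_rois <- function() {
  lab <- matrix(0L, 30, 30)
  lab[3:8, 3:8] <- 1L
  lab[15:20, 15:20] <- 2L
  roi_set(lab)
}

event_row <- function(roi, onset, dur, motif) {
  tibble::tibble(roi_id = as.integer(roi), onset_frame = as.integer(onset),
                 duration_frames = as.integer(dur),
                 onset_time_s = (onset - 1) / 10, duration_s = dur / 10,
                 motif_id = as.integer(motif), peak_correlation = 0.9)
}

test_that("per-ROI metrics average durations and partition events by motif", {
  rois <- make_test_rois()
  ev <- rbind(event_row(1, 1, 2, 3), event_row(1, 50, 4, 5))
  lng <- build_roi_metrics(rois, ev, name = "f1")
  expect_identical(nrow(lng), 2L)
  r1 <- lng[lng$roi_id == 1, ]
  expect_equal(r1$events_ROI, 2L)
  expect_equal(r1$avg_width, 3)
  expect_equal(r1$avg_width_s, 0.3)
  expect_equal(r1$motif_3 + r1$motif_5, 2L)
  # inactive ROI: zero events, missing width, all-zero motif columns
  r2 <- lng[lng$roi_id == 2, ]
  expect_equal(r2$events_ROI, 0L)
  expect_true(is.na(r2$avg_width))
  mcols <- as.matrix(lng[, paste0("motif_", 1:23)])
  expect_equal(unname(rowSums(mcols)), lng$events_ROI)
  expect_equal(lng$volume, c(36L, 36L))
  # orphan events are a consistency error
  expect_error(build_roi_metrics(rois, event_row(9, 1, 2, 1)), "absent")
})

test_that("image metrics compute counts, proportions and rates", {
  rois <- make_test_rois()
  ev <- rbind(event_row(1, 1, 2, 3), event_row(2, 30, 2, 4))
  man <- build_image_metrics(rois, ev, sync = NULL, duration_s = 300,
                             name = "f1")
  expect_equal(man$num_ROI, 2L)
  expect_equal(man$num_active_ROI, 2L)
  expect_equal(man$prop_active_ROI, 1)
  # 2 events / 2 ROIs / 5 min
  expect_equal(man$events_per_roi_per_min, 0.2)
  # the documented arithmetic: 120 events, 10 ROIs, 300 s -> 2.4
  expect_equal(120 / 10 / (300 / 60), 2.4)
  mcols <- as.matrix(man[, paste0("motif_", 1:23)])
  expect_equal(sum(mcols), nrow(ev))
})

test_that("an empty field yields a zero-count metrics row", {
  empty <- roi_set(matrix(0L, 10, 10))
  man <- build_image_metrics(empty, empty_event_table_for_test(),
                             sync = NULL, duration_s = 60)
  expect_equal(man$num_ROI, 0L)
  expect_equal(man$prop_active_ROI, 0)
  expect_equal(man$events_per_roi_per_min, 0)
  lng <- build_roi_metrics(empty, empty_event_table_for_test())
  expect_identical(nrow(lng), 0L)
})

test_that("the full pipeline runs end to end and is deterministic", {
  fld <- make_reference_image(field_spec(height = 96, width = 96,
                                         n_somata = 8, n_neurites = 6,
                                         rng_seed = 61L))
  set.seed(62)
  ev <- lapply(1:8, function(r) sample_event_times(4, 120))
  mv <- make_movie(fld$truth,
                   activity_spec(frame_rate_hz = 4, duration_s = 120,
                                 event_times = ev, baseline = 100,
                                 noise_sd = 10, rng_seed = 63L))
  d1 <- file.path(tempdir(), "run1")
  d2 <- file.path(tempdir(), "run2")
  r1 <- run_pipeline(fld$ref, mv$stack, sync_cfg = synchrony_config(rng_seed = 9L),
                     name = "demo", out_dir = d1)
  r2 <- run_pipeline(fld$ref, mv$stack, sync_cfg = synchrony_config(rng_seed = 9L),
                     name = "demo", out_dir = d2)
  expect_equal(r1$man$num_ROI, 8L, tolerance = 0) # well-separated field
  expect_gte(r1$man$num_active_ROI, 7L)
  expect_true(file.exists(file.path(d1, "man.csv")))
  for (f in c("man.csv", "long_data.csv", "events.csv", "corr_matrix.csv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("pipeline accepts TIFF paths and a high-resolution reference", {
  fld <- make_reference_image(field_spec(height = 64, width = 64,
                                         n_somata = 4, n_neurites = 0,
                                         rng_seed = 71L))
  mv <- make_movie(fld$truth,
                   activity_spec(frame_rate_hz = 4, duration_s = 30,
                                 event_times = rep(list(15), 4),
                                 noise_sd = 5, rng_seed = 72L))
  pr <- tempfile(fileext = ".tif")
  pm <- tempfile(fileext = ".tif")
  save_reference(fld$ref, pr)
  save_stack(mv$stack, pm)
  res <- run_pipeline(pr, pm, sync_cfg = synchrony_config(rng_seed = 1L))
  expect_identical(res$man$num_ROI, 4L)
  expect_identical(res$man$num_active_ROI, 4L)
  unlink(c(pr, pm, paste0(c(pr, pm), ".json")))
})
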