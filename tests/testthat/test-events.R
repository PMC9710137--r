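test_that("the default motif library honors its contract", {
  lib <- default_motif_library()
  expect_length(lib$motifs, 23)
  expect_identical(sum(lib$origin == "fluorosnnap"), 16L)
  expect_identical(sum(lib$origin == "capture"), 7L)
  lens <- vapply(lib$motifs, length, 1L)
  expect_true(all(lens >= 5))
  expect_true(all(vapply(lib$motifs, sd, 1) > 0))
  expect_true(all(vapply(lib$motifs, max, 1) == 1)) # peak-normalized
})

test_that("the motif library round trips through CSV exactly", {
  lib <- default_motif_library()
  p <- tempfile(fileext = ".csv")
  write_motif_library(lib, p)
  back <- read_motif_library(p)
  expect_equal(back$motifs, lib$motifs)
  expect_identical(back$origin, lib$origin)
  expect_equal(back$frame_rate_hz, 10)
  unlink(c(p, paste0(p, ".json")))
})

test_that("an embedded motif correlates at exactly +/-1 at its onset", {
  lib <- default_motif_library()
  m <- lib$motifs[[7]]
  tr <- rep(0, 300)
  tr[101:(100 + length(m))] <- m
  cm <- motif_correlation_map(tr, lib, height_threshold = -Inf)
  expect_equal(cm$Ca[7, 101], 1)
  cm2 <- motif_correlation_map(-tr, lib, height_threshold = -Inf)
  expect_equal(cm2$Ca[7, 101], -1)
})

test_that("height gating zeroes sub-threshold columns and flat windows", {
  lib <- default_motif_library()
  cm <- motif_correlation_map(rep(0, 300), lib, height_threshold = 0.1)
  expect_true(all(cm$Ca == 0))
  # flat trace with no gating: undefined correlations map to 0
  cm2 <- motif_correlation_map(rep(1, 300), lib, height_threshold = -Inf)
  expect_true(all(cm2$Ca == 0))
  expect_error(motif_correlation_map(rep(0, 10), lib), "shorter")
})

test_that("run extraction matches the hand-enumerated example", {
  fake <- structure(list(Ca = rbind(c(0, 0.8, 0.9, 0.6, 0.75)),
                         height_threshold = 0, trace = rep(1, 5)),
                    class = "corr_map")
  ev <- detect_events(fake, corr_threshold = 0.7)
  expect_identical(nrow(ev), 2L)
  expect_equal(ev$onset_frame, c(2L, 5L))
  expect_equal(ev$duration_frames, c(2L, 1L))
  expect_equal(ev$peak_correlation, c(0.9, 0.75))
  # silent map
  fake$Ca <- rbind(rep(0.2, 5))
  expect_identical(nrow(detect_events(fake, 0.7)), 0L)
  # threshold 0 picks up every positive run
  ev0 <- detect_events(fake, 0)
  expect_identical(nrow(ev0), 1L)
  expect_equal(ev0$duration_frames, 5L)
})

test_that("motif assignment at the run peak breaks ties to the lowest index", {
  ca <- rbind(c(0, 0.75, 0.80, 0),
              c(0, 0.75, 0.80, 0))
  fake <- structure(list(Ca = ca, height_threshold = 0, trace = rep(1, 4)),
                    class = "corr_map")
  ev <- detect_events(fake, 0.7)
  expect_identical(ev$motif_id, 1L)
})

test_that("event counts fall monotonically with both thresholds", {
  fxd <- fx_event_recovery()
  tr <- fxd$dff10$values[1, ]
  lib <- default_motif_library()
  counts_corr <- vapply(c(0.5, 0.7, 0.9), function(ct)
    nrow(detect_events(motif_correlation_map(tr, lib, 0.05), ct)), 1L)
  expect_true(all(diff(counts_corr) <= 0))
  counts_h <- vapply(c(0.02, 0.2, 0.8), function(h)
    nrow(detect_events(motif_correlation_map(tr, lib, h), 0.7)), 1L)
  expect_true(all(diff(counts_h) <= 0))
})

test_that("events within a ROI never overlap", {
  fxd <- fx_event_recovery()
  ev <- detect_all_events(fxd$dff10, corr_threshold = 0.7,
                          height_threshold = "auto")
  for (r in unique(ev$roi_id)) {
    e <- ev[ev$roi_id == r, ]
    e <- e[order(e$onset_frame), ]
    if (nrow(e) > 1)
      expect_true(all(diff(e$onset_frame) >= e$duration_frames[-nrow(e)]))
    expect_lte(sum(e$duration_frames), ncol(fxd$dff10$values))
  }
})

test_that("motif summaries count and normalize correctly", {
  ev <- tibble::tibble(roi_id = c(1L, 1L, 1L), onset_frame = c(1L, 10L, 20L),
                       duration_frames = c(2L, 2L, 2L),
                       onset_time_s = c(0, 0.9, 1.9),
                       duration_s = rep(0.2, 3),
                       motif_id = c(3L, 3L, 7L),
                       peak_correlation = rep(0.9, 3))
  s <- summarize_motifs(ev, n_rois = 2)
  expect_equal(s$field_counts$count[c(3, 7)], c(2L, 1L))
  expect_equal(sum(s$field_counts$count), 3L)
  p1 <- s$roi_percentages[s$roi_percentages$roi_id == 1, ]
  expect_equal(p1$pct[p1$motif_id == 3], 200 / 3)
  expect_equal(sum(p1$pct), 100)
  p2 <- s$roi_percentages[s$roi_percentages$roi_id == 2, ]
  expect_true(all(p2$pct == 0))
  s0 <- summarize_motifs(empty_event_table_for_test(), n_rois = 1)
  expect_true(all(s0$field_counts$count == 0))
})

test_that("the automatic height threshold is the robust 3-sigma rule", {
  z <- dff_matrix(matrix(0, 2, 50), 1:2, 10)
  expect_equal(estimate_height_threshold(z, "auto"), 0)
  expect_equal(estimate_height_threshold(z, 0.5), 0.5)
  set.seed(123)
  g <- dff_matrix(matrix(rnorm(1e5), 4), 1:4, 10)
  expect_equal(estimate_height_threshold(g, "auto"), 3, tolerance = 0.2 / 3)
  allna <- dff_matrix(matrix(NA_real_, 1, 10), 1L, 10)
  expect_error(estimate_height_threshold(allna, "auto"), "missing")
})
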