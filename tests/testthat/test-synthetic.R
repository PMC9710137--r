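test_that("an empty noise-free field is constant at the background level", {
  out <- make_reference_image(field_spec(height = 32, width = 32,
                                         n_somata = 0, n_neurites = 0,
                                         noise_sd = 0, background_level = 17))
  expect_true(all(out$ref$data == 17))
  expect_identical(max(out$truth$soma_label_map), 0L)
})

test_that("field generation is bit-identical under a fixed seed", {
  a <- make_reference_image(field_spec(rng_seed = 3L))
  b <- make_reference_image(field_spec(rng_seed = 3L))
  expect_identical(a$ref$data, b$ref$data)
  expect_identical(a$truth$soma_label_map, b$truth$soma_label_map)
  expect_equal(a$truth$soma_centers, b$truth$soma_centers)
})

test_that("label map carries exactly the somata and no neurites", {
  out <- fx_seg_field() # 30 somata, 40 neurites
  lab <- out$truth$soma_label_map
  expect_identical(sort(unique(lab[lab > 0])), 1:30)
  # every labeled pixel lies within its soma's half-maximum disk
  tc <- out$truth$soma_centers
  for (i in c(1, 15, 30)) {
    px <- which(lab == i, arr.ind = TRUE)
    d <- sqrt((px[, 1] - tc$row[i])^2 + (px[, 2] - tc$col[i])^2)
    expect_lte(max(d), tc$radius_px[i])
  }
})

test_that("impossible soma packing raises a generation error", {
  expect_error(
    make_reference_image(field_spec(height = 32, width = 32, n_somata = 60)),
    "packing")
})

test_that("a silent noise-free movie keeps every soma at baseline", {
  fld <- make_reference_image(field_spec(height = 48, width = 48,
                                         n_somata = 3, n_neurites = 0,
                                         noise_sd = 0, rng_seed = 8L))
  mv <- make_movie(fld$truth, activity_spec(frame_rate_hz = 4, duration_s = 10,
                                            baseline = 80, noise_sd = 0))
  tr <- extract_traces(mv$stack, roi_set(fld$truth$soma_label_map))
  expect_true(all(tr$values == 80))
})

test_that("a single noise-free event peaks at onset plus the kernel argmax", {
  fld <- make_reference_image(field_spec(height = 48, width = 48,
                                         n_somata = 1, n_neurites = 0,
                                         noise_sd = 0, rng_seed = 9L))
  sp <- activity_spec(frame_rate_hz = 4, duration_s = 30,
                      event_times = list(10), noise_sd = 0)
  mv <- make_movie(fld$truth, sp)
  tr <- extract_traces(mv$stack, roi_set(fld$truth$soma_label_map))
  # analytic argmax of the sampled kernel
  tt <- (seq_len(120) - 1) / 4
  k <- transient_kernel(tt - 10, sp$kernel_rise_s, sp$kernel_decay_s)
  expect_identical(which.max(tr$values[1, ]), which.max(k))
  # noise-free soma pixels reproduce the analytic kernel exactly
  expect_equal(tr$values[1, ], 100 * (1 + dff_ground_truth(10, sp)),
               tolerance = 1e-12)
})

test_that("sync blocks share event schedules exactly", {
  fld <- make_reference_image(field_spec(height = 96, width = 96,
                                         n_somata = 6, n_neurites = 0,
                                         noise_sd = 0, rng_seed = 10L))
  sp <- activity_spec(frame_rate_hz = 4, duration_s = 60,
                      event_times = list(c(10, 30), c(20, 40)),
                      sync_blocks = list(A = 1:3, B = 4:6), noise_sd = 0)
  mv <- make_movie(fld$truth, sp)
  ev <- mv$truth$events
  for (r in 1:3)
    expect_equal(ev$onset_time_s[ev$roi_id == r], c(10, 30))
  for (r in 4:6)
    expect_equal(ev$onset_time_s[ev$roi_id == r], c(20, 40))
  expect_identical(mv$truth$cluster_assignment, c(1L, 1L, 1L, 2L, 2L, 2L))
})

test_that("event times outside the recording are rejected", {
  expect_error(activity_spec(duration_s = 100, event_times = list(c(5, 100))),
               "event times")
  expect_error(activity_spec(kernel_rise_s = 2, kernel_decay_s = 1))
})

test_that("the benchmark suite is deterministic and complete", {
  d1 <- file.path(tempdir(), "suite1")
  d2 <- file.path(tempdir(), "suite2")
  m1 <- make_benchmark_suite(d1, seed = 7L, scale = 0.05)
  m2 <- make_benchmark_suite(d2, seed = 7L, scale = 0.05)
  expect_length(m1$fixtures, 5)
  expect_named(m1$fixtures, c("segmentation", "events", "sync", "drift",
                              "pharmacology"))
  # identical manifests (checksums included) => bit-identical files
  expect_equal(m1$fixtures, m2$fixtures)
  # the TTX-analog ground truth has no events
  ttx <- read.csv(file.path(d1, "ttx_events.csv"))
  expect_identical(nrow(ttx), 0L)
  unlink(c(d1, d2), recursive = TRUE)
})
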