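test_that("h-minima suppression: identity and constant cases", {
  m <- matrix(as.numeric(1:16), 4, 4)
  expect_identical(suppress_minima(m, 0), m)
  expect_equal(suppress_minima(matrix(5, 6, 6), 12), matrix(5, 6, 6))
  expect_error(suppress_minima(m, -1), "non-negative")
})

test_that("h-minima suppression equals the brute-force reconstruction oracle", {
  set.seed(42)
  for (i in 1:30) {
    img <- matrix(as.numeric(sample(0:30, 256, replace = TRUE)), 16, 16)
    h <- sample(1:12, 1)
    out <- suppress_minima(img, h)
    expect_equal(out, oracle_suppress_minima(img, h))
    # output bounded between the input and the lifted input
    expect_true(all(out >= img) && all(out <= img + h))
  }
})

test_that("region growing consumes a uniform image entirely", {
  fg <- region_grow_background(matrix(7, 9, 9), 1)
  expect_false(any(fg))
  expect_error(region_grow_background(matrix(1, 3, 3), 0), "positive")
})

test_that("region growing isolates bright blocks from a dim background", {
  img <- matrix(10, 8, 8)
  img[3:4, 5:6] <- 100
  fg <- region_grow_background(img, sd(img))
  expect_identical(which(fg), which(img == 100))
  img2 <- matrix(10, 12, 12)
  img2[2:3, 2:3] <- 90
  img2[9:10, 8:9] <- 110
  fg2 <- region_grow_background(img2, sd(img2))
  expect_identical(sort(which(fg2)), which(img2 > 10))
})

test_that("region growing matches the brute-force frontier oracle, ties included", {
  set.seed(17)
  for (i in 1:15) {
    img <- matrix(as.numeric(sample(0:5, 144, replace = TRUE)), 12, 12)
    tol <- runif(1, 0.5, 3)
    expect_identical(region_grow_background(img, tol),
                     oracle_region_grow(img, tol))
  }
})

test_that("watershed splitting: disjoint blobs are connected components", {
  m <- matrix(FALSE, 20, 20)
  m[2:5, 2:5] <- TRUE
  m[12:16, 10:14] <- TRUE
  lab <- split_and_label(m, matrix(1, 20, 20))
  expect_identical(max(lab), 2L)
  expect_identical(lab > 0, m)
  single <- matrix(FALSE, 8, 8); single[2:5, 2:5] <- TRUE
  l1 <- split_and_label(single, matrix(1, 8, 8))
  expect_identical(l1 > 0, single)
  expect_identical(max(l1), 1L)
  expect_identical(max(split_and_label(matrix(FALSE, 5, 5),
                                       matrix(0, 5, 5))), 0L)
})

test_that("touching equal somata 1.5 radii apart split into two labels", {
  r0 <- 6; sig <- r0 / sqrt(2 * log(2)); sep <- 1.5 * r0
  x <- matrix(seq_len(48), 48, 48); y <- t(x)
  c1 <- 24 - sep / 2; c2 <- 24 + sep / 2
  img <- 100 * pmax(exp(-((x - c1)^2 + (y - 24)^2) / (2 * sig^2)),
                    exp(-((x - c2)^2 + (y - 24)^2) / (2 * sig^2)))
  lab <- split_and_label(img > 50, img)
  expect_identical(max(lab), 2L)
  expect_true(lab[round(c1), 24] != lab[round(c2), 24])
  expect_true(all(lab[cbind(c(round(c1), round(c2)), c(24, 24))] > 0))
})

test_that("ROI filters drop lines and border objects but keep disks", {
  lab <- matrix(0L, 100, 100)
  cc <- expand.grid(r = 1:100, c = 1:100)
  disk <- (cc$r - 40)^2 + (cc$c - 40)^2 <= 15^2
  lab[cbind(cc$r[disk], cc$c[disk])] <- 1L
  lab[80, 20:79] <- 2L            # 1-px line, length 60
  lab[1:6, 90:95] <- 3L           # touches the border
  rs <- filter_rois(lab, segmentation_config(min_size_px = 30))
  expect_identical(rs$records$roi_id, 1L)
  expect_lte(rs$records$eccentricity, 0.05)
  excl <- attr(rs, "excluded")
  expect_setequal(excl$excluded_reason, c("eccentricity", "border"))
  expect_gt(excl$eccentricity[excl$excluded_reason == "eccentricity"], 0.99)
})

test_that("filtering relabels survivors contiguously and never grows ROIs", {
  lab <- matrix(0L, 30, 30)
  lab[5:10, 5:10] <- 1L   # 36 px, kept
  lab[20, 5:20] <- 2L     # line, dropped
  lab[15:20, 22:27] <- 3L # 36 px, kept
  rs <- filter_rois(lab, segmentation_config(min_size_px = 10))
  expect_identical(rs$records$roi_id, c(1L, 2L))
  expect_identical(sort(unique(as.vector(rs$label_map))), c(0L, 1L, 2L))
  expect_identical(sum(rs$label_map == 2L), 36L)
  expect_lte(nrow(rs$records), 3L)
  # empty input
  rs0 <- filter_rois(matrix(0L, 5, 5), segmentation_config(min_size_px = 3))
  expect_identical(n_rois(rs0), 0L)
})

test_that("a single-pixel ROI is assigned zero eccentricity", {
  expect_identical(roi_eccentricity(4, 7), 0)
})

test_that("segmenting a constant reference returns no ROIs", {
  expect_identical(n_rois(segment_reference(ref_image(matrix(3, 64, 64)))), 0L)
})

test_that("segmentation recovers seeded somata and rejects neurites", {
  out <- fx_seg_field() # 30 somata, 40 neurite distractors
  rois <- segment_reference(out$ref)
  rec <- rois$records
  tc <- out$truth$soma_centers
  hits <- vapply(seq_len(nrow(tc)), function(i) {
    d <- sqrt((rec$centroid_row - tc$row[i])^2 +
                (rec$centroid_col - tc$col[i])^2)
    any(d <= tc$radius_px[i])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # no surviving ROI away from every true soma (i.e. no neurite ROIs)
  false_rois <- vapply(seq_len(nrow(rec)), function(j) {
    d <- sqrt((tc$row - rec$centroid_row[j])^2 +
                (tc$col - rec$centroid_col[j])^2)
    !any(d <= 2 * tc$radius_px)
  }, logical(1))
  expect_identical(sum(false_rois), 0L)
  # deterministic rerun
  expect_identical(segment_reference(out$ref)$label_map, rois$label_map)
})
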