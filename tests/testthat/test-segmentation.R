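# Per-frame pipeline stages: crop, masks, binarisation, blob filter, holes.

test_that("crop_roi does exact coordinate bookkeeping", {
  f <- array(seq_len(10 * 10 * 3), dim = c(10, 10, 3)) %% 256
  expect_identical(crop_roi(f, c(1, 1, 10, 10)), f)
  sub <- crop_roi(f, c(3, 4, 4, 5))
  expect_identical(dim(sub), c(4L, 5L, 3L))
  expect_identical(sub[1, 1, ], f[3, 4, ])
  expect_identical(sub[4, 5, ], f[6, 8, ])
  expect_error(crop_roi(f, c(1, 7, 4, 5)), "right edge")
  expect_error(crop_roi(f, c(8, 1, 5, 5)), "bottom edge")
  expect_error(crop_roi(f, c(0, 1, 2, 2)), "top edge")
})

test_that("threshold_mask applies strict open intervals on all channels", {
  thr <- frontal_config()$garment_threshold
  inside <- lab_array(matrix(50), matrix(0), matrix(0))
  expect_true(threshold_mask(inside, thr)[1, 1])
  high_L <- lab_array(matrix(99), matrix(0), matrix(0))
  expect_false(threshold_mask(high_L, thr)[1, 1])
  # boundary-equal values are excluded (strict bounds)
  at_bound <- lab_array(matrix(98.620), matrix(0), matrix(0))
  expect_false(threshold_mask(at_bound, thr)[1, 1])
  # vacuous constraint keeps everything
  wide <- lab_threshold(L = c(-1e6, 1e6), a = c(-1e6, 1e6), b = c(-1e6, 1e6))
  lab <- lab_array(matrix(runif(20, 0, 100), 4, 5),
                   matrix(rnorm(20, 0, 50), 4, 5),
                   matrix(rnorm(20, 0, 50), 4, 5))
  expect_true(all(threshold_mask(lab, wide)))
})

test_that("replace_pixels changes exactly the masked pixels", {
  set.seed(7)
  f <- array(sample(0:255, 6 * 8 * 3, TRUE), dim = c(6, 8, 3))
  none <- matrix(FALSE, 6, 8)
  expect_identical(replace_pixels(f, none, c(27, 131, 135)), f)
  all_m <- matrix(TRUE, 6, 8)
  out <- replace_pixels(f, all_m, c(27, 131, 135))
  expect_true(all(out[, , 1] == 27 & out[, , 2] == 131 & out[, , 3] == 135))
  one <- none; one[3, 5] <- TRUE
  out1 <- replace_pixels(f, one, c(1, 2, 3))
  differs <- apply(out1 != f, c(1, 2), any)
  expect_identical(sum(differs), 1L)
  expect_equal(out1[3, 5, ], c(1, 2, 3), ignore_attr = TRUE)
  # property: pixel-difference count equals mask area
  for (i in 1:5) {
    m <- matrix(runif(48) < 0.3, 6, 8)
    o <- replace_pixels(f, m, c(250, 250, 250))
    expect_identical(sum(apply(o != f, c(1, 2), any)),
                     sum(m & !(f[, , 1] == 250 & f[, , 2] == 250 &
                                 f[, , 3] == 250)))
  }
  expect_error(replace_pixels(f, matrix(TRUE, 2, 2), c(0, 0, 0)), "dimensions")
})

test_that("water_mask keeps the open L* interval", {
  ls <- matrix(c(82.5, 200, 5, 160, 6, 159.9), 2, 3)
  m <- water_mask(ls, c(5, 160))
  expect_identical(as.vector(m), c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_true(all(water_mask(ls, c(-1, 256))))
})

test_that("waterline_filter zeroes rows above the line (1-based i >= line)", {
  m <- matrix(TRUE, 100, 7)
  out <- waterline_filter(m, 97)
  expect_identical(sum(out), 4L * 7L)       # rows 97..100 survive
  expect_true(all(!out[1:96, ]))
  expect_identical(waterline_filter(m, 1), m)  # nothing above the line
  empty <- matrix(FALSE, 10, 3)
  expect_identical(waterline_filter(empty, 5), empty)
  expect_error(waterline_filter(m, 101), "outside")
  # idempotent
  expect_identical(waterline_filter(out, 97), out)
})

test_that("binarise separates a bimodal image and flags constant ones", {
  g <- matrix(c(rep(10L, 32), rep(200L, 32)), 8, 8)
  bw <- binarise(g)
  thr <- attr(bw, "threshold")
  expect_gte(thr, 10)
  expect_lt(thr, 200)
  expect_identical(as.vector(bw), as.vector(g > thr))
  expect_identical(sum(bw), 32L)

  expect_warning(cw <- binarise(matrix(7L, 5, 5)), "constant")
  expect_false(any(cw))
  expect_true(is.na(attr(cw, "threshold")))
})

test_that("binarise equals the brute-force between-class-variance search", {
  set.seed(11)
  for (i in 1:25) {
    g <- matrix(sample(0:255, 256, TRUE), 16, 16)
    expect_identical(attr(binarise(g), "threshold"), oracle_otsu(g))
  }
})

test_that("filter_blobs keeps only components of at least min_area", {
  m <- matrix(FALSE, 80, 80)
  m[10:59, 10:79] <- TRUE          # 50 x 70 = 3500 px component
  m[70:74, 5] <- TRUE              # 5 px component
  out <- filter_blobs(m, 3000)
  expect_identical(count_area(out), 3500L)
  expect_true(all(out[10:59, 10:79]))
  expect_false(any(out[70:74, 5]))
  expect_identical(filter_blobs(m, 0), m)
  expect_false(any(filter_blobs(m, 4000)))
})

test_that("filter_blobs matches a brute-force flood-fill labeller", {
  set.seed(21)
  for (i in 1:15) {
    m <- matrix(runif(40 * 40) < 0.35, 40, 40)
    min_area <- sample(c(2, 5, 12, 40), 1)
    got <- filter_blobs(m, min_area)
    want <- oracle_filter_blobs(m, min_area)
    expect_identical(unname(got), unname(want))
    # subset of input, and every surviving component is large enough
    expect_true(all(!got | m))
    lab <- oracle_label(got, 8)
    if (max(lab) > 0)
      expect_true(all(tabulate(lab[lab > 0]) >= min_area))
  }
})

test_that("fill_holes fills enclosed holes only, and is idempotent", {
  solid <- matrix(FALSE, 8, 8); solid[3:6, 3:6] <- TRUE
  expect_identical(fill_holes(solid), solid)

  ring <- matrix(FALSE, 9, 9)
  ring[3:7, 3] <- TRUE; ring[3:7, 7] <- TRUE
  ring[3, 3:7] <- TRUE; ring[7, 3:7] <- TRUE
  filled <- fill_holes(ring)
  expect_identical(count_area(filled), 25L)    # full 5 x 5 disc region

  bay <- matrix(FALSE, 6, 6)
  bay[2:5, 2] <- TRUE; bay[2:5, 5] <- TRUE; bay[5, 2:5] <- TRUE
  expect_identical(fill_holes(bay), bay)       # open to the border

  set.seed(31)
  for (i in 1:10) {
    m <- matrix(runif(30 * 30) < 0.45, 30, 30)
    f <- fill_holes(m)
    expect_identical(f, oracle_fill_holes(m))
    expect_true(all(f[m]))                     # superset of the input
    expect_identical(fill_holes(f), f)
  }
})

test_that("count_area counts foreground pixels", {
  expect_identical(count_area(matrix(FALSE, 4, 4)), 0L)
  expect_identical(count_area(matrix(TRUE, 10, 10)), 100L)
})

test_that("process_frame recovers the silhouette area on synthetic scenes", {
  sc <- render_scene(scene_spec(seed = 3))
  res <- process_frame(sc$frame)
  expect_s3_class(res, "frame_result")
  expect_identical(res$area_pixels, count_area(res$final_mask))
  rel_err <- abs(res$area_pixels - sc$truth$area_pixels) /
    sc$truth$area_pixels
  expect_lt(rel_err, 0.05)
})

test_that("degenerate frames give area 0 with a warning code, not an error", {
  # swimmer entirely above the configured water line
  sc <- render_scene(scene_spec(seed = 4))
  res <- process_frame(sc$frame, frontal_config(waterline_row = 220))
  expect_identical(res$area_pixels, 0L)
  expect_gt(length(res$warnings), 0)

  # pure-water scene
  sc2 <- render_scene(scene_spec(swimmer = NULL, seed = 5))
  res2 <- process_frame(sc2$frame)
  expect_identical(res2$area_pixels, 0L)
  expect_gt(length(res2$warnings), 0)
})

test_that("a larger swimmer never yields a smaller reported area", {
  for (s in 1:20) {
    small <- render_scene(scene_spec(seed = s,
                                     swimmer = default_swimmer(1.0)))
    large <- render_scene(scene_spec(seed = s,
                                     swimmer = default_swimmer(1.15)))
    expect_gte(process_frame(large$frame)$area_pixels,
               process_frame(small$frame)$area_pixels)
  }
})
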