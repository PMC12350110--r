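test_that("disjoint bright disks are each counted and measured", {
  img <- draw_disks(120, 120, cx = c(20, 60, 100, 30, 90),
                    cy = c(20, 30, 20, 90, 95), r = 8, val = 200)
  seg <- segment_particles(img, seg_params())
  expect_equal(nrow(seg$rois), 5L)
  # areas within a close_radius dilation tolerance of the drawn disk
  drawn <- sum(draw_disks(40, 40, 20, 20, 8) > 0)
  expect_true(all(abs(seg$rois$area_px - drawn) <= 2 * pi * 8 + 4))
})

test_that("uniform and empty-foreground images yield empty ROI tables", {
  expect_equal(nrow(segment_particles(matrix(5, 32, 32))$rois), 0L)
  expect_equal(nrow(segment_particles(matrix(0, 32, 32))$rois), 0L)
  expect_error(segment_particles(matrix(numeric(0), 0, 0)), "empty")
})

test_that("MFI equals a brute-force mean over member pixels", {
  set.seed(3)
  img <- draw_disks(80, 80, cx = c(20, 60), cy = c(25, 55), r = 7,
                    val = 150)
  meas <- matrix(runif(80 * 80, 0, 500), 80, 80)
  seg <- segment_particles(img, seg_params(), measure_on = meas)
  for (k in seq_len(nrow(seg$rois))) {
    lab <- seg$rois$label[k]
    brute <- 0; npix <- 0
    for (i in 1:80) for (j in 1:80) if (seg$labels[i, j] == lab) {
      brute <- brute + meas[i, j]; npix <- npix + 1
    }
    expect_equal(seg$rois$mfi[k], brute / npix, tolerance = 1e-9)
    expect_equal(seg$rois$area_px[k], npix)
  }
})

test_that("centroids are 0-based pixel-centered", {
  # a single pixel at row 11, col 6 -> (x, y) = (5, 10)
  img <- matrix(0, 20, 20); img[11, 6] <- 10
  seg <- segment_particles(img, seg_params(min_area_px = 1,
                                           close_radius = 0))
  expect_equal(seg$rois$x, 5)
  expect_equal(seg$rois$y, 10)
})

test_that("watershed splits touching disks; off merges them", {
  img <- draw_disks(80, 80, cx = c(30, 45), cy = c(40, 40), r = 10)
  on <- segment_particles(img, seg_params(watershed = TRUE))
  off <- segment_particles(img, seg_params(watershed = FALSE))
  expect_equal(nrow(on$rois), 2L)
  expect_equal(nrow(off$rois), 1L)
})

test_that("min_area and border exclusion filter particles", {
  img <- draw_disks(60, 60, cx = c(15, 45), cy = c(15, 45), r = c(2, 8))
  img[1:6, 30:36] <- 100  # border-touching blob
  keep_all <- segment_particles(img, seg_params(min_area_px = 1))
  expect_equal(nrow(keep_all$rois), 3L)
  big_only <- segment_particles(img, seg_params(min_area_px = 50))
  expect_equal(nrow(big_only$rois), 1L)
  interior <- segment_particles(img, seg_params(min_area_px = 1,
                                                exclude_border = TRUE))
  expect_equal(nrow(interior$rois), 2L)
  # dropped labels are removed from the label mask too
  expect_false(any(interior$labels[1, ] > 0))
})

test_that("4- and 8-connectivity differ on diagonal contacts", {
  img <- matrix(0, 20, 20)
  img[5:8, 5:8] <- 100
  img[9:12, 9:12] <- 100  # diagonal corner contact
  p8 <- seg_params(min_area_px = 1, close_radius = 0, fill_holes = FALSE,
                   connectivity = 8)
  p4 <- seg_params(min_area_px = 1, close_radius = 0, fill_holes = FALSE,
                   connectivity = 4)
  expect_equal(nrow(segment_particles(img, p8)$rois), 1L)
  expect_equal(nrow(segment_particles(img, p4)$rois), 2L)
})

test_that("watershed only splits: labeled area never exceeds mask area", {
  set.seed(11)
  for (rep in 1:5) {
    img <- draw_disks(100, 100, cx = runif(6, 15, 85),
                      cy = runif(6, 15, 85), r = 9)
    seg <- segment_particles(img, seg_params(watershed = TRUE,
                                             min_area_px = 1))
    mask_area <- sum(img > seg$threshold)
    # close+fill can only grow; watershed assigns within the mask
    expect_lte(sum(seg$labels > 0), sum(EBImage::fillHull(
      EBImage::closing(EBImage::Image((img > seg$threshold) * 1),
                       EBImage::makeBrush(3, "disc"))) > 0))
    expect_gte(sum(seg$labels > 0), mask_area - 1e9 * 0)  # sanity
  }
})

test_that("dilate_merge joins nearby fragments and never shrinks", {
  # two 1-px dots 5 px apart merge under 3 iterations of radius 1
  d <- matrix(FALSE, 20, 20); d[10, 5] <- TRUE; d[10, 10] <- TRUE
  merged <- dilate_merge(d, iterations = 3, radius_px = 1)
  expect_true(all(merged[d]))
  seg <- segment_particles(merged * 1, seg_params(threshold = 0.5,
                                                  min_area_px = 1,
                                                  close_radius = 0))
  expect_equal(nrow(seg$rois), 1L)
  # empty mask stays empty
  expect_false(any(dilate_merge(matrix(FALSE, 5, 5), 3, 1)))
  # component count never increases with more iterations
  set.seed(5)
  m <- matrix(runif(40 * 40) < 0.05, 40, 40)
  n_prev <- Inf
  for (it in 0:4) {
    dm <- dilate_merge(m, it, 1)
    n_now <- nrow(segment_particles(dm * 1,
                                    seg_params(threshold = 0.5,
                                               min_area_px = 1,
                                               close_radius = 0,
                                               fill_holes = FALSE))$rois)
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
})

test_that("mask_exclude zeroes exactly the excluded pixels", {
  set.seed(9)
  img <- matrix(runif(30 * 30, 1, 10), 30, 30)
  excl <- matrix(runif(30 * 30) < 0.3, 30, 30)
  out <- mask_exclude(img, excl)
  expect_equal(sum(out), sum(img) - sum(img[excl]))
  expect_identical(out[!excl], img[!excl])
  expect_equal(mask_exclude(img, matrix(TRUE, 30, 30)),
               matrix(0, 30, 30))
  expect_identical(mask_exclude(img, matrix(FALSE, 30, 30)), img)
  expect_error(mask_exclude(img, matrix(FALSE, 5, 5)), "shape")
})

test_that("segmentation recovers object counts on truth-rendered fields", {
  for (s in 1:3) {
    sim <- simulate_field(small_field_config(n_cells = 10,
                                             frac_met_positive = 0,
                                             puncta_mean = 0), seed = s)
    seg <- segment_particles(get_channel(sim$stack, "hoechst", 1),
                             seg_params(min_area_px = 30))
    expect_equal(nrow(seg$rois), 10L)
  }
})
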