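# A hand-built single-cell scene: nucleus, MPO cell body, puncta.
scene <- function(punctum_xy = NULL, punctum_val = 300) {
  h <- w <- 96
  mpo <- draw_disks(h, w, 48, 48, 34, val = 60)
  hoechst <- draw_disks(h, w, 48, 48, 12, val = 400)
  sytox <- matrix(0, h, w)
  if (!is.null(punctum_xy)) {
    sytox <- draw_disks(h, w, punctum_xy[, 1], punctum_xy[, 2], 2,
                        val = punctum_val)
  }
  list(hoechst = hoechst, sytox = sytox, mpo = mpo)
}

test_that("cell ROIs contain their nucleus centroid exactly once", {
  sim <- simulate_field(small_field_config(n_cells = 12, puncta_mean = 0),
                        seed = 5)
  cells <- find_cell_rois(get_channel(sim$stack, "mpo", 1))
  expect_equal(nrow(cells$rois), 12L)
  idx <- cbind(round(sim$truth$cells$y) + 1, round(sim$truth$cells$x) + 1)
  ids <- cells$labels[idx]
  expect_true(all(ids > 0))
  expect_equal(length(unique(ids)), 12L)
  expect_equal(nrow(find_cell_rois(matrix(0, 64, 64))$rois), 0L)
})

test_that("touching cells separate under the forced watershed", {
  mpo <- draw_disks(80, 120, cx = c(40, 78), cy = c(40, 40), r = 22,
                    val = 80)
  cells <- find_cell_rois(mpo)
  expect_equal(nrow(cells$rois), 2L)
})

test_that("puncta are detected, assigned to their cell, and never nuclear", {
  pts <- cbind(c(48, 30, 66, 48, 40), c(28, 60, 60, 70, 26))
  sc <- scene(pts)
  nuc <- count_nuclei(sc$hoechst, seg_params(watershed = TRUE,
                                             min_area_px = 20))
  cells <- find_cell_rois(sc$mpo)
  det <- detect_puncta(sc$sytox, nuc$labels > 0, cells)
  expect_equal(nrow(det$puncta), 5L)
  expect_true(all(det$puncta$cell_id == det$puncta$cell_id[1]))
  expect_true(all(det$puncta$cell_id > 0))
  expect_equal(sum((det$label_stacks[[1]] > 0) & (nuc$labels > 0)), 0L)
})

test_that("a punctum inside the nucleus is excluded", {
  sc <- scene(cbind(48, 48))  # dead center of the nucleus
  nuc <- count_nuclei(sc$hoechst, seg_params(watershed = TRUE,
                                             min_area_px = 20))
  cells <- find_cell_rois(sc$mpo)
  det <- detect_puncta(sc$sytox, nuc$labels > 0, cells)
  expect_equal(nrow(det$puncta), 0L)
})

test_that("puncta outside every cell are flagged extracellular", {
  sc <- scene(cbind(c(48, 6), c(28, 6)))  # one in-cell, one in the corner
  nuc <- count_nuclei(sc$hoechst, seg_params(watershed = TRUE,
                                             min_area_px = 20))
  cells <- find_cell_rois(sc$mpo)
  det <- detect_puncta(sc$sytox, nuc$labels > 0, cells)
  expect_equal(nrow(det$puncta), 2L)
  expect_equal(det$n_extracellular, 1L)
  counts <- per_cell_counts(det, nrow(cells$rois))
  expect_equal(sum(counts) + det$n_extracellular, nrow(det$puncta))
})

test_that("z-stack detections link into single 3-D components", {
  h <- w <- 64
  nuclear <- matrix(FALSE, h, w)
  cells <- find_cell_rois(draw_disks(h, w, 32, 32, 28, val = 80))
  # same punctum in two adjacent slices, plus a second punctum in slice 3
  dna <- array(0, dim = c(3, h, w))
  dna[1, , ] <- draw_disks(h, w, 20, 32, 2, val = 300)
  dna[2, , ] <- draw_disks(h, w, 21, 32, 2, val = 300)
  dna[3, , ] <- draw_disks(h, w, 44, 32, 2, val = 300)
  det <- detect_puncta(dna, nuclear, cells)
  expect_equal(nrow(det$puncta), 3L)       # per-slice records
  expect_equal(det$n_puncta_3d, 2L)        # linked objects
  counts <- per_cell_counts(det, 1)
  expect_equal(unname(counts), 2L)
})

test_that("saturated channels classify every punctum as H+S+M+C", {
  pts <- cbind(c(48, 30), c(28, 60))
  sc <- scene(pts)
  nuc <- count_nuclei(sc$hoechst, seg_params(watershed = TRUE,
                                             min_area_px = 20))
  cells <- find_cell_rois(sc$mpo)
  det <- detect_puncta(sc$sytox, nuc$labels > 0, cells)
  sat <- matrix(1000, 96, 96)
  arr <- array(0, dim = c(4, 1, 96, 96))
  for (ci in 1:4) arr[ci, 1, , ] <- sat
  stack <- channel_stack(arr, c("hoechst", "sytox", "mpo", "cith3"))
  cl <- classify_puncta(det, stack, cells,
                        positivity_rule(method = "fixed",
                                        fixed = c(hoechst = 10, sytox = 10,
                                                  mpo = 10, cith3 = 10)))
  expect_true(all(cl$puncta$combo_class == "H+S+M+C"))
  expect_equal(sum(cl$class_fractions), 1, tolerance = 1e-9)
})

test_that("class fractions recover simulator truth on a rendered field", {
  cfg <- small_field_config(n_cells = 16, frac_met_positive = 0.75,
                            puncta_mean = 4, polarity_kappa = 0,
                            field_size_px = c(320L, 320L))
  sim <- simulate_field(cfg, seed = 3)
  ho <- get_channel(sim$stack, "hoechst", 1)
  nuc <- count_nuclei(ho)
  cells <- find_cell_rois(get_channel(sim$stack, "mpo", 1))
  det <- detect_puncta(ho, nuc$labels > 0, cells)
  cl <- classify_puncta(det, sim$stack, cells)
  expect_equal(cl$puncta$combo_class[cl$puncta$combo_class == "other"],
               character(0))
  expect_equal(sum(cl$class_fractions), 1, tolerance = 1e-9)
  truth_frac <- prop.table(table(factor(
    sim$truth$puncta$class_label,
    levels = c("H", "H+S", "H+S+M", "H+S+M+C"))))
  expect_lt(max(abs(cl$class_fractions[1:4] - as.numeric(truth_frac))),
            0.12)
})

test_that("puncta-positive cell percentages follow the counting rule", {
  expect_equal(puncta_positive_fraction(c(1, 2, 5, 1)), 100)
  expect_equal(puncta_positive_fraction(rep(0, 10)), 0)
  expect_equal(puncta_positive_fraction(c(2, 0, 0, 1), 4), 50)
  expect_error(puncta_positive_fraction(integer(), 0), "positive")
  expect_error(puncta_positive_fraction(1:5, 3), "more per-cell")
})
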