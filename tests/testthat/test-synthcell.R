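test_that("identical (config, seed) pairs give bit-identical output", {
  cfg <- sim_config(field_size_px = c(256L, 256L), n_cells = 10)
  a <- simulate_field(cfg, seed = 99)
  b <- simulate_field(cfg, seed = 99)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$cells, b$truth$cells)
  expect_identical(a$truth$puncta, b$truth$puncta)
  c2 <- simulate_field(cfg, seed = 100)
  expect_false(identical(a$stack$data, c2$stack$data))
})

test_that("an empty field renders background-only channels", {
  cfg <- small_field_config(n_cells = 0, field_size_px = c(64L, 64L))
  sim <- simulate_field(cfg, seed = 1)
  expect_equal(nrow(sim$truth$cells), 0L)
  expect_equal(nrow(sim$truth$puncta), 0L)
  for (ch in sim$stack$channel_names)
    expect_true(all(get_channel(sim$stack, ch, 1) ==
                    cfg$background_level))
})

test_that("pyroptotic cells appear in both nuclear and SYTOX channels", {
  cfg <- sim_config(field_size_px = c(320L, 320L), n_cells = 8,
                    frac_pyroptotic = 1, frac_apoptotic = 0,
                    frac_met_positive = 0, puncta_mean = 0,
                    noise_poisson = FALSE, noise_gaussian_sd = 0)
  sim <- simulate_field(cfg, seed = 12)
  idx <- cbind(round(sim$truth$cells$y) + 1, round(sim$truth$cells$x) + 1)
  ho <- get_channel(sim$stack, "hoechst", 1)
  sy <- get_channel(sim$stack, "sytox", 1)
  expect_true(all(ho[idx] > 200))
  expect_true(all(sy[idx] > 200))
})

test_that("rendered puncta agree with the truth list pixel for pixel", {
  cfg <- small_field_config(n_cells = 10, frac_met_positive = 0.5,
                            puncta_mean = 3, psf_sigma_px = 0,
                            background_level = 0,
                            field_size_px = c(320L, 320L))
  sim <- simulate_field(cfg, seed = 7)
  tr <- sim$truth
  ho <- get_channel(sim$stack, "hoechst", 1)
  # every truth punctum contributed its center pixel
  for (k in seq_len(nrow(tr$puncta))) {
    expect_gte(ho[round(tr$puncta$y[k]) + 1, round(tr$puncta$x[k]) + 1],
               cfg$intensity$punctum)
  }
  # every extranuclear bright pixel lies inside some truth punctum disk
  nuc <- matrix(FALSE, 320, 320)
  for (k in seq_len(nrow(tr$cells)))
    nuc <- nuc | (draw_disks(320, 320, tr$cells$x[k], tr$cells$y[k],
                             tr$cells$nucleus_radius_px[k] + 0.6) > 0)
  extra <- which(ho > 0 & !nuc, arr.ind = TRUE)
  if (nrow(extra)) {
    px <- extra[, 2] - 1; py <- extra[, 1] - 1
    covered <- rep(FALSE, length(px))
    for (k in seq_len(nrow(tr$puncta))) {
      covered <- covered |
        ((px - tr$puncta$x[k])^2 + (py - tr$puncta$y[k])^2 <=
           (tr$puncta$radius_px[k] + 0.1)^2)
    }
    expect_true(all(covered))
  }
})

test_that("staging is monotone in the rendered channels before noise", {
  cfg <- small_field_config(n_cells = 10, frac_met_positive = 0.5,
                            puncta_mean = 3, polarity_kappa = 0,
                            field_size_px = c(320L, 320L))
  sim <- simulate_field(cfg, seed = 9)
  tr <- sim$truth$puncta
  bg <- cfg$background_level
  thresh <- bg + 100
  for (k in seq_len(nrow(tr))) {
    i <- round(tr$y[k]) + 1; j <- round(tr$x[k]) + 1
    on <- c(get_channel(sim$stack, "hoechst", 1)[i, j],
            get_channel(sim$stack, "sytox", 1)[i, j],
            get_channel(sim$stack, "mpo", 1)[i, j],
            get_channel(sim$stack, "cith3", 1)[i, j]) > thresh
    expect_true(on[1])
    expect_equal(unname(on), seq_len(4) <= tr$stage[k])
  }
})

test_that("kappa = 0 puncta angles are uniform around the nucleus", {
  pvals <- numeric(10)
  for (s in 1:10) {
    cfg <- small_field_config(n_cells = 12, frac_met_positive = 1,
                              puncta_mean = 6, polarity_kappa = 0,
                              field_size_px = c(384L, 384L))
    sim <- simulate_field(cfg, seed = 100 + s)
    rel <- sim$truth$puncta$angle -
      sim$truth$cells$met_anchor_angle[sim$truth$puncta$cell_id]
    rel <- atan2(sin(rel), cos(rel))
    obs <- table(cut(rel, breaks = seq(-pi, pi, length.out = 9)))
    pvals[s] <- suppressWarnings(chisq.test(obs)$p.value)
  }
  expect_true(all(pvals > 0.001))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(frac_pyroptotic = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(frac_pyroptotic = 0.7, frac_apoptotic = 0.5),
               "<= 1")
  expect_error(sim_config(stage_probs = c(0.5, 0.5, 0.2, 0)), "sum to 1")
  expect_error(sim_config(condensed_area_factor = 1.2), "\\(0, 1\\)")
  expect_error(sim_config(condensed_intensity_factor = 0.5), "> 1")
  expect_error(sim_config(polarity_kappa = -1), ">= 0")
  expect_error(simulate_timelapse(sim_config(), plateau_frac = 1.5),
               "\\[0, 1\\]")
})

test_that("infeasible packing raises a placement error", {
  cfg <- small_field_config(n_cells = 400, field_size_px = c(96L, 96L))
  expect_error(simulate_field(cfg, seed = 1), "could not place")
})

test_that("time-lapse truth matches its frames", {
  cfg <- small_field_config(n_cells = 20, frac_met_positive = 0,
                            puncta_mean = 0, field_size_px = c(256L, 256L))
  tl <- simulate_timelapse(cfg, seed = 31, plateau_frac = 0.5,
                           duration_h = 6, interval_h = 0.5)
  expect_length(tl$frames, 13L)
  d <- tl$truth$death_time_h
  expect_true(all(is.na(d) | d >= 0))
  # hoechst appears only in frame 0
  expect_gt(max(get_channel(tl$frames[[1]], "hoechst", 1)), 100)
  expect_lt(max(get_channel(tl$frames[[5]], "hoechst", 1)),
            cfg$background_level + 1)
  # final dead fraction within 3 binomial sd of the plateau
  n <- nrow(tl$truth$cells)
  expect_lt(abs(mean(!is.na(d)) - 0.5), 3 * sqrt(0.25 / n) + 1e-9)
})
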