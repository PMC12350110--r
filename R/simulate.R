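# Synthetic multi-channel microscopy fields with full ground truth.
#
# Cells are modeled as a disk nucleus inside an annular cytoplasm; METs as
# ellipse blobs tangent to the cell boundary; cytoplasmic DNA puncta as
# small disks placed in the cytoplasm annulus with a von Mises angular
# distribution centered on the nucleus -> MET-anchor direction. Staining
# follows the staged combination classes: every punctum carries nuclear
# dye (H), stage >= 2 adds the vesicular DNA dye (S), stage >= 3 the
# granule protein (M), and stage 4 citrullinated histone (C). The forward
# optical model is Gaussian PSF blur, then background, then Poisson shot
# noise, then Gaussian read noise.

#' Simulation configuration
#'
#' Defaults emulate the conditions the quantification pipeline was designed
#' for: fields of a few hundred to ~2000 macrophages of which about 20%
#' die by pyroptosis and a few percent show condensed (apoptotic) nuclei
#' with roughly 0.4x area and 2x Hoechst intensity, about 16% of cells
#' carrying one MET blob anchored at the cell edge, and polarized
#' cytoplasmic DNA puncta with staged marker combinations.
#'
#' @param field_size_px image size `(H, W)` in pixels.
#' @param n_cells number of cells to place (overlap-free).
#' @param frac_pyroptotic fraction of cells dying by pyroptosis
#'   (SYTOX-positive whole nucleus).
#' @param frac_apoptotic fraction with condensed nuclei.
#' @param frac_met_positive fraction of (live) cells carrying one MET blob.
#' @param puncta_mean,puncta_dispersion negative-binomial mean and size of
#'   the per-MET-cell punctum count.
#' @param polarity_kappa von Mises concentration of punctum angles toward
#'   the MET anchor (0 = uniform).
#' @param stage_probs probability vector over the four staged combination
#'   classes (H, H+S, H+S+M, H+S+M+C); must sum to 1.
#' @param nucleus_radius_px,nucleus_radius_jitter nominal nucleus radius
#'   and uniform jitter (px).
#' @param condensed_area_factor area multiplier of condensed nuclei, in
#'   (0, 1).
#' @param condensed_intensity_factor Hoechst intensity multiplier of
#'   condensed nuclei, > 1.
#' @param cyto_radius_factor cytoplasm radius as a multiple of the nucleus
#'   radius.
#' @param met_axes_px ellipse semi-axes (tangential, radial) of MET blobs.
#' @param punctum_radius_px range of punctum radii (px).
#' @param psf_sigma_px Gaussian PSF sigma; 0 disables blurring.
#' @param background_level constant background (counts).
#' @param noise_poisson apply Poisson shot noise.
#' @param noise_gaussian_sd Gaussian read-noise sd (counts); 0 disables.
#' @param n_z number of z-slices (cell bodies appear in all slices, each
#'   punctum only in its own).
#' @param intensity named list of emission amplitudes (counts):
#'   `nucleus`, `cytoplasm`, `punctum`, `met`, `dead`.
#' @param min_spacing_px minimum distance between cell centers; `NULL`
#'   chooses automatically (cytoplasm diameter when METs/puncta are
#'   simulated, nucleus diameter otherwise).
#' @return an object of class `SimConfig`.
#' @export
sim_config <- function(field_size_px = c(768L, 768L),
                       n_cells = 200L,
                       frac_pyroptotic = 0.20,
                       frac_apoptotic = 0.02,
                       frac_met_positive = 0.16,
                       puncta_mean = 5, puncta_dispersion = 2,
                       polarity_kappa = 4,
                       stage_probs = c(0.25, 0.25, 0.25, 0.25),
                       nucleus_radius_px = 6,
                       nucleus_radius_jitter = 0.8,
                       condensed_area_factor = 0.4,
                       condensed_intensity_factor = 2,
                       cyto_radius_factor = 2.4,
                       met_axes_px = c(7, 4.5),
                       punctum_radius_px = c(1.2, 1.8),
                       psf_sigma_px = 0.8,
                       background_level = 20,
                       noise_poisson = TRUE,
                       noise_gaussian_sd = 5,
                       n_z = 1L,
                       intensity = list(nucleus = 400, cytoplasm = 60,
                                        punctum = 350, met = 380,
                                        dead = 500),
                       min_spacing_px = NULL) {
  cfg <- list(field_size_px = as.integer(field_size_px),
              n_cells = as.integer(n_cells),
              frac_pyroptotic = frac_pyroptotic,
              frac_apoptotic = frac_apoptotic,
              frac_met_positive = frac_met_positive,
              puncta_mean = puncta_mean,
              puncta_dispersion = puncta_dispersion,
              polarity_kappa = polarity_kappa,
              stage_probs = stage_probs,
              nucleus_radius_px = nucleus_radius_px,
              nucleus_radius_jitter = nucleus_radius_jitter,
              condensed_area_factor = condensed_area_factor,
              condensed_intensity_factor = condensed_intensity_factor,
              cyto_radius_factor = cyto_radius_factor,
              met_axes_px = met_axes_px,
              punctum_radius_px = punctum_radius_px,
              psf_sigma_px = psf_sigma_px,
              background_level = background_level,
              noise_poisson = isTRUE(noise_poisson),
              noise_gaussian_sd = noise_gaussian_sd,
              n_z = as.integer(n_z),
              intensity = intensity,
              min_spacing_px = min_spacing_px)
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param config a candidate configuration list.
#' @export
validate_sim_config <- function(config) {
  with(config, {
    for (f in c(frac_pyroptotic, frac_apoptotic, frac_met_positive))
      if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
    if (frac_pyroptotic + frac_apoptotic > 1)
      stop("frac_pyroptotic + frac_apoptotic must be <= 1")
    if (abs(sum(stage_probs) - 1) > 1e-9)
      stop("stage_probs must sum to 1")
    if (any(stage_probs < 0)) stop("stage_probs must be nonnegative")
    if (polarity_kappa < 0) stop("polarity_kappa must be >= 0")
    if (condensed_area_factor <= 0 || condensed_area_factor >= 1)
      stop("condensed_area_factor must be in (0, 1)")
    if (condensed_intensity_factor <= 1)
      stop("condensed_intensity_factor must be > 1")
    if (psf_sigma_px < 0) stop("psf_sigma_px must be >= 0")
    if (background_level < 0) stop("background_level must be >= 0")
    if (puncta_mean < 0 || puncta_dispersion <= 0)
      stop("invalid punctum-count distribution")
    if (n_z < 1L) stop("n_z must be >= 1")
    if (n_cells < 0L) stop("n_cells must be >= 0")
  })
  structure(config, class = c("SimConfig", "list"))
}

# --- geometry helpers -----------------------------------------------------

#' @noRd
add_disk <- function(mat, cx, cy, r, val) {
  h <- nrow(mat); w <- ncol(mat)
  r0 <- max(1L, floor(cy - r) + 1L); r1 <- min(h, ceiling(cy + r) + 1L)
  c0 <- max(1L, floor(cx - r) + 1L); c1 <- min(w, ceiling(cx + r) + 1L)
  if (r0 > r1 || c0 > c1) return(mat)
  ys <- (r0:r1) - 1; xs <- (c0:c1) - 1
  dy2 <- (ys - cy)^2
  dx2 <- (xs - cx)^2
  inside <- outer(dy2, dx2, "+") <= r^2
  mat[r0:r1, c0:c1][inside] <- mat[r0:r1, c0:c1][inside] + val
  mat
}

#' @noRd
add_ellipse <- function(mat, cx, cy, a, b, phi, val) {
  h <- nrow(mat); w <- ncol(mat)
  rr <- max(a, b)
  r0 <- max(1L, floor(cy - rr) + 1L); r1 <- min(h, ceiling(cy + rr) + 1L)
  c0 <- max(1L, floor(cx - rr) + 1L); c1 <- min(w, ceiling(cx + rr) + 1L)
  if (r0 > r1 || c0 > c1) return(mat)
  ys <- (r0:r1) - 1; xs <- (c0:c1) - 1
  gx <- outer(rep(1, length(ys)), xs - cx)
  gy <- outer(ys - cy, rep(1, length(xs)))
  u <- gx * cos(phi) + gy * sin(phi)
  v <- -gx * sin(phi) + gy * cos(phi)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  mat[r0:r1, c0:c1][inside] <- mat[r0:r1, c0:c1][inside] + val
  mat
}

# Overlap-free dart-throwing placement of cell centers.
#' @noRd
place_cells <- function(n, h, w, margin, min_dist, max_tries = 400L * n) {
  xs <- numeric(n); ys <- numeric(n)
  placed <- 0L; tries <- 0L
  if (w - 2 * margin <= 0 || h - 2 * margin <= 0)
    stop("field too small for the configured cell geometry")
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop(sprintf(paste0("could not place %d cells in a %dx%d field ",
                          "after %d tries (placed %d)"),
                   n, h, w, max_tries, placed))
    cx <- stats::runif(1, margin, w - 1 - margin)
    cy <- stats::runif(1, margin, h - 1 - margin)
    if (placed == 0L ||
        min((xs[1:placed] - cx)^2 + (ys[1:placed] - cy)^2) >= min_dist^2) {
      placed <- placed + 1L
      xs[placed] <- cx; ys[placed] <- cy
    }
  }
  data.frame(x = xs, y = ys)
}

# Apply the forward optical model to one rendered slice.
#' @noRd
apply_optics <- function(mat, config) {
  if (config$psf_sigma_px > 0)
    mat <- EBImage::imageData(
      EBImage::gblur(EBImage::Image(mat), sigma = config$psf_sigma_px))
  mat <- mat + config$background_level
  if (config$noise_poisson)
    mat <- matrix(stats::rpois(length(mat), pmax(mat, 0)),
                  nrow(mat), ncol(mat))
  if (config$noise_gaussian_sd > 0)
    mat <- mat + stats::rnorm(length(mat), 0, config$noise_gaussian_sd)
  pmax(mat, 0)
}

# --- field simulation -----------------------------------------------------

#' Simulate a multi-channel field with ground truth
#'
#' Renders the four channels of one microscopic field: `hoechst` shows all
#' nuclei (condensed nuclei smaller and brighter) plus every cytoplasmic
#' DNA punctum; `sytox` shows pyroptotic nuclei, puncta of stage >= 2, and
#' MET blobs; `mpo` shows the (weak) cell bodies, puncta of stage >= 3, and
#' MET blobs; `cith3` shows stage-4 puncta and MET blobs. PSF blur is
#' applied first, then background and noise, so the identical
#' `(config, seed)` pair always yields a bit-identical field.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the generator is fully deterministic given
#'   `(config, seed)`.
#' @return list with elements `stack` (a [channel_stack()]) and `truth`
#'   (class `FieldTruth`): `cells` (per-cell geometry, fate, intensity
#'   class, MET anchor), `puncta` (position, angle, stage class, owning
#'   cell), `mets` (blob geometry and anchor), plus the seed and config.
#' @export
simulate_field <- function(config = sim_config(), seed = 1L) {
  config <- validate_sim_config(config)
  with_seed(seed, simulate_field_impl(config, seed))
}

#' @noRd
simulate_field_impl <- function(config, seed) {
  h <- config$field_size_px[1]; w <- config$field_size_px[2]
  n <- config$n_cells
  nz <- config$n_z
  int <- config$intensity
  r_nom <- config$nucleus_radius_px
  jit <- config$nucleus_radius_jitter
  cyto_f <- config$cyto_radius_factor
  has_structures <- config$frac_met_positive > 0 || config$puncta_mean > 0
  cyto_max <- (r_nom + jit) * cyto_f
  min_dist <- if (!is.null(config$min_spacing_px)) config$min_spacing_px
              else if (has_structures) 2 * cyto_max + 4
              else 2 * (r_nom + jit) + 6
  margin <- if (has_structures)
    cyto_max + 2 * config$met_axes_px[2] + 4 else r_nom + jit + 4

  channels <- c("hoechst", "sytox", "mpo", "cith3")
  arr <- array(0, dim = c(4L, nz, h, w))

  empty_cells <- data.frame(
    cell_id = integer(), x = numeric(), y = numeric(),
    nucleus_radius_px = numeric(), nucleus_area_px = numeric(),
    cyto_radius_px = numeric(), fate = character(),
    intensity_class = character(), met_anchor_x = numeric(),
    met_anchor_y = numeric(), met_anchor_angle = numeric())
  empty_puncta <- data.frame(
    cell_id = integer(), x = numeric(), y = numeric(), z = integer(),
    angle = numeric(), r_from_center = numeric(), radius_px = numeric(),
    stage = integer(), class_label = character())
  empty_mets <- data.frame(
    cell_id = integer(), anchor_x = numeric(), anchor_y = numeric(),
    cx = numeric(), cy = numeric(), a = numeric(), b = numeric(),
    phi = numeric())

  if (n == 0L) {
    slices <- lapply(seq_len(4L * nz), function(i) {
      apply_optics(matrix(0, h, w), config)
    })
    k <- 1L
    for (ci in 1:4) for (zi in seq_len(nz)) {
      arr[ci, zi, , ] <- slices[[k]]; k <- k + 1L
    }
    truth <- structure(list(cells = empty_cells, puncta = empty_puncta,
                            mets = empty_mets, seed = seed,
                            config = config), class = "FieldTruth")
    return(list(stack = channel_stack(arr, channels), truth = truth))
  }

  pos <- place_cells(n, h, w, margin, min_dist)
  radii <- r_nom + stats::runif(n, -jit, jit)
  cyto_r <- radii * cyto_f

  # fates: exact counts, random assignment
  n_pyro <- round(config$frac_pyroptotic * n)
  n_apop <- round(config$frac_apoptotic * n)
  ord <- sample.int(n)
  fate <- rep("live", n)
  if (n_pyro > 0) fate[ord[seq_len(n_pyro)]] <- "pyroptotic"
  if (n_apop > 0) fate[ord[n_pyro + seq_len(n_apop)]] <- "apoptotic"

  condensed <- fate == "apoptotic"
  r_eff <- ifelse(condensed, radii * sqrt(config$condensed_area_factor),
                  radii)
  nuc_int <- ifelse(condensed,
                    int$nucleus * config$condensed_intensity_factor,
                    int$nucleus)

  # MET assignment among live cells
  n_met <- round(config$frac_met_positive * n)
  live_ids <- which(fate == "live")
  if (n_met > length(live_ids))
    stop("not enough live cells to host the configured MET fraction")
  met_ids <- if (n_met > 0) sort(sample(live_ids, n_met)) else integer()

  anchor_angle <- rep(NA_real_, n)
  mets <- empty_mets
  a_ax <- config$met_axes_px[1]; b_ax <- config$met_axes_px[2]
  blob_cx <- numeric(0); blob_cy <- numeric(0)
  for (ci in met_ids) {
    best <- NULL; best_score <- -Inf
    for (try in 1:60) {
      ang <- stats::runif(1, -pi, pi)
      bx <- pos$x[ci] + (cyto_r[ci] + b_ax) * cos(ang)
      by <- pos$y[ci] + (cyto_r[ci] + b_ax) * sin(ang)
      if (bx < a_ax + 1 || bx > w - 2 - a_ax ||
          by < a_ax + 1 || by > h - 2 - a_ax) next
      d_cells <- sqrt((pos$x[-ci] - bx)^2 + (pos$y[-ci] - by)^2)
      d_blobs <- if (length(blob_cx))
        sqrt((blob_cx - bx)^2 + (blob_cy - by)^2) else Inf
      score <- min(min(d_cells) - (cyto_max + a_ax),
                   min(d_blobs) - (2 * a_ax + 12))
      if (score > best_score) {
        best_score <- score
        best <- c(ang, bx, by)
      }
      if (score >= 0) break
    }
    if (is.null(best)) best <- c(0, pos$x[ci] + cyto_r[ci] + b_ax, pos$y[ci])
    anchor_angle[ci] <- best[1]
    blob_cx <- c(blob_cx, best[2]); blob_cy <- c(blob_cy, best[3])
    mets <- rbind(mets, data.frame(
      cell_id = ci,
      anchor_x = pos$x[ci] + cyto_r[ci] * cos(best[1]),
      anchor_y = pos$y[ci] + cyto_r[ci] * sin(best[1]),
      cx = best[2], cy = best[3], a = a_ax, b = b_ax,
      phi = best[1] + pi / 2))
  }

  # puncta for MET-positive cells
  puncta <- empty_puncta
  class_labels <- c("H", "H+S", "H+S+M", "H+S+M+C")
  for (ci in met_ids) {
    k <- stats::rnbinom(1, size = config$puncta_dispersion,
                        mu = config$puncta_mean)
    if (k == 0) next
    px <- numeric(0); py <- numeric(0); prad <- numeric(0)
    pang <- numeric(0); pr <- numeric(0)
    for (j in seq_len(k)) {
      for (try in 1:40) {
        ang <- rvonmises(1, mu = anchor_angle[ci],
                         kappa = config$polarity_kappa)
        rad <- stats::runif(1, config$punctum_radius_px[1],
                            config$punctum_radius_px[2])
        lo <- r_eff[ci] + rad + 2   # clear of the nucleus + guard band
        hi <- cyto_r[ci] - rad - 1
        if (hi <= lo) next
        rr <- stats::runif(1, lo, hi)
        x <- pos$x[ci] + rr * cos(ang); y <- pos$y[ci] + rr * sin(ang)
        if (length(px) == 0 ||
            min(sqrt((px - x)^2 + (py - y)^2) - (prad + rad)) >= 1.5 ||
            try == 40L) {
          px <- c(px, x); py <- c(py, y); prad <- c(prad, rad)
          pang <- c(pang, ang); pr <- c(pr, rr)
          break
        }
      }
    }
    if (length(px) == 0) next
    stages <- sample.int(4L, length(px), replace = TRUE,
                         prob = config$stage_probs)
    puncta <- rbind(puncta, data.frame(
      cell_id = ci, x = px, y = py,
      z = sample.int(nz, length(px), replace = TRUE),
      angle = pang, r_from_center = pr, radius_px = prad,
      stage = stages, class_label = class_labels[stages]))
  }
  rownames(puncta) <- NULL

  # --- render ------------------------------------------------------------
  base <- list(hoechst = matrix(0, h, w), sytox = matrix(0, h, w),
               mpo = matrix(0, h, w), cith3 = matrix(0, h, w))
  for (ci in seq_len(n)) {
    base$hoechst <- add_disk(base$hoechst, pos$x[ci], pos$y[ci],
                             r_eff[ci], nuc_int[ci])
    base$mpo <- add_disk(base$mpo, pos$x[ci], pos$y[ci], cyto_r[ci],
                         int$cytoplasm)
    if (fate[ci] == "pyroptotic")
      base$sytox <- add_disk(base$sytox, pos$x[ci], pos$y[ci],
                             r_eff[ci], int$dead)
  }
  for (mi in seq_len(nrow(mets))) {
    for (ch in c("sytox", "mpo", "cith3"))
      base[[ch]] <- add_ellipse(base[[ch]], mets$cx[mi], mets$cy[mi],
                                mets$a[mi], mets$b[mi], mets$phi[mi],
                                int$met)
  }

  for (zi in seq_len(nz)) {
    slice <- base
    pz <- puncta[puncta$z == zi, , drop = FALSE]
    for (pj in seq_len(nrow(pz))) {
      slice$hoechst <- add_disk(slice$hoechst, pz$x[pj], pz$y[pj],
                                pz$radius_px[pj], int$punctum)
      if (pz$stage[pj] >= 2)
        slice$sytox <- add_disk(slice$sytox, pz$x[pj], pz$y[pj],
                                pz$radius_px[pj], int$punctum)
      if (pz$stage[pj] >= 3)
        slice$mpo <- add_disk(slice$mpo, pz$x[pj], pz$y[pj],
                              pz$radius_px[pj], int$punctum)
      if (pz$stage[pj] >= 4)
        slice$cith3 <- add_disk(slice$cith3, pz$x[pj], pz$y[pj],
                                pz$radius_px[pj], int$punctum)
    }
    for (ch_i in seq_along(channels))
      arr[ch_i, zi, , ] <- apply_optics(slice[[channels[ch_i]]], config)
  }

  cells <- data.frame(
    cell_id = seq_len(n), x = pos$x, y = pos$y,
    nucleus_radius_px = r_eff, nucleus_area_px = pi * r_eff^2,
    cyto_radius_px = cyto_r, fate = fate,
    intensity_class = ifelse(condensed, "condensed", "normal"),
    met_anchor_x = pos$x + cyto_r * cos(anchor_angle),
    met_anchor_y = pos$y + cyto_r * sin(anchor_angle),
    met_anchor_angle = anchor_angle)
  truth <- structure(list(cells = cells, puncta = puncta, mets = mets,
                          seed = seed, config = config),
                     class = "FieldTruth")
  list(stack = channel_stack(arr, channels), truth = truth)
}

#' @export
print.FieldTruth <- function(x, ...) {
  cat(sprintf(
    "FieldTruth: %d cells (%d pyroptotic, %d apoptotic), %d METs, %d puncta\n",
    nrow(x$cells), sum(x$cells$fate == "pyroptotic"),
    sum(x$cells$fate == "apoptotic"), nrow(x$mets), nrow(x$puncta)))
  invisible(x)
}

# --- time-lapse simulation ------------------------------------------------

#' Simulate a time-lapse death series with ground truth
#'
#' Each cell is doomed independently with probability `plateau_frac`;
#' doomed cells die at a logistic-distributed onset time (location
#' `onset_midpoint_h`, scale `onset_scale_h`, truncated at 0) and from then
#' on show whole-nucleus SYTOX staining. Hoechst is rendered only in the
#' first frame, mirroring a single UV exposure at the start of imaging.
#'
#' @param config a [sim_config()] (geometry/noise settings; METs and puncta
#'   are not rendered in time-lapse mode).
#' @param seed integer seed.
#' @param plateau_frac asymptotic dead fraction, in `[0, 1]`.
#' @param onset_midpoint_h,onset_scale_h logistic onset parameters (hours).
#' @param duration_h total imaging time (default 16 h).
#' @param interval_h frame interval (default 0.25 h, i.e. 15 min).
#' @return list with `frames` (list of [channel_stack()]s with channels
#'   `hoechst`, `sytox` and `time_h` set) and `truth` (class
#'   `TimelapseTruth`): `death_time_h` per cell (`NA` for survivors),
#'   `frame_times_h`, and the cell table.
#' @export
simulate_timelapse <- function(config = sim_config(), seed = 1L,
                               plateau_frac = 0.20,
                               onset_midpoint_h = 5,
                               onset_scale_h = 1.2,
                               duration_h = 16, interval_h = 0.25) {
  config <- validate_sim_config(config)
  if (plateau_frac < 0 || plateau_frac > 1)
    stop("plateau_frac must lie in [0, 1]")
  if (interval_h <= 0 || duration_h <= 0)
    stop("interval and duration must be positive")
  with_seed(seed, {
    h <- config$field_size_px[1]; w <- config$field_size_px[2]
    n <- config$n_cells
    int <- config$intensity
    r_nom <- config$nucleus_radius_px
    jit <- config$nucleus_radius_jitter
    min_dist <- 2 * (r_nom + jit) + 6
    pos <- place_cells(n, h, w, r_nom + jit + 4, min_dist)
    radii <- r_nom + stats::runif(n, -jit, jit)

    doomed <- stats::runif(n) < plateau_frac
    death <- rep(NA_real_, n)
    death[doomed] <- pmax(0, stats::rlogis(sum(doomed),
                                           location = onset_midpoint_h,
                                           scale = onset_scale_h))
    times <- seq(0, duration_h, by = interval_h)

    hoechst0 <- matrix(0, h, w)
    for (ci in seq_len(n))
      hoechst0 <- add_disk(hoechst0, pos$x[ci], pos$y[ci], radii[ci],
                           int$nucleus)
    frames <- vector("list", length(times))
    for (ti in seq_along(times)) {
      sy <- matrix(0, h, w)
      dead_now <- which(!is.na(death) & death <= times[ti])
      for (ci in dead_now)
        sy <- add_disk(sy, pos$x[ci], pos$y[ci], radii[ci], int$dead)
      ho <- if (ti == 1L) hoechst0 else matrix(0, h, w)
      arr <- array(0, dim = c(2L, 1L, h, w))
      arr[1, 1, , ] <- apply_optics(ho, config)
      arr[2, 1, , ] <- apply_optics(sy, config)
      frames[[ti]] <- channel_stack(arr, c("hoechst", "sytox"),
                                    time_h = times[ti])
    }
    truth <- structure(
      list(death_time_h = death, frame_times_h = times,
           cells = data.frame(cell_id = seq_len(n), x = pos$x, y = pos$y,
                              nucleus_radius_px = radii, doomed = doomed),
           plateau_frac = plateau_frac, seed = seed),
      class = "TimelapseTruth")
    list(frames = frames, truth = truth)
  })
}

#' @export
print.TimelapseTruth <- function(x, ...) {
  cat(sprintf(
    "TimelapseTruth: %d cells, %d doomed, %d frames (%.2f-%.2f h)\n",
    nrow(x$cells), sum(x$cells$doomed), length(x$frame_times_h),
    min(x$frame_times_h), max(x$frame_times_h)))
  invisible(x)
}

#' Empirical death-time CDF of a simulated time-lapse
#'
#' Fraction of all cells dead at each query time — the ground-truth curve
#' that [build_death_curve()] should recover exactly in the noiseless
#' limit.
#' @param truth a `TimelapseTruth`.
#' @param times query times (defaults to the frame times).
#' @return numeric vector of dead fractions.
#' @export
truth_death_cdf <- function(truth, times = truth$frame_times_h) {
  stopifnot(inherits(truth, "TimelapseTruth"))
  d <- truth$death_time_h
  vapply(times, function(t) mean(!is.na(d) & d <= t), numeric(1))
}
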