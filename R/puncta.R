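# Per-cell detection and staining classification of cytoplasmic DNA puncta.

#' Identify cell-boundary ROIs from MPO staining
#'
#' MPO antibody staining covers the cell body; segmenting it (with the
#' watershed split on, so touching cells separate) yields one ROI per cell.
#' These ROIs are the "cell boundary ROI set" that every per-cell punctum
#' assignment uses.
#'
#' The MPO channel is trimodal — dark background, dim cell bodies, bright
#' puncta and traps — so the default automatic threshold is Otsu computed
#' in the log-intensity domain, which separates background from cell body
#' instead of cell body from the bright minority.
#'
#' @param mpo 2-D matrix of the MPO channel (a maximum-intensity projection
#'   for z-stacks).
#' @param params a [seg_params()]; `watershed` is forced on. An `"otsu"`
#'   threshold is resolved on `log1p` intensities. The default h-maxima
#'   suppression of 2 px matches cell-body scale (deeper than the
#'   nucleus-scale default of [seg_params()]).
#' @return a `SegResult` whose label matrix assigns each pixel to a cell.
#' @export
find_cell_rois <- function(mpo, params = seg_params(watershed = TRUE,
                                                    min_area_px = 100,
                                                    watershed_h = 2)) {
  params$watershed <- TRUE
  if (identical(params$threshold, "otsu"))
    params$threshold <- expm1(otsu_threshold(log1p(mpo)))
  segment_particles(mpo, params)
}

#' Detect cytoplasmic DNA puncta and assign them to cells
#'
#' The detection order mirrors the nuclear-exclusion design: nuclear pixels
#' are blacked out of the DNA image first (with a small dilation guard band
#' so blurred nuclear edges cannot leak through), the remainder is
#' thresholded and segmented into particles, and each punctum is assigned to
#' the cell ROI containing its centroid. Puncta whose centroid falls outside
#' every cell are kept but flagged extracellular (`cell_id = 0`).
#'
#' For a z-stack input the detection runs per slice and detections in
#' adjacent slices whose footprints are 26-connected are linked into a
#' single 3-D component; both the per-slice records and the linked
#' component count are reported, so a punctum spanning several slices is
#' not double-counted.
#'
#' @param dna 2-D matrix or `(z, y, x)` array of the DNA-puncta channel
#'   (SYTOX Orange for vesicular DNA; any DNA channel works).
#' @param nuclear_mask binary 2-D matrix of nuclear regions (e.g.
#'   `count_nuclei(...)$labels > 0`).
#' @param cells `SegResult` from [find_cell_rois()] on the same field.
#' @param params a [seg_params()] for punctum segmentation; the default
#'   minimum area of 3 px suppresses shot noise.
#' @param nuclear_dilate_px guard-band dilation (px) applied to the nuclear
#'   mask before exclusion (default 2).
#' @return list of class `PunctaResult`:
#'   \describe{
#'     \item{puncta}{data frame, one row per per-slice detection: `punctum_id`,
#'       `z` (1-based slice), `x`, `y`, `area_px`, `cell_id` (0 =
#'       extracellular), `component_3d` (linked 3-D object id).}
#'     \item{n_puncta_3d}{number of linked 3-D components.}
#'     \item{n_extracellular}{per-slice detections outside every cell.}
#'     \item{label_stacks}{list of per-slice punctum label matrices.}
#'     \item{exclusion}{the dilated nuclear mask that was applied.}
#'   }
#' @export
detect_puncta <- function(dna, nuclear_mask, cells,
                          params = seg_params(min_area_px = 3,
                                              close_radius = 0),
                          nuclear_dilate_px = 2L) {
  stopifnot(is.matrix(nuclear_mask), inherits(cells, "SegResult"))
  if (is.matrix(dna)) dna <- array(dna, dim = c(1L, nrow(dna), ncol(dna)))
  nz <- dim(dna)[1]
  excl <- if (nuclear_dilate_px > 0 && any(nuclear_mask > 0))
    dilate_merge(nuclear_mask, 1L, nuclear_dilate_px) else nuclear_mask > 0

  recs <- list()
  label_stacks <- vector("list", nz)
  pid <- 0L
  for (zi in seq_len(nz)) {
    slice <- mask_exclude(dna[zi, , ], excl)
    sp <- params
    if (identical(sp$threshold, "otsu")) {
      # threshold over non-excluded pixels only: the blacked-out nuclear
      # region would otherwise dominate the histogram as a spurious 0 mode
      sp$threshold <- otsu_threshold(slice[!excl])
    }
    seg <- segment_particles(slice, sp)
    label_stacks[[zi]] <- seg$labels
    r <- seg$rois
    if (nrow(r)) {
      ci <- cells$labels[cbind(pmin(pmax(round(r$y) + 1L, 1L), nrow(excl)),
                               pmin(pmax(round(r$x) + 1L, 1L), ncol(excl)))]
      recs[[zi]] <- data.frame(
        punctum_id = pid + seq_len(nrow(r)), z = zi, slice_label = r$label,
        x = r$x, y = r$y, area_px = r$area_px, mfi = r$mfi,
        cell_id = as.integer(ci))
      pid <- pid + nrow(r)
    }
  }
  puncta <- if (length(recs)) do.call(rbind, recs) else
    data.frame(punctum_id = integer(), z = integer(),
               slice_label = integer(), x = numeric(), y = numeric(),
               area_px = integer(), mfi = numeric(), cell_id = integer())
  rownames(puncta) <- NULL
  puncta$component_3d <- link_components_3d(label_stacks, puncta)

  structure(
    list(puncta = puncta,
         n_puncta_3d = length(unique(puncta$component_3d)),
         n_extracellular = sum(puncta$cell_id == 0L),
         label_stacks = label_stacks, exclusion = excl, params = params),
    class = "PunctaResult"
  )
}

# Link per-slice detections into 3-D components under 26-connectivity: two
# detections in adjacent slices are linked iff one footprint intersects the
# 3x3-dilated footprint of the other. Union-find with path halving.
#' @noRd
link_components_3d <- function(label_stacks, puncta) {
  n <- nrow(puncta)
  if (n == 0L) return(integer())
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nz <- length(label_stacks)
  if (nz > 1L) {
    box <- matrix(1, 3, 3)
    for (zi in seq_len(nz - 1L)) {
      a <- label_stacks[[zi]]; b <- label_stacks[[zi + 1L]]
      if (!any(a > 0) || !any(b > 0)) next
      a_dil <- EBImage::imageData(
        EBImage::dilate(EBImage::Image((a > 0) * 1), box)) > 0
      touching <- a_dil & b > 0
      if (!any(touching)) next
      # for each touching pixel of b, find which label of a it abuts
      idx <- which(touching)
      for (lb in unique(b[idx])) {
        bpix <- which(b == lb)
        nbr_mask <- EBImage::imageData(EBImage::dilate(
          EBImage::Image((b == lb) * 1), box)) > 0
        la_ids <- unique(a[nbr_mask & a > 0])
        ia <- which(puncta$z == zi & puncta$slice_label %in% la_ids)
        ib <- which(puncta$z == zi + 1L & puncta$slice_label == lb)
        for (i in ia) {
          ri <- find(i); rj <- find(ib[1])
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Staining-positivity rule for punctum classification
#'
#' @param method per-channel threshold strategy: `"otsu"` (Otsu over
#'   in-cell, extranuclear pixels), `"k_mad"` (background median +
#'   `k` median absolute deviations, background = pixels outside every cell
#'   ROI), or `"fixed"` (explicit per-channel values).
#' @param k MAD multiplier for `"k_mad"` (must be positive).
#' @param min_fraction a punctum is positive for a channel iff at least this
#'   fraction of its pixels exceeds the channel threshold (in (0, 1],
#'   default 0.5).
#' @param fixed named numeric vector of per-channel thresholds for
#'   `"fixed"`.
#' @return an object of class `ChannelPositivityRule`.
#' @export
positivity_rule <- function(method = c("otsu", "k_mad", "fixed"), k = 4,
                            min_fraction = 0.5, fixed = NULL) {
  method <- match.arg(method)
  stopifnot_scalar(k, "k")
  if (k <= 0) stop("'k' must be positive")
  stopifnot_scalar(min_fraction, "min_fraction")
  if (min_fraction <= 0 || min_fraction > 1)
    stop("'min_fraction' must be in (0, 1]")
  if (method == "fixed" && (is.null(fixed) || is.null(names(fixed))))
    stop("'fixed' thresholds must be a named numeric vector")
  structure(list(method = method, k = k, min_fraction = min_fraction,
                 fixed = fixed),
            class = "ChannelPositivityRule")
}

#' Classify detected puncta by their staining combination
#'
#' For each punctum and each of the four channels (Hoechst, SYTOX, MPO,
#' CitH3), the punctum is scored positive iff at least `min_fraction` of its
#' pixels exceed the channel's threshold. The flags map onto the staged
#' combination classes `H`, `H+S`, `H+S+M`, `H+S+M+C`; any non-monotone
#' combination is reported as `other`. Class fractions are normalized to the
#' total number of classified puncta.
#'
#' @param det a `PunctaResult` from [detect_puncta()].
#' @param stack the [channel_stack()] of the field.
#' @param cells the `SegResult` from [find_cell_rois()] (defines in-cell and
#'   background pixels for thresholding).
#' @param rule a [positivity_rule()].
#' @param channels names of the four channels in staging order
#'   (DNA dye, vesicular DNA dye, granule protein, citrullinated histone).
#' @return `det` with its `puncta` data frame gaining `pos_<channel>` flags
#'   and `combo_class`, plus elements `class_fractions` (named vector
#'   summing to 1) and `thresholds`.
#' @export
classify_puncta <- function(det, stack, cells,
                            rule = positivity_rule(),
                            channels = c("hoechst", "sytox", "mpo",
                                         "cith3")) {
  stopifnot(inherits(det, "PunctaResult"), inherits(stack, "ChannelStack"))
  missing_ch <- setdiff(channels, stack$channel_names)
  if (length(missing_ch))
    stop("channel(s) missing from stack: ",
         paste(missing_ch, collapse = ", "))
  nz <- dim(stack$data)[2]
  excl <- det$exclusion
  in_cell <- cells$labels > 0 & !excl
  in_bg <- cells$labels == 0 & !excl

  thresholds <- numeric(length(channels))
  names(thresholds) <- channels
  for (ch in channels) {
    pix <- unlist(lapply(seq_len(nz), function(zi) {
      sl <- get_channel(stack, ch, z = zi)
      if (rule$method == "k_mad") sl[in_bg] else sl[in_cell]
    }))
    thresholds[ch] <- switch(rule$method,
      otsu = otsu_threshold(pix),
      k_mad = stats::median(pix) + rule$k * stats::mad(pix),
      fixed = {
        if (is.na(rule$fixed[ch])) stop("no fixed threshold for ", ch)
        rule$fixed[[ch]]
      })
  }

  p <- det$puncta
  flags <- matrix(FALSE, nrow(p), length(channels),
                  dimnames = list(NULL, channels))
  if (nrow(p)) {
    for (zi in unique(p$z)) {
      lab <- det$label_stacks[[zi]]
      rows_z <- which(p$z == zi)
      for (ch in channels) {
        sl <- get_channel(stack, ch, z = zi)
        pos <- sl > thresholds[ch]
        for (i in rows_z) {
          pix <- lab == p$slice_label[i]
          flags[i, ch] <- mean(pos[pix]) >= rule$min_fraction
        }
      }
    }
  }
  combo <- apply(flags, 1, function(f) {
    key <- paste(as.integer(f), collapse = "")
    switch(key, "1000" = "H", "1100" = "H+S", "1110" = "H+S+M",
           "1111" = "H+S+M+C", "other")
  })
  for (ch in channels) p[[paste0("pos_", ch)]] <- flags[, ch]
  p$combo_class <- if (nrow(p)) combo else character()

  lev <- c("H", "H+S", "H+S+M", "H+S+M+C", "other")
  counts <- table(factor(p$combo_class, levels = lev))
  fractions <- if (nrow(p)) as.numeric(counts) / nrow(p) else
    rep(NA_real_, length(lev))
  names(fractions) <- lev

  det$puncta <- p
  det$class_fractions <- fractions
  det$thresholds <- thresholds
  det
}

#' Per-cell punctum counts
#'
#' @param det a `PunctaResult`.
#' @param n_cells total number of cells in the field; cells with no
#'   detected punctum get an explicit zero.
#' @param use_3d count linked 3-D components (default) rather than
#'   per-slice detections.
#' @return integer vector of length `n_cells`, named by cell id.
#' @export
per_cell_counts <- function(det, n_cells, use_3d = TRUE) {
  stopifnot(inherits(det, "PunctaResult"))
  stopifnot_scalar(n_cells, "n_cells", lo = 0)
  counts <- integer(n_cells)
  names(counts) <- seq_len(n_cells)
  p <- det$puncta[det$puncta$cell_id > 0, , drop = FALSE]
  if (nrow(p)) {
    if (use_3d) p <- p[!duplicated(p$component_3d), , drop = FALSE]
    tab <- table(p$cell_id)
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Percentage of cells carrying at least one cytoplasmic DNA punctum
#'
#' @param cell_counts integer vector of per-cell punctum counts (one entry
#'   per cell, zeros included), e.g. from [per_cell_counts()].
#' @param n_cells total cell count of the field (defaults to
#'   `length(cell_counts)`).
#' @return percentage in `[0, 100]`.
#' @export
puncta_positive_fraction <- function(cell_counts,
                                     n_cells = length(cell_counts)) {
  if (n_cells == 0) stop("n_cells must be positive")
  if (length(cell_counts) > n_cells)
    stop("more per-cell counts than cells")
  100 * sum(cell_counts >= 1) / n_cells
}
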