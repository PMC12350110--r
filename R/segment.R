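# Binary segmentation and labeled-particle measurement.
#
# Every quantification in the pipeline is built on the same chain:
# threshold -> morphological close -> hole fill -> (optional) watershed
# split -> connected-component labeling -> per-label measurement.

#' Segmentation parameters
#'
#' @param threshold `"otsu"` for an automatic per-image Otsu threshold
#'   (the default: manual thresholds are irreproducible), or a fixed numeric
#'   value on the image's intensity scale.
#' @param close_radius disk radius (px) of the morphological closing applied
#'   to the thresholded mask; `0` disables it.
#' @param fill_holes fill enclosed background holes in the mask.
#' @param watershed split touching objects by watershed on the negated
#'   distance transform (seeded with h-maxima suppression, height
#'   `watershed_h`).
#' @param watershed_h h-maxima suppression height in pixels (default 1,
#'   the standard distance-map watershed tolerance for nucleus-scale
#'   objects);
#'   larger values merge shallower splits.
#' @param min_area_px particles smaller than this (in pixels) are dropped.
#' @param exclude_border drop particles touching the image border.
#' @param connectivity pixel connectivity for component labeling, 4 or 8
#'   (default 8, the common particle-analysis convention).
#' @return an object of class `SegmentParams`.
#' @export
seg_params <- function(threshold = "otsu", close_radius = 1,
                       fill_holes = TRUE, watershed = FALSE,
                       watershed_h = 1, min_area_px = 5,
                       exclude_border = FALSE, connectivity = 8) {
  if (!identical(threshold, "otsu"))
    stopifnot_scalar(threshold, "threshold")
  stopifnot_scalar(close_radius, "close_radius", lo = 0)
  stopifnot_scalar(watershed_h, "watershed_h", lo = 0)
  stopifnot_scalar(min_area_px, "min_area_px", lo = 1)
  if (!connectivity %in% c(4, 8)) stop("'connectivity' must be 4 or 8")
  structure(
    list(threshold = threshold, close_radius = close_radius,
         fill_holes = isTRUE(fill_holes), watershed = isTRUE(watershed),
         watershed_h = watershed_h, min_area_px = min_area_px,
         exclude_border = isTRUE(exclude_border),
         connectivity = as.integer(connectivity)),
    class = "SegmentParams"
  )
}

#' Segment and measure particles in a single-channel image
#'
#' Runs the binary-segmentation chain (threshold, close, fill holes,
#' optional watershed split) and measures every labeled particle: area,
#' intensity-independent centroid, mean fluorescence intensity (MFI) and
#' bounding box. MFI is measured on `measure_on` when supplied, otherwise on
#' the segmented image itself.
#'
#' An image whose threshold leaves no foreground yields an empty ROI table,
#' not an error.
#'
#' @param image 2-D numeric matrix (rows = y, columns = x).
#' @param params a [seg_params()] object.
#' @param measure_on optional second matrix of identical shape on which MFI
#'   is measured.
#' @return a list of class `SegResult`:
#'   \describe{
#'     \item{rois}{data frame with columns `label`, `area_px`, `x`, `y`
#'       (0-based pixel-centered centroid), `mfi`, `bbox_x0`, `bbox_x1`,
#'       `bbox_y0`, `bbox_y1` (0-based, inclusive).}
#'     \item{labels}{integer label matrix, 0 = background.}
#'     \item{threshold}{the resolved threshold value.}
#'   }
#' @export
segment_particles <- function(image, params = seg_params(),
                              measure_on = NULL) {
  stopifnot(is.matrix(image), inherits(params, "SegmentParams"))
  if (length(image) == 0L) stop("empty image")
  if (!is.null(measure_on) && !all(dim(measure_on) == dim(image)))
    stop("'measure_on' must match the image shape")

  thr <- resolve_threshold(params$threshold, image)
  mask <- image > thr
  if (any(mask)) {
    ebm <- EBImage::Image(mask * 1)
    if (params$close_radius > 0)
      ebm <- EBImage::closing(ebm, disk_brush(params$close_radius))
    if (params$fill_holes)
      ebm <- EBImage::fillHull(ebm)
    if (params$watershed) {
      dm <- EBImage::distmap(ebm)
      lab <- EBImage::imageData(
        EBImage::watershed(dm, tolerance = params$watershed_h, ext = 1L))
      lab <- relabel_raster(lab)
    } else {
      lab <- label_components(EBImage::imageData(ebm) > 0,
                              params$connectivity)
    }
  } else {
    lab <- matrix(0L, nrow(image), ncol(image))
  }

  meas <- if (is.null(measure_on)) image else measure_on
  rois <- measure_labels(lab, meas)

  keep <- rois$area_px >= params$min_area_px
  if (params$exclude_border && nrow(rois)) {
    border_ids <- unique(c(lab[1, ], lab[nrow(lab), ],
                           lab[, 1], lab[, ncol(lab)]))
    keep <- keep & !(rois$label %in% border_ids)
  }
  dropped <- rois$label[!keep]
  if (length(dropped)) lab[lab %in% dropped] <- 0L
  rois <- rois[keep, , drop = FALSE]
  rownames(rois) <- NULL

  structure(list(rois = rois, labels = lab, threshold = thr),
            class = "SegResult")
}

#' @export
print.SegResult <- function(x, ...) {
  cat(sprintf("SegResult: %d particle(s), threshold %.4g\n",
              nrow(x$rois), x$threshold))
  invisible(x)
}

#' Measure every labeled region of a label matrix
#'
#' @param labels integer label matrix (0 = background).
#' @param intensity matrix of identical shape on which MFI is computed.
#' @return ROI data frame (see [segment_particles()]).
#' @export
measure_labels <- function(labels, intensity) {
  stopifnot(all(dim(labels) == dim(intensity)))
  idx <- which(labels > 0)
  if (length(idx) == 0L) {
    return(data.frame(label = integer(), area_px = integer(),
                      x = numeric(), y = numeric(), mfi = numeric(),
                      bbox_x0 = integer(), bbox_x1 = integer(),
                      bbox_y0 = integer(), bbox_y1 = integer()))
  }
  lab <- labels[idx]
  rows <- ((idx - 1L) %% nrow(labels)) + 1L   # 1-based row (y + 1)
  cols <- ((idx - 1L) %/% nrow(labels)) + 1L  # 1-based col (x + 1)
  f <- factor(lab)
  ids <- as.integer(levels(f))
  area <- as.integer(tabulate(f))
  # 0-based pixel-centered coordinates
  cx <- as.numeric(tapply(cols - 1L, f, mean))
  cy <- as.numeric(tapply(rows - 1L, f, mean))
  mfi <- as.numeric(tapply(intensity[idx], f, mean))
  data.frame(
    label = ids, area_px = area, x = cx, y = cy, mfi = mfi,
    bbox_x0 = as.integer(tapply(cols - 1L, f, min)),
    bbox_x1 = as.integer(tapply(cols - 1L, f, max)),
    bbox_y0 = as.integer(tapply(rows - 1L, f, min)),
    bbox_y1 = as.integer(tapply(rows - 1L, f, max))
  )
}

#' Repeated binary dilation to merge nearby segments
#'
#' Dilates a binary mask `iterations` times with a disk element of radius
#' `radius_px`, the operation used to merge multiple trap fragments
#' surrounding a single cell into one countable object. Foreground never
#' shrinks and the component count never increases.
#'
#' @param mask binary matrix (logical or 0/1).
#' @param iterations number of dilation passes (default 3).
#' @param radius_px disk radius of the structuring element (default 1).
#' @return logical matrix.
#' @export
dilate_merge <- function(mask, iterations = 3L, radius_px = 1L) {
  stopifnot(is.matrix(mask))
  stopifnot_scalar(iterations, "iterations", lo = 0)
  stopifnot_scalar(radius_px, "radius_px", lo = 1)
  m <- EBImage::Image((mask > 0) * 1)
  if (iterations >= 1 && any(mask > 0)) {
    br <- disk_brush(radius_px)
    for (i in seq_len(iterations)) m <- EBImage::dilate(m, br)
  }
  EBImage::imageData(m) > 0
}

#' Zero out image pixels inside an exclusion region
#'
#' Sets every pixel covered by `exclusion` to 0 and leaves all other pixels
#' bit-identical — the "fill the ROI with black" step used to remove nuclear
#' signal before extranuclear quantification.
#'
#' @param image numeric matrix.
#' @param exclusion binary matrix, label matrix (any value > 0 excludes), or
#'   a `SegResult` whose label matrix is used.
#' @return matrix of the same shape.
#' @export
mask_exclude <- function(image, exclusion) {
  if (inherits(exclusion, "SegResult")) exclusion <- exclusion$labels
  stopifnot(is.matrix(image), is.matrix(exclusion))
  if (!all(dim(image) == dim(exclusion)))
    stop("image and exclusion mask shapes differ")
  image[exclusion > 0] <- 0
  image
}
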