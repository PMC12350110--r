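# MET quantification from CitH3 staining.

#' Quantify CitH3-positive MET regions in a field
#'
#' Implements the extracellular-trap scoring chain: the CitH3 signal inside
#' nuclei is blacked out, the remainder is thresholded and segmented into
#' raw trap fragments, and the binary mask is then dilated repeatedly
#' (default three times) so that multiple fragments surrounding a single
#' cell merge into one countable object. The merged count is expressed as a
#' percentage of the nuclei in the field and, optionally, as a fold change
#' over a reference condition.
#'
#' Raw fragments are filtered by `params$min_area_px` and (by default)
#' border exclusion *before* dilation, so sub-resolution specks cannot seed
#' merged objects.
#'
#' @param cith3 2-D matrix of the CitH3 channel.
#' @param nuclei result of [count_nuclei()] on the same field (supplies the
#'   nuclear label mask and the cell-count denominator).
#' @param params a [seg_params()] for the MET segmentation; the default
#'   excludes border-touching fragments and uses a minimum area large
#'   enough to reject single puncta.
#' @param dilate_iterations number of dilation passes used to merge
#'   fragments (default 3).
#' @param dilate_radius_px disk radius of each dilation pass (default 1).
#' @param reference_percent optional MET percentage of a reference
#'   (control) condition; when supplied and positive, the fold ratio
#'   `percent / reference_percent` is reported.
#' @return list of class `METResult`: `n_met_segments_raw`, `n_met_merged`,
#'   `n_cells`, `percent`, `fold_vs_reference` (or `NA`), plus the raw and
#'   merged binary masks.
#' @export
quantify_mets <- function(cith3, nuclei,
                          params = seg_params(min_area_px = 40,
                                              exclude_border = TRUE),
                          dilate_iterations = 3L, dilate_radius_px = 1L,
                          reference_percent = NULL) {
  stopifnot(is.matrix(cith3))
  if (is.null(nuclei$labels) || is.null(nuclei$count))
    stop("'nuclei' must be a count_nuclei() result")
  if (nuclei$count == 0L)
    stop("zero nuclei in field: MET percentage is undefined")

  cleared <- mask_exclude(cith3, nuclei$labels)
  if (identical(params$threshold, "otsu")) {
    # exclude the blacked-out nuclear pixels from the histogram so they
    # cannot form a spurious low mode
    params$threshold <- otsu_threshold(cleared[nuclei$labels == 0])
  }
  seg <- segment_particles(cleared, params)
  n_raw <- nrow(seg$rois)

  raw_mask <- seg$labels > 0
  merged_mask <- dilate_merge(raw_mask, dilate_iterations, dilate_radius_px)
  n_merged <- max(label_components(merged_mask, params$connectivity))

  percent <- 100 * n_merged / nuclei$count
  fold <- NA_real_
  if (!is.null(reference_percent)) {
    stopifnot_scalar(reference_percent, "reference_percent")
    if (reference_percent <= 0)
      stop("fold ratio requires a positive reference percent")
    fold <- percent / reference_percent
  }
  structure(
    list(n_met_segments_raw = n_raw, n_met_merged = as.integer(n_merged),
         n_cells = nuclei$count, percent = percent,
         fold_vs_reference = fold,
         raw_mask = raw_mask, merged_mask = merged_mask),
    class = "METResult"
  )
}

#' @export
print.METResult <- function(x, ...) {
  cat(sprintf(
    "METs: %d raw fragment(s) -> %d merged; %d cells; %.2f%% MET-positive\n",
    x$n_met_segments_raw, x$n_met_merged, x$n_cells, x$percent))
  if (!is.na(x$fold_vs_reference))
    cat(sprintf("  fold vs reference: %.2f\n", x$fold_vs_reference))
  invisible(x)
}
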