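# Nuclear counting and condensed-nucleus (apoptosis) gating.

#' Count nuclei in a Hoechst image
#'
#' Segments the nuclear channel with the watershed split forced on (so
#' touching nuclei are separated) and returns the particle count. This count
#' is the per-field denominator for every per-cell percentage downstream.
#'
#' @param hoechst 2-D matrix of the nuclear (Hoechst 33342) channel.
#' @param params a [seg_params()]; `watershed` is forced to `TRUE`.
#' @return list with `count` (integer), `rois` (ROI data frame) and
#'   `labels` (nuclear label matrix).
#' @export
count_nuclei <- function(hoechst, params = seg_params(watershed = TRUE,
                                                      min_area_px = 30)) {
  params$watershed <- TRUE
  seg <- segment_particles(hoechst, params)
  list(count = nrow(seg$rois), rois = seg$rois, labels = seg$labels)
}

#' Condensation gate specification
#'
#' Apoptotic (condensed) nuclei are small and densely stained: the gate
#' flags nuclei with area below `area_max` and Hoechst MFI above `mfi_min`.
#' In `"relative"` mode (the default) both thresholds are fractions of the
#' per-field medians, which makes the gate independent of acquisition
#' settings; in `"absolute"` mode they are raw pixel/intensity values.
#'
#' @param area_max area threshold: px^2 (`absolute`) or fraction of the
#'   median nuclear area (`relative`, default 0.7).
#' @param mfi_min MFI threshold: intensity (`absolute`) or multiple of the
#'   median nuclear MFI (`relative`, default 1.4).
#' @param mode `"relative"` or `"absolute"`.
#' @return an object of class `GateSpec`.
#' @export
gate_spec <- function(area_max = 0.7, mfi_min = 1.4,
                      mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  stopifnot_scalar(area_max, "area_max", lo = 0)
  stopifnot_scalar(mfi_min, "mfi_min", lo = 0)
  if (area_max <= 0) stop("'area_max' must be positive")
  structure(list(area_max = area_max, mfi_min = mfi_min, mode = mode),
            class = "GateSpec")
}

#' Gate condensed (apoptotic) nuclei by MFI vs area
#'
#' Replaces manual dot-plot gating of MFI against nuclear area with a
#' deterministic rule: a nucleus is condensed iff
#' `area_px < area_max` and `mfi > mfi_min` (thresholds resolved per the
#' gate's mode). Relative mode requires at least 10 nuclei so the medians
#' are meaningful.
#'
#' @param nuclei ROI data frame (from [count_nuclei()] or
#'   [segment_particles()]) with columns `area_px` and `mfi`.
#' @param gate a [gate_spec()].
#' @return list of class `CondensationResult`: `n_total`, `n_condensed`,
#'   `fraction`, `flags` (per-nucleus logical), and the resolved
#'   `area_max`/`mfi_min` thresholds.
#' @export
gate_condensed <- function(nuclei, gate = gate_spec()) {
  if (is.list(nuclei) && !is.data.frame(nuclei) && !is.null(nuclei$rois))
    nuclei <- nuclei$rois
  stopifnot(is.data.frame(nuclei), inherits(gate, "GateSpec"))
  if (!all(c("area_px", "mfi") %in% names(nuclei)))
    stop("'nuclei' must have 'area_px' and 'mfi' columns")
  n <- nrow(nuclei)
  if (gate$mode == "relative") {
    if (n < 10L)
      stop("relative gating needs >= 10 nuclei to estimate medians (got ",
           n, ")")
    area_max <- gate$area_max * stats::median(nuclei$area_px)
    mfi_min <- gate$mfi_min * stats::median(nuclei$mfi)
  } else {
    area_max <- gate$area_max
    mfi_min <- gate$mfi_min
  }
  flags <- nuclei$area_px < area_max & nuclei$mfi > mfi_min
  structure(
    list(n_total = n, n_condensed = sum(flags),
         fraction = if (n > 0) sum(flags) / n else NA_real_,
         flags = flags, area_max = area_max, mfi_min = mfi_min),
    class = "CondensationResult"
  )
}

#' @export
print.CondensationResult <- function(x, ...) {
  cat(sprintf("Condensed nuclei: %d / %d (%.1f%%)\n",
              x$n_condensed, x$n_total, 100 * x$fraction))
  invisible(x)
}
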