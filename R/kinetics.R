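# Death-curve extraction from SYTOX time-lapse series.

#' Count SYTOX-positive (dead) cells in one time-lapse frame
#'
#' Dead cells show whole-nucleus SYTOX staining, so the frame's SYTOX
#' channel is segmented with a minimum area at nucleus scale — small enough
#' signal (puncta) is excluded by the size filter. Frames are counted
#' independently; no tracking is attempted.
#'
#' @param frame a [channel_stack()] containing a `sytox` channel, or a 2-D
#'   matrix of that channel.
#' @param params a [seg_params()]; the default minimum area of 30 px
#'   corresponds to a nucleus-sized object.
#' @param channel channel name used when `frame` is a `ChannelStack`.
#' @return integer count.
#' @export
count_sytox_cells <- function(frame,
                              params = seg_params(min_area_px = 30),
                              channel = "sytox") {
  img <- if (inherits(frame, "ChannelStack"))
    get_channel(frame, channel, z = 1) else frame
  nrow(segment_particles(img, params)$rois)
}

#' Build a death curve from a time-lapse frame series
#'
#' The per-frame SYTOX-positive count is normalized to the initial nucleus
#' count `n0` (from Hoechst at frame 0, the only time the UV channel is
#' acquired). When replicate fields of the same well are supplied, their
#' fractions are averaged per time point.
#'
#' @param frames list of [channel_stack()] frames in time order, each with
#'   a `time_h`; or a list of such lists (replicate fields).
#' @param n0 initial nucleus count(s): a scalar, or one value per replicate
#'   field. If `NULL`, counted from the `hoechst` channel of each field's
#'   first frame with [count_nuclei()].
#' @param params a [seg_params()] passed to [count_sytox_cells()].
#' @return list of class `DeathCurve`: `times_h`, `fraction_positive`
#'   (averaged over replicates), `n0` (per replicate), and
#'   `per_replicate` (fraction matrix, time x replicate).
#' @export
build_death_curve <- function(frames, n0 = NULL,
                              params = seg_params(min_area_px = 30)) {
  if (length(frames) && inherits(frames[[1]], "ChannelStack"))
    frames <- list(frames)
  nrep <- length(frames)
  if (nrep == 0L) stop("no frames supplied")
  times <- vapply(frames[[1]], function(f) f$time_h, numeric(1))
  if (any(diff(times) <= 0)) stop("frame timestamps must be increasing")
  if (is.null(n0)) {
    n0 <- vapply(frames, function(ff)
      count_nuclei(get_channel(ff[[1]], "hoechst", z = 1))$count, numeric(1))
  } else if (length(n0) == 1L) {
    n0 <- rep(n0, nrep)
  }
  if (any(n0 <= 0)) stop("initial nucleus count n0 must be positive")
  mat <- matrix(NA_real_, length(times), nrep)
  for (ri in seq_len(nrep)) {
    ff <- frames[[ri]]
    if (length(ff) != length(times))
      stop("replicate fields have different frame counts")
    mat[, ri] <- vapply(ff, count_sytox_cells, numeric(1),
                        params = params) / n0[ri]
  }
  structure(
    list(times_h = times, fraction_positive = rowMeans(mat),
         n0 = n0, per_replicate = mat),
    class = "DeathCurve"
  )
}

#' Construct a DeathCurve from precomputed fractions
#'
#' Convenience constructor for curves obtained outside the imaging path
#' (e.g. from exported counts).
#' @param times_h increasing time vector (hours).
#' @param fraction_positive matching vector of SYTOX-positive fractions.
#' @param n0 initial nucleus count.
#' @return a `DeathCurve`.
#' @export
death_curve <- function(times_h, fraction_positive, n0 = NA_integer_) {
  if (length(times_h) != length(fraction_positive))
    stop("times and fractions differ in length")
  if (any(diff(times_h) <= 0)) stop("times must be increasing")
  structure(list(times_h = times_h,
                 fraction_positive = fraction_positive, n0 = n0,
                 per_replicate = matrix(fraction_positive, ncol = 1)),
            class = "DeathCurve")
}

#' @export
print.DeathCurve <- function(x, ...) {
  cat(sprintf(
    "DeathCurve: %d points, %.2f-%.2f h, final fraction %.3f (n0 = %s)\n",
    length(x$times_h), min(x$times_h), max(x$times_h),
    x$fraction_positive[length(x$fraction_positive)],
    paste(x$n0, collapse = ",")))
  invisible(x)
}

#' Estimate the plateau of a death curve
#'
#' The plateau level is the mean of the final `k` points; the onset is the
#' earliest time after which every point stays within `tol` of that level.
#' A curve that never enters the tolerance band (e.g. one still rising at
#' the end) has an undefined onset, reported as `NA` with an explanatory
#' `reason`.
#'
#' @param curve a `DeathCurve` (>= 5 time points).
#' @param tol tolerance band half-width around the plateau level.
#' @param k number of final points defining the level (default 4).
#' @return list with `level`, `onset_time_h` (`NA` if undefined) and
#'   `reason` (`NULL` when defined).
#' @export
plateau_time <- function(curve, tol = 0.02, k = 4L) {
  stopifnot(inherits(curve, "DeathCurve"))
  f <- curve$fraction_positive
  if (length(f) < 5L) stop("at least 5 time points are required")
  if (k < 1L || k > length(f)) stop("invalid 'k'")
  level <- mean(f[(length(f) - k + 1L):length(f)])
  inband <- abs(f - level) <= tol
  # earliest index from which all later points stay in band
  ok <- rev(cumprod(rev(inband))) > 0
  if (!any(ok)) {
    return(list(level = level, onset_time_h = NA_real_,
                reason = "curve never stays within tol of the level"))
  }
  list(level = level, onset_time_h = curve$times_h[which(ok)[1]],
       reason = NULL)
}
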