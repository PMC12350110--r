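# Quadrant polarity of cytoplasmic puncta toward the MET release site.

#' Assign puncta to quadrants oriented toward the MET anchor
#'
#' A circular ROI of radius `radius_px` is centered on the nucleus and
#' divided into four 90-degree sectors, with sector 1 facing the MET
#' release site: the reference axis is the unit vector from the nucleus
#' center to the MET anchor, and a punctum at signed angle `theta` from that
#' axis falls in quadrant 1 when `|theta| <= 45` degrees, quadrant 2 when
#' `45 < theta <= 135`, quadrant 4 when `-135 <= theta < -45`, and
#' quadrant 3 otherwise. Puncta beyond `radius_px` are ignored; z-slices are
#' pooled.
#'
#' @param puncta data frame with columns `x` and `y` (punctum centroids),
#'   or a `PunctaResult` (its records are used).
#' @param nucleus_center numeric `(x, y)` of the nucleus center.
#' @param met_anchor numeric `(x, y)` of the MET anchor on the cell edge;
#'   must differ from `nucleus_center`.
#' @param radius_px counting radius (default `Inf`, i.e. the whole cell).
#' @return integer vector of four quadrant counts (quadrant 1 = toward the
#'   MET).
#' @export
assign_quadrants <- function(puncta, nucleus_center, met_anchor,
                             radius_px = Inf) {
  if (inherits(puncta, "PunctaResult")) puncta <- puncta$puncta
  stopifnot(is.data.frame(puncta), length(nucleus_center) == 2,
            length(met_anchor) == 2)
  axis <- c(met_anchor[1] - nucleus_center[1],
            met_anchor[2] - nucleus_center[2])
  if (all(axis == 0))
    stop("MET anchor coincides with the nucleus center")
  if (radius_px <= 0) stop("'radius_px' must be positive")
  counts <- integer(4)
  if (nrow(puncta) == 0L) return(counts)
  dx <- puncta$x - nucleus_center[1]
  dy <- puncta$y - nucleus_center[2]
  r <- sqrt(dx^2 + dy^2)
  keep <- r <= radius_px
  if (!any(keep)) return(counts)
  # signed angle from the reference axis, in (-pi, pi]
  theta <- atan2(axis[1] * dy[keep] - axis[2] * dx[keep],
                 axis[1] * dx[keep] + axis[2] * dy[keep])
  q <- ifelse(abs(theta) <= pi / 4, 1L,
       ifelse(theta > pi / 4 & theta <= 3 * pi / 4, 2L,
       ifelse(theta < -pi / 4 & theta >= -3 * pi / 4, 4L, 3L)))
  counts <- tabulate(q, nbins = 4L)
  counts
}

#' Summarize quadrant counts across cells and test polarization
#'
#' Aggregates per-cell quadrant counts (mean count and mean fraction per
#' quadrant) and tests quadrant 1 — the sector facing the MET — against
#' each of quadrants 2-4 with two-tailed Student t-tests on the per-cell
#' counts.
#'
#' @param counts matrix or data frame with one row per cell and four
#'   columns of quadrant counts, or a list of length-4 count vectors.
#' @return list of class `PolarityResult`: `per_cell` (count matrix),
#'   `mean_counts`, `mean_fractions`, and `tests` (data frame with the
#'   compared quadrant, t statistic and p-value).
#' @export
polarity_summary <- function(counts) {
  if (is.list(counts) && !is.data.frame(counts))
    counts <- do.call(rbind, counts)
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L) stop("expected 4 quadrant-count columns")
  if (nrow(counts) < 2L) stop("at least 2 cells are required")
  colnames(counts) <- paste0("q", 1:4)
  totals <- rowSums(counts)
  fracs <- counts / ifelse(totals > 0, totals, NA_real_)
  tests <- do.call(rbind, lapply(2:4, function(qi) {
    res <- compare_groups(list(counts[, 1], counts[, qi]),
                          labels = c("q1", paste0("q", qi)))
    data.frame(comparison = paste0("q1 vs q", qi),
               statistic = res$statistic, p_value = res$p_value)
  }))
  structure(
    list(per_cell = counts, mean_counts = colMeans(counts),
         mean_fractions = colMeans(fracs, na.rm = TRUE), tests = tests),
    class = "PolarityResult"
  )
}

#' @export
print.PolarityResult <- function(x, ...) {
  cat("Quadrant polarity over", nrow(x$per_cell), "cells\n")
  cat("  mean counts: ",
      paste(sprintf("q%d=%.2f", 1:4, x$mean_counts), collapse = "  "), "\n")
  for (i in seq_len(nrow(x$tests)))
    cat(sprintf("  %s: t = %.3f, p = %.3g %s\n", x$tests$comparison[i],
                x$tests$statistic[i], x$tests$p_value[i],
                p_stars(x$tests$p_value[i])))
  invisible(x)
}

#' Probability mass of a von Mises distribution on an angular interval
#'
#' Numerical integration of the von Mises density; used as the analytic
#' reference for quadrant occupancy under a polarized punctum distribution
#' (e.g. the quadrant-1 mass is `vonmises_mass(kappa, -pi/4, pi/4)`).
#'
#' @param kappa concentration parameter (>= 0; 0 is the uniform circle).
#' @param lower,upper interval bounds in radians, relative to the mean
#'   direction.
#' @return probability in `[0, 1]`.
#' @export
vonmises_mass <- function(kappa, lower, upper) {
  stopifnot_scalar(kappa, "kappa", lo = 0)
  dens <- function(t) {
    exp(kappa * (cos(t) - 1)) /
      (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
  }
  stats::integrate(dens, lower, upper, rel.tol = 1e-10)$value
}

#' Draw angles from a von Mises distribution
#'
#' Best-Fisher rejection sampler; `kappa = 0` reduces to the uniform
#' circle. Used by the field simulator to polarize puncta toward the MET
#' anchor.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @return numeric vector of angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  stopifnot_scalar(kappa, "kappa", lo = 0)
  if (kappa == 0) {
    th <- stats::runif(n, -pi, pi)
    return(th)
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      th <- sign(u3 - 0.5) * acos(f)
      out[i] <- atan2(sin(th + mu), cos(th + mu))
      i <- i + 1L
    }
  }
  out
}
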