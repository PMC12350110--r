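# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring the caller's state
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Otsu threshold of an intensity matrix or vector
#'
#' Wraps [EBImage::otsu()] for arbitrary-range data. A constant input has no
#' foreground/background split; `Inf` is returned so that `x > t` yields an
#' empty mask.
#' @noRd
otsu_threshold <- function(x, levels = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (length(v) == 0L) return(Inf)
  mn <- min(v); mx <- max(v)
  if (mx <= mn) return(Inf)
  img <- EBImage::Image(matrix((v - mn) / (mx - mn), nrow = 1L))
  t01 <- EBImage::otsu(img, range = c(0, 1), levels = levels)
  mn + t01 * (mx - mn)
}

#' Resolve a SegmentParams threshold spec against an image
#' @noRd
resolve_threshold <- function(threshold_method, image) {
  if (is.numeric(threshold_method)) return(as.numeric(threshold_method))
  if (identical(threshold_method, "otsu")) return(otsu_threshold(image))
  stop("unknown threshold method: ", threshold_method)
}

#' Connected-component labeling of a binary matrix
#'
#' [EBImage::bwlabel()] labels 4-connected components. For 8-connectivity,
#' 4-components that touch only diagonally are merged by union-find over
#' the diagonal adjacency pairs. Labels are renumbered 1..n in raster order
#' in both cases so the result is deterministic.
#' @noRd
label_components <- function(mask, connectivity = 8L) {
  mask <- mask > 0
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  n <- max(lab)
  if (connectivity == 8L && n > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonals
    a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonals
    sel1 <- a1 > 0 & b1 > 0 & a1 != b1
    sel2 <- a2 > 0 & b2 > 0 & a2 != b2
    pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
    if (nrow(pairs)) {
      parent <- seq_len(n)
      find <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      for (k in seq_len(nrow(pairs))) {
        ri <- find(pairs[k, 1]); rj <- find(pairs[k, 2])
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
      roots <- vapply(seq_len(n), find, integer(1))
      lab[lab > 0] <- roots[lab[lab > 0]]
    }
  }
  relabel_raster(lab)
}

#' Renumber positive labels 1..n by first occurrence in column-major order
#' @noRd
relabel_raster <- function(lab) {
  ids <- unique(as.vector(lab))
  ids <- ids[ids > 0]
  out <- matrix(0L, nrow(lab), ncol(lab))
  if (length(ids)) {
    out[lab > 0] <- match(lab[lab > 0], ids)
  }
  out
}

#' Disk structuring element of the given pixel radius
#' @noRd
disk_brush <- function(radius_px) {
  EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
}

stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a scalar in [%s, %s]", name,
                 format(lo), format(hi)), call. = FALSE)
  invisible(x)
}
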