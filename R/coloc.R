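# Cytoplasm-restricted Manders colocalization.

#' Manders colocalization of cytoplasmic DNA with a protein channel
#'
#' Computes the single-direction Manders coefficient M1 — the fraction of
#' cytoplasmic DNA signal residing in protein-positive pixels — after
#' removing the nuclear region from both channels:
#' \deqn{M1 = \frac{\sum_i D_i \, [D_i > t_D][P_i > t_P]}
#'                 {\sum_i D_i \, [D_i > t_D]}}
#' with the sums running over extranuclear pixels only. Only this direction
#' is meaningful when one condition has no cytoplasmic DNA at all (a
#' control cell), which is also why a field with no DNA-positive
#' cytoplasmic pixel yields an *undefined* result (`m1 = NA`, `defined =
#' FALSE`) rather than 0.
#'
#' @param dna 2-D matrix of the DNA channel (single z-slice).
#' @param protein 2-D matrix of the protein channel, same shape.
#' @param nuclear_mask binary matrix of the nuclear region removed from
#'   both channels.
#' @param thresholds `"otsu"` (default: per-channel Otsu computed over
#'   extranuclear pixels) or a named list/vector with elements `dna` and
#'   `protein`. Setting `dna = 0` reproduces the unthresholded-denominator
#'   variant.
#' @param both also compute M2 (protein into DNA-positive pixels); off by
#'   default, mirroring the one-sided design.
#' @return list of class `ColocResult`: `m1`, `defined`, `thresholds`,
#'   `n_pixels_dna_positive`, `coloc_map` (binary matrix of joint-positive
#'   cytoplasmic pixels), and `m2` when requested.
#' @export
manders_cytoplasmic <- function(dna, protein, nuclear_mask,
                                thresholds = "otsu", both = FALSE) {
  stopifnot(is.matrix(dna), is.matrix(protein), is.matrix(nuclear_mask))
  if (!all(dim(dna) == dim(protein)) ||
      !all(dim(dna) == dim(nuclear_mask)))
    stop("channel and mask shapes differ")
  cyt <- !(nuclear_mask > 0)
  dna_c <- mask_exclude(dna, nuclear_mask)
  prot_c <- mask_exclude(protein, nuclear_mask)
  if (identical(thresholds, "otsu")) {
    t_dna <- otsu_threshold(dna_c[cyt])
    t_prot <- otsu_threshold(prot_c[cyt])
  } else {
    t_dna <- thresholds[["dna"]]
    t_prot <- thresholds[["protein"]]
    if (is.null(t_dna) || is.null(t_prot))
      stop("'thresholds' needs elements 'dna' and 'protein'")
  }
  dna_pos <- cyt & dna_c > t_dna
  prot_pos <- cyt & prot_c > t_prot
  joint <- dna_pos & prot_pos
  denom <- sum(dna_c[dna_pos])
  res <- list(
    m1 = NA_real_, defined = FALSE,
    thresholds = c(dna = t_dna, protein = t_prot),
    n_pixels_dna_positive = sum(dna_pos),
    coloc_map = joint
  )
  if (sum(dna_pos) == 0L || denom <= 0) {
    res$reason <- "no DNA-positive cytoplasmic pixel; M1 is undefined"
  } else {
    res$m1 <- sum(dna_c[joint]) / denom
    res$defined <- TRUE
  }
  if (both) {
    denom2 <- sum(prot_c[prot_pos])
    res$m2 <- if (denom2 > 0) sum(prot_c[joint]) / denom2 else NA_real_
  }
  structure(res, class = "ColocResult")
}

#' @export
print.ColocResult <- function(x, ...) {
  if (x$defined)
    cat(sprintf("Manders M1 = %.4f over %d DNA-positive cytoplasmic px\n",
                x$m1, x$n_pixels_dna_positive))
  else cat("Manders M1 undefined:", x$reason, "\n")
  invisible(x)
}

#' Binary colocalization map of joint-positive cytoplasmic pixels
#'
#' The pixel set highlighted as "colocalized": extranuclear pixels above
#' threshold in both channels. Identical to the numerator support of
#' [manders_cytoplasmic()].
#'
#' @inheritParams manders_cytoplasmic
#' @return logical matrix.
#' @export
coloc_map <- function(dna, protein, nuclear_mask, thresholds = "otsu") {
  manders_cytoplasmic(dna, protein, nuclear_mask,
                      thresholds = thresholds)$coloc_map
}
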