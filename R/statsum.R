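# Group-comparison statistics and normality diagnostics.

#' Compare experimental groups
#'
#' Two groups: two-tailed Student t-test in its classical equal-variance
#' form (Welch available via `welch = TRUE`). Three or more groups: one-way
#' ANOVA with post-hoc Tukey HSD adjusted pairwise p-values.
#'
#' @param groups list of numeric vectors, one per group, each with n >= 2.
#' @param labels optional group names.
#' @param welch use the Welch (unequal-variance) t-test for two groups.
#' @return list of class `StatResult`: `design` (`"two_group"` or
#'   `"multi_group"`), `statistic` (t or F), `p_value`, and `pairwise`
#'   (data frame of Tukey-adjusted pairwise p-values; `NULL` for two
#'   groups).
#' @export
compare_groups <- function(groups, labels = NULL, welch = FALSE) {
  stopifnot(is.list(groups))
  if (length(groups) < 2L) stop("at least 2 groups are required")
  ns <- lengths(groups)
  if (any(ns < 2L)) stop("every group needs n >= 2")
  if (is.null(labels)) labels <- paste0("group", seq_along(groups))
  vars <- vapply(groups, stats::var, numeric(1))
  if (all(vars == 0)) {
    means <- vapply(groups, mean, numeric(1))
    if (length(unique(means)) == 1L && length(groups) == 2L) {
      # identical constant groups: no evidence of any difference
      return(structure(list(design = "two_group", statistic = 0,
                            p_value = 1, pairwise = NULL),
                       class = "StatResult"))
    }
    stop("zero within-group variance in all groups")
  }
  if (length(groups) == 2L) {
    tt <- stats::t.test(groups[[1]], groups[[2]], var.equal = !welch)
    structure(list(design = "two_group",
                   statistic = unname(tt$statistic),
                   p_value = tt$p.value, pairwise = NULL),
              class = "StatResult")
  } else {
    values <- unlist(groups, use.names = FALSE)
    grp <- factor(rep(labels, ns), levels = labels)
    fit <- stats::aov(values ~ grp)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$grp
    pairwise <- data.frame(pair = rownames(tk),
                           diff = tk[, "diff"],
                           p_adjusted = tk[, "p adj"],
                           row.names = NULL)
    structure(list(design = "multi_group",
                   statistic = an[["F value"]][1],
                   p_value = an[["Pr(>F)"]][1], pairwise = pairwise),
              class = "StatResult")
  }
}

#' @export
print.StatResult <- function(x, ...) {
  if (x$design == "two_group")
    cat(sprintf("Student t = %.4f, p = %.4g %s\n", x$statistic,
                x$p_value, p_stars(x$p_value)))
  else {
    cat(sprintf("One-way ANOVA F = %.4f, p = %.4g %s\n", x$statistic,
                x$p_value, p_stars(x$p_value)))
    for (i in seq_len(nrow(x$pairwise)))
      cat(sprintf("  Tukey %s: adj. p = %.4g %s\n", x$pairwise$pair[i],
                  x$pairwise$p_adjusted[i],
                  p_stars(x$pairwise$p_adjusted[i])))
  }
  invisible(x)
}

#' Normal quantile-quantile points and their correlation
#'
#' Theoretical quantiles are taken from the standard normal at plotting
#' positions `(i - 0.5) / n`; the correlation of the QQ pairs is a simple
#' normality diagnostic (near 1 for normal samples, visibly lower for
#' heavy-tailed data).
#'
#' @param sample numeric vector, n >= 3, non-constant.
#' @return list with `points` (data frame: `theoretical`, `empirical`) and
#'   `correlation`.
#' @export
qq_points <- function(sample) {
  sample <- as.numeric(sample)
  n <- length(sample)
  if (n < 3L) stop("at least 3 observations are required")
  if (stats::var(sample) == 0) stop("constant sample: QQ undefined")
  emp <- sort(sample)
  theo <- stats::qnorm((seq_len(n) - 0.5) / n)
  list(points = data.frame(theoretical = theo, empirical = emp),
       correlation = stats::cor(theo, emp))
}

#' Significance stars for a p-value
#'
#' Maps p-values to the star notation of figure legends:
#' `****` p < 0.0001, `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' `ns` otherwise.
#' @param p p-value(s).
#' @return character vector.
#' @export
p_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 1e-4) "****" else if (pi < 1e-3) "***"
    else if (pi < 0.01) "**" else if (pi < 0.05) "*" else "ns"
  }, character(1))
}

#' Write a run-level summary report
#'
#' Assembles a run directory: every supplied table as CSV, a markdown
#' summary listing them, and a JSON manifest with the configuration echo.
#'
#' @param dir output directory (created if needed).
#' @param tables named list of data frames.
#' @param config named list echoed into the manifest.
#' @param seed integer seed recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_report <- function(dir, tables = list(), config = list(),
                         seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lines <- c("# metquant run summary", "")
  for (nm in names(tables)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    persist_table(tables[[nm]], path)
    lines <- c(lines, sprintf("- `%s.csv`: %d row(s)", nm,
                              nrow(tables[[nm]])))
  }
  writeLines(lines, file.path(dir, "summary.md"))
  write_manifest(file.path(dir, "manifest.json"), config = config,
                 seed = seed)
  invisible(dir)
}
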