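# Shared image container and file I/O.

#' Multi-channel (optionally z-stacked) intensity image
#'
#' `ChannelStack` is the unit every pipeline stage consumes: a nonnegative
#' intensity array indexed `(channel, z, y, x)` with named channels and
#' pixel-size metadata. A plain 2-D image is represented with a z-extent of 1.
#' Pixel coordinates throughout the package are 0-based and pixel-centered,
#' with x increasing rightwards (columns) and y downwards (rows).
#'
#' @param data numeric array. Accepted shapes: `(y, x)` (one channel, one
#'   z-slice), `(z, y, x)` for a single-channel z-stack when
#'   `length(channel_names) == 1`, `(channel, y, x)` when it matches
#'   `length(channel_names)`, or the full `(channel, z, y, x)`.
#' @param channel_names character vector naming the channels in order,
#'   e.g. `c("hoechst", "sytox", "mpo", "cith3")`.
#' @param pixel_size_um physical pixel size in micrometres (scalar or one
#'   value per spatial axis), must be positive.
#' @param time_h optional acquisition time in hours (time-lapse frames).
#' @return An object of class `ChannelStack` with elements `data` (array
#'   `(channel, z, y, x)`), `channel_names`, `pixel_size_um`, `time_h`.
#' @examples
#' m <- matrix(runif(64), 8, 8)
#' cs <- channel_stack(m, "hoechst")
#' dim(cs$data)  # 1 1 8 8
#' @export
channel_stack <- function(data, channel_names, pixel_size_um = 1,
                          time_h = NULL) {
  nch <- length(channel_names)
  if (nch < 1L) stop("at least one channel name is required")
  d <- dim(data)
  if (is.null(d)) stop("'data' must be a matrix or array")
  if (length(d) == 2L) {
    if (nch != 1L) stop("2-D data but ", nch, " channel names")
    arr <- array(data, dim = c(1L, 1L, d[1], d[2]))
  } else if (length(d) == 3L) {
    if (d[1] == nch && nch > 1L) {
      arr <- array(0, dim = c(nch, 1L, d[2], d[3]))
      arr[, 1L, , ] <- data
    } else if (nch == 1L) {
      arr <- array(data, dim = c(1L, d[1], d[2], d[3]))
    } else {
      stop("cannot reconcile 3-D data of extent ", d[1],
           " on axis 1 with ", nch, " channel names")
    }
  } else if (length(d) == 4L) {
    if (d[1] != nch)
      stop("channel axis extent ", d[1], " does not match ",
           nch, " channel names")
    arr <- data
  } else {
    stop("'data' must have 2-4 dimensions, got ", length(d))
  }
  if (any(arr < 0)) stop("intensities must be nonnegative")
  if (any(!is.finite(arr))) stop("intensities must be finite")
  if (any(pixel_size_um <= 0)) stop("'pixel_size_um' must be positive")
  if (!is.null(time_h)) stopifnot_scalar(time_h, "time_h", lo = 0)
  structure(
    list(data = arr, channel_names = as.character(channel_names),
         pixel_size_um = pixel_size_um, time_h = time_h),
    class = "ChannelStack"
  )
}

#' @export
print.ChannelStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ChannelStack: %d channel(s) [%s], %d z-slice(s), %d x %d px\n",
              d[1], paste(x$channel_names, collapse = ", "), d[2], d[3], d[4]))
  invisible(x)
}

#' Extract one channel of a ChannelStack as a 2-D matrix or z-stack array
#'
#' @param stack a [channel_stack()].
#' @param channel channel name (preferred) or integer index.
#' @param z z-slice index, or `NULL` to return the full `(z, y, x)` array.
#' @return a `(y, x)` matrix when `z` is given (or the stack has a single
#'   slice), otherwise a `(z, y, x)` array.
#' @export
get_channel <- function(stack, channel, z = NULL) {
  stopifnot(inherits(stack, "ChannelStack"))
  ci <- if (is.character(channel)) match(channel, stack$channel_names)
        else as.integer(channel)
  if (is.na(ci) || ci < 1L || ci > dim(stack$data)[1])
    stop("channel not found: ", channel)
  nz <- dim(stack$data)[2]
  if (is.null(z)) {
    if (nz == 1L) return(stack$data[ci, 1L, , ])
    return(stack$data[ci, , , ])
  }
  stack$data[ci, z, , ]
}

#' Read a multi-page TIFF into a ChannelStack
#'
#' Pages are interpreted channel-major: all z-slices of channel 1, then all
#' z-slices of channel 2, and so on. The page count must be an exact multiple
#' of the number of mapped channels; anything else is an axis ambiguity and
#' raises an error naming the extents found. Intensities are rescaled from
#' the TIFF's native `[0, 1]` encoding back to integer counts
#' (`x * (2^bits - 1)`), which is bit-exact for integer-valued images.
#'
#' @param path path to a TIFF/OME-TIFF file.
#' @param channel_map character vector of channel names in page order.
#' @param pixel_size_um,time_h metadata forwarded to [channel_stack()].
#' @return a [channel_stack()].
#' @export
read_channel_stack <- function(path, channel_map, pixel_size_um = 1,
                               time_h = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nch <- length(channel_map)
  npg <- length(pages)
  if (npg %% nch != 0L)
    stop(sprintf(paste0("axis ambiguity: %d TIFF page(s) cannot be divided ",
                        "among %d channel(s)"), npg, nch))
  nz <- npg %/% nch
  bits <- attr(pages[[1]], "bits.per.sample")
  scale <- if (is.null(bits)) 65535 else 2^bits - 1
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  arr <- array(0, dim = c(nch, nz, h, w))
  k <- 1L
  for (ci in seq_len(nch)) {
    for (zi in seq_len(nz)) {
      pg <- pages[[k]]
      if (length(dim(pg)) == 3L) pg <- pg[, , 1L]  # drop extra samples
      if (nrow(pg) != h || ncol(pg) != w)
        stop("TIFF pages have inconsistent dimensions")
      arr[ci, zi, , ] <- round(pg * scale)
      k <- k + 1L
    }
  }
  channel_stack(arr, channel_map, pixel_size_um = pixel_size_um,
                time_h = time_h)
}

#' Write a ChannelStack as a 16-bit multi-page TIFF
#'
#' Pages are written channel-major (matching [read_channel_stack()]).
#' Intensities are stored as unsigned 16-bit counts; values must lie in
#' `[0, 65535]` and are rounded to the nearest integer.
#'
#' @param stack a [channel_stack()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_channel_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ChannelStack"))
  if (max(stack$data) > 65535)
    stop("intensities exceed the 16-bit range; rescale before writing")
  d <- dim(stack$data)
  pages <- list()
  k <- 1L
  for (ci in seq_len(d[1])) {
    for (zi in seq_len(d[2])) {
      pages[[k]] <- round(stack$data[ci, zi, , ]) / 65535
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' Write a measurement table as CSV
#'
#' Plain CSV with a header row and a locale-independent decimal point; the
#' export format used for every ROI/measurement table in the pipeline.
#' Re-reading with [utils::read.csv()] reproduces numeric values to 1e-9.
#'
#' @param table a data frame (e.g. an ROI table).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
persist_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  utils::write.csv(table, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records the configuration echo, seed and package version alongside every
#' run so that outputs are traceable.
#' @param path output path.
#' @param config named list echoed verbatim.
#' @param seed integer seed used for the run (or `NULL`).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = list(), seed = NULL) {
  manifest <- list(
    package = "metquant",
    version = as.character(utils::packageVersion("metquant")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
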