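# Pipeline configuration: a structured YAML file validated against a schema.

.config_schema <- list(
  channels       = list(type = "character"),
  seed           = list(type = "numeric", lo = 0, hi = 2^31 - 1),
  output_dir     = list(type = "character"),
  threshold      = list(type = "any"),        # "otsu" or a number
  close_radius   = list(type = "numeric", lo = 0, hi = 50),
  fill_holes     = list(type = "logical"),
  watershed      = list(type = "logical"),
  watershed_h    = list(type = "numeric", lo = 0, hi = 100),
  min_area_px    = list(type = "numeric", lo = 1, hi = 1e6),
  exclude_border = list(type = "logical"),
  connectivity   = list(type = "numeric", lo = 4, hi = 8),
  dilate_iterations = list(type = "numeric", lo = 0, hi = 100),
  dilate_radius_px  = list(type = "numeric", lo = 1, hi = 50),
  gate_area_max  = list(type = "numeric", lo = 0, hi = Inf),
  gate_mfi_min   = list(type = "numeric", lo = 0, hi = Inf),
  gate_mode      = list(type = "character"),
  pixel_size_um  = list(type = "numeric", lo = 1e-6, hi = 1e3),
  sim            = list(type = "list")
)

#' Read and validate a pipeline configuration file
#'
#' The configuration is a YAML mapping. Unknown keys are rejected and every
#' numeric parameter is checked against its documented closed range, so a
#' typo cannot silently change an analysis.
#'
#' @param path path to a YAML file.
#' @return a named list of validated settings with class `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param config a named list of settings (as parsed from YAML).
#' @export
validate_pipeline_config <- function(config) {
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(.config_schema))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (key in names(config)) {
    rule <- .config_schema[[key]]
    val <- config[[key]]
    if (rule$type == "numeric") {
      if (!is.numeric(val) || any(is.na(val)))
        stop("'", key, "' must be numeric")
      if (any(val < rule$lo) || any(val > rule$hi))
        stop(sprintf("'%s' = %s outside its allowed range [%s, %s]",
                     key, format(val[1]), format(rule$lo), format(rule$hi)))
    } else if (rule$type == "logical" && !is.logical(val)) {
      stop("'", key, "' must be true/false")
    } else if (rule$type == "character" && !is.character(val)) {
      stop("'", key, "' must be a string")
    }
  }
  structure(config, class = c("PipelineConfig", "list"))
}

#' Build SegmentParams from a pipeline configuration
#'
#' Maps the segmentation-related keys of a [read_pipeline_config()] result
#' onto [seg_params()], leaving unset keys at the module defaults.
#' @param config a `PipelineConfig`.
#' @return a [seg_params()] object.
#' @export
config_seg_params <- function(config) {
  take <- function(key, default) if (!is.null(config[[key]])) config[[key]] else default
  seg_params(
    threshold      = take("threshold", "otsu"),
    close_radius   = take("close_radius", 1),
    fill_holes     = take("fill_holes", TRUE),
    watershed      = take("watershed", FALSE),
    watershed_h    = take("watershed_h", 2),
    min_area_px    = take("min_area_px", 5),
    exclude_border = take("exclude_border", FALSE),
    connectivity   = take("connectivity", 8)
  )
}
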