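# image / table / config I-O -------------------------------------------------

#' Read and write raster images
#'
#' 8-bit RGB images are read from and written to TIFF or PNG (chosen by
#' extension); label maps round-trip through 16-bit single-channel TIFF
#' (cells per image are far below 65535).
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @return `read_color_image`: a [color_image()]; `read_label_map`: an
#'   integer matrix.
#' @name image_io
NULL

.img_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) "tiff"
  else if (ext == "png") "png"
  else stop("unsupported image format: .", ext)
}

#' @rdname image_io
#' @export
read_color_image <- function(path) {
  a <- switch(.img_format(path),
              tiff = tiff::readTIFF(path),
              png = png::readPNG(path))
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  color_image(round(a * 255))
}

#' @rdname image_io
#' @param img a [color_image()].
#' @export
write_color_image <- function(img, path) {
  img <- assert_color_image(img)
  a <- unclass(img) / 255
  switch(.img_format(path),
         tiff = tiff::writeTIFF(a, path, bits.per.sample = 8L),
         png = png::writePNG(a, path))
  invisible(path)
}

#' @rdname image_io
#' @param labels integer label map (values in `0..65535`).
#' @export
write_label_map <- function(labels, path) {
  stopifnot(is.matrix(labels), max(labels) <= 65535L)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname image_io
#' @export
read_label_map <- function(path) {
  a <- tiff::readTIFF(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  matrix(as.integer(round(a * 65535)), nrow(a), ncol(a))
}

#' Read and write feature tables
#'
#' CSV with the canonical header (identifiers, class, area, centroid, then
#' the 16 feature columns); the round-trip is lossless for the full
#' `print`-precision of doubles.
#'
#' @param table a `FeatureTable`.
#' @param path CSV path.
#' @name feature_io
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname feature_io
#' @export
read_feature_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Pipeline configuration
#'
#' One flat configuration drives every stage; it round-trips losslessly
#' through YAML and unknown keys are rejected, so a config file names
#' exactly the parameters the pipeline honors.  The colorspace constants
#' (sRGB/D65 white point, Rec. 709 gray weights) are recorded here for
#' provenance even though they are compile-time conventions.
#'
#' @param segmentation a [segmentation_params()] or list of overrides.
#' @param blue_fraction_mode `"median_ratio"` (ratio of channel medians) or
#'   `"pixel_ratio"`.
#' @param folds,variance_target,feature_set,models classification options.
#' @param seed pipeline seed.
#' @return object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(segmentation = segmentation_params(),
                            blue_fraction_mode = "median_ratio",
                            folds = 10L, variance_target = 0.99,
                            feature_set = "all",
                            models = c("knn", "logistic", "random_forest",
                                       "svm", "neural_net"),
                            seed = 1L) {
  if (!inherits(segmentation, "segmentation_params"))
    segmentation <- do.call(segmentation_params, segmentation)
  structure(list(
    colorspace = list(white_point = "D65", rgb_encoding = "sRGB",
                      gray_weights = unname(.gray_weights)),
    segmentation = unclass(segmentation),
    blue_fraction_mode = blue_fraction_mode,
    folds = as.integer(folds), variance_target = variance_target,
    feature_set = feature_set, models = models,
    seed = as.integer(seed)), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config` (write) / ignored (read).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  template <- pipeline_config()
  unknown <- setdiff(names(raw), names(template))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  seg <- raw$segmentation
  unknown_seg <- setdiff(names(seg), names(template$segmentation))
  if (length(unknown_seg))
    stop("unknown segmentation key(s): ", paste(unknown_seg, collapse = ", "))
  pipeline_config(
    segmentation = seg %||% list(),
    blue_fraction_mode = raw$blue_fraction_mode %||% template$blue_fraction_mode,
    folds = raw$folds %||% template$folds,
    variance_target = raw$variance_target %||% template$variance_target,
    feature_set = raw$feature_set %||% template$feature_set,
    models = raw$models %||% template$models,
    seed = raw$seed %||% template$seed)
}

#' Run manifest
#'
#' Every CLI/pipeline run emits a manifest naming the config hash that
#' produced the outputs, the seeds, package version, input checksums and
#' per-stage wall times, so any artifact can be traced to the exact
#' configuration.
#'
#' @param config a `pipeline_config`.
#' @param seeds named list/vector of seeds used.
#' @param inputs character vector of input file paths (checksummed).
#' @param timings named numeric vector of per-stage seconds.
#' @param warnings character vector of warnings raised.
#' @return list of class `"run_manifest"`.
#' @export
run_manifest <- function(config, seeds = list(), inputs = character(),
                         timings = numeric(), warnings = character()) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_pipeline_config(config, tmp)
  inputs <- inputs[file.exists(inputs)]
  structure(list(
    config_hash = unname(tools::md5sum(tmp)),
    seeds = seeds,
    package_version = as.character(utils::packageVersion("chromocell")),
    input_checksums = if (length(inputs))
      as.list(tools::md5sum(inputs)) else list(),
    timings = as.list(timings),
    warnings = warnings,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path JSON path.
#' @export
write_run_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
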