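# Image and configuration I/O. Intensity frames go to 16-bit grayscale PNG
# or TIFF; Fourier-domain maps (amplitude, phase) to 32-bit float TIFF.
# Run configurations round-trip through flat YAML.

#' Write an intensity image (16-bit TIFF / 8-bit PNG) or float map
#'
#' Intensity images (`float = FALSE`) are scaled to `[0, 1]` by their max and
#' quantized (16 bits for TIFF, 8 for PNG). Float maps (`float = TRUE`,
#' e.g. Fourier phase) are affinely mapped to `[0, 1]`, stored as 32-bit
#' float TIFF, and the range is recorded in a JSON sidecar
#' (`<path>.range.json`) so [read_float_tiff()] can restore the values.
#'
#' @param x matrix (or object with an `intensities`/`magnitudes`/`phase`
#'   field).
#' @param path output path ending in `.png` (intensity only) or `.tif(f)`.
#' @param float store as range-annotated 32-bit float TIFF.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path, float = FALSE) {
  if (is.list(x)) x <- x$intensities %||% x$magnitudes %||% x$phase
  ext <- tolower(tools::file_ext(path))
  if (float) {
    if (!ext %in% c("tif", "tiff")) stop("float maps must be written as TIFF")
    lo <- min(x); hi <- max(x)
    y <- if (hi > lo) (x - lo) / (hi - lo) else x * 0
    tiff::writeTIFF(y, path, bits.per.sample = 32L, reduce = FALSE)
    jsonlite::write_json(list(min = lo, max = hi),
                         paste0(path, ".range.json"), auto_unbox = TRUE,
                         digits = NA)
  } else {
    mx <- max(x)
    y <- if (mx > 0) x / mx else x
    if (ext == "png") {
      png::writePNG(y, path)
    } else if (ext %in% c("tif", "tiff")) {
      tiff::writeTIFF(y, path, bits.per.sample = 16L)
    } else {
      stop("unsupported image extension '", ext, "'")
    }
  }
  invisible(path)
}

#' Read a float map written by [write_image()] with `float = TRUE`
#'
#' @param path the `.tif` path; its `.range.json` sidecar must sit alongside.
#' @return numeric matrix with the original value range restored.
#' @export
read_float_tiff <- function(path) {
  rng <- jsonlite::read_json(paste0(path, ".range.json"))
  y <- tiff::readTIFF(path)
  y * (rng$max - rng$min) + rng$min
}

#' Read a grayscale speckle frame from PNG or TIFF
#'
#' Multi-channel images are averaged to one channel. Values are returned as
#' stored (0..1 for integer formats).
#'
#' @param path PNG or TIFF file.
#' @return a `speckle_frame` with provenance `"loaded"`.
#' @export
read_speckle <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image extension '", ext, "'"))
  if (length(dim(x)) == 3) x <- apply(x, c(1, 2), mean)
  if (any(!is.finite(x)) || any(x < 0)) stop("speckle frame must be finite and nonnegative")
  structure(list(intensities = x, provenance = "loaded"), class = "speckle_frame")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.run_config_keys <- c(
  "preset", "glyph", "support", "photons", "seed",
  "wavelength", "object_distance", "diffuser_camera_distance",
  "diffuser_thickness", "aperture_diameter", "sensor_shape", "pixel_pitch",
  "K", "stride", "n_angles", "M", "C", "half_width", "taper",
  "sigma_fraction", "beta", "n_hio", "n_er", "n_restarts", "method")

#' Default pipeline run configuration
#'
#' Flat key-value configuration merging scene and pipeline parameters; the
#' same structure round-trips through [write_run_config()] /
#' [read_run_config()] and is what every CLI run snapshots next to its
#' outputs.
#'
#' @param ... overrides for any known key.
#' @return named list (`run_config`).
#' @export
run_config <- function(...) {
  base <- list(preset = "fast", glyph = "5", support = NULL, photons = NULL,
               seed = 1L, K = 128L, stride = 16L, n_angles = 18L, M = NULL,
               C = 0.7, half_width = NULL, taper = "tukey",
               sigma_fraction = 0.125, beta = 0.9, n_hio = 200L, n_er = 50L,
               n_restarts = 5L, method = "bispectrum")
  ov <- list(...)
  bad <- setdiff(names(ov), .run_config_keys)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  base[names(ov)] <- ov
  structure(base, class = "run_config")
}

#' Write a run configuration as flat YAML
#' @param config a [run_config()].
#' @param path output `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

#' Read a run configuration, rejecting unknown keys
#' @param path a YAML file written by [write_run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  bad <- setdiff(names(vals), .run_config_keys)
  if (length(bad)) stop("unknown config key(s) in ", path, ": ",
                        paste(bad, collapse = ", "))
  do.call(run_config, vals)
}
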