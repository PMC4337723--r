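#' Write a two-channel image as a multi-page 16-bit TIFF
#'
#' Page 1 is the nuclear-stain channel, page 2 the transcription-factor
#' channel; counts are stored as 16-bit samples.
#'
#' @param image a `flow_image`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  stopifnot(inherits(image, "flow_image"))
  pages <- list(image$ch1 / 65535, image$ch2 / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a two-channel TIFF written by [write_image_tiff()]
#'
#' @param path TIFF path.
#' @param pixel_size_um microns per pixel of the stored image.
#' @param x_cm optional chamber position to attach.
#' @return a `flow_image` (without ground-truth masks).
#' @export
read_image_tiff <- function(path, pixel_size_um, x_cm = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2) stop("expected a 2-page TIFF", call. = FALSE)
  to_counts <- function(p) {
    m <- round(p * 65535)
    storage.mode(m) <- "integer"
    m
  }
  structure(
    list(ch1 = to_counts(pages[[1]]), ch2 = to_counts(pages[[2]]),
         pixel_size_um = pixel_size_um, x_cm = x_cm,
         shear_dyn_cm2 = NA_real_, true_masks = NULL, saturated = NA_integer_,
         params = list(source = path)),
    class = "flow_image")
}

#' Write the ground truth of a scene as CSV
#'
#' @param scene a `flow_scene`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(scene, path) {
  stopifnot(inherits(scene, "flow_scene"))
  df <- scene$cells
  df$x_cm <- scene$x_cm
  df$pixel_size_um <- scene$pixel_size_um
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# unit conversion factors to CGS for chamber config files
.unit_to_cgs <- list(
  cm = 1, mm = 0.1, m = 100, um = 1e-4,
  cm3_s = 1, ml_s = 1, ml_min = 1 / 60, ul_min = 1e-3 / 60,
  poise = 1, cP = 0.01, Pa_s = 10,
  dyn_cm2 = 1, Pa = 10)

convert_unit <- function(field, name) {
  if (is.numeric(field)) return(field)  # bare number: CGS assumed
  if (is.list(field) && !is.null(field$value)) {
    unit <- field$unit %||% "cgs"
    if (unit == "cgs") return(field$value)
    f <- .unit_to_cgs[[unit]]
    if (is.null(f)) {
      stop(sprintf("unknown unit '%s' for %s", unit, name), call. = FALSE)
    }
    return(field$value * f)
  }
  stop(sprintf("config field %s must be a number or {value, unit}", name),
       call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a chamber configuration from YAML
#'
#' Fields: `gasket_height`, `flow_rate`, `viscosity`, `channel_length`,
#' `shear_inlet`, `shear_outlet`. Each may be a bare number (CGS units
#' assumed: cm, cm^3/s, poise, dyn/cm^2) or a `{value, unit}` mapping with
#' SI or laboratory units (`mm`, `m`, `um`, `ml_min`, `cP`, `Pa_s`, `Pa`,
#' ...); everything is converted to CGS at load. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return a [chamber_config()].
#' @export
read_chamber_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  wanted <- c("gasket_height", "flow_rate", "viscosity", "channel_length",
              "shear_inlet", "shear_outlet")
  extra <- setdiff(names(cfg), wanted)
  if (length(extra) > 0) {
    stop(sprintf("unknown chamber config key(s): %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  missing <- setdiff(wanted, names(cfg))
  if (length(missing) > 0) {
    stop(sprintf("missing chamber config key(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  vals <- vapply(wanted, function(k) convert_unit(cfg[[k]], k), numeric(1))
  chamber_config(gasket_height_cm = vals[["gasket_height"]],
                 flow_rate_cm3_s = vals[["flow_rate"]],
                 viscosity_poise = vals[["viscosity"]],
                 channel_length_cm = vals[["channel_length"]],
                 shear_inlet_dyn_cm2 = vals[["shear_inlet"]],
                 shear_outlet_dyn_cm2 = vals[["shear_outlet"]])
}
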