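#' Gradient flow-chamber configuration
#'
#' Describes a tapered parallel-plate flow chamber in which the channel width
#' narrows along the flow axis so that wall shear stress increases linearly
#' from `shear_inlet_dyn_cm2` at x = 0 to `shear_outlet_dyn_cm2` at
#' x = `channel_length_cm`. Under lubrication theory the local wall shear in a
#' parallel-plate channel is tau = 6 mu Q / (h^2 w), so a linear shear ramp
#' corresponds to the width profile w(x) = 6 mu Q / (h^2 tau(x)). All units
#' are CGS: cm, cm^3/s, poise, dyn/cm^2.
#'
#' @param gasket_height_cm gasket (gap) height h in cm.
#' @param flow_rate_cm3_s volumetric flow rate Q in cm^3/s.
#' @param viscosity_poise medium dynamic viscosity mu in poise.
#' @param channel_length_cm channel length L in cm.
#' @param shear_inlet_dyn_cm2 wall shear at the wide (inlet) end, dyn/cm^2.
#' @param shear_outlet_dyn_cm2 wall shear at the narrow (outlet) end,
#'   dyn/cm^2. Equal inlet/outlet shear describes a uniform (untapered)
#'   chamber.
#' @return an object of class `chamber_config`.
#' @examples
#' cfg <- chamber_config(0.08, 0.533, 0.01, 7, 2, 60)
#' position_to_shear(cfg, c(0, 3.5, 7))
#' @export
chamber_config <- function(gasket_height_cm, flow_rate_cm3_s,
                           viscosity_poise, channel_length_cm,
                           shear_inlet_dyn_cm2, shear_outlet_dyn_cm2) {
  check_positive(gasket_height_cm = gasket_height_cm,
                 flow_rate_cm3_s = flow_rate_cm3_s,
                 viscosity_poise = viscosity_poise,
                 channel_length_cm = channel_length_cm,
                 shear_inlet_dyn_cm2 = shear_inlet_dyn_cm2,
                 shear_outlet_dyn_cm2 = shear_outlet_dyn_cm2)
  structure(
    list(gasket_height_cm = gasket_height_cm,
         flow_rate_cm3_s = flow_rate_cm3_s,
         viscosity_poise = viscosity_poise,
         channel_length_cm = channel_length_cm,
         shear_inlet_dyn_cm2 = shear_inlet_dyn_cm2,
         shear_outlet_dyn_cm2 = shear_outlet_dyn_cm2),
    class = "chamber_config")
}

#' @export
print.chamber_config <- function(x, ...) {
  cat("Gradient flow chamber (CGS units)\n")
  cat(sprintf("  gasket height : %.3f cm\n", x$gasket_height_cm))
  cat(sprintf("  flow rate     : %.4g cm^3/s\n", x$flow_rate_cm3_s))
  cat(sprintf("  viscosity     : %.4g poise\n", x$viscosity_poise))
  cat(sprintf("  length        : %.3g cm\n", x$channel_length_cm))
  cat(sprintf("  shear range   : %.3g -> %.3g dyn/cm^2\n",
              x$shear_inlet_dyn_cm2, x$shear_outlet_dyn_cm2))
  invisible(x)
}

#' Preset chamber configurations
#'
#' Two presets reproducing the published operating ranges of the gradient
#' chamber: `"huvec"` spans 2-60 dyn/cm^2 with the 0.8 mm gasket and
#' `"hdlec"` spans 0.5-20 dyn/cm^2 with the 1.6 mm gasket. The flow rate
#' (0.533 cm^3/s, i.e. 32 ml/min) and channel length (7 cm) are package
#' choices giving centimetre-scale channel widths; only the shear ranges and
#' gasket heights are published values.
#'
#' @param name `"huvec"` or `"hdlec"`.
#' @return a [chamber_config()].
#' @export
chamber_preset <- function(name = c("huvec", "hdlec")) {
  name <- match.arg(name)
  switch(name,
    huvec = chamber_config(gasket_height_cm = 0.08, flow_rate_cm3_s = 0.533,
                           viscosity_poise = 0.01, channel_length_cm = 7,
                           shear_inlet_dyn_cm2 = 2,
                           shear_outlet_dyn_cm2 = 60),
    hdlec = chamber_config(gasket_height_cm = 0.16, flow_rate_cm3_s = 0.533,
                           viscosity_poise = 0.01, channel_length_cm = 7,
                           shear_inlet_dyn_cm2 = 0.5,
                           shear_outlet_dyn_cm2 = 20))
}

#' Wall shear stress in a parallel-plate channel
#'
#' tau = 6 mu Q / (h^2 w), the standard lubrication-theory relation for fully
#' developed laminar flow between parallel plates of local width w and gap h.
#'
#' @param flow_rate_cm3_s volumetric flow rate Q (cm^3/s).
#' @param viscosity_poise dynamic viscosity mu (poise).
#' @param gasket_height_cm gap height h (cm).
#' @param width_cm local channel width w (cm).
#' @return wall shear stress in dyn/cm^2.
#' @examples
#' plate_shear(0.1667, 0.01, 0.08, 1)  # ~1.56 dyn/cm^2
#' @export
plate_shear <- function(flow_rate_cm3_s, viscosity_poise,
                        gasket_height_cm, width_cm) {
  check_positive(flow_rate_cm3_s = flow_rate_cm3_s,
                 viscosity_poise = viscosity_poise,
                 gasket_height_cm = gasket_height_cm,
                 width_cm = width_cm)
  6 * viscosity_poise * flow_rate_cm3_s / (gasket_height_cm^2 * width_cm)
}

check_position <- function(config, x_cm) {
  if (any(!is.finite(x_cm)) || any(x_cm < 0) ||
      any(x_cm > config$channel_length_cm)) {
    stop(sprintf("axial position must lie within [0, %g] cm",
                 config$channel_length_cm), call. = FALSE)
  }
  invisible(TRUE)
}

#' Wall shear stress at an axial position of a gradient chamber
#'
#' Shear increases linearly along the chamber:
#' tau(x) = tau_in + (tau_out - tau_in) x / L.
#'
#' @param config a [chamber_config()].
#' @param x_cm axial position(s) in cm, within \[0, L\].
#' @return shear stress in dyn/cm^2 (vectorised over `x_cm`).
#' @export
position_to_shear <- function(config, x_cm) {
  stopifnot(inherits(config, "chamber_config"))
  check_position(config, x_cm)
  with(config, shear_inlet_dyn_cm2 +
       (shear_outlet_dyn_cm2 - shear_inlet_dyn_cm2) * x_cm / channel_length_cm)
}

#' Channel width profile of a gradient chamber
#'
#' The width w(x) = 6 mu Q / (h^2 tau(x)) is the unique taper producing a
#' linear shear ramp under the parallel-plate relation; it decreases
#' monotonically along the chamber when outlet shear exceeds inlet shear.
#'
#' @inheritParams position_to_shear
#' @return channel width in cm (vectorised over `x_cm`).
#' @export
width_profile <- function(config, x_cm) {
  stopifnot(inherits(config, "chamber_config"))
  check_position(config, x_cm)
  with(config, 6 * viscosity_poise * flow_rate_cm3_s /
       (gasket_height_cm^2 * position_to_shear(config, x_cm)))
}

#' Tabulate the shear and width profile of a chamber
#'
#' @inheritParams position_to_shear
#' @param n number of evenly spaced axial sample points.
#' @return a tibble with columns `x_cm`, `width_cm`, `shear_dyn_cm2`.
#' @export
chamber_profile <- function(config, n = 50) {
  stopifnot(inherits(config, "chamber_config"), n >= 2)
  x <- seq(0, config$channel_length_cm, length.out = n)
  tibble::tibble(x_cm = x,
                 width_cm = width_profile(config, x),
                 shear_dyn_cm2 = position_to_shear(config, x))
}

#' Wall shear stress in a cylindrical vessel (Poiseuille flow)
#'
#' tau = 8 mu V / D for fully developed laminar flow in a cylinder of
#' diameter D with mean velocity V: the estimator used to place the umbilical
#' vein at roughly 8-12.5 dyn/cm^2 from literature viscosity, velocity and
#' diameter values.
#'
#' @param viscosity_poise blood viscosity mu (poise).
#' @param velocity_cm_s mean flow velocity V (cm/s).
#' @param diameter_cm lumen diameter D (cm).
#' @return wall shear stress in dyn/cm^2.
#' @examples
#' poiseuille_wall_shear(0.09, 7.1, 0.41)  # ~12.5 dyn/cm^2
#' @export
poiseuille_wall_shear <- function(viscosity_poise, velocity_cm_s,
                                  diameter_cm) {
  check_positive(viscosity_poise = viscosity_poise,
                 velocity_cm_s = velocity_cm_s,
                 diameter_cm = diameter_cm)
  8 * viscosity_poise * velocity_cm_s / diameter_cm
}
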