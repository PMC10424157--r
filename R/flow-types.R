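#' Channel slide geometry
#'
#' Describes the fluid path of a shallow channel slide: a footprint of uniform
#' height with cylindrical inlet/outlet ports. The plan footprint is either a
#' rectangle or an ellipse whose major axis equals the channel length and
#' minor axis equals the channel width.
#'
#' @param height channel height in metres (the small dimension, across which
#'   the parabolic velocity profile develops).
#' @param width channel width in metres; must be >= height.
#' @param length channel length in metres.
#' @param inlet_diameter diameter of the cylindrical inlet port in metres.
#' @param plan_shape `"rectangle"` or `"ellipse"` plan footprint.
#' @return An object of class `channel_geometry`.
#' @seealso [ibidi_slide_geometry()] for the commercial 0.4 mm slide.
#' @examples
#' channel_geometry(0.4e-3, 5e-3, 50e-3, 3.5e-3, "ellipse")
#' @export
channel_geometry <- function(height, width, length, inlet_diameter,
                             plan_shape = c("rectangle", "ellipse")) {
  plan_shape <- match.arg(plan_shape)
  for (nm in c("height", "width", "length", "inlet_diameter")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("invalid geometry: `", nm, "` must be a single positive number",
           call. = FALSE)
    }
  }
  if (height > width) {
    stop("invalid geometry: `height` must not exceed `width`", call. = FALSE)
  }
  structure(
    list(height = height, width = width, length = length,
         inlet_diameter = inlet_diameter, plan_shape = plan_shape),
    class = "channel_geometry"
  )
}

#' Geometry of the ibidi mu-Slide I Luer 0.4 channel slide
#'
#' The commercial slide used for monolayer culture under flow: 0.4 mm channel
#' height, 5 mm width, 50 mm length, 3.5 mm Luer ports, with an elliptical
#' plan footprint of uniform height.
#'
#' @param plan_shape plan footprint; the physical slide tapers at the ports,
#'   modeled by default as an ellipse.
#' @return A `channel_geometry`.
#' @export
ibidi_slide_geometry <- function(plan_shape = c("ellipse", "rectangle")) {
  channel_geometry(height = 0.4e-3, width = 5e-3, length = 50e-3,
                   inlet_diameter = 3.5e-3, plan_shape = match.arg(plan_shape))
}

#' Fluid properties
#'
#' @param dynamic_viscosity dynamic viscosity in Pa s. Default is water at
#'   room temperature (1.0e-3 Pa s), the usual approximation for culture
#'   medium.
#' @param density density in kg/m^3 (default 1000, water).
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(dynamic_viscosity = 1.0e-3, density = 1000) {
  if (!is.numeric(dynamic_viscosity) || dynamic_viscosity <= 0 ||
      !is.numeric(density) || density <= 0) {
    stop("fluid properties must be positive numbers", call. = FALSE)
  }
  structure(list(dynamic_viscosity = dynamic_viscosity, density = density),
            class = "fluid_properties")
}

#' Flow condition
#'
#' A volumetric flow rate plus the fluid driven through the channel. Rates
#' can be given in SI (m^3/s) or in the bench units ul/min and ml/day; they
#' are stored in SI.
#'
#' @param rate volumetric flow rate (>= 0) in `unit`.
#' @param unit one of `"m3/s"`, `"ul/min"`, `"ml/day"`.
#' @param fluid a [fluid_properties()] object.
#' @return An object of class `flow_condition` with the rate in m^3/s.
#' @examples
#' flow_condition(300, "ul/min")  # the physiological-flow operating point
#' flow_condition(1, "ml/day")    # the nutritive-flow operating point
#' @export
flow_condition <- function(rate, unit = c("m3/s", "ul/min", "ml/day"),
                           fluid = fluid_properties()) {
  unit <- match.arg(unit)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate < 0) {
    stop("`rate` must be a single non-negative number", call. = FALSE)
  }
  stopifnot(inherits(fluid, "fluid_properties"))
  structure(
    list(flow_rate = flow_rate_si(rate, unit), fluid = fluid),
    class = "flow_condition"
  )
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf(
    "<channel_geometry> %s plan, h = %.3g mm, w = %.3g mm, L = %.3g mm, inlet d = %.3g mm\n",
    x$plan_shape, x$height * 1e3, x$width * 1e3, x$length * 1e3,
    x$inlet_diameter * 1e3))
  invisible(x)
}

#' @export
print.flow_condition <- function(x, ...) {
  cat(sprintf(
    "<flow_condition> Q = %.4g m^3/s (%.4g ul/min, %.4g ml/day), mu = %.3g Pa s\n",
    x$flow_rate, m3s_to_ul_min(x$flow_rate), m3s_to_ml_day(x$flow_rate),
    x$fluid$dynamic_viscosity))
  invisible(x)
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("<fluid_properties> mu = %.3g Pa s, rho = %.3g kg/m^3\n",
              x$dynamic_viscosity, x$density))
  invisible(x)
}
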