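#' Mean inlet velocity through the cylindrical port
#'
#' The volumetric flow rate divided by the circular cross-sectional area of
#' the inlet port. At 300 ul/min through a 3.5 mm port this is 5.2e-4 m/s.
#'
#' @param condition a [flow_condition()].
#' @param geometry a [channel_geometry()].
#' @return mean inlet velocity in m/s.
#' @export
inlet_velocity <- function(condition, geometry) {
  stopifnot(inherits(condition, "flow_condition"),
            inherits(geometry, "channel_geometry"))
  area <- pi * geometry$inlet_diameter^2 / 4
  condition$flow_rate / area
}

#' Parallel-plate wall shear stress
#'
#' The infinite-parallel-plate closed form for fully developed laminar flow
#' in a wide shallow channel: tau = 6 mu Q / (w h^2). This is the standard
#' first approximation for channel slides whose width greatly exceeds their
#' height, and the analytic baseline the other solvers are compared against.
#'
#' @inheritParams inlet_velocity
#' @return wall shear stress in Pa (use [pa_to_dyn_cm2()] for dyn/cm^2).
#' @examples
#' g <- ibidi_slide_geometry()
#' pa_to_dyn_cm2(plate_shear(flow_condition(300, "ul/min"), g))  # ~0.375
#' @export
plate_shear <- function(condition, geometry) {
  stopifnot(inherits(condition, "flow_condition"),
            inherits(geometry, "channel_geometry"))
  mu <- condition$fluid$dynamic_viscosity
  6 * mu * condition$flow_rate / (geometry$width * geometry$height^2)
}

# numerically stable sech: 1/cosh(x) = 2 e^-x / (1 + e^-2x), safe for large x
sech_stable <- function(x) {
  e <- exp(-abs(x))
  2 * e / (1 + e * e)
}

# series factors for fully developed laminar flow in a rectangular duct of
# width w >= height h, evaluated over the first n_terms odd harmonics:
#   S: bottom-wall centerline shear factor, tau = (G h / 2) * S
#   F: flow-rate factor, Q = G w h^3 / (12 mu) * F
rect_duct_factors <- function(w, h, n_terms) {
  n <- seq(1, by = 2, length.out = n_terms)
  a <- n * pi * w / (2 * h)
  S <- 1 - (8 / pi^2) * sum(sech_stable(a) / n^2)
  F <- 1 - (192 / pi^5) * (h / w) * sum(tanh(a) / n^5)
  list(S = S, F = F)
}

#' Rectangular-duct wall shear stress (exact Fourier series)
#'
#' Exact solution of fully developed laminar flow in a rectangular duct,
#' evaluated as the shear stress on the bottom wall at the lateral centerline
#' for a prescribed volumetric flow rate. For finite aspect ratio the side
#' walls steal flow area, so at fixed Q the centerline shear exceeds the
#' parallel-plate value; as width/height grows the two converge.
#'
#' @inheritParams inlet_velocity
#' @param n_terms number of odd series harmonics (>= 1; default 101, far past
#'   convergence for all practical aspect ratios).
#' @return wall shear stress in Pa.
#' @seealso [fd_duct_shear()] for an independent finite-difference
#'   cross-check of the same quantity.
#' @export
rect_duct_shear <- function(condition, geometry, n_terms = 101) {
  stopifnot(inherits(condition, "flow_condition"),
            inherits(geometry, "channel_geometry"))
  if (!is.numeric(n_terms) || length(n_terms) != 1L || n_terms < 1) {
    stop("invalid parameter: `n_terms` must be >= 1", call. = FALSE)
  }
  if (geometry$width < geometry$height) {
    stop("invalid geometry: duct solution expects width >= height",
         call. = FALSE)
  }
  fac <- rect_duct_factors(geometry$width, geometry$height, as.integer(n_terms))
  plate_shear(condition, geometry) * fac$S / fac$F
}

# duct/plate shear correction factor at local aspect ratio w/h
duct_correction <- function(w, h, n_terms = 101) {
  fac <- rect_duct_factors(w, h, n_terms)
  fac$S / fac$F
}

#' Shear-stress profile along the channel centerline
#'
#' Wall shear stress at the bottom surface along the axial centerline, the
#' line where attached cells experience flow. The channel is treated in the
#' lubrication (Hele-Shaw) limit: at each axial station the local plan width
#' `w(x)` carries the full flow rate, so the local shear is
#' `6 mu Q / (w(x) h^2)`, optionally multiplied by the rectangular-duct
#' finite-width correction at the local aspect ratio. For a rectangular plan
#' the profile is constant; for an elliptical plan the width is maximal at
#' mid-length, so the shear has its minimum there.
#'
#' @inheritParams inlet_velocity
#' @param n_positions number of axial stations (>= 3).
#' @param clip fraction of the length clipped at each end (default 0.05,
#'   i.e. the central 90%), excluding the degenerate zero-width tips of an
#'   elliptical plan and the port regions where the flow is not developed.
#' @param duct_correction apply the rectangular-duct finite-width correction
#'   at the local aspect ratio (default `FALSE`, pure lubrication).
#' @return An object of class `shear_profile`: axial positions (m), shear
#'   (Pa), and `summary`, the shear at exactly mid-length.
#' @examples
#' prof <- plan_shear_profile(flow_condition(300, "ul/min"),
#'                            ibidi_slide_geometry())
#' pa_to_dyn_cm2(prof$summary)
#' @export
plan_shear_profile <- function(condition, geometry, n_positions = 101,
                               clip = 0.05, duct_correction = FALSE) {
  stopifnot(inherits(condition, "flow_condition"),
            inherits(geometry, "channel_geometry"))
  if (!is.numeric(n_positions) || length(n_positions) != 1L || n_positions < 3) {
    stop("invalid parameter: `n_positions` must be >= 3", call. = FALSE)
  }
  L <- geometry$length
  x <- seq(clip * L, (1 - clip) * L, length.out = as.integer(n_positions))
  tau_at <- function(x) {
    wx <- local_width(geometry, x)
    ok <- wx > 0
    tau <- rep(NA_real_, length(x))
    mu <- condition$fluid$dynamic_viscosity
    tau[ok] <- 6 * mu * condition$flow_rate / (wx[ok] * geometry$height^2)
    if (duct_correction) {
      tau[ok] <- tau[ok] * vapply(wx[ok], duct_correction_capped,
                                  numeric(1), h = geometry$height)
    }
    tau
  }
  tau <- tau_at(x)
  keep <- !is.na(tau)
  structure(
    list(axial_positions = x[keep], shear = tau[keep],
         summary = tau_at(L / 2), geometry = geometry,
         flow_rate = condition$flow_rate,
         duct_correction = duct_correction),
    class = "shear_profile"
  )
}

# local plan width at axial position x
local_width <- function(geometry, x) {
  L <- geometry$length
  if (geometry$plan_shape == "rectangle") {
    w <- rep(geometry$width, length(x))
    w[x < 0 | x > L] <- 0
    w
  } else {
    t <- (x - L / 2) / (L / 2)
    s <- pmax(0, 1 - t^2)
    geometry$width * sqrt(s)
  }
}

# duct correction, falling back to 1 where the local width drops below the
# height (near elliptical tips, outside the duct solution's validity)
duct_correction_capped <- function(w, h) {
  if (w < h) return(1)
  duct_correction(w, h)
}

#' @export
print.shear_profile <- function(x, ...) {
  cat(sprintf(
    "<shear_profile> %d positions over [%.3g, %.3g] mm; mid-length shear %.4g Pa (%.4g dyn/cm^2)\n",
    length(x$axial_positions), min(x$axial_positions) * 1e3,
    max(x$axial_positions) * 1e3, x$summary, pa_to_dyn_cm2(x$summary)))
  invisible(x)
}

#' @export
as.data.frame.shear_profile <- function(x, ...) {
  data.frame(position_m = x$axial_positions,
             shear_pa = x$shear,
             shear_dyn_cm2 = pa_to_dyn_cm2(x$shear))
}

#' @export
plot.shear_profile <- function(x, ...) {
  plot(x$axial_positions * 1e3, pa_to_dyn_cm2(x$shear), type = "l",
       xlab = "axial position (mm)", ylab = "wall shear stress (dyn/cm^2)",
       ...)
  graphics::abline(v = x$geometry$length / 2 * 1e3, lty = 3)
  invisible(x)
}

#' Flow rate producing a target wall shear stress
#'
#' Inverts the (strictly increasing, linear) shear-vs-flow-rate map of the
#' chosen model by bisection. Use this to pick an operating point: e.g. a
#' target of 0.35 dyn/cm^2 under the parallel-plate model of the 0.4 x 5 mm
#' slide gives 280 ul/min.
#'
#' @param target_shear target wall shear stress in Pa (> 0).
#' @param geometry a [channel_geometry()].
#' @param fluid a [fluid_properties()].
#' @param model `"plate"` or `"rect_duct"` shear model.
#' @param tol relative tolerance on the recovered shear (default 1e-9).
#' @return volumetric flow rate in m^3/s.
#' @examples
#' q <- flow_rate_for_shear(dyn_cm2_to_pa(0.35), ibidi_slide_geometry())
#' m3s_to_ul_min(q)  # 280
#' @export
flow_rate_for_shear <- function(target_shear, geometry,
                                fluid = fluid_properties(),
                                model = c("plate", "rect_duct"),
                                tol = 1e-9) {
  model <- match.arg(model)
  stopifnot(inherits(geometry, "channel_geometry"))
  if (!is.numeric(target_shear) || length(target_shear) != 1L ||
      !is.finite(target_shear) || target_shear <= 0) {
    stop("invalid parameter: `target_shear` must be a single positive number",
         call. = FALSE)
  }
  shear_of <- function(q) {
    cond <- flow_condition(q, "m3/s", fluid)
    switch(model,
           plate = plate_shear(cond, geometry),
           rect_duct = rect_duct_shear(cond, geometry))
  }
  # analytic plate estimate brackets the root: tau is linear in Q
  q_est <- target_shear * geometry$width * geometry$height^2 /
    (6 * fluid$dynamic_viscosity)
  lo <- 0
  hi <- 10 * q_est
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    tau <- shear_of(mid)
    if (abs(tau - target_shear) / target_shear < tol) return(mid)
    if (tau < target_shear) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
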