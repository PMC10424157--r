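#' Unit conversions for flow rate and shear stress
#'
#' Internal computations are in SI units (m, m^3/s, Pa). These helpers convert
#' between SI and the bench units used at the interface: microlitres per
#' minute and millilitres per day for volumetric flow rate, and dyn/cm^2 for
#' wall shear stress (1 dyn/cm^2 = 0.1 Pa).
#'
#' @param x numeric vector of values to convert.
#' @return numeric vector of converted values.
#' @name units
NULL

#' @rdname units
#' @export
ul_min_to_m3s <- function(x) x * 1e-9 / 60

#' @rdname units
#' @export
m3s_to_ul_min <- function(x) x * 60 / 1e-9

#' @rdname units
#' @export
ml_day_to_m3s <- function(x) x * 1e-6 / 86400

#' @rdname units
#' @export
m3s_to_ml_day <- function(x) x * 86400 / 1e-6

#' @rdname units
#' @export
pa_to_dyn_cm2 <- function(x) x * 10

#' @rdname units
#' @export
dyn_cm2_to_pa <- function(x) x / 10

# normalize a rate given in `unit` to m^3/s
flow_rate_si <- function(rate, unit = c("m3/s", "ul/min", "ml/day")) {
  unit <- match.arg(unit)
  switch(unit,
    "m3/s"   = rate,
    "ul/min" = ul_min_to_m3s(rate),
    "ml/day" = ml_day_to_m3s(rate)
  )
}
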