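#' Physical constants for the evapotranspiration model
#'
#' Bundles the fixed physical constants used throughout the package.  The
#' defaults are the values the sensitivity analysis is defined at: the
#' psychrometric constant and the gas constant of air follow the fixed-value
#' table of the analysis (`R_air = 288.0` J kg^-1 K^-1 as printed there,
#' although 287 is the textbook value -- override it if you prefer), and the
#' latent heat of vaporization is held at 2.5e6 J/kg, the value consistent
#' with the published uWUE unit conversions.
#'
#' @param c_p specific heat of air at constant pressure, J kg^-1 K^-1.
#' @param R universal gas constant, J mol^-1 K^-1.
#' @param R_air gas constant of dry air, J kg^-1 K^-1.
#' @param gamma psychrometric constant, Pa/K.
#' @param M_C molar mass of carbon, g/mol.
#' @param L_v latent heat of vaporization of water, J/kg.
#' @return An object of class `physical_constants`: a named list of the six
#'   constants.
#' @examples
#' physical_constants()
#' physical_constants(R_air = 287) # conventional dry-air gas constant
#' @export
physical_constants <- function(c_p = 1004.0, R = 8.314, R_air = 288.0,
                               gamma = 64.50, M_C = 12.011, L_v = 2.5e6) {
  x <- list(c_p = c_p, R = R, R_air = R_air, gamma = gamma,
            M_C = M_C, L_v = L_v)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("physical constant '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  structure(x, class = "physical_constants")
}

#' @export
print.physical_constants <- function(x, ...) {
  cat("Physical constants:\n")
  cat(sprintf("  c_p   = %g J/kg/K   (specific heat of air)\n", x$c_p))
  cat(sprintf("  R     = %g J/mol/K  (universal gas constant)\n", x$R))
  cat(sprintf("  R_air = %g J/kg/K   (gas constant of air)\n", x$R_air))
  cat(sprintf("  gamma = %g Pa/K     (psychrometric constant)\n", x$gamma))
  cat(sprintf("  M_C   = %g g/mol    (molar mass of carbon)\n", x$M_C))
  cat(sprintf("  L_v   = %g J/kg     (latent heat of vaporization)\n", x$L_v))
  invisible(x)
}

#' Read constant overrides from a plain-text config file
#'
#' The file holds `key = value` lines (`#` comments and blank lines are
#' ignored).  Recognized keys are the fields of [physical_constants()]; any
#' key given overrides the default, everything else keeps its default.
#'
#' @param path path to the config file.
#' @return A `physical_constants` object.
#' @export
read_constants <- function(path) {
  kv <- read_config(path)
  known <- names(formals(physical_constants))
  use <- kv[names(kv) %in% known]
  do.call(physical_constants, use)
}

# Parse "key = value" lines into a named list of numerics.
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("malformed config line (expected 'key = value'): ", ln,
           call. = FALSE)
    key <- trimws(parts[1])
    val <- suppressWarnings(as.numeric(trimws(parts[2])))
    if (is.na(val))
      stop("non-numeric value for config key '", key, "'", call. = FALSE)
    out[[key]] <- val
  }
  out
}

# Name of the saturation vapor pressure formula; recorded in CSV metadata so
# an alternate formulation can be swapped in and traced.
ESAT_FORMULA <- "Tetens"

.T_MIN <- 230
.T_MAX <- 340

check_temperature <- function(T) {
  if (!is.numeric(T) || any(!is.finite(T)))
    stop("temperature must be finite numeric (K)", call. = FALSE)
  if (any(T <= .T_MIN | T >= .T_MAX))
    stop("temperature out of range: esat/delta_slope are defined for ",
         .T_MIN, " K < T < ", .T_MAX, " K (did you pass degrees C?)",
         call. = FALSE)
  invisible(T)
}

#' Saturation vapor pressure (Tetens formula)
#'
#' `esat()` gives the saturation vapor pressure over liquid water and
#' `delta_slope()` its analytic temperature derivative
#' \eqn{\Delta = de_s/dT}, the Clausius-Clapeyron slope that enters the
#' Penman-Monteith equation.  Both use the Tetens form
#' \deqn{e_s(T) = 610.78 \exp\!\left(17.27\,\frac{T - 273.15}{T - 35.85}\right) \mathrm{Pa},}
#' smooth over the whole atmospheric range so that the derivative is exact
#' rather than a finite difference.
#'
#' @param T air temperature, K (vectorized).  Valid range 230 K < T < 340 K.
#' @return `esat`: saturation vapor pressure, Pa.  `delta_slope`: Pa/K.
#' @examples
#' esat(293.15)          # ~2338 Pa at 20 C
#' delta_slope(293.15)   # ~145 Pa/K
#' @export
esat <- function(T) {
  check_temperature(T)
  610.78 * exp(17.27 * (T - 273.15) / (T - 35.85))
}

#' @rdname esat
#' @export
delta_slope <- function(T) {
  check_temperature(T)
  # d/dT of the Tetens exponent: 17.27 * (273.15 - 35.85) / (T - 35.85)^2
  esat(T) * 17.27 * (273.15 - 35.85) / (T - 35.85)^2
}

#' Density of air from the ideal gas law
#'
#' @param P air pressure, Pa.
#' @param T air temperature, K.
#' @param consts a [physical_constants()] object (supplies `R_air`).
#' @return air density, kg/m^3.
#' @export
air_density <- function(P, T, consts = physical_constants()) {
  if (any(!is.finite(P)) || any(P <= 0)) stop("P must be positive", call. = FALSE)
  if (any(!is.finite(T)) || any(T <= 0)) stop("T must be positive", call. = FALSE)
  P / (consts$R_air * T)
}

#' Vapor pressure deficit from relative humidity
#'
#' @param T air temperature, K.
#' @param RH relative humidity as a fraction in \[0, 1\].
#' @return VPD = esat(T) * (1 - RH), Pa.
#' @export
vpd_from_rh <- function(T, RH) {
  if (any(!is.finite(RH)) || any(RH < 0) || any(RH > 1))
    stop("RH must be a fraction in [0, 1]", call. = FALSE)
  esat(T) * (1 - RH)
}

#' Convert temperature from degrees Celsius to Kelvin
#' @param T_C temperature, degrees C.
#' @return temperature, K.
#' @export
celsius_to_kelvin <- function(T_C) T_C + 273.15

#' Unit conversions for the plant parameters
#'
#' `convert_g1()` converts the Medlyn slope parameter from kPa^1/2 (the unit
#' used in the stomatal-conductance literature) to Pa^1/2 (the internal
#' unit), a factor of sqrt(1000).  `convert_uwue()` converts underlying
#' water use efficiency from g C hPa^1/2 kg^-1 H2O (the unit of the
#' eddy-covariance literature) to umol C Pa^1/2 J^-1: grams of carbon become
#' micromoles via the molar mass of carbon, kilograms of water become joules
#' via the latent heat of vaporization, and hPa^1/2 becomes Pa^1/2 via a
#' factor of 10.
#'
#' @param value parameter value in the literature unit (vectorized, > 0).
#' @param consts a [physical_constants()] object (supplies `M_C` and `L_v`
#'   for `convert_uwue`).
#' @return the value in internal units (Pa^1/2, or umol C Pa^1/2 J^-1).
#' @examples
#' convert_g1(4.00)     # 126.49 Pa^1/2, the median literature slope
#' convert_uwue(9.52)   # 3.17 umol C Pa^1/2 / J, the median uWUE
#' @export
convert_g1 <- function(value) {
  if (any(!is.finite(value)) || any(value <= 0))
    stop("g1 must be positive", call. = FALSE)
  value * sqrt(1000)
}

#' @rdname convert_g1
#' @export
convert_uwue <- function(value, consts = physical_constants()) {
  if (any(!is.finite(value)) || any(value <= 0))
    stop("uWUE must be positive", call. = FALSE)
  value * (1e6 / consts$M_C) * (1 / consts$L_v) * 10
}

#' Convert latent heat flux to a water-depth evaporation rate
#' @param ET latent heat flux, W/m^2.
#' @param consts a [physical_constants()] object.
#' @return equivalent evaporation, mm/day.
#' @export
et_mm_day <- function(ET, consts = physical_constants()) {
  ET / consts$L_v * 86400
}
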