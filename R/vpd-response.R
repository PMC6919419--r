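#' Sign term of the ET sensitivity to VPD
#'
#' The dimensionless factor of \eqn{\partial ET/\partial VPD} whose sign
#' decides whether evapotranspiration rises or falls with atmospheric
#' demand:
#' \deqn{\frac{c_p}{R_{air}} - \frac{\gamma c_a}{1.6\,R\,uWUE}\,
#'       \frac{2 g_1 + \sqrt{VPD}}{2 (g_1 + \sqrt{VPD})^2}.}
#' The first piece is the direct atmospheric-demand contribution; the
#' second is the stomatal-closure contribution, which weakens as VPD grows
#' (the modulating ratio is decreasing in VPD), so the term is increasing
#' in VPD, `g1`, and `uWUE`.  It is finite at `VPD = 0`, where the ratio
#' equals \eqn{1/(2 g_1)} times 2, i.e. \eqn{1/g_1}.
#'
#' @param VPD vapor pressure deficit, Pa (vectorized, >= 0).
#' @param plant a [plant_params()] object.
#' @param consts a [physical_constants()] object.
#' @param c_a CO2 mole fraction, umol/mol.
#' @return dimensionless sign term (vector).
#' @export
sign_term <- function(VPD, plant, consts = physical_constants(), c_a = 400) {
  stopifnot(inherits(plant, "plant_params"))
  if (any(VPD < 0)) stop("VPD must be nonnegative", call. = FALSE)
  s <- sqrt(VPD)
  consts$c_p / consts$R_air -
    (consts$gamma * c_a / (1.6 * consts$R * plant$uWUE)) *
      (2 * plant$g1 + s) / (2 * (plant$g1 + s)^2)
}

#' Scaling term of the ET sensitivity to VPD
#'
#' The strictly positive environmental prefactor
#' \eqn{g_a P / (T (\Delta + \gamma))} that sets the magnitude (but never
#' the sign) of the ET response to VPD.  It grows with aerodynamic
#' conductance and shrinks with temperature, both directly (1/T) and
#' through the Clausius-Clapeyron slope \eqn{\Delta(T)}: cold, well-mixed
#' conditions amplify the response.
#'
#' @param forcing a [forcing()] object (uses `T`, `P`, `g_a`).
#' @param consts a [physical_constants()] object.
#' @return scaling term, (W m^-2 Pa^-1) per unit of the dimensionless sign
#'   term.
#' @export
scaling_term <- function(forcing, consts = physical_constants()) {
  stopifnot(inherits(forcing, "forcing"))
  Delta <- delta_slope(forcing$T)
  forcing$g_a * forcing$P / (forcing$T * (Delta + consts$gamma))
}

#' Analytic sensitivity of ET to VPD
#'
#' The partial derivative of the explicit Penman-Monteith ET with respect
#' to VPD at fixed temperature (so \eqn{\Delta} and \eqn{e_s} are held
#' constant and VPD varies through relative humidity), factored as the
#' product of [scaling_term()] and [sign_term()].  Net radiation enters ET
#' only through the VPD-independent \eqn{\Delta R_{net}} term, so the
#' derivative is independent of `R_net`.
#'
#' @param forcing a [forcing()] object.
#' @param plant a [plant_params()] object.
#' @param consts a [physical_constants()] object.
#' @return An object of class `response_decomposition`: a data frame with
#'   columns `VPD`, `sign_term`, `scaling_term`, `dET_dVPD` (W m^-2 Pa^-1),
#'   and `regime` (`"conservative"` where the derivative is negative,
#'   `"intensive"` where positive).
#' @examples
#' f <- forcing(T = 293.15, VPD = seq(100, 4000, by = 100),
#'              R_net = 400, g_a = 0.035)
#' p <- plant_params(g1 = convert_g1(4), uWUE = convert_uwue(9.52))
#' head(det_dvpd(f, p))
#' @export
det_dvpd <- function(forcing, plant, consts = physical_constants()) {
  stopifnot(inherits(forcing, "forcing"), inherits(plant, "plant_params"))
  sg <- sign_term(forcing$VPD, plant, consts, c_a = forcing$c_a)
  sc <- scaling_term(forcing, consts)
  d <- sg * sc
  out <- data.frame(VPD = forcing$VPD, sign_term = sg, scaling_term = sc,
                    dET_dVPD = d,
                    regime = ifelse(sg < 0, "conservative", "intensive"),
                    stringsAsFactors = FALSE)
  class(out) <- c("response_decomposition", "data.frame")
  out
}

#' @export
print.response_decomposition <- function(x, ...) {
  cat("ET-VPD response decomposition (dET/dVPD = sign * scaling):\n")
  NextMethod()
  invisible(x)
}

#' Critical VPD where the ET response changes sign
#'
#' Finds the root of [sign_term()] in VPD, the atmospheric demand at which
#' \eqn{\partial ET/\partial VPD = 0} -- under the optimal square-root
#' stomatal model this is the local minimum of the concave-up ET-VPD curve.
#' A sign change is bracketed by scanning 64 log-spaced points over the
#' search interval and refined with Brent's method; the sign term is
#' monotone increasing in VPD, so the root is unique when it exists.
#'
#' @param plant a [plant_params()] object.
#' @param consts a [physical_constants()] object.
#' @param c_a CO2 mole fraction, umol/mol.
#' @param interval search interval in VPD, Pa (positive, increasing).
#' @return An object of class `critical_vpd`: list with `vpd_crit` (Pa, or
#'   `NA` when no root), `status` (`"root"` or `"none"`), and `side`
#'   (`"everywhere_positive"` or `"everywhere_negative"` when no root,
#'   `NA` otherwise).
#' @examples
#' p <- plant_params(g1 = convert_g1(4), uWUE = convert_uwue(9.52))
#' critical_vpd(p) # ~993 Pa: ET falls with VPD below ~1 kPa, rises above
#' @export
critical_vpd <- function(plant, consts = physical_constants(), c_a = 400,
                         interval = c(1e-2, 1e4)) {
  stopifnot(inherits(plant, "plant_params"))
  if (length(interval) != 2L || any(!is.finite(interval)) ||
      interval[1] <= 0 || interval[2] <= interval[1])
    stop("interval must be positive and increasing", call. = FALSE)
  grid <- exp(seq(log(interval[1]), log(interval[2]), length.out = 64))
  vals <- sign_term(grid, plant, consts, c_a)
  out <- list(vpd_crit = NA_real_, status = "none", side = NA_character_)
  class(out) <- "critical_vpd"
  ix <- which(vals[-1] * vals[-length(vals)] <= 0)
  if (length(ix) == 0) {
    out$side <- if (all(vals > 0)) "everywhere_positive" else "everywhere_negative"
    return(out)
  }
  root <- stats::uniroot(function(v) sign_term(v, plant, consts, c_a),
                         lower = grid[ix[1]], upper = grid[ix[1] + 1],
                         tol = 1e-12)$root
  out$vpd_crit <- root
  out$status <- "root"
  out
}

#' @export
print.critical_vpd <- function(x, ...) {
  if (x$status == "root")
    cat(sprintf("Critical VPD: %.2f Pa (dET/dVPD < 0 below, > 0 above)\n",
                x$vpd_crit))
  else
    cat("Critical VPD: none on the search interval; sign term",
        sub("_", " ", x$side), "\n")
  invisible(x)
}

#' Classify the water-use regime over a VPD interval
#'
#' Labels an ecosystem water-conservative (ET decreases with VPD throughout
#' the interval), water-intensive (ET increases throughout), or mixed, in
#' which case the critical VPD separating the two behaviors is returned.
#'
#' @param plant a [plant_params()] object.
#' @param vpd_range interval of VPD, Pa (length 2, nonnegative, increasing).
#' @param consts a [physical_constants()] object.
#' @param c_a CO2 mole fraction, umol/mol.
#' @return list with `regime` (`"water_conservative"`, `"water_intensive"`,
#'   or `"mixed"`) and `vpd_crit` (Pa; `NA` unless mixed).
#' @export
classify_regime <- function(plant, vpd_range, consts = physical_constants(),
                            c_a = 400) {
  stopifnot(inherits(plant, "plant_params"))
  if (length(vpd_range) != 2L || any(vpd_range < 0) ||
      vpd_range[2] <= vpd_range[1])
    stop("vpd_range must be a nonnegative increasing interval", call. = FALSE)
  lo <- sign_term(vpd_range[1], plant, consts, c_a)
  hi <- sign_term(vpd_range[2], plant, consts, c_a)
  # sign term is monotone increasing in VPD, so the endpoints decide
  if (lo >= 0 && hi >= 0)
    return(list(regime = "water_intensive", vpd_crit = NA_real_))
  if (lo <= 0 && hi <= 0)
    return(list(regime = "water_conservative", vpd_crit = NA_real_))
  cv <- critical_vpd(plant, consts, c_a,
                     interval = c(max(vpd_range[1], 1e-6), vpd_range[2]))
  list(regime = "mixed", vpd_crit = cv$vpd_crit)
}
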