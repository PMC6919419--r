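#' Atmospheric forcing for the evapotranspiration model
#'
#' Collects the environmental state at which the model is evaluated.  Give
#' exactly one of `VPD` or `RH`; the other is derived from the saturation
#' vapor pressure at `T`.  All fields may be vectors (recycled to a common
#' length), so a forcing object can hold a VPD grid or a half-hourly time
#' series.
#'
#' @param T air temperature, K.
#' @param P air pressure, Pa.
#' @param VPD vapor pressure deficit, Pa (mutually exclusive with `RH`).
#' @param RH relative humidity, fraction in \[0, 1\] (mutually exclusive
#'   with `VPD`).
#' @param R_net net radiation minus ground heat flux, W/m^2.
#' @param g_a aerodynamic conductance, m/s.
#' @param c_a ambient CO2 mole fraction, umol CO2 / mol air.
#' @param check_saturation enforce `VPD <= esat(T)`?  The default `TRUE` is
#'   the physical constraint on observed air.  Sensitivity sweeps evaluate
#'   the analytic ET response on a fixed VPD grid across all temperatures,
#'   where VPD acts as an abstract coordinate that can exceed the cold-air
#'   saturation limit; they pass `FALSE`, and the stored `RH` then goes
#'   negative to keep the identity `VPD = esat(T) * (1 - RH)` exact.
#' @return An object of class `forcing`: a list with fields `T`, `P`, `VPD`,
#'   `RH`, `R_net`, `g_a`, `c_a`, all the same length.
#' @examples
#' forcing(T = 293.15, VPD = 1000, R_net = 400, g_a = 0.035)
#' forcing(T = 293.15, RH = 0.5, R_net = 400, g_a = 0.035)
#' @export
forcing <- function(T, P = 1e5, VPD = NULL, RH = NULL,
                    R_net = 400, g_a = 0.035, c_a = 400,
                    check_saturation = TRUE) {
  check_temperature(T)
  if (is.null(VPD) == is.null(RH))
    stop("give exactly one of VPD or RH", call. = FALSE)
  if (is.null(VPD)) {
    if (any(!is.finite(RH)) || any(RH < 0) || any(RH > 1))
      stop("RH must be a fraction in [0, 1]", call. = FALSE)
    VPD <- vpd_from_rh(T, RH)
  } else {
    if (any(!is.finite(VPD)) || any(VPD < 0))
      stop("VPD must be nonnegative (Pa)", call. = FALSE)
    es <- esat(T)
    if (check_saturation && any(VPD > es * (1 + 1e-12)))
      stop("VPD exceeds saturation vapor pressure esat(T)", call. = FALSE)
    RH <- 1 - VPD / es
  }
  if (any(!is.finite(P)) || any(P <= 0)) stop("P must be positive", call. = FALSE)
  if (any(!is.finite(g_a)) || any(g_a <= 0)) stop("g_a must be positive", call. = FALSE)
  if (any(!is.finite(c_a)) || any(c_a <= 0)) stop("c_a must be positive", call. = FALSE)
  if (any(!is.finite(R_net))) stop("R_net must be finite", call. = FALSE)
  n <- max(length(T), length(P), length(VPD), length(RH),
           length(R_net), length(g_a), length(c_a))
  structure(list(T = rep_len(T, n), P = rep_len(P, n),
                 VPD = rep_len(VPD, n), RH = rep_len(RH, n),
                 R_net = rep_len(R_net, n), g_a = rep_len(g_a, n),
                 c_a = rep_len(c_a, n)),
            class = "forcing")
}

#' @export
print.forcing <- function(x, ...) {
  n <- length(x$T)
  cat("Atmospheric forcing (", n, if (n == 1) " record):\n" else " records):\n",
      sep = "")
  show <- function(v) if (n == 1) format(v) else
    paste0("[", format(min(v)), ", ", format(max(v)), "]")
  cat("  T     ", show(x$T), "K\n")
  cat("  P     ", show(x$P), "Pa\n")
  cat("  VPD   ", show(x$VPD), "Pa\n")
  cat("  R_net ", show(x$R_net), "W/m^2\n")
  cat("  g_a   ", show(x$g_a), "m/s\n")
  cat("  c_a   ", show(x$c_a), "umol/mol\n")
  invisible(x)
}

#' Plant parameters of the optimal (square-root) stomatal model
#'
#' The two ecosystem-scale constants of the explicit ET expression: the
#' Medlyn slope `g1` (how willingly stomata trade water for carbon; larger
#' means stomata stay more open per unit carbon gain) and the underlying
#' water use efficiency `uWUE = GPP * sqrt(VPD) / ET`, approximately
#' conserved within a plant functional type over the growing season.
#'
#' @param g1 Medlyn slope parameter, Pa^1/2.  Use [convert_g1()] for values
#'   quoted in kPa^1/2.
#' @param uWUE underlying water use efficiency, umol C Pa^1/2 J^-1.  Use
#'   [convert_uwue()] for values quoted in g C hPa^1/2 kg^-1 H2O.
#' @return An object of class `plant_params`.
#' @examples
#' plant_params(g1 = convert_g1(4), uWUE = convert_uwue(9.52))
#' @export
plant_params <- function(g1, uWUE) {
  if (!is.numeric(g1) || length(g1) != 1L || !is.finite(g1) || g1 <= 0)
    stop("g1 must be a single positive number (Pa^1/2)", call. = FALSE)
  if (!is.numeric(uWUE) || length(uWUE) != 1L || !is.finite(uWUE) || uWUE <= 0)
    stop("uWUE must be a single positive number", call. = FALSE)
  structure(list(g1 = g1, uWUE = uWUE), class = "plant_params")
}

#' @export
print.plant_params <- function(x, ...) {
  cat("Plant parameters: g1 =", format(x$g1), "Pa^1/2, uWUE =",
      format(x$uWUE), "umol C Pa^1/2 / J\n")
  invisible(x)
}

#' Penman-Monteith latent heat flux
#'
#' The classical combination equation for evapotranspiration,
#' \deqn{ET = \frac{\Delta R_{net} + g_a \rho_a c_p VPD}
#'                 {\Delta + \gamma (1 + g_a / g_s)},}
#' with ET in energy units (W/m^2).  Pass `g_s = Inf` for the
#' infinite-conductance (wet-surface) limit, in which the denominator
#' reduces to \eqn{\Delta + \gamma}.
#'
#' @param forcing a [forcing()] object.
#' @param g_s stomatal (canopy) conductance, m/s; positive, `Inf` allowed.
#' @param consts a [physical_constants()] object.
#' @return latent heat flux ET, W/m^2 (vector, one per forcing record).
#' @export
penman_monteith <- function(forcing, g_s, consts = physical_constants()) {
  stopifnot(inherits(forcing, "forcing"))
  if (any(is.na(g_s)) || any(g_s <= 0))
    stop("g_s must be positive (m/s); got a nonpositive value", call. = FALSE)
  Delta <- delta_slope(forcing$T)
  rho_a <- air_density(forcing$P, forcing$T, consts)
  ratio <- ifelse(is.infinite(g_s), 0, forcing$g_a / g_s)
  (Delta * forcing$R_net + forcing$g_a * rho_a * consts$c_p * forcing$VPD) /
    (Delta + consts$gamma * (1 + ratio))
}

#' Medlyn unified stomatal conductance at ecosystem scale
#'
#' \deqn{g_s = \frac{R\,T}{P}\,1.6\left(1 + \frac{g_1}{\sqrt{VPD}}\right)
#'             \frac{GPP}{c_a},}
#' the optimal-photosynthesis conductance model expressed in m/s (the
#' leading \eqn{RT/P} converts from molar units), with the 1.6 factor for
#' the diffusivity ratio of water vapor to CO2.
#'
#' @param GPP gross primary production, umol C m^-2 s^-1 (nonnegative).
#' @param forcing a [forcing()] object; `VPD` must be strictly positive.
#' @param g1 Medlyn slope, Pa^1/2.
#' @param consts a [physical_constants()] object.
#' @return stomatal conductance, m/s.
#' @export
medlyn_gs <- function(GPP, forcing, g1, consts = physical_constants()) {
  stopifnot(inherits(forcing, "forcing"))
  if (any(GPP < 0)) stop("GPP must be nonnegative", call. = FALSE)
  if (any(forcing$VPD <= 0))
    stop("VPD must be strictly positive (1/sqrt(VPD) is singular at 0)",
         call. = FALSE)
  (consts$R * forcing$T / forcing$P) * 1.6 *
    (1 + g1 / sqrt(forcing$VPD)) * GPP / forcing$c_a
}

#' Stomatal conductance closed with underlying water use efficiency
#'
#' Substituting \eqn{GPP = uWUE \cdot ET / \sqrt{VPD}} into the Medlyn model
#' removes the GPP dependence:
#' \deqn{g_s = \frac{R\,T}{P}\,1.6\left(1 + \frac{g_1}{\sqrt{VPD}}\right)
#'             \frac{uWUE \cdot ET}{c_a \sqrt{VPD}}.}
#' A nonpositive `ET` returns a nonpositive conductance with an
#' `"unphysical_et"` flag attribute rather than an error, so that parameter
#' sweeps remain smooth; the underlying theory is asserted for
#' growing-season conditions with ET > 0.
#'
#' @param ET latent heat flux, W/m^2.
#' @param forcing a [forcing()] object; `VPD` must be strictly positive.
#' @param plant a [plant_params()] object.
#' @param consts a [physical_constants()] object.
#' @return stomatal conductance, m/s, with attribute `flags` (character
#'   vector, empty when all inputs are physical).
#' @export
gs_closure <- function(ET, forcing, plant, consts = physical_constants()) {
  stopifnot(inherits(forcing, "forcing"), inherits(plant, "plant_params"))
  if (any(forcing$VPD <= 0))
    stop("VPD must be strictly positive (1/sqrt(VPD) is singular at 0)",
         call. = FALSE)
  gs <- (consts$R * forcing$T / forcing$P) * 1.6 *
    (1 + plant$g1 / sqrt(forcing$VPD)) *
    plant$uWUE * ET / (forcing$c_a * sqrt(forcing$VPD))
  flags <- if (any(ET < 0)) "unphysical_et" else character()
  attr(gs, "flags") <- flags
  gs
}

#' Explicit Penman-Monteith evapotranspiration
#'
#' The closed-form ET obtained by substituting the uWUE-closed Medlyn
#' conductance into the Penman-Monteith equation and solving for ET:
#' \deqn{ET = \frac{\Delta R_{net} + \frac{g_a P}{T}\left(
#'   \frac{c_p\,VPD}{R_{air}} -
#'   \frac{\gamma\,c_a\,VPD}{(g_1 + \sqrt{VPD})\,1.6\,R\,uWUE}\right)}
#'   {\Delta + \gamma}.}
#' ET depends only on environmental variables and the two plant constants;
#' the implicit dependence on itself through stomatal conductance is gone.
#' At `VPD = 0` the closure term vanishes and ET equals the equilibrium
#' rate \eqn{\Delta R_{net} / (\Delta + \gamma)} (the conductance and GPP
#' limits are infinite there and are reported as `Inf` with a flag).
#'
#' @param forcing a [forcing()] object (`VPD >= 0`).
#' @param plant a [plant_params()] object.
#' @param consts a [physical_constants()] object.
#' @return An object of class `et_result`: list with fields `ET` (W/m^2),
#'   `g_s` (m/s), `GPP` (umol C m^-2 s^-1), and `flags` (character vector;
#'   `"negative_et"` when any ET <= 0, `"vpd_zero"` when any VPD = 0).
#' @examples
#' f <- forcing(T = 293.15, VPD = 1000, R_net = 400, g_a = 0.035)
#' p <- plant_params(g1 = convert_g1(4), uWUE = convert_uwue(9.52))
#' et_explicit(f, p)
#' @export
et_explicit <- function(forcing, plant, consts = physical_constants()) {
  stopifnot(inherits(forcing, "forcing"), inherits(plant, "plant_params"))
  Delta <- delta_slope(forcing$T)
  V <- forcing$VPD
  closure <- consts$c_p * V / consts$R_air -
    consts$gamma * forcing$c_a * V /
      ((plant$g1 + sqrt(V)) * 1.6 * consts$R * plant$uWUE)
  ET <- (Delta * forcing$R_net + (forcing$g_a * forcing$P / forcing$T) * closure) /
    (Delta + consts$gamma)
  GPP <- ifelse(V > 0, plant$uWUE * ET / sqrt(V), Inf)
  gs <- ifelse(V > 0,
               (consts$R * forcing$T / forcing$P) * 1.6 *
                 (1 + plant$g1 / sqrt(pmax(V, .Machine$double.xmin))) *
                 plant$uWUE * ET / (forcing$c_a * sqrt(pmax(V, .Machine$double.xmin))),
               Inf)
  flags <- character()
  if (any(ET <= 0)) flags <- c(flags, "negative_et")
  if (any(V == 0)) flags <- c(flags, "vpd_zero")
  structure(list(ET = ET, g_s = gs, GPP = GPP, flags = flags),
            class = "et_result")
}

#' @export
print.et_result <- function(x, ...) {
  n <- length(x$ET)
  if (n == 1) {
    cat(sprintf("Explicit PM evapotranspiration:\n  ET  = %.4f W/m^2  (%.3f mm/day)\n",
                x$ET, et_mm_day(x$ET)))
    cat(sprintf("  g_s = %.6g m/s\n  GPP = %.4g umol C/m^2/s\n", x$g_s, x$GPP))
  } else {
    cat("Explicit PM evapotranspiration over", n, "records:\n")
    print(summary(x$ET))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Batch evaluation of explicit ET over a forcing table
#'
#' Runs [et_explicit()] row-wise over a data frame of forcing records, the
#' CSV exchange format used by the command line interface and produced by
#' [synthetic_forcing()].
#'
#' @param df data frame with columns `T_K`, `P_Pa`, `Rnet_Wm2`, `ga_ms`,
#'   `ca_umol_mol`, and `VPD_Pa` (or `RH` if `VPD_Pa` is absent).  Extra
#'   columns (e.g. `time`) are carried through.
#' @param plant a [plant_params()] object.
#' @param consts a [physical_constants()] object.
#' @return the input data frame with appended columns `ET_Wm2`, `gs_ms`,
#'   `GPP`, and `flags` (per-record, `""` when clean).
#' @export
et_batch <- function(df, plant, consts = physical_constants()) {
  need <- c("T_K", "P_Pa", "Rnet_Wm2", "ga_ms", "ca_umol_mol")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("forcing table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  f <- if ("VPD_Pa" %in% names(df))
    forcing(T = df$T_K, P = df$P_Pa, VPD = df$VPD_Pa, R_net = df$Rnet_Wm2,
            g_a = df$ga_ms, c_a = df$ca_umol_mol)
  else if ("RH" %in% names(df))
    forcing(T = df$T_K, P = df$P_Pa, RH = df$RH, R_net = df$Rnet_Wm2,
            g_a = df$ga_ms, c_a = df$ca_umol_mol)
  else stop("forcing table needs a VPD_Pa or RH column", call. = FALSE)
  res <- et_explicit(f, plant, consts)
  df$ET_Wm2 <- res$ET
  df$gs_ms <- res$g_s
  df$GPP <- res$GPP
  df$flags <- ifelse(res$ET <= 0, "negative_et",
                     ifelse(f$VPD == 0, "vpd_zero", ""))
  df
}
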