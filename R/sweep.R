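# Literature ranges of the four varied parameters: plant parameters at the
# ~15th/50th/85th percentiles of growing-season values, T and g_a at
# percentiles of flux-tower conditions rounded to 5 C and 0.005 m/s.
SWEEP_LEVELS <- list(
  g1   = c(63.25, 126.49, 189.74),    # Pa^1/2
  uWUE = c(2.33, 3.17, 4.01),         # umol C Pa^1/2 / J
  T    = c(283.15, 293.15, 303.15),   # K (10/20/30 C)
  g_a  = c(0.015, 0.035, 0.055)       # m/s
)

SWEEP_FIXED <- list(P = 1e5, gamma = 64.50, R_air = 288.00, c_a = 400)

#' Parameter grid of the ET-response sweep
#'
#' The Cartesian product of the min/med/max levels of the four varied
#' parameters: the two plant parameters `g1` and `uWUE` (which control the
#' sign term -- 9 distinct sign-term parameterizations) and the two
#' environmental parameters `T` and `g_a` (which control the scaling term
#' -- 9 distinct scaling values), for 81 response curves in total.
#' Everything else is held at the fixed values `P = 1e5` Pa,
#' `gamma = 64.50` Pa/K, `R_air = 288.00` J/kg/K, `c_a = 400` umol/mol.
#'
#' @return An object of class `sweep_grid`: a data frame with 81 rows and
#'   columns `g1`, `uWUE`, `T`, `g_a` (lexicographic order, `g_a` fastest),
#'   with the fixed values attached as attribute `fixed`.
#' @export
build_grid <- function() {
  g <- expand.grid(g_a = SWEEP_LEVELS$g_a, T = SWEEP_LEVELS$T,
                   uWUE = SWEEP_LEVELS$uWUE, g1 = SWEEP_LEVELS$g1,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("g1", "uWUE", "T", "g_a")]
  rownames(g) <- NULL
  attr(g, "fixed") <- SWEEP_FIXED
  class(g) <- c("sweep_grid", "data.frame")
  g
}

#' @export
print.sweep_grid <- function(x, ...) {
  cat("ET-VPD sweep grid: 81 parameter combinations",
      "(9 sign x 9 scaling)\n")
  NextMethod()
  invisible(x)
}

#' ET-VPD response curves over the sweep grid
#'
#' Evaluates the analytic sensitivity decomposition on a VPD grid for every
#' parameter combination, the data behind the sweep figures.
#'
#' @param grid a [build_grid()] data frame (or any data frame with columns
#'   `g1`, `uWUE`, `T`, `g_a`).
#' @param vpd_grid positive ascending VPD values, Pa.
#' @return data frame with one row per (combination, VPD): columns `curve`
#'   (1..nrow(grid)), the four parameters, `VPD_Pa`, `sign_term`,
#'   `scaling_term`, `dET_dVPD_Wm2_per_Pa`, `regime`.
#' @export
response_curves <- function(grid = build_grid(),
                            vpd_grid = seq(10, 4000, by = 10)) {
  if (any(vpd_grid <= 0) || is.unsorted(vpd_grid, strictly = TRUE))
    stop("vpd_grid must be positive and strictly ascending", call. = FALSE)
  fixed <- attr(grid, "fixed")
  if (is.null(fixed)) fixed <- SWEEP_FIXED
  consts <- physical_constants(gamma = fixed$gamma, R_air = fixed$R_air)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- plant_params(g1 = grid$g1[i], uWUE = grid$uWUE[i])
    f <- forcing(T = grid$T[i], P = fixed$P, VPD = vpd_grid,
                 g_a = grid$g_a[i], c_a = fixed$c_a,
                 check_saturation = FALSE)
    d <- det_dvpd(f, p, consts)
    out[[i]] <- data.frame(curve = i, g1 = grid$g1[i], uWUE = grid$uWUE[i],
                           T_K = grid$T[i], ga_ms = grid$g_a[i],
                           VPD_Pa = vpd_grid, sign_term = d$sign_term,
                           scaling_term = d$scaling_term,
                           dET_dVPD_Wm2_per_Pa = d$dET_dVPD,
                           regime = d$regime, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Rank the 9 (g1, uWUE) pairs by sign-term value, and the 9 (T, g_a) pairs
# by scaling-term value, at a reference VPD.  The published figures label
# curves "min/med/max of the sign (scaling) term" without stating the
# selection rule; ranking term values at the median of the VPD grid is this
# package's interpretation, recorded in CSV metadata.
rank_terms <- function(vpd_ref = 2000, fixed = SWEEP_FIXED) {
  consts <- physical_constants(gamma = fixed$gamma, R_air = fixed$R_air)
  sign_pairs <- expand.grid(g1 = SWEEP_LEVELS$g1, uWUE = SWEEP_LEVELS$uWUE,
                            KEEP.OUT.ATTRS = FALSE)
  sign_pairs$value <- mapply(function(g1, u)
    sign_term(vpd_ref, plant_params(g1, u), consts, c_a = fixed$c_a),
    sign_pairs$g1, sign_pairs$uWUE)
  scal_pairs <- expand.grid(T = SWEEP_LEVELS$T, g_a = SWEEP_LEVELS$g_a,
                            KEEP.OUT.ATTRS = FALSE)
  scal_pairs$value <- mapply(function(T, ga)
    scaling_term(forcing(T = T, P = fixed$P, VPD = vpd_ref, g_a = ga,
                         c_a = fixed$c_a, check_saturation = FALSE), consts),
    scal_pairs$T, scal_pairs$g_a)
  pick <- function(df) df[order(df$value)[c(1, ceiling(nrow(df) / 2), nrow(df))], ]
  list(sign = pick(sign_pairs), scaling = pick(scal_pairs),
       sign_med = sign_pairs[order(sign_pairs$value)[ceiling(nrow(sign_pairs) / 2)], ],
       scaling_med = scal_pairs[order(scal_pairs$value)[ceiling(nrow(scal_pairs) / 2)], ])
}

#' Nine-curve figure subsets of the sweep
#'
#' The 81 sweep curves are summarized in the figures by nine-curve
#' subsets: `"sign_by_scaling"` crosses the min/med/max sign-term parameter
#' pairs with the min/med/max scaling-term pairs; `"sign"` varies the nine
#' (g1, uWUE) pairs at the median scaling pair; `"scaling"` varies the nine
#' (T, g_a) pairs at the median sign pair.  "Min/med/max" of a term means
#' the parameter pair producing the smallest/median/largest term value at
#' the reference VPD (`vpd_ref`, the midpoint of the default VPD grid).
#'
#' @param which one of `"sign_by_scaling"`, `"sign"`, `"scaling"`.
#' @param vpd_grid VPD values, Pa.
#' @param vpd_ref reference VPD for ranking term values, Pa.
#' @return data frame as in [response_curves()] plus label columns
#'   `sign_level` and `scaling_level` where applicable.
#' @export
figure_curves <- function(which = c("sign_by_scaling", "sign", "scaling"),
                          vpd_grid = seq(10, 4000, by = 10),
                          vpd_ref = stats::median(vpd_grid)) {
  which <- match.arg(which)
  rk <- rank_terms(vpd_ref)
  lev <- c("min", "med", "max")
  if (which == "sign_by_scaling") {
    sign_p <- rk$sign
    scal_p <- rk$scaling
    combos <- expand.grid(si = 1:3, sj = 1:3, KEEP.OUT.ATTRS = FALSE)
    grid <- data.frame(g1 = sign_p$g1[combos$si], uWUE = sign_p$uWUE[combos$si],
                       T = scal_p$T[combos$sj], g_a = scal_p$g_a[combos$sj])
    extra <- data.frame(sign_level = lev[combos$si],
                        scaling_level = lev[combos$sj])
  } else if (which == "sign") {
    pairs <- expand.grid(g1 = SWEEP_LEVELS$g1, uWUE = SWEEP_LEVELS$uWUE,
                         KEEP.OUT.ATTRS = FALSE)
    grid <- data.frame(g1 = pairs$g1, uWUE = pairs$uWUE,
                       T = rk$scaling_med$T, g_a = rk$scaling_med$g_a)
    extra <- data.frame(sign_level = NA_character_, scaling_level = "med")
  } else {
    pairs <- expand.grid(T = SWEEP_LEVELS$T, g_a = SWEEP_LEVELS$g_a,
                         KEEP.OUT.ATTRS = FALSE)
    grid <- data.frame(g1 = rk$sign_med$g1, uWUE = rk$sign_med$uWUE,
                       T = pairs$T, g_a = pairs$g_a)
    extra <- data.frame(sign_level = "med", scaling_level = NA_character_)
  }
  attr(grid, "fixed") <- SWEEP_FIXED
  curves <- response_curves(grid, vpd_grid)
  cbind(curves, extra[curves$curve, , drop = FALSE], row.names = NULL)
}

#' Synthetic half-hourly diurnal forcing
#'
#' Generates a reproducible synthetic forcing series for batch testing:
#' net radiation follows a truncated sinusoid (0 at night, up to 600 W/m^2
#' at solar noon), temperature a 288-303 K sinusoid peaking in early
#' afternoon, relative humidity a 0.4-0.9 sinusoid anti-phased with
#' temperature, pressure constant at 1e5 Pa, and aerodynamic conductance
#' drawn once per day uniformly from \[0.015, 0.055\] m/s.  This emulates
#' the gross diurnal structure of growing-season flux-tower forcing, not
#' its weather-driven variability.
#'
#' @param seed integer RNG seed; the same seed always yields the same table.
#' @param n_days number of days (48 half-hourly records per day).
#' @return data frame with columns `time` (hours since start), `T_K`,
#'   `P_Pa`, `RH`, `VPD_Pa`, `Rnet_Wm2`, `ga_ms`, `ca_umol_mol`.
#' @export
synthetic_forcing <- function(seed = 1L, n_days = 2L) {
  if (n_days < 1) stop("n_days must be >= 1", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  ga_day <- stats::runif(n_days, 0.015, 0.055)
  hours <- seq(0, n_days * 24 - 0.5, by = 0.5)
  tod <- hours %% 24
  solar <- sin(pi * (tod - 6) / 12)          # sunrise 06, sunset 18
  Rnet <- 600 * pmax(solar, 0)
  T_K <- 295.5 + 7.5 * sin(pi * (tod - 9) / 12)   # 288-303 K, peak ~15:00
  RH <- 0.65 - 0.25 * sin(pi * (tod - 9) / 12)    # 0.4-0.9, anti-phased
  data.frame(time = hours, T_K = T_K, P_Pa = 1e5, RH = RH,
             VPD_Pa = vpd_from_rh(T_K, RH), Rnet_Wm2 = Rnet,
             ga_ms = ga_day[floor(hours / 24) + 1L], ca_umol_mol = 400)
}

#' Write a result table as CSV with a metadata header
#'
#' Numeric columns are written at full double precision (17 significant
#' digits) with fixed formatting so repeated runs are byte-identical.
#' Metadata (the saturation-vapor-pressure formula, the figure selection
#' rule, grid settings) is recorded as leading `#` comment lines.
#'
#' @param df data frame to write.
#' @param path output file path, or `""` for standard output.
#' @param meta named character vector of extra metadata lines.
#' @return `path`, invisibly.
#' @export
write_curves_csv <- function(df, path, meta = character()) {
  meta <- c(package = paste0("etvpd ", utils::packageVersion("etvpd")),
            esat_formula = ESAT_FORMULA, meta)
  header <- sprintf("# %s: %s", names(meta), meta)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  con <- if (nzchar(path)) file(path, "w") else stdout()
  if (nzchar(path)) on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
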