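# Shared fixtures and independent numeric oracles for the test suite.

# Median plant parameters as printed in the literature-range table.
med_plant <- plant_params(g1 = 126.49, uWUE = 3.17)

# The three literature levels of each varied parameter.
lv_g1 <- c(63.25, 126.49, 189.74)
lv_uwue <- c(2.33, 3.17, 4.01)
lv_T <- c(283.15, 293.15, 303.15)
lv_ga <- c(0.015, 0.035, 0.055)

# All nine (g1, uWUE) sign-parameter combinations.
plant_combos <- expand.grid(g1 = lv_g1, uWUE = lv_uwue)

# Saturation checking is off: the analytic response is evaluated on VPD
# grids that extend past the cold-air saturation limit.
med_forcing <- function(VPD = 1000, T = 293.15, g_a = 0.035, R_net = 400)
  forcing(T = T, P = 1e5, VPD = VPD, R_net = R_net, g_a = g_a, c_a = 400,
          check_saturation = FALSE)

# Central finite difference of et_explicit in VPD at fixed T (the same
# fixed-temperature convention as the analytic derivative).
fd_det_dvpd <- function(VPD, plant, T = 293.15, g_a = 0.035, R_net = 400,
                        consts = physical_constants(), rel_step = 1e-3) {
  h <- VPD * rel_step
  et_at <- function(v) et_explicit(med_forcing(v, T = T, g_a = g_a,
                                               R_net = R_net),
                                   plant, consts)$ET
  (et_at(VPD + h) - et_at(VPD - h)) / (2 * h)
}

# Independent second derivative for concavity cross-checks: 5-point central
# stencil with one Richardson extrapolation step (error O(h^6)), accurate
# enough to locate inflection roots to ~1e-8 in nondimensional VPD.
num_d2 <- function(f, x, h = x * 1e-2) {
  five <- function(s)
    (-f(x + 2 * s) + 16 * f(x + s) - 30 * f(x) + 16 * f(x - s) - f(x - 2 * s)) /
      (12 * s^2)
  (16 * five(h / 2) - five(h)) / 15
}

# Penman-Monteith written out directly (independent of the package
# implementation, and without the g_s > 0 domain guard, so the algebraic
# fixed-point identity can be checked even in the flagged ET <= 0 regime).
pm_hand <- function(f, gs, consts = physical_constants()) {
  D <- delta_slope(f$T)
  rho <- f$P / (consts$R_air * f$T)
  (D * f$R_net + f$g_a * rho * consts$c_p * f$VPD) /
    (D + consts$gamma * (1 + f$g_a / gs))
}

# The generalized closure function h(V) = V^(n+m)/(V^m + g*), written out
# independently of the package internals.
h_fun <- function(V, n, m, g_star) V^(n + m) / (V^m + g_star)
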