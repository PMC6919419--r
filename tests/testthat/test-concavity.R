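test_that("generalized ET reduces to the optimal model at n = m = 1/2", {
  gen <- generalized_params(g_star = 126.49, m = 0.5, n = 0.5,
                            wue_star = 3.17)
  V <- seq(50, 4000, length.out = 40)
  f <- med_forcing(VPD = V)
  expect_equal(et_general(f, gen), et_explicit(f, med_plant)$ET,
               tolerance = 1e-12)
})

test_that("generalized ET is the fixed point of the generalized conductance", {
  cn <- physical_constants()
  cases <- expand.grid(n = c(0.3, 0.5, 0.9), m = c(0.5, 1.0, 1.2),
                       V = c(300, 1500))
  for (i in seq_len(nrow(cases))) {
    n <- cases$n[i]; m <- cases$m[i]; V <- cases$V[i]
    gen <- generalized_params(g_star = 110, m = m, n = n, wue_star = 3.17)
    f <- med_forcing(VPD = V)
    ET <- et_general(f, gen)
    # generalized closure written out independently of the implementation
    gs <- (cn$R * f$T / f$P) * 1.6 * (1 + gen$g_star / V^m) *
      gen$wue_star * ET / (f$c_a * V^n)
    recovered <- if (gs > 0) penman_monteith(f, gs) else pm_hand(f, gs)
    expect_equal(recovered, ET, tolerance = 1e-10)
  }
})

test_that("large-VPD closure behaves like the conductance exponent dictates", {
  # with m = 1, n = 1/2 the closure term h(V) = V^(3/2)/(V + g*) ~ sqrt(V)
  # at large VPD: h(4V)/h(V) -> 2
  g_star <- 110
  Vbig <- 1e6 * g_star
  ratio <- h_fun(4 * Vbig, 0.5, 1, g_star) / h_fun(Vbig, 0.5, 1, g_star)
  expect_equal(ratio, 2, tolerance = 1e-4)
})

test_that("inflection quadratic coefficients match the algebraic expansion", {
  q <- inflection_quadratic(0.5, 0.5)
  expect_equal(unname(q), c(-0.25, -0.75, 0))
  q2 <- inflection_quadratic(0.5, 1)
  expect_equal(unname(q2), c(-0.25, -1.5, 0.75))
  # the positive root of q2 is 2*sqrt(3) - 3
  roots <- sort(Re(polyroot(rev(q2))))
  expect_equal(max(roots), 2 * sqrt(3) - 3, tolerance = 1e-12)
})

test_that("closed-form inflection locus matches the quadratic and known values", {
  opt <- inflection_locus(0.5, 0.5)
  expect_equal(opt$status, "root")
  expect_equal(opt$x_star, 0)
  leu <- inflection_locus(0.5, 1) # Leuning-type linear VPD conductance
  expect_equal(leu$status, "root")
  expect_equal(leu$x_star, 2 * sqrt(3) - 3, tolerance = 1e-12)
  expect_equal(inflection_locus(1, 0.7)$status, "singular")
  expect_equal(inflection_locus(0, 0.7)$status, "singular")
})

test_that("closed form, quadratic root, and numeric second derivative agree on a grid", {
  g_star <- 110
  exps <- seq(0.05, 1.5, length.out = 30)
  n_checked <- 0L
  for (n in exps) for (m in exps) {
    if (abs(n - 1) < 1e-9) next
    sol <- inflection_locus(n, m)
    q <- inflection_quadratic(n, m)
    if (sol$status != "root" || sol$x_star <= 1e-6) {
      # no interior inflection: the quadratic must not change sign on x > 0
      x_probe <- 10^seq(-3, 3, length.out = 50)
      vals <- q[["A"]] * x_probe^2 + q[["B"]] * x_probe + q[["C"]]
      expect_true(all(vals < 1e-9) || all(vals > -1e-9))
      next
    }
    # quadratic root agreement
    qval <- q[["A"]] * sol$x_star^2 + q[["B"]] * sol$x_star + q[["C"]]
    expect_equal(qval, 0, tolerance = 1e-8)
    # numeric root of the second derivative of the closure function
    V_star <- (sol$x_star * g_star)^(1 / m)
    d2 <- function(V) num_d2(function(u) h_fun(u, n, m, g_star), V)
    V_num <- uniroot(d2, c(V_star * 0.5, V_star * 2), tol = 1e-12)$root
    expect_equal(V_num^m / g_star, sol$x_star, tolerance = 1e-8)
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 100) # the grid genuinely exercises the root branch
})

test_that("concavity classification follows nondimensional VPD against the locus", {
  # optimal exponents: concave up for any VPD and slope
  for (g_star in c(63.25, 110, 189.74)) {
    gen <- generalized_params(g_star, 0.5, 0.5, 3.17)
    expect_true(all(concavity_class(c(10, 500, 2000, 9000), gen) ==
                      "concave_up"))
  }
  # linear conductance model: threshold at x* = 2*sqrt(3) - 3; the closure
  # grows superlinearly below the inflection (ET concave down there) and
  # like sqrt(VPD) above it (ET concave up)
  gen1 <- generalized_params(g_star = 110, m = 1, n = 0.5, wue_star = 3.17)
  expect_equal(concavity_class(0.2 * 110, gen1), "concave_down")
  expect_equal(concavity_class(1.0 * 110, gen1), "concave_up")
  # cross-check with the sign of the numeric second derivative of h
  # (ET is concave up exactly where h'' < 0)
  expect_gt(num_d2(function(u) h_fun(u, 0.5, 1, 110), 0.2 * 110), 0)
  expect_lt(num_d2(function(u) h_fun(u, 0.5, 1, 110), 1.0 * 110), 0)
  # singular exponent falls back to the numeric probe without error
  gen_sing <- generalized_params(g_star = 110, m = 0.5, n = 1, wue_star = 3.17)
  expect_true(concavity_class(1000, gen_sing) %in%
                c("concave_up", "concave_down", "inflection"))
})

test_that("concavity is independent of wue_star and R_net", {
  gen_a <- generalized_params(110, 1, 0.5, 0.4)
  gen_b <- generalized_params(110, 1, 0.5, 4.0)
  V <- c(20, 45, 300, 2000)
  expect_identical(concavity_class(V, gen_a), concavity_class(V, gen_b))
  # numeric second derivative of ET keeps its sign under 10x R_net changes
  for (Rn in c(80, 800)) {
    d2et <- num_d2(function(v) et_general(med_forcing(VPD = v, R_net = Rn),
                                          gen_a), 300)
    expect_gt(d2et, 0) # x = 300/110 > x*: concave up, either radiation
  }
})

test_that("ET is concave up across all plant combinations at optimal exponents", {
  V <- 10^seq(0, 4, length.out = 25)
  for (i in seq_len(nrow(plant_combos))) {
    p <- plant_params(plant_combos$g1[i], plant_combos$uWUE[i])
    d2 <- sapply(V, function(v) num_d2(
      function(u) et_explicit(med_forcing(VPD = u), p)$ET, v))
    expect_true(all(d2 > 0))
  }
})

test_that("phase curves cover the three scenarios and validate against the quadratic", {
  fc <- figure4_curves()
  expect_setequal(unique(fc$scenario),
                  c("m_varying", "n_varying", "n_equals_m"))
  at <- function(sc, v) fc[fc$scenario == sc & abs(fc$exponent - v) < 1e-9, ]
  expect_equal(at("n_equals_m", 0.5)$x_star, 0)
  expect_equal(at("m_varying", 1)$x_star, 2 * sqrt(3) - 3, tolerance = 1e-12)
  # every emitted locus is a root of its quadratic
  for (i in seq_len(nrow(fc))) {
    nm <- switch(fc$scenario[i],
                 m_varying = c(0.5, fc$exponent[i]),
                 n_varying = c(fc$exponent[i], 0.5),
                 n_equals_m = c(fc$exponent[i], fc$exponent[i]))
    q <- inflection_quadratic(nm[1], nm[2])
    expect_equal(q[["A"]] * fc$x_star[i]^2 + q[["B"]] * fc$x_star[i] + q[["C"]],
                 0, tolerance = 1e-8)
  }
  # dimensionalized VPD uses m = 1/2, g* = 110: VPD = (x* g*)^2
  expect_equal(fc$vpd_pa, (fc$x_star * 110)^2, tolerance = 1e-12)
})

test_that("generalized parameters are validated", {
  expect_error(generalized_params(-1, 0.5, 0.5, 3), "positive")
  expect_error(generalized_params(110, 2, 0.5, 3), "exponents")
  expect_error(generalized_params(110, 0.5, 0, 3), "exponents")
  expect_error(generalized_params(110, 0.5, 0.5, -3), "positive")
  expect_error(et_general(med_forcing(VPD = 0),
                          generalized_params(110, 0.5, 0.5, 3.17)),
               "positive")
})
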