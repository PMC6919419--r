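#' Generalized stomatal model parameters
#'
#' Frees the stomatal conductance closure from the optimal square-root
#' assumption by introducing free VPD exponents: `m` in the conductance
#' model (`1 + g_star / VPD^m`) and `n` in the generalized water use
#' efficiency (`wue_star = GPP * VPD^n / ET`).  At `m = n = 1/2` with
#' `g_star = g1` and `wue_star = uWUE` the generalized pathway coincides
#' with the optimal one.
#'
#' @param g_star slope parameter, units Pa^m.
#' @param m VPD exponent in the conductance model, in (0, 1.5].
#' @param n VPD exponent in the water use efficiency, in (0, 1.5].
#' @param wue_star generalized water use efficiency, umol C Pa^n J^-1.
#' @return An object of class `generalized_params`.
#' @export
generalized_params <- function(g_star, m = 0.5, n = 0.5, wue_star) {
  if (!is.numeric(g_star) || length(g_star) != 1L || g_star <= 0)
    stop("g_star must be a single positive number", call. = FALSE)
  if (!is.numeric(wue_star) || length(wue_star) != 1L || wue_star <= 0)
    stop("wue_star must be a single positive number", call. = FALSE)
  for (e in list(m = m, n = n)) {
    if (!is.numeric(e) || length(e) != 1L || e <= 0 || e > 1.5)
      stop("exponents m and n must lie in (0, 1.5]", call. = FALSE)
  }
  structure(list(g_star = g_star, m = m, n = n, wue_star = wue_star),
            class = "generalized_params")
}

#' @export
print.generalized_params <- function(x, ...) {
  cat(sprintf("Generalized stomatal model: g* = %g Pa^%g, m = %g, n = %g, *WUE = %g\n",
              x$g_star, x$m, x$n, x$wue_star))
  invisible(x)
}

# Closure function h(V) = V^(n+m) / (V^m + g_star); ET'' = -K h'' with K > 0,
# so the concavity of ET in VPD is decided entirely by h.
h_closure <- function(V, gen) {
  V^(gen$n + gen$m) / (V^gen$m + gen$g_star)
}

#' Explicit ET under the generalized stomatal model
#'
#' The analogue of [et_explicit()] with free VPD exponents: substituting
#' the generalized conductance closure into Penman-Monteith gives
#' \deqn{ET = \frac{\Delta R_{net} + \frac{g_a P}{T}\left(
#'   \frac{c_p VPD}{R_{air}} - \frac{\gamma c_a}{1.6 R\,wue^*}
#'   \frac{VPD^{n+m}}{VPD^m + g^*}\right)}{\Delta + \gamma}.}
#'
#' @param forcing a [forcing()] object (`VPD > 0`).
#' @param gen a [generalized_params()] object.
#' @param consts a [physical_constants()] object.
#' @return ET, W/m^2 (vector).
#' @export
et_general <- function(forcing, gen, consts = physical_constants()) {
  stopifnot(inherits(forcing, "forcing"), inherits(gen, "generalized_params"))
  if (any(forcing$VPD <= 0))
    stop("VPD must be strictly positive for the generalized model",
         call. = FALSE)
  Delta <- delta_slope(forcing$T)
  closure <- consts$c_p * forcing$VPD / consts$R_air -
    (consts$gamma * forcing$c_a / (1.6 * consts$R * gen$wue_star)) *
      h_closure(forcing$VPD, gen)
  (Delta * forcing$R_net + (forcing$g_a * forcing$P / forcing$T) * closure) /
    (Delta + consts$gamma)
}

#' Quadratic whose positive roots locate the ET-VPD inflection
#'
#' Setting the second VPD-derivative of the closure function
#' \eqn{h(V) = V^{n+m}/(V^m + g^*)} to zero and substituting the
#' nondimensional VPD \eqn{x = VPD^m / g^*} reduces the condition to
#' \eqn{A x^2 + B x + C = 0} with
#' \deqn{A = n(n-1),\quad B = 2n^2 + 2nm - 2n - m^2 - m,\quad
#'       C = (n+m)(n+m-1).}
#' The sign of \eqn{A x^2 + B x + C} equals the sign of \eqn{h''}, so the
#' quadratic also classifies concavity away from its roots (ET is concave
#' up exactly where \eqn{h'' < 0}).
#'
#' @param n VPD exponent in the water use efficiency.
#' @param m VPD exponent in the conductance model.
#' @return named numeric vector `c(A, B, C)`.
#' @export
inflection_quadratic <- function(n, m) {
  n <- unname(n)
  m <- unname(m)
  c(A = n * (n - 1),
    B = 2 * n^2 + 2 * n * m - 2 * n - m^2 - m,
    C = (n + m) * (n + m - 1))
}

#' Closed-form inflection locus of the generalized ET-VPD curve
#'
#' The nondimensional VPD \eqn{x^* = VPD^m/g^*} at which the ET-VPD curve
#' switches between concave up and concave down:
#' \deqn{x^* = \frac{m\left(m - 2n + 1 -
#'   \sqrt{m^2 - 4mn + 2m - 4n^2 + 4n + 1}\right)}{2n(n-1)} - 1.}
#' The locus does not depend on the water use efficiency `wue_star`, only
#' on the exponents.  At the optimal exponents `n = m = 1/2` it collapses
#' to \eqn{x^* = 0}: the curve is concave up for every VPD > 0 regardless
#' of the plant constants.  The closed form agrees with the positive root
#' of [inflection_quadratic()] wherever one exists; any degenerate case is
#' reported through `status` instead of an error.
#'
#' @param n VPD exponent in the water use efficiency; `n = 0` and `n = 1`
#'   are singular (the quadratic degenerates).
#' @param m VPD exponent in the conductance model.
#' @return An object of class `inflection_solution`: list with `x_star`
#'   (nondimensional VPD of the inflection; `NA` unless `status = "root"`,
#'   except `x_star = 0` for the boundary case of a locus at the origin),
#'   `status` (one of `"root"`, `"none_concave_up"`, `"none_concave_down"`,
#'   `"singular"`), and `flag` (character; notes when both quadratic roots
#'   are positive and the smaller was taken).
#' @examples
#' inflection_locus(n = 0.5, m = 0.5)  # x* = 0: concave up everywhere
#' inflection_locus(n = 0.5, m = 1)    # x* = 2*sqrt(3) - 3
#' @export
inflection_locus <- function(n, m) {
  out <- list(x_star = NA_real_, status = "none_concave_up",
              flag = character())
  class(out) <- "inflection_solution"
  if (n %in% c(0, 1)) {
    out$status <- "singular"
    return(out)
  }
  disc <- m^2 - 4 * m * n + 2 * m - 4 * n^2 + 4 * n + 1
  q <- inflection_quadratic(n, m)
  if (disc < 0) {
    out$status <- concavity_side(q)
    return(out)
  }
  xs <- m * (m - 2 * n + 1 - sqrt(disc)) / (2 * n * (n - 1)) - 1
  # the closed form is one quadratic root; the companion root guards the
  # (unobserved on the supported domain) case of two positive roots
  other <- sort((-q[["B"]] + c(-1, 1) * sqrt(q[["B"]]^2 - 4 * q[["A"]] * q[["C"]])) /
                  (2 * q[["A"]]))
  pos <- other[other > 1e-12]
  if (xs > 1e-12) {
    if (length(pos) == 2) out$flag <- "two_positive_roots_smaller_taken"
    out$x_star <- min(xs, pos)
    out$status <- "root"
  } else if (abs(xs) <= 1e-12) {
    # locus at the origin: concave up for every VPD > 0 (optimal exponents)
    out$x_star <- 0
    out$status <- "root"
  } else if (length(pos)) {
    out$flag <- "closed_form_root_negative_companion_taken"
    out$x_star <- pos[1]
    out$status <- "root"
  } else {
    out$status <- concavity_side(q)
  }
  out
}

# Which side of concavity holds when the quadratic has no positive root:
# sign(h'') = sign(A x^2 + B x + C), and ET is concave up where h'' < 0.
concavity_side <- function(q) {
  probe <- q["A"] + q["B"] + q["C"] # value at x = 1
  if (probe < 0) "none_concave_up" else "none_concave_down"
}

#' @export
print.inflection_solution <- function(x, ...) {
  switch(x$status,
    root = cat(sprintf("Inflection at nondimensional VPD x* = VPD^m/g* = %.6g\n",
                       x$x_star)),
    none_concave_up = cat("No inflection: ET-VPD curve concave up throughout\n"),
    none_concave_down = cat("No inflection: ET-VPD curve concave down throughout\n"),
    singular = cat("Singular exponent (n = 0 or 1): use the numeric probe\n"))
  if (length(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Concavity of the ET-VPD curve at a given VPD
#'
#' Evaluates the sign of the inflection quadratic at the nondimensional
#' VPD \eqn{x = VPD^m/g^*}; negative means the closure function is concave
#' up in ET terms (`"concave_up"`), positive `"concave_down"`, and a value
#' within `tol` of zero `"inflection"`.  For the singular exponents
#' `n` in \{0, 1\} the quadratic degenerates and a numeric second
#' derivative of the closure function is used instead.
#'
#' @param VPD vapor pressure deficit, Pa (> 0, vectorized).
#' @param gen a [generalized_params()] object (or any list with `g_star`,
#'   `m`, `n`).
#' @param tol half-width of the `"inflection"` band on the quadratic value.
#' @return character vector of `"concave_up"`, `"concave_down"`,
#'   `"inflection"`.
#' @export
concavity_class <- function(VPD, gen, tol = 1e-10) {
  if (any(VPD <= 0)) stop("VPD must be strictly positive", call. = FALSE)
  x <- VPD^gen$m / gen$g_star
  if (gen$n %in% c(0, 1)) {
    h2 <- vapply(VPD, function(v) numeric_second_deriv(
      function(u) h_closure(u, gen), v), numeric(1))
    val <- h2 # sign(h'') directly
  } else {
    q <- inflection_quadratic(gen$n, gen$m)
    val <- q[["A"]] * x^2 + q[["B"]] * x + q[["C"]]
  }
  ifelse(abs(val) <= tol, "inflection",
         ifelse(val < 0, "concave_up", "concave_down"))
}

# Central 5-point second derivative, step scaled to the abscissa.
numeric_second_deriv <- function(f, x, h = x * 1e-4) {
  (-f(x + 2 * h) + 16 * f(x + h) - 30 * f(x) + 16 * f(x - h) - f(x - 2 * h)) /
    (12 * h^2)
}

#' Inflection-locus phase curves over the exponent space
#'
#' Sweeps one VPD exponent at a time and records where the ET-VPD curve
#' switches concavity, producing the phase diagram separating concave-up
#' from concave-down solutions in the (exponent, nondimensional VPD)
#' plane.  Three scenarios are supported: `m_varying` (n held at 1/2),
#' `n_varying` (m held at 1/2), and `n_equals_m` (both exponents equal).
#' The interpretation that the non-varying exponent sits at the optimal
#' 1/2 is recorded in the `held` column.  A dimensionalized VPD column is
#' added for physical reading, using `m = 1/2` and `g_star = 110` Pa^1/2
#' (a representative average of plant-functional-type slope values), i.e.
#' \eqn{VPD = (x^* g^*)^2}.
#'
#' @param scenarios subset of
#'   `c("m_varying", "n_varying", "n_equals_m")`.
#' @param step grid step for the varying exponent over (0, 1.5].
#' @param g_star_dim slope used for the dimensionalized VPD column, Pa^1/2.
#' @return data frame with columns `scenario`, `exponent`, `x_star`,
#'   `vpd_pa` (dimensionalized), and `held` (the fixed exponent, `NA` for
#'   `n_equals_m`).  Rows where no inflection exists are omitted.
#' @export
figure4_curves <- function(scenarios = c("m_varying", "n_varying", "n_equals_m"),
                           step = 0.01, g_star_dim = 110) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  grid <- seq(step, 1.5, by = step)
  rows <- list()
  for (sc in scenarios) {
    for (v in grid) {
      nm <- switch(sc,
                   m_varying = c(n = 0.5, m = v),
                   n_varying = c(n = v, m = 0.5),
                   n_equals_m = c(n = v, m = v))
      sol <- inflection_locus(nm["n"], nm["m"])
      if (sol$status != "root") next
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc, exponent = v, x_star = sol$x_star,
        vpd_pa = (sol$x_star * g_star_dim)^2,
        held = switch(sc, m_varying = 0.5, n_varying = 0.5,
                      n_equals_m = NA_real_),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
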