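---
title: "The ET-VPD sensitivity framework: model, decomposition, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ET-VPD sensitivity framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etvpd)
```

## The problem

Vapor pressure deficit is the drying power of the atmosphere.  It drives
evapotranspiration through the aerodynamic term of the surface energy
balance, but it also closes stomata, reducing canopy conductance.  Which
effect wins at the ecosystem scale is not obvious, and answering it from
flux observations alone is hard because VPD covaries with temperature,
radiation, and soil moisture.  `etvpd` answers it analytically, as a
partial derivative: the change in ET for a conceptual change in VPD with
every other environmental variable held fixed.

## Model and assumptions

The package composes three established ingredients:

1. **Penman-Monteith** for ET as latent heat flux (W m^-2), with
   aerodynamic conductance `g_a` taken as an input (no roughness-based
   estimation).
2. **The Medlyn unified stomatal conductance model**, in which conductance
   scales with `GPP/c_a` and declines with `sqrt(VPD)` through the slope
   parameter `g1`.
3. **Underlying water use efficiency**, `uWUE = GPP*sqrt(VPD)/ET`, treated
   as a plant-functional-type constant over the growing season.

Substituting 3 into 2 removes GPP; substituting the result into 1 and
solving for ET gives the explicit form implemented by `et_explicit()`.
The derivation assumes a well-coupled canopy (leaf-surface VPD equals
measurement-height VPD), transpiration-dominated ET (soil evaporation
small, most defensible for forests in the growing season), and `g1`/`uWUE`
constant under the VPD perturbation.  Feedbacks (e.g. ET changing surface
temperature and hence `R_net`) are deliberately outside the partial
derivative: temperature is mathematically fixed.

The derivative convention matters: `det_dvpd()` differentiates at fixed
temperature, i.e. VPD varies through relative humidity while the
saturation vapor pressure and its slope stay put.  RH and `e_s` are treated
as independent coordinates.  The finite-difference oracle in the test suite
uses the same convention, which is what lets the analytic and numeric
derivatives agree to ~1e-7 relative error.

## The sign/scaling decomposition

`det_dvpd()` returns the product of two factors with clean
interpretations:

- the **sign term** (dimensionless, `sign_term()`):
  `c_p/R_air - (gamma*c_a/(1.6*R*uWUE)) * (2*g1+sqrt(VPD))/(2*(g1+sqrt(VPD))^2)`.
  The first piece is atmospheric demand; the second is stomatal closure.
  It is increasing in VPD, `g1`, and `uWUE`, finite at VPD = 0 (the
  modulating ratio tends to `1/g1`), and crosses zero at most once — the
  critical VPD found by `critical_vpd()` with a 64-point log-spaced
  bracket scan followed by Brent's method (`stats::uniroot`, tolerance
  1e-12).  Deterministic; no seeds.
- the **scaling term** (positive, `scaling_term()`):
  `g_a*P/(T*(Delta+gamma))`.  Cold air and rough, well-ventilated canopies
  amplify the response; the term never changes its sign.

```{r}
p_med <- plant_params(g1 = 126.49, uWUE = 3.17)
critical_vpd(p_med)
```

At the median plant parameters the response changes sign near 1 kPa:
ecosystems are water conservative in moist air and water intensive in dry
air, with a local minimum of ET at the critical VPD.

## Parameters, units, and defaults

| quantity | unit | default | why |
|---|---|---|---|
| `g1` | Pa^1/2 | 126.49 (median) | literature range 63.25-189.74, i.e. 2-6 kPa^1/2 (`convert_g1()`); ~15th/50th/85th percentile of plant types |
| `uWUE` | umol C Pa^1/2 J^-1 | 3.17 (median) | literature range 2.33-4.01, from 6.99-12.05 g C hPa^1/2 kg^-1 (`convert_uwue()`) |
| `T` | K | 283.15/293.15/303.15 in sweeps | 10/20/30 C, growing-season percentiles rounded to 5 C |
| `g_a` | m/s | 0.015/0.035/0.055 in sweeps | flux-tower percentiles rounded to 0.005 m/s |
| `P`, `gamma`, `R_air`, `c_a` | Pa, Pa/K, J/kg/K, umol/mol | 1e5, 64.50, 288.00, 400 | held fixed in the sweep |
| `c_p` | J/kg/K | 1004 | standard dry-air value; configurable |
| `L_v` | J/kg | 2.5e6 | the value consistent with the published uWUE conversions; temperature-independent by design |

`R_air = 288.0` J kg^-1 K^-1 follows the fixed-value table this analysis
is defined at even though 287 is the textbook constant; both are supported
(`physical_constants(R_air = 287)` or a config file), and the default
follows the source table.  ET is carried in W m^-2 throughout — matching
the uWUE units — with `et_mm_day()` converting on output only.  `c_a` is a
mole fraction and is never converted to partial pressure.  Saturation
vapor pressure uses the Tetens formula (smooth, standard in
micrometeorology, analytic derivative supplies Delta); the formula name is
recorded in CSV metadata so an alternative could be swapped in and traced.

## Generalized exponents and concavity

`et_general()` frees both VPD exponents: `m` in the conductance model and
`n` in the WUE ratio.  The concavity of ET in VPD is governed by the
closure function `h(V) = V^(n+m)/(V^m + g*)` through `ET'' = -K h''` with
`K > 0`.  Nondimensionalizing with `x = VPD^m/g*` turns `h'' = 0` into the
quadratic `A x^2 + B x + C = 0` with `A = n(n-1)`,
`B = 2n^2 + 2nm - 2n - m^2 - m`, `C = (n+m)(n+m-1)`
(`inflection_quadratic()`), and the closed form in `inflection_locus()` is
exactly one root of that quadratic (the discriminants are related by
`B^2 - 4AC = m^2 (m^2 - 4mn + 2m - 4n^2 + 4n + 1)`).

Design choices in this module that were genuinely open:

- **Authority of the quadratic.**  The closed-form locus is validated, in
  tests, against both the quadratic root and a numeric second-derivative
  root of `h`; the quadratic derivation is treated as ground truth.  Note
  the orientation: below the inflection (`x < x*`) the closure grows
  superlinearly, so `h'' > 0` and ET is concave *down*; above it ET is
  concave *up*.  In the exponent-space phase diagram
  (`figure4_curves()`) this is equivalent to "parameter space below the
  locus curve is concave up", since raising an exponent at fixed `x` moves
  the point above the curve.
- **Degenerate exponents.**  `n = 0` and `n = 1` make the quadratic
  degenerate; `inflection_locus()` reports status `"singular"` and
  `concavity_class()` falls back to a numeric second-derivative probe
  rather than a symbolic limit, because the behavior there is not defined
  by the theory.
- **Branch choice.**  The positive root is taken; if both roots were
  positive (not observed on the supported domain `(0, 1.5]`, guarded
  anyway) the smaller is reported with a flag.
- **Phase-diagram scenarios.**  The non-varying exponent is held at the
  optimal 1/2 (an interpretation, labeled in the output); the
  dimensionalized VPD column assumes `m = 1/2`, `g* = 110` Pa^1/2, a
  representative average slope.

At `n = m = 1/2` the locus is `x* = 0`: concave up for all VPD and any
plant constants, which the test suite verifies numerically across all nine
(g1, uWUE) combinations on VPD in [1, 1e4] Pa.

## The sweep experiment

`build_grid()` crosses the three literature levels of the four varied
parameters into 81 combinations — 9 sign-term parameterizations
(g1 x uWUE) by 9 scaling values (T x g_a) — and `response_curves()`
evaluates the decomposition on a VPD grid, by default 10-4000 Pa in 10 Pa
steps (the plotting range is a package choice, recorded in CSV metadata).
Among the 81 curves some are negative throughout (water conservative),
some positive throughout (water intensive), and the rest change sign.
Nine-curve figure subsets are selected by `figure_curves()`; since no
selection rule is published for "min/med/max of a term", the pairs are
ranked by their term value at the median VPD of the grid, an
interpretation recorded in the output metadata.

Two deliberate conventions:

- **VPD as a free coordinate.**  `forcing()` enforces
  `VPD <= esat(T)` by default, as observed air must.  The sweep evaluates
  the *analytic* response surface on a common VPD grid across all
  temperatures, where VPD up to 4000 Pa exceeds saturation at 10 C; those
  paths pass `check_saturation = FALSE`, and the stored RH goes negative
  to keep `VPD = esat(T)*(1-RH)` exact.
- **Negative ET is flagged, not clipped.**  Extreme corners of the
  parameter space drive the explicit ET below zero, outside the domain
  where the uWUE/Medlyn theory is asserted.  Values are returned with a
  `negative_et` flag so sweeps stay smooth and the fixed-point identity
  remains checkable.

## Synthetic forcing

`synthetic_forcing()` emulates the gross diurnal structure of
growing-season flux-tower forcing: half-hourly records, truncated-sine net
radiation (0-600 W m^-2), temperature 288-303 K peaking mid-afternoon,
relative humidity 0.4-0.9 anti-phased with temperature, constant 1e5 Pa
pressure, and one aerodynamic conductance per day drawn uniformly from
0.015-0.055 m/s.  It does not emulate weather variability, cloud, rain,
advection, or instrument noise — so tests passing on it demonstrate the
numerical and algebraic integrity of the pipeline, not skill against real
eddy-covariance data.  The generator is seeded and restores the session
RNG state, making batch outputs byte-reproducible.

## Numerical choices and problem sizes

Fixed-point consistency (substituting the closed conductance back into
Penman-Monteith recovers ET to 1e-10 relative error) is checked on a
5x5x5 (VPD, g1, uWUE) grid; the analytic derivative is checked against
central finite differences (relative step 1e-3) on a 10-VPD by 9-combo
grid; the inflection locus is cross-validated on a 30x30 exponent grid
with a Richardson-extrapolated five-point second-derivative oracle; the
full sweep uses the 400-point VPD grid.  These sizes keep the whole suite
and the acceptance script in the tens of seconds while exercising every
code path.

## Known limitations

- The theory is asserted for growing-season, transpiration-dominated,
  well-coupled canopies with ET > 0; outside that envelope results carry
  flags, not guarantees.
- No soil-moisture dependence of `g1`/`uWUE` is modeled, and no
  land-atmosphere feedbacks: everything is a one-way partial derivative.
- `g_a` is an input; no aerodynamic theory is included.
- The empirical exponent fits near 0.55 found for some site networks are
  not reproduced here; exponents are user inputs to the generalized model.
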