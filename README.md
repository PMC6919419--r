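# etvpd

Does evapotranspiration (ET) rise or fall when the air gets drier?  At the
leaf scale, stomata close as vapor pressure deficit (VPD) increases; at the
ecosystem scale the surface energy balance also constrains the flux, and the
two effects can pull in opposite directions.  `etvpd` implements a
closed-form theory of the one-way (partial-derivative) ET response to VPD
for ecohydrologists and land-atmosphere researchers who want to disentangle
the VPD effect from covarying drivers such as soil moisture.

## The model

The Penman–Monteith equation gives ET (as latent heat flux, W m⁻²)

```
ET = (Δ·R_net + g_a·ρ_a·c_p·VPD) / (Δ + γ·(1 + g_a/g_s))
```

with Δ the Clausius–Clapeyron slope of saturation vapor pressure, γ the
psychrometric constant, g_a and g_s the aerodynamic and canopy (stomatal)
conductances.  The Medlyn unified stomatal conductance model,

```
g_s = (R·T/P) · 1.6 · (1 + g1/√VPD) · GPP/c_a ,
```

depends on gross primary production, which itself depends on ET.  Closing
the loop with underlying water use efficiency, uWUE = GPP·√VPD/ET —
approximately constant within a plant functional type during the growing
season — removes GPP and yields ET explicitly:

```
ET = [Δ·R_net + (g_a·P/T)·(c_p·VPD/R_air − γ·c_a·VPD / ((g1+√VPD)·1.6·R·uWUE))] / (Δ+γ)
```

Its analytic derivative factors into a positive environmental *scaling term*
`g_a·P/(T(Δ+γ))` and a dimensionless *sign term*

```
c_p/R_air − (γ·c_a / (1.6·R·uWUE)) · (2g1+√VPD) / (2(g1+√VPD)²)
```

whose sign separates *water-conservative* (∂ET/∂VPD < 0) from
*water-intensive* (> 0) behavior, crossing zero at a critical VPD.  A
generalized model with free VPD exponents (m in conductance, n in the WUE
ratio) shows how the exponent choice sets the concavity of the ET–VPD
curve, with a closed-form inflection locus in nondimensional VPD
(VPD^m/g\*); at the optimal exponents n = m = ½ the curve is concave up for
every VPD and any plant parameters.

## Worked example

```r
library(etvpd)

# median literature parameters: g1 = 4 kPa^0.5, uWUE = 9.52 g C hPa^0.5/kg
p <- plant_params(g1 = convert_g1(4.00), uWUE = convert_uwue(9.52))
f <- forcing(T = 293.15, P = 1e5, VPD = 1000, R_net = 400, g_a = 0.035)

et_explicit(f, p)
#> Explicit PM evapotranspiration:
#>   ET  = 254.8483 W/m^2  (8.808 mm/day)
#>   g_s = 0.0124546 m/s
#>   GPP = 25.55 umol C/m^2/s

critical_vpd(p)
#> Critical VPD: 992.10 Pa (dET/dVPD < 0 below, > 0 above)

inflection_locus(n = 0.5, m = 1)   # Leuning-type linear VPD conductance
#> Inflection at nondimensional VPD x* = VPD^m/g* = 0.464102
```

At the median parameters, ET *decreases* with drying air up to roughly
1 kPa VPD and increases beyond it — a concave-up response with a local
minimum.  Under a linear-VPD conductance model the curve instead switches
from concave down to concave up at VPD^m/g\* ≈ 0.464.

The full sweep over the literature ranges (3 levels each of g1, uWUE, T,
g_a → 81 curves) is available as `response_curves(build_grid())` or from
the shell via the `exec/etvpd` script, e.g.
`etvpd sweep --out curves.csv`.

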