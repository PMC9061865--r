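# nanorelease

Temperature-dependent multi-mechanism modelling of drug release from
biodegradable polymer nanoparticles.

Controlled release from PLGA-type nanoparticles is rarely governed by a
single process: a fraction of the payload leaves in an **initial burst**
from at or near the particle surface, another fraction is freed as the
polymer matrix hydrolyses and relaxes (**degradation–relaxation**), and
the remainder escapes by **Fickian diffusion** through the matrix. This
package models the cumulative fractional release `Mt/M∞` as a convex
combination of those three mechanistic kernels and makes every rate
parameter an explicit function of incubation temperature through
Arrhenius laws. It is aimed at formulation scientists and modellers who
fit in-vitro release curves measured at several temperatures and want to
interpolate or extrapolate release behaviour across a temperature range.

## The models

Each kernel maps time *t* (days) into a release fraction:

- burst: `x_b(t) = 1 − exp(−k_b t)` — first-order interfacial transfer;
- degradation–relaxation: `x_r(t) = 1 / (1 + exp(−k_r (t − t_max)))` — a
  Prout–Tompkins-type logistic whose midpoint `t_max` is the time of
  maximum release rate;
- diffusion: `x_d(t) = 1 − (6/π²) Σ n⁻² exp(−n²π² D_e t_sec / r₁²)` — the
  series solution for diffusion out of a sphere of radius `r₁` with a
  uniform initial distribution and sink (zero surface concentration)
  boundary.

The **BR** model combines the first two, `x = θ_b x_b + (1−θ_b) x_r`
(4 parameters); the **BRD** model adds diffusion,
`x = θ_b x_b + θ_r x_r + θ_d x_d` with `θ_b + θ_r + θ_d = 1`
(6 free parameters). Every rate parameter follows an Arrhenius law
`p(T) = A exp(−Ea/(R T))` with `R = 1.9872 cal mol⁻¹ K⁻¹`; `Ea` may be
negative (`t_max` shrinks with temperature). Fits are scored with R² and
the adjusted R² `1 − (1−R²)(n−1)/(n−p−1)` so the 4- and 6-parameter
models can be compared fairly.

## Worked example

Fit the BR model to a synthetic 37 °C release profile and regress the
burst-rate constants measured at three temperatures:

```r
library(nanorelease)

p <- reference_params("br", 37)      # theta_b 0.5567, k_b 1.8053 /day, ...
prof <- generate_profile(p, noise = noise_spec(sd = 0.01, seed = 1),
                         temperature_K = 310.15)
fit_br(prof)
#> BR model fit: n = 23 points, p = 4 parameters
#> BR release parameters
#>   theta_b = 0.5715  k_b = 1.7846 /day
#>   theta_r = 0.4285  k_r = 0.1204 /day  t_max = 20.4463 day
#>   RSS = 0.001479   R^2 = 0.9967   adj. R^2 = 0.9960

s <- reference_parameter_series("br", "k_b")
fit_arrhenius(s$temperatures_K, s$values, mode = "endpoints")
#> Arrhenius law for parameter: A = 1703.04, Ea = 4.2215 kcal/mol (R = 1.9872 cal/mol/K)
#>   fitted from 2 point(s), mode = endpoints
```

The fitted `theta_b` says ~57% of the payload left in the burst; the
Arrhenius fit converts the 37/47/57 °C burst constants into an apparent
activation energy of ≈4.22 kcal mol⁻¹, so burst release roughly doubles
between 37 °C and 60 °C. `temperature_sweep()` turns such laws into a
full release surface over a temperature range, and
`mechanism_contributions()` decomposes any curve into its per-mechanism
parts.

A command-line interface mirrors the R surface
(`Rscript inst/cli/nanorelease.R <fit|simulate|synth|sweep|arrhenius> ...`).

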