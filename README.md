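# frontfish

Statistical association between fine-scale ocean fronts and mesopelagic fish
concentration, plus a gradient-climbing model of fish aggregation — with a
fully synthetic, ground-truthed stand-in for the restricted survey and
satellite data such analyses normally require.

## What it does

**Who it is for.** Biological oceanographers and movement ecologists who want
to (a) test the front–biomass processing chain (Lagrangian diagnostics →
acoustic transect statistics) against a known generative law, and (b) explore
a mechanistic model of how actively swimming mid-trophic fish (myctophids)
could concentrate on frontal tracer structures within hours to weeks.

**The statistics.** Acoustic Fish Concentration (AFC) is the mean
bifrequency backscatter of 29 of 30 depth layers (10–300 m; the 0–10 m layer
is excluded for surface noise) per 1.1-km acoustic unit. Fronts are detected
along the track as colocated finite-size Lyapunov exponents
FSLE = log(δf/δ0)/τ above 0.08 day⁻¹, or SST gradients above 0.009 °C/km.
The battery: front/no-front bootstrap difference of means (pooled-null
resampling), Mann–Whitney, linear quantile regression at the 75/90/95/99th
percentiles by direct pinball-loss minimisation (front intensity as a
*limiting factor*: it bounds the upper AFC quantiles without determining the
mean), and Pearson regression restricted to chlorophyll-rich water
(> 0.22 mg/m³).

**The model.** A fish compares the tracer (a zooplankton proxy) perceived at
distance `p_R` left and right under uniform noise and swims at speed `V`
toward the larger value. The mean drift is

    U_F = sign(∂T/∂x) · V · r(2 − r),  r = |∂T/∂x| / (∂T/∂x)_MAX clamped to [0, 1]

and the fish concentration ρ evolves by the 1-D continuity equation
∂ρ/∂t = −∂(ρ U_F)/∂x (Lax scheme). Over an 8-km tracer plateau with ~5-km
sigmoid edges, density peaks double at the plateau margins within about six
hours and the plateau-mean amplification reaches ~3.6× in 4 days; a 70-km
plateau keeps two persistent edge peaks. A companion scenario stretches a
tracer filament under strain γ and diffusion D (width
w(t)² = D/γ + (w0² − D/γ)e^(−2γt)) and reports the "school life time" during
which the gradient still permits noise-free climbing.

## Worked example

```r
library(frontfish)

## mechanistic model: 8-km plateau, default parameters
cfg <- gradclimb_config()               # V = 0.15 m/s, p_R = 100 m, dx = 100 m
run <- simulate_plateau(cfg, tracer_profile(cfg))
tail(run$diagnostics$plateau_mean, 1)   # 3.559  (plateau-mean amplification, 4 d)
run$doubling_time_s / 3600              # 6.17   (hours to 2x rho0 at the edges)

## statistics on the reference synthetic survey
w <- reference_survey(seed = 1)         # ~4200 units, 2868 at night
sp <- threshold_split(w$night, "fsle")  # 638 units over the 0.08/day threshold
bootstrap_mean_diff(sp$over, sp$under, n_boot = 10000, seed = 3)[c("mean_over", "mean_under", "p")]
# $mean_over 1.098; $mean_under 1.012; $p 0   (p < 1e-4: no null resample as extreme)

fit <- quantile_regression(w$night$fsle, w$night$afc, taus = 0.9,
                           scale = "raw", n_boot = 1000, seed = 11)
fit$slope                               # 2.43, 95% CI [2.32, 2.50]
generative_quantile_slope(0.9, w$spec$slope, mean(w$night$chl_rich))
# 2.49: the closed-form generative 90th-percentile slope, inside the CI

chl_gated_regression(w$night, "fsle", 0.22)$R   # 0.598, vs 0.369 ungated

## filament: strain 0.1/day, diffusivity 1 m^2/s
fs <- filament_scenario(gradclimb_config(L = 100e3))
fs$lifetime_days                        # 21.5 days of noise-free climbing
```

The bootstrap and quantile numbers say: AFC over fronts is significantly
higher than away from them; the 90th-percentile response of AFC to front
intensity recovers the generative limiting-factor slope; and gating on
chlorophyll-rich water strengthens the linear front–AFC correlation, because
in the generative law (as in the ecological hypothesis) the front effect is
active only where prey is available.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the installed package, the 8-km plateau run at
default parameters and writes the plateau-mean amplification at 4 days
(targets `t1`/`t2`, dimensionless fold over the initial concentration) and
the first time the edge density doubles (`t3`, hours) as JSON.
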