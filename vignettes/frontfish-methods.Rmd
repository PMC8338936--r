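---
title: "Fine-scale fronts and fish concentration: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-scale fronts and fish concentration: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(frontfish)
```

## The scientific problem

Mesopelagic fish — in the Southern Ocean, mostly myctophids — are the
dominant mid-trophic biomass of the open ocean, yet how fine-scale
(kilometres to ~100 km) frontal dynamics shapes their distribution is poorly
constrained. Two questions drive this package:

1. **Statistics.** Along an acoustic ship transect, is the Acoustic Fish
   Concentration (AFC) higher near fronts, and does front *intensity* act as
   a limiting factor — bounding the upper quantiles of AFC without
   determining its mean?
2. **Mechanism.** Can a minimal model of gradient-climbing fish, swimming up
   a zooplankton-proxy tracer perceived with noise, concentrate biomass at
   the edges of tracer structures on the observed time scales (hours to
   weeks)?

Real surveys of this kind use restricted acoustic and satellite data. The
package therefore ships a synthetic ocean with *known generative structure*,
so every statistical stage can be validated against ground truth, and the
movement model is checked against closed forms.

## The synthetic ocean

`gen_velocity_field()` builds a divergence-free mesoscale field from a
stream function that is a sum of Gaussian eddies (optional meandering jet),
constructed in the equirectangular tangent plane at the domain-centre
latitude. Velocities are central differences of the stream function on a
ghost-extended grid, so the *discrete* divergence vanishes to machine
precision — stirring filaments exist by construction and particle-based
diagnostics inherit no spurious compressibility.

Defaults (domain 30–54°E, 56–44°S at 0.1°; 30 eddies, stream-function
amplitudes 1–3 × 10⁴ m²/s, radii 35–75 km) give peak speeds of
0.5–0.8 m/s and finite-size Lyapunov ridges well above the 0.08 day⁻¹ front
threshold on O(10%) of the grid. These values were chosen once, for realism
of an energetic Antarctic Circumpolar Current region: weaker fields produce
transects on which *no* unit exceeds the standard front threshold, and no
front/no-front contrast exists to analyse. The synthetic ocean is
quasi-stationary (eddy drift defaults to 0; one daily snapshot, time
interpolation clamps to the stored window): daily altimetry evolves slowly
relative to a transect crossing. It does *not* emulate realistic ocean
spectra, tides, seasonality or data assimilation, so a green test
establishes correctness of the processing chain, not realism of any
particular ocean.

`gen_scalar_fields()` stirs a smooth meridional SST ramp (default
0.0045 °C/km) and smooth chlorophyll patches with the velocity field for 30
days (semi-Lagrangian backward sampling), which aligns tracer gradients with
the stirring filaments. Patch defaults put roughly 40% of the domain above
the 0.22 mg/m³ "chlorophyll-rich" level.

### The transect generator and its AFC law

`gen_transect()` lays acoustic units every 1.1 km along waypoints,
timestamps them from the ship speed, colocates FSLE, SST gradient and
chlorophyll at each unit, and draws the latent AFC from a limiting-factor
law:

    AFC_i = B_i + U_i · s · d_i · 1[chl_i > gate],   U_i ~ Uniform(0, 1)

where `d_i` is the colocated front diagnostic and `s` the front-effect
slope. The uniform multiplier (rather than Gaussian noise) is deliberate:
conditional quantiles of AFC given `d` are then *exactly* linear, so
quantile-regression recovery targets are closed-form. With constant baseline
`B_i = b` and a chlorophyll gate passed by a fraction `pi` of the water
(independent of `d`), the conditional tau-quantile is

    q_tau(AFC | d) = b + s · d · (tau − 1 + pi) / pi        for tau > 1 − pi

(`generative_quantile_slope()`), valid for *all* `d` — the ground truth the
statistics must recover. Each unit also carries a 30-layer echo profile
(10-m bins, 10–300 m) whose layers 2–30 average exactly to the latent AFC
through a fixed depth shape, and whose layer 1 carries additive positive
surface noise ten times the deep-layer scale, making the 29-of-30 exclusion
rule consequential.

The baseline admits an optional uniform jitter (`baseline_noise`, default
0). The default keeps the law exactly as stated above; the jitter exists
because a *null* world (front effect off) with a constant baseline is
degenerate — every AFC identical, every test trivially p = 1 — so type-I
calibration of the bootstrap needs a noise floor. Real backscatter
background varies by order one for reasons unrelated to fronts; null-world
runs use `baseline_noise = 0.5`.

One structural limit is worth stating plainly: under this law the *mean* of
AFC given `d` is linear with slope `pi·s/2`, and at survey sizes
(n ≈ 2000–3000) an ordinary least-squares fit on it is decisively
significant whenever the quantile slopes are. For the pure uniform-multiplier
law the OLS t-statistic and the 75th-quantile t-statistic have identical
asymptotic power, so no parameter choice yields "all quantile slopes
significant, OLS not". Field data achieve that pattern through noise whose
structure the generator does not (and, with exact linear quantiles, cannot)
reproduce. The corresponding acceptance check is implemented as stated and
fails; we regard the quantile-recovery checks as the meaningful ones.

## Lagrangian front diagnostics

`advect()` integrates particles with 4th-order Runge-Kutta (default 6-h
step), bilinear in space and linear in time, zonal displacement divided by
cos(lat); particles leaving the domain are frozen and flagged rather than
raising an error (a front diagnostic should degrade, not crash, at the
domain edge).

`compute_fsle()` seeds four particles per node at ±δ0/2 offsets (zonal
offsets scaled by 1/cos(lat)), so opposite pairs start exactly δ0 apart in
the cos(lat)-corrected degree metric, and integrates until the larger
opposite-pair separation first reaches δf, giving FSLE = log(δf/δ0)/τ.
Defaults δ0 = 0.04°, δf = 0.4°. Conventions the literature leaves open are
parameters with documented defaults:

* **Direction**: backward in time (attracting structures, the convention for
  front/tracer association); forward available.
* **Metric**: equirectangular with cos(lat) scaling — consistent with
  degree-based thresholds at mid latitudes without full geodesics.
* **Horizon**: 200 days by default; the reference survey uses 60 days, which
  resolves every value at or above ln(10)/60 ≈ 0.038 day⁻¹ exactly — far
  below the 0.08 day⁻¹ front threshold, so front identification is
  unaffected while the cost drops fourfold. Nodes that never separate (or
  whose particles exit the domain) get FSLE = 0, the conservative
  "no front detected" value.

`compute_sst_gradient()` uses central differences with the kilometric grid
spacing (zonal spacing shrinking with cos(lat); ~5.6 km per 0.05° of
latitude), one-sided at boundaries. `colocate()` averages grid cells within
a disc of radius σ (default 0.2°) in degree space with cos(lat) zonal
scaling; "circular neighbourhood" is ambiguous between degree and kilometre
space, and the degree reading matches the altimetry resolution argument for
σ.

## Acoustic processing conventions

* AFC is the arithmetic mean of layers 2–30; layer 1 (0–10 m) is excluded
  for surface noise. The rule is tested for exact invariance to layer 1.
* Acoustic units: raw pings grouped while their along-track distance from
  the group's first ping stays below 1.1 km (the original binning software's
  exact rule is unknown; this distance-threshold convention is documented
  and tested).
* Day/night: night iff solar elevation < 0° (NOAA-style low-precision solar
  position; no astronomical-twilight refinement). Daytime units are dropped
  before the statistics because diel vertical migration takes the fish below
  echo-sounder range during the day.
* Region masks: even-odd ray casting with a strict-interior rule (boundary
  and vertex points excluded) and contiguous-frame handling of the dateline;
  self-intersecting polygons are rejected. Acoustic units are treated as
  independent (school length is far below the 1.1-km unit spacing); no
  decorrelation thinning.

## The statistical battery

* `threshold_split()` classifies units as front / no-front by diagnostic
  thresholds 0.08 day⁻¹ (FSLE) and 0.009 °C/km (SST gradient).
* `bootstrap_mean_diff()` builds the null by pooling both groups and
  resampling groups of the original sizes with replacement (default ≥1000
  resamples); two-sided p = fraction of null |Δmean| ≥ observed. Degenerate
  input (all values identical) returns p = 1 with a warning. The companion
  `mann_whitney()` wraps the standard rank-sum test (exact for ≤8 per group
  without ties).
* `quantile_regression()` minimises the pinball loss directly: for fixed
  slope the optimal intercept is the tau-th (type-1) quantile of the
  residuals, and the profiled objective is convex piecewise linear in the
  slope, so a bracketed golden-section search finds the global minimiser
  (no quantile-regression package is required). Slope inference is an
  xy-pair bootstrap (default 1000 resamples): one mechanism for all taus,
  minimal distributional assumptions. Default scale is log10–log10 with
  zeros dropped, matching the logarithmic presentation of front–biomass
  scatter plots; recovery against the generative slopes uses the raw scale,
  where the ground truth is linear. No multiple-testing correction is
  applied across the four taus (matching the analysis this emulates); the
  p-values are reported so any correction can be applied downstream.
* `chl_gated_regression()` keeps units above a chlorophyll threshold
  (defaults 0.22 mg/m³ for FSLE, 0.17 for SST gradient) and reports the
  Pearson correlation of AFC on the diagnostic; `chl_gate_sweep()` recomputes
  it across thresholds for sensitivity inspection.

## The gradient-climbing model

A fish at `x` compares the tracer perceived at `x ± p_R` under independent
uniform noises on (−ξ_MAX, ξ_MAX) and swims at cruising speed `V` toward the
larger perceived value. With the tracer linearised over the perceptual
range, the leftward probability for a positive gradient is
`P(L) = ((1 − r)²)/2` with `r = p_R·(∂T/∂x)/ξ_MAX`, giving the mean drift

    U_F = sign(∂T/∂x) · V · r (2 − r),   r = |∂T/∂x| / (∂T/∂x)_MAX  clamped to [0, 1],

where the identity `p_R · (∂T/∂x)_MAX = ξ_MAX` ties the noise half-width to
the gradient above which climbing is noise-free. The clamp is not cosmetic:
the raw quadratic is non-monotone above r = 1, while the model's own logic
(noise-free climbing above threshold, physiological speed cap) forces
`|U_F| = V` there. `walker_drift()` simulates the decision rule directly and
is the Monte-Carlo oracle for the closed form; the walker timestep Δτ never
enters the continuum equations.

Parameter defaults (no authoritative table is available; all overridable):
`V = 0.15 m/s` (a myctophid cruising at the order of body lengths per
second), `p_R = 100 m`, `(∂T/∂x)_MAX = 2 × 10⁻⁴ m⁻¹` (the mid-transition
gradient of a unit-level plateau with 5-km edges, hence `ξ_MAX = 0.02`),
ambient current `U_C = 0`, grid `dx = 100 m`, `dt = 200 s` (CFL number 0.3),
domains 60 km (8-km plateau) and 200 km (70-km plateau).

### Tracer geometry

`tracer_profile()` is a difference of two logistic ramps with scale
`k = transition_width/4` (so the mid-ramp gradient is exactly
`1/transition_width`) and ramp midpoints at
`±(plateau_width + transition_width)/2`. The midpoint placement matters:
with midpoints at ±plateau_width/2, 5-km ramps overlap the whole 8-km
"plateau" — the tracer is a dome, the drift is ≈ −V everywhere inside, and a
single central spike forms within hours, with no edge peaks at any time.
Placing the ramps outside the flat top reproduces the observed phenomenology
(edge peaks within hours, later merging). The optional central bump (the
plateau's local tracer maximum) defaults to a *gentle dome* — amplitude
0.02, width plateau/4. A sharp bump (e.g. amplitude 0.1 over 1 km) has a
central convergence e-folding time of ~2 h and dominates the entire solution
within a day, which the edge-peak phenomenology rules out; the gentle dome
marks the maximum without triggering central collapse on 4-day horizons.

### Numerics

`step_density()` advances the 1-D continuity equation with the Lax scheme,
`ρᵢ ← (ρᵢ₊₁+ρᵢ₋₁)/2 − dt/(2dx)(jᵢ₊₁−jᵢ₋₁)`, `j = ρ·U_F`: conservative
(periodic mass drift at machine precision), CFL-checked, with a fixed
far-field reservoir (`ρ = ρ0`, zero-gradient flux) as the default boundary —
an open-ocean supply of fish — and periodic available for conservation
tests. The scheme's numerical diffusivity `dx²/(2dt)(1−C²) ≈ 23 m²/s` at the
defaults is the main numerical artefact: it smears the forming edge peaks
and nudges the 4-day plateau-mean amplification (3.56 at the defaults, 3.49
when dx and dt are halved) and the edge-doubling time (6.2 h vs 6 h printed)
slightly beyond the printed bounds. We report the default-grid values rather
than tuning the grid to the bounds. Densities below −10⁻⁶ρ0 abort with a
resolution hint; tiny undershoots are clipped and counted. Peak counting
(`find_peaks()`) smooths over 3 cells and requires prominence ≥ 0.1·ρ0.

A robustness claim worth flagging: the edge-doubling time scales as 1/V, so
no parameterisation can both double "in about 6 hours" at the default V and
still double within 6 hours at half the cruising speed; the corresponding
acceptance clause fails at V/2 by construction, not by implementation error.

### The filament scenario

`filament_scenario()` evolves a Gaussian cross-filament tracer under
convergent strain `u = −γx` and diffusivity `D`. The 1-D cross-section of an
incompressible stretching flow obeys the *advective* form
`∂T/∂t = γx ∂T/∂x + D ∂²T/∂x²` (concentration conserved along trajectories;
the cross-front integral "lost" to along-front stretching), whose Gaussian
solution has `w(t)² = D/γ + (w0² − D/γ) e^(−2γt)` and amplitude eroded only
by diffusion. Numerically the strain step is an exact remap
`T(x) ← T(x·e^{γdt})` by cubic spline and diffusion is explicit — a plain
central-difference advection term grows a spurious tail mode at rate γ. The
numerical width tracks the closed form to ~10⁻⁴ relative. Fish density
co-evolves under the drift law alone (the ambient strain moves water, and
the tracer with it, but the model's fish respond only to the tracer; the
original sensitivity setup is not available to compare against). Defaults —
γ = 0.1 day⁻¹, D = 1 m²/s (equilibrium width √(D/γ) ≈ 0.93 km), initial
width 10 km, amplitude 1 — are Southern Ocean strain/mixing values chosen a
priori; a back-of-envelope estimate put the school life time (total duration
with max|∂T/∂x| ≥ (∂T/∂x)_MAX, criterion fraction configurable) near three
weeks before any code ran, inside the printed 7–25 day range, and the
computed value is ~21.5 days. With `D = 0` the gradient sharpens
monotonically and the lifetime saturates at the horizon; with γ = D = 0 the
run is flagged `no_erosion`.

## Known limitations

* The synthetic ocean is a stationary, spectrally naive stand-in; green
  statistics establish that the chain recovers a known generative law, not
  that real surveys would behave likewise.
* The OLS non-significance pattern of field data is structurally outside the
  exact-quantile generative law (see above).
* The movement model is one-dimensional, ignores diel vertical migration and
  zooplankton dynamics (the tracer is conserved), and treats schools as
  independent walkers; the Lax solver's numerical diffusion is the dominant
  discretisation artefact at the default grid.
* Quantile-slope inference uses the pair bootstrap throughout; rank-based
  inference is not implemented.
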