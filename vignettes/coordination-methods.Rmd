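---
title: "Coordinated C3 photosynthesis and the CO2 fertilization effect: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinated C3 photosynthesis and the CO2 fertilization effect: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coordphoto)
```

## What this package models

`coordphoto` is a desk-scale laboratory for one question: how strongly does
rising atmospheric CO2 stimulate gross primary production (GPP) when leaves
are allowed to re-balance their nitrogen investment between carboxylation
and electron-transport capacity? The package couples

* a Farquhar–von Caemmerer C3 leaf with temperature-dependent kinetics,
* a daily **coordination** optimization of the ratio `bJV = Jmax0/Vcmax0`
  under a conserved effective-nitrogen budget,
* a two-leaf (sunlit/shaded) toy canopy with a prognostic leaf-area pool
  and a one-pool ecosystem-respiration surrogate,
* a scenario runner with factorial driver experiments (CO2, temperature,
  precipitation) and a leaf-level/greening partition of the CO2 effect, and
* a seasonal-cycle toolkit: the residual ecosystem flux
  `Reco' = GPP − NLS`, its 25-member phase/amplitude perturbation ensemble,
  a one-box Northern-Hemisphere concentration surrogate, and the detrended
  max−min seasonal amplitude (ASC).

Everything is driven by a seeded synthetic forcing generator, so every
result in the package is a pure function of a configuration and a seed.

## The leaf model

Gross assimilation is the minimum of the Rubisco-limited and
electron-transport-limited rates,

$$A_c = V_{cmax}\,\frac{c_i - \Gamma^*}{c_i + K_m}, \qquad
  A_j = \frac{J}{4}\,\frac{c_i - \Gamma^*}{c_i + 2\Gamma^*},$$

with $K_m = K_c (1 + O/K_o)$ and $J$ the smaller root of the
non-rectangular hyperbola
$\theta J^2 - (\alpha I + J_{max}) J + \alpha I J_{max} = 0$.
Kinetic constants follow the Bernacchi et al. (2001) Arrhenius forms:

| constant | 25 °C value | activation energy (J mol⁻¹) |
|---|---|---|
| $\Gamma^*$ | 42.75 µmol mol⁻¹ | 37 830 |
| $K_c$ | 404.9 µmol mol⁻¹ | 79 430 |
| $K_o$ | 278.4 mmol mol⁻¹ | 36 380 |
| $V_{cmax}$ scaling | 1 | 65 330 |
| $J_{max}$ scaling | 1 | 43 540 |
| $R_d$ scaling | 1 | 46 390 |

with $O = 210$ mmol mol⁻¹, giving $K_m(25°C) = 710.3$ µmol mol⁻¹. The
capacity responses are plain Arrhenius (no high-temperature optimum); the
forcing generator keeps leaf temperatures below ~40 °C where deactivation
would matter. Mesophyll conductance is not represented: `Vcmax25` is the
effective capacity, as is standard when parameters are inferred from gas
exchange without a mesophyll term.

Two stomatal closures are available. The default is the slope-form coupled
model, equivalent to $c_i/c_s = g_1/(g_1 + \sqrt{D})$ with
$g_1 = 5.67\ \mathrm{kPa}^{0.5}$, chosen so that $\chi = c_i/c_s = 0.85$ at
1 kPa vapour-pressure deficit — the relatively high operating $c_i$ of a
coupled land-surface scheme. The alternative is a prescribed fixed
$\chi$ (0.80 by default), the configuration used for the
electron-transport-limited reference elasticities. The coupled closure is
solved by bounded fixed-point iteration on $c_i$ (tolerance $10^{-6}$
µmol mol⁻¹, 100 iterations maximum); with zero residual conductance it
converges in one step.

Co-limitation uses the exact minimum of $A_c$ and $A_j$ by default; a
quadratic smoothed minimum (curvature 0.99) is available through
`colimit_theta`, but all shipped diagnostics use the exact form because the
reference elasticity values are only reproducible without smoothing.

## Coordination: optimizing bJV under a nitrogen budget

Leaf nitrogen available to the photosynthetic machinery is summarized by
the conserved quantity

$$N_{eff} = V_{cmax,0} + c_{cost}\,J_{max,0},$$

and at the end of each simulated day the ratio `bJV` is chosen to maximize
the photosynthesis that the leaf *would have accumulated* over the previous
five days of sub-diurnal meteorology (the approximate turnover time of
photosynthetic nitrogen), per unit $N_{eff}$:

1. a ring buffer keeps 5 days of sub-diurnal leaf environments for the
   sunlit and shaded classes (absorbed PAR, leaf temperature, VPD, CO2,
   sunlit fraction, stress weight);
2. for a candidate `bJV`, the implied capacities are
   $V_{cmax,0} = N_{eff}/(1 + c_{cost}\,b_{JV})$,
   $J_{max,0} = b_{JV} V_{cmax,0}$, applied to every record;
3. a 9-point bracketing scan plus golden-section refinement finds the
   maximizer over $b_{JV} \in [0.5, 5]$ to a tolerance of $10^{-4}$;
   plateaus and boundary optima return the boundary value, and a
   non-unimodal scan (never observed in practice) falls back to a dense
   grid with a warning.

The optimization is on gross accumulated photosynthesis by default
(switchable to net): day respiration is proportional to `Vcmax0` and so
nearly cancels in the comparison across candidate ratios. The history is
prefilled with the first forcing day and the first optimization happens at
day 5; under stationary forcing the update is at its fixed point after a
single optimization, and the 30-day spin-ups used in the experiments leave
a per-day `bJV` drift below $10^{-3}$.

The single free constant $c_{cost}$ was calibrated once, in closed form
(`analysis/00_calibrate_cost.R`): at the co-limitation point the
nitrogen-constrained elasticity is the convex combination
$(1-w)\beta_{A_c} + w\beta_{A_j}$ with
$w = 4 c f_c / (f_j + 4 c f_c)$, and $c_{cost} = 0.746$ puts the
coordinated elasticity at 0.56 for 400 ppm, $\chi = 0.85$, 25 °C. The same
constant gives an equilibrium `bJV` of 1.67 under the temperate diurnal
forcing preset, inside the observed range of Jmax:Vcmax ratios.

A consequence worth knowing: at the optimum the bright hours of the day sit
essentially *on* the $A_c = A_j$ crossing. The robust way to diagnose
emergent co-limitation is therefore the growth-condition mean ratio (the
assimilation-weighted means of the two rates, `ratio_growth` in
`colimitation_summary()`), which is 1.01–1.07 across the five biome
presets. A naive partition of assimilation by which rate is the lesser is a
knife-edge classification for exactly those records that matter most, and
its ratio is correspondingly unstable; both are reported.

## Elasticity diagnostics

The dimensionless elasticity $\beta = (\partial A/\partial c)(c/A)$ is
evaluated as a central finite difference of $\ln A$ against $\ln c_s$ with
a ±1 µmol mol⁻¹ step — small enough for three-digit elasticities, far above
float noise. With a `coordination_state` supplied, the capacities are
re-optimized at each perturbed concentration under fixed $N_{eff}$, which
is what makes the coordinated $\beta$ exceed the fixed-capacity one: the
nitrogen constraint converts part of the Rubisco-limited sensitivity into
realized sensitivity. The leaf model has no boundary layer, so $c_a$ and
$c_s$ coincide and the `mode` field is a label.

`beta_table()` evaluates three regimes at 25 °C: coordinated (coupled
stomata), electron-transport-limited with coupled stomata (`bJV = 1.3`,
`Vcmax25` × 1.25 — the coordination-disabled configuration), and
electron-transport-limited with fixed $\chi = 0.8$. With the shipped
constants the 400→800 ppm pairs are 55.5→32.5%, 34.5→17.9% and
36.5→18.9%.

## Canopy, leaf area and the ecosystem pool

Incident PAR is split by Beer's law with extinction coefficient 0.5 (beam
path stretched by the solar zenith), PAR albedo 0.05, and a fixed diffuse
fraction 0.3 penetrating with the unprojected coefficient; the sunlit LAI
fraction follows $(1-e^{-kL/\cos z})\cos z/(kL)$. Daily NPP is a fixed
half of GPP; a fraction `allocation_fraction` of NPP builds leaf carbon,
which turns over at `leaf_turnover` into a single decomposing ecosystem
pool respiring at `reco_base_rate`·Q10^((T−25)/10) with Q10 = 2. The net
land sink proxy is `NLS = GPP − Ra − Rh`, and carbon is conserved exactly
at every step. Soil moisture enters only as a multiplicative stress factor
equal to the smooth [0, 1] soil-water index of the forcing — linear in the
bucket index, applied to assimilation and to the coordination weights.

The leaf-level component of a CO2 experiment is accumulated during the run
as the *exact* difference between assimilation at the actual and at the
baseline-year CO2 with every other element of the state held fixed — the
secant form of $\partial A/\partial c_s \cdot \Delta c_s$ evaluated over
the actual increment, with $\Delta c_s$ referenced to the first scenario
year. The secant (rather than a local derivative times $\Delta c_s$) makes
two identities exact by construction: leaf-level + greening = total CO2
effect, and greening = 0 when leaf area and capacities are frozen.

## Synthetic forcing and the toy globe

The weather-generator surrogate produces 3-hourly meteorology per cell:
PAR from solar geometry times an AR(1) daily cloud transmission in
[0.35, 0.85]; air temperature as a diurnal sinusoid around a seasonally
varying daily mean with AR(1) daily anomalies (sd 1.5 °C); relative
humidity with small AR(1) noise, from which VPD is recomputed whenever a
temperature anomaly is applied; and an AR(1)-plus-base soil-water index.
A recycled block (default 5 years) underlies all scenarios; annual driver
tables add a linear warming trend plus AR(1) interannual temperature
anomalies (sd 0.3 °C) and multiplicative precipitation factors (sd 0.08)
only when the scenario varies that driver, mirroring the
recycled-meteorology factorial design. Leaf temperature equals air
temperature.

The default toy globe has 20 equal-area cells drawn evenly from five biome
presets (tropical, temperate and boreal forest, semiarid, grassland) with
latitudes sampled per preset. Equilibrium leaf-area indices range from
~0.6 (semiarid) to ~6 (tropical). What the generator does *not* emulate:
real geographic area weights, cloud–radiation coupling, rainfall events
(only a smooth bucket index), nutrient cycles, disturbance and land-use
change. Passing tests therefore demonstrate the mechanisms and their
relative magnitudes at toy scale, not a calibrated reproduction of the
observed global carbon cycle.

## Experiments and reference magnitudes

* **Acclimation.** Equilibrating the coordination update under a repeating
  temperate diurnal cycle and stepping CO2 gives a 17% decline of
  Vcmax/Jmax for 400→600 ppm and an 11% decline of Vcmax for 366→567 ppm —
  the field-experiment-scale downregulation of Rubisco capacity.
* **Historic CO2-only run.** On the default toy globe the CO2-driven GPP
  increase splits 73% leaf-level / 27% greening.
* **Doubling run.** The constant-climate 300→600 ppm ramp (5-year plateaus
  at both ends so the first/last 5-year averaging windows sample the
  endpoints exactly) raises toy-globe GPP by ≈62%. This is higher than the
  ≈47% a full land-surface model produces, and deliberately left so: the
  equal-weight toy gives warm cells a large GPP share, and leaf kinetics
  make $\beta$ much larger at 30 °C than at 25 °C
  ($\beta_{A_c}(c_i{=}347)$ is 0.95 at 30 °C versus 0.82 at 25 °C), while
  the sparse-canopy presets sit in the steep part of the light-capture
  curve where the greening feedback amplifies relative change (the
  semiarid preset most of all). Re-weighting the globe to damp this would
  be curve-fitting, so the number stands as an honest toy-scale
  overestimate; the *contrast* that matters — coordination versus the
  electron-transport-limited configuration — is preserved
  (`analysis/04_doubling.R`).
* **Seasonal cycle.** The 25-member ensemble perturbs the phase (±14 days,
  by circular daily interpolation within each year on an internal 360-day
  calendar — a sub-monthly shift cannot be an index shift) and the
  amplitude (±20%, scaling the anomaly about each year's mean, the only
  formulation that leaves "amplitude" well-posed under conservation) of
  `Reco'`, restoring each year's total exactly by a uniform additive
  rebalance. The one-box surrogate `dC/dt = −F/κ − (C−C_bg)/τ` uses
  κ = 2.124 PgC ppm⁻¹ and τ = 24 months; it is linear, so the detrended
  amplitude responds exactly proportionally to flux-anomaly scaling.
  Detrending is per-epoch; member selection uses a single box (one
  "station").

## Numerical choices and degenerate inputs

* Finite-difference step for $\beta$: ±1 µmol mol⁻¹; optimizer tolerance
  $10^{-4}$ on `bJV`; ci solver tolerance $10^{-6}$ µmol mol⁻¹.
* Exact-min co-limitation everywhere a reference value is computed.
* Dark steps (zenith ≥ 90° or zero PAR) produce exactly zero absorbed PAR
  and zero assimilation; empty canopies absorb nothing (guarded
  denominators with vanishing numerators).
* Flat coordination objectives (e.g. all-dark histories) return the upper
  boundary by the tie rule; ties are resolved to a boundary whenever the
  scan endpoints are within $10^{-9}$ (relative) of the refined optimum.
* The spin-ups used are: 10 years for the toy-globe scenario runs (the
  leaf pool equilibrates in ~3–5 years; a constant-CO2 control shows a GPP
  trend of 0.3 ± 1.0 gC m⁻² yr⁻² afterwards), 30 days for leaf-level
  coordination equilibria. Problem sizes (20 cells, 80–111-year spans,
  3-hourly steps) were chosen so each experiment completes in minutes on a
  single CPU.

## Known limitations

Single effective big-leaf pair per cell; no phenology beyond the leaf
pool; no nutrient feedbacks (the nitrogen budget is leaf-internal); the
stress factor is not coupled to transpiration, so sparse canopies lack the
water ceiling that would damp their greening response; Arrhenius-only
capacity scaling; one-box transport. Each of these is a deliberate
surrogate for machinery that a full terrestrial biosphere model carries
and this package intentionally does not.
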