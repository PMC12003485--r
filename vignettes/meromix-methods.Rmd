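---
title: "Methods: stability, layer detection, gating and seasonal aggregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stability, layer detection, gating and seasonal aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meromix)
```

meromix implements the computational chain used to monitor a small alpine
meromictic lake: standardising CTD casts, converting temperature and
conductivity into density and water-column stability, locating the
bacterial layer (BL) of anoxygenic phototrophic sulfur bacteria from
turbidity, enumerating the three phototroph phenotypes by flow cytometry,
and summarising the meteorological context. This vignette explains each
model, its assumptions, the tunable parameters, and the numerical and
design choices behind them.

## CTD profiles

A cast is a tibble with one row per depth and canonical columns
(`depth_m`, `temp_c`, `cond_raw_uScm`, `k20_uScm`, `do_mgL`, `turb_ftu`,
`bgapc_ppb`, `par`). Optional channels are simply absent when a sensor was
not fitted or broken — absence propagates through the pipeline rather than
being imputed, which mirrors how instrument outages appear in real
multi-year records.

Ingestion (`parse_ctd_table()`) sorts by depth and averages duplicate
depths, so a shuffled export and a sorted one give the same profile. Casts
that mix down- and up-cast samples can instead be trimmed to the leading
monotone segment with `downcast_only = TRUE`; trimming is not the default
because it would discard data from files whose row order is merely
scrambled. When the instrument reports pressure, depth is derived as
`0.010197 m per mbar` of excess pressure over the shallowest sample — the
freshwater hydrostatic conversion with g = 9.81 m s⁻²; the surface offset
defaults to the cast's minimum pressure because alpine-station barometric
pressure varies from day to day.

Conductivity is normalised to a 20 °C reference with the linear
compensation model `κ₂₀ = κ_T / (1 + α_t (T − 20))`, α_t = 0.020 °C⁻¹ by
default. Probe firmwares differ in the exact compensation they apply and
the coefficient is rarely documented, so α_t is exposed as an argument;
2 %/°C is the common limnological default and is exact at the reference
temperature regardless of its value.

Quality control (`qc_and_regrid()`) applies a running-median despike
(window 5 samples; a single-sample spike cannot survive) and linear
interpolation onto a uniform grid, 0.1 m by default — the spacing the
stability quadrature assumes. No extrapolation is performed beyond the
observed depth range; boundary handling is deferred to the stability step
where it is flagged.

## Density and Schmidt stability

Density is `ρ_w(T, S) = ρ′_w(T) + β S` with the cubic
`ρ′_w = 999.84 + 6.55×10⁻² T − 8.56×10⁻³ T² + 5.94×10⁻⁵ T³` (kg m⁻³) and
salinity `S = α κ₂₀`, α = 0.72×10⁻³ kg m⁻³ (µS cm⁻¹)⁻¹ — an ion-specific
calibration for a sulfate/bicarbonate-dominated crenogenic basin. The
cubic's maximum sits at 3.99 °C, the familiar density maximum of fresh
water, which the tests verify by brute-force scan.

One unit subtlety deserves a paragraph. The haline contraction coefficient
is conventionally quoted as 0.96×10⁻³ kg g⁻¹. With S expressed in kg m⁻³
(equivalently g l⁻¹), the dimensionally consistent multiplier is the
dimensionless 0.96, and that is the default: it yields a density excess of
β·α·κ₂₀ ≈ 0.28 kg m⁻³ across a 400 µS cm⁻¹ chemocline — the right scale to
sustain meromixis. Taking the literal 0.96×10⁻³ against S in kg m⁻³ would
make the salinity term ~10⁻⁴ kg m⁻³, physically negligible; both readings
are available through `density_params(beta = ...)` so the choice is
auditable rather than buried.

Schmidt stability is evaluated as

\[ \mathrm{Sc} = \frac{1}{A_o} \int_0^{z_{bot}} g\, \rho_w(z)\,(z - z_v)\,
   A(z)\, dz \]

by composite trapezoid on a 0.1 m grid — deliberately no higher-order
scheme, so the quadrature can be checked against closed forms: a two-layer
step in a box lake gives `g Δρ h₁ h₂ / 2` (647.46 J m⁻² for Δρ = 1.2,
h₁ = 10, h₂ = 11 m) and a linear gradient gives `g Γ H³ / 12`
(757.09 J m⁻² for Γ = 0.1 kg m⁻⁴, H = 21 m); the trapezoid error on the
linear oracle decreases by exactly 4× per grid halving.

Two `z_v` conventions are provided. `as_printed` (default) uses a fixed
reference depth, 5.3 m — the published centre-of-volume depth of the
basin — and reproduces the stability formula exactly as practitioners
print it. When the fixed value is not the discrete centre of volume of the
hypsometry actually used, the full density (not only its anomaly)
contributes to the integral, which can dominate the result; this is a
property of the convention, not a bug, and the companion `anomaly` mode
recomputes `z_v` on the quadrature grid, making Sc exactly invariant to
`ρ → ρ + c` and non-negative for stable profiles. The headline multi-year
stability of ~175 kJ m⁻² reported for the real lake arises in the
`as_printed` convention with the measured hypsometric curve and its
associated `z_v`; reproducing that number requires those deposited data,
so the package's tests anchor on the closed-form oracles and on the
convention-equivalence property instead.

Boundary handling: casts rarely reach exactly 0 or `z_bot`, so the
shallowest/deepest densities are extended as constants to the integration
limits and the result carries an `extrapolated` flag.

When no measured area–depth curve is available, a power-law stand-in
`A(z) = A_o (1 − z/z_bot)^q` is provided; its centre of volume has the
closed form `z_bot/(q+2)`, and `q = 1.96` reproduces the published 5.3 m
for a 21 m basin. Defaults `A_o = 0.23 km²` and `z_bot = 21 m` follow the
stability formula's stated constants; the site's morphometric table lists
261,000 m² and 21.5 m, and both alternatives are plain arguments.

## Bacterial-layer detection

The BL is the maximal contiguous depth interval with turbidity strictly
above 10 FTU. Boundaries are refined by linear interpolation of the
threshold crossing between the bracketing samples, which makes top, bottom
and thickness insensitive to the sampling grid (a 0.2 m chemocline
sampling interval would otherwise quantise thickness in 0.2 m steps).
When several intervals exceed the threshold, the one containing the global
turbidity maximum is chosen — the layer is a single feature, and the
strongest peak is it; a `deepest` tie-break is available by argument. A
minimum thickness of 0.1 m discards single-sample spikes that despiking
missed. How boundary interpolation and minimum thickness should be done is
not fixed by field convention; both choices are exposed and documented
here as this package's own.

The five sampling depths follow mechanically from the detected interval:
1 m above the top, the top, 50 cm below the top, the bottom, and 1 m below
the bottom, clipped to the water column with a flag when clipping occurs.

Isotherm depth (shallowest interpolated crossing of a target temperature,
e.g. the 10 °C and 5 °C lines drawn on seasonal sections) and oxycline
depth (shallowest drop of dissolved oxygen below 0.5 mg l⁻¹ — a
configurable convention, since no standard threshold exists) use the same
crossing machinery. Seasonal series keep casts without a detected layer as
gap rows so the time base stays complete, and record whether the layer
bottom sits above the 13.5 m reference horizon.

## Flow-cytometry gating

Acquisition thresholds are strict inequalities — FSC-H > 2000 excludes
abiotic particles, FL3-A > 1100 keeps only (bacterio)chlorophyll
autofluorescent cells — matching the instrument's "greater than"
semantics. Phenotype classification is one-dimensional size gating on
log10(FSC-A) with two cuts (defaults 4.5 and 5.5, left-closed intervals):
below the first cut GSB (< 1 µm cells), between the cuts small-celled PSB
(~4 µm), above large-celled PSB (~10 µm). A 1-D gate was chosen because
size ordering is what separates these phenotypes once the red-fluorescence
threshold has removed everything non-phototrophic; the cuts are config
parameters, and the synthetic generator places its clusters at log10
means 4, 5 and 6 (sd 0.1) — 5σ from the cuts, so misclassification is
essentially impossible and recovery tests have sharp expectations. Events
with FSC-A = 0 cannot be placed on a log scale; they are flagged, excluded
from counts and tallied.

Concentration is `count / acquired volume` (cells ml⁻¹); the acquired
volume is a required input because it is an instrument run parameter, not
derivable from events. Layer summaries are the arithmetic mean and the
sample standard deviation (n − 1) over the three in-layer positions; the
flanking positions are reported but excluded from the layer mean.

## Meteorological aggregation

Monthly summaries work on the native record cadence (typically 10 min):
temperature mean and sd, net radiation integrated as Σ(W m⁻² × interval
seconds) → J m⁻², rainfall totals in mm. A month with fewer than half its
expected records is flagged `low_coverage` rather than dropped — a failed
pyranometer should be visible, not silently absent. Resampling to coarser
windows (8 h, daily) uses block means for intensive quantities and block
sums for rainfall, so monthly totals are invariant to the window; a
cumulative-rainfall column accompanies the output for storm-event plots.

The interannual trend is ordinary least squares of annual mean temperature
on calendar year — a descriptive trend line (≥ 3 years required), not a
climate attribution model. The fitted object supports `tidy()` and
`glance()`.

Historical tables extract per-cast surface values (mean over the
shallowest 0.5 m) and bottom values (mean over the deepest 1 m); the
windows are robustness choices — probes rarely start exactly at 0 m — and
are arguments. Bottom hydrogen sulfide is the mean of observations between
18 and 20 m inclusive; sulfide is ingested as data, never computed.
Per-cast rows aggregate to yearly mean ± sd with `summarize_yearly()`,
which supports both single-visit years and multi-cast seasons.

## The synthetic generator

`gen_ctd_profile()` builds casts from logistic (sigmoid) transitions for
temperature, κ₂₀ and dissolved oxygen — smooth chemocline transitions with
no published functional form, so the simplest saturating curve is used —
plus a Gaussian turbidity peak (baseline 1 FTU) for the BL and optional
Gaussian channel noise. Scenario defaults describe a mid-summer alpine
meromictic basin: 15 °C over 4 °C, κ₂₀ 150 → 400 µS cm⁻¹ across a
chemocline at 11 m, oxygen 8 mg l⁻¹ vanishing below ~10 m, a 24 FTU peak
at 13 m with σ = 0.5 m. These are testing conditions chosen to match the
phenomenology of such lakes, not measured facts about any particular one.

`gen_season()` drifts the layer centre and width linearly across a season
(default: sinking 1.5 m, thinning from σ 0.5 to 0.35 m — the canonical
late-summer pattern) and returns the exact analytic > 10 FTU crossings as
ground truth. `gen_fcm_events()` allocates events multinomially among the
three phenotype clusters and debris, with debris drawn strictly below both
acquisition thresholds so retention tests have exact binomial
expectations. `gen_meteo()` produces a seasonal temperature sinusoid plus
linear trend (default 0.0325 °C yr⁻¹) with AR(1) noise, Poisson storm
arrivals with gamma rainfall depths, and a clear-sky radiation cycle
damped on storm days. All generators are bit-reproducible for a fixed
seed.

What the generators do *not* emulate: sensor drift and lag, thermal-mass
artefacts, internal waves and bioconvective fine structure, double peaks
in turbidity, non-Gaussian cytometry tails, and weather regime changes.
Passing tests therefore demonstrate that the algorithms recover known
structure exactly as specified, not that they are robust to every artefact
of real instruments.

## Problem sizes and Monte-Carlo choices

Tests run casts of 211 samples (0.1 m over 21 m), seasons of 5–10 casts,
event tables of 3,000–10,000 events, and a 200-seed trend Monte-Carlo on
35 annual means — sizes at which every analytic expectation used in the
tests is sharp. The trend Monte-Carlo uses `gen_annual_means()` (truth
line + N(0, 0.2 °C) annual noise) rather than 200 full 35-year 10-minute
weather series, because the OLS-recovery property being tested lives
entirely at the annual-mean level; `gen_meteo()` is separately exercised
at daily cadence over 35 years to show the same slope emerges from a
full series.

## Known limitations

* The κ₂₀ compensation model is linear; probes applying nonlinear
  firmware compensation will differ slightly away from 20 °C.
* `as_printed` stability depends on the supplied hypsometry through both
  `A(z)` and the mismatch between the fixed `z_v` and the true centre of
  volume; comparisons across hypsometries should use `anomaly` mode.
* Gating is 1-D; populations overlapping in size but separable in
  fluorescence would need the two-channel extension.
* Monthly coverage flags use the median record interval to estimate the
  expected count; series with changing cadence inside a month will
  mis-estimate coverage.
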