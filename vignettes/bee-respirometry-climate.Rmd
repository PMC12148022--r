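---
title: "Metabolic rate, gas-exchange frequency and climate: methods and design"
author: "beephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic rate, gas-exchange frequency and climate: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beephys)
```

## The scientific question

Two long-debated hypotheses link insect physiology to climate. The
*metabolic cold adaptation* (MCA) hypothesis predicts that ectotherms from
cold environments evolve higher temperature-specific metabolic rates, to
compensate for the slowing of biochemical reactions in the cold. The
*hygric* hypothesis predicts that dry environments favour discontinuous
gas exchange (DGC) — the alternation of spiracle-closed breath-holds and
brief CO2 bursts — and, by extension, lower frequencies of gas exchange
(FGE), because keeping the spiracles shut limits respiratory water loss.
The two traits are physiologically coupled (FGE rises with metabolic
rate), so `beephys` treats them jointly: it derives both traits from
flow-through respirometry traces, joins site climate, compares *a priori*
model sets for each hypothesis by AIC, and asks whether the FGE~MR
relationship itself shifts along the climate gradient.

The intended setting is an altitudinal gradient on a tropical island:
sixteen collection sites spanning roughly 0–1100 m, a rain shadow
splitting them into a wet and a dry side, highlands about 5°C cooler and
about 100 mm per month wetter than the lowlands, and four bee species
measured on a seven-channel respirometry system at 25°C.

## From CO2 trace to traits

Each recording contains a pre- and post-measurement empty-chamber
baseline segment and a measurement window during which one bee sits in a
chamber flushed at a known flow rate.

1. **STP flow correction** (`flow_to_stp()`): the volumetric flow is
   referenced to 0°C and 101.3 kPa and discounted for water-vapour
   dilution, `FR·(273.15/(273.15+T))·(P/101.3)·(1−f_H2O)`. The exact
   form of the vapour correction used in the original protocol is not
   documented; this standard dilution factor is applied only when
   ambient metadata are supplied.
2. **Drift correction** (`fit_baseline_drift()`): an ordinary
   least-squares line through the pooled baseline samples estimates the
   incurrent concentration Fi(t) at any time; analyser drift is assumed
   linear, matching the linear model used in the field protocol.
3. **Settling trim** (`trim_settling()`): the first and last 10 min of a
   60 min recording are discarded by default.
4. **Cycle detection** (`detect_cycles()`): no published algorithm
   exists for this step, so the package defines one and exposes every
   constant in `resp_opts()`. The baseline-subtracted signal is smoothed
   with a centred 5 s moving mean; the burst threshold is
   `max(3 × MAD of the interburst residuals, 10% of the 95th-percentile
   excess)`; a burst must exceed that threshold for at least 5 s
   (so noise blips that merely graze it are rejected), ends by
   hysteresis at half the threshold, and bursts separated by less than
   10 s are merged. Two guard rails matter in practice: a trace whose
   95th-percentile excess is below `min_amplitude_ppm` (1 ppm, the
   order of an infrared analyser's noise floor) is classed "no DGC"
   rather than mined for bursts, and a burst already under way at the
   analysis-window edge is dropped because its apparent onset lacks the
   washout latency of interior bursts and would bias cycle spans.
5. **Metabolic rate** (`compute_vco2()`): the pointwise rate
   `FR·(Fe−Fi)/(1−Fe)` (fractional concentrations) is averaged over the
   first seven complete cycles. Negative instantaneous values are kept —
   clipping them would bias the mean upward — and only a negative window
   mean is flagged.
6. **Frequency of gas exchange** (`compute_fge()`): `k / span` in
   min^−1. The protocol's wording, "start of the first breath until the
   end of the seventh breath", omits the final interburst pause and so
   slightly overestimates frequency. The default (`fge_mode = "period"`)
   therefore measures from burst 1's start to burst 8's start — exactly
   seven full cycle periods — and falls back to the strict wording when
   no eighth burst exists; `fge_mode = "span"` reproduces the strict
   definition throughout. This choice is deliberate and documented
   because the published definition is ambiguous.

Records with fewer than seven complete cycles are excluded by default
(flagged, not erred); `require_k = FALSE` accepts three or more with a
quality flag.

## Climate variables

Saturated vapour pressure uses the Tetens relation
`SVP = 0.61078·exp(17.27·T/(T+237.3))` kPa. The original analysis cites
an external meteorological source for its SVP equation without printing
it; Tetens is the standard member of that family, and the constants are
arguments so a Magnus variant can be swapped in. Vapour pressure deficit
is `SVP − VP`, floored at zero with a warning: monthly climatological
means can place VP above SVP at the coldest-month temperature, and a
negative drying power is not physically meaningful for these hypotheses.

## Hypothesis sets and model comparison

`build_mca_set()` and `build_hygric_set()` each return five models —
T_min, P_dry, VPD, T_min+P_dry, and an altitude-only null. Climate
variables are never mixed beyond T_min+P_dry because they are strongly
collinear along an altitudinal gradient (`compute_vif()` implements the
usual screen). Every model includes log10 body mass; FGE models add
log10 metabolic rate; multispecies scope adds species and its
interactions with mass (and with MR for the FGE set). Measurement block
and analyser channel are crossed random intercepts throughout.

Fitting uses `lme4` with Gaussian responses. Metabolic rate and mass are
log10-transformed; FGE is left untransformed (the published coefficients
are consistent with an untransformed response, and both conventions can
be run by transforming the column). Comparison uses full maximum
likelihood by default because the candidate models differ in fixed
effects; REML is available, and the benchmark tests try both since the
original report does not state which produced its tables. AIC is
`−2·logLik + 2·k` with `k` counting fixed coefficients plus variance
parameters; Akaike weights are `exp(−Δi/2)` normalised; marginal R² is
the variance of the fixed-effect predictor over the sum of that
variance, the random-intercept variances and the residual variance.
Reported denominator degrees of freedom use a containment-style
approximation, `n − (total random-effect levels) − (fixed
coefficients)`; p-values on those df are approximate, as they always are
for mixed models. Singular fits (a variance component estimated at zero)
are legitimate boundary solutions and stay in the ranking; only genuine
optimizer failures are excluded, with a warning.

Missing data are dropped once, over the union of all columns any model
in a set uses, so every AIC in a table refers to identical rows.

## Trait covariation across species

`species_slopes()` fits, per species with at least 10 individuals,
`FGE ~ log10 MR + log10 mass + (1|block) + (1|channel)` and keeps the MR
coefficient and its standard error. `slope_climate_set()` then compares
five ordinary regressions of those slopes on species' mean climates.
Species' climates are collection-weighted means (each bee contributes
its site), matching a "mean collection altitude" design; a per-site
unweighted option exists. The second stage is unweighted by default — a
`1/se²` weighting is available but off, since the design being emulated
did not weight. With four species these regressions have one or two
residual degrees of freedom; they remain well-defined and their AICs
finite, but the fragility is real and `rank_flag` marks any model with
no residual df at all.

## What the simulators generate, and why

The test surface rests on two generators with known truth.

**Traces** (`simulate_trace()`): square-wave spiracle openings (duty
cycle `burst_fraction`) convolved with first-order chamber washout
(`washout_tau`, default 15 s), a linearly drifting baseline, and
additive Gaussian ppm noise. The washout ODE is integrated exactly over
each sampling interval, so the simulated excess CO2 integrates to
`true_vco2 × time` by construction — the conservation oracle the trace
pipeline is tested against (recovery within 0.1% on noiseless traces;
the only leakage is the washout tail at the record end, of order
`tau × final excess`). Burst shape, washout and the noise model are the
package's own design: the field protocol describes none of them, and
this is the simplest construction that produces realistically rounded
bursts. A cycle-period jitter parameter exists but defaults to zero
because within-individual period variability is unreported; nothing in
the suite depends on its magnitude.

**Trait tables** (`simulate_trait_table()`): the generative model is
exactly the model the inference module fits — log10 MR linear in log10
mass (0.76), T_min (−0.041 per °C) and P_dry (−0.002 per mm), with
block, channel and residual Gaussian components; FGE built from log10 MR
with species-specific slopes plus its own random structure. Sites follow
`simulate_climate_gradient()`: temperature and precipitation are exact
linear functions of altitude per side (lapse −0.005°C/m, gain
0.1 mm/m, a 60 mm rain-shadow offset), and per-site relative humidity
scatters (SD 0.08) around side levels of 0.85 (wet) and 0.70 (dry).
That humidity scatter deserves a note: without it, VPD would be an
exact function of temperature and side, making the T_min+P_dry and VPD
hypotheses nearly indistinguishable by AIC — a degeneracy no measured
climatology exhibits. Its default was fixed once, together with the
variance components (block 0.06, channel 0.04, residual 0.105 on log10
MR, giving a marginal R² near 0.5 for the best model at the default
design), and with FGE-model SDs (block 0.05, channel 0.03, residual
0.05) and species slopes (0.95, 0.67, 0.40, 0.12 from lowland to
highland) spaced so that per-species slopes are estimable — and their
rank order recoverable — at field-realistic sample sizes of 16–45 bees
per minor species.

What the generators do **not** emulate: activity artifacts, temperature
ramps, O2 or H2O channels, multi-modal cycle periods, non-Gaussian
analyser noise, spatially structured climate error, or collinearity
between mass and sex. Passing tests therefore demonstrate that the
algorithms recover known structure under the stated assumptions, not
that field data meet those assumptions.

## Problem sizes and runtime choices

The test suite works at the field design (16 sites × 13 bees = 208
rows, 4 species, 10 blocks, 7 channels) for parameter-recovery loops —
100 replicates for fixed-effect coverage and model ranking, 20 for
slope rank order — and at a reduced 8 × 12 design for structural
checks. Traces for oracle tests are 25–60 min at 1 Hz. These sizes were
chosen so the full suite completes in well under a minute per property
while still operating at the sample sizes whose statistical behaviour
is being claimed.

## A worked example

```{r example, eval = FALSE}
params <- trait_sim_params(seed = 1)
sites  <- simulate_climate_gradient(params)
tab    <- simulate_trait_table(params, sites)

compare_models(build_mca_set("multispecies"), tab$traits)

slopes <- species_slopes(tab$traits)
slope_climate_set(slopes)
```

## Known limitations

* Degrees of freedom and p-values use a containment approximation;
  packages disagree on mixed-model df, and AIC-based ranking (the
  primary inferential tool here) does not depend on them.
* The burst detector is threshold-based; traces whose interburst
  baseline wanders nonlinearly faster than the linear drift model can
  absorb will need the detection constants adjusted via `resp_opts()`.
* The second-stage covariation regressions inherit the fragility of
  n-of-species sample sizes; treat their R² values as descriptive.
* Benchmarks against the published field tables require the original
  supplementary trait table, which is not redistributable here; the
  corresponding tests document the expected surface and run whenever
  that file is installed under `inst/extdata/`.
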