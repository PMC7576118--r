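---
title: "Methods: camera-trap distance sampling in ctds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: camera-trap distance sampling in ctds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctds)
```

## The estimator and its assumptions

`ctds` treats each camera trigger opportunity as one point-count sample
of a wedge of angle θ around the camera, truncated at radius *w*. The
estimator stack is conventional point-transect distance sampling:

* detections decline with radial distance according to a detection
  function g(r) with g(0) = 1;
* observed radial distances have density f(r) = r·g(r) / ∫₀ʷ u·g(u) du
  (the annulus availability 2r/w² weighted by g);
* density is D̂ = n / (S · a0 · p̂) with a0 = (θ/360)·π·w² the wedge
  area, S the summed snapshot count and p̂ = (2/w²)∫ r·g(r) dr.

The assumptions this inherits: animals at distance zero are detected
with certainty; distances are measured without systematic error; the
population is closed over the survey period; animals are available for
detection during — and only during — the diel availability window; and
snapshots are far enough apart that a detection does not change
subsequent behaviour. Temporal autocorrelation between snapshots does
not bias the point estimate (counts and effort both accumulate), but it
does inflate the between-camera variance, which is why the variance is
estimated empirically across cameras rather than from a Poisson
assumption.

## Parameters that matter

| parameter | unit | default | role |
|---|---|---|---|
| t | s | 15 | snapshot interval; effort = operating seconds / t |
| θ | degree | 50 | camera field of view; scales effort and wedge area |
| w | m | 40 | truncation radius; default is the maximum observed distance per stratum |
| α | — | 0.1 | study-wide error rate: 90% intervals and GOF gate p ≥ 0.1 |
| window | — | sunrise − 1 h → sunset + 2 h | diel availability for a diurnal species |
| A | km² | 6.2 | area to which density is expanded |

Timestamps are local standard time under a fixed UTC offset; no
daylight-saving shifts are applied, because field cameras keep a fixed
clock. Availability windows are computed per day from the NOAA
solar-position equations (a monthly-midpoint convention would differ by
at most a couple of minutes per day; the daily computation is the finer
of the two and is what `censor_records()` uses). Snapshot counts are
kept real-valued: effort is a rate denominator, not an event count.

## Detection fitting numerics

* Free parameters are optimized on an unconstrained scale (log σ, log b,
  raw adjustment coefficients) by BFGS, with a multi-start over
  σ₀ ∈ {sd(r)/2, sd(r), 2·sd(r)}.
* The likelihood of adjusted models is unbounded in corners of the
  parameter space where g develops a spike (the classic pathology of
  series adjustments). Rather than constrain the optimizer, any fit
  whose g is negative or non-monotone on a 100-point grid is flagged
  `rejected` and excluded from model selection — simpler, and
  reproducible.
* Distances of exactly zero would contribute −∞ through f(0) = 0; they
  are offset to 0.25 m, half the 0.5 m field measurement resolution,
  and counted in `zero_offset_n`.
* `var(p̂)` comes from the delta method with a numerical Hessian; the
  half-normal closed form for p̂ is required (and tested) to agree with
  the quadrature to 1e-6.
* Ties in AIC are broken by fewer parameters, then lexicographic key
  name, so ranking is deterministic.

## Goodness of fit

The χ² test bins distances into 5 equal-width bins by default (matching
how camera-trap distance data are usually histogrammed), merging
rightmost bins until every expected count reaches 5; degrees of freedom
are bins − 1 − parameters, floored at 1. With steeply declining
detection and modest n, the rightmost merged bin can stay below an
expected count of 5 — the result is then flagged not computable, and the
model-selection gate treats it as unassessed rather than failed (a model
cannot be rejected by a test that could not run). The gate itself
excludes models with GOF p < α before ΔAIC is computed, so a
well-fitting model is never shadowed by a poorly fitting one with lower
AIC.

## Variance, intervals, degrees of freedom

The encounter-rate variance is the effort-weighted between-camera
estimator var = K/(K−1) · Σ e_k²(n_k/e_k − rate)² / (Σe_k)², df = K − 1.
The total CV adds the detection CV in quadrature. Intervals are
log-normal, C = exp(t_{1−α/2,df}·√log(1+cv²)), with Satterthwaite df
combining K − 1 (encounter) and n − q (detection); this matches the
magnitude of published camera-trap interval widths better than the
plain-z form, which remains available through `df = Inf`. Model
averaging over models within 2 ΔAIC uses AIC weights and the
unconditional variance Σ wᵢ(varᵢ + (N̂ᵢ − N̄)²); the averaged df is the
weight-averaged member df — a pragmatic choice, since no exact df exists
for a mixture.

Strata are fitted independently per category × period; the "adults"
stratum pools ram, ewe and adult-unknown distances (all animals
older than 1.5 years) rather than summing the ram and ewe estimates.
When both a young and a ewe estimate exist in the fall, their ratio
×100 is a by-product the reporting layer can compute; it is a plain
quotient of the two point estimates.

## The synthetic-data generator

`simulate_survey()` emulates the survey the estimator assumes: a fixed
population of `true_N` animals in a square arena of 6.2 km², grouped
into clusters (zero-truncated Poisson sizes, mean 4, members scattered
with 30 m Gaussian spread), 11 cameras on a square grid with a seeded
random origin, snapshot moments every 15 s inside the daily availability
window, detection by a half-normal with σ = 6 m inside a 50° wedge
truncated at 40 m, and distances rounded to 0.5 m to mimic a
rangefinder. Group positions are redrawn independently at every
snapshot ("ideal mixing").

Design notes:

* A square arena cannot hold 11 grid points at exactly 800 m spacing
  once cameras are inset from the boundary, so the spacing shrinks by
  10% steps until the grid fits; the inset is w + 5·spread so that the
  animal intensity at every wedge equals N/A without edge corrections.
* Group centres are simulated only within a disc of radius
  w + 5·spread around each camera (events elsewhere cannot produce a
  detection); the neglected Gaussian tail is below 4e-6.
* Ideal mixing is the default because the point estimate is agnostic to
  temporal autocorrelation; clustering still produces overdispersed
  counts (several group members can be recorded in one snapshot), which
  is the dominant variance source the between-camera estimator must
  absorb. An extreme-clustering configuration (one large group) is
  exercised in the tests and inflates the encounter CV as expected.
* What the generator does **not** emulate: terrain and vegetation
  occlusion, camera-specific detection differences, attraction or
  avoidance of cameras, population turnover, and persistent spatial
  preferences that would make some cameras systematically busier.
  Passing recovery tests therefore demonstrates estimator correctness
  under the model's own assumptions, not robustness to their violation
  in field data.

Recovery experiments default to fitting the half-normal key alone — the
true generating model — so coverage isolates estimator calibration from
model-selection error; a wider grid can be passed.

## Problem sizes

The bundled tests fit detection functions at n = 300–1000 distances,
run the GOF calibration at 100 replicates of n = 1000, and the
full-pipeline coverage experiment at 200 replicates of a 14-day,
11-camera survey with true N = 60 (about one minute of compute). The
worked example in the README uses an 8-day survey with true N = 150.

## Known limitations

* No detection covariates and no left truncation (deliberate scope).
* Cluster size is not modelled in estimation: animals are treated as
  independent observations, so interval coverage relies on the
  between-camera variance absorbing within-group dependence.
* The GOF equal-width binning loses power for steeply declining g at
  small n, where it often reports "not computable".
* The spreadsheet-era data path expects CSV; spreadsheets must be
  exported before ingestion.
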