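# ctds — camera-trap distance sampling

`ctds` estimates the abundance of unmarked animals from camera-trap
imagery using point-transect distance sampling. It is aimed at wildlife
biologists monitoring species in terrain where aerial surveys or
capture–mark–recapture are impractical — mountain ungulates are the
motivating case — and at survey designers who need to know how many
cameras a target precision requires.

## The model

A camera trap behaves as a point-count sampler: every trigger
opportunity (one per snapshot interval *t*, here 15 s) samples a wedge of
angle θ (here 50°) out to a truncation radius *w* (here 40 m), with area

    a0 = (θ / 360) · π · w²

The probability of recording an animal declines with its radial distance
*r* from the camera. `ctds` fits the standard detection functions

| key         | g(r)                    |
|-------------|-------------------------|
| uniform     | 1                       |
| half-normal | exp(−r² / 2σ²)          |
| hazard-rate | 1 − exp(−(r/σ)^(−b))    |

optionally multiplied by cosine, simple-polynomial or Hermite-polynomial
series adjustments in r/w, by maximizing the point-transect likelihood
for the observed radial distances, whose density is
f(r) = r·g(r) / ∫ u·g(u) du. The mean detection probability within the
wedge is p̂ = (2/w²) ∫ r·g(r) dr, and density and abundance follow from

    D̂ = n / (S · a0 · p̂),      N̂ = D̂ · A

where *n* is the number of detections, *S* the total number of snapshots
across cameras (operating seconds inside the diel availability window —
one hour before sunrise to two hours after sunset, from NOAA solar
position — divided by *t*), and *A* the study area. The total CV
combines the between-camera encounter-rate CV with the detection CV in
quadrature; intervals are log-normal with Satterthwaite degrees of
freedom. Candidate detection models are gated on a χ² goodness-of-fit
test, ranked by AIC, and model-averaged (with unconditional variance)
whenever several fall within 2 ΔAIC. A design planner extrapolates the
achieved CV to other numbers of camera sites via cv(K)² =
cv_enc²·(K0/K) + cv_det².

## Worked example

Simulate a two-week survey of a clustered population of 150 animals
under the default design (6.2 km² arena, 11 cameras on a grid, t = 15 s,
θ = 50°, half-normal detection with σ = 6 m), then run the full
pipeline:

```r
library(ctds)
cfg <- simulation_config(true_N = 150, period_days = 8)
sim <- simulate_survey(cfg, seed = 17)

periods <- list(sim = survey_period("sim", cfg$start_date,
                                    cfg$start_date + cfg$period_days - 1))
ac <- analysis_config(sim$observations, sim$deployments, periods = periods,
                      grid = list(detection_config("half_normal", truncation_w = 40),
                                  detection_config("hazard_rate", truncation_w = 40)))
run_analysis(ac)
```

```
Camera-trap distance-sampling report
 stratum period status n_obs  N_hat  D_hat ci_low ci_high      cv cv_encounter
    rams    sim     OK    96  52.46  8.461  37.88   72.65 0.19743      0.06751
    ewes    sim     OK   109  70.02 11.293  57.48   85.30 0.11863      0.06999
   young    sim     OK    47  39.23  6.328  28.55   53.91 0.19054      0.12259
  adults    sim     OK   205 130.50 21.048 112.43  151.46 0.08934      0.05570
```

The simulated population held 120 adults (150 × the default 80% adult
share); the pipeline estimates 130.5 with a 90% interval of 112.4–151.5
that covers the truth. `N_hat` is the model-averaged abundance,
`cv_encounter`/`cv_detection` are its variance components, and
`n_models` (not shown above) counts the models within 2 ΔAIC that were
averaged. A 200-replicate calibration of this pipeline
(`recovery_experiment(simulation_config(), n_reps = 200, seed = 1)`)
gives 90% interval coverage of 0.895 and median relative bias −0.8%.

For survey design, `required_sites(11, 0.47, 0.3)` reports that a survey
achieving CV = 0.47 with 11 cameras needs 27 sites to reach CV = 0.3.

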