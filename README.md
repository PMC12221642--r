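# gazeflock

Gaze following — orienting your own gaze where another individual is
looking — is a core building block of social attention, and in
group-living animals the interesting question is collective: does an
observer respond more strongly when *more* flock mates provide the cue?
Answering that for a flock of pigeons on a motion-capture stage
requires a long chain of quantitative steps, and `gazeflock`
implements that chain as a tested, reusable R pipeline:

1. **Head pose** — per-frame least-squares rigid alignment (Kabsch) of
   a 4-marker head template, then construction of the head-local frame:
   origin at the eye midpoint, forward axis 30° above the origin–beak
   line (the "horizon"), right-handed X toward the right eye,
   gap interpolation and zero-phase smoothing, with saccade and
   grooming masks.
2. **Gaze geometry** — foveal cones at ±75° azimuth and a binocular
   cone at 0°, each with a 10° half angle, intersected with 0.25 m
   spheres around the stimulus windows. A cone with apex `a` and axis
   `u` crosses a sphere (center `c`, radius `r`) iff
   `angle(u, c − a) ≤ θ_half + asin(r / ‖c − a‖)`.
   Runs of filtered crossings ≥ 300 ms become looking bouts.
3. **Trial bookkeeping** — table-side assignment, per-observer
   per-presentation response rows, the "actual number of
   demonstrators" (demonstrator-side birds that looked at the target,
   filtered by observer grooming), and the exclusion rules (switchers,
   fly-offs, test presentations without demonstrator looks).
4. **Inference** — binomial and Poisson GLMMs (lme4) with z-scored
   predictors, per-individual random intercepts and slopes with a
   documented non-convergence fallback ladder, χ²(1) likelihood-ratio
   tests, AIC comparison of linear vs quadratic demonstrator effects,
   10,000-draw simulation-based confidence bands, and overdispersion /
   VIF / leave-one-individual-out Cook's distance diagnostics.
5. **Synthetic data** — a generator that emits marker trajectories with
   known ground truth (scheduled looks, saccade jumps, grooming,
   switches) and response tables with known effect sizes, so every
   stage is validated against construction.

Everything configurable lives in a YAML `scene_config` (frame rate,
ROI spheres, cone set, 300 deg/s saccade threshold, 300 ms fixation
minimum, smoothing and grooming parameters); no threshold is hard-coded.

## Worked example

Simulate a 10-bird flock (two tables, top/bottom stimulus windows,
counterbalanced test/control presentations), run the full pipeline, and
fit the demonstrator-count model on the statistical twin of the
resulting table:

```r
library(gazeflock)

cfg <- scene_config()                      # 100 Hz, default rig layout
scenario <- random_flock_scenario(cfg, n_birds = 10, n_trials = 2,
                                  pattern = "TC-CT-TC-TC",
                                  presentation_s = 8, gap_s = 2,
                                  seed = 42)
gen <- generate_flock_trajectories(scenario,
                                   synthetic_head_calibration(), cfg)
res <- run_gaze_pipeline(gen$markers, gen$calibs, cfg,
                         scenario$schedule)

nrow(res$bouts)                 # 62 looking bouts recovered
classify_field_usage(res$bouts)
#>     foveal  binocular
#> 0.90322581 0.09677419
res$exclusion_report
#>                   reason n
#> 1 no_demonstrator_looked 8
```

Ninety percent of recovered looks used a fovea — the generator
schedules foveal and binocular looks at its default 92:8 ratio, and the
pipeline's cone labeling recovers that mix. Eight observer rows fall in
test presentations where no demonstrator looked and are excluded.

The model stage, at the scale of a full combined dataset (70 observers,
1,470 rows, true demonstrator effect 0.324 on the z scale):

```r
g <- generate_response_table(
  effect_spec(beta_cond = 0, beta_dem = 0.324, sd_slope_cond = 0,
              n_individuals = 70, n_presentations = 21), seed = 104)
fit <- fit_glmm(glmm_spec("poisson", "n_looks",
                          "n_actual_demonstrators",
                          random = "uncorrelated"), g$table)
fit
#> GLMM (poisson) n_looks ~ n_actual_demonstrators | 1470 obs, 70 individuals
#>   AIC 3982.5, logLik -1987.3, random: uncorrelated
#>   n_actual_demonstrators: chisq(1) = 62.722, beta = 0.342, p = 0.000
```

The fitted slope (0.342 ± its Wald interval) covers the generating
0.324; the likelihood-ratio χ²(1) is reported per tested predictor, and
`glmm_diagnostics(fit)` adds the overdispersion ratio (≈ 0.89 here),
VIFs and per-individual Cook's distances. `simulate_ci(fit, newdata)`
returns the 2.5–97.5 percentile band of 10,000 parameter draws for
plotting predicted responses.

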