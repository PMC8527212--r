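# shoalmotion

Collective-motion analytics and group-level reaction norms for small animal
groups tracked on video.

Repeatedly tested groups of social fish can differ consistently in their
collective movement (*collective personality*) and in how that movement
changes over time (*collective plasticity*). shoalmotion implements the
analysis chain for detecting both, from raw tracking output to model
selection:

1. **Trajectory I/O** — long-format CSV of per-frame positions (`group, day,
   trial, frame, id, x, y`), pixel→mm conversion, validity masking.
2. **Preprocessing** — complete-frame filter, speed-outlier exclusion
   (50 px/frame ≈ 46 cm/s at 2.7 px/mm and 25 fps), Savitzky–Golay smoothing
   (13 frames ≈ 0.5 s, degree 3) over contiguous valid runs, segmentation
   into 2.5-min analysis intervals with a 30-s retention minimum.
3. **Six interval metrics** — median polarization
   (P = ‖mean unit heading‖ ∈ [0,1]), median centroid speed (mm/s), median
   convex hull area (mm²), polarized/unpolarized transition rate
   (threshold 0.65, per frame), mean maximum speed cross-correlation to the
   nearest neighbour (lags ±300 frames), and mean leadership switch rate
   during polarized motion.
4. **Reaction-norm mixed models** — interval and day as continuous fixed
   effects; candidate group random structures (none / intercept /
   intercept + interval slope / intercept + day slope) compared by
   conditional AIC (Vaida–Blanchard, hat-matrix-trace effective df) for
   mixed models and AICc otherwise, with a Δ > 2 support rule and automatic
   flagging of overfitted fits (random-effect correlations at ±1).
   Between-group variance along a covariate,
   σ²(c) = σ²_int + 2cρσ_intσ_slope + c²σ²_slope, with parametric-bootstrap
   CIs; per-group BLUP reaction norms; Satterthwaite F-tests; a beta-family
   mixed model (logit link, adaptive Gauss–Hermite quadrature) for the
   leadership switch rate.
5. **Synthetic data** — a zonal (repulsion/alignment/attraction) schooling
   simulator with group-specific sociability intercepts and day slopes, and
   a direct metric-level sampler from the reaction-norm model, both with
   ground truth for validation.

## Worked example

Simulate a reduced study (4 groups, days 1/4/8/12, two 40-s intervals per
day), compute the metric table and compare random-effect structures for
polarization:

```r
library(shoalmotion)

cfg <- school_sim_config(n_groups = 4, seed = 42)
st  <- simulate_study(cfg, days = c(1, 4, 8, 12), intervals = 1:2,
                      n_frames = 1000)
blocks <- lapply(st$datasets, function(ds) {
  b <- preprocess_trajectories(ds, preprocess_config(min_interval_s = 20))[[1]]
  b$interval_index <- attr(ds, "interval_index")
  b
})
mt <- metrics_table(blocks)
head(mt[, 1:8], 4)
#>   group day trial interval polarization centroid_speed hull_area transition_rate
#> 1   g01   1   d01        1        0.658           55.9     12203           0.095
#> 2   g01   1   d01        2        0.645           53.8     11947           0.086
#> 3   g01   4   d04        1        0.621           51.5     13207           0.085
#> 4   g01   4   d04        2        0.561           46.5     14343           0.073
```

Each row is one analysis unit: one within-trial interval of one group on one
day. Polarization near 0.65 means the shoal hovers around the
polarized/unpolarized boundary; centroid speed and hull area are in mm/s and
mm².

```r
cand <- list(model_spec("polarization", random_intercept = FALSE),
             model_spec("polarization"),
             model_spec("polarization", random_slopes = "interval"),
             model_spec("polarization", random_slopes = "day"))
compare_models(cand, mt)
#>                       label criterion   value effective_df delta rank
#> 1               none / none      AICc  -74.12        4.000 65.57    3
#> 2     group identity / none      cAIC -102.60        6.764 37.08    2
#> 3 group identity / interval      cAIC      NA           NA    NA   NA
#> 4      group identity / day      cAIC -139.69        9.761  0.00    1
```

The day-random-slope model wins by a wide margin (Δ = 37 to the next
reliable model): groups differ not just on average but in their day-by-day
trajectories — which is exactly how the generator was configured. The
interval-slope model estimated a degenerate intercept–slope correlation and
is excluded from ranking (missing criterion). The between-group variance
trend then shows how group differences change over days:

```r
ft <- fit_lmm(model_spec("polarization", random_slopes = "day"), mt)
variance_at_covariate(ft, "day", c(2, 6, 12), nboot = 200, seed = 1)
#>   center variance    lower   upper
#> 1      2  0.00396 0.000149 0.01054
#> 2      6  0.00272 0.000130 0.00773
#> 3     12  0.00461 0.000165 0.01186
```

A full run (simulate/read → preprocess → metrics → model comparison →
variance trends → reaction norms → manifest) is one call,
`run_pipeline("config.yaml")`, or from a shell:

```sh
Rscript inst/scripts/run_pipeline.R --config inst/extdata/demo_config.yaml
```

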