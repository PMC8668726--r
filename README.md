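# escapeflight

Quantifying what a backpack radio-tag costs a small songbird in upward
escape-flight performance — and validating the whole measurement chain by
parameter recovery on synthetic data.

The package is written for movement ecologists and flight biomechanists who
run (or review) tag-burden experiments: a bird escapes upward through a
filmed section of a vertical flight tunnel, four synchronized 400 fps
cameras record it, and every flight yields a trajectory-average speed *U*, a
wingbeat frequency *f*, and a maximum wingspan *b*<sub>max</sub>.

## The model at the core

Actuator-disk theory summarizes a bird's climbing capacity by its disk
loading — weight per swept wing-disk area:

    A = (π/4) b_max²          W/A = 4 m g / (π b_max²)       (g = 9.81 m/s²)

and the speed cost of a tag decomposes into a mass-independent offset plus a
term linear in the tag-induced loading increase:

    ΔU = ΔU_tag + dU/d(W/A) · ΔW_tag/A

Everything between raw pixels and those quantities is implemented here:

| stage | functions |
|---|---|
| synthetic study generator | `flight_sim_params()`, `generate_cohort()`, `simulate_trials()`, `synthesize_trajectory()`, `simulate_study()` |
| DLT calibration & triangulation | `fit_dlt()`, `dlt_project()`, `triangulate()`, `triangulate_tracks()`, `calibrate_cameras()` |
| kinematics | `reconstruct_track()`, `kalman_smooth()` (RTS), `trajectory_average_speed()`, `wingbeat_frequency()`, `max_wingspan()`, `analyze_study()` |
| actuator disk & tag effect | `disk_area()`, `disk_loading()`, `tag_effect_model()`, `predict_speed_reduction()`, `loading_slope_to_per_gram()`, `percent_reduction()` |
| mixed-model inference | `analysis_table()`, `fit_main_models()`, `posthoc_contrasts()`, `marginal_slopes()`, `summarize_group_effects()` |
| orchestration & recovery | `run_pipeline()`, `recover_parameters()` |

## Worked example

Predict what a tag costs a reference bird with disk loading 18 N/m² and a
tag-free escape speed of 3.10 m/s, using fitted coefficients
ΔU_tag = −0.11 m/s and dU/d(W/A) = −0.11 m²·s/kg:

```r
library(escapeflight)
m <- tag_effect_model(tag_offset = -0.11, loading_slope = -0.11,
                      reference_loading = 18, reference_speed_tagfree = 3.10)
p5 <- predict_speed_reduction(m, loading = 18, tag_frac = 0.05)
p7 <- predict_speed_reduction(m, loading = 18, tag_frac = 0.07)
round(c(dU_5pct = p5$delta_U, dU_7pct = p7$delta_U), 3)
#> dU_5pct dU_7pct
#>  -0.209  -0.249
percent_reduction(p5$delta_U_mass_independent, 3.10)$percent_rounded
#> [1] 4
percent_reduction(p5$delta_U_mass_dependent, 3.10)$percent_rounded
#> [1] 3
```

So a 5% tag costs 0.21 m/s: a 4% speed loss that any tag causes regardless
of its mass, plus 3% more from the added disk loading (a 7% tag: 0.25 m/s).

Run the full synthetic study through the pipeline and fit the models:

```r
study <- simulate_study(flight_sim_params(), seed = 1)   # 18 birds, 360 flights
fr    <- analyze_study(study)                            # calibrate, triangulate, smooth
tab   <- analysis_table(disk_loading_table(fr))
fits  <- fit_main_models(tab)
marginal_slopes(fits$speed_real, tab, "loading_real")$average
#> [1] -0.1496  (generating value -0.11; a single replicate, SE ~0.03)
```

Or from a shell, via the thin CLI wrapper (subcommands `run`, `simulate`,
`calibrate`, `kinematics`, `aggregate`, `infer`, `predict`, `recover`):

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/escapeflight", package="escapeflight"))') \
    predict --loading 18 --speed 3.10 --tag-frac 0.05
```

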