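---
title: "Methods: from camera pixels to tag-effect inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from camera pixels to tag-effect inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(escapeflight)
```

# The scientific problem

Small songbirds are routinely fitted with backpack radio-tags. A tag adds
weight and may hinder the bird in other ways (harness, centre-of-gravity
shift, "discomfort"), and the question for anyone deploying tags is how much
escape-flight performance the bird gives up, and whether it recovers over
time. `escapeflight` implements the complete analysis chain used to answer
that question in a vertical flight-tunnel experiment: a bird escapes upward
through a filmed volume, four synchronized high-speed cameras record it, and
per-flight measurements feed a mixed-model analysis of an actuator-disk
loading model.

The package also ships a first-class synthetic-study generator, so the whole
chain is validated by parameter recovery: generate a cohort whose true
effect sizes are known, push the synthetic pixel tracks through the real
pipeline, and check that the fitted models return the generating values.

# The actuator-disk model

An upward-escaping bird must produce thrust at least equal to its weight.
Actuator-disk theory models the beating wings as a circular disk of diameter
equal to the maximum wingspan $b_{max}$:

$$A = \tfrac{1}{4}\pi b_{max}^2, \qquad W/A = \frac{4\,m g}{\pi b_{max}^2},$$

with $g = 9.81\ \mathrm{m/s^2}$. The disk loading $W/A$ (N/m²) is the ratio
of weight to thrust capacity: the higher it is, the slower the bird can
climb. Two variants are carried through the analysis: the *fictive* loading
($W_{bird}/A$, bird mass alone, a proxy for body-mass change) and the *real*
loading ($W_{bird+tag}/A$).

The tag effect on escape speed decomposes additively:

$$\Delta U = \Delta U_{tag} + \frac{dU}{d(W/A)}\cdot\frac{\Delta W_{tag}}{A},$$

a mass-independent offset $\Delta U_{tag}$ plus a term linear in the
tag-induced loading increase. `tag_effect_model()` /
`predict_speed_reduction()` evaluate this model; with offset and slope both
$-0.11$ (in m/s and m²·s/kg) a 5% tag on a reference bird with
$W/A = 18\ \mathrm{N/m^2}$ costs $0.11 + 0.11 \cdot 0.9 = 0.209$ m/s.
`loading_slope_to_per_gram()` converts the loading slope to a per-gram
speed cost at fixed wingspan, $dU/dm = (dU/d(W/A)) \cdot g/A \cdot 10^{-3}$;
note that at $A = 110\ \mathrm{cm^2}$ and slope $-0.11$ this evaluates to
$-0.098$ m/s/g — the function computes the value, it does not impose one.

# Videogrammetry

**DLT calibration.** Each camera is an 11-parameter Direct Linear
Transformation fitted by linear least squares from bead correspondences
(`fit_dlt()`). We deliberately use the classical linear model with no lens
distortion terms and no bundle adjustment: it is the standard choice for
small calibrated volumes, it is exactly testable (noise-free beads must
reproject to machine precision), and distortion would be unobservable in
synthetic data anyway. Six non-coplanar beads determine the fit (12
equations, 11 unknowns); the default field uses 30. Coplanarity and
degenerate triangulation geometry are rejected when the smallest singular
value falls below $10^{-8}$ of the largest.

**Triangulation.** Each camera observing pixel $(u,v)$ contributes two
linear ray equations in $(x,y,z)$; two or more cameras give an
overdetermined system solved by least squares (`triangulate()`, vectorized
across frames in `triangulate_tracks()` via the 3×3 normal equations). The
test suite pins the linear solution against a brute-force lattice search
over candidate 3D points.

**Gap policy.** Frames seen by fewer than two cameras are linearly
interpolated when the gap is at most 3 frames; longer gaps split the track
and the longest segment is kept; segments under 10 frames are flagged
unusable. Frames are 0-indexed, frame $k$ is at time $k/\mathrm{fps}$.

**Kalman/RTS smoothing.** Per axis, a two-state (position, velocity)
constant-velocity model with white-acceleration process noise, forward
filtered and then Rauch–Tung–Striebel smoothed (`kalman_smooth()`). RTS
(fixed-interval) smoothing rather than filter output is the right choice for
offline tracks: it removes the filter's velocity lag. Defaults: process
acceleration SD $q = 2g \approx 19.6\ \mathrm{m/s^2}$ (the scale of in-flight
accelerations over one frame), measurement SD $r = 0.25$ mm (≈0.5 px of
tracking noise through the default camera geometry); both are exposed and
overridable, since the minimal constant-velocity model is an assumption, not
a measurement. The filter initializes from the first two frames, so exactly
linear noise-free motion is reproduced to machine precision — a property the
tests assert.

**Per-flight measurements.** Trajectory-average speed $U$ is defined as the
mean Euclidean norm of the smoothed velocity (the net-displacement/duration
alternative is computed alongside as `U_net_ms`). Wingbeat frequency is
$f = (n_{onsets}-1)/(t_{last}-t_{first})$ from the downstroke-onset frames,
so it is invariant to time origin and to position-frame dropouts. Maximum
wingspan $b_{max}$ is the largest simultaneous wingtip separation over at
least one full wingbeat, measured once per bird (on the first flight of the
first test day) and held constant — wingspan does not change over a month.

# The synthetic study generator

`generate_cohort()` / `simulate_trials()` / `synthesize_trajectory()`
emulate the full experiment: 18 birds, 3 per sex × treatment cell
(control, 0.9 g lighter tag, 1.2 g heavier tag), test days 1, 7, 14 and 28
after deployment, five flights per bird-day (360 trials). Per-flight truth
follows

$$U = \beta_0 + \beta_{W/A}\,(W_{bird+tag}/A) + \Delta U_{tag}\,[tagged]
  + \beta_{T,treat}\,T + b_{bird} + \varepsilon,$$

with defaults $\beta_{W/A} = -0.11$ m²·s/kg, $\Delta U_{tag} = -0.11$ m/s,
day slopes 0.010/0.003/0.007 m/s/day (control/lighter/heavier), and the
analogous frequency model (baseline 23.0 s⁻¹, slope 0.010 s⁻¹/day). The
test day enters as its literal value $T \in \{1,7,14,28\}$. Body mass drifts
up by 0.06%/day compounded (≈1.6% from day 1 to day 28).

Choices the underlying experiment does not pin down, made once and surfaced
in `flight_sim_params()`:

* **Body masses** are not published; means are back-derived from the
  published tag-mass fractions (0.9 g ≈ 6% and 1.2 g ≈ 7–8% of body mass):
  females ~N(15.0, 0.8) g, males ~N(16.5, 0.8) g, truncated at ±2 SD.
* **Wingspans** are set so the sexed mean fictive disk loadings are
  ~18.0 (F) and ~17.7 (M) N/m²: females ~N(0.1020, 0.0025) m, males
  ~N(0.1079, 0.0025) m. (These means are what the loadings and masses
  jointly imply; the often-quoted ~110 cm² mean disk area is not consistent
  with them and is not forced.)
* **Variance components** are not published (only SEs of group means):
  residual SDs 0.25 m/s and 0.8 s⁻¹, bird-intercept SDs 0.10 m/s and
  0.5 s⁻¹, chosen to reproduce group-mean SEs of the observed magnitude
  (~±0.2 m/s at n = 6 birds).
* **Trajectory waveform** (invented plumbing): vertical ascent at the true
  speed through the 0.4 m focal section, a 5 mm vertical bob at the wingbeat
  frequency, a 3 mm slow lateral wobble, wingtip span oscillating between
  0.55·b and b once per wingbeat, downstroke onsets at the span maxima,
  projected through the four cameras with 0.5 px Gaussian noise. Amplitudes
  are small relative to the 0.4 m path, so the speed estimate is insensitive
  to them (the bob inflates mean |v| by ≲2%; the tests allow 3%).

What the generator does *not* emulate: photorealistic images and tracking
failures, bird decision-making or habituation mechanisms, harness
aerodynamics, non-Gaussian tracking outliers. Passing recovery tests
therefore validate the estimation chain under the stated statistical
assumptions, not the behaviour of real trackers on real video.

`noiseless_params()` zeroes every stochastic term *including* the bob and
wobble: under it the pipeline must return each trial's true speed to better
than $10^{-3}$ relative — the package's end-to-end integrity check. The
wingbeat frequency is excluded from that bound by construction: downstroke
onsets are integer frame indices, and frame quantization at 400 fps over a
~0.13 s flight bounds $\hat f$ only to about ±0.5 s⁻¹.

# Inference

`fit_main_models()` fits, by REML with a bird-level random intercept
(`lme4`/`lmerTest`), with test day numeric and all two-way interactions:

* fictive loading ~ treatment, sex, day (disk loading as body-mass proxy);
* speed ~ loading, treatment, day — once with fictive and once with real
  loading (sex excluded: collinear with loading);
* frequency ~ loading, treatment, day.

`posthoc_contrasts()` adds the targeted follow-ups: loading over time in
tagged vs untagged birds; pairwise treatment speed differences with no
covariates; and the tagged-vs-untagged speed model with and without the
day interaction. Singular random-effect fits are reported with variance 0
and a flag, not treated as failure; if the mixed fit errors outright
(e.g. zero residual variance in noise-free data) the fixed-effects OLS fit
is used with a logged warning — with no between-bird variance the two
estimators coincide, a property the tests assert.

Because the published per-treatment slopes are conditional summaries of an
interaction model, slopes are extracted as *marginal* slopes: the day slope
per treatment at the mean loading, and the loading slope averaged over
treatments at the mean day (`marginal_slopes()`). This is computed directly
from the fixed-effect vector and cross-checked in the tests against
`emmeans::emtrends()`. Wald summaries use Satterthwaite df where `lmerTest`
provides them; reproducing any particular F denominator df is explicitly a
non-goal — recovery targets are coefficients, not test statistics.

Percent summaries round half away from zero to integer percent. The percent
change over the study period is `slope × span / baseline`; the span of the
default design is reported over the full 28-day period, and the report notes
the day-1 anchor used, since a 27- vs 28-day convention changes the value by
under 0.05 percentage points.

# Parameter recovery and problem sizes

`recover_parameters()` repeats generate → measure → fit over replicate
cohorts and tabulates the estimates. Two routes: `"videogrammetry"` (full
pipeline, the default) and `"direct"` (models fitted to generator truth;
isolates the statistical stage). With 200 replicates the Monte-Carlo SE of
the mean loading-slope estimate is ≈0.002 m²·s/kg, comfortably inside the
±0.03 band the recovery checks use. The shipped test suite runs 60
videogrammetry replicates (~2 min) plus smaller Monte-Carlo batches per
module; the acceptance script runs 200. One full replicate (360 flights,
4 cameras, ~50 frames each) takes ≈1.3 s single-threaded.

# Known limitations

* The constant-velocity Kalman model under-weights the wingbeat bob
  (acceleration amplitude ~100 m/s² at 23 Hz vs the 2 g process default);
  this damps the bob's contribution to $U$ slightly. Since the bob is a
  nuisance term, that is acceptable — but it is why the speed tolerance on
  bob-bearing synthetic trials is 3%, not $10^{-3}$.
* $b_{max}$ is sampled at 400 fps, biasing the span maximum down by up to
  ~0.9 mm at default amplitudes; well inside the 2 mm test tolerance.
* The mixed models assume Gaussian residuals and a single random intercept;
  random slopes are not modeled (nor identifiable from 4 days per bird).
* No lens distortion, rolling shutter, or tracking outliers are simulated;
  measurement-error structure in real recordings will be heavier-tailed.
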