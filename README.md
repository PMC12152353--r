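# foragekin

Kinematic segmentation and analysis of pick-and-place foraging movements.

## What this package is for

In interactive visual-foraging experiments, participants repeatedly pick
small objects (e.g., LEGO bricks of an instructed color) from one pad of
a table and place them on another, under placing instructions (collect,
sort, pile) that vary how precisely the objects must be put down. An
overhead camera films the hand at 200 fps and a markerless pose
estimator converts each trial video into per-frame keypoint coordinates
with confidence scores. `foragekin` turns those keypoint tracks into
movement-level science:

* **pose I/O** — read/write per-joint keypoint tables (CSV: `frame`,
  `joint`, `x`, `y`, `likelihood`), linearly interpolate samples whose
  likelihood falls below 0.7, and calibrate pixels/frames to cm/ms;
* **kinematics** — per-frame speed (Euclidean displacement) and
  acceleration, smoothed with a third-order Savitzky–Golay filter
  (59-frame window);
* **segmentation** — detect movement starts and ends as peaks of an
  *objective function*, the per-frame product of probability signals
  (region proximity, inverted speed, speed/acceleration/likelihood
  threshold gates, shifted Gaussian event weights), with mutual
  suppression between start and end detection, a 50-frame minimum peak
  distance, count validation against the trial's search size, and the
  more-than-one-third participant exclusion rule;
* **dependent measures** — movement duration, average/peak speed,
  deceleration time (% of movement after peak speed), distance, path
  ratio (traveled/direct path), and first-movement onset;
* **activation maps** — difference-image quantification of *where*
  picking and placing occurred (HSV binarization, Gaussian blurs,
  absolute difference, 150 floor, 0–100% scale) with quadrant means;
* **statistics** — participant × condition aggregation, t-based
  confidence intervals, the arcsine-square-root transform for extreme
  proportions, and default-prior (Jeffreys–Zellner–Siow) Bayes-factor
  *t*-tests, `delta ~ Cauchy(0, 1/sqrt(2))`, paired or one-sample,
  one- or two-sided;
* **synthetic data** — a first-class generator of balanced trial
  schedules (9-trial blocks, 3 × 3 × 3 design), asymmetric minimum-jerk
  hand trajectories with planted condition effects (transport
  deceleration fractions, first-target size bias, near-left quadrant
  preference, onset distribution), tracking noise, likelihood dropouts,
  dropped-object artifacts, and start/end scene-image pairs — so the
  whole pipeline is testable end to end without any external download.

The deceleration-time statistic at the heart of the condition contrasts
is, per movement, `100 * (n_end - n_peak) / (n_end - n_start)` on the
smoothed speed; the JZS Bayes factor is
`BF10 = ∫ p(t | delta) Cauchy(delta; 0, r) d delta / p(t | 0)` computed
by adaptive quadrature (relative tolerance 1e-8).

## Worked example

```r
library(foragekin)

params  <- cohort_params(n_participants = 8, trials_per_participant = 27,
                         seed = 1)
cohort  <- generate_cohort(params)        # 216 simulated trials
seg     <- segment_cohort(cohort)         # reach/transport segmentation
mean(seg$status$transport_ok)
#> [1] 1

measures  <- measure_cohort(cohort, seg)
transport <- measures[measures$phase == "transport", ]
agg <- aggregate_measures(transport, dvs = "deceleration_pct",
                          keys = c("participant_id", "instruction"))
round(tapply(agg$deceleration_pct, agg$instruction, mean), 1)
#> collect    pile    sort
#>    50.8    53.3    52.3

pile  <- agg$deceleration_pct[agg$instruction == "pile"]
sort_ <- agg$deceleration_pct[agg$instruction == "sort"]
jzs_ttest_bf(pile, sort_, design = "paired", direction = "greater")
#> JZS t-test (Cauchy prior, r = 0.7071, greater): t(7) = 6.567, BF10 = 212.8
```

Every trial was segmented into its planted reaches and transports; the
aggregated transport deceleration times order collect < sort < pile,
recovering the planted precision-demand effect, and the directional
Bayes factor of 212.8 says the data are ~213 times more likely under
"piling decelerates longer than sorting" than under no difference.

## Package layout

* `R/` — implementation (synthetic data, pose I/O, kinematics,
  segmentation, dependent measures, activation maps, statistics,
  cohort pipeline)
* `tests/testthat/` — unit, property and acceptance tests; all fixtures
  are generated in code
* `vignettes/foraging-kinematics.Rmd` — the methods vignette: model,
  assumptions, parameter choices, numerical details, limitations
* `scripts/acceptance.R` — headline-quantity reproduction script
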