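# caninesway

Static posturography for dogs: center-of-pressure (COP) sway analysis from
pressure-mat recordings.

Postural control in quietly standing subjects is quantified through the COP —
the point of application of the resultant ground-reaction force — whose 2-D
trajectory on a pressure-sensitive walkway is the stabilogram. `caninesway`
is aimed at veterinary gait labs and aging researchers who need a tested,
scriptable version of the full analysis chain:

* **COP extraction** — pressure-weighted centroids per frame, invalid-frame
  flagging, zero-phase 4th-order Butterworth low-pass at 5 Hz;
* **window selection** — the 7 × 70-frame protocol of acceptable quiet
  standing (two-pass, round-robin, non-overlapping), with the exclusion rule
  for dogs that cannot supply 7 windows;
* **the 16 time-domain sway measures** per window, averaged per dog:
  velocity, acceleration (CC/ML/overall), range (CC/ML), RMS distance
  (CC/ML/overall), 95% confidence ellipse area, sway area, and frequency
  revolve (CC/ML/overall). Craniocaudal (CC) and mediolateral (ML) axes, mm
  units, `T = (N−1)/fs`;
* **cohort statistics** — fractional-lifespan age grouping (Greer-type
  height/weight lifespan model), ICC(2,k) trial-to-trial reliability with
  McGraw–Wong confidence intervals, morphometric regressions, row-wise
  correlation matrices, forward stepwise logistic group discrimination with
  a BIC limit and ROC AUC, and joint-pain × proprioception interaction
  models;
* **a seeded synthetic-cohort generator** (smooth drift + postural-adjustment
  and tremor resonances, Markov acceptability masks, Gaussian paw-blob frame
  rendering) so the whole pipeline is testable end to end.

For the overall measure of sway magnitude, the RMS distance of an N-sample
window with resultant distances RD(n) from the mean COP is

```
RMS_Ov = sqrt( (1/N) * sum_n RD(n)^2 ),   RD(n) = sqrt((ml_n - ml̄)^2 + (cc_n - c̄c)^2)
```

and the package's population-SD convention makes
`RMS_Ov² = RMS_CC² + RMS_ML²` hold exactly. The methods vignette
(`vignettes/posturography-methods.Rmd`) documents every measure, the filter,
the selection protocol, the statistical models and the generator's design
choices.

## Worked example

Simulate the default cohort (40 adults, 24 seniors, 10 trials of 8 s at
67 Hz), run the pipeline and the cohort analyses:

```r
library(caninesway)

sim <- simulate_cohort(synth_config(seed = 7))
wm  <- window_metrics(sim$cop, sim$masks)   # filter, select 7x70, 16 measures
dm  <- dog_metrics(wm)                      # average windows per dog
an  <- analyze_cohort(dm, sim$dogs, window_metrics = wm)
an
#> <sway_cohort_analysis> 40 adults, 24 seniors
#>   reliability: 13/16 metrics good or excellent
#> Forward stepwise (logistic), n = 64
#>   selected: rms_ml, acc_ml
#>   R^2 = 0.381, AUC = 0.881

glance(an$stepwise)
#> # A tibble: 1 × 5
#>   n_selected r.squared   auc   bic     n
#>        <int>     <dbl> <dbl> <dbl> <int>
#> 1          2     0.381 0.881  64.9    64
```

Reading the output: most measures are reliable across the 7 windows
(ICC(2,7) good or excellent; the frequency-revolve measures are the usual
exception), and the stepwise discriminator of seniors versus adults pairs an
extension measure (`rms_ml`, seniors sway farther) with an acceleration
measure (`acc_ml`, entering with a negative sign as a suppressor of the
large shared between-dog variance) — together classifying age group with an
in-sample AUC of 0.88. Group medians are in `an$group_medians` (e.g. RMS Ov
2.44 mm in adults vs 3.03 mm in seniors for this seed), the reliability
table in `an$reliability`, and `plot_reliability()`, `plot_cop_path()` and
`plot_metric_by_group()` draw the standard figures.

Real recordings enter the same way through `read_frame_stack()` (tidy long
CSV of pressure frames), `extract_cop_series()`, and `read_cohort_table()`;
a mapping-driven `import_s2()` adapter ingests externally deposited
processed-data sheets exported to CSV.

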