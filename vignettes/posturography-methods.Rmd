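---
title: "Static posturography in dogs: models, measures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static posturography in dogs: models, measures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caninesway)
```

## The problem

Postural control degrades with age. In quietly standing subjects it is
quantified through the center of pressure (COP) — the point of application of
the resultant ground-reaction force — whose two-dimensional trajectory (the
stabilogram) is recorded by a pressure-sensitive walkway or force plate.
`caninesway` implements a complete pipeline for canine static posturography:
from raw pressure frames to COP trajectories, to the classical set of sixteen
time-domain sway measures, to cohort-level reliability and age/pain analyses,
together with a synthetic-cohort generator that makes every stage testable
without animals.

The axes follow the veterinary convention: craniocaudal (CC, head-to-tail,
the quadruped analogue of anteroposterior) and mediolateral (ML). All
distances are in mm, times in s.

## From pressure frames to COP

A recording is an ordered stack of pressure frames (grids of sensel values)
at a fixed sampling rate (67 frames/s for the protocol this package targets;
8 s trials of 536 frames). The COP of a frame is the pressure-weighted
centroid of the grid, with sensel centers at `(col * pitch, row * pitch)`.
Frames whose total pressure falls below a threshold (default 1% of the
recording's median total load) carry no stance signal — the dog stepped off
or shifted — and are flagged invalid rather than producing a spurious
centroid.

The coordinate series is low-pass filtered at 5 Hz before analysis.
Quiet-standing sway lives below a few Hz; the filter removes sensor noise
that would otherwise dominate the velocity and acceleration measures. The
filter is a 4th-order Butterworth applied forward and backward (zero phase),
so features are not time-shifted and path-length measures carry no lag bias.
The forward-backward pass uses odd-reflection padding with steady-state edge
initialization; a constant series passes through bit-exactly, and the
response at the cutoff is the squared Butterworth magnitude. The filter is
applied to the COP coordinates, not the raw pressure grids: the pressure
field itself is not the quantity of interest, and filtering coordinates
commutes with the centroid only for the former. Filtering requires at least
13 samples; the filter is always applied to whole trials before windowing,
never to 70-frame windows.

## Window selection

Only frames in which the dog stands square, still and looking forward are
analysable; these are marked in a per-frame acceptability mask (produced by
video review in practice, by a Markov model in simulation). The protocol
requires 7 non-overlapping windows of 70 consecutive acceptable frames per
dog. Selection is two-pass: first one window per trial in recording order
(earliest admissible start); if fewer than 7 result, the trials are cycled
again round-robin, each visit taking the earliest window that does not
overlap windows already taken from that trial. Windows may abut but never
overlap. Dogs that cannot supply 7 windows are excluded (a typed condition
carrying the number found). The earliest-start greedy choice within a trial
attains the maximum possible number of disjoint windows (it is the classical
interval-scheduling argument), a property the test suite checks against an
independent dynamic-programming packer.

## The sixteen sway measures

Per 70-frame window, with `T = (N - 1)/fs` the elapsed time:

* **Path measures** — mean velocity per axis (total CC or ML distance per
  second) and overall (vector path length per second); mean absolute
  acceleration per axis (mean absolute change of the signed frame-to-frame
  velocity, so decelerations do not cancel accelerations) and overall (mean
  absolute change of the scalar speed).
* **Extension measures** — range per axis (max minus min); RMS distance per
  axis (population standard deviation) and overall (RMS of the resultant
  distance, RD, the per-sample distance from the window's mean COP); the 95%
  confidence ellipse area `2 * pi * F_0.95(2, N - 2) * sqrt(det S)` with `S`
  the sample covariance; and the sway area (mean-anchored triangle areas
  swept per second).
* **Hybrid frequency measures** — the overall frequency revolve
  `vel_ov / (2 * pi * mean(RD))` (rotation rate of an equivalent circle) and
  the directional frequencies `vel_axis / (4 * sqrt(2) * mean|deviation|)`
  (equivalent sinusoid).

Three conventions deserve a note, because the literature is not uniform:

* `T = (N - 1)/fs`, the time actually spanned by the samples, rather than
  `N/fs`. For 70-frame windows the two differ by a factor 69/70; a consistent
  choice matters more than which one.
* The per-axis RMS uses the population (divide-by-N) standard deviation, so
  the identity `rms_ov^2 = rms_cc^2 + rms_ml^2` holds exactly — the test
  suite asserts it to 1e-9 on thousands of random segments. The ellipse area
  uses the sample (N-1) covariance, following the standard PAREA form.
* The overall acceleration differences scalar speeds, not vector velocity
  second differences. Scalar-speed differencing is what produces the
  empirically observed ordering `acc_ov` well below `acc_cc` on oscillatory
  paths (a vector second difference cannot fall below its largest component).
* Directional frequencies use the `4 * sqrt(2)` constant of the classical
  measure set rather than the `2 * pi` a literal sinusoid argument would
  give; for a pure sinusoid of frequency f the measure returns
  `pi * f / (2 * sqrt(2)) ≈ 1.11 f`.
* Frequencies are undefined on a motionless window and are reported as
  missing, never as zero; per-dog averages are taken over the defined
  windows.

Per dog, the 16 measures are averaged over the 7 windows.

## Cohort analyses

Age groups are defined by fractional lifespan (FLS): chronological age
divided by the lifespan predicted from withers height and weight by a linear
model (default coefficients transcribed from Greer et al. 2007:
13.62 + 0.0702 × height[in] − 0.0538 × weight[lb], stored per cm/kg). Dogs of
5 kg or less are ineligible (their COP is not reliably detected); adults
(group A) are older than 1 year with FLS ≤ 0.75; seniors (group B) have
FLS > 0.75.

Sway measures are strictly positive and right-skewed, so model-based analyses
use natural logs; clinical scores include zeros and use `log(x + 1)`.
Shapiro-Wilk normality checks are available through `stats::shapiro.test`
as a reported gate, not reimplemented.

* **Reliability** is ICC(2,k): two-way random effects, absolute agreement,
  average of the k = 7 windows, computed from the two-way ANOVA mean squares,
  with the McGraw-Wong F-based 95% interval. Labels: > 0.9 excellent,
  (0.75, 0.9] good, [0.5, 0.75] moderate, < 0.5 poor (the published prose
  leaves boundary membership open; this package fixes the half-open bands
  just given).
* **Morphometric regressions**: simple OLS of each log measure on weight,
  height and length (adults only), reporting Pearson r and the two-sided t
  test.
* **Correlation matrix**: Pearson over the 13 analysis measures (frequency
  revolve excluded for poor reliability) with listwise deletion ("row-wise"
  in JMP terminology).
* **Group discrimination**: forward stepwise logistic regression over the 13
  log measures. Entry is by smallest likelihood-ratio p-value with
  `p_enter = 0.05`; a step is also refused if it would increase the BIC,
  which is what bounds model size. Forward-only, no removal steps — the
  originating software's exact rules are not documented, and forward-with-BIC
  is the most reproducible reading. In-sample ROC AUC (Mann-Whitney form,
  ties counting one half) summarizes the final model. Perfect-separation
  warnings during candidate fits are caught and surfaced once as a
  `separation` flag on the result.
* **Pain models**: linear models of a log measure on `log(pain + 1)`,
  conscious-proprioception status and their interaction, with standardized
  coefficients and per-stratum correlations.

## The synthetic cohort generator

`synth_config()` / `simulate_cohort()` generate per-dog metadata, per-trial
COP series, and acceptability masks. The generator's purpose is to reproduce
the *statistical structure* the analyses assume — not quadruped biomechanics.
Its defaults are the package's study conditions and were chosen as follows.

**Sway signal.** Each axis is the sum of three stationary Gaussian
components:

1. a *slow drift* — by default a double-pole low-pass process (pole 0.97 CC /
   0.978 ML at 67 Hz). A single AR(1) is available (`slow_poles = 1`) but its
   f^-2 spectral tail leaks drift energy into the velocity and acceleration
   measures; a standing body's center of mass cannot jump between frames, and
   the inertia-consistent f^-4 tail keeps the drift where it belongs, in the
   extension measures;
2. a *mid-band postural adjustment* resonance (~1.5 Hz, SD 1.0 mm CC),
   active corrective motion that contributes to path length but, scaling as
   ω versus the tremor's ω², little to acceleration;
3. a *narrowband tremor* resonance (~4.5 Hz, SD 1.7 mm CC). Acceleration of
   a narrowband motion scales with its squared angular frequency, so this
   component carries most of the acceleration and much of the velocity
   signal while adding well under 1 mm of filtered displacement.

ML amplitudes are a fixed fraction of CC (0.45 tremor, 0.6 adjustment,
ratio ~0.7 for drift), reproducing the larger craniocaudal sway of standing
dogs. The component SDs were calibrated so that a default adult cohort
reproduces the scale of published canine quiet-standing values (velocities
around 23/9.5 mm/s CC/ML, CC acceleration around 500 mm/s², RMS around
2/1.1 mm, 95% ellipse around 40 mm²).

**Between-dog structure.** The drift (and adjustment) amplitude scales with
body length (`size_alpha = 1`) and with a per-dog lognormal factor; seniors
carry a multiplier `senior_gamma = 1.4` on the slow channel. Tremor intensity
scales with size, with joint pain (`pain_jitter_gain` extra tremor SD per
pain unit, doubled when conscious proprioception is abnormal), and with its
own per-dog factor. Critically, one *shared* "overall swayiness" factor
(SD 0.3 on the log scale) multiplies both channels, with only small
channel-specific factors (SD 0.1): this is what makes all sway measures
strongly correlated between dogs, as real cohorts show. In that regime a
second, highly correlated variable can still enter a BIC-limited stepwise —
as a suppressor of the shared variance — which is exactly how an
acceleration measure joins an extension measure in the default end-to-end
analysis.

**Everything else.** Morphometrics are drawn from a correlated trivariate
normal matched to published cohort summaries (means 21 kg / 51.5 cm /
56.5 cm, pairwise correlations 0.86), truncated to the eligibility bounds.
Senior joint pain is negative-binomial (mean 4.5, size 3; adults are
pain-free by eligibility), abnormal proprioception affects 37.5% of seniors.
Masks are two-state Markov chains (`p_stay = 0.995`, `p_recover = 0.4`,
stationary acceptability ≈ 0.99) started from their stationary law.
`render_frames()` inverts the pipeline for testing: it distributes the load
over four Gaussian paw blobs, solving per-frame loads (non-negative, summing
to one, closest to quarter loads) so the frame centroid reproduces the input
COP exactly.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: actual paw-substitution dynamics, weight
shifts and leaning against the leash; non-Gaussian heavy-tailed sway;
habituation across trials; breed-specific stance geometry; any mechanistic
link between pain and tremor. The generator targets summary structure, and
conclusions about real dogs require real recordings.

## Numerical and degenerate-input choices

* Windows are 0-based, half-open `[start, start + 70)` throughout.
* `ellipse95_area()` clips a numerically negative covariance determinant to
  zero (perfectly collinear windows).
* `icc_2k()` refuses degenerate variance decompositions rather than
  returning an out-of-range value.
* Problem sizes in the test suite: the analytic and identity suites run on
  1,000 random 70-sample segments; oracle-equivalence suites use 100-200
  random instances; the end-to-end analysis simulates the full default
  cohort (64 dogs × 10 trials × 536 frames) once at a fixed seed.

## Reproducing the packaged results

`scripts/acceptance.R --seed <int> --out <path>` regenerates the default
cohort at the given seed, runs the complete pipeline, and writes the headline
quantities (group medians of RMS Ov, the stepwise AUC and model size, the
ICC(2,7) of overall velocity) as JSON. The README shows a worked example with
the numbers it prints.
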