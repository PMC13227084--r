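---
title: "Handwriting kinematics and pentagon-copy group comparison: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Handwriting kinematics and pentagon-copy group comparison: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphomotor)
```

# The problem

Subtle cognitive decline in older adults is often accompanied by changes
in fine motor control that conventional physical-performance batteries
miss. Online (pen-stream) handwriting — time-sampled digitizer output of
position, pressure, tilt and pen status at a nominal 100 Hz — captures
motor behaviour both on the writing surface and during in-air
transitions, and kinematic summaries of these signals can differ between
groups defined by performance on the intersecting-pentagons copying
task, a classic visuoconstructional screen.

`graphomotor` implements the full analysis machinery for such a study:

1. reading, writing and validating pen-stream recordings
   (`read_svc()`, `write_svc()`, `validate_recording()`);
2. stroke segmentation and extraction of eight kinematic features per
   task (`segment_strokes()`, `extract_features()`);
3. automated binary scoring of the pentagon-copy drawing
   (`score_pentagon()`);
4. rule-based clinical scoring (SPPB components and composite, Timed Up
   and Go bands — `sppb_*()`, `tug_category()`);
5. the two-group statistical pipeline: unadjusted tests, age- and
   sex-adjusted linear models, log transform of nonnormal outcomes,
   Benjamini–Hochberg FDR and the category-by-feature significance
   tally (`run_analysis()`);
6. a seeded synthetic cohort generator (`generate_cohort()`) so every
   stage is testable without participant data.

# Data model

A task recording holds time-ordered samples `x, y, t, status, azimuth,
altitude, pressure`. Coordinates are integer device units (200 units/mm
by default — configurable, as pen tablets differ); timestamps are in
milliseconds at a nominal 10 ms interval; `status` is 1 while the pen
touches the surface and 0 while it moves in proximity above it;
pressure (arbitrary device units) must be zero while the pen is up.
Files use a plain-text SVC dialect: a sample-count header line, then one
line of seven integers per sample, named `<participant>_T<task>.svc`.

Ten tasks fall in three categories: tasks 1–2 are cognitive-effort tasks
(copying intersecting pentagons, drawing a house), tasks 3–6 fine motor
control (Archimedean spiral, straight line, spring, concentric circles),
tasks 7–10 mechanical (signatures, capital letters, phrase copying).

# Kinematic features

Eight features summarise each recording. Per-interval quantities are
computed over consecutive sample pairs; the interval between two samples
is attributed to the *earlier* sample's pen status, a deterministic
convention that makes stroke durations partition the recording span
exactly.

* **Time down** (ms): total duration of surface contact.
* **Time on air** (ms): total in-proximity duration; individual pen-up
  gaps are capped at `max_gap_ms` (default 1000 ms) so out-of-proximity
  dropouts cannot dominate the total. Capping is flagged.
* **Mean / max pressure** (au): over pen-down samples.
* **Mean / max speed** (mm/s): per-interval Euclidean displacement over
  the interval length. By default speed is computed over *all* intervals
  (pen-down, in-air and the transitions between them): in-air transits
  are fast, and only with them included can maximum speeds reach the
  thousands of mm/s observed for these tasks while mean speeds stay in
  the tens. `speed_scope = "down_only"` restricts to pen-down intervals.
* **Mean / max acceleration** (mm/s²): absolute first difference of
  consecutive interval speeds divided by the later interval's length.
  No smoothing is applied. Reported mean accelerations from study data
  depend strongly on the (usually unpublished) differentiation and
  smoothing scheme, so no numerical equivalence with any particular
  published kinematic value is claimed for speed-derivative features;
  the contract here is the documented formula, verified against an
  independent re-implementation.

Degenerate inputs (fewer than 2 samples; no pen-down sample) yield zero
features with a flag rather than an error, so batch extraction never
stops on a corrupt file.

# Pentagon-copy scoring

A drawing passes (score 1) iff it contains exactly **two closed
polygons**, **five sides each**, whose interiors **partially overlap** —
positive intersection area, with neither figure containing the other.
Rotation and tremor are disregarded: every threshold is metric or
angular, so scoring is invariant under rigid motion of the drawing.

The geometric procedure is this package's own operationalization of
those criteria (studies typically score the drawing manually):

1. pen-down strokes are chained when one ends within the closure
   tolerance (3 mm) of where the next begins; a chain whose free ends
   meet within the same tolerance is a candidate closed polygon;
2. the chain is simplified by recursive farthest-point
   (Ramer–Douglas–Peucker) reduction at 1 mm; when several points tie
   for farthest (the chord can run parallel to a polygon edge), the
   earliest point within numerical tolerance of the maximum is chosen —
   a deterministic tie-break;
3. consecutive sides turning by less than 25° are merged, and the
   closing segment counts as one side, so `n_sides` equals the vertex
   count of the cleaned cycle;
4. the intersection area of the two candidate polygons is computed by
   Sutherland–Hodgman clipping plus the shoelace formula. The clip
   polygon is assumed convex — true for the pentagon stimulus and for
   every synthetic fixture the thresholds were calibrated on. Overlap
   below 0.1% of the smaller polygon's area does not count; overlap
   above 99% counts as containment. Both bounds are configurable
   (`scoring_config()`).

These tolerances were calibrated on noise-free synthetic fixtures and
are verified in the test suite: exact agreement with generator ground
truth across side counts 3–7 and disjoint/partial/nested placements, and
at least 95% agreement under radial vertex jitter of 5% of the figure
radius. A hand-drawn pentagon with very shaky, high-curvature sides can
still defeat the 25° collinearity merge; the scorer is a screening
instrument for clean-to-moderately-noisy drawings, not a substitute for
expert review of pathological ones.

# Clinical scoring

SPPB component scores follow the published cut-offs: side-by-side and
semi-tandem stands score 1 point at 10 s, the tandem stand scores 0/1/2
at 3 s and 10 s; the 4-m gait and 5× chair-stand bands use the printed
thresholds. Printed band endpoints leave micro-gaps (4.65 vs 4.66 s for
gait; 11.19 vs 11.20 s and 59 vs 60 s for the chair stand); the package
closes them by continuity with the printed endpoints — gait
`(-Inf, 3.62) -> 4, [3.62, 4.65] -> 3, (4.65, 6.52] -> 2, (6.52, Inf) -> 1`;
chair `< 11.20 -> 4, [11.20, 13.69] -> 3, (13.69, 16.69] -> 2,
(16.69, 60] -> 1, > 60 or unable -> 0`. Whether a study rounds inputs to
two decimals before banding is usually unstated; the continuity
convention makes scoring total and monotone, which the tests verify over
a dense grid. The composite (0–12) maps to severe (0–3), moderate (4–6),
mild (7–9) and minimal (10–12) limitation categories. TUG times under
10 s are within normal limits and 10–20 s indicate onset of functional
decline; the `impaired` label above 20 s is this package's extension to
make the banding total.

# Statistical pipeline

Per variable, on complete cases:

1. group means and SDs on the original scale;
2. unadjusted comparison — Shapiro–Wilk in each group at α = .05
   decides between a Welch two-sample *t* test and a Mann–Whitney U
   test (exact enumeration when both groups have ≤ 8 untied values,
   tie-corrected normal approximation otherwise);
3. transform decision — nonnormal outcomes (Shapiro–Wilk, α = .05) that
   are strictly positive are natural-log transformed before the
   adjusted model; the coefficient is then reported on the log scale
   with the `log_transformed` flag set, rather than silently mixing
   scales;
4. adjusted model — OLS of the (possibly transformed) outcome on group,
   age and sex, with group coded altered = 1 and sex coded female = 1,
   so a positive coefficient means a higher value in the altered group.
   CI and p come from the *t* distribution with n − 4 df. A residual
   variance of numerically zero marks the fit degenerate instead of
   reporting a spurious p;
5. Benjamini–Hochberg adjustment applied once across the family. The
   default family is the 80 handwriting variables;
   `handwriting_plus_physical` and `per_category` are available because
   the family choice is rarely stated explicitly in publications and
   materially affects the tally;
6. the 3 × 8 category-by-feature count of tests with FDR-adjusted
   p < .05.

`bh_adjust()` implements the step-up definition directly
(`adj_(i) = min(1, min_{j>=i} m p_(j)/j)` on the sorted vector); the
test suite checks exact elementwise agreement with an independent
brute-force implementation and near-equality with `stats::p.adjust`.

# The synthetic cohort generator

Because raw participant-level data for studies of this design are
rarely deposited, the generator is a first-class module: it encodes the
cohort structure the pipeline assumes and gives every downstream stage
a ground truth.

Defaults encode the emulated study conditions: 93 participants with
normal and 81 with altered pentagon-copy performance; group mean ages
69.6 (SD 5.9) and 72.9 (SD 5.6) years, truncated below at the 60-year
inclusion bound (inverse-CDF sampling), so the altered group is older on
average — the age confound that motivates covariate adjustment; 108/174
female; and per-variable outcome means and SDs equal to the published
group summary statistics, the only available printed anchor.

Outcomes follow `y = mu_group + b_age (age - 70) + b_sex female + e`
with Gaussian `e`. Age is centred at 70 so `mu_group` stays
interpretable as the group mean at a typical age. Variables for which
this Gaussian model would put more than 1% of its mass below zero
(short contact times, pressures with large SDs) are instead drawn from
a lognormal whose two moments are matched exactly to the configured
group mean and SD, with covariate shifts acting on the log scale. These
are inherently positive, right-skewed measures, and a clipped normal
would both distort them and — the practical consequence — inject a
point mass at zero whose skew inflates the extreme tail of the
adjusted-model *t* statistic under the null. The published analysis
itself notes that nonnormal variables required log transformation,
which is the behaviour this choice reproduces: the pipeline's transform
step engages for exactly these variables. Remaining linear-scale draws
are clipped at zero with a logged clip count (under the defaults, below
1% per variable).

Handwriting age/sex slopes default to zero, so the configured group
means are also the marginal group means — the printed tables constrain
nothing more. Physical-performance outcomes (invented, realistic
older-adult means and SDs; the emulated study's physical summary table
is not reproduced here) default to *zero direct group effect with
nonzero age slopes*: unadjusted group differences arise purely through
the older altered group and disappear under age/sex adjustment,
reproducing the attenuation pattern that motivates adjusted models.
The same mechanism is exposed for handwriting variables through
`b_age`, and the test suite uses it to verify the attenuation behaviour
quantitatively.

Outcomes are generated independently across variables: no covariance
structure is published, so independence is a stand-in, not an inference
about any real cohort. Passing tests therefore demonstrate correctness
of the machinery under independence, normality/lognormality and linear
covariate effects — not robustness to correlated features, tremor
spectra, or biomechanically realistic handwriting.

The trajectory tier (`tier = "trajectories"` or `"both"`) renders an
actual pen recording per participant and task whose extracted time
down, time on air, mean pressure and mean speed hit the drawn
feature-tier values — time features within one 10 ms sampling interval,
pressure and mean speed within 5% (integer device-unit rounding is the
limiting factor). Constant step length makes per-interval speed
constant; pressure is constant over pen-down samples, so max pressure
equals mean pressure in rendered data. The rendered tier exercises the
I/O and extraction path end to end; distributional realism of the
trajectories is a non-goal.

# Numerical choices and problem sizes

* Duplicate timestamps: first occurrence kept (preserves monotone time
  for differentiation), later duplicates dropped and reported.
* Sampling-rate validation flags a mean inter-sample interval deviating
  from 10 ms by more than 20% (configurable).
* RDP tie-break: earliest index within `1e-9 (1 + d_max)` of the
  maximum distance.
* Intersection thresholds: overlap counted above 1e-3, containment
  above 0.99, of the smaller polygon's area.
* Degenerate model fits (zero residual variance) report `p = NA` with a
  flag.

The test suite verifies the Monte-Carlo properties at these sizes,
chosen to give 3-standard-error resolution around the nominal rates:
1,000 random recordings against the naive feature oracle; 1,000 random
vectors against the brute-force BH oracle; 100 random designs against
the normal-equations oracle plus 1,000 simulated cohorts (n = 174) for
95% CI coverage in [93%, 97%]; 1,000 null cohorts × 80 outcomes for
false-discovery control; 400 confounded cohorts for the attenuation
pattern; 75 noise-free and 500 jittered pentagon fixtures. The
acceptance script (`scripts/acceptance.R`) recomputes the same
quantities at moderately reduced replicate counts (stated in its
output's `n` fields).

# Known limitations

* The pentagon scorer assumes near-convex figures and clean closure;
  heavily tremulous drawings need expert review.
* Acceleration features are sensitive to the sampling interval and
  carry no smoothing; cross-study numerical comparability of
  speed-derivative features is limited.
* The generator's independence across variables understates multiplicity
  stress compared with correlated real features; an equicorrelated
  extension is a natural follow-up.
* Published adjusted coefficients from any real study reflect its raw
  data; with only printed group summaries available, the generator can
  match moments but not joint distributions, so per-variable regression
  output on synthetic cohorts is comparable in structure, not cell by
  cell.
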