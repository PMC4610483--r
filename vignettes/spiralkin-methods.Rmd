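---
title: "Scoring motor symptoms from digital spiral tracings: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring motor symptoms from digital spiral tracings: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiralkin)
```

## The measurement problem

Patients with advanced Parkinson's disease alternate within the day between
bradykinesia (slowness, hesitation, arrests) and medication-induced
dyskinesia (fast, irregular, involuntary movement). Both states disturb a
spiral-tracing task, but in nearly opposite directions, which makes the task
a usable at-home probe of motor state: a touch-screen device shows a
pre-drawn Archimedean spiral, the patient traces it from the centre outward
within about 10 s, and the device stores pen position in screen pixels with
millisecond timestamps at a nominal 10 Hz.

`spiralkin` implements the full analysis chain for such recordings:
kinematic series, a 29-feature spatiotemporal panel, correlation-matrix PCA,
cross-validated classification of bradykinesia versus dyskinesia, and
agreement statistics. Because no public recordings of this kind exist, the
package also ships a seeded simulator whose presets encode the two symptom
archetypes; all quantitative claims in the tests are made against that
simulator or against analytic fixed points, never against unavailable
patient data.

## Kinematic series

For samples \((x_i, y_i, t_i)\) and an origin \(O\):

* speed \(v_i = \lVert p_{i+1} - p_i \rVert / (t_{i+1} - t_i)\),
* radius \(r_i = \lVert p_i - O \rVert\),
* angle \(\varphi_i\): four-quadrant arctangent, unwrapped by folding any
  inter-sample jump larger than \(\pi\),
* radial velocity \(RV_i = (r_{i+1} - r_i)/(t_{i+1}-t_i)\) and angular
  velocity \(AV_i = (\varphi_{i+1} - \varphi_i)/(t_{i+1}-t_i)\).

The default origin is the **first drawn point**: the protocol starts the
tracing at the template centre, and using the drawing's own first sample
keeps the method self-contained when the template registration is unknown
(a known template centre can be passed instead). Per-interval series are
indexed to the left endpoint. Two degenerate situations are handled
explicitly:

* duplicate timestamps (a zero \(\Delta t\) would make every velocity
  undefined) are collapsed to the first sample with a warning at trial
  construction;
* a sample coinciding exactly with the origin has no defined angle; its
  angle is carried over from the nearest neighbour, and such zero-radius
  samples are excluded from the polar spiral fits, since a point at the
  origin lies on every spiral through the origin and carries no shape
  information.

## The feature panel

The panel has 29 named features. Conventions that the original
descriptions leave open were fixed once, as follows, and are exposed in
`feature_config()`:

* **Moments.** `Sp.mean` is the arithmetic mean of per-interval speeds;
  `Sp.cv` divides the sample standard deviation (n−1 denominator,
  used everywhere in the package) by the mean; `Sp.skew` is
  \((\sum(v_i-\bar v)^3/n)/s^3\). `Dt.mean` is the mean inter-sample time.
* **Wavelet band.** A single-level discrete wavelet transform with the
  20-tap Daubechies-10 filter splits the signal at half the Nyquist
  frequency; at 10 Hz sampling the detail band is 2.5–5 Hz, where
  dyskinetic irregularity lives. Boundary handling is half-sample symmetric
  extension, which minimises edge artifacts on ~100-sample signals;
  series shorter than 21 samples (the filter support plus one) yield
  missing values. `Rv.hf.cv` = sd/|mean| of the radial-velocity detail
  coefficients is heavy-tailed by construction (the detail mean of any
  signal is near zero); it is kept in this form deliberately because the
  panel is consumed through rank-robust PCA after standardisation.
* **Approximate Entropy.** Pincus' ApEn with \(m = 2\),
  \(r = 0.2\,\mathrm{sd}\), Chebyshev distance, self-matches included.
  A constant series returns 0 (maximal regularity). The implementation is
  validated against an \(O(n^2)\) double-loop enumeration to \(10^{-10}\).
* **Delta-peaks.** Local extremes are detected after collapsing plateaus
  (runs of equal values) to their first element; the first and last points
  are always included. `avgP`/`stdP` summarise the absolute differences
  between consecutive extreme values; `nPeaks` divides the extreme count by
  the series length. `incDev` measures drift of irregularity: the
  delta-peak series is scanned with overlapping windows of length
  `max(2, floor(len/3))` at 30 evenly spaced offsets (all distinct offsets
  when fewer exist) and the Spearman correlation of window order with
  window standard deviation is reported. When fewer than four delta-peaks
  exist — typical for the monotone angle series of a clean tracing — there
  is no variability trend to measure and the feature is defined as 0 rather
  than missing; reporting it as missing would discard most clean trials
  under the panel's complete-case policy, which would be absurd for the
  *best* drawings.
* **Inward fraction.** `Rv.pn005` is the percentage of drawn *path length*
  (not sample count) on intervals with \(RV < -0.05\) px/s; the slightly
  negative threshold absorbs measurement noise. The threshold is in device
  pixel units per second and is configurable.
* **Asymmetry.** Per axis through the origin, the absolute difference of
  the extreme-point distances divided by their sum; `TOTSYMM` adds the
  horizontal and vertical asymmetries. Note an inherent floor: a perfect
  spiral with \(k\) full turns has extent \(2\pi k b\) on one side and
  \(\pi(2k-1) b\) on the other, giving `TOTSYMM` ≈ 0.19 at three turns.
  Comparisons should therefore be relative, which is how the classifier
  consumes the feature.
* **Fit errors.** Least squares of \(r = a + b\varphi\) in polar space.
  `Err` (free intercept) and `Err0` (forced through the origin) use the
  first-sample origin; `errBF`/`err0BF` repeat both after translating the
  drawing so its *virtual optimal origin* \(O_u\) — the translation
  minimising the unconstrained fit RMSE — sits at the origin. \(O_u\) is
  found by differential evolution (DE/rand/1/bin, population 20, weight
  0.8, crossover 0.9, at most 100 generations, seeded) over the bounding
  box of the drawing expanded by 25% per side. The population always
  contains the first-sample origin, so `errBF` can never exceed `Err`; no
  analogous guarantee exists for `err0BF` versus `Err0`, because \(O_u\)
  optimises the unconstrained error only, and small inversions are indeed
  observed (~0.03 px on simulated tracings). The search is deterministic
  given its seed; convergence is declared when the population objective
  spread falls below \(10^{-6}(1+|f_{best}|)\), and a warning is issued
  only when the spread remains above 1% — with a fixed generation budget
  the best member is the result either way.

All features are invariant under rigid translation; speed/extent-scaled
features are 1-homogeneous under spatial scaling while `Sp.cv`, `Sp.skew`,
ApEn, `nPeaks`, `incDev`, `Rv.pn005` and `TOTSYMM` are scale-free (ApEn
through its sd-proportional tolerance).

The panel enumerates 29 names although the dimension-reduction stage is
often described over 28; which single feature would be dropped is not
determinable, so all 29 are computed and the PCA consumes whatever the
configuration includes (default: all).

## Scoring

**PCA.** Features are z-scored and decomposed (`prcomp` on the scaled
matrix — the correlation-matrix method). Zero-variance features are dropped
with a warning; rows with any missing feature are excluded (no imputation).
Signs follow a deterministic convention (dominant loading positive). Four
components are retained by default, mirroring the usual
"~70% cumulative variance" retention heuristic for this panel.

**Examples.** Symptoms are rated per *case* (a test occasion of three
tracings) while features are per tracing; the case score is the mean of its
per-trial component scores. Cases below a mean impairment of 5 (0–10 scale,
supplied as external metadata) are excluded — mild tracings carry too
little symptom-specific signal for either humans or classifiers. When
several raters labelled a case, one eligible rating (bradykinesia or
dyskinesia only) is drawn uniformly with a fixed seed, so each rater is
equally represented in expectation.

**Classification.** Stratified k-fold (default 10) cross-validation with
pooled out-of-fold predictions. "Default parameters" is toolkit-relative,
so the package fixes concrete values: MLP = one hidden layer of
\(\lceil (p+2)/2 \rceil\) units trained for up to 500 epochs (`nnet`'s
BFGS optimiser; the historically common learning-rate/momentum backprop
settings have no counterpart here and the optimiser choice does not affect
the fitted family); RF = 100 trees; SVMs at cost 1 (RBF \(\gamma = 1/p\));
unpenalised logistic regression. AUC comes from the pooled out-of-fold
probability rankings with midrank ties.

**Metrics.** For the 2×2 table with bradykinesia positive, accuracy is the
agreement fraction and the weighted kappa is computed from the margins
(linear weights; identical to unweighted Cohen's kappa for two categories).
Sensitivity and specificity follow the *predicted-margin* convention of the
reference evaluation tables (TP over all cases *called* bradykinesia, TN
over all cases *called* dyskinesia); because this differs from the common
truth-margin definition, both variants are returned with explicit names.
Rater agreement is summarised by the same kappa plus percent agreement and
false-positive/negative rates; reliability across raters or repeated trials
is the literal mean of all pairwise Pearson correlations (the phrasing
"mean of all possible correlations" is implemented as written rather than
as a model-based intraclass correlation, a deliberate choice recorded
here).

## The simulator

`sim_profile()`/`simulate_trial()` generate tracings at 10 Hz for up to
10 s (about 100 samples), ending early when the three template turns are
completed — fast tracers finish in ~6 s, bradykinetic ones rarely finish at
all. The angle advances at `base_angular_rate * speed_scale` (1.9 rad/s
baseline, i.e. three turns in ten seconds) modulated by a smooth lognormal
process (AR(1) on the log scale, lag correlation 0.9); the radius is
`pitch * angle` plus class-specific perturbations; positions get isotropic
white jitter.

Class presets encode the archetypes:

* *bradykinetic* — `speed_scale` 0.5; two Poisson-placed arrests of 0.7 s
  (angular rate collapses to 5%, then a 0.5 s festinating burst at 180%);
  very small jitter (0.1 px) and smooth speed modulation (sd 0.04), so the
  speed profile is slow and *regular*; lateral centre drift
  (`asymmetry_bias` 0.12).
* *dyskinetic* — `speed_scale` 1.5; a 2.5 px-RMS radial perturbation
  synthesised as Fourier-filtered white noise restricted to 2.5–5 Hz, which
  lands in the level-1 wavelet detail band by construction; 2 px jitter.
* *healthy* — unit speed, minimal noise; *tremor* — a radial sinusoid at
  4 Hz (kept below the 5 Hz Nyquist limit of 10 Hz sampling).

These defaults were fixed so that the documented archetype signatures hold
at the defaults — dyskinetic/bradykinetic mean speed ratio well above 3
(~280 vs ~42 px/s), radial-velocity detail-band sd ~70 vs ~6, higher speed
ApEn for dyskinesia, higher asymmetry for bradykinesia — each ordering in
at least 95% of seed pairs. Reproducing the speed-complexity ordering
forces the bradykinetic preset toward low positional jitter, which in turn
keeps its wavelet-band magnitude below what a real device would record;
the orderings, not the absolute band magnitudes, are what the validation
relies on. Cohorts add between-subject heterogeneity (sd 0.3 on log
`speed_scale`, 0.2 on the log band amplitude, 0.02 on asymmetry) and three
tracings per subject, mirroring the recording protocol.

What the simulator deliberately does **not** model: biomechanics of the arm,
pen pressure, pen lifts (the device format encodes none), device pixel
quantisation, micrographia-like progressive shrinking, or mixed symptom
states. Passing tests therefore demonstrate that the *pipeline recovers the
statistical signatures it targets*, not that it classifies real patients at
any particular accuracy; on the clean synthetic cohort the classes are
nearly separable (cross-validated accuracy ≈ 100%), which real rater-labelled
data would not be.

## Numerical choices and problem sizes

* Tolerances: ApEn vs brute force \(10^{-10}\); least squares vs grid
  minimisation \(10^{-6}\); DE origin recovery within 0.5 px of a known
  centre; wavelet coefficients vs an independent filter-bank reference to
  \(10^{-12}\).
* Ties in extremes are resolved by plateau collapse; Spearman ties by
  midranks (base `cor`).
* The test suite and the acceptance script use a 50 + 50-subject synthetic
  cohort (300 tracings) for the end-to-end check and ≤ 500-example null
  calibrations; these sizes give stable statistics while keeping a full run
  in tens of seconds.

## Known limitations

* Tremor is generated by the simulator but not targeted by the panel; at
  10 Hz sampling, action tremor (6–10 Hz) aliases and cannot be quantified
  — only the sub-Nyquist preset is simulated.
* Features are computed in device pixel units; no physical (mm) calibration
  is applied, so cross-device comparability relies on the scale-free
  features and on PCA standardisation.
* `Rv.hf.cv` is heavy-tailed (near-zero denominator); `TOTSYMM` has a
  turns-dependent floor; both are documented above and handled by
  standardisation rather than redefinition.
* The per-case aggregation (mean of per-trial component scores) is the
  simplest defensible rule; rating-time animation shows raters the three
  tracings jointly, and no aggregation rule is canonical.
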