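---
title: "Simulating and analyzing navigation through an auditory density space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing navigation through an auditory density space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soundnav)
```

## The problem

Spatial navigation recruits a well-characterized brain network, but many of
the quantities people navigate are not spatial: one can move toward a
remembered loudness, pitch, or texture. `soundnav` implements a complete
desk-scale model system for studying *navigation along an auditory feature*:
the **spectral density** of tone stacks — brief chords of randomly drawn pure
tones whose component count determines a percept ranging from "beepy"
(sparse) to "noisy" (dense). A participant hears a 2-s target sound, holds
its density in mind over a silent maintenance interval, and then steers an
ongoing tone-stack stream up or down in density with two buttons until it
matches the target. Yoked control conditions remove the memory component, the
adjustment component, or both, while matching acoustics and button presses.

Because the human dataset is not bundled, every stage of the pipeline runs on
simulated observers and simulated multi-subject BOLD volumes with planted
effects. The package is therefore a *calibration and validation instrument*:
it demonstrates which analyses are unbiased, which thresholds control error
rates, and how well planted effects are recovered — all statements about the
pipeline, not about human brains.

## The density scale

Density discrimination follows Weber-like behavior: just-noticeable
differences grow with density, so the stimulus dimension uses
logarithmically spaced tone counts. `make_density_scale(2, 196, 26)` places
26 levels geometrically between 2 and 196 tones and rounds to integers.
Rounding collides at the sparse end (the exact second point, 2.40, rounds
to 2); collisions are resolved by incrementing to the next unused integer,
preserving strict monotonicity and exact endpoints. The collision region
(levels ~2–11) therefore deviates from the exact geometric grid by up to two
tone counts; the dense end matches the grid to within rounding.

Tone stacks are 190 ms with 2-ms raised-cosine ramps and 10-ms gaps
(`synth_stack`, `synth_series`). Component frequencies are drawn
log-uniformly on 250–4000 Hz, freshly for every stack. Stacks are equated
for RMS over the full stack; because RMS scaling is applied per stack, the
equalization is exact by construction. Component phases are drawn uniformly
on [0, 2*pi*) to avoid onset artifacts; the sample rate defaults to 44.1 kHz.
These last three choices are conventional and immaterial to the analyses.

## The experimental design

`build_run()` generates one 28-trial run: seven sets of the four conditions
MA/MP/NA/NP (Memory/No-memory crossed with Adjust/Parity), ordered so that
MA precedes NA and MP precedes NP within each set and no condition repeats
consecutively. Memory trials present ten stacks at the target density;
non-memory trials alternate the lowest and highest levels. Maintenance
silences are uniform on 1–3 s, inter-trial intervals on 0–2 s. Start/target
pairs come from a 28-pair set (`make_pair_set`) stratifying targets over
level-range quartiles with 14 upward and 14 downward trajectories of at
least 5 levels — the published design states the sampling goals but not the
pairs, so this is one consistent instantiation.

Acoustic and motor matching work by yoking (`yoke_trials`): each parity
trial replays the 40-stack adjustment series of the most recent adjustment
trial of matching memory status, and each adjustment trial's ignored digits
copy the most recent parity trial's stream. A parity trial with no earlier
source in the run receives a seeded dummy random-walk series; digit streams
bootstrap from a random dummy trial. Digit counts follow the press-matching
rule: previous adjustment trial's count plus the running mean of unanswered
digits (0.5 at block start), stochastically rounded, clamped to the six
available one-second slots (seconds 2–7 of the 8-s phase). The running mean
resets per block; at pure design time, before any observer has been
simulated, the 0.5 fallback applies throughout and a session simulator can
supply the live history.

## Simulated observers

`psychometric_observer(sigma_log, lapse_rate)` judges which of two stacks is
denser with P(correct) = (1 − lapse) * Phi(|delta| / (sqrt(2) * sigma)) +
lapse/2, where delta is the log-density difference. The two-down/one-up
staircase (`run_staircase`) tracks the 70.7% point: step 1/3 in log units
until the second reversal, then 1/6, stopping at six reversals and averaging
the final two. Two properties matter for interpreting it:

* Additive steps bound the resolution: an ideal observer's estimate
  converges to roughly half the final step size, not zero.
* The six-reversal estimate is nearly unbiased only when the track starts
  near threshold. A start far above threshold lets early errors trigger the
  step-size reduction during the descent, leaving the final reversals on the
  transient (3–6 percentage points of upward bias). The convergence
  calibration therefore initializes the track just above the observer's
  threshold, which measures the procedure's asymptote — its stationary
  tracking point is 70.7% regardless of start.

`navigation_observer()` generates adjustment behavior: it stores the target
log-density with memory noise, reads the current level with perceptual
noise, presses toward the remembered target one level per 200-ms stack, and
commits (stops for the rest of the trial) once the perceived distance falls
below its stop criterion. The defaults (`memory_sigma = 0.45`,
`perceive_sigma = 0.15`, `stop_criterion = 0.6`, log-density units; one
scale step is about 0.18) were calibrated once so that simulated sessions
resemble trained participants: ~95% of trials end closer to the target than
they started, mean final distance ~15% of the scale, undershoot on the
start side of the target in ~80% of trials, parity accuracy ~90%. These are
calibration knobs, not fitted values. NA trials use a random-direction
press policy whose rate is matched to the running MA press rate, mirroring
the instruction to use a similar number of presses. The scale clips at its
boundaries; there is no wraparound.

## Behavioral scoring

`navigation_score` counts level steps between final and target sounds and
flags improvement and undershoot. `parity_score` implements the
dislocation-tolerant accuracy: matches divided by the larger of digit and
response counts, where a response series whose count differs from the digit
count (an extra or a missing response) is aligned by the best single
insertion or deletion; equal counts are scored positionally. Under this
reading a pure guesser scores 50% in expectation, the task's nominal chance
level; always maximizing over shifted alignments at equal counts would
inflate a guesser well above chance, which is why the count-difference
reading was adopted. `rating_accuracy` is Spearman's rho with missing
ratings imputed at 2.5 (the scale midpoint) and `NA` returned for
zero-variance series. `transform_proportion`/`transform_correlation` apply
the arcsine-square-root and Fisher z transforms. `exclusion_flags`
reproduces the cohort rules: more than 2 SD below the group mean on
adjustment performance (performance = negative mean final distance), or
head motion above 3 mm.

## Synthetic BOLD data

`make_grid_and_rois()` builds a small ellipsoidal "brain" (default
20 x 20 x 16 voxels at 3 mm, TR 1.056 s) with disjoint compact regions
standing in for auditory cortex, hippocampus, inferior frontal gyrus and
posterior cingulate. `generate_subject()` sums:

* HRF-convolved condition boxcars and the centered density modulator,
  scaled per ROI with additive per-subject deviations (`subject_sigma`);
* a multivoxel low-vs-high density pattern driven by the HRF-convolved
  binary label series. The pattern has a component shared across the cohort
  plus a per-subject voxelwise idiosyncrasy of equal magnitude
  (`pattern_subject_sigma = 1`). Both are deliberate: across-participant
  decoding targets the consistent component of individually variable codes,
  and a second-level t-test over cross-validation folds is degenerate if
  subjects are literally identical — fold maps then differ only by a common
  scalar and t diverges;
* AR(1) noise (coefficient 0.3), cosine drift inside the high-pass band,
  and a partial leak of the motion and respiration nuisance series (the
  respiration stand-in is a 0.25-Hz sinusoid sampled on the TR grid).

What the generator does **not** emulate: EPI artifacts, field inhomogeneity,
true motion displacement of the image grid, physiological noise beyond the
supplied regressors, spatial autocorrelation of the noise, and anatomical
variability — passing tests show the analysis code is correct and
calibrated, not that it would survive every property of real data.

## Univariate GLM

`build_design()` assembles whole-trial condition boxcars convolved with the
canonical double-gamma HRF (peak 6 s, undershoot 16 s, ratio 6, 32-s
support, unit peak), centered parametric modulators serially orthogonalized
in their declared order (matching the time-then-distance construction used
for the distance analysis), a cosine high-pass basis below 1/230 Hz, and
nuisance columns. `fit_glm()` uses OLS with optional AR(1) prewhitening; the
coefficient is the pooled lag-1 autocorrelation of the OLS residuals.
Contrasts use the standard weights (memory: MA+MP−NA−NP; adjustment:
MA+NA−MP−NP; interaction: (MA−MP)−(NA−NP)). Group inference is a voxelwise
one-sample t-test; family-wise error control uses sign-flip max-statistic
permutation (exact enumeration of all 2^n sign patterns for n <= 12),
with Bonferroni as a fast fallback, 6-connectivity clusters, a minimum
extent of 5 voxels, and small-volume correction by restricting the same
procedure to an a priori mask.

## Crossnobis searchlight

The across-participant multivariate analysis labels every adjustment-phase
stack low or high density (levels 1–13 vs 14–26; labels can change within a
trial), by adjustment direction, or whole trials by target half. Per
subject, a two-regressor GLM yields one beta pattern per label; the pattern
difference is whitened per searchlight neighborhood by the inverse square
root of a Ledoit–Wolf-regularized noise covariance estimated from the GLM
residuals (correlations shrunk toward zero with the analytically estimated
intensity, variances retained — computing the intensity on standardized
residuals makes whitening invariant to voxel rescaling). The searchlight is
a 4-mm sphere: with 3-mm voxels, a center and its six face neighbors.

Leave-one-participant-out cross-validation defines one fold per subject:
`d = (mean training-subject whitened difference) . (left-out subject's
whitened difference) / P`. The estimator is unbiased — its null expectation
is zero and individual folds can be negative — in contrast to the naive
squared distance, which is strictly positive under the null; the test suite
demonstrates both. Fold maps are smoothed at 6-mm FWHM and tested against
zero one-sided with the shared permutation FWE machinery.

## Problem sizes and numerical choices

The test and calibration workloads use: 500 staircases for the convergence
calibration; 200 null cohorts of 8 subjects on a 12^3 grid for the
unbiasedness and FWE calibrations; and ten replicates of 10-subject cohorts
on a 14 x 14 x 12 grid with one 28-trial run per subject (~487 volumes) for
parameter recovery, with a 60-voxel region carrying a density-modulator
amplitude of −0.8 and a 150-voxel region carrying a shared density pattern
of amplitude 0.1 (~3x the beta estimation noise). The pattern region is
deliberately large relative to the 6-mm kernel so that the smoothed group
peak falls inside it rather than on the smoothing fringe. The two effects
are recovered from separate cohorts: both are density-driven, so a uniform
univariate response is itself decodable and a multivoxel density pattern
loads voxelwise on the density modulator — planting both in one cohort makes
each analysis peak in the other's region by construction. Degenerate inputs
are handled explicitly: zero-variance voxels are masked in group maps,
constant modulators are dropped with a warning, rank-deficient designs
raise an error naming the collinear columns, and staircase deltas are
floored at 10^-6.

## Known limitations

* The 28 start/target pairs, staircase step units and start value, the NA
  press policy, and the digit-count history scope are under-specified in
  the source design; the package's choices are documented above and flagged
  in the function documentation.
* Searchlight whitening assumes more residual frames than neighborhood
  voxels (amply satisfied at 7-voxel neighborhoods).
* Permutation inference assumes sign-symmetric subject effects under the
  null; the synthetic generator satisfies this by construction.
* The rating simulator is a coarse latent-variable binning, sufficient to
  exercise the Spearman scoring but not a model of human ratings.
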