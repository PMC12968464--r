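# soundnav

Simulation and analysis of *navigation through an auditory feature space*.

The feature is the **spectral density** of a tone stack — the number of
concurrent pure tones, randomly drawn on a log-frequency band, in a 190-ms
chord. Sparse stacks sound "beepy", dense ones "noisy". In the task this
package models, a listener hears a 2-s target sound, holds its density in
mind across a silent maintenance interval, and then steers an ongoing
tone-stack stream up or down in density with two buttons until it matches
the remembered target. A 2 x 2 design (memory x adjustment: conditions MA,
MP, NA, NP) separates the memory and adjustment components while yoked
stimulus streams and a digit parity task match acoustics and button presses
across conditions.

`soundnav` provides the full pipeline at desk scale, with simulated
observers and simulated multi-subject BOLD data in place of participants:

* **Stimuli** — a 26-level geometric density scale from 2 to 196 tones
  (`make_density_scale`), RMS-equated tone-stack synthesis and WAV export
  (`synth_series`, `write_wav`).
* **Design** — fully resolved 28-trial runs with ordering constraints,
  press-matched digit streams and acoustic yoking (`build_run`,
  `yoke_trials`, `as_event_table`).
* **Observers** — a signal-detection discrimination observer with a
  two-down/one-up adaptive staircase converging on the 70.7% point
  (`run_staircase`: step 1/3 in log units until the second reversal, then
  1/6; threshold = mean of the final two of six reversals), and a noisy
  navigating agent for the adjustment phase (`simulate_adjustment`).
* **Scoring** — navigation distance in scale steps, dislocation-tolerant
  parity accuracy, Spearman rating accuracy with midpoint imputation,
  arcsine/Fisher transforms, and cohort exclusion rules (`parity_score`,
  `rating_accuracy`, `exclusion_flags`).
* **Synthetic BOLD** — multi-subject 4D datasets with planted univariate
  density modulation, a cross-subject multivoxel density pattern, AR(1)
  noise, drift and nuisance series (`generate_cohort`).
* **GLM** — canonical double-gamma HRF, centered serially-orthogonalized
  parametric modulators, 1/230-Hz cosine high-pass, AR(1) prewhitening,
  condition contrasts, and sign-flip max-statistic permutation FWE with
  cluster extent and small-volume correction (`build_design`, `fit_glm`,
  `threshold_fwe`).
* **MVPA** — across-participant crossnobis searchlight: per-neighborhood
  Ledoit–Wolf variance-retaining noise normalization, 4-mm spherical
  searchlight, leave-one-participant-out cross-validated distances, 6-mm
  smoothing and group inference (`crossnobis_loso`, `smooth_and_test`).

The crossnobis distance for fold *f* (left-out subject *f*) and a
neighborhood of *P* voxels is

    d_f = (mean_{s != f} w_s)' w_f / P,    w_s = Sigma_s^{-1/2} (b_s^low - b_s^high)

which is unbiased under the null (zero expectation, individual folds may be
negative), unlike the naive squared distance.

## Worked example

Simulate a four-run session for one observer and score it:

```r
library(soundnav)
scale <- make_density_scale()           # 26 levels, 2..196 tones
sess  <- simulate_session(scale, n_runs = 4, seed = 42)
round(summarize_session(sess), 3)
#>   prop_closer mean_final_distance mean_final_distance_frac prop_undershoot
#> 1       0.929               3.857                    0.154           0.857
#>   parity_mp parity_np rho_ma rho_mp rho_na rho_np
#> 1     0.899     0.904  0.391  0.483   0.51  0.763
```

The simulated participant ends closer to the target than it started on 93%
of memory-adjustment trials, finishes on average 3.9 levels (15% of the
scale) from the target, undershoots (stops on the starting side of the
target) on 86% of trials, and scores ~90% on the digit parity task — the
qualitative signature of a trained human participant. `sess$events` holds
BIDS-events-like tables (one row per instruction, stack, digit, press and
rating event) that feed the GLM and searchlight stages; see the vignette
for the full neuroimaging walk-through on synthetic cohorts.

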