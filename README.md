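# gaitlds

Phase-dependent local dynamic stability and gait-feature analysis of
free-living trunk accelerometry, for fall-risk biostatistics.

Repeated fallers among community-dwelling older adults differ from
nonfallers in how quickly small stride-to-stride perturbations of the trunk
are absorbed — and that rate depends on *where in the step cycle* the
perturbation occurs. `gaitlds` implements the full analysis chain for
3-axis (AP/ML/V) lower-back accelerometer recordings sampled at 100 Hz:

* **Walking-bout detection** (≥ 60 s) with an amplitude filter and a
  locomotor-band spectral-energy filter.
* **Preprocessing**: orthogonal Daubechies-4 wavelet detrending (an exact
  orthogonal projection — idempotent, perfectly reconstructing), trapezoidal
  integration to intrastep 3D velocity, step onsets at vertical-velocity
  maxima.
* **Phase-dependent local dynamic stability** λ at 0–80% of the step cycle
  from two 6D state spaces — differential `[a, v]` and delayed
  `[v(t), v(t+3Δt)]` — via perturbation reaction curves
  ⟨d_i(t)⟩: λ is either the OLS slope of ln⟨d_i(t)⟩ over the first 10% of
  the cycle (eq. 1) or the two-point log-ratio (1/t_n)·ln(d(t_n)/d(0)),
  t_n = 10% of the cycle (eq. 2). Negative λ = locally stable gait.
* **Wolf's phase-independent exponent** per axis (6D delay embedding,
  lag 8, orientation-preserving neighbour replacement), plus an
  average-mutual-information lag selector.
* **46 gait features** (harmonic ratios, step/stride regularity, step
  symmetry, RMS/range, dominant-frequency shape, timing/volume measures,
  the Wolf exponents and the 8 phase-λ features).
* **PLS-DA with target projection**: NIPALS PLS1 (4 latent variables),
  TP loadings in [−1, 1] ranking each feature's discriminant value,
  leave-one-out cross-validated sensitivity/specificity/AUC, Mann–Whitney
  group tests, and test–retest ICC(A,1) between the first and last third of
  each subject's bouts.
* **A synthetic-cohort generator** with analytically known, per-phase AR(1)
  ground-truth contraction rates, used by the end-to-end validation.

## Worked example

Simulate a cohort in which "nonfallers" have weaker deviation contraction
(larger λ) at 0% and 60% of the step cycle, then run the full pipeline:

```r
library(gaitlds)

cfg <- gait_sim_config(n_subjects_per_group = c(faller = 31, nonfaller = 39),
                       bouts_per_subject = c(10, 12), seed = 2015)
cohort <- simulate_cohort(cfg)
res <- run_pipeline(cohort, pipeline_config(phases = c(0, 0.6)))
make_report(res)
```

Output (abridged; ~5 min on one CPU):

```
Classification (leave-one-out):
  X1: sensitivity 0.97  specificity 0.97  AUC 1.00  error 0.03
  X2: ...            AUC 0.90 ...
  X3: ...            AUC 1.00 ...

Top |TP| loadings (X1):
  1. lambda_diff_p0_eq2 ...   # all eight phase-dependent stability
  ...                         # features rank above the 38 conventional ones

Test-retest ICC (first vs last third of bouts):
  lambda_diff_p0_eq1: 0.94 [...]
  ...
  lambda_lag_p60_eq2: 0.89 [...]
```

Reading it: `X1` (all 46 features) and `X3` (only the 8 phase-λ features)
separate the groups almost perfectly, `X2` (the 38 conventional features
alone) does clearly worse — the phase-dependent stability features carry
the discriminant signal, exactly the injected ground truth. Group medians
of λ are larger (less stable) for the simulated nonfallers at phases 0% and
60% with Mann–Whitney p < 1e-5, and all eight features are highly
repeatable across bout splits (ICC 0.89–0.98).

Per-module entry points: `detect_walking_bouts()`, `preprocess_bout()`,
`embed_differential()` / `embed_delayed()`, `reaction_curve()` +
`lambda_eq1()` / `lambda_eq2()`, `wolf_lambda()`, `bout_gait_features()`,
`assemble_matrices()`, `fit_pls_nipals()` + `target_projection()`,
`cross_validate()`, `icc_absolute()`. A command-line wrapper with
`simulate` / `detect-bouts` / `run-all` verbs lives in
`inst/cli/gaitlds-cli.R`.

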