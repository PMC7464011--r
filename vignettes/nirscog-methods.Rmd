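---
title: "Models and methods behind nirscog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nirscog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirscog)
```

`nirscog` implements one coherent analysis: does baseline dorsolateral
prefrontal (DLPFC) activity during a training task, measured with a
two-channel dual source-detector fNIRS device, predict cognitive change
after a two-arm training intervention? This vignette documents the models,
the defaults and the design decisions, in the order data flow through the
package.

## 1. The synthetic trial

Real trials of this design rarely deposit raw data, so the package treats
the generative model as a first-class, tested component rather than a test
fixture. The generator emulates:

* **Cohort structure.** 72 participants by default (36 per arm), two
  thirds male, ages drawn from a truncated normal (mean 21.6 y, SD 1.26 y,
  range 18–30) — a young-adult university sample. Arms are assigned by
  stratified blocked randomization: permuted blocks of 4 within each sex
  stratum at a 1:1 ratio, so strata whose sizes are multiples of 4 (the
  default 48 M / 24 F) always split exactly evenly.
* **Cognitive scores.** Eleven outcomes spanning processing speed (Cd,
  SS), inhibition (rST, ST), short-term memory (DS-F, DS-B), working
  memory (LNS, WMU), attention (D-CAT) and episodic memory (LM immediate
  and delayed). Baseline scores are normal with instrument-typical means
  and SDs; the change score is

  $$\Delta_j = \mu_{ACT,j} + \delta_j\,\mathbf 1[\text{BT}] +
     \sigma_j\left(\rho_{L,j} z_L + \rho_{R,j} z_R +
     \sqrt{1-\rho_{L,j}^2-\rho_{R,j}^2}\,\varepsilon\right),$$

  where $z_L, z_R$ are the participant's latent neural amplitudes
  standardized by their within-arm theoretical moments. This construction
  makes $\rho$ the *exact* generative within-arm brain–change correlation,
  which is what the recovery and cross-validation tests rely on. Default
  $\delta_j$ and $\sigma_j$ values are in score units, calibrated to
  magnitudes plausible for four weeks of training (e.g. a 3.8-point arm
  difference on digit-symbol coding against a change SD of ~5); default
  $\rho = 0.4$ on both sides for the four outcomes where an association is
  simulated (Cd, SS, LNS, WMU) and 0 elsewhere.
* **Latent amplitudes.** Log-normal per side (activation is positive),
  arithmetic mean 1.0 a.u. in the training arm vs 0.65 in the control arm
  (sdlog 0.4), reproducing a baseline group difference in game-related
  activity. Equal-mean configurations (`null_effect_config()`) remove it.
* **Recordings.** Deep signal = amplitude × (game boxcar ⊗ double-gamma
  HRF, unit peak) + coupling × systemic + linear drift + white noise;
  shallow signal = the same systemic component + its own drift + noise.
  The systemic term is a 0.08 Hz Mayer-wave sinusoid (0.3 a.u.) plus a
  1.1 Hz cardiac sinusoid (0.3 a.u.), both with random phases, plus AR(1)
  wander (φ = 0.995, innovation SD 0.02 at 10 Hz, stationary SD ≈ 0.2).
  The three components deliberately exercise all three cleanup stages: the
  cardiac tone is removed by the low-pass filter, the Mayer wave and the
  AR(1) wander pass the filter and can only be removed by the
  short-separation regression, and the drift by detrending.

The device model is a single-wavelength (810 nm) total-hemoglobin
instrument: no oxy/deoxy separation exists in the data, so none is
modelled. The sampling rate (10 Hz) and the 150 s R-V-R-V-R session
length (five 30 s blocks) are declared defaults, configurable throughout.

What the generator does **not** emulate: motion artifacts (spikes,
baseline jumps), task-correlated systemic responses (the systemic phase is
independent of the block design), optode-coupling drop-outs, practice
effects within the recording, or non-normal score distributions. Passing
tests therefore demonstrate correctness of the pipeline's arithmetic and
its behaviour under the stated noise model — not robustness to artifacts
real fNIRS data can contain.

Reproducibility is seed-stream based: a master seed spawns one substream
per participant (scores, amplitudes) and per recording, so outputs are
independent of generation order and byte-identical across runs.

## 2. Preprocessing

The chain is detrend → low-pass → short-separation regression → baseline
correction → block averaging, applied in that order, with detrending and
filtering applied to the shallow and deep channels separately before the
regression consumes both.

* **Detrend**: OLS straight-line removal over the whole recording.
* **Low-pass**: 4th-order Butterworth at 0.1 Hz, run forward and backward
  so the phase response is zero and block boundaries are not displaced;
  the magnitude response is squared (the single-pass −3 dB point becomes
  −6 dB). Because two-pass IIR filters have start-up transients, the
  series is mean-centred and extended by odd reflection (12/cutoff
  seconds, capped at the series length) before filtering and trimmed
  after; the DC gain is then 1 to numerical precision and the contract at
  0.5 Hz (< 5% amplitude) and 0.01 Hz (> 95%) follows the closed form
  $|H(f)|^2 = (1 + (f/f_c)^{8})^{-1}$.
* **Short-separation regression**: the neural series is the residual of
  OLS of deep on shallow with intercept, fitted over the entire recording.
  A per-block fit would track slow coupling changes but is noisier; the
  whole-recording fit is the shipped choice. A constant shallow channel
  (zero variance) leaves nothing to regress out; the deep channel is then
  mean-centred and a warning raised.
* **Baseline correction**: each game block has the mean of its
  *immediately preceding* rest block subtracted; rest blocks are centred
  on their own means. Schedules are validated so this pairing always
  exists.
* **Activity scalar**: the mean of the corrected signal over all
  game-block samples (equivalently, per-block means weighted by sample
  counts). Whether one averages both game blocks or only one is a genuine
  degree of freedom in this design; both-blocks is implemented because it
  halves the estimator variance, and per-block means are exposed on the
  `activity_estimate` so users can depart from it.

Stage order matters: regressing before baseline correction (the shipped
order) is not the same operation as the reverse, and the test suite pins
the shipped order by checking the two disagree.

## 3. Permutation inference

All group comparisons are covariate-adjusted permutation tests built on
one statistic: the partial F for the group term,
$F = \frac{(SSE_r - SSE_f)/1}{SSE_f/(n - p)}$, comparing the full model
(intercept + covariates + group) to the reduced model without group. This
equals the classical ANCOVA F, and the test suite verifies it against an
independent two-model `lm()` computation at 1e-10.

* **Permutation scheme**: Freedman–Lane. Residuals of the reduced
  (covariates-only) model are permuted, added back to the reduced fit,
  and F recomputed, which preserves the nuisance structure under the
  null. With no covariates the permutation distribution collapses onto
  the $\binom{n}{n_1}$ distinct group relabellings; when that count is at
  most `n_perm` it is enumerated exhaustively and the p-value is the
  exact proportion of assignments with $F^* \ge F_{obs}$ (a relative tie
  tolerance of 1e-8 absorbs floating-point ties). Otherwise the
  Monte-Carlo p is $(b + 1)/(B + 1)$, which cannot be zero; the default
  is $B = 10{,}000$.
* **Effect size**: $\eta^2 = SS_{group}/SS_{total}$ with the partial
  (Type-III-like) group SS in the numerator and the total SS about the
  mean in the denominator. Users preferring partial η² can form
  $SS_{group}/(SS_{group} + SSE_f)$ from the reported pieces.
* **Regression direction**: the brain–behaviour model is ambiguous in
  this design — one can regress change on activity or activity on change
  with the same covariates (pre-score, age, sex). Both are implemented
  behind a `direction` flag; the default (`change_on_brain`) regresses
  change on activity because that is the direction with a prediction
  use-case, and cross-validation always uses it. All continuous variables
  are z-scored before fitting so the focal coefficient is a standardized
  β; the binary sex indicator keeps its 0/1 coding.
* **FDR**: Benjamini–Hochberg step-up, implemented directly (ordered
  p-values, $\min_{j \ge i} \min(1, m p_{(j)}/j)$) and cross-checked
  against `p.adjust(, "BH")` in the tests. Families follow the analysis
  structure: the two baseline-activity tests, the eleven change-score
  tests, and the per-side-and-outcome regressions each form one family.

A note on degrees of freedom: the baseline model
`activity ~ group + age + sex` on 72 participants has 68 residual df, and
the change model `change ~ group + pre + age + sex` has 67. Reports of
this design sometimes print F(1, 67) for both; the package reports the df
its own models imply.

## 4. Cross-validated prediction

For each hemisphere and outcome, `change ~ activity + pre + age + sex` is
fitted by least squares on 4/5 of the training arm and evaluated on the
held-out fifth, k = 5, fold sizes within one participant of each other.
Because the trial's outcomes live on different scales, each fold's RMSE is
computed on the outcome standardized by *training-fold* statistics (no
leakage from the test fold): an RMSE of 1 is then the error of an
uninformative model and values are comparable across outcomes and sides.
The left and right models share the fold assignment, making the side
comparison paired and removing fold-assignment noise from the contrast.
Whether a single published RMSE per side refers to one outcome or pools
over outcomes is ambiguous in this design, so the package reports
per-outcome rows plus a pooled (mean over outcomes) row per side and
takes no side.

## 5. Numerical and degenerate-input choices

* Permutation p-values use $(b+1)/(B+1)$; exact enumerations use the
  plain proportion including the identity assignment.
* Singular designs abort naming the collinear columns; zero-variance
  focal predictors abort; a zero-variance shallow channel degrades to
  mean-centering with a warning; a CV fold with zero training-outcome
  variance is excluded from the mean with a warning.
* Game/rest block membership uses the half-open convention
  $start \le t < end$ on the grid $t_k = (k-1)/f_s$, so contiguous blocks
  partition samples exactly.
* The HRF is the conventional double-gamma (shapes 6 and 16, rate 1,
  undershoot ratio 6): zero at $t = 0$, peak near 5 s, positive integral.
  The neural regressor is normalized to unit peak so the simulated
  amplitude is in the same units as the plateau response.

## 6. Problem sizes

The shipped tests and the acceptance script use the trial's native scale
— 72 participants, 150 s recordings at 10 Hz, 10,000 permutations for
single analyses — and scale repetition counts (e.g. 1000 null replicates
at 500 permutations for the type-I-error check; 100 seeded cohorts for
the cross-validation ordering check) so the full suite completes in a few
minutes on one core. These counts are stated in the tests themselves;
enlarging them tightens the Monte-Carlo bands but changes nothing
qualitatively.

## 7. Known limitations

* The preprocessing targets slow systemic structure; it has no motion
  artifact correction, and the simulation generates none.
* Total-Hb only: no chromophore separation, so findings about "activity"
  are about total-hemoglobin change.
* The generator's systemic physiology is phase-independent of the task;
  task-locked scalp responses (which short-separation regression handles
  in real data but which bias naive pipelines more strongly) are not
  simulated.
* Freedman–Lane is one of several valid covariate-adjusted permutation
  schemes; sequential-SS iterative schemes used by some ANOVA-permutation
  software give different (usually close) p-values and are out of scope.
* Missing data abort the analysis by design (the target design is a
  no-dropout trial); there is no imputation machinery.
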