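---
title: "Mode-wise Poincare descriptors for stress classification: methods and design"
author: "StressVMD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mode-wise Poincare descriptors for stress classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(StressVMD)
```

## The problem

Mental-arithmetic stress leaves a measurable trace in scalp EEG and in the
ECG: the short-term variability of band-limited oscillatory activity
differs between subjects who cope with the task ("good" performers, label
G) and subjects who do not ("bad" performers, label B). StressVMD
implements a complete pipeline for detecting that trace in multichannel
EDF recordings:

1. **Decomposition.** Each channel is split into K band-limited intrinsic
   modes by variational mode decomposition (VMD).
2. **Description.** Each retained mode is summarised by three descriptors
   of its second-order difference (Poincare) plot: fitted-ellipse area,
   mean radial distance and the central tendency measure (CTM).
3. **Screening.** Descriptors are screened for class differences with the
   Wilcoxon signed-rank test.
4. **Classification.** A multilayer perceptron (MLP) and a support vector
   machine (SVM) classify subject-trial feature vectors per brain-region
   channel group under a 70/10/20 percentage split and 10-fold
   cross-validation, reported as sensitivity, specificity, accuracy, F1
   and Cohen's kappa.

## Variational mode decomposition

VMD poses decomposition as an optimisation: find modes $u_k$ and center
frequencies $\omega_k$ minimising the summed bandwidths

$$\min_{u_k,\omega_k} \sum_k \left\| \partial_t \left[ \left( \delta(t) +
\tfrac{j}{\pi t} \right) * u_k(t) \right] e^{-j\omega_k t} \right\|_2^2
\quad \text{s.t.} \quad \sum_k u_k = f,$$

i.e. each mode, made analytic by its Hilbert transform and shifted to
baseband at its own center frequency, should be as smooth (narrowband) as
possible while the modes jointly reconstruct the input. The ADMM solution
alternates, entirely in the frequency domain:

* a Wiener-filter mode update
  $\hat u_k \leftarrow (\hat f - \sum_{i \neq k} \hat u_i +
  \hat\lambda/2)\, / \,(1 + 2\alpha(\omega - \omega_k)^2)$,
* a center-frequency update (the spectral centroid of $|\hat u_k|^2$ over
  the positive half-spectrum), and
* the dual ascent
  $\hat\lambda \leftarrow \hat\lambda + \tau(\hat f - \sum_k \hat u_k)$,

until the summed relative change of the modes falls below `tol`. The
input is mirror-extended by half its length on each side before the FFT
to suppress boundary artifacts, and the extension is cropped after
inversion. Modes are returned sorted by ascending center frequency, so
"mode 1" is always the slowest rhythm.

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `K` | 10 | — | number of modes; features keep modes 1–8 |
| `alpha` | 2000 | — | bandwidth penalty; larger = narrower modes |
| `tau` | 0 | — | dual step; 0 leaves a residual, reported not dropped |
| `tol` | 1e-7 | relative | convergence threshold on mode change |
| `maxIter` | 500 | — | ADMM iteration cap |
| `init` | uniform | — | center-frequency start (uniform/zero/random) |

The defaults are the conventional choices for this ADMM scheme; all are
caller-overridable. With `tau = 0` the reconstruction constraint is soft:
broadband noise that belongs to no narrow mode stays in the `residual`
slot. There is no dedicated DC mode; the lowest mode may absorb a DC
offset.

Degenerate inputs are handled explicitly: an all-zero signal is a fixed
point (all-zero modes, convergence after one sweep, center frequencies at
their initial values with zero energy), non-finite samples and signals
shorter than $2K$ are rejected. Center-frequency estimates are clamped
into $[0, f_s/2]$ before reporting.

## Poincare descriptors

For a mode $x(t)$ the second-order difference plot scatters
$X(t) = x(t+1) - x(t)$ against $Y(t) = x(t+2) - x(t+1)$. With raw second
moments $S_X^2 = \overline{X^2}$, $S_Y^2 = \overline{Y^2}$,
$S_{XY} = \overline{XY}$ (about the origin — difference sequences of
oscillatory modes are essentially zero-mean, and the moments are used
uncentred deliberately), the descriptors are:

* **ellipse area** $\pi a b$ where $a, b$ are the square roots of the
  eigenvalues $\lambda_\pm = \big( (S_X^2 + S_Y^2) \pm D \big)/2$,
  $D = \sqrt{(S_X^2 - S_Y^2)^2 + 4 S_{XY}^2}$, of the second-moment
  matrix. The eigenvalue form guarantees real, nonnegative radii; any
  tiny negative $\lambda_-$ produced by round-off is clamped by absolute
  value.
* **mean distance** $m$: the average Euclidean distance of the plot
  points from the origin. The radius tag `r` carried alongside `m` in
  feature tables is metadata only; `m` itself does not depend on it.
* **CTM**: the fraction of points strictly inside the circle of radius
  `r` (default 0.5) around the origin — high CTM means the differences
  concentrate near zero.

All three are scale-equivariant in the expected way (area scales with
$c^2$, $m$ and the radii with $|c|$, and CTM of scaled data equals CTM of
the original at radius $r/|c|$), which the test suite asserts.

## Feature table, balancing, screening

The feature map is long-format: one row per (subject, trial, channel,
mode) holding the three descriptors and the class label, with modes 1–8
retained out of the 10 extracted. Flattened per subject-trial this yields
a channels × 8 × 3 feature vector.

Class imbalance (the emulated dataset has 26 G vs 10 B subjects) is
handled the way the source protocol describes — by adding "dummy
participants", i.e. whole-subject channel-wise copies — applied to the
*minority* class until the counts match, since replicating the majority
cannot balance anything. Replicas get fresh synthetic ids and the draw is
seed-deterministic.

Screening uses the two-sided Wilcoxon signed-rank test per descriptor
column at significance 0.05 (95% confidence). Pairing across the two
classes is positional after sorting each class by (subject, trial,
channel, mode); this is well defined exactly because balancing has
equalised the counts, and makes the screen reproducible. Zero differences
are dropped; the exact null is used up to 25 nonzero pairs, the
continuity-corrected normal approximation beyond. A numerical caveat the
tests document exhaustively: at n = 15–16 nonzero pairs the corrected
normal approximation can deviate from the exact tail by up to 0.011, but
only in a band of the null support where the exact p is 0.33–0.56 — far
from any screening decision at 0.05; everywhere the exact p is below 0.3,
and for all n ≥ 17, the two routes agree within 0.01.

## Classification protocol

The classification unit is the subject-trial feature vector, and all
splitting is **subject-level** and stratified by class: both trials of a
subject are always on the same side of every train/test boundary, so a
subject's identity can never leak across. Features are standardised to
zero mean and unit variance using training-set statistics only.

* **MLP**: 3 hidden layers × 10 ReLU units, sigmoid output, binary
  cross-entropy with L2 penalty 1e-4, full-batch Adam at learning rate
  0.001 for 200 epochs (the training sets here are far smaller than a
  conventional minibatch). Under the percentage split the 10% validation
  block is used for best-weight monitoring; k-fold runs have no
  validation block. Implemented in-package in vectorised R — compact,
  deterministic under a seed.
* **SVM**: C-classification with RBF kernel $\exp(-g|x-y|^2)$, cost
  0.90, $g = 0.02$, numerical tolerance 0.001 (via libsvm). The
  protocol's "epsilon" and "iteration limit" settings are
  regression-solver parameters that have no meaning for C-classification
  and are documented as inert.
* **Protocols**: one stratified 70/10/20 subject-level split (per class,
  train and validation counts are `round(n * fraction)`, the remainder is
  test), or stratified 10-fold CV whose per-fold predictions are pooled
  into a single confusion matrix — so pooled TP+TN+FP+FN equals the
  instance count and every instance is evaluated exactly once. Both
  protocols are reported because the source protocol does not say which
  the printed tables use.

Metrics: sensitivity, specificity and accuracy as percentages, F1 as a
fraction, and Cohen's kappa with expected agreement from the confusion
marginals. A rate with a zero denominator is reported `NA` and flagged,
never silently zero. The stressed class (B) is the positive class.

Gender-restricted comparisons (good vs bad among female or male subjects
only) are implemented but expected weak, and the parietal region is not
part of the standard region sweep, matching the source protocol's own
findings.

## The synthetic generator

Real recordings cannot ship with the package, so the generator emulates
the public layout: 21 named channels (20 EEG + 1 ECG), a long baseline
trial and a shorter task trial, one sampling rate, G/B labels in a
subject-info table. Each EEG channel is

$$x(t) = \sum_b A_b \,\big(1 + m_b(t)\big)\cos(2\pi f_b t + \varphi_b) +
\varepsilon(t),$$

with bands at 4, 8, 12, 20 and 30 Hz (the classical delta/theta-to-beta
range, spread across VMD modes), amplitudes falling with frequency, and
$m_b(t)$ smooth zero-mean modulation noise. The **only** class difference
is the modulation variance: class B draws $m_b$ with variance multiplied
by $(1 + \text{effectSize})$. That places the class signal exactly in the
mode-wise amplitude variability that the Poincare descriptors measure —
not in mean amplitude — mirroring the mechanism the pipeline is built to
detect. The ECG channel is a ~1.1 Hz spike train identical in law for
both classes. `effectSize = 0` makes the classes exchangeable, giving a
proper null.

What the generator does *not* emulate: 1/f background spectra, artifacts
(blinks, EMG), inter-channel correlation from volume conduction,
nonstationary band frequencies, or any physiological coupling between the
EEG and ECG channels. Passing tests on synthetic data therefore
demonstrate that the pipeline recovers class differences in mode-wise
variability when they exist and stays at chance when they do not — they
do not certify performance on real recordings.

## Problem sizes used in the checks

The shipped tests and the acceptance script run the full pipeline at
sizes chosen to keep the whole suite fast while leaving every stage
non-trivial:

* end-to-end experiment: 10 + 10 subjects, 5 channels (two frontal, one
  temporal, one central, the ECG), 64 Hz, 6 s task / 12 s baseline
  trials, K = 10 with modes 1–8, MLP, 10-fold CV — strong effect
  (effectSize 3) versus null (effectSize 0);
* effect-size sweep: 6 + 6 subjects, 4 s / 8 s records, 4-fold CV, ADMM
  capped at 150 iterations with `tol` 1e-6, 10 seeds per effect size over
  {0, 0.5, 1, 2, 3}, checking that the median pooled accuracy is
  nondecreasing in effect size.

At these sizes the within-trial estimate of a mode's amplitude
variability is stable enough for near-perfect separation at effectSize 3;
much shorter records leave too few independent envelope fluctuations per
trial and the descriptors become noisy.

## Numerical and design notes

* EDF I/O is implemented in-package (fixed-width ASCII header, 16-bit
  samples, per-channel physical scaling). Channel bounds are quantised to
  short exact decimals *before* scaling so that writing and reading use
  identical values; round trips are exact to the 16-bit step. The
  sampling rate always comes from the file header, never from an assumed
  constant.
* Channel-to-region mapping is by 10-20 label prefix (after stripping an
  optional `"EEG "` prefix): `Fp*/F*` frontal, `T*` temporal, `C*`
  central, `P*` parietal, `O*` occipital, `A*/M*` behind-ear, anything
  containing `ECG` the ECG group. For the standard 21-channel montage
  these seven groups partition the montage. A YAML config can override
  any group explicitly.
* The subject-info parser accepts G/B, good/bad and the public table's
  0/1 coding, and CSV or TSV delimiters.
* Ties and degenerate cases: constant signals produce a one-point
  Poincare plot at the origin (area 0, CTM 1); a feature with fewer than
  two nonzero paired differences is marked untestable and never retained;
  an undefined metric (zero denominator) is `NA` plus a flag.

## Known limitations

* VMD hyperparameters interact: very small `alpha` lets modes overlap,
  very large `alpha` can over-split a band; `K` larger than the number of
  genuine narrowband components makes the surplus modes share noise
  energy. The defaults behave well for rhythm-like signals but are not
  auto-tuned.
* The MLP is intentionally minimal (no dropout, no batch norm, no early
  stopping beyond validation-best weights); it matches the declared
  protocol rather than the state of the art.
* Mean distance `m` is defined independent of the CTM radius `r`; if a
  downstream convention expects an `r`-dependent mean, the descriptor
  must be extended.
* The pipeline assumes one sampling rate per recording; mixed-rate EDF
  files are rejected rather than resampled.
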