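---
title: "Decoding event-related potentials with canonical correlation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding event-related potentials with canonical correlation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccaerp)
```

## The model

Event-related potentials (ERPs) are stereotyped EEG deflections time-locked
to stimulus events. Attention-based BCIs present sequences of stimuli in
which rare attended events (targets) elicit additional components — the
P300 over centro-parietal sites, the N2pc contralateral to an attended
visual hemifield, fronto-central error potentials after erroneous feedback.
Which electrodes carry that signal varies across tasks and people, so
`ccaerp` learns a *spatial filter* from training data instead of requiring
channel selection.

Let an epoch be the `d1 × m` multichannel response to one event. Training
epochs are transposed and stacked (epoch-major, time-minor) into the
brain-signal matrix `X` (`n × d1`, `n = epochs × m`), and a model-signal
matrix `Y` (`n × d2`) is stacked alongside it, one template block per
epoch. Canonical correlation analysis solves

$$ (U, V) = \operatorname*{argmax}_{A,B}\ \mathrm{corr}(XA,\ YB) $$

yielding spatial filters `A` (`d1 × d`) and model-signal weights `B`
(`d2 × d`), with `d = min(rank X, rank Y)` components sorted by descending
canonical correlation $\rho_i$.

**Model signals.** Two template kinds are supported.

* *Impulse*: each block is the `m × m` identity. Every model signal is an
  impulse at one sample, so `V = YB` can take an arbitrary time course and
  the columns of `B` directly display the learned canonical ERP (or
  difference-wave) time courses, because `I_m B = B`.
* *Average*: each block is the condition-mean epoch (`m × d1`). The
  noise-reduced average brain response itself serves as the model; `B` is
  then a second spatial filter. It is cheaper when `d1 < m` and equivalent
  to the impulse model for target-only fits (below).

**Contrast.** With `contrast = 1`, nontarget epochs are included with their
model blocks multiplied by −1: the CCA then maximizes correlation with the
target-minus-nontarget *difference wave*, cancelling the common sensory
response and isolating the attention-dependent modulation. With
`contrast = 0` only target epochs are used. The contrast applies to filter
estimation only; at prediction the filters are applied to all epochs.

**Two exact identities.** For target-only fits both identities below hold
algebraically, for any data, because column-centering `Y` subtracts the
time-mean of the mean epoch: writing `Tcc` for the time-centered target
mean, the average model has `Σxy = Σyy = N·Tcc'Tcc`, so `A` and `B` solve
the same eigenproblem (`B = A/ρ` before normalization) — their columns are
perfectly correlated; and both the impulse and the average model reduce the
`X`-side eigenproblem to `Σxx⁻¹ N·Tcc'Tcc` — identical spatial filters from
different model signals. The package's acceptance checks verify both to
1e-6 on simulated sessions. Neither identity survives `contrast = 1`, where
the degree of residual `A`–`B` correlation indicates how small the
nontarget ERPs are.

**Decision rule.** Only the first `k` components are used (`components`
option: a fixed count, default 3, or a p-value threshold on Bartlett's
chi-square approximation, $-(n-1-\tfrac{d_1+d_2+1}{2})\ln\Lambda_k$ with
$\Lambda_k=\prod_{i\ge k}(1-\rho_i^2)$ on $(d_1-k+1)(d_2-k+1)$ degrees of
freedom). For each candidate class `c` a model sequence `Y_c` is assembled
over the test sequence's epochs (all epochs signed ±1 under contrast;
only the class's own epochs otherwise) and features are extracted:

* **R** — the `k` Pearson correlations between the columns of
  `XA` and `Y_c B` over the concatenated sequence;
* **U** — for each component, the mean canonical epoch over the epochs in
  which `c` was stimulated, concatenated (`k·m` values).

The intended class maximizes the probability of having elicited target
responses: the classifier posterior of "is target", or for the
maximum-correlation rule the mean of the `k` correlations. Ties break to
the lowest class index. In binary mode (empty `trgtID`, labels in
`stimID`) each epoch is classified on its own features, with
`maxcorr` predicting class 1 iff the mean correlation is positive — a rule
that is deliberately left biased under class imbalance, which the
per-class accuracies of `cross_validate_decoder()` expose.

**Classifiers.** Shrinkage LDA pools the within-class covariance (maximum
likelihood) and shrinks it toward `tr(S)/d·I` with the analytic
Ledoit–Wolf-style intensity, clipped to [0, 1]; the posterior is the
discriminant's logistic link with the log-prior offset. The linear SVM
(libsvm) sets the box constraint `C = 1/mean‖x‖²`, which exactly
compensates feature rescaling, and calibrates posteriors by a logistic fit
on the training decision values — no inner cross-validation, since BCI
training sets are small. Gaussian naive Bayes floors per-class variances at
1e-12. Custom classifiers plug in as a `list(fit, predict_posterior)`
contract. No class reweighting is applied by default.

**Activation patterns.** Filter weights are not interpretable topographies;
`activation_patterns()` converts the backward model `U = XA` to the forward
model, `Cov(X)·A_k·Cov(U_k)⁻¹` (equal to the columns of `(A⁻¹)'` when `A`
is square), columns scaled to unit maximum absolute value.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `model` | `impulse` | model-signal templates (impulse/average) |
| `contrast` | 1 | include sign-flipped nontarget model signals |
| `components` | 3 | canonical components kept (or `"p:0.05"`) |
| `feature_space` | `R` | correlations (`R`) or canonical epochs (`U`) |
| `classifier` | `maxcorr` | `maxcorr`, `lda`, `svm`, `nb`, or custom |
| `alphabet` | none | class-to-character map for readable output |

Impulse models suit spatially distinct sources and arbitrary time courses;
average models are cheaper when channels are fewer than samples per epoch.
Contrast should be enabled whenever the informative signal is a
*modulation* of a response present in both conditions (N2pc, RSVP) and may
be disabled when the target response itself is the signal (overt matrix
spellers). `maxcorr` requires `R`; LDA and SVM handle the high-dimensional
`U` space through their regularization.

## Preprocessing helpers

The decoder expects conventionally preprocessed epochs (a typical chain:
bandpass 1.0–12.5 Hz, resample to ~50 Hz, baseline-correct, epoch 0–800 ms
after onset). `eeg_bandpass()` uses a Butterworth design applied
forward–backward: zero phase preserves ERP latencies at the cost of
doubling the effective order. `eeg_resample()` low-passes at 0.45 of the
target rate (zero-phase, order 8) and evaluates the result on the output
grid by cubic splines; the output length is `floor(N·fs_out/fs_in)` with
sample `k` at time `(k−1)/fs_out`. All time windows are half-open
`[start, stop)` seconds, converted to samples by rounding half away from
zero — so "0–800 ms" at 50 Hz is exactly 40 samples including the onset
sample, and "the 116 ms before onset" is `[−0.116, 0)`. Filtering before
epoching avoids edge transients; a package test verifies that filtering and
epoching commute for interior epochs to 1e-6 relative accuracy.

## What the generators emulate — and what they do not

`simulate_speller()` (matrix and RSVP layouts), `simulate_lateralized()`
and `simulate_binary()` produce epochs with the statistical skeleton of the
four paradigm families: Gaussian-windowed ERP components with fixed
topographies (occipital visual-evoked on every event; centro-parietal
P300-like on targets; a small antisymmetric N2pc-like difference; a
fronto-central error component on the minority class), multiplied per epoch
by a nonnegative random gain (sd 0.3) to emulate trial-to-trial amplitude
variability, on top of AR(1) channel noise (φ = 0.9, sd 1.0) plus white
sensor noise (sd 0.5). Class allocations are deterministic (exact counts;
randomness only orders events), flash schedules are seeded permutations,
and identical seeds give bit-identical output.

Default amplitudes were fixed once to land the matrix-speller defaults in
the accuracy regime published for comparable 8-channel systems
(cross-validated accuracies in the mid-90s at 15 repetitions): evoked 1.2,
P300 1.2, N2pc-like difference 0.25 (≈1/5 of the evoked response, the
realistic ratio that also makes a target-only model fail on the lateralized
paradigm, as it does in practice), error component 1.0.

The generators do **not** model biophysical volume conduction, latency
jitter, eye or muscle artifacts, non-stationary background rhythms, or
inter-subject topography variation. Passing tests therefore demonstrate
correctness of the algorithmic pipeline and recoverability under controlled
conditions — not expected performance on any particular recording.

## Numerical choices

* CCA: column-center both matrices, pivoted thin QR of each, SVD of
  `Qx'Qy`; coefficients back-solved from the R factors and scaled to
  unit-variance variates. Rank tolerance `max(n,d)·eps·|R₁₁|`; dropped
  columns give zero coefficient rows.
* Component signs are arbitrary in CCA; each component is oriented so the
  largest-magnitude entry of `B`'s column is positive (applied jointly to
  `A` and `B`), making results reproducible.
* Test data are centered with the *training* column means; no test-set
  statistics enter prediction.
* Degenerate (zero-variance) correlation inputs define r = 0; a class never
  stimulated in a sequence (possible with `contrast = 0`) yields zero
  features and a warning rather than an error, keeping prediction total.
* Under `contrast = 1` with average models, nontarget epochs are paired
  with the *negated nontarget mean* (condition-specific). The alternative —
  negating the target mean — is available as
  `contrast_template = "negated_target"`.
* Repetition truncation keeps the *first* `r` repetition blocks of each
  test sequence; generators record the block structure as the
  `n_repetitions` attribute of the event table.
* Cross-validation folds partition whole sequences (or class-stratified
  epochs in binary mode) by a seeded permutation; every fold refits
  templates, CCA, patterns and classifier from its training part only.

## Design decisions that were genuinely open

* *Negative instances for classifier training.* One instance per
  (sequence, candidate class) pair — 1 positive and C−1 negatives per
  training sequence. Deterministic, matches the posterior-argmax decision
  rule, and needs no sampling policy.
* *Correlation features over the whole concatenated sequence* rather than
  averaged per repetition: the model-sequence construction concatenates all
  of a sequence's epochs, so the correlation is computed once over that
  concatenation.
* *SVM posterior calibration on training decision values* (no inner CV):
  favoring the small training sets typical of BCI sessions over calibration
  optimality.
* *Resampling implementation*: zero-phase low-pass plus spline evaluation
  on the output grid, chosen over polyphase FIR after the latter proved
  numerically inaccurate at large decimation ratios; the floor-length
  convention is part of the documented contract.
* *Binary-mode thresholds*: posterior 0.5, mean correlation 0. Simple,
  deterministic, and deliberately uncorrected for imbalance so that the
  reported per-class accuracies reveal the majority-class bias.

## Problem sizes used by the test suite

Unit tests run on 6-sequence, 5-repetition sessions (6–36 classes, 8
channels, 40 samples per epoch). The end-to-end checks use a 20-sequence,
15-repetition matrix-speller session for the feature/classifier grid, 108
test sequences for the chance-level control, 20 simulated subjects at
`snr_scale = 0.6` (a deliberately sub-ceiling regime in which repetitions
matter) for the repetition curve, and 40 lateralized sequences for the
contrast comparison. These sizes were chosen as the smallest at which the
statistical assertions are stable.

## Known limitations

* The Bartlett approximation behind p-value component selection is
  asymptotic; for very short training sets a fixed `k` is safer.
* `maxcorr` in binary mode is biased toward the majority class by
  construction; prefer LDA/SVM posteriors under imbalance.
* The average model with `contrast = 1` is sensitive to nontarget ERP
  structure; impulse models are the safer default when nontarget responses
  resemble target responses.
* Decoders are fit offline on epoched arrays; there is no online/adaptive
  refitting.
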