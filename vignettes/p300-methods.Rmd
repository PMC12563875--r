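---
title: "Models and methods: spatiotemporal P300 analysis and prior-guided classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: spatiotemporal P300 analysis and prior-guided classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the generative
model behind the synthetic cohort, the CSTP estimator and its numerical
choices, the statistics battery, the network architecture and training
scheme, and what the shipped tests do and do not establish. Nothing stated
here goes beyond what the test suite and `scripts/acceptance.R` actually
compute.

## 1. The problem

In a visual oddball paradigm, rare task-relevant (target) stimuli evoke the
P300, a positive stimulus-locked deflection peaking roughly 300 ms after
onset with a fronto-central scalp maximum. Psychiatric cohorts — here a
PTSD-vs-control contrast — are repeatedly reported to show *attenuated
amplitudes* and *delayed latencies* of this component. The package asks two
questions of such data: (i) can the spatiotemporal group differences be
quantified channel-by-channel, and (ii) can single trials be classified by
group, using the observed priors (which channels, which latency window) to
guide a learned model.

Clinical recordings of this kind are generally not shareable, so the
package treats the data-generating process itself as a first-class,
testable module, and anchors every quantitative claim to the synthetic
cohort it defines.

## 2. The synthetic cohort

`sim_config()` encodes the study conditions:

* **Montage and rates.** Ten 10–20 electrodes (Fp1, Fp2, Fz, C3, Cz, C4,
  Pz, O1, Oz, O2), raw sampling at 1000 Hz, epochs later decimated to
  250 Hz.
* **Paradigm.** Per subject, 2 runs × 2 blocks × 25 trials. Each trial is a
  1 s target cue followed by 9 matrix flashes at 0.5 s spacing, exactly one
  of which contains the target (the 5×5 row/column geometry — 2 of 10
  flashes intersect the target character — is abstracted to a 1:8
  target:nontarget event stream; no visual rendering is simulated).
* **The component.** The P300 is a Gaussian bump
  `a·exp(-(t-ℓ)²/(2w²))` with per-trial draws of latency `ℓ`, amplitude
  `a`, and width `w`. The shape is a modelling choice — the literature
  specifies peak latency, amplitude and an approximate width, which are
  exactly the Gaussian's three parameters. Nontarget flashes evoke nothing.
* **Topography.** Fixed gains Fz 1.0, Cz 0.9, C3/C4 0.8, Pz 0.6, Fp1/Fp2
  0.4, O1/Oz/O2 0.3 — a fronto-central maximum consistent with where group
  differences concentrate in this literature. The exact values are ours.
* **Groups.** HC: 312 ms mean latency, 5 µV mean amplitude at the maximal
  channel. PTSD: 415 ms and 2.5 µV (half). The latency anchors are the
  reported group peaks; the ×0.5 attenuation operationalizes "overall lower
  amplitudes", whose magnitude is never printed. Per-trial jitter defaults:
  latency sd 25 ms, amplitude sd 1 µV, width 45 ± 5 ms.
* **Background.** Per channel, 1/f ("pink") noise generated by spectral
  shaping of white noise, scaled to 4 µV RMS, plus a 10 Hz sinusoid of
  2 µV with random phase. Nothing about noise is specified by the source
  literature; the level was calibrated once so that the synthetic data
  reproduce the *reported discriminability structure*: at the full 100
  trials per subject the subject-level amplitude effect size at Fz lands
  near the reported |d| ≈ 1.2, and a noiseless-template ideal observer
  reaches ≈ 88 % single-trial accuracy / AUC 0.95 — the regime in which the
  published trial-level accuracies (93 % network, 84.6 % CSTP+SVM) are
  possible. With substantially more noise those reported magnitudes would
  be unattainable by *any* classifier, i.e. the generator would not emulate
  the data it stands in for.
* **What the generator does not emulate.** Between-subject parameter
  variability (all subjects of a group share the same P300 distribution),
  ocular/EMG artifacts (a pass-through hook marks where an ICA cleaner
  would sit), electrode drift, and session effects. Passing tests therefore
  demonstrate correctness of the algorithms under controlled conditions,
  not clinical performance.

Determinism: every recording is reproducible from `(seed, subject_seed)`;
the event schedule, per-trial draws and noise come from a single seeded
stream.

## 3. Preprocessing

The fixed stage order is band-pass → average reference → (artifact hook) →
epoch → baseline → decimate, and the runner refuses configurations whose
low-pass edge exceeds the output Nyquist rate.

* **Filtering.** 0.1–30 Hz, realized as order-4 Butterworth high- and
  low-pass sections applied forward-backward (zero phase). Because
  transfer-function polynomials are numerically unusable at a normalized
  cutoff of 2·10⁻⁴, the filters are built as biquad cascades from the
  analog prototype poles (bilinear transform); channels are demeaned first,
  which makes DC rejection exact, and reflection padding suppresses the
  slow high-pass edge transient. The zero-phase magnitude is the squared
  Butterworth response — e.g. a 50 Hz tone is attenuated to
  `1/(1+(50/30)^8) ≈ 1.7 %` RMS, which the tests verify against this
  closed form.
* **Epochs.** Half-open window `[-100, 600)` ms (700 samples at 1000 Hz);
  events whose window crosses a recording edge are dropped with a warning
  rather than padded. Baseline is the per-trial, per-channel mean over
  `[-100, 0)` ms; correction is idempotent. Decimation keeps every 4th
  sample (anti-aliasing is already guaranteed by the 30 Hz low-pass),
  giving 175 samples at 250 Hz with the axis starting exactly at −100 ms.
  Simple sample-keeping is chosen over a resampling filter stack for bit-
  level reproducibility.
* The average reference subtracts the instantaneous cross-channel mean; on
  the synthetic topography this scales the Fz P300 by `1 − mean(gains)`,
  which is why measured *referenced* amplitudes are smaller than the
  configured generator amplitudes while latencies are untouched.

## 4. CSTP: the estimator and its numerics

`cstp()` maximizes the between-class spatiotemporal variance ratio

`J(W, V) = tr(W' Σ₁(V) W) / tr(W' Σ₂(V) W)`

by alternating two generalized eigenproblems: given `V`, solve
`Σ₁(V) w = λ (Σ₁(V)+Σ₂(V)) w`; given `W`, the analogous `T×T` problem for
`V`. Following the CSP convention, `⌈M/2⌉` eigenvectors from the top and
`⌊M/2⌋` from the bottom of the spectrum are kept, so variance increases of
*either* class are representable. Design choices that were genuinely open:

* **Per-trial normalization.** Class covariances average trace-normalized
  per-trial outer products. Two normalizers are implemented; the *fit* uses
  division by the raw trial energy `tr(XX')`. Under this choice the spatial
  and temporal eigen-steps provably ascend one and the same objective
  (both reduce to `Σ trials |W'XV|²_F / tr(XX')` ratios), making the
  alternation true coordinate ascent; normalizing by the *projected* trace
  `tr(ZZ')` (also available in `class_covariances()`) gives each half-step
  a different denominator, and the alternation then equilibrates measurably
  below the optimum of the recorded objective. The tests verify, on
  2-channel/4-sample instances, that the fitted `J` attains an exhaustive
  1°-grid search over unit filter pairs.
* **Rank handling.** When trials × filters is smaller than the matrix
  dimension (routine for the 175-sample temporal problem), `Σ₁+Σ₂` is
  singular and the bottom generalized eigenvectors would otherwise live in
  the data null space — directions that separate the training set
  perfectly and explode on unseen trials. The eigenproblem is therefore
  solved inside the span of the composite covariance (rank-truncated
  whitening, threshold `10⁻⁹` of the top eigenvalue), with a ridge
  `γ·λ_max` applied within the span. The fitting default is the numerical
  `γ = 10⁻⁶`; the cross-validation harness refits CSTP per training fold
  with `γ = 0.2`, the classic regularized-CSP remedy for small folds, where
  unregularized temporal filters saturate at within-fold eigenvalues of
  exactly 0/1 and transfer at chance.
* **Monotonicity and restarts.** The recorded objective trace is
  non-decreasing by construction: an update that would lower `J` terminates
  the iteration at the previous (best) iterate, with a non-convergence
  flag. Initialization candidates are the leading eigenvectors of `R₁+R₂`
  plus the discriminative generalized eigenvectors of the unprojected
  temporal problem from either end of the spectrum, plus seeded random
  orthonormal restarts; the best final `J` wins. Eigenvector signs are
  fixed by making the largest-magnitude entry positive; eigenvalue ties
  break by index order.
* **Features.** `f_space^m = log( var(Z[m,·]) / Σ var(Z[m',·]) )` and the
  temporal analogue, concatenated to an `M+K` vector per trial; each block
  exponentiates and sums to 1 by construction (asserted to 10⁻⁸). PCA for
  visualization is column-centered SVD on flattened raw epochs vs. feature
  vectors, no scaling.

Whether filters are learned from target epochs only (the default here,
with groups as the two classes) or from all epochs is not dictated by the
estimator; target-only matches the analysis the statistics battery runs.

## 5. Group statistics

Per channel, three pooled-variance independent-sample t-tests on
per-subject trial-averaged quantities: window-mean amplitude, peak
amplitude, and peak latency, all inside 250–500 ms (closed window, argmax
peak, earliest-sample tie-break). "Mean amplitude" is operationalized as
the window mean over the same 250–500 ms used for peaks — the natural
single choice where the source analysis names no window for it. The t sign
convention is PTSD − HC, so attenuated patient amplitudes give negative t
and d. Bonferroni correction multiplies each p by the channel count and
caps at 1; the table reports raw *and* corrected columns with significance
flags from the corrected values. (Published tables of this kind sometimes
print raw p-values against a corrected threshold; reporting both columns
sidesteps the ambiguity.) Under the null (identical groups) the test suite
verifies, over 2000 simulated replicates, that the per-channel uncorrected
rejection rate sits inside the binomial band around α = 0.05 and the
family-wise error after correction stays at or below α.

## 6. P300-STTCNet

Architecture (all sizes config-exposed; defaults in parentheses):

1. **Channel prior.** One trainable gain per input channel, initialized at
   1.5 for Fz, C3, Cz, C4 and 1.0 elsewhere — the channels where the group
   statistics concentrate. Gains multiply the standardized input and are
   updated by the optimizer like any weight.
2. **Tokens.** Time samples are tokens (175 at 250 Hz); the 10-channel
   vector at each sample is linearly embedded to `d_model` (64). Sinusoidal
   positional encoding is added: attention is permutation-invariant over
   tokens, and without position information the model would be blind to
   latency — the very quantity that separates the groups.
3. **Encoder.** Four post-norm layers of multi-head attention (4 heads) and
   a feed-forward block (128), residual connections and layer
   normalization. Attention is `softmax(QK'/√d_k + PriorMask)V`; the mask
   adds `λ` (default 1.0) to the logits of every key whose time lies in the
   closed 250–450 ms window, uniformly over query rows, shared across heads
   and layers, and is not trained. `λ = 0` and unit channel gains reduce
   the model to a plain Transformer-CNN (asserted by forward-pass
   comparison), and a constant mask changes nothing by softmax shift
   invariance. The statistics battery uses 250–500 ms while the mask uses
   250–450 ms; both windows are honored as given, without reconciling them.
4. **Head.** The encoded `n × d` representation is treated as a one-plane
   image: conv(16 @ 3×3) → ReLU → max-pool(2×2) → conv(32 @ 3×3) → ReLU →
   max-pool(2×2) → flatten → MLP (64) → 2 logits.

**Implementation.** No deep-learning runtime is used: forward and backward
passes are written directly on double-precision matrices (batched token
projections share one BLAS call across trials; convolutions use cached
im2col index tables; pooling stores argmax indices). Every gradient is
analytic and checked against central finite differences at 10⁻⁴ relative
tolerance in the test suite, including the channel-gain and masked-
attention pathways. Training is Adam (lr 10⁻³, β 0.9/0.999) on softmax
cross-entropy, batch 32, dropout 0.1 after the embedding, each sublayer
output and the MLP hidden layer, with two stabilizers that unit tests
showed to be necessary rather than cosmetic: the output layer is
initialized at 0.1× Glorot scale (near-uniform initial class
probabilities) and gradients are clipped to unit global norm — without
them the first optimizer steps on low-SNR EEG kill the convolutional
ReLUs and the loss freezes at log 2. Early stopping monitors a stratified
trial-level validation split (patience 30, best weights restored). All
randomness — initialization, split, batch order, dropout — derives from
one seed; identical seeds give bit-identical fitted weights.

Classification is per single target epoch; a subject-level majority vote
is available as an option on `predict()`.

## 7. Evaluation

`make_folds()` deals shuffled subjects round-robin within class, so fold
class counts differ by at most one and each subject is held out exactly
once; with 12+12 subjects and k = 4, every test fold holds 3+3 subjects.
`cv_classify()` enforces a strict leakage audit (any subject appearing on
both sides of a split aborts) and refits CSTP inside each training fold —
feature learning never sees test subjects. The SVM baseline is an RBF
kernel with `C = 0.1` on CSTP features (`γ = 1/(p·var)`, via scaling), and
the control is the same SVM on flattened raw epochs. Metrics are accuracy,
precision, recall and F1 for the PTSD-positive class, trapezoidal ROC AUC
from the positive-class score (softmax probability for the network,
oriented decision values for the SVM), and raw plus row-normalized
confusion matrices; across-fold aggregation reports the mean with a normal-
approximation 95 % interval `mean ± 1.96·sd/√k` (across folds, not across
trials — the source format is ambiguous and folds are the resampling
unit here).

## 8. Problem sizes used by the shipped checks

The properties checked are scale-free, so the suite runs them at reduced
sizes chosen to exercise every code path:

* Simulator anchors: 1 subject per group, 3 target trials, noiseless;
  the acceptance script uses the full default 100 trials per subject.
* CSTP oracles: 2-channel toys (4 samples for the grid search at 1°/2°
  resolution; 40 samples for the planted-direction recovery).
* Null statistics: 2000 replicates of 6+6 subject averages over 3
  channels.
* Classifier comparison: the full 12+12-subject cohort with 25 target
  trials per subject, epochs at 125 Hz (the 30 Hz low-pass leaves nothing
  above 62.5 Hz, and attention cost scales with the squared token count);
  network `d_model` 24, 12 training epochs, no early stopping. Under these
  conditions the network reaches mean CV accuracy ≈ 0.61 (AUC ≈ 0.63)
  against ≈ 0.46 for both SVM baselines — clearly above chance and the
  controls, but far below both the ideal-observer ceiling (≈ 0.88) and the
  full-scale training regime, which the shipped checks deliberately do not
  attempt.
* The gradient check runs a 2-layer, `d_model = 12` configuration on
  20-token epochs.

## 9. Known limitations

* The generator omits between-subject variability; subject-level
  cross-validation on it therefore measures noise-robust generalization,
  not inter-individual transfer.
* CSTP is a variance-contrast method: under heavy correlated (1/f) noise
  its log-variance features carry much less of the group information than
  a matched filter on the mean waveform, and the CSTP+SVM baseline's
  performance on the synthetic cohort reflects that.
* The Transformer-CNN is data-hungry; at the reduced trial budgets of the
  test suite it operates well below its asymptotic accuracy.
* Only the 3×3-kernel / 2×2-pool CNN geometry is implemented; other
  values in `sttcnet_config()` are rejected explicitly.
* Frequency-domain features, artifact models, and cross-session effects
  are out of scope.
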