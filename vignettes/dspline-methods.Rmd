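---
title: "Discriminative spatial patterns for ERP classification: model, synthetic world, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dspline methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

`dspline` classifies single-trial, stimulus-locked EEG epochs by projecting
each trial onto a small set of discriminant directions learned from
class-labelled training trials, then running a k-nearest-neighbour classifier
under repeated cross-validation. This vignette records the model and its
assumptions, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the design choices made where the
design was genuinely open.

## The model

Each trial is an `N × T′` matrix (channels × retained samples, microvolts),
vectorized channel-major into `x ∈ R^D`, `D = N·T′`. With class means `M_j`,
grand mean `M`, and class sizes `n_j`:

* within-class scatter `S_W = Σ_j Σ_i (x_ji − M_j)(x_ji − M_j)'`
* between-class scatter `S_B = Σ_j n_j (M_j − M)(M_j − M)'`

The Fisher criterion `J(W) = |W'S_B W| / |W'S_W W|` is maximized by the
leading eigenvectors of the pencil `(S_B, S_W)`. Two backends are provided.

**Classic (oracle) backend.** `S_W⁻¹S_B` is non-symmetric, and a naive
eigendecomposition can return complex pairs. `dsp_classic()` instead
eigendecomposes the regularized `S_W`, whitens `S_B` symmetrically and
eigendecomposes the (symmetric) result — the spectrum is provably real.
This backend materializes `D × D` matrices and is intended for moderate `D`
and as the reference in tests.

**Improved backend.** Because the projected mean difference and the
eigenvalue enter the eigenvector equation only as scalars, the direction of
each solution can be read off in closed form, one direction per class:

```
w_j = (S_W + γ·c·I)⁻¹ n_j (M_j − M),   c = mean(diag(S_W))
```

`dsp_improved()` returns the `K` unit-normalized columns in sorted label
order. Note the per-class reading is forced: the sum `Σ_j n_j (M_j − M)` is
*identically zero* for any labelled data (since `Σ_j n_j M_j = nM`), so a
single summed direction would be degenerate; the zero-sum identity is kept as
a standing test. For `K = 2` the per-class direction is proportional to the
Fisher/LDA direction `(S_W + γcI)⁻¹(M_1 − M_2)`, which is exactly the leading
generalized eigenvector — the two backends agree to `|cos| ≥ 1 − 1e-6` on
nonsingular instances, and this equivalence is an acceptance criterion. A
corollary worth knowing: for binary tasks the two returned columns are
identical after sign normalization, so the feature pair is redundant (KNN is
unaffected; selection drops the duplicate).

**Regularization.** At `N = 60`, `T′ = 182`, `D = 10 920` and a few hundred
trials, `S_W` is always rank-deficient. Both backends therefore use a
mean-diagonal ridge `γ·c·I`. The default `γ = 1e-3` is a numerical floor
that keeps the solve well-posed without visibly distorting the projection;
it is configurable, and the choice of strength matters by regime — see
"Numerical choices" below.

**Matrix-free solve.** For `D > 2000` (or `D > 4n`) the inverse is applied
through the centered-data identity
`(γcI + Xc'Xc)⁻¹b = (b − Xc'(γcI_n + XcXc')⁻¹Xc b)/γc`,
so only `n × n` and `n × D` arrays are formed. Dense and low-rank routes
agree to `1e-6` relative (tested at `D = 500`), and the low-rank route runs
at the full `D = 10 920`.

**Features.** `z_i = W1' x_i + Δ`, `Δ = −W1' M`. The offset is computed from
the *training* grand mean and frozen for test-split transforms, so centering
leaks nothing.

## Preprocessing conventions

All defaults are set in one place (`run_config()`); sample indices in the
public API are 0-based.

* **Epoch span** −200…+800 ms (baseline −200…0 ms) at 500 Hz: `T = 501`,
  onset index 100. +800 ms is the minimum span containing the P400–700
  window; −200 ms is the conventional ERP baseline.
* **Band edges** delta 1–4, theta 4–8, alpha 8–13, beta 13–30, whole
  1–30 Hz — the standard conventions consistent with a 1–30 Hz broadband
  analysis.
* **Filter** 4th-order Butterworth prototype applied forward–backward
  (zero phase). Zero phase preserves component latencies, on which the
  windows depend. No signal-processing dependency was available, so the
  bilinear-transform design and the forward–backward pass (odd-reflection
  padding, steady-state initial conditions) are implemented here and frozen
  against an independent reference implementation in the tests.
* **Artifact rejection** retains trials whose every sample lies within
  ±75 µV, bounds inclusive. Stage order is filter → baseline → reject,
  i.e. the threshold applies to baseline-corrected signals.
* **Component windows** N70/P120/P300 are 5-sample windows centred on the
  nominal latency (half-width 2 at 500 Hz); N170–P200 and P400–700 include
  every sample in the inclusive ms range; ms→samples is round-to-nearest.
  At 500 Hz: 5/5/16/5/151 samples, `T′ = 182`. Centering symmetric windows
  on the nominal latency is the least-biased reading of "samples around the
  peak"; the exact counts for the range components are configurable.

## Classification protocol

KNN with `k = 3`, Euclidean distance, majority vote; vote ties go to the
class of the nearest tied-class neighbour, distance ties to the lower
training index — predictions are deterministic. Cross-validation is
stratified 5-fold, repeated 10 times with re-randomized folds (repeat `r`
seeded `seed + r − 1`). ACC is the mean of repeat-level accuracies; SD is
across repeats (the natural unit of replication here); SEN/SPE come from
confusion counts pooled over all folds and repeats, with the first-named
condition of a pair as the positive class. Features are ordered by
univariate Fisher score (deterministic, index-ordered ties; zero
within-class variance ranks first and is flagged), and sequential forward
selection returns the shortest prefix achieving the maximal mean accuracy
plus the full accuracy-vs-prefix curve.

**Nested vs pooled.** The projection is supervised, so fitting it on the
full set before cross-validating its features leaks test labels; with
`n ≪ D` the leak is large enough to push permuted-label accuracy far above
chance. The default (`mode = "nested"`) refits the DSP model — and, when
requested, the feature selection — inside every training fold; the
permutation null then sits at 50% as it must, and this is verified as an
acceptance criterion. `mode = "pooled"` reproduces the conventional
fit-once shortcut for comparison. The nested selection's inner loop uses 2
CV repeats (not 10): the inner protocol is unconstrained, and deeper nesting
changes cost, not contract.

## The synthetic world

The generator emulates a 60-channel, 500 Hz, three-condition acquisition
with 98 trials per condition (presets scale this down for CI). Each trial is
stationary Gaussian `1/f` background noise (RMS 5 µV, exponent 1 — the
standard EEG noise floor after broadband filtering) plus the class's
component effects: Gaussian-envelope bumps at the five component latencies,
optionally carrying a phase-locked oscillation, with per-trial Gaussian
latency jitter (SD 5 ms) and a fixed unit-norm spatial topography per
component. Class-amplitude triples (2–8 µV differences) are stated once in
`default_sim_components()`.

Two semantic points were fixed after their first formulations proved
physically wrong, and are worth recording:

* **Amplitude means peak-electrode microvolts.** With unit-norm
  topographies, treating the amplitude as the norm of the planted vector
  makes the per-electrode signal shrink as channels are added — a "6 µV"
  component would peak at 0.7 µV at 60 channels, and the full-montage world
  became *harder* than the 8-channel one. The generator therefore scales the
  topography so its largest entry carries the stated amplitude, which is
  what an ERP amplitude means at the scalp.
* **Deflection widths are physiological, not window-derived.** Envelope SDs
  tied to the 5-sample extraction windows (2.5 ms) put the components'
  spectra far above 30 Hz, so the mandatory broadband filter erased them.
  Point components now use field-typical widths (N70 10 ms, P120 12 ms,
  P300 40 ms), which keeps them inside the analysis band; range components
  use SD = window width / 4 (7.5 / 75 ms). The extraction window samples the
  deflection around its peak; it does not bound its duration.

Artifact trials receive a planted 150 µV spike, guaranteeing exceedance of
the ±75 µV bound, and are recorded in the ground truth, so rejection can be
checked for exactness. `analytic_direction()` returns the noise-whitened
clean mean-difference direction implied by a config — exact, because the
synthesis spectrum's autocovariance is known in closed form and channels are
generated independently — and is validated against a 10 000-trial
Monte-Carlo estimate.

**What the generator does not emulate:** volume conduction and spatially
correlated noise (channels are independent), eye-blink/muscle waveforms
(artifacts are bare spikes), non-stationarity across a session, and
participant-level variability. A green end-to-end test therefore establishes
that the machinery is correct and honestly evaluated — not that real
action-intention EEG is separable at any particular accuracy.

## Numerical choices

* Discriminant columns are unit-norm with the largest-magnitude entry made
  positive; scale and sign are free in the model, and the convention makes
  backends comparable.
* Ridge strength by regime: `γ = 1e-3` (default) is right for the pipeline's
  `D ≫ n` regime, where it acts as a numerical floor. In the opposite regime
  (`D ≪ n`, as in the recovery preset with spherical noise) a near-zero
  ridge whitens with the raw sample covariance, whose `D/n` fluctuations
  rotate the estimated direction regardless of estimator quality; the
  recovery acceptance test therefore evaluates at strong shrinkage
  (`γ = 10`), where the shrinkage target coincides with the true covariance.
  Conclusions there are stable for `γ` anywhere in the strong-shrinkage
  range.
* The zero-phase filter's initial-condition solve is ill-conditioned for
  narrow low-frequency bands; it is solved without a condition check, as
  reference implementations do, and the filtering tests pin the results.
* Degenerate inputs fail loudly: single-class scatter, empty vectorization,
  empty baseline, out-of-bounds windows (naming the component), `k` larger
  than the training set, classes smaller than the fold count. Identical
  class specifications make `analytic_direction()` return a flagged zero
  vector rather than an arbitrary direction.

## Limitations

The improved backend returns per-class directions (`m = K`) rather than an
eigen-subspace of chosen rank; for binary tasks that is the full Fisher
solution, but for `K > 2` the classic backend is the reference for
higher-rank projections. Scatter fitting is refit per class pair by default
(a flag to fit all classes once and subset is deliberately out of scope).
The CLI covers simulate/run; streaming or online operation is out of scope.
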