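---
title: "Oscillating prediction-error precisions: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oscillating prediction-error precisions: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betagate)
```

## The problem and the model

Online syllable recognition requires analyzing the current acoustic chunk
while holding on to internal expectations about what it should be. In a
predictive-coding hierarchy this balance is set by *precisions* — the
inverse-variance weights on prediction-error signals. `betagate` implements
a recognizer in which the precisions of the bottom-up errors of two
functional groups (syllable-identity units and syllable-timing units)
*oscillate* at a configurable frequency `psi`, so the inference process
alternates rhythmically between a bottom-up-dominated (information intake)
and a top-down-dominated (consolidation) regime.

The hierarchy, top to bottom:

* **Precision oscillator** `(p1, p2)`: a harmonic pair rotating at `psi`
  Hz (`k1 = 2*pi*psi/1000` radians per 1 ms sample). The coordinate `p2`
  drives log-linear precision schedules. The noise-free pair is integrated
  with the exact per-sample rotation map, which keeps `p1^2 + p2^2`
  constant to machine precision; a forward-Euler update would inflate the
  amplitude by tens of percent over a 5 s trace, so the exact map is used
  throughout.
* **Variant schedules** (`variant_config()`): the causal log-precisions
  are affine in `p2`. The `identity` variant oscillates only the syllable
  units (`2.5 + 2 p2`), `timing` only the gamma units (`1.5 + 4 p2`),
  `full_antiphase` both with opposite signs, `full_samephase` both with
  the same sign, and `stationary` freezes both at their intercepts with no
  oscillator states (17 rather than 19 state variables). Hidden-state
  log-precisions are 3 (syllable), 5 (gamma), 5 (oscillator) in all
  variants. The oscillator starts at `(p1, p2) = (0, 1)`: the amplitude is
  a free choice (unit amplitude makes the slopes span their intended
  log-precision ranges, e.g. `exp(1.5 - 4 p2)` covers `exp(-2.5)` to
  `exp(5.5)`).
* **Theta module** (`theta_state()`, `theta_step()`): a canonical theta
  neuron, `dphi/dt = (1 - cos phi) + I (1 + cos phi)`, with drive
  `I = I0 (1 + 0.25 * envelope)`. The baseline `I0 = (pi/200)^2` gives a
  free-running cycle of ~199 ms (about 5 Hz, the natural syllable rate)
  under 1 ms Euler steps. Its phase emits a Gaussian onset pulse at a
  predefined phase, and its *rate signal* is the instantaneous cycle
  frequency implied by the current drive (`sqrt(I / I_ref)`, since the
  theta-neuron period is `pi/sqrt(I)`). We deliberately do not use the raw
  `dphi/dt`, which is strongly phase-dependent within a cycle and would
  make the downstream gamma speed pulsate; the drive-implied frequency is
  the cycle-scale version of the same quantity. During inference the
  reference drive includes the sentence-mean envelope, so gamma runs at
  its rest rate for typical input and speeds up transiently at energetic
  onsets.
* **Gamma sequence** (`gamma_state()`, `gamma_step()`): eight units in an
  asymmetric Lotka–Volterra winnerless competition (a stable heteroclinic
  channel). Each unit inhibits all others with weight 1.5 except its
  cyclic successor (0.5), so dominance passes in fixed order
  1→2→…→8→1. The gain 0.74 and activation floor `1e-4` were calibrated
  once so that at rest a new unit becomes dominant every ~24.75 ms: 40
  dominance transitions per second and 5 complete 8-unit cycles per
  second, the two intrinsic rhythms of the model.
* **Syllable units**: one evidence accumulator per candidate (in sentence
  processing, one per syllable *token*, each tied to that token's stored
  template). Their softmax is the model's instantaneous belief about
  syllable identity. In the generative direction they are perfect
  integrators; during inference they integrate precision-weighted
  bottom-up errors and are reset toward uniform when the last gamma unit
  dominates (threshold 0.6, shared with the segmentation markers).
* **Spectral level** (`hopfield_step()`): a stable linear relaxation of
  the 6-channel spectral state toward the compositional prediction
  `sum_k softmax_k (T_k y)` — the syllable-probability-weighted,
  gamma-position-weighted blend of stored template columns. Only its
  fixed-point behavior matters downstream, so the full attractor energy is
  simplified to first-order relaxation (rate 0.2/ms).

## Inversion

`invert()` is a first-order precision-weighted gradient flow on squared
prediction errors, run forward in lockstep with the stimulus at 1 ms
steps. The bottom-up syllable error of unit `i` is the projection of the
spectral input error onto that unit's direction of influence on the
prediction, `z_pe_i = softmax_i * (T_i y - shat) . eps`; the accumulator
update is `eta_omega * V_omega(t) * z_pe_i` with `V_omega(t)` evaluated on
the concurrently integrated oscillator. The gamma units receive the
analogous timing error weighted by `V_gamma(t)`. This exposes exactly the
mechanism of interest — oscillating precisions gating bottom-up influence —
without the full generalized-coordinate embedding of generalized
filtering, whose extra machinery none of the package's claims depend on.

Two numerical choices deserve emphasis:

* **State noise.** The accumulators receive i.i.d. Gaussian state noise
  (sd 0.005 per ms) during evidence accumulation. This is part of the
  stochastic inference scheme, and it is load-bearing: without any state
  noise the precision gain multiplies signal and noise identically and the
  scheduled gain modulation is nearly performance-neutral. With it, phases
  of high precision genuinely improve the per-step signal-to-noise ratio
  of integration, and the oscillating variants express their
  characteristic frequency dependence (a penalty when whole syllables fall
  into a low-precision half-cycle at 2 Hz, a benefit at 20–30 Hz).
* **Resets suspend integration.** While the reset gate is on (`h(t) = 0`)
  the error and noise terms are suspended and only the relaxation toward
  uniform acts. This matches the bookkeeping of the integration-efficacy
  metric, which excludes active resetting periods: evidence integration is
  simply not happening there. Relaxation preserves the accumulator
  ranking, so a decision read right after a reset still reflects the
  pre-reset winner.

Learning rates (`eta_omega = 0.016`, `eta_gamma = 0.002`) and the state
noise sd were calibrated once on noiseless single-syllable stimuli under
the stationary baseline — the smallest syllable learning rate on a coarse
grid giving fully reliable recognition, and the largest noise sd that
keeps it fully reliable — and frozen before any variant comparison.
Sentences that reach a non-finite state are returned with
`status = "singular"` and excluded from paired analyses explicitly, never
silently dropped.

Segmentation markers are the strict local maxima of the *last* gamma
unit's output with amplitude at least 0.6 (plateaus tie-break to their
first sample). The alternative convention (first gamma unit) can be
obtained by passing `trace$y[1, ]` to `segmentation_markers()`.

## The synthetic corpus

The generator emulates the statistical structure of reduced natural-speech
inputs: a 6-channel spectrogram at 1000 samples/s plus a slow amplitude
envelope, with ~200 ms mean syllable duration. Templates are 6×8 smoothed
uniform random fields, min-max scaled, whose column sums are then
normalized to a fixed decaying onset arc (`exp(-0.215 * (0:7))`). The arc
is a deliberate addition: with unconstrained column energies the summed
envelope of a random template need not rise at syllable onsets, and
envelope peaks would not register syllable boundaries. With it, each
syllable contributes exactly one envelope peak (~25 ms after onset plus
the 25 ms group delay of the causal 50 ms boxcar), while the temporal
binning round-trip (`render_stimulus()` then `binned_average()` recovers
templates exactly for 8-divisible durations) is untouched. Durations are
Gamma-distributed (mean 200 ms, cv 0.3 by default), floored at 8 ms so
every temporal bin has at least one sample. Stimulus noise is rectified
Gaussian (default sd 0.1), a free parameter of the corpus.

What passing tests on this corpus do and do not show: they demonstrate
that the inference machinery, metrics, and the qualitative
frequency-dependence of oscillating precisions behave as designed under
controlled statistics. They do not establish performance on natural
speech — real spectrograms have channel correlations, coarticulation,
amplitude variation across syllables, and syllable inventories far larger
than the per-sentence token sets used here.

## Experiments and statistics

`frequency_sweep()` runs every sentence × variant × frequency condition
with per-sentence inference seeds shared across conditions, so all
comparisons are paired; the stationary baseline is computed once and
broadcast. `bootstrap_summary()` is a percentile bootstrap of the mean
(10000 replicates by default). `paired_tests()` reports Wilcoxon
signed-rank z statistics (normal approximation with tie and zero
corrections — the z value itself is the quantity of interest), Bonferroni
thresholds of `alpha/m` (0.05/8 = 0.00625 for the default 8-frequency
grid), per-variant Friedman tests across frequencies with
Bonferroni-corrected post-hoc pairwise comparisons, and a two-way analysis
of variance with variant as a discrete factor and frequency as a
continuous predictor. The default frequency grid is
`c(2, 5, 10, 20, 30, 40, 50, 60)` Hz, spanning the tested 2–60 Hz range.

Problem sizes used by the shipped checks: 5 s oscillator traces, 2–4 s
gamma rest simulations, 20 single-syllable inventories, and a 60-sentence
corpus (inventory 10, five 200 ms-scale syllables per sentence, stimulus
noise 0.1) for the variant comparison — enough sentences that the paired
mean difference between the anti-phase variant at 20–30 Hz and the
stationary baseline is resolved well beyond its standard error.

## Metric conventions

* Sample windows are half-open `[start, end)`; a boundary sample belongs
  to the following syllable. This resolves the double counting a closed
  interval would create at shared boundaries.
* Normalized entropy carries a leading minus sign so that it lies in
  `[0, 1]` with 1 at uniform (the sign is occasionally dropped in informal
  statements of the formula); it is base-independent after normalization.
* Integration efficacy aggregates per-unit values with a plain mean by
  default; `rms = TRUE` switches to root-sum-square.
* Log-likelihoods and the information criterion use natural logarithms;
  recognizer probabilities on true syllables are floored at machine
  epsilon and the sentence flagged when the floor binds.
* Degenerate (empty) segmentation windows are skipped with a warning;
  winner ties break to the lowest unit index.

## Known limitations

* The generative model is a contract-level reconstruction: theta/gamma
  constants, the heteroclinic-channel matrix, and the spectral level are
  calibrated to the documented rates and fixed points rather than ported
  from any specific reference implementation, and inversion is plain
  precision-weighted gradient flow rather than generalized filtering in
  generalized coordinates.
* Per-sentence candidate sets mean that repeated syllable tokens are
  genuinely ambiguous to the identity units; the overlap metric charges
  that ambiguity to the recognizer.
* Absolute metric levels on the synthetic corpus are not comparable to
  natural-speech results; only within-corpus contrasts (variant,
  frequency) are meaningful.
* The oscillator's amplitude and the inference noise magnitudes are design
  choices (documented above), not derived quantities.

## A minimal session

```{r, eval = FALSE}
inv <- make_inventory(10, seed = 1)
corp <- make_corpus(30, inv, n_syl = 5, cv = 0.3, noise_sd = 0.1, seed = 1)
tab <- frequency_sweep(corp, c("stationary", "full_antiphase"),
                       psis = c(2, 20, 30), seed = 1)
sweep_summary(tab, "overlap")
paired_tests(tab, "overlap", m = 8)$contrasts
```
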