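---
title: "Decoding semantic category from intracranial time-frequency features: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding semantic category from intracranial time-frequency features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Electrocorticography (ECoG) grids over ventral anterior temporal cortex
record voltages that mix local population activity (gamma, ~30–60 Hz, and
high gamma, ~60–200 Hz) with lower-frequency activity that may reflect
longer-range interactions. `ecogdecode` implements a decoding pipeline that
asks, per frequency band and per timepoint, whether a binary stimulus
category (animate vs inanimate; animate coded 0, inanimate 1) can be read
out of time-frequency power or phase — and whether the code that supports
that readout is *static* (one pattern throughout processing) or *dynamic*
(the informative pattern, and even its sign, changes over time).

Because raw patient recordings cannot be redistributed, the package is
validated end-to-end on a synthetic generator that plants known codes into
realistic 1/f background noise. Every downstream claim the test suite makes
is therefore a claim about recovering a known ground truth.

# Pipeline and models

## Preprocessing

Epochs span -1000..3000 ms around stimulus onset at 1000 Hz. The retained
steps are: baseline correction (per channel, subtracting the mean over
-200..-1 ms across good trials), common average referencing, optional
boxcar downsampling (pairs of neighbouring samples averaged; an odd final
sample is dropped), and extreme-trial rejection: per channel, mean and SD
are pooled over timepoints and trials, and any trial containing a sample
beyond 10 SD on any channel is *flagged*, never deleted — repetition
averaging needs to know which stimuli end up with no good trials so their
power can be median-interpolated later.

## Time-frequency extraction

Complex Morlet wavelets on a 60-step log-spaced grid from 4 to 200 Hz, with
cycle counts interpolated linearly in log-frequency from 5 cycles at 4 Hz
to 15 at 200 Hz. Only the endpoints of the cycle schedule are canonical;
log-linear interpolation matches the log-spaced grid, rising by a constant
increment per grid step. Wavelets are normalized to unit total energy; the
scale cancels in dB normalization, and the unit-energy convention is stated
so oracle tests can reproduce coefficients exactly.

Band edges are half-open — theta [4,8), alpha [8,13), beta [13,30), gamma
[30,60), high gamma [60,200] — which is the unique assignment reproducing
the canonical per-band counts 11/7/13/10/19 on the 60-point grid: the
nominal printed ranges ("13–30", "30–60") overlap at their shared edges and
cannot all be closed intervals.

Power is `|coefficient|^2`, averaged over the (typically four) repetitions
of each stimulus, then decibel-normalized: `10*log10(P / B)` where `B(e,f)`
is the mean raw-trial power over -300..-100 ms. The gap before onset keeps
temporal leakage of post-stimulus activity (wavelets are long at 4 Hz) out
of the baseline. We take `B` over raw trials rather than
repetition-averaged power; with balanced repetitions the two differ only
in sampling noise. Missing stimuli are filled with the across-stimulus
median per (electrode, frequency, time) cell. Phase cannot be averaged, so
trials are repetition-averaged *before* the transform and phase is the
coefficient argument in (-pi, pi]; zero-magnitude cells are NA rather than
silently 0.

Outputs are sampled 0..1650 ms every 10 ms by default. The -1000 ms
pre-stimulus margin exceeds the half-support of the longest (4 Hz, 5-cycle)
wavelet (~0.7 s), so both the baseline window and the analysis window are
free of edge contamination at default settings; output samples whose
wavelet support leaves the epoch are flagged.

## Decoding

Feature vectors at a timepoint concatenate, per electrode, either all
selected frequencies (power/phase) or all samples of a 50 ms window centred
on the timepoint (voltage). "50 ms centred" is ambiguous by one sample at
1000 Hz; we use the inclusive window, 51 samples per electrode.

Classifiers are LASSO (L1)-regularized logistic regressions: minimize mean
logistic deviance plus `lambda * sum(|beta|)`, intercept unpenalized,
features standardized internally with coefficients reported on the original
scale (the `glmnet` conventions; model fitting is delegated to glmnet and
checked in the test suite against an independent proximal-gradient solver
to 1e-4 across the penalty grid). The penalty is searched on 100
log-spaced values descending from 0.2 to 0.002 by inner stratified
cross-validation, scoring mean squared error between the predicted
probability and the 0/1 label (probability scale, not link scale), with
ties broken toward the larger, sparser penalty. The outer loop is
stratified 10-fold over the 100 stimuli — each fold holds out 10 stimuli,
5 per class — with the partition fixed across timepoints so the same model
can be tested at every other timepoint, yielding a train-by-test temporal
generalization matrix alongside the diagonal accuracy timecourse.
Predicted class is 1 when the predicted probability is at least 0.5, which
is uncontroversial on balanced hold-outs. The inner fold count defaults to
10 (the convention of the fitting tool this mirrors); the reduced test
configurations use smaller inner folds, which only coarsens the penalty
selection. Separately, a full-data model per timepoint (penalty selected on
all stimuli) is stored for coefficient inspection only — it is never
scored.

Group aggregation is the unweighted mean over subjects of per-subject
fold-mean accuracies.

## Inference

Timecourses are compared to chance (0.5) with one-tailed, one-sample
t-tests across subjects (df = subjects - 1); pairs of feature sets with
two-sided paired t-tests. p-values are Benjamini-Hochberg adjusted at
alpha = 0.05. The FDR family is all timepoints within one timecourse
comparison, or all train-by-test cells within one generalization analysis —
per-analysis families matching figure-wise reporting; the family choice is
stated because it is not derivable from the method alone. Zero-variance
cases are flagged degenerate, never dropped silently.

The best-classifier map asks, per test timepoint, which training timepoints
perform statistically indistinguishably from the best one: cells not
reliably worse than the best are "best-equivalent" (the best cell itself is
so by construction); reliably worse cells that still beat chance are
"above-chance"; the rest are "chance". A dynamic code produces squares
whose on-diagonal corners are best-equivalent while the off-diagonal
corners are not.

## Dynamics

Rows of the generalization matrix are compared by cosine distance and
clustered agglomeratively (complete linkage — the clustering routine's
convention, stated explicitly because the choice is otherwise open) with
the tree cut at k = 10 by default; k is exposed because no stability
criterion fixes it. Generalization width is quantified as the signed
trapezoidal area between each training time's test-timecourse and chance,
taken over classifiers trained every 50 ms, and summarized by a continuous
piecewise-linear fit whose breakpoint count (0..3) and locations are chosen
by BIC = `n*log(RSS/n) + p*log(n)`, `p = 2 + 2*breaks`. The breakpoint
search is exhaustive on the 50 ms grid for up to two breakpoints and greedy
for the third: deterministic and exactly BIC-comparable at this scale. The
reference tool for segmented regression does not print its BIC
definition, so ours is stated above and validated against constructed
hinges (exact recovery when noiseless; within one grid step in >= 90% of
noisy replicates).

Code direction: from the full-data models, the mean coefficient per
electrode and band per subject; at group level, the number of subjects
selecting the electrode (nonzero mean) and the proportion of those with a
negative mean. With animate = 0, a negative coefficient means increased
power signals the animate class. Proportions are undefined (NA) where no
subject selects the electrode. Cortical-surface projection and smoothing
are out of scope; the map is a per-electrode table keyed to channel
coordinates.

# The synthetic generator

The generator emulates the study design: 100 stimuli (50 per class), four
runs with every stimulus shown once per run in random order, 1000 Hz
sampling, epochs -1000..3000 ms. Background noise is 1/f^alpha (alpha = 1
by default), synthesized by spectral shaping of white noise, independent
per channel — deliberately without cross-channel structure, so common
average referencing cannot manufacture artifactual effects. Planted effects
are band-limited sinusoids: carrier frequency drawn uniformly in the band
per trial and electrode, uniform random phase, amplitude
`envelope(t) * amplitude_by_class[class]`. A sign schedule can swap the
class amplitudes over stated intervals (a dynamic, sign-reversing code).
The `fig6` envelope family — linear rise to a peak, exponential decay,
with earlier peaks paired to faster decays — produces the
early-strong/fast-decay versus late-weak/persistent response profiles
whose decoding signature is full retrograde plus diminishing anterograde
generalization. The linear rise keeps late-peaking electrodes informative
soon after onset, which is what makes full retrograde generalization
possible.

What the generator does *not* emulate: ictal/interictal artifacts, volume
conduction, eye movements, line noise, and single-trial phase consistency.
The random-phase default makes phase decoding fail by construction — a
deliberately conservative null for the phase pathway; a phase-locked option
(phase 0/pi by class) exists for testing the phase machinery, but its
physiological realism is unvalidated. Passing tests on this generator
demonstrate that the machinery recovers known codes under realistic noise,
not that real vATL data contain such codes.

## A note on finite stimulus samples

With 20 stimuli per class and four repetitions, the stimulus-level averaged
noise is fixed once per dataset, and occasional seeds show chance
class–noise correlations strong enough that a cross-validated decoder
genuinely generalizes on them (held-out stimuli share the correlated noise
pattern). This is a property of small stimulus samples, not a bug: the
per-seed null accuracy distribution is wider than binomial, which is why
the chance-level checks in the test suite are phrased over means across
seeds or groups, and why electrode-recovery checks use the study-sized 50
stimuli per class, where such correlations are much weaker.

# Numerical and scenario choices

* Planted-band specificity scenarios use a 32–48 Hz effect, interior to the
  30–60 Hz gamma band: Morlet bandwidth at the neighbouring band centres
  (sigma_f = f / cycles) implies that an effect touching the band edge
  leaks class information into beta/high-gamma features, which the
  specificity check requires to stay at chance. The choice follows from
  wavelet bandwidth arithmetic, not from tuning.
* Reduced problem sizes for simulation suites: 12 log-spaced frequencies
  (4–200 Hz), 30 timepoints at 50 ms or 13 at 100 ms, 5 outer / 4 inner
  folds, 16 or 8 channels, 10–20 stimuli per class. These sizes keep each
  suite in minutes while leaving the tested contrasts far from threshold
  (e.g. planted-gamma accuracy ~0.98 against a 0.9 criterion).
* Null-calibration groups use 20 stimuli per class and 2 runs. The type-I
  error of the FDR-controlled group inference does not depend on these
  counts, but the *mean* cross-validated accuracy under the null carries a
  small pessimistic bias that scales inversely with hold-out size (an
  overfit model's noise pattern anti-correlates with held-out samples
  drawn from the same finite pool); very small stimulus samples push that
  bias past the sampling error of the chance-level check, so the
  calibration uses a stimulus count in the regime the check presumes. Simulation epochs are shortened to -500..2000 ms
  wherever the analysis window ends by 1450 ms; the pre-stimulus margin
  still exceeds the longest wavelet half-support.
* Determinism: every stochastic step takes an explicit seed; subject,
  noise and inner-CV seeds are derived arithmetically (modulo 2^31 - 1)
  from the master seed. The same configuration reproduces bit-identical
  artifacts and checksums.
* Degenerate inputs: zero-SD channels are skipped with a warning during
  rejection; zero baseline power, all-missing stimuli, single-class labels
  and zero-norm generalization rows raise errors naming the problem.

# Limitations

* The LASSO path is fit by coordinate descent (glmnet) with a tightened
  convergence threshold; coefficients agree with an independent solver to
  1e-4, which bounds, but does not eliminate, solver-dependent wobble in
  selected-feature sets near the selection boundary.
* The piecewise fit searches breakpoints on the sampling grid only;
  breakpoints between grid points are attributed to the nearest candidate.
* The best-classifier map inherits the low power of paired t-tests across
  small cohorts; with 4 subjects only large accuracy differences separate
  categories.
* Band-wise decoding inherits wavelet spectral leakage: effects within
  ~2 bandwidths of a band edge are visible from the neighbouring band.
  This is physics, not implementation; interpret band specificity
  accordingly.
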