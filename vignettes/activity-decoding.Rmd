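---
title: "Decoding activity states from wristband inertial data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding activity states from wristband inertial data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actidecode)
```

## The problem

A wristband IMU samples three acceleration channels (in g) and three
angular-velocity channels (in deg/s) at roughly 50 Hz while a subject
moves through a sequence of activities. The task is to recover, for every
one-second window of signal, which of four activities — stationary,
walking, running, squat — the subject was performing. A per-window
classifier treats windows independently and therefore produces occasional
isolated misclassifications ("interruptions"): a window or two of, say,
running in the middle of a long walking bout, something that cannot happen
physically at this time scale. The package couples the classifier with a
hidden Markov model over the activity sequence precisely to remove those.

## The model chain

**Mean filter.** Each channel is denoised with a centered moving average of
odd width `N` (default 5 samples, i.e. 0.1 s). The window is truncated at
the sequence edges rather than padded: truncation preserves the
constant-signal identity exactly (a constant input is returned unchanged),
which keeps the degenerate zero-noise cases well defined all the way down
the chain. `N = 5` is short relative to every activity's oscillation
period (≥ 0.36 s), so it suppresses sensor noise without attenuating the
class-discriminating oscillations.

**Windows and features.** Windows are 50 samples with step 10 (80 %
overlap), indexed half-open `[s, s + 50)` from 0-based starts. A window's
label is the majority of its per-sample labels; ties go to the label of
the earliest sample belonging to a tied class — a fixed, tested rule,
since windows straddling an activity boundary genuinely have mixed
content. Ten statistics per channel (mean, sd, variance, max, min, range,
median, RMS, skewness, kurtosis — the standard statistical-feature battery
for inertial activity recognition) give 60 features per window. The sample
(n−1) denominator is used for all dispersion statistics, and skewness and
kurtosis of a constant window are defined as 0 rather than NaN, because
zero-noise stationary windows are legitimate inputs. Features are
standardized per column; zero-variance columns are flagged and map to 0.

**Classifier.** A feedforward network with one hidden layer of 32 sigmoid
units (60-32-4) is trained by full-batch gradient descent on the MSE
between sigmoid outputs and one-hot targets. The choice of MSE with
sigmoid outputs (rather than softmax/cross-entropy) is deliberate: it is
the classical backpropagation formulation this pipeline is built around,
and the analytic gradients are verified against central finite differences
in the test suite. Pseudo-posterior scores are obtained by renormalizing
the four output activations to sum to one — a documented approximation,
used only when soft emissions are requested. Weights initialize uniformly
on `±init_scale/√n_in`; biases start at zero.

The constructor defaults (`train_config()`: α = 0.1, 200 epochs) describe
one conservative full-batch step per epoch and suit small demonstration
problems. On the packaged benchmark (~9,000 training windows) that budget
stops far short of convergence, so every benchmark-scale fit in this
package uses α = 0.5 with 1,500–2,000 epochs, which drives the training
loss to a plateau (the per-epoch trace is returned and plottable via
`plot()` on the fitted network). Full batch keeps training deterministic
and order-invariant; a mini-batch mode exists behind the configuration for
larger data.

**HMM.** The smoother is a discrete HMM whose four hidden states are the
true activities and whose observation alphabet is the classifier's
predicted labels. All three parameter groups are estimated supervised,
with pseudocount 1 smoothing:

* `π` and `A` from first-window and bigram counts of the training
  window-label sequences. With dwell times of 3–10 s and a window step of
  0.2 s, self-transitions dominate (`a_ii ≈ 0.95`), which is exactly the
  prior knowledge — activities persist — that the raw classifier lacks.
* `B` from the trained classifier's confusion matrix on its own training
  windows: `b_i(o)` is the probability that the classifier says `o` when
  the truth is `i`. This is deterministic, cheap, and directly encodes how
  the classifier errs, which is the information Viterbi needs to overrule
  it. Baum-Welch EM (with likelihood-ranked random restarts) is provided
  for the unsupervised case but is not the default coupling.

Decoding uses per-step-scaled forward/backward recursions (the classical
remedy for underflow; log-space is used only in Viterbi) and breaks
Viterbi ties toward the lower state index. A zero-probability observation
sequence yields `log_lik = -Inf` with a structured flag rather than an
error, so callers can fall back gracefully. Two smoothing modes exist:
Viterbi over the hard label sequence (default) and argmax of the state
posteriors; a soft-emission variant replaces the per-step emission term by
`B` applied to the renormalized scores. Viterbi-on-hard-labels is the
default because it is the minimal, fully discrete coupling and its
behavior is easiest to reason about (and to enumerate in tests).

## The synthetic generator

Each activity is a per-channel sinusoid plus white Gaussian noise;
acceleration carries a gravity baseline of `(0, 0, 1)` g. The defaults
encode the qualitative structure that makes the four classes separable on
a wrist: running exceeds walking in amplitude and frequency on every
accelerometer axis (0.8–1.0 g at 2.8 Hz vs 0.2–0.3 g at 1.8 Hz), the
stationary class is noise only, and squatting is slow (0.5 Hz) with a
rising z-acceleration ramp of 0.4 g within each repetition — the
signature that makes squats the easiest class to recognize. Noise
defaults (0.02–0.08 g, 1–5 deg/s) keep windowed features clearly
separated; a single `noise_scale` multiplier degrades them for stress
tests. Activities switch according to a Markov chain (default: never
repeat, uniform otherwise) with dwell times uniform on 3–10 s, so windows
rarely straddle boundaries, but boundary windows — the realistic hard
case — are retained, never dropped.

What the generator does **not** emulate: biomechanical gait structure
(harmonics, left/right asymmetry), sensor bias and drift, orientation
change of the wrist during a bout, and between-subject variability.
Passing the packaged benchmarks therefore demonstrates that the
implementation is correct and that the classifier–smoother coupling works
as designed; it does not certify any particular accuracy on real
wristband recordings.

## Problem sizes and numerical choices

The packaged benchmark is 40 sequences of ~60 s at 50 Hz (generator seed
1234), split 75/25 by sequence index — about 8,900 training and 3,100 test
windows; on it the smoothed window accuracy is ≥ 96 % (the acceptance
script recomputes this end to end). The stress suite uses a smaller
configuration (8 sequences × 40 s) at five-fold noise, where the raw
classifier reliably commits isolated interruptions across seeds and
smoothing must strictly improve accuracy. These sizes were chosen as the
smallest at which segment statistics (class coverage in both splits,
several interruptions per split) are stable.

Other fixed conventions, each covered by a test: stochastic-matrix rows
are validated to 1e-6 and renormalized exactly; `Σᵢ α̂ₜ(i)β̂ₜ(i) = 1`
under joint scaling is the forward–backward consistency check; EM
log-likelihood may not decrease by more than 1e-9; EM states starved of
occupancy reset to uniform rows with a warning; argmax ties anywhere
(classifier prediction, Viterbi backtracking) resolve to the lowest
index; model files store doubles at 17 significant digits so a
save/load round trip reproduces decodes bit-for-bit.

Indexing conventions: recordings and CSV files label activities `0:3`
(stationary, walking, running, squat) and window starts are 0-based,
while the HMM API uses R-native `1..N` states and `1..M` symbols; the
pipeline maps label `l` to state `l + 1` internally.

## Known limitations

* The confusion-matrix emission model is estimated on training windows,
  so it understates test-time error rates of the classifier; the
  pseudocount keeps it from ever being degenerate, but strongly
  miscalibrated emissions would dilute the smoother's advantage.
* Smoothing assumes activities persist; genuinely brief activities
  (shorter than ~3 windows) would be smoothed away by design.
* The HMM is fit globally, not per recording, and the generator's
  switch-chain is first-order — both match the modelling assumptions, but
  real curricula of exercises may have longer-range structure.
* No frequency-domain features; with heavily overlapping amplitude ranges
  between classes the 10-statistic battery would saturate before spectral
  features would.
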