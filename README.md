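# actidecode

Window-level decoding of human activity states from wrist-worn six-axis
inertial data, for researchers in exercise/behavioral science who need a
light-weight, fully inspectable alternative to deep sequence models.

The package targets recordings of four physical-education movements —
**stationary, walking, running, squat** — sampled at about 50 Hz by a
wristband IMU (3-axis acceleration in g, 3-axis angular velocity in deg/s).

## Method

The classifier–smoother chain is:

1. **Denoising.** Each channel is filtered with a centered mean filter,
   `y[n] = (1/N) Σ_{k=-(N-1)/2}^{(N-1)/2} x[n+k]` (default `N = 5`,
   truncated at the boundaries).
2. **Windowing.** Sliding windows of 50 samples (1 s) with step 10; each
   window gets the majority label of its samples.
3. **Features.** Ten statistics per channel — mean, sd, variance, max, min,
   range, median, RMS, skewness, kurtosis — giving a 60-dimensional vector
   per window, standardized column-wise.
4. **BPNN.** A from-scratch feedforward network (default 60-32-4, sigmoid
   units) trained by plain gradient descent on the mean-squared error
   `E = (1/2n) Σᵢ ‖yᵢ − ŷᵢ‖²` against one-hot targets, with
   backpropagation deltas `δ^(L) = (a^(L) − y) ⊙ g′(z^(L))`,
   `δ^(l) = (w^(l+1))ᵀ δ^(l+1) ⊙ g′(z^(l))` and updates
   `w ← w − α ∂E/∂w`.
5. **HMM smoothing.** A discrete hidden Markov model `λ = (π, A, B)` over
   the four activities observes the classifier's predicted labels:
   `π`, `A` are estimated from the training window-label sequences, and
   `B` is the classifier's (pseudocount-smoothed) training confusion
   matrix. Viterbi decoding of the raw label sequence removes the
   isolated, implausibly short label flips a per-window classifier makes.
   Scaled forward/backward recursions, posterior (γ) decoding and
   Baum-Welch EM are also provided.

A synthetic recording generator (per-activity sinusoid + noise models,
with the squat's characteristic rising z-acceleration ramp and a Markov
chain over activity segments) supplies labeled benchmarks, so everything
is testable without external data.

## Worked example

```r
library(actidecode)

cfg   <- generator_config(seed = 99, n_sequences = 6, sequence_length_s = 30)
bench <- make_benchmark(cfg)           # 4 train + 2 test recordings

pipe <- har_fit(bench$train,
                train = train_config(learning_rate = 0.5, epochs = 1500))
print(pipe)
#> <har_pipeline> four-activity decoder
#>   features : 60-dim (10 stats x 6 channels), windows 50/10, mean filter N=5
#>   network  : 60-32-4, final loss 0.012903
#>   smoothing: viterbi (hard emissions), HMM self-transition 0.952 (mean)
#>   fitted on 4 recording(s), 642 windows

decoded <- predict(pipe, bench$test[[1]])
print(decoded)
#> <har_decoded> 152 windows
#>   raw vs smoothed agreement: 0.9868
#>   raw accuracy     : 0.9803
#>   smoothed accuracy: 0.9934

evaluate_decoded(decoded)$smoothed$confusion
#>     predicted
#> true  0  1  2 3
#>    0 67  0  0 0
#>    1  1 40  0 0
#>    2  0  0 44 0
#>    3  0  0  0 0
```

The printed numbers mean: the raw network already labels 98.0 % of the
1-second windows correctly; HMM smoothing removes its isolated flips and
lifts window accuracy to 99.3 %, leaving a single boundary-window error in
the confusion matrix (row = true activity 0–3, column = predicted; this
particular test recording happens to contain no squat segment, hence the
empty last row).

A shell front end over the same functions is in
`inst/cli/actidecode.R` (`simulate`, `train`, `decode`, `evaluate`,
`benchmark` subcommands).

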