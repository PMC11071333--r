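#' Parametric signal model for one activity class
#'
#' Describes the six-axis inertial signature of a single activity as a
#' per-channel sinusoid plus Gaussian noise, with an optional within-cycle
#' z-axis acceleration ramp used for the squat class. Channels are ordered
#' `ax, ay, az, gx, gy, gz`; acceleration is in g (gravity baseline
#' `(0, 0, 1)` g at rest), angular velocity in deg/s.
#'
#' @param activity_id Integer class code in `0:3`
#'   (0 = stationary, 1 = walking, 2 = running, 3 = squat).
#' @param accel_baseline Length-3 gravity projection onto the accelerometer
#'   axes, in g.
#' @param osc_freq_hz Oscillation frequency per channel (length 1, 3 or 6), Hz.
#' @param osc_amp Oscillation amplitude per channel (length 1, 3 or 6);
#'   g for the three acceleration channels, deg/s for the gyroscope channels.
#' @param trend_slope_z Rise of the z-axis acceleration over one oscillation
#'   cycle (g per cycle); a sawtooth ramp resetting each cycle. The squat
#'   signature; 0 for the other activities.
#' @param noise_sd Gaussian noise standard deviation per channel
#'   (length 1, 3 or 6), in the channel's units.
#' @return An object of class `activity_model`.
#' @seealso [default_activity_models()], [generate_segment()]
#' @export
activity_model <- function(activity_id, accel_baseline = c(0, 0, 1),
                           osc_freq_hz = 0, osc_amp = 0,
                           trend_slope_z = 0, noise_sd = 0) {
  activity_id <- assert_count(activity_id, "activity_id", min = 0L)
  if (activity_id > 3L) stop_invalid("`activity_id` must be in 0:3")
  if (length(accel_baseline) != 3L || !is.numeric(accel_baseline) ||
      any(!is.finite(accel_baseline)))
    stop_invalid("`accel_baseline` must be a finite length-3 vector (g)")
  osc_freq_hz <- recycle6(osc_freq_hz, "osc_freq_hz")
  osc_amp <- recycle6(osc_amp, "osc_amp")
  noise_sd <- recycle6(noise_sd, "noise_sd")
  if (any(osc_freq_hz < 0)) stop_invalid("`osc_freq_hz` must be >= 0")
  if (any(osc_amp < 0)) stop_invalid("`osc_amp` must be >= 0")
  if (any(noise_sd < 0)) stop_invalid("`noise_sd` must be >= 0")
  assert_scalar_number(trend_slope_z, "trend_slope_z")
  structure(
    list(activity_id = activity_id, accel_baseline = as.numeric(accel_baseline),
         osc_freq_hz = osc_freq_hz, osc_amp = osc_amp,
         trend_slope_z = trend_slope_z, noise_sd = noise_sd),
    class = "activity_model"
  )
}

#' Default activity models for the four-class benchmark
#'
#' One [activity_model()] per class, calibrated so that the class-conditional
#' signal ranges are ordered the way wrist-worn recordings of these movements
#' are: running exceeds walking exceeds stationary in both amplitude and
#' frequency on every accelerometer axis, and squatting is slow (about one
#' repetition every two seconds) with a distinctive rising ramp on the z-axis
#' acceleration within each repetition.
#'
#' @param noise_scale Multiplier applied to every model's `noise_sd`;
#'   values above 1 degrade the windowed features and make the raw classifier
#'   commit the short, isolated label flips that sequence smoothing targets.
#' @return Named list of four `activity_model` objects
#'   (`stationary`, `walking`, `running`, `squat`).
#' @export
default_activity_models <- function(noise_scale = 1) {
  assert_scalar_number(noise_scale, "noise_scale", nonneg = TRUE)
  ns <- function(sd) sd * noise_scale
  list(
    stationary = activity_model(0L, osc_freq_hz = 0, osc_amp = 0,
                                noise_sd = ns(c(0.02, 0.02, 0.02, 1, 1, 1))),
    walking    = activity_model(1L, osc_freq_hz = 1.8,
                                osc_amp = c(0.25, 0.20, 0.30, 60, 40, 50),
                                noise_sd = ns(c(0.05, 0.05, 0.05, 3, 3, 3))),
    running    = activity_model(2L, osc_freq_hz = 2.8,
                                osc_amp = c(0.80, 0.60, 1.00, 200, 150, 180),
                                noise_sd = ns(c(0.08, 0.08, 0.08, 5, 5, 5))),
    squat      = activity_model(3L, osc_freq_hz = 0.5,
                                osc_amp = c(0.15, 0.10, 0.25, 30, 20, 40),
                                trend_slope_z = 0.4,
                                noise_sd = ns(c(0.05, 0.05, 0.05, 3, 3, 3)))
  )
}

#' Configuration for the synthetic recording generator
#'
#' @param activity_models List of four [activity_model()] objects with
#'   `activity_id` 0..3 (in that order).
#' @param sample_rate_hz Sampling frequency in Hz.
#' @param switch_matrix 4x4 row-stochastic matrix; row i gives the
#'   distribution of the next activity after a segment of activity i.
#'   The default never repeats an activity (zero diagonal, uniform
#'   off-diagonal), so segment durations are governed entirely by
#'   `dwell_range_s`.
#' @param dwell_range_s Length-2 `(min, max)` of the uniform dwell-time
#'   distribution, in seconds, for how long one activity persists.
#' @param n_sequences Number of recordings in a generated benchmark.
#' @param sequence_length_s Minimum duration of each recording, seconds.
#' @param seed Integer seed; mandatory so benchmarks are reproducible.
#' @param noise_scale Convenience multiplier forwarded to
#'   [default_activity_models()] when `activity_models` is not supplied.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(activity_models = default_activity_models(noise_scale),
                             sample_rate_hz = 50,
                             switch_matrix = NULL,
                             dwell_range_s = c(3, 10),
                             n_sequences = 40,
                             sequence_length_s = 60,
                             seed = 1234,
                             noise_scale = 1) {
  assert_scalar_number(sample_rate_hz, "sample_rate_hz", positive = TRUE)
  assert_count(n_sequences, "n_sequences")
  assert_scalar_number(sequence_length_s, "sequence_length_s", positive = TRUE)
  seed <- assert_count(seed, "seed", min = 0L)
  if (length(dwell_range_s) != 2L || any(dwell_range_s <= 0) ||
      dwell_range_s[1] > dwell_range_s[2])
    stop_invalid("`dwell_range_s` must be (min, max) with 0 < min <= max")
  if (!is.list(activity_models) || length(activity_models) != 4L ||
      !all(vapply(activity_models, inherits, TRUE, "activity_model")))
    stop_invalid("`activity_models` must be a list of four activity_model objects")
  ids <- vapply(activity_models, `[[`, 0L, "activity_id")
  if (!identical(as.integer(ids), 0:3))
    stop_invalid("`activity_models` must carry activity_id 0,1,2,3 in order")
  if (is.null(switch_matrix)) {
    switch_matrix <- matrix(1 / 3, 4, 4)
    diag(switch_matrix) <- 0
  }
  switch_matrix <- check_stochastic(switch_matrix, "switch_matrix")
  structure(
    list(activity_models = activity_models, sample_rate_hz = sample_rate_hz,
         switch_matrix = switch_matrix, dwell_range_s = as.numeric(dwell_range_s),
         n_sequences = as.integer(n_sequences),
         sequence_length_s = sequence_length_s, seed = seed),
    class = "generator_config"
  )
}

#' Construct a six-axis inertial recording
#'
#' @param samples T x 6 numeric matrix, columns `ax, ay, az, gx, gy, gz`.
#' @param sample_rate_hz Sampling frequency in Hz.
#' @param labels Optional length-T integer vector of per-sample activity
#'   labels in `0:3`.
#' @param subject_id Optional identifier string.
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(samples, sample_rate_hz, labels = NULL,
                          subject_id = NULL) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 6L || nrow(samples) < 1L || !is.numeric(samples))
    stop_invalid("`samples` must be a numeric T x 6 matrix with T >= 1")
  assert_scalar_number(sample_rate_hz, "sample_rate_hz", positive = TRUE)
  colnames(samples) <- channel_names()
  if (!is.null(labels)) {
    if (length(labels) != nrow(samples))
      stop_invalid("`labels` must have one entry per sample")
    labels <- as.integer(labels)
    if (any(is.na(labels)) || any(labels < 0L) || any(labels > 3L))
      stop_invalid("`labels` must be integers in 0:3")
  }
  structure(
    list(samples = samples, sample_rate_hz = sample_rate_hz,
         labels = labels, subject_id = subject_id),
    class = "imu_recording"
  )
}

#' @export
print.imu_recording <- function(x, ...) {
  cat("<imu_recording> ", nrow(x$samples), " samples @ ", x$sample_rate_hz,
      " Hz (", format(nrow(x$samples) / x$sample_rate_hz, digits = 4),
      " s)\n", sep = "")
  if (!is.null(x$labels)) {
    tab <- table(factor(x$labels, levels = 0:3,
                        labels = c("stationary", "walking", "running", "squat")))
    cat("  labels: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
        sep = "")
  } else cat("  labels: none\n")
  invisible(x)
}

# Evaluate one activity's noiseless signal at times t (seconds) given phases.
activity_signal <- function(model, t, phases) {
  n <- length(t)
  out <- matrix(0, n, 6L)
  for (c in 1:6) {
    base <- if (c <= 3) model$accel_baseline[c] else 0
    osc <- model$osc_amp[c] *
      sin(2 * pi * model$osc_freq_hz[c] * t + phases[c])
    out[, c] <- base + osc
  }
  # squat signature: sawtooth ramp on z-acceleration, one ramp per cycle
  f <- model$osc_freq_hz[3]
  if (model$trend_slope_z != 0 && f > 0)
    out[, 3] <- out[, 3] + model$trend_slope_z * ((t * f) %% 1)
  out
}

#' Generate one constant-activity segment
#'
#' Draws `floor(duration_s * rate_hz)` samples from an [activity_model()]:
#' per-channel sinusoid with a random phase, plus the squat ramp where
#' configured, plus white Gaussian noise. Consumes the current R random
#' stream; seed upstream (e.g. `set.seed()`) for reproducibility.
#'
#' @param model An [activity_model()].
#' @param duration_s Segment duration in seconds (> 0).
#' @param rate_hz Sampling rate in Hz (> 0).
#' @return An [imu_recording()] with every sample labeled
#'   `model$activity_id`.
#' @export
generate_segment <- function(model, duration_s, rate_hz) {
  if (!inherits(model, "activity_model"))
    stop_invalid("`model` must be an activity_model")
  assert_scalar_number(duration_s, "duration_s", positive = TRUE)
  assert_scalar_number(rate_hz, "rate_hz", positive = TRUE)
  n <- floor(duration_s * rate_hz)
  if (n < 1L) stop_invalid("duration too short for one sample at this rate")
  t <- (seq_len(n) - 1) / rate_hz
  phases <- stats::runif(6L, 0, 2 * pi)
  clean <- activity_signal(model, t, phases)
  noise <- matrix(stats::rnorm(n * 6L), n, 6L) *
    rep(model$noise_sd, each = n)
  imu_recording(clean + noise, rate_hz, labels = rep(model$activity_id, n))
}

#' Generate a multi-activity recording
#'
#' Concatenates constant-activity segments: the first activity is uniform on
#' the four classes, subsequent activities follow the configuration's
#' `switch_matrix`, and each segment's dwell time is uniform on
#' `dwell_range_s`. Generation stops with the first segment that brings the
#' total length to at least `sequence_length_s`.
#'
#' @param config A [generator_config()].
#' @param seed Seed applied before generation; defaults to `config$seed`.
#'   Pass `NULL` to consume the current random stream instead.
#' @param first_activity Optional class in `0:3` forcing the starting
#'   activity (default: drawn uniformly).
#' @return A labeled [imu_recording()].
#' @export
generate_sequence <- function(config, seed = config$seed,
                              first_activity = NULL) {
  if (!inherits(config, "generator_config"))
    stop_invalid("`config` must be a generator_config")
  if (!is.null(seed)) set.seed(seed)
  rate <- config$sample_rate_hz
  target <- ceiling(config$sequence_length_s * rate)
  act <- if (is.null(first_activity)) sample.int(4L, 1L)
         else assert_count(first_activity, "first_activity", min = 0L) + 1L
  pieces <- list()
  total <- 0L
  while (total < target) {
    dwell <- stats::runif(1L, config$dwell_range_s[1], config$dwell_range_s[2])
    seg <- generate_segment(config$activity_models[[act]], dwell, rate)
    pieces[[length(pieces) + 1L]] <- seg
    total <- total + nrow(seg$samples)
    act <- sample.int(4L, 1L, prob = config$switch_matrix[act, ])
  }
  imu_recording(
    do.call(rbind, lapply(pieces, `[[`, "samples")),
    rate,
    labels = unlist(lapply(pieces, `[[`, "labels"), use.names = FALSE)
  )
}

#' Generate a reproducible train/test benchmark
#'
#' Generates `config$n_sequences` recordings (sequence i seeded with
#' `config$seed + i`, so the set is reproducible and order-independent) and
#' splits them 75/25 by sequence index: the first 75 percent train, the rest
#' test. Both splits are checked to contain all four activities.
#'
#' @param config A [generator_config()] with `n_sequences >= 2`.
#' @return List with elements `train` and `test`, each a list of
#'   [imu_recording()] objects.
#' @export
make_benchmark <- function(config) {
  if (!inherits(config, "generator_config"))
    stop_invalid("`config` must be a generator_config")
  if (config$n_sequences < 2L)
    stop_invalid("`n_sequences` must be >= 2 to form a train/test split")
  recs <- lapply(seq_len(config$n_sequences), function(i)
    generate_sequence(config, seed = config$seed + i))
  n_train <- max(1L, floor(0.75 * config$n_sequences))
  if (n_train >= config$n_sequences) n_train <- config$n_sequences - 1L
  split <- list(train = recs[seq_len(n_train)],
                test = recs[(n_train + 1L):config$n_sequences])
  for (part in names(split)) {
    seen <- sort(unique(unlist(lapply(split[[part]], `[[`, "labels"))))
    if (!identical(seen, 0:3))
      stop_invalid("benchmark ", part, " split is missing activity class(es) ",
                   paste(setdiff(0:3, seen), collapse = ", "),
                   "; increase n_sequences or sequence_length_s")
  }
  split
}
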