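#' Centered moving-average (mean) filter
#'
#' Replaces each sample by the average of the `N` samples centered on it,
#' `y[n] = (1/N) * sum_{k=-(N-1)/2}^{(N-1)/2} x[n+k]`. At the two boundaries
#' the averaging window is truncated to the indices that exist (no padding),
#' which keeps constant signals exactly constant. Output length equals input
#' length.
#'
#' @param x Numeric vector.
#' @param n Odd window size, `1 <= n <= length(x)`.
#' @return Filtered numeric vector, same length as `x`.
#' @export
mean_filter <- function(x, n = 5L) {
  if (!is.numeric(x) || length(x) < 1L)
    stop_invalid("`x` must be a non-empty numeric vector")
  n <- assert_count(n, "n")
  if (n %% 2L == 0L) stop_invalid("`n` must be odd")
  if (n > length(x)) stop_invalid("`n` must not exceed length(x)")
  if (n == 1L) return(x)
  T <- length(x)
  h <- (n - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(T) - h, 1L)
  hi <- pmin(seq_len(T) + h, T)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Sliding-window specification
#'
#' @param length Window length in samples (default 50, i.e. one second at
#'   50 Hz).
#' @param step Hop between consecutive window starts in samples (default 10).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(length = 50L, step = 10L) {
  length <- assert_count(length, "length", min = 2L)
  step <- assert_count(step, "step")
  if (step > length) stop_invalid("`step` must be <= `length`")
  structure(list(length = length, step = step), class = "window_spec")
}

# Majority label of a window; ties go to the class of the earliest sample
# belonging to one of the tied classes.
majority_label <- function(labels) {
  counts <- tabulate(labels + 1L, nbins = 4L)
  tied <- which(counts == max(counts)) - 1L
  if (length(tied) == 1L) return(tied)
  labels[match(TRUE, labels %in% tied)]
}

#' Cut a recording into fixed sliding windows
#'
#' Windows are half-open sample ranges `[s, s + length)` with 0-based starts
#' `0, step, 2*step, ...`; the count is
#' `floor((T - length)/step) + 1`. Each window's label is the majority of its
#' per-sample labels (ties broken toward the label of the earliest tied-class
#' sample).
#'
#' @param recording An [imu_recording()].
#' @param spec A [window_spec()].
#' @return List of class `imu_windows` with `windows` (list of
#'   `length x 6` matrices), `starts` (0-based), and `labels` (or `NULL` for
#'   unlabeled recordings).
#' @export
slide_windows <- function(recording, spec = window_spec()) {
  if (!inherits(recording, "imu_recording"))
    stop_invalid("`recording` must be an imu_recording")
  T <- nrow(recording$samples)
  if (T < spec$length)
    stop_invalid("recording too short: ", T, " samples, need at least ",
                 spec$length, " for one window")
  starts <- seq.int(0L, T - spec$length, by = spec$step)
  wins <- lapply(starts, function(s)
    recording$samples[(s + 1L):(s + spec$length), , drop = FALSE])
  labels <- NULL
  if (!is.null(recording$labels))
    labels <- vapply(starts, function(s)
      majority_label(recording$labels[(s + 1L):(s + spec$length)]), 0L)
  structure(list(windows = wins, starts = as.integer(starts), labels = labels),
            class = "imu_windows")
}

#' Names of the ten per-channel statistics, in feature order
#' @return Character vector of length 10.
#' @export
har_stat_names <- function() {
  c("mean", "sd", "var", "max", "min", "range", "median", "rms",
    "skewness", "kurtosis")
}

# The ten statistics of one channel. Constant channels get skewness and
# kurtosis 0 by convention (zero-noise stationary windows are legal input).
channel_stats <- function(x, n_stats = 10L) {
  m <- mean(x)
  s <- stats::sd(x)                    # n - 1 denominator throughout
  mx <- max(x)
  mn <- min(x)
  if (s > 0) {
    sk <- e1071::skewness(x, type = 1)
    ku <- e1071::kurtosis(x, type = 1) # excess kurtosis, 0 for a Gaussian
  } else {
    sk <- 0
    ku <- 0
  }
  full <- c(m, s, s * s, mx, mn, mx - mn, stats::median(x),
            sqrt(mean(x * x)), sk, ku)
  full[seq_len(n_stats)]
}

#' Statistical feature vector of one window
#'
#' Computes, for each of the six channels, the ordered statistic set
#' mean, standard deviation, variance, maximum, minimum, range, median,
#' root-mean-square, skewness, kurtosis, and concatenates them channel-major:
#' `c(stats(ax), stats(ay), ..., stats(gz))` — 60 features for the full set.
#'
#' @param window `length x 6` numeric matrix with finite values.
#' @param n_stats Number of leading statistics per channel to keep
#'   (default 10; used by the feature-dimension sweep).
#' @return Numeric vector of length `6 * n_stats`.
#' @export
extract_features <- function(window, n_stats = 10L) {
  window <- as.matrix(window)
  if (ncol(window) != 6L || nrow(window) < 2L)
    stop_invalid("`window` must be a numeric matrix with 6 columns and >= 2 rows")
  if (any(!is.finite(window))) stop_invalid("`window` contains non-finite values")
  n_stats <- assert_count(n_stats, "n_stats")
  if (n_stats > 10L) stop_invalid("`n_stats` must be <= 10")
  as.numeric(vapply(1:6, function(c) channel_stats(window[, c], n_stats),
                    numeric(n_stats)))
}

#' Windowed feature dataset of one or more recordings
#'
#' Mean-filters every channel, cuts the recording into sliding windows and
#' extracts the per-window statistical features; the standard front end of
#' the classifier.
#'
#' @param recordings An [imu_recording()] or list of them.
#' @param spec A [window_spec()].
#' @param filter_width Odd mean-filter window in samples (1 disables
#'   filtering; default 5).
#' @param n_stats Statistics per channel (default 10 for 60 features).
#' @return Object of class `feature_dataset`: `features` (W x 6*n_stats
#'   matrix), `labels` (length-W integer vector or NULL), `window_starts`
#'   (0-based), `sequence` (recording index per window), `stat_names`.
#' @export
window_features <- function(recordings, spec = window_spec(),
                            filter_width = 5L, n_stats = 10L) {
  if (inherits(recordings, "imu_recording")) recordings <- list(recordings)
  if (!length(recordings) ||
      !all(vapply(recordings, inherits, TRUE, "imu_recording")))
    stop_invalid("`recordings` must be imu_recording objects")
  feats <- list(); labs <- list(); starts <- list(); seqid <- list()
  has_lab <- vapply(recordings, function(r) !is.null(r$labels), TRUE)
  if (any(has_lab) && !all(has_lab))
    stop_invalid("recordings must be all labeled or all unlabeled")
  any_labels <- all(has_lab)
  for (r in seq_along(recordings)) {
    rec <- recordings[[r]]
    filtered <- rec$samples
    if (filter_width > 1L)
      for (c in 1:6) filtered[, c] <- mean_filter(filtered[, c], filter_width)
    frec <- imu_recording(filtered, rec$sample_rate_hz, labels = rec$labels)
    w <- slide_windows(frec, spec)
    feats[[r]] <- t(vapply(w$windows, extract_features, numeric(6L * n_stats),
                           n_stats = n_stats))
    labs[[r]] <- w$labels
    starts[[r]] <- w$starts
    seqid[[r]] <- rep(r, length(w$starts))
  }
  features <- do.call(rbind, feats)
  colnames(features) <- paste(rep(channel_names(), each = n_stats),
                              rep(har_stat_names()[seq_len(n_stats)], 6L),
                              sep = "_")
  structure(
    list(features = features,
         labels = if (any_labels) unlist(labs, use.names = FALSE) else NULL,
         window_starts = unlist(starts, use.names = FALSE),
         sequence = unlist(seqid, use.names = FALSE),
         stat_names = har_stat_names()[seq_len(n_stats)]),
    class = "feature_dataset"
  )
}

#' Fit a per-column standardizer
#'
#' Stores per-column means and sample standard deviations. Columns with zero
#' variance are flagged; they standardize to exactly 0.
#'
#' @param features W x p numeric matrix, `W >= 2`.
#' @return Object of class `feature_normalizer` with `center`, `scale`,
#'   `constant` (logical flag per column).
#' @export
fit_normalizer <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2L)
    stop_invalid("need at least 2 rows to fit a normalizer")
  center <- colMeans(features)
  scale <- apply(features, 2L, stats::sd)
  constant <- scale == 0
  scale[constant] <- 1
  structure(list(center = center, scale = scale, constant = constant),
            class = "feature_normalizer")
}

#' Apply a fitted standardizer
#'
#' @param normalizer A [fit_normalizer()] result.
#' @param features Matrix with the same column count the normalizer was
#'   fit on.
#' @return Standardized matrix `(x - center) / scale`; flagged constant
#'   columns are set to 0.
#' @export
apply_normalizer <- function(normalizer, features) {
  if (!inherits(normalizer, "feature_normalizer"))
    stop_invalid("`normalizer` must come from fit_normalizer()")
  features <- as.matrix(features)
  if (ncol(features) != length(normalizer$center))
    stop_invalid("feature width ", ncol(features), " does not match the ",
                 length(normalizer$center), " columns the normalizer was fit on")
  out <- sweep(sweep(features, 2L, normalizer$center), 2L, normalizer$scale, "/")
  out[, normalizer$constant] <- 0
  out
}
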