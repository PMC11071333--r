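#' Fit the full activity-decoding pipeline
#'
#' The modelling entry point of the package. From labeled six-axis
#' recordings it fits, in order: the mean filter + sliding-window +
#' statistical-feature front end, a per-column standardizer, a
#' backpropagation network on the standardized window features, and a
#' four-state hidden Markov model whose initial/transition probabilities
#' come from the training window-label sequences (bigram counts) and whose
#' emission matrix is the trained classifier's smoothed training confusion
#' matrix — i.e. the HMM observes the classifier's predicted labels and
#' knows how the classifier errs.
#'
#' @param recordings List of labeled [imu_recording()] objects (or one).
#' @param window A [window_spec()] (default 50-sample windows, step 10).
#' @param filter_width Odd mean-filter width in samples (default 5).
#' @param hidden Hidden-layer widths for the classifier (default 32).
#' @param train A [train_config()]; its seed fixes all training randomness.
#' @param smoothing `"viterbi"` (default) decodes the single best state
#'   path; `"posterior"` takes the per-window argmax of the state
#'   posteriors.
#' @param emission `"hard"` (default): the HMM observes the predicted
#'   labels through the confusion-matrix emissions. `"soft"`: the per-step
#'   emission likelihood is the emission matrix applied to the classifier's
#'   renormalized scores.
#' @param n_stats Statistics per channel, 1..10 (default 10, so 60
#'   features).
#' @param pseudocount Additive smoothing for the HMM estimates (default 1).
#' @return Object of class `har_pipeline`.
#' @seealso [predict.har_pipeline()], [evaluate_decoded()],
#'   [run_benchmark()]
#' @export
har_fit <- function(recordings, window = window_spec(), filter_width = 5L,
                    hidden = 32L, train = train_config(),
                    smoothing = c("viterbi", "posterior"),
                    emission = c("hard", "soft"),
                    n_stats = 10L, pseudocount = 1) {
  if (inherits(recordings, "imu_recording")) recordings <- list(recordings)
  smoothing <- match.arg(smoothing)
  emission <- match.arg(emission)
  if (!length(recordings) ||
      !all(vapply(recordings, inherits, TRUE, "imu_recording")))
    stop_invalid("`recordings` must be imu_recording objects")
  if (any(vapply(recordings, function(r) is.null(r$labels), TRUE)))
    stop_invalid("all training recordings must carry per-sample labels")
  ds <- window_features(recordings, spec = window, filter_width = filter_width,
                        n_stats = n_stats)
  present <- sort(unique(ds$labels))
  if (!identical(present, 0:3)) {
    missing <- setdiff(0:3, present)
    names <- c("stationary", "walking", "running", "squat")[missing + 1L]
    stop_invalid("training data contains no windows of class ",
                 paste(missing, " (", names, ")", sep = "", collapse = ", "))
  }
  normalizer <- fit_normalizer(ds$features)
  x <- apply_normalizer(normalizer, ds$features)
  net <- bpnn_train(x, ds$labels, hidden = hidden, config = train,
                    classes = 0:3)
  pred <- predict(net, x)
  B <- hmm_emission_from_confusion(ds$labels + 1L, pred$labels + 1L,
                                   n_states = 4L,
                                   pseudocount = pseudocount)
  seqs <- split(ds$labels + 1L, ds$sequence)
  sup <- hmm_estimate_supervised(unname(seqs), n_states = 4L,
                                 pseudocount = pseudocount)
  structure(
    list(normalizer = normalizer, network = net,
         hmm = hmm_params(sup$pi, sup$A, B),
         window = window, filter_width = as.integer(filter_width),
         n_stats = as.integer(n_stats), smoothing = smoothing,
         emission = emission, pseudocount = pseudocount,
         fitted_on = list(n_sequences = length(recordings),
                          n_windows = nrow(x), seed = train$seed)),
    class = "har_pipeline"
  )
}

#' @export
print.har_pipeline <- function(x, ...) {
  cat("<har_pipeline> four-activity decoder\n")
  cat("  features : ", 6L * x$n_stats, "-dim (", x$n_stats,
      " stats x 6 channels), windows ", x$window$length, "/",
      x$window$step, ", mean filter N=", x$filter_width, "\n", sep = "")
  cat("  network  : ", paste(x$network$params$layer_sizes, collapse = "-"),
      ", final loss ",
      format(x$network$trace[length(x$network$trace)], digits = 5),
      "\n", sep = "")
  cat("  smoothing: ", x$smoothing, " (", x$emission, " emissions), ",
      "HMM self-transition ",
      format(mean(diag(x$hmm$A)), digits = 3), " (mean)\n", sep = "")
  cat("  fitted on ", x$fitted_on$n_sequences, " recording(s), ",
      x$fitted_on$n_windows, " windows\n", sep = "")
  invisible(x)
}

#' @export
summary.har_pipeline <- function(object, ...) {
  print(object)
  cat("\nHMM transition matrix:\n")
  print(round(object$hmm$A, 3))
  cat("\nEmission (confusion) matrix:\n")
  print(round(object$hmm$B, 3))
  invisible(object)
}

#' Decode one recording with a fitted pipeline
#'
#' Runs the front end and classifier to get raw per-window labels and
#' scores, then smooths the label sequence with the fitted HMM.
#'
#' @param object A fitted [har_fit()] pipeline.
#' @param newdata An [imu_recording()] long enough for at least one window.
#' @param smoothing,emission Optional overrides of the fitted settings.
#' @param ... Unused.
#' @return Object of class `har_decoded`: `window_starts`, `raw_labels`,
#'   `raw_scores` (W x 4), `smoothed_labels`, `truth_labels` (if the
#'   recording is labeled); all labels in `0:3`.
#' @export
predict.har_pipeline <- function(object, newdata,
                                 smoothing = object$smoothing,
                                 emission = object$emission, ...) {
  if (!inherits(newdata, "imu_recording"))
    stop_invalid("`newdata` must be an imu_recording")
  smoothing <- match.arg(smoothing, c("viterbi", "posterior"))
  emission <- match.arg(emission, c("hard", "soft"))
  ds <- window_features(newdata, spec = object$window,
                        filter_width = object$filter_width,
                        n_stats = object$n_stats)
  x <- apply_normalizer(object$normalizer, ds$features)
  pred <- predict(object$network, x)
  hmm <- object$hmm
  lik <- if (emission == "hard")
    t(hmm$B[, pred$labels + 1L, drop = FALSE])
  else
    pred$scores %*% t(hmm$B)
  smoothed <- if (smoothing == "viterbi")
    viterbi_lik(hmm$pi, hmm$A, lik)$path - 1L
  else {
    post <- posteriors_lik(hmm$pi, hmm$A, lik)
    if (post$zero_prob) pred$labels
    else max.col(post$gamma, ties.method = "first") - 1L
  }
  structure(
    list(window_starts = ds$window_starts, raw_labels = pred$labels,
         raw_scores = pred$scores, smoothed_labels = as.integer(smoothed),
         truth_labels = ds$labels),
    class = "har_decoded"
  )
}

#' @export
print.har_decoded <- function(x, ...) {
  cat("<har_decoded> ", length(x$raw_labels), " windows\n", sep = "")
  agree <- mean(x$raw_labels == x$smoothed_labels)
  cat("  raw vs smoothed agreement: ", format(agree, digits = 4), "\n",
      sep = "")
  if (!is.null(x$truth_labels)) {
    cat("  raw accuracy     : ",
        format(mean(x$raw_labels == x$truth_labels), digits = 4), "\n",
        "  smoothed accuracy: ",
        format(mean(x$smoothed_labels == x$truth_labels), digits = 4), "\n",
        sep = "")
  }
  invisible(x)
}

#' Count short label interruptions
#'
#' An interruption is a maximal constant run shorter than `min_run` windows
#' whose two flanking runs share a single (different) label — the isolated
#' flip a frame classifier makes and sequence smoothing removes. Runs at
#' the sequence edges are not interruptions.
#'
#' @param labels Integer label vector.
#' @param min_run Minimum plausible run length in windows (default 3).
#' @return Integer count.
#' @export
count_interruptions <- function(labels, min_run = 3L) {
  min_run <- assert_count(min_run, "min_run")
  r <- rle(as.integer(labels))
  k <- length(r$lengths)
  if (k < 3L) return(0L)
  mid <- 2:(k - 1L)
  sum(r$lengths[mid] < min_run &
        r$values[mid - 1L] == r$values[mid + 1L])
}

eval_report <- function(pred, truth, min_run, method_tag) {
  classes <- 0:3
  confusion <- table(factor(truth, levels = classes),
                     factor(pred, levels = classes))
  confusion <- matrix(as.integer(confusion), 4L, 4L,
                      dimnames = list(true = classes, predicted = classes))
  row_tot <- rowSums(confusion)
  recall <- ifelse(row_tot > 0, diag(confusion) / row_tot, NA_real_)
  list(method_tag = method_tag,
       frame_accuracy = mean(pred == truth),
       per_class_recall = as.numeric(recall),
       confusion = confusion,
       interruption_count = count_interruptions(pred, min_run))
}

#' Evaluate a decoded sequence against ground truth
#'
#' Frame (window-level) accuracy, per-class recall, the 4x4 confusion
#' matrix and the interruption count, for the raw classifier track and the
#' HMM-smoothed track side by side.
#'
#' @param decoded A [predict.har_pipeline()] result with truth labels.
#' @param min_run Interruption threshold in windows (default 3, about
#'   0.6 s at step 10 and 50 Hz).
#' @return List with elements `raw` and `smoothed`, each containing
#'   `frame_accuracy`, `per_class_recall`, `confusion`,
#'   `interruption_count`, `method_tag`.
#' @export
evaluate_decoded <- function(decoded, min_run = 3L) {
  if (!inherits(decoded, "har_decoded"))
    stop_invalid("`decoded` must come from predict() on a har_pipeline")
  if (is.null(decoded$truth_labels))
    stop_invalid("cannot evaluate: the decoded recording has no truth labels")
  list(raw = eval_report(decoded$raw_labels, decoded$truth_labels,
                         min_run, "bpnn"),
       smoothed = eval_report(decoded$smoothed_labels, decoded$truth_labels,
                              min_run, "bpnn+hmm"))
}

#' Generate, fit and score a synthetic benchmark end to end
#'
#' Generates the benchmark split from `config`, fits the pipeline on the
#' training recordings, decodes every test recording, and pools the
#' window-level results. With `sweep = TRUE` the fit/decode cycle is
#' repeated for feature subsets of 2, 4, 6, 8 and 10 statistics per
#' channel.
#'
#' @param config A [generator_config()].
#' @param sweep If `TRUE`, also return the feature-dimension sweep table.
#' @param min_run Interruption threshold (default 3 windows).
#' @inheritParams har_fit
#' @return Object of class `har_benchmark`: `summary` (one-row data frame
#'   with raw/smoothed accuracy and interruption counts), `per_class`
#'   (recall per activity and track), `reports` (per-recording
#'   [evaluate_decoded()] results), `pipeline`, and optionally `sweep`.
#' @export
run_benchmark <- function(config = generator_config(), window = window_spec(),
                          filter_width = 5L, hidden = 32L,
                          train = train_config(),
                          smoothing = c("viterbi", "posterior"),
                          emission = c("hard", "soft"),
                          n_stats = 10L, pseudocount = 1,
                          min_run = 3L, sweep = FALSE) {
  smoothing <- match.arg(smoothing)
  emission <- match.arg(emission)
  bench <- make_benchmark(config)
  score <- function(k) {
    pipe <- har_fit(bench$train, window = window, filter_width = filter_width,
                    hidden = hidden, train = train, smoothing = smoothing,
                    emission = emission, n_stats = k,
                    pseudocount = pseudocount)
    decoded <- lapply(bench$test, function(rec) predict(pipe, rec))
    reports <- lapply(decoded, evaluate_decoded, min_run = min_run)
    raw <- unlist(lapply(decoded, `[[`, "raw_labels"))
    smo <- unlist(lapply(decoded, `[[`, "smoothed_labels"))
    truth <- unlist(lapply(decoded, `[[`, "truth_labels"))
    list(pipe = pipe, decoded = decoded, reports = reports,
         raw_report = eval_report(raw, truth, min_run, "bpnn"),
         smoothed_report = eval_report(smo, truth, min_run, "bpnn+hmm"),
         n_windows = length(truth))
  }
  full <- score(n_stats)
  interruptions <- function(track) sum(vapply(
    full$reports, function(r) r[[track]]$interruption_count, 0L))
  summary <- data.frame(
    n_features = 6L * n_stats,
    n_test_windows = full$n_windows,
    raw_accuracy = full$raw_report$frame_accuracy,
    smoothed_accuracy = full$smoothed_report$frame_accuracy,
    raw_interruptions = interruptions("raw"),
    smoothed_interruptions = interruptions("smoothed")
  )
  per_class <- data.frame(
    activity = c("stationary", "walking", "running", "squat"),
    raw_recall = full$raw_report$per_class_recall,
    smoothed_recall = full$smoothed_report$per_class_recall
  )
  sweep_tab <- NULL
  if (sweep) {
    ks <- c(2L, 4L, 6L, 8L, 10L)
    rows <- lapply(ks, function(k) {
      r <- if (k == n_stats) full else score(k)
      data.frame(n_stats = k, n_features = 6L * k,
                 raw_accuracy = r$raw_report$frame_accuracy,
                 smoothed_accuracy = r$smoothed_report$frame_accuracy)
    })
    sweep_tab <- do.call(rbind, rows)
  }
  structure(list(summary = summary, per_class = per_class,
                 reports = full$reports, pipeline = full$pipe,
                 sweep = sweep_tab),
            class = "har_benchmark")
}

#' @export
print.har_benchmark <- function(x, ...) {
  cat("<har_benchmark>\n")
  s <- x$summary
  cat(sprintf("  test windows      : %d\n", s$n_test_windows))
  cat(sprintf("  raw accuracy      : %.4f  (%d interruptions)\n",
              s$raw_accuracy, s$raw_interruptions))
  cat(sprintf("  smoothed accuracy : %.4f  (%d interruptions)\n",
              s$smoothed_accuracy, s$smoothed_interruptions))
  cat("  per-class recall (raw / smoothed):\n")
  for (i in seq_len(nrow(x$per_class)))
    cat(sprintf("    %-10s %.4f / %.4f\n", x$per_class$activity[i],
                x$per_class$raw_recall[i], x$per_class$smoothed_recall[i]))
  if (!is.null(x$sweep)) {
    cat("  feature-dimension sweep:\n")
    print(x$sweep, row.names = FALSE)
  }
  invisible(x)
}

#' Serialize a fitted pipeline to JSON
#'
#' Stores the window spec, filter width, normalizer statistics, network
#' weights and HMM parameters at full precision, with a format-version
#' field; [load_pipeline()] restores an object whose decodes are
#' bit-identical.
#'
#' @param pipeline A fitted [har_fit()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_pipeline <- function(pipeline, path) {
  if (!inherits(pipeline, "har_pipeline"))
    stop_invalid("`pipeline` must be a fitted har_pipeline")
  net <- pipeline$network
  obj <- list(
    format = "actidecode-pipeline-1",
    window = list(length = pipeline$window$length, step = pipeline$window$step),
    filter_width = pipeline$filter_width,
    n_stats = pipeline$n_stats,
    smoothing = pipeline$smoothing,
    emission = pipeline$emission,
    pseudocount = pipeline$pseudocount,
    normalizer = list(center = pipeline$normalizer$center,
                      scale = pipeline$normalizer$scale,
                      constant = pipeline$normalizer$constant),
    network = list(layer_sizes = net$params$layer_sizes,
                   activation = net$params$activation,
                   weights = net$params$weights,
                   biases = net$params$biases,
                   classes = net$classes,
                   trace = net$trace),
    hmm = list(pi = pipeline$hmm$pi, A = pipeline$hmm$A, B = pipeline$hmm$B),
    fitted_on = pipeline$fitted_on
  )
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE), path)
  invisible(path)
}

#' Restore a pipeline saved with [save_pipeline()]
#'
#' @param path JSON file path.
#' @return A `har_pipeline` object.
#' @export
load_pipeline <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (is.null(obj$format) || obj$format != "actidecode-pipeline-1")
    stop_invalid("`", path, "` is not an actidecode pipeline file ",
                 "(missing or unknown format field)")
  normalizer <- structure(
    list(center = as.numeric(obj$normalizer$center),
         scale = as.numeric(obj$normalizer$scale),
         constant = as.logical(obj$normalizer$constant)),
    class = "feature_normalizer")
  params <- structure(
    list(layer_sizes = as.integer(obj$network$layer_sizes),
         weights = lapply(obj$network$weights, function(w)
           matrix(as.numeric(w), nrow = NROW(w))),
         biases = lapply(obj$network$biases, as.numeric),
         activation = obj$network$activation),
    class = "bpnn_params")
  net <- structure(list(params = params, trace = as.numeric(obj$network$trace),
                        classes = as.integer(obj$network$classes),
                        config = NULL),
                   class = "bpnn")
  structure(
    list(normalizer = normalizer, network = net,
         hmm = hmm_params(obj$hmm$pi, obj$hmm$A, obj$hmm$B),
         window = window_spec(obj$window$length, obj$window$step),
         filter_width = as.integer(obj$filter_width),
         n_stats = as.integer(obj$n_stats),
         smoothing = obj$smoothing, emission = obj$emission,
         pseudocount = obj$pseudocount,
         fitted_on = obj$fitted_on),
    class = "har_pipeline"
  )
}
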