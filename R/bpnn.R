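#' Training configuration for the backpropagation network
#'
#' @param learning_rate Gradient-descent step size (> 0).
#' @param epochs Number of passes over the training set.
#' @param batch_mode `"full_batch"` (the default; one averaged gradient step
#'   per epoch) or `"mini_batch"`.
#' @param batch_size Mini-batch size (ignored in full-batch mode).
#' @param seed Seed controlling initialization and mini-batch shuffling.
#' @param init_scale Half-width multiplier of the uniform weight
#'   initialization (see [bpnn_init()]).
#' @param early_stop_patience Optional integer: stop when the loss has not
#'   improved for this many consecutive epochs.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.1, epochs = 200L,
                         batch_mode = c("full_batch", "mini_batch"),
                         batch_size = 32L, seed = 1L, init_scale = 0.5,
                         early_stop_patience = NULL) {
  assert_scalar_number(learning_rate, "learning_rate", positive = TRUE)
  epochs <- assert_count(epochs, "epochs")
  batch_mode <- match.arg(batch_mode)
  batch_size <- assert_count(batch_size, "batch_size")
  seed <- assert_count(seed, "seed", min = 0L)
  assert_scalar_number(init_scale, "init_scale", nonneg = TRUE)
  if (!is.null(early_stop_patience))
    early_stop_patience <- assert_count(early_stop_patience, "early_stop_patience")
  structure(list(learning_rate = learning_rate, epochs = epochs,
                 batch_mode = batch_mode, batch_size = batch_size, seed = seed,
                 init_scale = init_scale,
                 early_stop_patience = early_stop_patience),
            class = "train_config")
}

activation_fun <- function(name) {
  switch(name,
         sigmoid = list(g = function(z) 1 / (1 + exp(-z)),
                        # derivative expressed through the activation value
                        gprime_a = function(a) a * (1 - a)),
         tanh = list(g = tanh, gprime_a = function(a) 1 - a * a),
         stop_invalid("unknown activation `", name, "`"))
}

#' Initialize network parameters
#'
#' Weights of layer l are drawn uniformly on
#' `[-init_scale/sqrt(n_{l-1}), +init_scale/sqrt(n_{l-1})]`; biases start
#' at zero.
#'
#' @param layer_sizes Integer vector of layer widths, input first
#'   (e.g. `c(60, 32, 4)`); at least two layers.
#' @param seed Optional seed for reproducible initialization.
#' @param init_scale Half-width multiplier (0 gives all-zero weights).
#' @param activation Hidden-layer activation, `"sigmoid"` (default) or
#'   `"tanh"`; the output layer is always sigmoid.
#' @return Object of class `bpnn_params` with `weights` (list of
#'   `n_l x n_{l-1}` matrices), `biases` (list of vectors), `layer_sizes`,
#'   `activation`.
#' @export
bpnn_init <- function(layer_sizes, seed = NULL, init_scale = 0.5,
                      activation = "sigmoid") {
  if (length(layer_sizes) < 2L || any(layer_sizes < 1L))
    stop_invalid("`layer_sizes` needs >= 2 layers of width >= 1")
  layer_sizes <- as.integer(layer_sizes)
  activation_fun(activation)  # validate
  if (!is.null(seed)) set.seed(seed)
  L <- length(layer_sizes) - 1L
  weights <- vector("list", L)
  biases <- vector("list", L)
  for (l in seq_len(L)) {
    n_in <- layer_sizes[l]
    n_out <- layer_sizes[l + 1L]
    lim <- init_scale / sqrt(n_in)
    weights[[l]] <- matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in)
    biases[[l]] <- rep(0, n_out)
  }
  structure(list(layer_sizes = layer_sizes, weights = weights, biases = biases,
                 activation = activation),
            class = "bpnn_params")
}

#' Forward pass for a single input
#'
#' Computes `z^(l) = w^(l) a^(l-1) + b^(l)`, `a^(l) = g(z^(l))` layer by
#' layer and returns all activations for reuse by [bpnn_backward()].
#'
#' @param params A [bpnn_init()] object.
#' @param x Numeric input vector of length `layer_sizes[1]`.
#' @return List with `a` (activations per layer, `a[[1]]` = input) and
#'   `z` (pre-activations, `z[[1]]` = NULL).
#' @export
bpnn_forward <- function(params, x) {
  if (!inherits(params, "bpnn_params")) stop_invalid("`params` must be bpnn_params")
  if (!is.numeric(x) || length(x) != params$layer_sizes[1L] || any(!is.finite(x)))
    stop_invalid("`x` must be a finite vector of length ", params$layer_sizes[1L])
  act <- activation_fun(params$activation)
  L <- length(params$weights)
  a <- vector("list", L + 1L)
  z <- vector("list", L + 1L)
  a[[1L]] <- as.numeric(x)
  for (l in seq_len(L)) {
    z[[l + 1L]] <- as.numeric(params$weights[[l]] %*% a[[l]] + params$biases[[l]])
    g <- if (l == L) activation_fun("sigmoid")$g else act$g
    a[[l + 1L]] <- g(z[[l + 1L]])
  }
  list(a = a, z = z)
}

# Vectorized forward over a matrix of inputs (rows = samples).
bpnn_forward_batch <- function(params, X) {
  act <- activation_fun(params$activation)
  L <- length(params$weights)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- tcrossprod(A[[l]], params$weights[[l]])
    Z <- sweep(Z, 2L, params$biases[[l]], "+")
    g <- if (l == L) activation_fun("sigmoid")$g else act$g
    A[[l + 1L]] <- g(Z)
  }
  A
}

#' Mean-squared-error loss
#'
#' `E = (1/(2n)) * sum_i ||y_i - yhat_i||^2`, the squared error summed over
#' all output units and averaged over samples (with the conventional 1/2).
#'
#' @param predictions n x K numeric matrix of network outputs.
#' @param targets n x K matrix of (one-hot) targets.
#' @return Scalar loss, >= 0, and 0 exactly when the matrices are equal.
#' @export
bpnn_loss <- function(predictions, targets) {
  predictions <- as.matrix(predictions)
  targets <- as.matrix(targets)
  if (!all(dim(predictions) == dim(targets)))
    stop_invalid("`predictions` and `targets` must have identical shapes")
  sum((targets - predictions)^2) / (2 * nrow(predictions))
}

#' Backpropagation gradients for a single sample
#'
#' Output-layer error `delta^(L) = (a^(L) - y) * g'(z^(L))` is propagated
#' backwards via `delta^(l) = (w^(l+1))' delta^(l+1) * g'(z^(l))`; the
#' gradients are `dE/dw^(l) = delta^(l) (a^(l-1))'` and
#' `dE/db^(l) = delta^(l)` (loss `E = (1/2)||y - a^(L)||^2` for one sample).
#'
#' @param params A [bpnn_init()] object.
#' @param forward The cached [bpnn_forward()] result for the same params.
#' @param y Target vector (length = output width).
#' @return List with `weights` and `biases` gradient lists mirroring the
#'   parameter shapes.
#' @export
bpnn_backward <- function(params, forward, y) {
  if (is.null(forward$a) || is.null(forward$z))
    stop_invalid("`forward` must be the cached result of bpnn_forward()")
  L <- length(params$weights)
  K <- params$layer_sizes[length(params$layer_sizes)]
  if (length(y) != K) stop_invalid("`y` must have length ", K)
  act <- activation_fun(params$activation)
  gw <- vector("list", L)
  gb <- vector("list", L)
  aL <- forward$a[[L + 1L]]
  delta <- (aL - y) * activation_fun("sigmoid")$gprime_a(aL)
  for (l in rev(seq_len(L))) {
    gw[[l]] <- delta %o% forward$a[[l]]
    gb[[l]] <- delta
    if (l > 1L)
      delta <- as.numeric(crossprod(params$weights[[l]], delta)) *
        act$gprime_a(forward$a[[l]])
  }
  list(weights = gw, biases = gb)
}

# Batch gradients: average of per-sample gradients (matches the 1/(2n) loss).
bpnn_backward_batch <- function(params, A, Y) {
  act <- activation_fun(params$activation)
  L <- length(params$weights)
  n <- nrow(Y)
  gw <- vector("list", L)
  gb <- vector("list", L)
  AL <- A[[L + 1L]]
  delta <- (AL - Y) * activation_fun("sigmoid")$gprime_a(AL) / n
  for (l in rev(seq_len(L))) {
    gw[[l]] <- crossprod(delta, A[[l]])
    gb[[l]] <- colSums(delta)
    if (l > 1L)
      delta <- (delta %*% params$weights[[l]]) * act$gprime_a(A[[l]])
  }
  list(weights = gw, biases = gb)
}

#' Gradient-descent parameter update
#'
#' `w <- w - alpha * dE/dw`, `b <- b - alpha * dE/db` for every layer.
#'
#' @param params A [bpnn_init()] object.
#' @param gradients Gradient list from [bpnn_backward()].
#' @param alpha Learning rate (> 0).
#' @return Updated `bpnn_params`.
#' @export
bpnn_update <- function(params, gradients, alpha) {
  assert_scalar_number(alpha, "alpha", positive = TRUE)
  for (l in seq_along(params$weights)) {
    if (any(!is.finite(gradients$weights[[l]])) ||
        any(!is.finite(gradients$biases[[l]])))
      stop_invalid("non-finite gradients in layer ", l,
                   "; training likely diverged — try a smaller learning rate")
    params$weights[[l]] <- params$weights[[l]] - alpha * gradients$weights[[l]]
    params$biases[[l]] <- params$biases[[l]] - alpha * gradients$biases[[l]]
  }
  params
}

#' Train a backpropagation network classifier
#'
#' Plain gradient descent on the mean-squared error between sigmoid outputs
#' and one-hot targets. Full-batch mode takes one averaged gradient step per
#' epoch; mini-batch mode shuffles each epoch under the configured seed.
#'
#' @param x Numeric feature matrix (rows = samples), typically standardized.
#' @param y Integer class labels (any set of codes; `0:3` in the activity
#'   pipeline).
#' @param hidden Integer vector of hidden-layer widths (default 32).
#' @param config A [train_config()].
#' @param classes Optional explicit class codes (defaults to
#'   `sort(unique(y))`).
#' @return Object of class `bpnn`: `params`, `trace` (per-epoch loss),
#'   `classes`, `config`.
#' @export
bpnn_train <- function(x, y, hidden = 32L, config = train_config(),
                       classes = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop_invalid("empty training set")
  if (length(y) != nrow(x)) stop_invalid("`y` must have one label per row of `x`")
  classes <- classes %||% sort(unique(as.integer(y)))
  K <- length(classes)
  if (K < 2L) stop_invalid("need at least two classes")
  idx <- match(as.integer(y), classes)
  if (any(is.na(idx))) stop_invalid("`y` contains labels outside `classes`")
  Y <- matrix(0, nrow(x), K)
  Y[cbind(seq_len(nrow(x)), idx)] <- 1
  layer_sizes <- c(ncol(x), as.integer(hidden), K)
  params <- bpnn_init(layer_sizes, seed = config$seed,
                      init_scale = config$init_scale)
  alpha <- config$learning_rate
  trace <- numeric(config$epochs)
  best <- Inf
  stall <- 0L
  n <- nrow(x)
  for (ep in seq_len(config$epochs)) {
    if (config$batch_mode == "full_batch") {
      A <- bpnn_forward_batch(params, x)
      trace[ep] <- bpnn_loss(A[[length(A)]], Y)
      grads <- bpnn_backward_batch(params, A, Y)
      params <- bpnn_update(params, grads, alpha)
    } else {
      ord <- sample.int(n)
      for (start in seq.int(1L, n, by = config$batch_size)) {
        rows <- ord[start:min(start + config$batch_size - 1L, n)]
        A <- bpnn_forward_batch(params, x[rows, , drop = FALSE])
        grads <- bpnn_backward_batch(params, A, Y[rows, , drop = FALSE])
        params <- bpnn_update(params, grads, alpha)
      }
      A <- bpnn_forward_batch(params, x)
      trace[ep] <- bpnn_loss(A[[length(A)]], Y)
    }
    if (!is.finite(trace[ep]))
      stop_invalid("non-finite training loss at epoch ", ep,
                   "; try a smaller learning_rate")
    if (!is.null(config$early_stop_patience)) {
      if (trace[ep] < best - 1e-12) {
        best <- trace[ep]
        stall <- 0L
      } else stall <- stall + 1L
      if (stall >= config$early_stop_patience) {
        trace <- trace[seq_len(ep)]
        break
      }
    }
  }
  structure(list(params = params, trace = trace, classes = classes,
                 config = config),
            class = "bpnn")
}

#' @export
print.bpnn <- function(x, ...) {
  cat("<bpnn> layers ", paste(x$params$layer_sizes, collapse = "-"),
      ", ", x$params$activation, " hidden units, ",
      length(x$trace), " epochs, final loss ",
      format(x$trace[length(x$trace)], digits = 6), "\n", sep = "")
  invisible(x)
}

#' Per-epoch training-loss curve
#' @param x A fitted [bpnn_train()] object.
#' @param ... Passed to [plot()].
#' @export
plot.bpnn <- function(x, ...) {
  plot(seq_along(x$trace), x$trace, type = "l", xlab = "epoch",
       ylab = "MSE loss", main = "BPNN training loss", ...)
  invisible(x)
}

#' Predict window classes
#'
#' Labels are the argmax of the output activations (ties go to the lowest
#' class index); scores are the activations renormalized to sum to one per
#' row, the pseudo-posteriors consumed by the HMM stage.
#'
#' @param object A fitted [bpnn_train()] object.
#' @param newdata Feature matrix with the training feature width, normalized
#'   with the training normalizer.
#' @param ... Unused.
#' @return List with `labels` (class codes) and `scores` (rows sum to 1).
#' @export
predict.bpnn <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$params$layer_sizes[1L])
    stop_invalid("`newdata` has ", ncol(newdata), " features; the network ",
                 "expects ", object$params$layer_sizes[1L])
  A <- bpnn_forward_batch(object$params, newdata)
  out <- A[[length(A)]]
  rs <- rowSums(out)
  scores <- out / ifelse(rs > 0, rs, 1)
  scores[rs == 0, ] <- 1 / ncol(out)
  list(labels = object$classes[max.col(out, ties.method = "first")],
       scores = scores)
}
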