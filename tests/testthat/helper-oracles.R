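# Independent oracles and small fixture builders shared across test files.

# Exhaustive path-enumeration oracle for a discrete HMM: total likelihood,
# state posteriors and the single best path, by summing/maximizing over all
# N^T hidden-state paths. Tractable only for tiny fixtures, which is the
# point: it shares no code with the package's recursions.
enum_hmm <- function(pi, A, B, obs) {
  N <- length(pi)
  T <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), T)))
  probs <- apply(paths, 1L, function(s) {
    p <- pi[s[1L]] * B[s[1L], obs[1L]]
    if (T > 1L) for (t in 2:T) p <- p * A[s[t - 1L], s[t]] * B[s[t], obs[t]]
    p
  })
  total <- sum(probs)
  gamma <- matrix(0, T, N)
  for (t in seq_len(T)) for (i in seq_len(N))
    gamma[t, i] <- sum(probs[paths[, t] == i]) / total
  best <- which.max(probs)
  list(likelihood = total,
       gamma = gamma,
       best_path = as.integer(paths[best, ]),
       best_prob = probs[best])
}

# Probability of one explicit state path (enumeration-style product).
hmm_path_prob <- function(pi, A, B, obs, s) {
  p <- pi[s[1L]] * B[s[1L], obs[1L]]
  if (length(obs) > 1L) for (t in 2:length(obs))
    p <- p * A[s[t - 1L], s[t]] * B[s[t], obs[t]]
  p
}

random_hmm_fixture <- function(N, M) {
  rdirich <- function(n) {
    x <- matrix(stats::rexp(n * 1L), 1L, n)
    as.numeric(x / sum(x))
  }
  rstoch <- function(r, c) {
    m <- matrix(stats::rexp(r * c) + 0.05, r, c)
    m / rowSums(m)
  }
  hmm_params(rdirich(N), rstoch(N, N), rstoch(N, M))
}

# Central finite differences of the single-sample MSE loss with respect to
# every weight and bias, via repeated forward passes.
numeric_bpnn_grads <- function(params, x, y, h = 1e-5) {
  loss_at <- function(p) {
    out <- bpnn_forward(p, x)$a
    bpnn_loss(matrix(out[[length(out)]], 1L), matrix(y, 1L))
  }
  gw <- params$weights
  gb <- params$biases
  for (l in seq_along(params$weights)) {
    for (k in seq_along(params$weights[[l]])) {
      p1 <- params; p1$weights[[l]][k] <- p1$weights[[l]][k] + h
      p2 <- params; p2$weights[[l]][k] <- p2$weights[[l]][k] - h
      gw[[l]][k] <- (loss_at(p1) - loss_at(p2)) / (2 * h)
    }
    for (k in seq_along(params$biases[[l]])) {
      p1 <- params; p1$biases[[l]][k] <- p1$biases[[l]][k] + h
      p2 <- params; p2$biases[[l]][k] <- p2$biases[[l]][k] - h
      gb[[l]][k] <- (loss_at(p1) - loss_at(p2)) / (2 * h)
    }
  }
  list(weights = gw, biases = gb)
}

max_rel_grad_err <- function(analytic, numeric) {
  err <- 0
  for (l in seq_along(analytic$weights)) {
    for (part in c("weights", "biases")) {
      a <- analytic[[part]][[l]]
      n <- numeric[[part]][[l]]
      err <- max(err, abs(a - n) / pmax(abs(n), 1e-4))
    }
  }
  err
}

# A recording with hand-chosen samples (constant per channel) and labels.
constant_recording <- function(T, value = 0, labels = NULL, rate = 50) {
  imu_recording(matrix(value, T, 6L), rate, labels = labels)
}

# Small two-feature, two-class linearly separable training set.
separable_toy <- function(n_per_class = 10L, gap = 2, seed = 42L) {
  set.seed(seed)
  x <- rbind(
    cbind(stats::rnorm(n_per_class, -gap, 0.3), stats::rnorm(n_per_class, -gap, 0.3)),
    cbind(stats::rnorm(n_per_class, gap, 0.3), stats::rnorm(n_per_class, gap, 0.3))
  )
  list(x = x, y = rep(c(0L, 1L), each = n_per_class))
}

elevated_noise_config <- function(seed) {
  generator_config(n_sequences = 8L, sequence_length_s = 40,
                   seed = seed, noise_scale = 5)
}

benchmark_train_config <- function(seed = 1L) {
  train_config(learning_rate = 0.5, epochs = 1500L, seed = seed)
}
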