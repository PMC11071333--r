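#' Discrete hidden Markov model parameters
#'
#' A first-order HMM over `N` hidden states emitting one of `M` discrete
#' symbols per step: initial distribution `pi`, row-stochastic transition
#' matrix `A` (`A[i, j] = P(next = j | current = i)`) and emission matrix
#' `B` (`B[i, o] = P(observe o | state i)`). States and symbols are indexed
#' `1..N` and `1..M`.
#'
#' @param pi Length-N initial state probability vector.
#' @param A N x N transition matrix, rows summing to 1.
#' @param B N x M emission matrix, rows summing to 1.
#' @return Object of class `hmm_params`.
#' @export
hmm_params <- function(pi, A, B) {
  A <- check_stochastic(as.matrix(A), "A")
  B <- check_stochastic(as.matrix(B), "B")
  pi <- check_prob_vector(pi, "pi")
  if (length(pi) != nrow(A) || nrow(A) != ncol(A) || nrow(B) != nrow(A))
    stop_invalid("inconsistent dimensions: need length(pi) = nrow(A) = ncol(A) = nrow(B)")
  structure(list(pi = pi, A = A, B = B,
                 n_states = nrow(A), n_symbols = ncol(B)),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("<hmm_params> ", x$n_states, " states, ", x$n_symbols, " symbols\n",
      sep = "")
  cat("pi:", format(x$pi, digits = 4), "\n")
  cat("A:\n"); print(round(x$A, 4))
  cat("B:\n"); print(round(x$B, 4))
  invisible(x)
}

check_obs <- function(obs, M) {
  obs <- as.integer(obs)
  if (length(obs) < 1L || any(is.na(obs)) || any(obs < 1L) || any(obs > M))
    stop_invalid("observations must be integers in 1..", M)
  obs
}

# Core scaled recursions operate on an explicit T x N per-step emission
# likelihood matrix so the pipeline can substitute soft (classifier-score)
# emissions for the B-column lookups.
hmm_forward_lik <- function(pi, A, lik) {
  T <- nrow(lik)
  N <- ncol(lik)
  alpha <- matrix(0, T, N)
  scale <- numeric(T)
  a <- pi * lik[1L, ]
  scale[1L] <- sum(a)
  if (scale[1L] == 0)
    return(list(log_lik = -Inf, alpha = alpha, scale = scale, zero_prob = TRUE))
  alpha[1L, ] <- a / scale[1L]
  if (T > 1L) for (t in 2:T) {
    a <- as.numeric(alpha[t - 1L, ] %*% A) * lik[t, ]
    scale[t] <- sum(a)
    if (scale[t] == 0)
      return(list(log_lik = -Inf, alpha = alpha, scale = scale, zero_prob = TRUE))
    alpha[t, ] <- a / scale[t]
  }
  list(log_lik = sum(log(scale)), alpha = alpha, scale = scale,
       zero_prob = FALSE)
}

hmm_backward_lik <- function(pi, A, lik, scale) {
  T <- nrow(lik)
  N <- ncol(lik)
  beta <- matrix(0, T, N)
  beta[T, ] <- 1
  if (T > 1L) for (t in (T - 1L):1L)
    beta[t, ] <- as.numeric(A %*% (lik[t + 1L, ] * beta[t + 1L, ])) /
      scale[t + 1L]
  # log-likelihood recomputed through the beta recursion (consistency check)
  ll_beta <- log(sum(pi * lik[1L, ] * beta[1L, ])) +
    if (T > 1L) sum(log(scale[2:T])) else 0
  list(beta = beta, log_lik_beta = ll_beta)
}

#' HMM forward algorithm (scaled)
#'
#' Computes `alpha_t(i) = P(o_1..o_t, q_t = i | lambda)` with per-step
#' scaling (each row of the returned `alpha` is normalized; the scaling
#' factors multiply back to the likelihood), and
#' `log P(O | lambda) = sum_t log(scale_t)`.
#'
#' An observation sequence of probability zero is a value, not an error:
#' the result carries `log_lik = -Inf` and `zero_prob = TRUE`.
#'
#' @param params An [hmm_params()] object.
#' @param obs Integer symbol sequence in `1..M`.
#' @return List with `log_lik`, `alpha` (T x N, scaled), `scale` (length T),
#'   `zero_prob`.
#' @export
hmm_forward <- function(params, obs) {
  if (!inherits(params, "hmm_params")) stop_invalid("`params` must be hmm_params")
  obs <- check_obs(obs, params$n_symbols)
  hmm_forward_lik(params$pi, params$A, params$B[, obs, drop = FALSE] |> t())
}

#' HMM backward algorithm (scaled)
#'
#' `beta_T(i) = 1`; `beta_t(i) = sum_j A[i,j] B[j, o_{t+1}] beta_{t+1}(j)`,
#' scaled with the forward pass's factors so that
#' `sum_i alpha_t(i) beta_t(i) = 1` at every step.
#'
#' @inheritParams hmm_forward
#' @return List with `beta` (T x N, scaled), `scale`, `log_lik`, and
#'   `log_lik_beta` (the likelihood reconstructed through the beta
#'   recursion).
#' @export
hmm_backward <- function(params, obs) {
  if (!inherits(params, "hmm_params")) stop_invalid("`params` must be hmm_params")
  obs <- check_obs(obs, params$n_symbols)
  lik <- t(params$B[, obs, drop = FALSE])
  fwd <- hmm_forward_lik(params$pi, params$A, lik)
  if (fwd$zero_prob)
    return(list(beta = matrix(NA_real_, length(obs), params$n_states),
                scale = fwd$scale, log_lik = -Inf, log_lik_beta = -Inf,
                zero_prob = TRUE))
  bwd <- hmm_backward_lik(params$pi, params$A, lik, fwd$scale)
  list(beta = bwd$beta, scale = fwd$scale, log_lik = fwd$log_lik,
       log_lik_beta = bwd$log_lik_beta, zero_prob = FALSE)
}

posteriors_lik <- function(pi, A, lik) {
  T <- nrow(lik)
  N <- ncol(lik)
  fwd <- hmm_forward_lik(pi, A, lik)
  if (fwd$zero_prob)
    return(list(gamma = matrix(NA_real_, T, N), xi = NULL,
                log_lik = -Inf, zero_prob = TRUE, alpha = fwd$alpha,
                beta = NULL, scale = fwd$scale))
  bwd <- hmm_backward_lik(pi, A, lik, fwd$scale)
  gamma <- fwd$alpha * bwd$beta
  gamma <- gamma / rowSums(gamma)
  xi <- NULL
  if (T > 1L) {
    xi <- array(0, c(T - 1L, N, N))
    for (t in seq_len(T - 1L)) {
      m <- (fwd$alpha[t, ] %o% (lik[t + 1L, ] * bwd$beta[t + 1L, ])) * A /
        fwd$scale[t + 1L]
      xi[t, , ] <- m / sum(m)
    }
  }
  list(gamma = gamma, xi = xi, log_lik = fwd$log_lik, zero_prob = FALSE,
       alpha = fwd$alpha, beta = bwd$beta, scale = fwd$scale)
}

#' State posteriors from the forward-backward algorithm
#'
#' `gamma_t(i) = P(q_t = i | O, lambda)` and
#' `xi_t(i, j) = P(q_t = i, q_{t+1} = j | O, lambda)`, the E-step quantities
#' of Baum-Welch.
#'
#' @inheritParams hmm_forward
#' @return List with `gamma` (T x N, rows sum to 1), `xi`
#'   ((T-1) x N x N array, each slice sums to 1; `NULL` for T = 1),
#'   `log_lik`, `zero_prob`.
#' @export
hmm_posteriors <- function(params, obs) {
  if (!inherits(params, "hmm_params")) stop_invalid("`params` must be hmm_params")
  obs <- check_obs(obs, params$n_symbols)
  res <- posteriors_lik(params$pi, params$A, t(params$B[, obs, drop = FALSE]))
  res[c("gamma", "xi", "log_lik", "zero_prob")]
}

viterbi_lik <- function(pi, A, lik) {
  T <- nrow(lik)
  N <- ncol(lik)
  logA <- log(A)
  logL <- log(lik)
  delta <- matrix(-Inf, T, N)
  psi <- matrix(1L, T, N)
  delta[1L, ] <- log(pi) + logL[1L, ]
  if (T > 1L) for (t in 2:T) for (j in seq_len(N)) {
    cand <- delta[t - 1L, ] + logA[, j]
    psi[t, j] <- which.max(cand)       # first max = lowest state index
    delta[t, j] <- cand[psi[t, j]] + logL[t, j]
  }
  path <- integer(T)
  path[T] <- which.max(delta[T, ])
  log_prob <- delta[T, path[T]]
  if (T > 1L) for (t in (T - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  list(path = path, log_prob = log_prob,
       zero_prob = !is.finite(log_prob))
}

#' Viterbi decoding
#'
#' Most probable hidden-state path in log space; ties at each backtracking
#' step break toward the lower state index. The path log-probability never
#' exceeds the total sequence log-likelihood.
#'
#' @inheritParams hmm_forward
#' @return List with `path` (states in `1..N`), `log_prob`, `zero_prob`.
#' @export
hmm_viterbi <- function(params, obs) {
  if (!inherits(params, "hmm_params")) stop_invalid("`params` must be hmm_params")
  obs <- check_obs(obs, params$n_symbols)
  viterbi_lik(params$pi, params$A, t(params$B[, obs, drop = FALSE]))
}

#' Simulate state and observation sequences from an HMM
#'
#' @param object An [hmm_params()] object.
#' @param nsim Sequence length.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return List with integer vectors `states` and `obs`, both in `1..`.
#' @export
simulate.hmm_params <- function(object, nsim = 1L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  nsim <- assert_count(nsim, "nsim")
  states <- integer(nsim)
  obs <- integer(nsim)
  states[1L] <- sample.int(object$n_states, 1L, prob = object$pi)
  for (t in seq_len(nsim)) {
    if (t > 1L)
      states[t] <- sample.int(object$n_states, 1L,
                              prob = object$A[states[t - 1L], ])
    obs[t] <- sample.int(object$n_symbols, 1L, prob = object$B[states[t], ])
  }
  list(states = states, obs = obs)
}

#' @export
logLik.hmm_params <- function(object, obs, ...) {
  ll <- if (is.list(obs)) sum(vapply(obs, function(o) hmm_forward(object, o)$log_lik, 0))
        else hmm_forward(object, obs)$log_lik
  structure(ll, class = "logLik", df = with(object,
    (n_states - 1) + n_states * (n_states - 1) + n_states * (n_symbols - 1)))
}

random_stochastic <- function(n, m) {
  x <- matrix(stats::runif(n * m, 0.5, 1.5), n, m)
  x / rowSums(x)
}

#' Baum-Welch (EM) estimation of HMM parameters
#'
#' Expectation step via [hmm_posteriors()] on every sequence; maximization
#' step re-estimates `pi` from the time-1 posteriors, `A` from summed
#' pairwise posteriors and `B` from symbol-weighted state posteriors.
#' The total log-likelihood is non-decreasing across iterations.
#'
#' @param sequences List of integer symbol sequences (or one vector).
#' @param n_states Number of hidden states.
#' @param n_symbols Symbol alphabet size.
#' @param init Optional [hmm_params()] starting point; by default a seeded
#'   random stochastic initialization is used.
#' @param seed Seed for the random initialization.
#' @param max_iter Iteration cap.
#' @param tol Convergence threshold on the log-likelihood improvement.
#' @param n_restarts Number of random initializations when `init` is not
#'   given (seeds `seed, seed + 1, ...`); the run with the best final
#'   log-likelihood is returned. EM only finds local optima, so a handful
#'   of restarts is the standard guard against degenerate solutions.
#' @return List with `params` (fitted [hmm_params()]) and `log_lik`
#'   (per-iteration total log-likelihood of the returned run).
#' @export
hmm_baum_welch <- function(sequences, n_states, n_symbols, init = NULL,
                           seed = 1L, max_iter = 100L, tol = 1e-6,
                           n_restarts = 1L) {
  if (!is.list(sequences)) sequences <- list(sequences)
  if (!length(sequences)) stop_invalid("`sequences` must be non-empty")
  n_states <- assert_count(n_states, "n_states")
  n_symbols <- assert_count(n_symbols, "n_symbols")
  n_restarts <- assert_count(n_restarts, "n_restarts")
  sequences <- lapply(sequences, check_obs, n_symbols)
  if (is.null(init) && n_restarts > 1L) {
    runs <- lapply(seq_len(n_restarts) - 1L, function(k)
      hmm_baum_welch(sequences, n_states, n_symbols, init = NULL,
                     seed = seed + k, max_iter = max_iter, tol = tol,
                     n_restarts = 1L))
    finals <- vapply(runs, function(r) r$log_lik[length(r$log_lik)], 0)
    return(runs[[which.max(finals)]])
  }
  if (is.null(init)) {
    set.seed(seed)
    init <- hmm_params(rep(1 / n_states, n_states),
                       random_stochastic(n_states, n_states),
                       random_stochastic(n_states, n_symbols))
  }
  if (init$n_states != n_states || init$n_symbols != n_symbols)
    stop_invalid("`init` dimensions do not match n_states/n_symbols")
  par <- init
  ll_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    pi_acc <- numeric(n_states)
    A_num <- matrix(0, n_states, n_states)
    B_num <- matrix(0, n_states, n_symbols)
    total_ll <- 0
    for (obs in sequences) {
      post <- posteriors_lik(par$pi, par$A, t(par$B[, obs, drop = FALSE]))
      if (post$zero_prob)
        stop_invalid("a training sequence has zero probability under the ",
                     "current parameters; smooth the initialization")
      total_ll <- total_ll + post$log_lik
      pi_acc <- pi_acc + post$gamma[1L, ]
      if (!is.null(post$xi)) A_num <- A_num + apply(post$xi, c(2L, 3L), sum)
      for (k in seq_len(n_symbols)) {
        rows <- obs == k
        if (any(rows))
          B_num[, k] <- B_num[, k] + colSums(post$gamma[rows, , drop = FALSE])
      }
    }
    ll_trace <- c(ll_trace, total_ll)
    # M step with starvation guard: unvisited states fall back to uniform
    new_pi <- pi_acc / sum(pi_acc)
    fix_rows <- function(m, what) {
      rs <- rowSums(m)
      starved <- rs == 0
      if (any(starved)) {
        warning("state(s) ", paste(which(starved), collapse = ", "),
                " starved of occupancy; resetting ", what, " row(s) to uniform",
                call. = FALSE)
        m[starved, ] <- 1
        rs[starved] <- ncol(m)
      }
      m / rs
    }
    par <- hmm_params(new_pi, fix_rows(A_num, "transition"),
                      fix_rows(B_num, "emission"))
    if (iter > 1L &&
        abs(ll_trace[iter] - ll_trace[iter - 1L]) < tol) break
  }
  list(params = par, log_lik = ll_trace)
}

#' Supervised estimation of initial and transition probabilities
#'
#' Counts first symbols (for `pi`) and bigrams (for `A`) across labeled
#' state sequences, with additive smoothing. Rows with no observed
#' transitions and zero pseudocount fall back to uniform with a warning.
#'
#' @param label_sequences List of integer state sequences in `1..n_states`
#'   (or one vector).
#' @param n_states Number of states.
#' @param pseudocount Additive smoothing constant (>= 0).
#' @return List with `pi` and `A`.
#' @export
hmm_estimate_supervised <- function(label_sequences, n_states,
                                    pseudocount = 0) {
  if (!is.list(label_sequences)) label_sequences <- list(label_sequences)
  if (!length(label_sequences)) stop_invalid("`label_sequences` must be non-empty")
  n_states <- assert_count(n_states, "n_states")
  assert_scalar_number(pseudocount, "pseudocount", nonneg = TRUE)
  label_sequences <- lapply(label_sequences, check_obs, n_states)
  pi_counts <- rep(pseudocount, n_states)
  A_counts <- matrix(pseudocount, n_states, n_states)
  for (s in label_sequences) {
    pi_counts[s[1L]] <- pi_counts[s[1L]] + 1
    if (length(s) > 1L)
      for (t in seq_len(length(s) - 1L))
        A_counts[s[t], s[t + 1L]] <- A_counts[s[t], s[t + 1L]] + 1
  }
  rs <- rowSums(A_counts)
  if (any(rs == 0)) {
    warning("state(s) ", paste(which(rs == 0), collapse = ", "),
            " never observed as transition source; using uniform row(s)",
            call. = FALSE)
    A_counts[rs == 0, ] <- 1
    rs[rs == 0] <- n_states
  }
  if (sum(pi_counts) == 0) pi_counts <- rep(1, n_states)
  list(pi = pi_counts / sum(pi_counts), A = A_counts / rs)
}

#' Emission matrix from a labeled confusion table
#'
#' When the HMM observes a frame classifier's predicted labels, the emission
#' distribution of true state i is exactly the classifier's confusion row:
#' `B[i, o] = (count(true = i, pred = o) + pseudocount) /
#' (count(true = i) + n_symbols * pseudocount)`.
#'
#' @param true_labels Integer vector of true states in `1..n_states`.
#' @param predicted_labels Equal-length vector of predicted symbols in
#'   `1..n_symbols`.
#' @param n_states Number of states.
#' @param n_symbols Symbol alphabet size (default `n_states`).
#' @param pseudocount Additive smoothing (default 1 keeps every row strictly
#'   positive).
#' @return N x M row-stochastic emission matrix.
#' @export
hmm_emission_from_confusion <- function(true_labels, predicted_labels,
                                        n_states, n_symbols = n_states,
                                        pseudocount = 1) {
  if (length(true_labels) != length(predicted_labels))
    stop_invalid("`true_labels` and `predicted_labels` must have equal length")
  n_states <- assert_count(n_states, "n_states")
  n_symbols <- assert_count(n_symbols, "n_symbols")
  assert_scalar_number(pseudocount, "pseudocount", nonneg = TRUE)
  true_labels <- check_obs(true_labels, n_states)
  predicted_labels <- check_obs(predicted_labels, n_symbols)
  counts <- matrix(0, n_states, n_symbols)
  for (t in seq_along(true_labels))
    counts[true_labels[t], predicted_labels[t]] <-
      counts[true_labels[t], predicted_labels[t]] + 1
  row_tot <- rowSums(counts)
  if (pseudocount == 0 && any(row_tot == 0))
    stop_invalid("true class(es) ", paste(which(row_tot == 0), collapse = ", "),
                 " absent and pseudocount is 0; emission row undefined")
  (counts + pseudocount) / (row_tot + n_symbols * pseudocount)
}

#' Serialize HMM parameters to JSON
#' @param params An [hmm_params()] object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
hmm_to_json <- function(params, path = NULL) {
  if (!inherits(params, "hmm_params")) stop_invalid("`params` must be hmm_params")
  obj <- list(format = "actidecode-hmm-1", pi = params$pi,
              A = params$A, B = params$B)
  js <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Deserialize HMM parameters from JSON
#' @param input File path or JSON string produced by [hmm_to_json()].
#' @return An [hmm_params()] object.
#' @export
hmm_from_json <- function(input) {
  obj <- jsonlite::fromJSON(input)
  if (is.null(obj$format) || obj$format != "actidecode-hmm-1")
    stop_invalid("not an actidecode HMM file (missing/unknown format field)")
  hmm_params(obj$pi, obj$A, obj$B)
}
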