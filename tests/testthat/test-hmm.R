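test_that("parameter validation enforces stochasticity", {
  expect_error(hmm_params(c(0.5, 0.6), diag(2), diag(2)), "pi")
  expect_error(hmm_params(c(0.5, 0.5),
                          matrix(c(0.9, 0.2, 0.2, 0.8), 2, byrow = TRUE),
                          diag(2)),
               "A")
  expect_error(hmm_params(c(0.5, 0.5), matrix(c(0, 0, 0.5, 0.5), 2,
                                              byrow = TRUE), diag(2)),
               "zeros")
  p <- hmm_params(c(0.5, 0.5), matrix(0.5, 2, 2), matrix(0.5, 2, 2))
  expect_equal(rowSums(p$A), c(1, 1), tolerance = 1e-12)
})

test_that("single-state likelihood is the product of emissions", {
  B <- matrix(c(0.2, 0.3, 0.5), 1)
  p <- hmm_params(1, matrix(1, 1, 1), B)
  obs <- c(1, 3, 3, 2)
  f <- hmm_forward(p, obs)
  expect_equal(f$log_lik, sum(log(B[1, obs])), tolerance = 1e-12)
  b <- hmm_backward(p, obs)
  # beta_t (unscaled) = prod_{s>t} b(o_s); verify at t = 1
  unscaled_beta1 <- b$beta[1, 1] * prod(f$scale[2:4])
  expect_equal(unscaled_beta1, prod(B[1, obs[2:4]]), tolerance = 1e-12)
})

test_that("deterministic identity chain gives probability one", {
  p <- hmm_params(c(1, 0), diag(2), diag(2))
  expect_equal(hmm_forward(p, c(1, 1, 1))$log_lik, 0)
  v <- hmm_viterbi(p, c(1, 1, 1))
  expect_equal(v$path, c(1L, 1L, 1L))
  expect_equal(v$log_prob, 0)
  # an impossible observation has zero probability, flagged not thrown
  f0 <- hmm_forward(p, c(2, 1))
  expect_true(f0$zero_prob)
  expect_equal(f0$log_lik, -Inf)
})

test_that("forward, posteriors and viterbi match exhaustive enumeration", {
  set.seed(21)
  for (i in 1:40) {
    N <- sample(2:3, 1)
    M <- sample(2:3, 1)
    T <- sample(2:6, 1)
    p <- random_hmm_fixture(N, M)
    obs <- sample.int(M, T, replace = TRUE)
    oracle <- enum_hmm(p$pi, p$A, p$B, obs)
    f <- hmm_forward(p, obs)
    expect_equal(f$log_lik, log(oracle$likelihood), tolerance = 1e-10)
    post <- hmm_posteriors(p, obs)
    expect_equal(post$gamma, oracle$gamma, tolerance = 1e-10)
    v <- hmm_viterbi(p, obs)
    # the decoded path must attain the enumerated maximum (paths may tie
    # to within floating-point rounding, so compare probabilities)
    expect_gte(hmm_path_prob(p$pi, p$A, p$B, obs, v$path),
               oracle$best_prob * (1 - 1e-9))
    expect_equal(v$log_prob, log(oracle$best_prob), tolerance = 1e-10)
    # path probability can never exceed the total sequence probability
    expect_lte(v$log_prob, f$log_lik + 1e-12)
  }
})

test_that("scaled backward pass satisfies the consistency identities", {
  set.seed(22)
  for (i in 1:10) {
    p <- random_hmm_fixture(3, 3)
    obs <- sample.int(3, 8, replace = TRUE)
    f <- hmm_forward(p, obs)
    b <- hmm_backward(p, obs)
    expect_equal(b$beta[8, ], rep(1, 3))
    # sum_i alphahat_t(i) betahat_t(i) = 1 at every t under joint scaling,
    # i.e. sum_i alpha_t(i) beta_t(i) = P(O | lambda) unscaled
    expect_equal(rowSums(f$alpha * b$beta), rep(1, 8), tolerance = 1e-10)
    expect_equal(b$log_lik_beta, f$log_lik, tolerance = 1e-8)
  }
})

test_that("posteriors are one-hot under an identity-emission chain", {
  p <- hmm_params(c(0.5, 0.5), matrix(0.5, 2, 2), diag(2))
  obs <- c(1, 2, 2, 1)
  g <- hmm_posteriors(p, obs)$gamma
  expect_equal(g, diag(2)[obs, ], tolerance = 1e-12)
})

test_that("a fully symmetric model decodes to all-ones by the tie rule", {
  p <- hmm_params(c(0.5, 0.5), matrix(0.5, 2, 2), matrix(0.5, 2, 2))
  expect_equal(hmm_viterbi(p, c(1, 2, 1, 2))$path, rep(1L, 4))
})

test_that("Baum-Welch log-likelihood never decreases", {
  set.seed(23)
  truth <- hmm_params(c(0.7, 0.3),
                      matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE),
                      matrix(c(0.8, 0.1, 0.1, 0.1, 0.1, 0.8), 2, byrow = TRUE))
  sims <- lapply(1:3, function(i) simulate(truth, nsim = 150L, seed = 23 + i)$obs)
  fit <- hmm_baum_welch(sims, 2, 3, seed = 5, max_iter = 40)
  expect_true(all(diff(fit$log_lik) >= -1e-9))
  expect_equal(rowSums(fit$params$A), c(1, 1), tolerance = 1e-12)
  expect_equal(rowSums(fit$params$B), c(1, 1), tolerance = 1e-12)
  # starting at the generating parameters stays (near) stationary
  fit0 <- hmm_baum_welch(sims, 2, 3, init = truth, max_iter = 5)
  expect_true(all(diff(fit0$log_lik) >= -1e-9))
})

test_that("single-state Baum-Welch recovers empirical frequencies in one step", {
  obs <- c(1, 1, 2, 3, 3, 3)
  fit <- hmm_baum_welch(obs, 1, 3, init = hmm_params(1, matrix(1, 1, 1),
                                                     matrix(1 / 3, 1, 3)),
                        max_iter = 1)
  expect_equal(fit$params$B[1, ], c(2, 1, 3) / 6, tolerance = 1e-12)
})

test_that("supervised estimation counts bigrams and first symbols", {
  est <- hmm_estimate_supervised(c(1L, 1L, 2L, 2L), 2, pseudocount = 0)
  expect_equal(est$A[1, ], c(0.5, 0.5))
  expect_equal(est$A[2, ], c(0, 1))
  expect_equal(est$pi, c(1, 0))
  # smoothing-only limit: a single symbol and pseudocount 1
  est1 <- suppressWarnings(hmm_estimate_supervised(list(1L), 2, pseudocount = 1))
  expect_equal(est1$A[2, ], c(0.5, 0.5))
  expect_equal(est1$pi, c(2, 1) / 3)
  # counts are invariant to sequence order
  a <- hmm_estimate_supervised(list(c(1L, 2L), c(2L, 2L, 1L)), 2, 0)
  b <- hmm_estimate_supervised(list(c(2L, 2L, 1L), c(1L, 2L)), 2, 0)
  expect_equal(a, b)
  expect_error(hmm_estimate_supervised(list(), 2), "non-empty")
})

test_that("confusion-matrix emissions follow smoothed count arithmetic", {
  B <- hmm_emission_from_confusion(c(1, 2, 3, 4), c(1, 2, 3, 4), 4,
                                   pseudocount = 0)
  expect_equal(B, diag(4))
  B2 <- hmm_emission_from_confusion(c(rep(1, 4), 2, 3, 4),
                                    c(1, 1, 1, 2, 2, 3, 4), 4,
                                    pseudocount = 0)
  expect_equal(B2[1, ], c(0.75, 0.25, 0, 0))
  # heavy smoothing approaches uniform rows
  B3 <- hmm_emission_from_confusion(rep(1, 4), c(1, 1, 1, 2), 2,
                                    pseudocount = 1e6)
  expect_equal(B3[1, ], c(0.5, 0.5), tolerance = 1e-3)
  expect_error(hmm_emission_from_confusion(c(1, 1), c(1, 2), 2,
                                           pseudocount = 0),
               "absent")
})

test_that("HMM parameters survive a JSON round trip", {
  p <- random_hmm_fixture(3, 4)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  hmm_to_json(p, path)
  q <- hmm_from_json(path)
  expect_equal(q$pi, p$pi, tolerance = 1e-15)
  expect_equal(q$A, p$A, tolerance = 1e-15)
  expect_equal(q$B, p$B, tolerance = 1e-15)
  expect_error(hmm_from_json('{"format":"other"}'), "format")
})
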