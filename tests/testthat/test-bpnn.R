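test_that("initialization has the right shapes, seed and scale behavior", {
  p <- bpnn_init(c(60, 32, 4), seed = 1)
  expect_equal(dim(p$weights[[1]]), c(32L, 60L))
  expect_equal(dim(p$weights[[2]]), c(4L, 32L))
  expect_equal(p$biases[[1]], rep(0, 32))
  expect_identical(bpnn_init(c(60, 32, 4), seed = 1), p)
  lim <- 0.5 / sqrt(60)
  expect_lte(max(abs(p$weights[[1]])), lim)
  p0 <- bpnn_init(c(5, 3, 2), seed = 1, init_scale = 0)
  expect_true(all(p0$weights[[1]] == 0) && all(p0$weights[[2]] == 0))
  expect_error(bpnn_init(c(5)), "layers")
})

test_that("forward pass matches hand evaluation", {
  p <- bpnn_init(c(3, 2, 2), seed = 1, init_scale = 0)
  out <- bpnn_forward(p, c(0.3, -0.1, 2))
  expect_equal(out$a[[2]], c(0.5, 0.5))  # sigmoid(0)
  expect_equal(out$a[[3]], c(0.5, 0.5))
  # 1-1-1 chain, unit weights, zero bias, x = 0
  p1 <- bpnn_init(c(1, 1, 1), init_scale = 0)
  p1$weights <- list(matrix(1), matrix(1))
  out1 <- bpnn_forward(p1, 0)
  expect_equal(out1$a[[2]], 0.5)
  expect_equal(out1$a[[3]], 1 / (1 + exp(-0.5)), tolerance = 1e-9)
  expect_equal(out1$a[[3]], 0.622459, tolerance = 1e-6)
  # 2-2-1 net against an independent step-by-step evaluation
  p2 <- bpnn_init(c(2, 2, 1), init_scale = 0)
  p2$weights <- list(matrix(c(0.15, 0.25, 0.20, 0.30), 2), matrix(c(0.4, 0.45), 1))
  p2$biases <- list(c(0.35, 0.35), 0.6)
  x <- c(0.05, 0.10)
  sig <- function(z) 1 / (1 + exp(-z))
  h <- sig(c(0.15 * 0.05 + 0.20 * 0.10 + 0.35, 0.25 * 0.05 + 0.30 * 0.10 + 0.35))
  o <- sig(0.4 * h[1] + 0.45 * h[2] + 0.6)
  out2 <- bpnn_forward(p2, x)
  expect_equal(out2$a[[2]], h, tolerance = 1e-12)
  expect_equal(out2$a[[3]], o, tolerance = 1e-12)
  expect_error(bpnn_forward(p2, c(1, 2, 3)), "length")
})

test_that("MSE loss follows (1/2n) * total squared error", {
  y <- matrix(c(1, 0, 0, 0), 1)
  expect_equal(bpnn_loss(y, y), 0)
  yhat <- matrix(c(0, 1, 0, 0), 1)
  expect_equal(bpnn_loss(yhat, y), 1.0)
  # additivity over samples
  y2 <- rbind(c(1, 0), c(0, 1))
  yh2 <- rbind(c(0.5, 0), c(0, 0.25))
  e1 <- sum((y2[1, ] - yh2[1, ])^2)
  e2 <- sum((y2[2, ] - yh2[2, ])^2)
  expect_equal(bpnn_loss(yh2, y2), (e1 + e2) / 4)
  expect_error(bpnn_loss(matrix(1, 2, 2), matrix(1, 2, 3)), "shape")
})

test_that("gradients vanish exactly at a perfect fit", {
  p <- bpnn_init(c(3, 4, 2), seed = 5)
  fwd <- bpnn_forward(p, c(0.1, 0.2, 0.3))
  g <- bpnn_backward(p, fwd, fwd$a[[3]])  # target = current output
  for (l in 1:2) {
    expect_true(all(g$weights[[l]] == 0))
    expect_true(all(g$biases[[l]] == 0))
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(11)
  for (sizes in list(c(4, 3, 2), c(6, 5, 3))) {
    p <- bpnn_init(sizes, seed = sample(1e4, 1), init_scale = 1)
    x <- stats::rnorm(sizes[1])
    y <- as.numeric(seq_len(sizes[length(sizes)]) == 1)
    g <- bpnn_backward(p, bpnn_forward(p, x), y)
    ng <- numeric_bpnn_grads(p, x, y)
    expect_lt(max_rel_grad_err(g, ng), 1e-6)
  }
})

test_that("1-1-1 gradients match symbolic differentiation", {
  p <- bpnn_init(c(1, 1, 1), init_scale = 0)
  p$weights <- list(matrix(1), matrix(1))
  fwd <- bpnn_forward(p, 0)
  y <- 1
  g <- bpnn_backward(p, fwd, y)
  a1 <- 0.5
  a2 <- 1 / (1 + exp(-0.5))
  d2 <- (a2 - y) * a2 * (1 - a2)
  d1 <- d2 * 1 * a1 * (1 - a1)
  expect_equal(g$weights[[2]][1, 1], d2 * a1, tolerance = 1e-12)
  expect_equal(g$biases[[2]], d2, tolerance = 1e-12)
  expect_equal(g$weights[[1]][1, 1], d1 * 0, tolerance = 1e-12)
  expect_equal(g$biases[[1]], d1, tolerance = 1e-12)
})

test_that("gradient-descent update subtracts alpha times the gradient", {
  p <- bpnn_init(c(2, 2, 2), seed = 3)
  zero <- list(weights = lapply(p$weights, function(w) w * 0),
               biases = lapply(p$biases, function(b) b * 0))
  expect_identical(bpnn_update(p, zero, 0.5), p)
  g <- list(weights = lapply(p$weights, function(w) w * 0 + 1),
            biases = lapply(p$biases, function(b) b * 0 + 2))
  p2 <- bpnn_update(p, g, 1)
  expect_equal(p2$weights[[1]], p$weights[[1]] - 1)
  expect_equal(p2$biases[[2]], p$biases[[2]] - 2)
  # two half-steps with a frozen gradient equal one full step
  pa <- bpnn_update(bpnn_update(p, g, 0.5), g, 0.5)
  expect_equal(pa$weights[[1]], bpnn_update(p, g, 1)$weights[[1]],
               tolerance = 1e-14)
  bad <- g; bad$weights[[1]][1, 1] <- NaN
  expect_error(bpnn_update(p, bad, 0.1), "non-finite")
})

test_that("training solves a linearly separable toy problem", {
  toy <- separable_toy()
  net <- bpnn_train(toy$x, toy$y, hidden = 4L,
                    config = train_config(learning_rate = 0.5, epochs = 500L,
                                          seed = 2))
  expect_true(all(is.finite(net$trace)))
  pred <- predict(net, toy$x)
  expect_equal(pred$labels, toy$y)
  expect_equal(rowSums(pred$scores), rep(1, nrow(toy$x)), tolerance = 1e-12)
})

test_that("training is deterministic and order-invariant in full batch", {
  toy <- separable_toy()
  cfg <- train_config(learning_rate = 0.3, epochs = 50L, seed = 9)
  n1 <- bpnn_train(toy$x, toy$y, hidden = 3L, config = cfg)
  n2 <- bpnn_train(toy$x, toy$y, hidden = 3L, config = cfg)
  expect_identical(n1, n2)
  perm <- sample(nrow(toy$x))
  n3 <- bpnn_train(toy$x[perm, ], toy$y[perm], hidden = 3L, config = cfg)
  expect_equal(n1$trace, n3$trace, tolerance = 1e-12)
  expect_equal(n1$params$weights, n3$params$weights, tolerance = 1e-12)
})

test_that("a sufficiently small full-batch step never increases the loss", {
  set.seed(13)
  for (i in 1:5) {
    x <- matrix(stats::rnorm(60), 10, 6)
    y <- sample(0:1, 10, replace = TRUE)
    before <- bpnn_train(x, y, hidden = 4L,
                         config = train_config(learning_rate = 1e-4,
                                               epochs = 2L, seed = i))
    expect_lte(before$trace[2], before$trace[1] + 1e-12)
  }
})

test_that("prediction breaks ties toward the lowest class index", {
  p <- bpnn_init(c(2, 2, 4), init_scale = 0)  # all outputs identical
  net <- structure(list(params = p, trace = 0, classes = 0:3, config = NULL),
                   class = "bpnn")
  pred <- predict(net, matrix(c(1, 2), 1))
  expect_equal(pred$labels, 0L)
  expect_equal(sum(pred$scores), 1)
  expect_error(predict(net, matrix(1, 1, 5)), "features")
})

test_that("batch gradients equal the average of per-sample gradients", {
  set.seed(17)
  p <- bpnn_init(c(5, 4, 3), seed = 1)
  X <- matrix(stats::rnorm(20), 4, 5)
  Y <- diag(3)[c(1, 2, 3, 1), ]
  bg <- actidecode:::bpnn_backward_batch(p, actidecode:::bpnn_forward_batch(p, X), Y)
  acc <- NULL
  for (i in 1:4) {
    g <- bpnn_backward(p, bpnn_forward(p, X[i, ]), Y[i, ])
    if (is.null(acc)) acc <- g
    else for (l in 1:2) {
      acc$weights[[l]] <- acc$weights[[l]] + g$weights[[l]]
      acc$biases[[l]] <- acc$biases[[l]] + g$biases[[l]]
    }
  }
  for (l in 1:2) {
    expect_equal(bg$weights[[l]], acc$weights[[l]] / 4, tolerance = 1e-12)
    expect_equal(bg$biases[[l]], acc$biases[[l]] / 4, tolerance = 1e-12)
  }
})
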