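# Internal validation helpers shared across modules.

stop_invalid <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("`", name, "` must be a single finite number")
  if (positive && x <= 0) stop_invalid("`", name, "` must be > 0")
  if (nonneg && x < 0) stop_invalid("`", name, "` must be >= 0")
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop_invalid("`", name, "` must be an integer >= ", min)
  invisible(as.integer(x))
}

# Validates a row-stochastic matrix; returns it exactly renormalized.
check_stochastic <- function(m, name, tol = 1e-6) {
  if (!is.matrix(m) || !is.numeric(m))
    stop_invalid("`", name, "` must be a numeric matrix")
  if (any(!is.finite(m)) || any(m < 0))
    stop_invalid("`", name, "` must have finite non-negative entries")
  rs <- rowSums(m)
  if (any(rs == 0))
    stop_invalid("`", name, "` has a row of zeros (degenerate distribution)")
  if (any(abs(rs - 1) > tol))
    stop_invalid("rows of `", name, "` must sum to 1 (max deviation ",
                 format(max(abs(rs - 1))), ")")
  m / rs
}

check_prob_vector <- function(p, name, tol = 1e-6) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0))
    stop_invalid("`", name, "` must be a finite non-negative probability vector")
  s <- sum(p)
  if (abs(s - 1) > tol)
    stop_invalid("`", name, "` must sum to 1 (got ", format(s), ")")
  p / s
}

recycle6 <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop_invalid("`", name, "` must be finite numeric")
  if (length(x) == 1L) rep(x, 6L)
  else if (length(x) == 3L) rep(x, 2L)  # accel triplet reused for gyro
  else if (length(x) == 6L) x
  else stop_invalid("`", name, "` must have length 1, 3 or 6")
}

channel_names <- function() c("ax", "ay", "az", "gx", "gy", "gz")
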