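# Independent oracles, deliberately written against the maths rather than
# the package internals.

# Algebraic steady state: at constant inflow every node pressure is
# constant, so each branch carries a constant flow through its internal
# resistance, tap and tube, and all branches see the same total drop from
# the junction to the common node. Bisection on that drop.
steady_oracle <- function(config, q_in) {
  br <- config$branches
  beta <- br$b + br$r2 + config$r_internal
  q_of <- function(delta) (-beta + sqrt(beta^2 + 4 * br$a * delta)) / (2 * br$a)
  lo <- 0
  hi <- 1
  while (sum(q_of(hi)) < q_in) hi <- hi * 10
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (sum(q_of(mid)) >= q_in) hi <- mid else lo <- mid
  }
  delta <- (lo + hi) / 2
  q <- q_of(delta)
  p_common <- config$p_atrium + config$terminal$r_t * q_in
  list(
    p_aorta = p_common + delta,
    p_common = p_common,
    q_branch = q,
    p_branch = p_common + delta - config$r_internal * q
  )
}

# Dense linear-system solve of the junction equations:
# unknowns (p_a, q_1..q_4); q_j * r_j + p_j - p_a = 0; sum q_j = q_in.
junction_dense_oracle <- function(r_internal, p_branch, q_in) {
  A <- matrix(0, 5, 5)
  b <- numeric(5)
  for (j in 1:4) {
    A[j, j] <- r_internal[j]
    A[j, 5] <- -1
    b[j] <- -p_branch[j]
  }
  A[5, 1:4] <- 1
  b[5] <- q_in
  x <- solve(A, b)
  list(p_aorta = x[5], q_branch = x[1:4])
}

# Trapezoid cycle mean of a periodic series (closing the cycle at t = T).
trapz_cycle_mean <- function(times, values, period) {
  tt <- c(times, period)
  vv <- c(values, values[1])
  sum(diff(tt) * (head(vv, -1) + tail(vv, -1)) / 2) / period
}

expect_rel_equal <- function(actual, expected, rel) {
  scale <- max(abs(expected))
  if (scale == 0) scale <- 1
  expect_lt(max(abs(actual - expected)) / scale, rel)
}
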