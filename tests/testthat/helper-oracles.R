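# Independent oracles and shared fixtures for the test suite.

# Depth-first enumeration over all action/observation sequences of the N = 1
# decision tree: an independent implementation of the optimal value (no
# lattice tables, no vectorization). Returns the optimal value at node
# (t, n_right) and the set of optimal actions there ("sample"/"right"/"left").
oracle_node <- function(t, n, horizon, rw, prior = prior_params()) {
  alpha <- prior$alpha0 + n
  beta <- prior$beta0 + (t - n)
  pr <- 1 - stats::pbeta(0.5, alpha, beta)
  r_right <- rw$reward_correct * pr + rw$reward_error * (1 - pr)
  r_left <- rw$reward_correct * (1 - pr) + rw$reward_error * pr
  vals <- c(sample = NA_real_, right = r_right, left = r_left)
  if (t < horizon) {
    w1 <- alpha / (alpha + beta)
    vals[["sample"]] <- rw$sample_cost +
      (1 - w1) * oracle_node(t + 1, n, horizon, rw, prior)$value +
      w1 * oracle_node(t + 1, n + 1, horizon, rw, prior)$value
  }
  v <- max(vals, na.rm = TRUE)
  list(value = v, optimal = names(vals)[!is.na(vals) & vals >= v - 1e-12])
}

# Brute-force Bayes on a grid: pointwise product of the prior density and the
# binomial likelihoods of an observation sequence, renormalized by composite
# Simpson quadrature (the grid must have an odd number of equally spaced
# points). Independent of the conjugate update path.
grid_bayes_posterior <- function(z_seq, N, p_grid, prior = prior_params()) {
  log_post <- stats::dbeta(p_grid, prior$alpha0, prior$beta0, log = TRUE)
  for (z in z_seq)
    log_post <- log_post + stats::dbinom(z, N, p_grid, log = TRUE)
  dens <- exp(log_post - max(log_post))
  m <- length(p_grid)
  stopifnot(m %% 2L == 1L)
  h <- p_grid[2] - p_grid[1]
  wts <- rep(c(2, 4), length.out = m)
  wts[c(1, m)] <- 1
  area <- h / 3 * sum(wts * dens)
  dens / area
}

# Pearson chi-square goodness of fit with pooling so every expected count is
# at least `min_expected`. Returns the p-value.
pooled_chisq_pvalue <- function(counts, probs, min_expected = 5) {
  stopifnot(length(counts) == length(probs))
  n <- sum(counts)
  keep <- probs > 0 | counts > 0
  counts <- counts[keep]
  probs <- probs[keep]
  # pool adjacent cells until each expected count reaches the floor
  pooled_c <- numeric(0)
  pooled_p <- numeric(0)
  acc_c <- 0
  acc_p <- 0
  for (i in seq_along(counts)) {
    acc_c <- acc_c + counts[i]
    acc_p <- acc_p + probs[i]
    if (n * acc_p >= min_expected) {
      pooled_c <- c(pooled_c, acc_c)
      pooled_p <- c(pooled_p, acc_p)
      acc_c <- 0
      acc_p <- 0
    }
  }
  if (acc_p > 0) {
    pooled_c[length(pooled_c)] <- pooled_c[length(pooled_c)] + acc_c
    pooled_p[length(pooled_p)] <- pooled_p[length(pooled_p)] + acc_p
  }
  pooled_p <- pooled_p / sum(pooled_p)
  expected <- n * pooled_p
  x2 <- sum((pooled_c - expected)^2 / expected)
  stats::pchisq(x2, df = length(pooled_c) - 1, lower.tail = FALSE)
}

# Default study configuration solved once per test file.
default_test_policy <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- solve_policy(reward_params(-1, 200, -200), horizon = 500)
    cache
  }
})

# A minimal policy-solution stand-in whose rightward boundary is an exact
# hyperbola (synthetic; for read-out round-trip checks only).
synthetic_hyperbolic_solution <- function(a = 0.4, tau = 30, horizon = 300,
                                          t0 = 5L) {
  t_all <- 0:horizon
  theta <- 0.5 + a * tau / (t_all + tau)
  theta[t_all < t0] <- NA_real_
  structure(list(horizon = horizon, N = 1L,
                 theta_right = theta, theta_left = 1 - theta,
                 converged = TRUE, certified_t = horizon),
            class = "policy_solution")
}
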