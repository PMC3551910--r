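#' Beta belief state over the spike-success probability
#'
#' The posterior over the hidden success probability p after a sequence of
#' binomial spike-count observations is Beta(alpha, beta), where
#' `alpha = alpha0 + n_right` and `beta = beta0 + n_left`. The belief is
#' therefore fully described by the prior offsets and the two spike counts;
#' equivalently by the lattice point (t, n_right) with `t = n_total / N`.
#'
#' @param alpha,beta Positive shape parameters of the current posterior.
#' @param prior A [prior_params()] object giving the prior offsets, used to
#'   recover the observation counts.
#' @return An object of class `belief_state` with fields `alpha`, `beta`,
#'   `n_right`, `n_total`.
#' @examples
#' b <- belief_state(2, 1)        # one rightward spike seen under flat prior
#' point_estimate(b)              # 1
#' prob_direction_right(b)        # 0.75
#' @export
belief_state <- function(alpha = NULL, beta = NULL, prior = prior_params()) {
  stopifnot(inherits(prior, "prior_params"))
  if (is.null(alpha)) alpha <- prior$alpha0
  if (is.null(beta)) beta <- prior$beta0
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0,
            is.numeric(beta), length(beta) == 1L, beta > 0)
  n_right <- alpha - prior$alpha0
  n_left <- beta - prior$beta0
  if (n_right < 0 || n_left < 0)
    stop("posterior parameters cannot be smaller than the prior offsets",
         call. = FALSE)
  structure(list(alpha = alpha, beta = beta, prior = prior,
                 n_right = n_right, n_total = n_right + n_left),
            class = "belief_state")
}

#' @export
print.belief_state <- function(x, ...) {
  cat(sprintf("Belief state: Beta(%g, %g)  [n_right = %g of %g observed spikes]\n",
              x$alpha, x$beta, x$n_right, x$n_total))
  cat(sprintf("  point estimate p_hat = %.4f, P(rightward) = %.4f\n",
              point_estimate(x), prob_direction_right(x)))
  invisible(x)
}

#' Conjugate belief update with a spike-count observation
#'
#' Observing z rightward spikes out of N updates the beta posterior to
#' Beta(alpha + z, beta + N - z).
#'
#' @param b A [belief_state()].
#' @param z Integer count of rightward spikes, 0 <= z <= N.
#' @param N Total spikes in the step.
#' @return The updated `belief_state`.
#' @export
update_belief <- function(b, z, N) {
  stopifnot(inherits(b, "belief_state"))
  N <- as.integer(N)
  if (length(z) != 1L || is.na(z) || z != floor(z) || z < 0L || z > N)
    stop("`z` must be a single integer in [0, N]", call. = FALSE)
  belief_state(b$alpha + z, b$beta + (N - z), prior = b$prior)
}

#' Point estimate of the success probability
#'
#' The count ratio `n_right / n_total`, the coordinate in which the decision
#' boundaries are expressed. Defined as 1/2 before any observation (the
#' symmetry point of the prior). The posterior mean `alpha / (alpha + beta)`
#' is available via [posterior_mean()] for diagnostics.
#'
#' @param b A [belief_state()].
#' @return Value in \[0, 1\].
#' @export
point_estimate <- function(b) {
  stopifnot(inherits(b, "belief_state"))
  if (b$n_total <= 0) 0.5 else b$n_right / b$n_total
}

#' Posterior mean of the success probability
#'
#' @param b A [belief_state()].
#' @return `alpha / (alpha + beta)`.
#' @export
posterior_mean <- function(b) {
  stopifnot(inherits(b, "belief_state"))
  b$alpha / (b$alpha + b$beta)
}

#' Posterior probability that motion is rightward
#'
#' Marginalizing the beta posterior over coherence, the probability of
#' rightward motion is `P(p > 1/2 | b) = 1 - I_{1/2}(alpha, beta)`, with
#' I the regularized incomplete beta function. Computed as
#' `pbeta(1/2, beta, alpha)` (the mirror identity), which is numerically
#' stable for large shape parameters.
#'
#' @param b A [belief_state()].
#' @return Probability in \[0, 1\].
#' @export
prob_direction_right <- function(b) {
  stopifnot(inherits(b, "belief_state"))
  stats::pbeta(0.5, b$beta, b$alpha)
}

#' Posterior density over a grid of success probabilities
#'
#' Beta(alpha, beta) density evaluated on a user grid; mainly a diagnostic for
#' cross-checking the conjugate update against brute-force Bayes on a grid.
#'
#' @param b A [belief_state()].
#' @param p_grid Numeric vector of points in (0, 1).
#' @return Density values at `p_grid`.
#' @export
posterior_density <- function(b, p_grid) {
  stopifnot(inherits(b, "belief_state"))
  if (any(p_grid <= 0) || any(p_grid >= 1))
    stop("`p_grid` must lie strictly inside (0, 1)", call. = FALSE)
  stats::dbeta(p_grid, b$alpha, b$beta)
}
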