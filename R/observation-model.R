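#' MT population firing rates for a stimulus
#'
#' Linear-in-coherence rate model. The population preferring the true motion
#' direction fires at `base_rate * (1 + drive_pref * c)` and the opposing
#' population at `base_rate * (1 - drive_null * c)`. `f_right` is the rate of
#' the rightward-preferring population, so it takes the preferred-direction
#' value when `direction == "right"` and the null-direction value otherwise.
#'
#' @param coherence Motion coherence in \[0, 1\].
#' @param direction `"left"` or `"right"`, the true motion direction.
#' @param mt An [mt_params()] object.
#' @return Named numeric vector `c(f_right =, f_left =)` in spikes/s.
#' @examples
#' firing_rates(0.5, "right", mt_params())  # c(60, 30) with defaults
#' @export
firing_rates <- function(coherence, direction, mt = mt_params()) {
  stopifnot(inherits(mt, "mt_params"))
  check_direction(direction)
  if (!is.numeric(coherence) || length(coherence) != 1L ||
      is.na(coherence) || coherence < 0 || coherence > 1)
    stop("`coherence` must be a single number in [0, 1]", call. = FALSE)
  f_pref <- mt$base_rate * (1 + mt$drive_pref * coherence)
  f_null <- mt$base_rate * (1 - mt$drive_null * coherence)
  if (f_null <= 0)
    stop("configuration error: null-direction rate is not positive ",
         "(drive_null * coherence >= 1)", call. = FALSE)
  if (direction == "right") c(f_right = f_pref, f_left = f_null)
  else                      c(f_right = f_null, f_left = f_pref)
}

#' Spike-success probability of a stimulus
#'
#' The probability that a spike from the pooled MT population comes from the
#' rightward-preferring neurons: `p = f_right / (f_right + f_left)`. This
#' single number jointly encodes direction (p > 1/2 means rightward) and
#' coherence (distance from 1/2), and is the hidden parameter the belief
#' tracks.
#'
#' @inheritParams firing_rates
#' @return Probability in (0, 1).
#' @examples
#' success_prob(0, "right")            # 0.5
#' success_prob(0.5, "right")          # 2/3 with default MT parameters
#' @export
success_prob <- function(coherence, direction, mt = mt_params()) {
  f <- firing_rates(coherence, direction, mt)
  unname(f[["f_right"]] / (f[["f_right"]] + f[["f_left"]]))
}

#' Probability mass of an observed right-spike count
#'
#' Conditioned on N total spikes per step, the count z of rightward-preferring
#' spikes follows Binomial(N, p); this is the POMDP observation distribution.
#'
#' @param z Integer count(s) of right-preferring spikes, 0 <= z <= N.
#' @param N Total spikes per step.
#' @param p Success probability in \[0, 1\].
#' @return Probability mass at `z` (vectorized over `z`).
#' @export
observation_pmf <- function(z, N, p) {
  N <- as.integer(N)
  stopifnot(N >= 1L, is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  if (any(z != floor(z)) || any(z < 0L) || any(z > N))
    stop("`z` must be integer(s) in [0, N]", call. = FALSE)
  stats::dbinom(z, N, p)
}

#' Sample one observation step from the MT encoding model
#'
#' Draws one POMDP step under the Poisson-race picture: the pooled MT
#' population emits spikes as a Poisson process with rate `f_right + f_left`,
#' the step lasts until N spikes have arrived (a Gamma(N, rate) duration), and
#' each spike is right-preferring with probability `p`, so the observed count
#' is Binomial(N, p).
#'
#' @inheritParams firing_rates
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return List with `z` (right-spike count), `n_right`, `n_left`,
#'   `duration_s` (step duration in seconds), and `p` (the success
#'   probability used).
#' @export
sample_step <- function(coherence, direction, mt = mt_params(), seed) {
  stopifnot(!missing(seed))
  f <- firing_rates(coherence, direction, mt)
  p <- unname(f[["f_right"]] / (f[["f_right"]] + f[["f_left"]]))
  N <- mt$spikes_per_step
  set.seed(as.integer(seed))
  z <- stats::rbinom(1L, N, p)
  duration <- stats::rgamma(1L, shape = N, rate = sum(f))
  list(z = z, n_right = z, n_left = N - z, duration_s = duration, p = p)
}
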