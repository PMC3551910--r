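#' MT population encoding parameters
#'
#' Parameters of the linear-in-coherence rate model for the two
#' direction-selective MT populations. The population preferring the true
#' motion direction fires at `base_rate * (1 + drive_pref * c)` spikes/s and
#' the opposing population at `base_rate * (1 - drive_null * c)`, where `c` is
#' the motion coherence. `spikes_per_step` (N) sets the observation
#' granularity: the belief is updated each time N spikes have arrived from the
#' pooled MT population.
#'
#' The defaults are documented placeholders in the spirit of classic MT
#' recordings (a 40 spikes/s zero-coherence rate, and drives that keep both
#' rates positive up to full coherence); users fitting published MT data
#' should override them.
#'
#' @param base_rate Zero-coherence firing rate of each population, spikes/s.
#' @param drive_pref Dimensionless rate gain in the preferred direction.
#' @param drive_null Dimensionless rate suppression in the null direction;
#'   must be < 1 so the null rate stays positive at full coherence.
#' @param spikes_per_step Integer N >= 1, spikes observed per belief update.
#' @return An object of class `mt_params`.
#' @examples
#' mt <- mt_params()
#' firing_rates(0.5, "right", mt)
#' @export
mt_params <- function(base_rate = 40, drive_pref = 1.0, drive_null = 0.5,
                      spikes_per_step = 1L) {
  stopifnot(is.numeric(base_rate), length(base_rate) == 1L, base_rate > 0,
            is.numeric(drive_pref), length(drive_pref) == 1L, drive_pref >= 0,
            is.numeric(drive_null), length(drive_null) == 1L, drive_null >= 0)
  if (drive_null >= 1)
    stop("`drive_null` must be < 1 so the null-direction rate stays positive ",
         "for all coherences", call. = FALSE)
  spikes_per_step <- as.integer(spikes_per_step)
  if (is.na(spikes_per_step) || spikes_per_step < 1L)
    stop("`spikes_per_step` must be an integer >= 1", call. = FALSE)
  structure(list(base_rate = base_rate, drive_pref = drive_pref,
                 drive_null = drive_null, spikes_per_step = spikes_per_step),
            class = "mt_params")
}

#' @export
print.mt_params <- function(x, ...) {
  cat("MT encoding parameters\n")
  cat(sprintf("  base rate   : %g spikes/s at zero coherence\n", x$base_rate))
  cat(sprintf("  drives      : +%g (preferred), -%g (null) per unit coherence\n",
              x$drive_pref, x$drive_null))
  cat(sprintf("  granularity : N = %d spike(s) per belief update\n",
              x$spikes_per_step))
  invisible(x)
}

#' Beta prior over the spike-success probability
#'
#' The prior over the hidden success probability p (the probability that a
#' pooled MT spike comes from the rightward-preferring population) is
#' Beta(alpha0, beta0). The model fixes the symmetric case; the uniform prior
#' alpha0 = beta0 = 1 is the default.
#'
#' @param alpha0,beta0 Positive shape parameters.
#' @return An object of class `prior_params`.
#' @export
prior_params <- function(alpha0 = 1, beta0 = 1) {
  stopifnot(is.numeric(alpha0), length(alpha0) == 1L, alpha0 > 0,
            is.numeric(beta0), length(beta0) == 1L, beta0 > 0)
  if (alpha0 != beta0)
    warning("asymmetric prior: the task model assumes a symmetric prior ",
            "(alpha0 == beta0); mirror symmetries will not hold",
            call. = FALSE)
  structure(list(alpha0 = alpha0, beta0 = beta0), class = "prior_params")
}

#' @export
print.prior_params <- function(x, ...) {
  cat(sprintf("Beta prior over p: Beta(%g, %g)\n", x$alpha0, x$beta0))
  invisible(x)
}

#' Reward structure of the task
#'
#' The only free behavioral parameters of the model: a (negative) cost per
#' observed spike, a positive reward for a correct choice, and a non-positive
#' reward for an incorrect choice. The optimal policy depends on these only
#' through their ratios, so `sample_cost = -1` fixes the reward unit.
#'
#' @param sample_cost Cost per observed spike; must be negative.
#' @param reward_correct Reward for a correct direction choice; positive.
#' @param reward_error Reward for an incorrect choice; non-positive.
#' @return An object of class `reward_params`.
#' @examples
#' reward_params(-1, 200, -200)
#' @export
reward_params <- function(sample_cost = -1, reward_correct = 200,
                          reward_error = -200) {
  stopifnot(is.numeric(sample_cost), length(sample_cost) == 1L,
            is.numeric(reward_correct), length(reward_correct) == 1L,
            is.numeric(reward_error), length(reward_error) == 1L)
  if (!is.finite(sample_cost) || sample_cost >= 0)
    stop("`sample_cost` must be a finite negative number", call. = FALSE)
  if (!is.finite(reward_correct) || reward_correct <= 0)
    stop("`reward_correct` must be a finite positive number", call. = FALSE)
  if (!is.finite(reward_error) || reward_error > 0)
    stop("`reward_error` must be finite and <= 0", call. = FALSE)
  structure(list(sample_cost = sample_cost, reward_correct = reward_correct,
                 reward_error = reward_error), class = "reward_params")
}

#' @export
print.reward_params <- function(x, ...) {
  cat("Reward parameters\n")
  cat(sprintf("  sampling cost : %g per spike\n", x$sample_cost))
  cat(sprintf("  correct choice: %+g\n", x$reward_correct))
  cat(sprintf("  error choice  : %+g\n", x$reward_error))
  invisible(x)
}

#' LIP read-out parameters
#'
#' Parameters of the firing-rate read-out that maps the belief point estimate
#' relative to the collapsing boundary onto an LIP-like rate:
#' `rate = max(floor, bound_rate + gain * (p_hat - theta_R(t)))`.
#' A rightward saccade is triggered exactly when the rate reaches
#' `bound_rate`, i.e. when the point estimate reaches the boundary.
#'
#' Defaults are documented placeholders at physiologically plausible scales
#' (a ~70 spikes/s decision bound and an early zero-coherence rate around
#' 20 spikes/s); the buildup window of 18 steps corresponds to roughly 225 ms
#' at the step duration implied by the default MT rates.
#'
#' @param bound_rate Firing rate at decision, spikes/s; positive.
#' @param gain Rate change per unit of (p_hat - theta_R), spikes/s; positive.
#' @param floor Lower bound on the rate, spikes/s; non-negative.
#' @param buildup_window Number of early steps used for buildup-rate fits.
#' @return An object of class `lip_params`.
#' @export
lip_params <- function(bound_rate = 70, gain = 100, floor = 0,
                       buildup_window = 18L) {
  stopifnot(is.numeric(bound_rate), length(bound_rate) == 1L, bound_rate > 0,
            is.numeric(gain), length(gain) == 1L, gain >= 0,
            is.numeric(floor), length(floor) == 1L, floor >= 0)
  buildup_window <- as.integer(buildup_window)
  if (is.na(buildup_window) || buildup_window < 2L)
    stop("`buildup_window` must be an integer >= 2 (steps)", call. = FALSE)
  structure(list(bound_rate = bound_rate, gain = gain, floor = floor,
                 buildup_window = buildup_window), class = "lip_params")
}

#' @export
print.lip_params <- function(x, ...) {
  cat("LIP read-out parameters\n")
  cat(sprintf("  bound rate : %g spikes/s\n", x$bound_rate))
  cat(sprintf("  gain       : %g spikes/s per unit (p_hat - theta)\n", x$gain))
  cat(sprintf("  rate floor : %g spikes/s\n", x$floor))
  cat(sprintf("  buildup window : %d steps\n", x$buildup_window))
  invisible(x)
}

# internal: validate a direction argument
check_direction <- function(direction) {
  if (!is.character(direction) || length(direction) != 1L ||
      !direction %in% c("left", "right"))
    stop('`direction` must be "left" or "right"', call. = FALSE)
  direction
}
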