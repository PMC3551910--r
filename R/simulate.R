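#' Per-trial seeds from a base seed
#'
#' The simulator uses a counter-based seeding scheme: a base seed
#' deterministically generates one independent integer seed per trial index,
#' so any trial can be re-simulated in isolation and experiments are
#' reproducible and parallelizable without shared-state generators.
#'
#' @param base_seed Integer base seed.
#' @param n Number of trial seeds.
#' @return Integer vector of length `n`.
#' @export
trial_seeds <- function(base_seed, n) {
  set.seed(as.integer(base_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate one trial under a solved policy
#'
#' Draws binomial spike-count observations under the true stimulus, updates
#' the belief lattice point after each step, and acts per the policy until a
#' terminal action. If the horizon is reached without a voluntary decision
#' (which has negligible probability under a converged policy) the forced
#' terminal action at the horizon row is taken and the record is flagged
#' `truncated`.
#'
#' @param coherence,direction True stimulus.
#' @param sol A converged [solve_policy()] solution.
#' @param mt An [mt_params()] object; its `spikes_per_step` must match the
#'   policy's `N`.
#' @param seed Integer seed; the trial is fully reproducible given the seed.
#' @return An object of class `trial_record`: stimulus fields, `p_success`,
#'   `seed`, per-step observations `z`, cumulative counts `n_right` and
#'   `n_total`, `decision_step`, `choice` (`"right"`/`"left"`), `truncated`.
#' @export
simulate_trial <- function(coherence, direction, sol, mt = mt_params(), seed) {
  stopifnot(inherits(sol, "policy_solution"), inherits(mt, "mt_params"),
            !missing(seed))
  if (!isTRUE(sol$converged))
    stop("policy is not certified stationary; refusing to simulate",
         call. = FALSE)
  if (mt$spikes_per_step != sol$N)
    stop("`mt$spikes_per_step` does not match the policy's N", call. = FALSE)
  p <- success_prob(coherence, direction, mt)
  N <- sol$N
  Tmax <- sol$horizon
  set.seed(as.integer(seed))
  z <- stats::rbinom(Tmax, N, p)
  n_right <- cumsum(z)
  res <- decision_from_counts(sol, n_right)
  keep <- seq_len(res$decision_step)
  structure(list(coherence = coherence, direction = direction, p_success = p,
                 seed = as.integer(seed), z = z[keep],
                 n_right = n_right[keep], n_total = N * keep,
                 decision_step = res$decision_step, choice = res$choice,
                 truncated = res$truncated),
            class = "trial_record")
}

# internal: first crossing of the policy's count thresholds along a
# cumulative right-spike path covering steps 1..horizon.
decision_from_counts <- function(sol, n_right) {
  Tmax <- sol$horizon
  root <- sol$action[[1L]][1L]
  if (root != 1L)
    return(list(decision_step = 0L, choice = ACTIONS[root], truncated = FALSE))
  kr <- sol$k_right[2:(Tmax + 1L)]
  kl <- sol$k_left[2:(Tmax + 1L)]
  cross_r <- !is.na(kr) & n_right >= kr
  cross_l <- !is.na(kl) & n_right <= kl
  t_stop <- which(cross_r | cross_l)[1L]
  if (is.na(t_stop)) {
    # horizon reached: forced terminal action at the last row
    a <- sol$action[[Tmax + 1L]][n_right[Tmax] + 1L]
    list(decision_step = Tmax, choice = ACTIONS[a], truncated = TRUE)
  } else {
    list(decision_step = t_stop,
         choice = if (cross_r[t_stop]) "right" else "left",
         truncated = FALSE)
  }
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("Trial: c = %g, direction %s (p = %.4f), seed %d\n",
              x$coherence, x$direction, x$p_success, x$seed))
  cat(sprintf("  choice %s at step %d%s\n", x$choice, x$decision_step,
              if (x$truncated) " (horizon-truncated)" else ""))
  invisible(x)
}

#' Simulate a behavioral experiment
#'
#' Runs `n_trials` seeded trials at each coherence (per-trial seeds from
#' [trial_seeds()] with a global trial counter across coherences) and
#' tabulates accuracy and reaction times. Accuracy is scored over decided
#' (non-truncated) trials, matching [psychometric_chronometric()].
#'
#' @param coherences Coherence levels.
#' @param n_trials Trials per coherence.
#' @param sol A converged [solve_policy()] solution.
#' @param mt An [mt_params()] object.
#' @param seed Base seed for the experiment.
#' @param direction True motion direction for all trials.
#' @param keep_trials If TRUE, also return the per-trial records as a data
#'   frame (one row per trial).
#' @return An object of class `sim_experiment`: `summary` data frame with one
#'   row per coherence (`coherence`, `n`, `n_decided`, `accuracy`,
#'   `accuracy_se`, `p_right`, `mean_rt_correct_steps`, `rt_correct_se`,
#'   `mean_rt_error_steps`), and `trials` (NULL unless `keep_trials`).
#' @export
simulate_experiment <- function(coherences, n_trials, sol, mt = mt_params(),
                                seed = 1L, direction = "right",
                                keep_trials = FALSE) {
  stopifnot(inherits(sol, "policy_solution"), inherits(mt, "mt_params"))
  if (!isTRUE(sol$converged))
    stop("policy is not certified stationary; refusing to simulate",
         call. = FALSE)
  if (mt$spikes_per_step != sol$N)
    stop("`mt$spikes_per_step` does not match the policy's N", call. = FALSE)
  n_trials <- as.integer(n_trials)
  stopifnot(n_trials >= 1L)
  check_direction(direction)
  seeds <- trial_seeds(seed, n_trials * length(coherences))
  N <- sol$N
  Tmax <- sol$horizon
  kr <- sol$k_right[2:(Tmax + 1L)]
  kl <- sol$k_left[2:(Tmax + 1L)]
  cr_def <- !is.na(kr)
  cl_def <- !is.na(kl)
  root <- sol$action[[1L]][1L]
  all_trials <- if (keep_trials) vector("list", length(coherences)) else NULL
  rows <- vector("list", length(coherences))
  for (ci in seq_along(coherences)) {
    p <- success_prob(coherences[ci], direction, mt)
    choice <- character(n_trials)
    step <- integer(n_trials)
    trunc <- logical(n_trials)
    tseed <- seeds[(ci - 1L) * n_trials + seq_len(n_trials)]
    for (i in seq_len(n_trials)) {
      if (root != 1L) {
        choice[i] <- ACTIONS[root]; step[i] <- 0L; trunc[i] <- FALSE
        next
      }
      set.seed(tseed[i])
      n_right <- cumsum(stats::rbinom(Tmax, N, p))
      crossed <- (cr_def & n_right >= kr) | (cl_def & n_right <= kl)
      t_stop <- which(crossed)[1L]
      if (is.na(t_stop)) {
        a <- sol$action[[Tmax + 1L]][n_right[Tmax] + 1L]
        choice[i] <- ACTIONS[a]; step[i] <- Tmax; trunc[i] <- TRUE
      } else {
        choice[i] <- if (cr_def[t_stop] && n_right[t_stop] >= kr[t_stop])
          "right" else "left"
        step[i] <- t_stop; trunc[i] <- FALSE
      }
    }
    decided <- !trunc
    correct_side <- direction
    is_correct <- choice == correct_side & decided
    n_dec <- sum(decided)
    acc <- sum(is_correct) / n_dec
    rt_cor <- step[is_correct]
    rt_err <- step[decided & choice != correct_side]
    rows[[ci]] <- data.frame(
      coherence = coherences[ci], n = n_trials, n_decided = n_dec,
      accuracy = acc, accuracy_se = sqrt(acc * (1 - acc) / n_dec),
      p_right = mean(choice == "right" & decided),
      mean_rt_correct_steps = mean(rt_cor),
      rt_correct_se = stats::sd(rt_cor) / sqrt(length(rt_cor)),
      mean_rt_error_steps = if (length(rt_err)) mean(rt_err) else NA_real_)
    if (keep_trials)
      all_trials[[ci]] <- data.frame(
        coherence = coherences[ci], direction = direction,
        trial = seq_len(n_trials), seed = tseed, decision_step = step,
        choice = choice, truncated = trunc)
  }
  structure(list(summary = do.call(rbind, rows),
                 trials = if (keep_trials) do.call(rbind, all_trials) else NULL,
                 base_seed = as.integer(seed), direction = direction),
            class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("Simulated experiment (base seed %d, direction %s)\n",
              x$base_seed, x$direction))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Empirical crossing-time distribution of simulated trials
#'
#' Tabulates the decision-step distribution of a simulated experiment's raw
#' trials at one coherence, split by choice, for comparison with the analytic
#' crossing distributions of [first_passage()].
#'
#' @param trials The `trials` data frame of a [simulate_experiment()] run with
#'   `keep_trials = TRUE`.
#' @param coherence Which coherence level to tabulate.
#' @param horizon Policy horizon (length of the returned vectors minus 1).
#' @return List with per-step counts `count_right`, `count_left` (indexed by
#'   step 0..horizon) and `n` (decided trials at this coherence).
#' @export
crossing_histogram <- function(trials, coherence, horizon) {
  sel <- trials$coherence == coherence & !trials$truncated
  tr <- trials[sel, ]
  count_at <- function(ch) {
    tabulate(tr$decision_step[tr$choice == ch] + 1L, nbins = horizon + 1L)
  }
  list(count_right = count_at("right"), count_left = count_at("left"),
       n = nrow(tr))
}
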