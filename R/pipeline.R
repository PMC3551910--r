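#' Serialize a policy solution to JSON
#'
#' Writes the value and action tables (ragged rows over the evidence lattice),
#' the integer count thresholds, the ratio boundaries, and the solve metadata.
#' Action tables and thresholds are integers, so a policy read back with
#' [read_policy_json()] reproduces identical behavioral predictions.
#'
#' @param sol A [solve_policy()] solution.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_policy_json <- function(sol, path) {
  stopifnot(inherits(sol, "policy_solution"))
  payload <- list(
    horizon = sol$horizon, N = sol$N,
    reward = unclass(sol$reward), prior = unclass(sol$prior),
    converged = sol$converged, certified_t = sol$certified_t,
    k_right = sol$k_right, k_left = sol$k_left,
    theta_right = sol$theta_right, theta_left = sol$theta_left,
    value = sol$value, action = sol$action)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' Read a policy solution from JSON
#'
#' @param path Path written by [write_policy_json()].
#' @return A `policy_solution`.
#' @export
read_policy_json <- function(path) {
  if (!file.exists(path))
    stop("policy file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_int_na <- function(v) {
    v <- vapply(v, function(e) if (is.null(e)) NA_integer_ else as.integer(e),
                integer(1))
    v
  }
  structure(list(
    horizon = as.integer(x$horizon), N = as.integer(x$N),
    reward = reward_params(x$reward$sample_cost, x$reward$reward_correct,
                           x$reward$reward_error),
    prior = prior_params(x$prior$alpha0, x$prior$beta0),
    value = lapply(x$value, as.numeric),
    action = lapply(x$action, as.integer),
    k_right = as_int_na(as.list(x$k_right)),
    k_left = as_int_na(as.list(x$k_left)),
    theta_right = as.numeric(x$theta_right),
    theta_left = as.numeric(x$theta_left),
    converged = x$converged, certified_t = as.integer(x$certified_t)),
    class = "policy_solution")
}

#' Run the modeling pipeline
#'
#' Orchestrates solve -> predict -> simulate -> lip from a single validated
#' configuration, writing machine-readable artifacts to `out_dir`:
#' `policy.json`, `boundaries.csv` (t, theta_R, theta_L), `curves.csv`
#' (analytic psychometric/chronometric table), `trials.csv` (raw simulated
#' trials) plus `sim_summary.csv`, `lip.csv` (t, urgency_rate) plus
#' `buildup.csv`, and a `manifest.json` recording the configuration, its hash,
#' seeds, package version and output checksums. With a fixed configuration the
#' outputs are byte-identical across reruns.
#'
#' Stages may be run individually; a stage that needs the policy loads
#' `policy.json` from `out_dir` if "solve" is not part of the same run, and
#' errors if it is missing.
#'
#' @param cfg A `run_config` (see [default_config()], [load_config()]).
#' @param stages Subset of `c("solve", "predict", "simulate", "lip")`,
#'   executed in pipeline order.
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with the computed objects (`policy`, `curves`,
#'   `experiment`, `urgency`, `buildup`) and `manifest`.
#' @export
run_pipeline <- function(cfg = default_config(),
                         stages = c("solve", "predict", "simulate", "lip"),
                         out_dir = ".", quiet = FALSE) {
  cfg <- validate_config(unclass(cfg))
  stages <- match.arg(stages, c("solve", "predict", "simulate", "lip"),
                      several.ok = TRUE)
  stages <- intersect(c("solve", "predict", "simulate", "lip"), stages)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  obj <- config_objects(cfg)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  outputs <- character()
  add_output <- function(f) outputs <<- c(outputs, f)
  result <- list()

  need_policy <- function() {
    if (!is.null(result$policy)) return(result$policy)
    pf <- file.path(out_dir, "policy.json")
    if (!file.exists(pf))
      stop("stage dependency missing: no solved policy in this run and no ",
           pf, "; run the \"solve\" stage first", call. = FALSE)
    read_policy_json(pf)
  }

  if ("solve" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    result$policy <- solve_policy(obj$rewards, obj$prior,
                                  N = cfg$mt$spikes_per_step,
                                  horizon = cfg$horizon)
    pf <- file.path(out_dir, "policy.json")
    write_policy_json(result$policy, pf)
    add_output(pf)
    bf <- file.path(out_dir, "boundaries.csv")
    utils::write.csv(extract_boundaries(result$policy), bf, row.names = FALSE)
    add_output(bf)
    say("solve: horizon %d, converged = %s (%.1fs)", cfg$horizon,
        result$policy$converged, proc.time()[["elapsed"]] - t0)
  }
  if ("predict" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    pol <- need_policy()
    result$curves <- psychometric_chronometric(pol, obj$mt, cfg$coherences,
                                               cfg$direction)
    cf <- file.path(out_dir, "curves.csv")
    utils::write.csv(result$curves, cf, row.names = FALSE)
    add_output(cf)
    say("predict: %d coherence levels (%.1fs)", length(cfg$coherences),
        proc.time()[["elapsed"]] - t0)
  }
  if ("simulate" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    pol <- need_policy()
    result$experiment <- simulate_experiment(cfg$coherences, cfg$sim$n_trials,
                                             pol, obj$mt, cfg$sim$seed,
                                             cfg$direction, keep_trials = TRUE)
    tf <- file.path(out_dir, "trials.csv")
    utils::write.csv(result$experiment$trials, tf, row.names = FALSE)
    add_output(tf)
    sf <- file.path(out_dir, "sim_summary.csv")
    utils::write.csv(result$experiment$summary, sf, row.names = FALSE)
    add_output(sf)
    say("simulate: %d trials x %d coherences (%.1fs)", cfg$sim$n_trials,
        length(cfg$coherences), proc.time()[["elapsed"]] - t0)
  }
  if ("lip" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    pol <- need_policy()
    result$urgency <- urgency_signal(pol, obj$lip)
    lf <- file.path(out_dir, "lip.csv")
    utils::write.csv(data.frame(t = result$urgency$signal$t,
                                urgency_rate = result$urgency$signal$rate),
                     lf, row.names = FALSE)
    add_output(lf)
    result$buildup <- buildup_rates(pol, obj$mt, obj$lip, cfg$coherences,
                                    n_trials = cfg$lip$n_trials,
                                    seed = cfg$sim$seed)
    bf <- file.path(out_dir, "buildup.csv")
    utils::write.csv(result$buildup$slopes, bf, row.names = FALSE)
    add_output(bf)
    say("lip: urgency + buildup over %d coherences (%.1fs)",
        length(cfg$coherences), proc.time()[["elapsed"]] - t0)
  }

  manifest <- list(
    package = "pomdpdots",
    version = as.character(utils::packageVersion("pomdpdots")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(cfg),
    config_hash = config_hash(cfg),
    seed = cfg$sim$seed,
    stages = stages,
    outputs = as.list(unname(vapply(outputs, function(f)
      unname(tools::md5sum(f)), character(1)))))
  names(manifest$outputs) <- basename(outputs)
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  result$manifest <- manifest
  invisible(result)
}

# internal: md5 of the canonical YAML rendering of a config
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(cfg), tf)
  unname(tools::md5sum(tf))
}
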