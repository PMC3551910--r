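test_that("configs validate, fill defaults, and reject unknown keys", {
  cfg <- default_config()
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$rewards$sample_cost, -1)
  # minimal file: defaults filled in
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("rewards:\n  reward_correct: 150", f)
  cfg2 <- load_config(f)
  expect_equal(cfg2$rewards$reward_correct, 150)
  expect_equal(cfg2$mt$base_rate, 40)
  expect_equal(cfg2$horizon, 500L)
  # invalid value reported with its key path
  expect_error(validate_config(list(rewards = list(sample_cost = 1))),
               "rewards.sample_cost", fixed = TRUE)
  # unknown keys rejected
  expect_error(validate_config(list(rewards = list(bribe = 5))),
               "rewards.bribe", fixed = TRUE)
  expect_error(validate_config(list(banana = 1)), "banana")
  # multiple errors reported together
  err <- tryCatch(validate_config(list(rewards = list(sample_cost = 1),
                                       horizon = -3)),
                  error = conditionMessage)
  expect_match(err, "rewards.sample_cost")
  expect_match(err, "horizon")
  expect_error(load_config("no/such/file.yaml"), "not found")
})

test_that("configs round-trip through YAML unchanged", {
  cfg <- default_config()
  cfg$rewards$reward_correct <- 123
  cfg$coherences <- c(0, 0.1)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, f)
  cfg2 <- load_config(f)
  expect_equal(unclass(cfg2), unclass(validate_config(unclass(cfg))))
})

test_that("the pipeline writes its artifacts and reruns byte-identically", {
  cfg <- validate_config(list(
    rewards = list(reward_correct = 100, reward_error = -100),
    horizon = 300L, coherences = c(0, 0.256),
    sim = list(n_trials = 300L, seed = 11L),
    lip = list(n_trials = 100L, buildup_window = 10L)))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  res <- run_pipeline(cfg, out_dir = d1, quiet = TRUE)
  files <- c("policy.json", "boundaries.csv", "curves.csv", "trials.csv",
             "sim_summary.csv", "lip.csv", "buildup.csv", "manifest.json")
  expect_true(all(file.exists(file.path(d1, files))))
  expect_true(res$policy$converged)
  run_pipeline(cfg, out_dir = d2, quiet = TRUE)
  for (f in setdiff(files, "manifest.json"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  # manifest checksums describe the outputs
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$outputs$`curves.csv`,
               unname(tools::md5sum(file.path(d1, "curves.csv"))))
  expect_equal(man$config$rewards$reward_correct, 100)
})

test_that("stages depend on a solved policy", {
  cfg <- validate_config(list(horizon = 120L, coherences = 0.256,
                              sim = list(n_trials = 50L)))
  d <- withr::local_tempdir()
  expect_error(run_pipeline(cfg, stages = "predict", out_dir = d, quiet = TRUE),
               "dependency")
  # solve first, then predict alone works from the stored policy
  cfg2 <- validate_config(list(
    rewards = list(reward_correct = 100, reward_error = -100),
    horizon = 300L, coherences = 0.256, sim = list(n_trials = 50L)))
  run_pipeline(cfg2, stages = "solve", out_dir = d, quiet = TRUE)
  res <- run_pipeline(cfg2, stages = "predict", out_dir = d, quiet = TRUE)
  expect_equal(nrow(res$curves), 1)
  # the reloaded policy reproduces the in-memory predictions
  pol <- read_policy_json(file.path(d, "policy.json"))
  direct <- solve_policy(reward_params(-1, 100, -100), horizon = 300)
  expect_identical(pol$action, direct$action)
  expect_equal(psychometric_chronometric(pol, coherences = 0.256),
               psychometric_chronometric(direct, coherences = 0.256))
})

test_that("policy JSON serialization round-trips", {
  sol <- solve_policy(reward_params(-1, 50, -50), horizon = 60,
                      check_stationarity = FALSE)
  sol$converged <- NA  # as stored
  f <- withr::local_tempfile(fileext = ".json")
  write_policy_json(sol, f)
  back <- read_policy_json(f)
  expect_identical(back$action, sol$action)
  expect_identical(back$k_right, sol$k_right)
  expect_identical(back$k_left, sol$k_left)
  expect_equal(back$value, sol$value, tolerance = 1e-12)
  expect_equal(back$theta_right, sol$theta_right)
  expect_equal(back$reward$reward_correct, 50)
})
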