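test_that("a certain attender is called and screened once per 52-week cycle", {
  ag <- small_population(n = 1, seed = 1)
  ag$times_called <- 0L; ag$times_attended <- 0L
  ag$pct_prior_adherence <- 0; ag$last_result <- "none"
  res <- run_simulation(ag, short_screening(n_cycles = 2),
                        fixed_probability = 1, seed = 5)
  ev <- res$events
  expect_equal(nrow(ev), 2)
  expect_true(all(ev$event == "attended"))
  expect_equal(diff(ev$week), 52)
  expect_equal(res$agents$times_called, 2L)
  expect_equal(res$agents$times_attended, 2L)
  expect_equal(res$agents$pct_prior_adherence, 100)
  expect_true(all(ev$outcome %in% c("positive", "negative", "inconclusive")))
})

test_that("a certain non-attender accumulates calls but no attendance", {
  ag <- small_population(n = 1, seed = 2)
  ag$times_called <- 0L; ag$times_attended <- 0L
  ag$pct_prior_adherence <- 0; ag$last_result <- "none"
  res <- run_simulation(ag, short_screening(n_cycles = 10),
                        fixed_probability = 0, seed = 6)
  expect_equal(res$agents$times_called, 10L)
  expect_equal(res$agents$times_attended, 0L)
  expect_equal(res$agents$pct_prior_adherence, 0)
  expect_identical(res$agents$last_result, "none")
  expect_true(all(res$events$event == "not_attended"))
})

test_that("zero cycles produce an empty event log", {
  ag <- small_population(n = 10, seed = 3)
  res <- run_simulation(ag, short_screening(n_cycles = 0),
                        fixed_probability = 1, seed = 7)
  expect_equal(nrow(res$events), 0)
  expect_equal(nrow(adherence_rates(res)), 0)
})

test_that("event counts reconcile with agent history updates (conservation)", {
  ag <- small_population(n = 400, seed = 4)
  before_called <- sum(ag$times_called)
  before_attended <- sum(ag$times_attended)
  res <- run_simulation(ag, short_screening(n_cycles = 3),
                        decision = decision_config("logistic"), seed = 8)
  ev <- res$events
  expect_equal(nrow(ev), sum(res$agents$times_called) - before_called)
  expect_equal(sum(ev$event == "attended"),
               sum(res$agents$times_attended) - before_attended)
  # per subregion and cycle: attended + not_attended = calls resolved
  tab <- adherence_rates(res, by = "subregion_cycle")
  expect_true(all(tab$calls >= tab$attended))
  expect_equal(sum(tab$calls), nrow(ev))
  # every agent decided once per cycle
  expect_true(all(table(ev$id) == 3))
})

test_that("marginal outcome sampling matches the configured probabilities", {
  cfg <- screening_config()
  set.seed(41)
  draws <- sample_outcome(cfg, 1e5)
  se_pos <- sqrt(0.04 * 0.96 / 1e5)
  se_neg <- sqrt(0.93 * 0.07 / 1e5)
  expect_lt(abs(mean(draws == "positive") - 0.04), 3 * se_pos)
  expect_lt(abs(mean(draws == "negative") - 0.93), 3 * se_neg)
  expect_error(screening_config(p_positive = 0.5), "sum to 1")
})

test_that("diagnostic outcome mode reflects sensitivity and specificity", {
  set.seed(42)
  all_disease <- screening_config(outcome_mode = "diagnostic",
                                  disease_prevalence = 1)
  draws <- sample_outcome(all_disease, 1e5)
  se <- sqrt(0.96 * 0.04 / 1e5)
  expect_lt(abs(mean(draws == "positive") - 0.96), 3 * se)

  no_disease <- screening_config(outcome_mode = "diagnostic",
                                 disease_prevalence = 0)
  draws0 <- sample_outcome(no_disease, 1e5)
  se0 <- sqrt(0.06 * 0.94 / 1e5)
  expect_lt(abs(mean(draws0 == "positive") - 0.06), 3 * se0)
})

test_that("runs are deterministic under a fixed seed", {
  ag <- small_population(n = 150, seed = 10)
  cfg <- short_screening(n_cycles = 2)
  dec <- decision_config("combined", variability = 0.1)
  r1 <- run_simulation(ag, cfg, dec, seed = 99)
  r2 <- run_simulation(ag, cfg, dec, seed = 99)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$agents, r2$agents)
})

test_that("replicate runs derive distinct but reproducible seeds", {
  ag <- small_population(n = 100, seed = 11)
  cfg <- short_screening(n_cycles = 1)
  reps <- run_replicates(ag, cfg, decision_config("logistic"),
                         n_replicates = 5, base_seed = 7)
  expect_length(reps, 5)
  expect_length(unique(vapply(reps, function(r) r$seed, numeric(1))), 5)
  reps2 <- run_replicates(ag, cfg, decision_config("logistic"),
                          n_replicates = 5, base_seed = 7)
  expect_identical(lapply(reps, `[[`, "events"),
                   lapply(reps2, `[[`, "events"))

  one <- run_replicates(ag, cfg, decision_config("logistic"),
                        n_replicates = 1, base_seed = 7)
  expect_length(one, 1)
})

test_that("impossible agent states are rejected", {
  ag <- small_population(n = 5, seed = 12)
  ag$state[2] <- "teleported"
  expect_error(run_simulation(ag, short_screening(1), fixed_probability = 1),
               "impossible agent state")
  ag2 <- small_population(n = 5, seed = 13)
  ag2$times_attended <- ag2$times_called + 1L
  expect_error(run_simulation(ag2, short_screening(1), fixed_probability = 1),
               "times_attended")
})

test_that("staggered first calls spread over the first cycle", {
  ag <- small_population(n = 200, seed = 14)
  res <- run_simulation(ag, short_screening(n_cycles = 1,
                                            stagger_first_call = TRUE),
                        fixed_probability = 1, seed = 15)
  first_weeks <- res$events$week
  expect_gt(length(unique(first_weeks)), 10)
})

test_that("cumulative adherence stabilizes for constant-probability agents", {
  ag <- small_population(n = 500, seed = 16)
  res <- run_simulation(ag, short_screening(n_cycles = 8),
                        fixed_probability = 0.6, seed = 17)
  tr <- convergence_trace(res)
  overall <- tr[tr$subregion == "overall", ]
  changes <- abs(diff(overall$rate))
  # per-cycle change of the cumulative rate shrinks roughly as 1/cycles
  expect_lt(changes[length(changes)], max(changes[1], 1e-9) + 1e-9)
  expect_lt(mean(utils::tail(changes, 3)), mean(utils::head(changes, 3)) + 0.5)
})
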