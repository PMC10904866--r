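# minimal run_result with a controlled number of attended/not-attended events
fake_run <- function(attended, calls, subregion = "Alto Minho",
                     replicate = 1L) {
  ev <- data.frame(
    week = 4L, id = seq_len(calls), subregion = subregion, cycle = 1L,
    event = c(rep("attended", attended), rep("not_attended", calls - attended)),
    probability = 0.7, last_result_prior = "none",
    outcome = NA_character_, stringsAsFactors = FALSE)
  structure(list(events = ev, agents = NULL, seed = replicate,
                 replicate = replicate, n_weeks = 52L), class = "run_result")
}

test_that("replicate summaries reproduce the Student-t interval closed form", {
  # rates 73.5/73.9/74.3/74.7/75.1 -> mean 74.30, sd 0.632456;
  # frozen independently: CI95 = 74.30 +/- 2.776445*sd/sqrt(5)
  runs <- lapply(seq_along(c(735, 739, 743, 747, 751)), function(i) {
    fake_run(c(735, 739, 743, 747, 751)[i], 1000, replicate = i)
  })
  rep5 <- summarize_replicates(runs)
  row <- rep5[rep5$subregion == "Alto Minho", ]
  expect_equal(row$mean, 74.30, tolerance = 1e-9)
  expect_equal(row$sd, 0.632456, tolerance = 1e-5)
  expect_equal(c(row$ci95_lo, row$ci95_hi), c(73.514703, 75.085297),
               tolerance = 1e-5)
  expect_equal(c(row$ci99_lo, row$ci99_hi), c(72.997765, 75.602235),
               tolerance = 1e-5)
  # CI99 contains CI95 contains the mean
  expect_true(row$ci99_lo < row$ci95_lo && row$ci95_lo < row$mean)
  expect_true(row$mean < row$ci95_hi && row$ci95_hi < row$ci99_hi)
})

test_that("identical replicates give degenerate intervals", {
  runs <- lapply(1:3, function(i) fake_run(700, 1000, replicate = i))
  rep3 <- summarize_replicates(runs)
  row <- rep3[rep3$subregion == "Alto Minho", ]
  expect_equal(row$mean, 70)
  expect_equal(row$sd, 0)
  expect_equal(row$ci95_lo, 70)
  expect_equal(row$ci99_hi, 70)
})

test_that("a single replicate yields no intervals, with a warning", {
  expect_warning(rep1 <- summarize_replicates(fake_run(700, 1000)),
                 "fewer than 2 replicates")
  expect_true(all(is.na(rep1$ci95_lo)))
})

test_that("reference comparisons flag values outside the intervals", {
  runs <- lapply(seq_along(c(735, 739, 743, 747, 751)), function(i) {
    fake_run(c(735, 739, 743, 747, 751)[i], 1000, replicate = i)
  })
  inside <- data.frame(subregion = "Alto Minho", real_rate = 74.10)
  r_in <- summarize_replicates(runs, inside)
  row <- r_in[r_in$subregion == "Alto Minho", ]
  expect_false(row$outside_ci95)
  expect_equal(row$difference, 0.20, tolerance = 1e-9)

  outside <- data.frame(subregion = "Alto Minho", real_rate = 70.0)
  r_out <- summarize_replicates(runs, outside)
  expect_true(r_out[r_out$subregion == "Alto Minho", "outside_ci95"])
  expect_true(r_out[r_out$subregion == "Alto Minho", "outside_ci99"])
})

test_that("report rates equal rates recomputed from the raw events", {
  ag <- small_population(n = 300, seed = 30)
  runs <- run_replicates(ag, short_screening(n_cycles = 2),
                         decision_config("logistic"), n_replicates = 3,
                         base_seed = 31)
  rep <- summarize_replicates(runs)
  for (g in rep$subregion) {
    rates <- vapply(runs, function(r) {
      ev <- r$events
      if (g != "overall") ev <- ev[ev$subregion == g, ]
      100 * sum(ev$event == "attended") / nrow(ev)
    }, numeric(1))
    expect_equal(rep$mean[rep$subregion == g], mean(rates), tolerance = 1e-12)
  }
})

test_that("interval half-widths shrink with more replicates", {
  ag <- small_population(n = 200, seed = 32)
  cfg <- short_screening(n_cycles = 1)
  many <- run_replicates(ag, cfg, fixed_probability = 0.7,
                         n_replicates = 16, base_seed = 33)
  few <- many[1:4]
  hw <- function(runs) {
    r <- summarize_replicates(runs)
    row <- r[r$subregion == "overall", ]
    (row$ci95_hi - row$ci95_lo) / 2
  }
  expect_lt(hw(many), hw(few))
})

test_that("convergence traces are cumulative and bounded", {
  ag <- small_population(n = 200, seed = 34)
  res <- run_simulation(ag, short_screening(n_cycles = 4),
                        fixed_probability = 0.7, seed = 35)
  tr <- convergence_trace(res)
  overall <- tr[tr$subregion == "overall", ]
  expect_true(all(diff(overall$calls) > 0))       # monotone denominator
  expect_true(all(overall$rate >= 0 & overall$rate <= 100))
  expect_lt(abs(overall$rate[nrow(overall)] - 70), 5)
  # snapshots at specific weeks are extractable
  expect_true(all(overall$week %in% (0:519)))
  snap <- overall[overall$week <= 52, ]
  expect_equal(nrow(snap), 1)

  none <- run_simulation(ag, short_screening(n_cycles = 2),
                         fixed_probability = 0, seed = 36)
  tr0 <- convergence_trace(none)
  expect_true(all(tr0$rate == 0))
})

test_that("subgroup reports stack per-subgroup rows over a shared layout", {
  ag <- small_population(n = 600, seed = 37)
  expect_equal(sum(ag$cluster == 1) + sum(ag$cluster == 2), nrow(ag))
  expect_setequal(c(train_subregions(), test_subregions()), subregion_names())

  cfg <- short_screening(n_cycles = 1)
  parts <- split_train_test(ag)
  groups <- list(all = ag, cluster1 = ag[ag$cluster == 1, ],
                 train = parts$train, test = parts$test)
  runs <- lapply(groups, function(g) {
    run_replicates(g, cfg, fixed_probability = 0.65, n_replicates = 2,
                   base_seed = 38)
  })
  rep <- subgroup_report(runs, reference = reference_adherence())
  expect_setequal(unique(rep$subgroup), names(groups))
  expect_true(all(c("mean", "sd", "ci95_lo", "real_rate", "difference")
                  %in% names(rep)))
  # identical subgroup populations give identical rows under paired seeds
  rep_dup <- subgroup_report(list(a = runs$all, b = runs$all))
  a <- rep_dup[rep_dup$subgroup == "a", -1]
  b <- rep_dup[rep_dup$subgroup == "b", -1]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("the shipped reference table covers all eight subregions", {
  ref <- reference_adherence()
  expect_setequal(ref$subregion, subregion_names())
  expect_true(all(ref$real_rate > 60 & ref$real_rate < 80))
})
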