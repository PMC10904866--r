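test_that("membership functions evaluate their analytic forms", {
  dom <- c(0, 100)
  lin <- mf_linear(0, 1, 100, 0, dom)
  expect_equal(evaluate_membership(lin, 50), 0.5)
  expect_equal(evaluate_membership(lin, c(0, 100)), c(1, 0))

  g <- mf_gaussian(4, 2, c(0, 12))
  expect_equal(evaluate_membership(g, 4), 1)  # peak-normalized, not a density

  gm <- mf_gaussian_max(0, 8, 2, c(0, 12))
  expect_equal(evaluate_membership(gm, 4), exp(-2), tolerance = 1e-12)
  expect_equal(evaluate_membership(gm, 4), 0.1353352832, tolerance = 1e-9)

  inc <- mf_gaussian(50000, 17000, c(0, 1e5))
  expect_equal(evaluate_membership(inc, 33000), exp(-0.5), tolerance = 1e-12)
  expect_equal(evaluate_membership(inc, 33000), 0.6065306597, tolerance = 1e-9)
})

test_that("membership output is clamped to [0,1] and the domain", {
  steep <- mf_linear(0, -1, 100, 2, c(0, 100))  # line exceeding [0,1]
  x <- seq(0, 100, by = 1)
  y <- evaluate_membership(steep, x)
  expect_true(all(y >= 0 & y <= 1))
  expect_warning(evaluate_membership(mf_linear(0, 1, 100, 0, c(0, 100)), 150),
                 "clamped")
})

test_that("degenerate membership parameters are rejected", {
  expect_error(mf_gaussian(4, 0, c(0, 12)), "sd > 0")
  expect_error(mf_gaussian_max(0, 8, -1, c(0, 12)), "sd > 0")
  expect_error(mf_linear(5, 0, 5, 1, c(0, 10)), "distinct")
  expect_error(mf_gaussian(4, 2, c(10, 0)), "lo < hi")
})

test_that("all default memberships stay in [0,1] over random in-domain inputs", {
  set.seed(11)
  for (cp in default_fuzzy_components()) {
    for (v in cp$inputs) {
      x <- runif(200, v$domain[1], v$domain[2])
      for (mf in v$terms) {
        y <- evaluate_membership(mf, x)
        expect_true(all(y >= 0 & y <= 1))
      }
    }
  }
})

test_that("rule activation is the minimum over antecedent memberships", {
  comps <- default_fuzzy_components()
  barriers <- comps$access_barriers
  inputs <- list(age = 40, income = 20000, location_score = 20,
                 urbanization = 0.8)
  degrees <- vapply(names(inputs), function(v) {
    evaluate_membership(barriers$inputs[[v]]$terms[["easy"]],
                        inputs[[v]])
  }, numeric(1))
  all_easy <- fuzzy_rule(c(age = "easy", income = "easy",
                           location_score = "easy", urbanization = "easy"),
                         "strong")
  expect_equal(fire_rule(all_easy, barriers$inputs, inputs), min(degrees))

  # absorbing zero: age=100 has easy-membership... 1; use difficult at 100 -> 0
  zero_rule <- fuzzy_rule(c(age = "difficult", income = "easy"), "strong")
  expect_equal(fire_rule(zero_rule, barriers$inputs,
                         list(age = 100, income = 0)), 0)

  # single antecedent: identity
  single <- fuzzy_rule(c(income = "difficult"), "weak")
  expect_equal(fire_rule(single, barriers$inputs, list(income = 33000)),
               exp(-0.5), tolerance = 1e-12)

  expect_error(fire_rule(all_easy, barriers$inputs, list(age = 40)),
               "income")
})

test_that("majority rule generation is exhaustive, duplicate-free and correct", {
  comps <- default_fuzzy_components()
  expect_length(comps$access_barriers$rules, 16)
  expect_length(comps$disease_knowledge$rules, 8)
  expect_length(comps$program_quality$rules, 8)

  fav <- list(access_barriers = c(age = "easy", income = "easy",
                                  location_score = "easy",
                                  urbanization = "easy"),
              disease_knowledge = c(age = "high", education_score = "high",
                                    pct_prior_adherence = "high"),
              program_quality = c(reminder_score = "high",
                                  waiting_time = "high",
                                  notice_weeks = "high"))
  for (nm in names(comps)) {
    cp <- comps[[nm]]
    n_in <- length(cp$inputs)
    keys <- vapply(cp$rules, function(r) {
      paste(names(r$antecedents), r$antecedents, sep = "=", collapse = ";")
    }, character(1))
    expect_length(unique(keys), 2^n_in)
    need <- ceiling(n_in / 2)
    for (r in cp$rules) {
      n_fav <- sum(r$antecedents == fav[[nm]][names(r$antecedents)])
      expect_identical(r$consequent, if (n_fav >= need) "strong" else "weak")
    }
  }

  # 2 favorable of 3 is already a majority
  kn <- comps$disease_knowledge
  r <- Filter(function(r) r$antecedents[["age"]] == "high" &&
                r$antecedents[["education_score"]] == "high" &&
                r$antecedents[["pct_prior_adherence"]] == "low", kn$rules)
  expect_identical(r[[1]]$consequent, "strong")

  one_term <- fuzzy_variable("x", c(0, 1), list(
    a = mf_linear(0, 0, 1, 1, c(0, 1)), b = mf_linear(0, 1, 1, 0, c(0, 1))))
  expect_error(generate_majority_rules(list(one_term), c(y = "a")),
               "favorable_labels")
})

test_that("COG defuzzification handles flat, ramp and empty aggregates", {
  knob <- two_knob_component()
  # both consequents clipped at 0.5 -> aggregate constant 0.5 -> midpoint
  expect_equal(defuzzify_component(knob, list(v_strong = 50, v_weak = 50)), 50,
               tolerance = 1e-9)
  # pure strong ramp mu(x) = x/100: analytic centroid 200/3
  expect_equal(defuzzify_component(knob, list(v_strong = 100, v_weak = 0)),
               200 / 3, tolerance = 0.02)
  # all activations zero -> domain midpoint fallback
  far <- fuzzy_variable("z", c(0, 100), list(
    lo = mf_gaussian(0, 0.1, c(0, 100)), hi = mf_gaussian(100, 0.1, c(0, 100))))
  dead <- fuzzy_component("dead", list(far), propensity_out <- two_knob_component()$output,
                          list(fuzzy_rule(c(z = "lo"), "strong"),
                               fuzzy_rule(c(z = "hi"), "weak")))
  expect_equal(defuzzify_component(dead, list(z = 50)), 50)
  # empty rule base is a configuration error
  expect_error(fuzzy_component("none", list(far), propensity_out, list()),
               "empty rule base")
})

test_that("COG of symmetric aggregates is the domain midpoint", {
  knob <- two_knob_component()
  for (v in c(10, 35, 60, 90)) {
    expect_equal(defuzzify_component(knob, list(v_strong = v, v_weak = v)), 50,
                 tolerance = 1e-9)
  }
})

test_that("COG agrees with the brute-force integration oracle", {
  set.seed(202)
  knob <- two_knob_component()
  for (i in 1:60) {
    inp <- list(v_strong = runif(1, 0, 100), v_weak = runif(1, 0, 100))
    expect_equal(defuzzify_component(knob, inp), oracle_cog(knob, inp),
                 tolerance = 0.1)
  }
  comps <- default_fuzzy_components()
  ag <- small_population(n = 40, seed = 5)
  inputs <- default_component_inputs(ag)
  for (cp in comps) {
    for (i in seq_len(20)) {
      one <- lapply(inputs, function(x) rep_len(x, nrow(ag))[i])
      expect_equal(defuzzify_component(cp, one), oracle_cog(cp, one),
                   tolerance = 0.1)
    }
  }
})

test_that("component scores are within the output domain", {
  set.seed(77)
  comps <- default_fuzzy_components()
  ag <- small_population(n = 100, seed = 6)
  inputs <- default_component_inputs(ag)
  for (cp in comps) {
    sc <- component_scores(cp, inputs)
    expect_true(all(sc >= 0 & sc <= 100))
  }
})

test_that("vectorized component scores match the scalar path", {
  comps <- default_fuzzy_components()
  ag <- small_population(n = 25, seed = 9)
  inputs <- default_component_inputs(ag)
  n <- nrow(ag)
  for (cp in comps) {
    vec <- component_scores(cp, inputs)
    scal <- vapply(seq_len(n), function(i) {
      defuzzify_component(cp, lapply(inputs, function(x) rep_len(x, n)[i]))
    }, numeric(1))
    expect_equal(vec, scal, tolerance = 1e-10)
  }
})

test_that("component score is monotone in prior adherence", {
  kn <- default_fuzzy_components()$disease_knowledge
  pct <- seq(0, 100, by = 5)
  sc <- component_scores(kn, list(age = 60, education_score = 40,
                                  pct_prior_adherence = pct))
  expect_true(all(diff(sc) >= -1e-9))
})

test_that("component definitions round-trip through JSON and match the shipped file", {
  comps <- default_fuzzy_components()
  tmp <- withr::local_tempfile(fileext = ".json")
  write_fuzzy_components(comps, tmp)
  back <- read_fuzzy_components(tmp)
  strip <- function(x) lapply(x, unclass)
  expect_equal(strip(back), strip(comps))

  shipped <- read_fuzzy_components(system.file("extdata",
                                               "fuzzy_components.json",
                                               package = "drscreensim"))
  expect_equal(strip(shipped), strip(comps))
})

test_that("list_rules reports the full 32-rule base", {
  rules <- list_rules(print = FALSE)
  expect_equal(nrow(rules), 32)
  expect_equal(sum(rules$component == "access_barriers"), 16)
  out <- capture.output(list_rules())
  expect_equal(sum(grepl("IF ", out, fixed = TRUE)), 32)
})
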