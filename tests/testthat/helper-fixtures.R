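# shared fixtures, built in code at test time

# small population + short program for fast end-to-end runs
small_population <- function(n = 300, seed = 42) {
  spec <- population_spec(total_size = n)
  generate_population(spec, seed = seed)
}

short_screening <- function(n_cycles = 3, ...) {
  screening_config(n_cycles = n_cycles, ...)
}

# brute-force Mamdani + COG oracle, independent of the package's
# defuzzification path: per-rule truncation, pointwise max aggregation,
# rectangle-rule centroid on a fine grid
oracle_cog <- function(component, crisp_inputs, n_grid = 100001L) {
  acts <- vapply(component$rules, function(r) {
    degrees <- vapply(names(r$antecedents), function(v) {
      mf <- component$inputs[[v]]$terms[[r$antecedents[[v]]]]
      evaluate_membership(mf, as.numeric(crisp_inputs[[v]]),
                          warn_clamp = FALSE)
    }, numeric(1))
    min(degrees)
  }, numeric(1))
  dom <- component$output$domain
  g <- seq(dom[1], dom[2], length.out = n_grid)
  agg <- rep(0, n_grid)
  for (i in seq_along(component$rules)) {
    cons <- component$output$terms[[component$rules[[i]]$consequent]]
    agg <- pmax(agg, pmin(acts[i], evaluate_membership(cons, g,
                                                       warn_clamp = FALSE)))
  }
  if (sum(agg) <= 0) return(mean(dom))
  sum(g * agg) / sum(agg)
}

# a two-input component whose strong/weak activations can be set directly:
# strong activation = v_strong/100, weak activation = v_weak/100
two_knob_component <- function() {
  ramp_up <- function(dom) mf_linear(dom[1], 0, dom[2], 1, dom)
  ramp_dn <- function(dom) mf_linear(dom[1], 1, dom[2], 0, dom)
  v1 <- fuzzy_variable("v_strong", c(0, 100),
                       list(high = ramp_up(c(0, 100)),
                            low = ramp_dn(c(0, 100))))
  v2 <- fuzzy_variable("v_weak", c(0, 100),
                       list(high = ramp_up(c(0, 100)),
                            low = ramp_dn(c(0, 100))))
  out <- fuzzy_variable("propensity", c(0, 100),
                        list(strong = ramp_up(c(0, 100)),
                             weak = ramp_dn(c(0, 100))))
  fuzzy_component("knob", list(v1, v2), out, list(
    fuzzy_rule(c(v_strong = "high"), "strong"),
    fuzzy_rule(c(v_weak = "high"), "weak")))
}

# crisp inputs for the three default components, one agent per row
# (program-level scalars expanded to one value per agent)
default_component_inputs <- function(agents, screening = screening_config()) {
  inputs <- list(age = agents$age, income = agents$income,
                 location_score = screening$location_score,
                 urbanization = agents$urbanization,
                 education_score = agents$education_score,
                 pct_prior_adherence = agents$pct_prior_adherence,
                 reminder_score = screening$reminder_score,
                 waiting_time = screening$waiting_time_minutes,
                 notice_weeks = screening$notice_weeks)
  lapply(inputs, rep_len, nrow(agents))
}
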