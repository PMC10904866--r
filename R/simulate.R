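#' Create a simulation world
#'
#' Bundles the agent roster with the screening, decision and scenario
#' configuration into a mutable world object advanced by [step_week()].
#' Agents follow the four-state machine not_called -> called ->
#' attended / not_attended -> not_called: a call letter moves an agent to
#' "called"; `notice_weeks` later the decision engine is invoked; attenders
#' receive an outcome and both branches update their history, re-enter
#' "not_called", and are re-called `interval_weeks` after the previous call.
#'
#' @param agents agent roster (data frame from [generate_population()]).
#' @param screening a [screening_config()].
#' @param decision a [decision_config()].
#' @param scenarios list of [scenario()]s applied to decision probabilities.
#' @param components fuzzy components (default [default_fuzzy_components()]).
#' @param logistic a [logistic_model()] (default [default_logistic_model()]).
#' @param fixed_probability if non-`NULL`, every agent decides with this
#'   constant probability instead of an engine (useful for calibration
#'   checks).
#' @return object of class `sim_world`.
#' @export
sim_world <- function(agents, screening = screening_config(),
                      decision = decision_config(),
                      scenarios = list(),
                      components = default_fuzzy_components(),
                      logistic = default_logistic_model(),
                      fixed_probability = NULL) {
  stopifnot(inherits(screening, "screening_config"),
            inherits(decision, "decision_config"))
  if (!all(agents$times_attended <= agents$times_called)) {
    stop("integrity error: times_attended exceeds times_called", call. = FALSE)
  }
  bad_state <- setdiff(unique(agents$state),
                       c("not_called", "called", "attended", "not_attended"))
  if (length(bad_state)) {
    stop("integrity error: impossible agent state(s): ",
         paste(bad_state, collapse = ", "), call. = FALSE)
  }
  if (screening$stagger_first_call) {
    agents$next_call_week <- sample.int(screening$interval_weeks,
                                        nrow(agents), replace = TRUE) - 1L
  }
  structure(list(agents = agents, screening = screening, decision = decision,
                 scenarios = scenarios, components = components,
                 logistic = logistic, fixed_probability = fixed_probability,
                 events = list(), week = 0L),
            class = "sim_world")
}

#' Advance the world by one week
#'
#' Issues call letters to agents whose `next_call_week` equals `week`, and
#' resolves decisions for agents whose screening date (call week +
#' `notice_weeks`) equals `week`: the decision engine produces a
#' probability, active scenarios modify it, the decision policy draws the
#' action, attendance yields a sampled outcome, and the screening history
#' (times called, percent prior adherence, last result) is updated on both
#' branches before the next call is scheduled `interval_weeks` after the
#' current one.
#'
#' @param world a [sim_world()].
#' @param week integer week index.
#' @return the updated world.
#' @export
step_week <- function(world, week) {
  stopifnot(inherits(world, "sim_world"))
  ag <- world$agents
  sc <- world$screening

  due_call <- !is.na(ag$next_call_week) & ag$next_call_week == week
  if (any(due_call)) {
    ag$state[due_call] <- "called"
    ag$call_week[due_call] <- week
  }

  due_decide <- ag$state == "called" &
    !is.na(ag$call_week) & (ag$call_week + sc$notice_weeks) == week
  if (any(due_decide)) {
    idx <- which(due_decide)
    sub <- ag[idx, , drop = FALSE]

    if (!is.null(world$fixed_probability)) {
      p <- rep(world$fixed_probability, length(idx))
      p_log <- p_fuz <- NULL
    } else {
      mode <- world$decision$mode
      p_log <- if (mode %in% c("logistic", "combined")) {
        logistic_probability(world$logistic, list(
          pct_prior_adherence = sub$pct_prior_adherence,
          times_called = sub$times_called + 1L,  # current call counts
          last_result = sub$last_result))
      }
      p_fuz <- if (mode %in% c("fuzzy", "combined")) {
        fuzzy_probability(list(
          age = sub$age, income = sub$income,
          location_score = sc$location_score,
          urbanization = sub$urbanization,
          education_score = sub$education_score,
          pct_prior_adherence = sub$pct_prior_adherence,
          reminder_score = sc$reminder_score,
          waiting_time = sc$waiting_time_minutes,
          notice_weeks = sc$notice_weeks),
          components = world$components,
          variability = world$decision$variability)
      }
      p <- combine_probability(world$decision, p_log, p_fuz)
    }

    for (s in world$scenarios) p <- apply_scenario(s, sub, p)

    adhere <- if (world$decision$decision_policy == "bernoulli") {
      stats::runif(length(idx)) < p
    } else {
      p > world$decision$threshold
    }

    outcome <- rep(NA_character_, length(idx))
    if (any(adhere)) outcome[adhere] <- sample_outcome(sc, sum(adhere))

    world$events[[length(world$events) + 1L]] <- data.frame(
      week = week,
      id = sub$id,
      subregion = sub$subregion,
      cycle = ag$times_called[idx] + 1L,
      event = ifelse(adhere, "attended", "not_attended"),
      probability = p,
      last_result_prior = sub$last_result,
      outcome = outcome,
      stringsAsFactors = FALSE)

    ag$times_called[idx] <- ag$times_called[idx] + 1L
    ag$times_attended[idx] <- ag$times_attended[idx] + adhere
    ag$pct_prior_adherence[idx] <-
      100 * ag$times_attended[idx] / ag$times_called[idx]
    ag$last_result[idx] <- ifelse(adhere, outcome, ag$last_result[idx])
    ag$state[idx] <- ifelse(adhere, "attended", "not_attended")
    ag$next_call_week[idx] <- sub$call_week + sc$interval_weeks
  }

  world$agents <- ag
  world$week <- week + 1L
  world
}

#' Run a full simulation
#'
#' Executes `n_cycles * interval_weeks` weekly steps of the agent state
#' machine and returns the complete event log plus the final roster.
#' Deterministic under a fixed seed.
#'
#' @inheritParams sim_world
#' @param seed integer seed for all randomness in the run.
#' @param replicate replicate index stored in the result (bookkeeping).
#' @return object of class `run_result`: a list with `events` (one row per
#'   resolved decision: week, agent, subregion, cycle, event, decision
#'   probability, prior last result, outcome), `agents` (final roster),
#'   `seed`, `replicate`, and `n_weeks`.
#' @export
run_simulation <- function(agents, screening = screening_config(),
                           decision = decision_config(),
                           scenarios = list(),
                           components = default_fuzzy_components(),
                           logistic = default_logistic_model(),
                           fixed_probability = NULL,
                           seed = NULL, replicate = 1L) {
  if (!is.null(seed)) set.seed(seed)
  world <- sim_world(agents, screening, decision, scenarios, components,
                     logistic, fixed_probability)
  n_weeks <- screening$n_cycles * screening$interval_weeks
  for (w in seq_len(n_weeks) - 1L) {
    world <- step_week(world, w)
  }
  events <- if (length(world$events)) {
    do.call(rbind, world$events)
  } else {
    data.frame(week = integer(0), id = integer(0), subregion = character(0),
               cycle = integer(0), event = character(0),
               probability = numeric(0), last_result_prior = character(0),
               outcome = character(0), stringsAsFactors = FALSE)
  }
  structure(list(events = events, agents = world$agents, seed = seed,
                 replicate = replicate, n_weeks = n_weeks),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  rate <- if (nrow(x$events)) 100 * mean(x$events$event == "attended") else NA
  cat(sprintf(paste0("<run_result> replicate %d: %d agents, %d weeks, ",
                     "%d decisions, cumulative adherence %.2f%%\n"),
              x$replicate, nrow(x$agents), x$n_weeks, nrow(x$events), rate))
  invisible(x)
}

#' Replicate runs
#'
#' Runs `n_replicates` independent simulations of the same configuration.
#' Per-replicate seeds are drawn reproducibly from `base_seed`, so the same
#' base seed always yields the same replicate set.
#'
#' @inheritParams run_simulation
#' @param n_replicates number of replicate runs (default from `screening`).
#' @param base_seed integer seed from which replicate seeds are derived.
#' @return list of [run_result][run_simulation] objects.
#' @export
run_replicates <- function(agents, screening = screening_config(),
                           decision = decision_config(),
                           scenarios = list(),
                           components = default_fuzzy_components(),
                           logistic = default_logistic_model(),
                           fixed_probability = NULL,
                           n_replicates = screening$n_replicates,
                           base_seed = 1L) {
  stopifnot(n_replicates >= 1)
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max, n_replicates)
  lapply(seq_len(n_replicates), function(i) {
    run_simulation(agents, screening, decision, scenarios, components,
                   logistic, fixed_probability, seed = seeds[i],
                   replicate = i)
  })
}

#' Adherence rates from a run
#'
#' Cumulative adherence per subregion (and overall) over the whole run:
#' attended decisions divided by resolved calls, in percent.
#'
#' @param result a [run_result][run_simulation].
#' @param by grouping: `"subregion"`, `"cycle"` or `"subregion_cycle"`.
#' @return data frame with grouping columns, `calls`, `attended` and
#'   `rate` (percent). An `overall` row is appended for subregion grouping.
#' @export
adherence_rates <- function(result, by = c("subregion", "cycle",
                                           "subregion_cycle")) {
  by <- match.arg(by)
  ev <- result$events
  if (!nrow(ev)) {
    return(data.frame(subregion = character(0), calls = integer(0),
                      attended = integer(0), rate = numeric(0)))
  }
  keys <- switch(by,
                 subregion = list(subregion = ev$subregion),
                 cycle = list(cycle = ev$cycle),
                 subregion_cycle = list(subregion = ev$subregion,
                                        cycle = ev$cycle))
  agg <- stats::aggregate(list(calls = rep(1L, nrow(ev)),
                               attended = as.integer(ev$event == "attended")),
                          by = keys, FUN = sum)
  if (by == "subregion") {
    agg <- rbind(agg, data.frame(subregion = "overall",
                                 calls = nrow(ev),
                                 attended = sum(ev$event == "attended")))
  }
  agg$rate <- 100 * agg$attended / agg$calls
  agg[do.call(order, unname(agg[intersect(c("subregion", "cycle"),
                                          names(agg))])), , drop = FALSE]
}
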