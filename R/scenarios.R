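#' Intervention scenarios
#'
#' A scenario modifies the decision probability of agents matched by a
#' side-effect-free selector predicate, leaving all other agents untouched.
#' Actions: `set` (override to `amount`), `add` (add `amount` probability
#' points, i.e. a stated "+5%" is read as +0.05 = 5 percentage points), or
#' `multiply` (scale by `amount`). Results are always clipped to \[0, 1\].
#' Multiple active scenarios compose left-to-right.
#'
#' @param name scenario label.
#' @param selector function taking the agent data frame and returning a
#'   logical vector (one entry per agent row); must not modify its input.
#' @param action one of `"set"`, `"add"`, `"multiply"`.
#' @param amount action parameter: the override probability, the additive
#'   probability delta, or the multiplicative factor.
#' @return object of class `scenario`.
#' @seealso [scenario_preset()] for the three shipped interventions.
#' @export
scenario <- function(name, selector, action = c("set", "add", "multiply"),
                     amount) {
  action <- match.arg(action)
  stopifnot(is.function(selector), is_scalar_number(amount))
  if (action == "set" && (amount < 0 || amount > 1)) {
    stop_config("scenario '", name, "': set amount must be in [0, 1]")
  }
  if (action == "multiply" && amount < 0) {
    stop_config("scenario '", name, "': multiply amount must be >= 0")
  }
  structure(list(name = name, selector = selector, action = action,
                 amount = amount), class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s: %s %g on selected agents\n",
              x$name, x$action, x$amount))
  invisible(x)
}

#' Apply a scenario to decision probabilities
#'
#' @param scn a [scenario()].
#' @param agents agent data frame of the deciding agents (one row per
#'   probability).
#' @param p numeric vector of decision probabilities in \[0, 1\].
#' @return modified probability vector, clipped to \[0, 1\]; entries of
#'   agents not matched by the selector are returned unchanged.
#' @export
apply_scenario <- function(scn, agents, p) {
  stopifnot(inherits(scn, "scenario"), length(p) == nrow(agents))
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("probabilities must be in [0, 1]", call. = FALSE)
  }
  sel <- scn$selector(agents)
  stopifnot(is.logical(sel), length(sel) == nrow(agents))
  sel[is.na(sel)] <- FALSE
  p[sel] <- switch(scn$action,
                   set = scn$amount,
                   add = p[sel] + scn$amount,
                   multiply = p[sel] * scn$amount)
  clamp(p, 0, 1)
}

#' Shipped intervention presets
#'
#' The three hypothetical public-health interventions evaluated with the
#' simulator:
#'
#' 1. `"positive_result"` — diabetics whose last screening result was
#'    positive attend with probability 0.95 (a data-quality intervention:
#'    their observed adherence is believed to be biased downward by
#'    hospital follow-up).
#' 2. `"prior_attendees"` — diabetics who have attended at least once gain
#'    5 percentage points of adherence probability (a short training session
#'    on the day of the screening).
#' 3. `"young_students"` — diabetics under 25 years of age who are students
#'    gain 20 percentage points (school information sessions).
#'
#' @param name preset name (see above).
#' @return a [scenario()].
#' @export
scenario_preset <- function(name = c("positive_result", "prior_attendees",
                                     "young_students")) {
  name <- match.arg(name)
  switch(name,
    positive_result = scenario(
      "positive_result",
      function(agents) agents$last_result == "positive",
      action = "set", amount = 0.95),
    prior_attendees = scenario(
      "prior_attendees",
      function(agents) agents$times_attended >= 1,
      action = "add", amount = 0.05),
    young_students = scenario(
      "young_students",
      function(agents) agents$age < 25 & agents$occupation == "student",
      action = "add", amount = 0.20))
}

#' Compare baseline and intervention runs
#'
#' Produces the per-subregion table of baseline adherence rate, scenario
#' adherence rate, and their difference (percentage points), averaged over
#' replicates. Arms must be paired: same population and seeds, differing
#' only in the active scenarios.
#'
#' @param baseline,scenario_runs lists of [run_result][run_simulation]
#'   objects (or single results) for the two arms.
#' @return data frame with columns `subregion`, `baseline`, `scenario`,
#'   `difference`.
#' @export
compare_scenarios <- function(baseline, scenario_runs) {
  as_list <- function(x) if (inherits(x, "run_result")) list(x) else x
  mean_rates <- function(runs) {
    tabs <- lapply(as_list(runs), adherence_rates, by = "subregion")
    all <- do.call(rbind, tabs)
    stats::aggregate(list(rate = all$rate),
                     by = list(subregion = all$subregion), FUN = mean)
  }
  b <- mean_rates(baseline)
  s <- mean_rates(scenario_runs)
  if (!setequal(b$subregion, s$subregion)) {
    stop("mismatched subregion sets between arms", call. = FALSE)
  }
  m <- merge(b, s, by = "subregion", suffixes = c("_baseline", "_scenario"))
  out <- data.frame(subregion = m$subregion,
                    baseline = m$rate_baseline,
                    scenario = m$rate_scenario,
                    difference = m$rate_scenario - m$rate_baseline)
  out[order(out$subregion != "overall", out$subregion), , drop = FALSE]
}
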