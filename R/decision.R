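#' Decision-engine configuration
#'
#' Chooses how an agent's adherence probability is formed and turned into a
#' yes/no decision: from the logistic model alone, from the mean of the
#' three fuzzy component scores, or from a weighted combination of the two
#' (default weights 50/50).
#'
#' @param mode one of `"logistic"`, `"fuzzy"`, `"combined"`.
#' @param weight_logistic,weight_fuzzy non-negative combination weights,
#'   summing to 1 (combined mode only).
#' @param variability magnitude of the zero-mean uniform noise added to the
#'   fuzzy probability, in probability units (noise ~ U(-variability/2,
#'   +variability/2), result clipped to \[0, 1\]).
#' @param decision_policy `"bernoulli"` (stochastic draw at the decision
#'   probability, the default) or `"threshold"` (attend iff p > `threshold`).
#' @param threshold cut-point for the threshold policy.
#' @return object of class `decision_config`.
#' @export
decision_config <- function(mode = c("logistic", "fuzzy", "combined"),
                            weight_logistic = 0.5, weight_fuzzy = 0.5,
                            variability = 0,
                            decision_policy = c("bernoulli", "threshold"),
                            threshold = 0.5) {
  mode <- match.arg(mode)
  decision_policy <- match.arg(decision_policy)
  if (!is_scalar_number(variability) || variability < 0 || variability > 1) {
    stop_config("variability must be in [0, 1]")
  }
  if (weight_logistic < 0 || weight_fuzzy < 0 ||
      abs(weight_logistic + weight_fuzzy - 1) > 1e-9) {
    stop_config("weights must be non-negative and sum to 1")
  }
  if (!is_scalar_number(threshold) || threshold < 0 || threshold > 1) {
    stop_config("threshold must be in [0, 1]")
  }
  structure(list(mode = mode, weight_logistic = weight_logistic,
                 weight_fuzzy = weight_fuzzy, variability = variability,
                 decision_policy = decision_policy, threshold = threshold),
            class = "decision_config")
}

#' @export
print.decision_config <- function(x, ...) {
  cat(sprintf("<decision_config> mode=%s", x$mode))
  if (x$mode == "combined") {
    cat(sprintf(" (weights %.2f/%.2f)", x$weight_logistic, x$weight_fuzzy))
  }
  cat(sprintf(", variability=%.3g, policy=%s\n", x$variability,
              x$decision_policy))
  invisible(x)
}

#' Fuzzy adherence probability
#'
#' Evaluates the three Mamdani components at the agent/program crisp inputs,
#' averages the three centre-of-gravity scores (each on \[0, 100\]), rescales
#' to \[0, 1\], and adds zero-mean uniform noise of magnitude `variability`
#' (clipped to \[0, 1\]). With `variability = 0` the result is deterministic.
#'
#' @param components named list of the three [fuzzy_component()]s (default
#'   [default_fuzzy_components()]).
#' @param crisp_inputs named list of equal-length numeric vectors covering
#'   all ten component inputs: `age`, `income`, `location_score`,
#'   `urbanization`, `education_score`, `pct_prior_adherence`,
#'   `reminder_score`, `waiting_time`, `notice_weeks` (scalars are recycled).
#' @param variability noise magnitude in \[0, 1\].
#' @param n_grid output-domain discretization for the COG.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
fuzzy_probability <- function(crisp_inputs,
                              components = default_fuzzy_components(),
                              variability = 0, n_grid = 1001L) {
  n <- max(lengths(crisp_inputs))
  crisp_inputs <- lapply(crisp_inputs, function(x) rep_len(as.numeric(x), n))
  scores <- vapply(components, component_scores, numeric(n),
                   crisp_inputs = crisp_inputs, n_grid = n_grid)
  if (n == 1L) scores <- matrix(scores, nrow = 1)
  p <- rowMeans(scores) / 100
  if (variability > 0) {
    p <- p + stats::runif(n, -variability / 2, variability / 2)
  }
  clamp(p, 0, 1)
}

#' Combine engine probabilities
#'
#' Returns the decision probability implied by the configured mode:
#' `p_logistic`, `p_fuzzy`, or their weighted mean.
#'
#' @param config a [decision_config()].
#' @param p_logistic,p_fuzzy probability vectors in \[0, 1\].
#' @return numeric vector of decision probabilities.
#' @export
combine_probability <- function(config, p_logistic = NULL, p_fuzzy = NULL) {
  stopifnot(inherits(config, "decision_config"))
  switch(config$mode,
    logistic = p_logistic,
    fuzzy = p_fuzzy,
    combined = config$weight_logistic * p_logistic +
               config$weight_fuzzy * p_fuzzy)
}

#' Draw the adherence decision
#'
#' Applies the configured decision policy to the mode-appropriate
#' probability: a Bernoulli draw (default) or a hard threshold.
#'
#' @inheritParams combine_probability
#' @return logical vector: `TRUE` = attends the screening.
#' @export
decide <- function(config, p_logistic = NULL, p_fuzzy = NULL) {
  p <- combine_probability(config, p_logistic, p_fuzzy)
  decide_at <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE)) {
      stop("decision probabilities must be in [0, 1]", call. = FALSE)
    }
    if (config$decision_policy == "bernoulli") {
      stats::runif(length(p)) < p
    } else {
      p > config$threshold
    }
  }
  decide_at(p)
}
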