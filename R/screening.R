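#' Screening-strategy configuration
#'
#' Parameters of the screening program as run by the regional health
#' administration: a 52-week interval between screenings, test sensitivity
#' 96% and specificity 94%, marginal outcome probabilities 4% positive / 93%
#' negative / 3% inconclusive, calls sent 4 weeks ahead of the screening
#' date, a 10-minute waiting time on the day, and reminders still an
#' incipient practice (low reminder score).
#'
#' @param interval_weeks weeks between successive calls (>= 1; default 52).
#' @param sensitivity,specificity test characteristics in \[0, 1\]
#'   (defaults 0.96 / 0.94), used by the diagnostic outcome mode.
#' @param outcome_mode `"marginal"` (default: outcomes drawn from the
#'   marginal probabilities) or `"diagnostic"` (a latent disease state is
#'   drawn at `disease_prevalence` and the test applied to it).
#' @param p_positive,p_negative,p_inconclusive marginal outcome
#'   probabilities, summing to 1 (defaults 0.04 / 0.93 / 0.03).
#' @param disease_prevalence latent prevalence for the diagnostic mode.
#' @param reminder_score reminder-intensity score on \[0, 100\] (default 20:
#'   reminders are incipient).
#' @param waiting_time_minutes waiting time on the screening day (default 10).
#' @param notice_weeks weeks between call letter and screening date
#'   (default 4; must be < `interval_weeks`).
#' @param location_score screening-location difficulty score on \[0, 100\]
#'   (default 30: screening happens in local primary-care units).
#' @param stagger_first_call if `TRUE`, first calls are spread uniformly
#'   over the first cycle instead of all being issued in week 0.
#' @param n_cycles number of screening cycles to simulate (default 10).
#' @param n_replicates default number of replicate runs (default 5).
#' @return object of class `screening_config`.
#' @export
screening_config <- function(interval_weeks = 52,
                             sensitivity = 0.96, specificity = 0.94,
                             outcome_mode = c("marginal", "diagnostic"),
                             p_positive = 0.04, p_negative = 0.93,
                             p_inconclusive = 0.03,
                             disease_prevalence = 0.05,
                             reminder_score = 20,
                             waiting_time_minutes = 10,
                             notice_weeks = 4,
                             location_score = 30,
                             stagger_first_call = FALSE,
                             n_cycles = 10, n_replicates = 5) {
  outcome_mode <- match.arg(outcome_mode)
  if (!is_scalar_number(interval_weeks) || interval_weeks < 1) {
    stop_config("screening: interval_weeks must be >= 1")
  }
  probs <- c(p_positive, p_negative, p_inconclusive)
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9) {
    stop_config("screening: outcome probabilities must be >= 0 and sum to 1")
  }
  for (nm in c("sensitivity", "specificity", "disease_prevalence")) {
    v <- get(nm)
    if (!is_scalar_number(v) || v < 0 || v > 1) {
      stop_config("screening: ", nm, " must be in [0, 1]")
    }
  }
  if (notice_weeks < 0 || notice_weeks >= interval_weeks) {
    stop_config("screening: notice_weeks must be in [0, interval_weeks)")
  }
  if (n_cycles < 0 || n_replicates < 1) {
    stop_config("screening: n_cycles must be >= 0 and n_replicates >= 1")
  }
  structure(list(interval_weeks = as.integer(interval_weeks),
                 sensitivity = sensitivity, specificity = specificity,
                 outcome_mode = outcome_mode, p_positive = p_positive,
                 p_negative = p_negative, p_inconclusive = p_inconclusive,
                 disease_prevalence = disease_prevalence,
                 reminder_score = reminder_score,
                 waiting_time_minutes = waiting_time_minutes,
                 notice_weeks = as.integer(notice_weeks),
                 location_score = location_score,
                 stagger_first_call = isTRUE(stagger_first_call),
                 n_cycles = as.integer(n_cycles),
                 n_replicates = as.integer(n_replicates)),
            class = "screening_config")
}

#' @export
print.screening_config <- function(x, ...) {
  cat(sprintf(paste0("<screening_config> interval=%dw, notice=%dw, ",
                     "sens/spec=%.2f/%.2f, outcomes(%s)=%.2f/%.2f/%.2f, ",
                     "%d cycles x %d replicates\n"),
              x$interval_weeks, x$notice_weeks, x$sensitivity, x$specificity,
              x$outcome_mode, x$p_positive, x$p_negative, x$p_inconclusive,
              x$n_cycles, x$n_replicates))
  invisible(x)
}

#' Sample screening outcomes
#'
#' In marginal mode (the default), outcomes are drawn directly from the
#' configured positive/negative/inconclusive probabilities. In diagnostic
#' mode a latent disease state is drawn at `disease_prevalence`; the test is
#' positive with probability `sensitivity` for diseased agents and
#' `1 - specificity` for healthy ones, and non-positive results are recorded
#' as inconclusive with probability `p_inconclusive / (p_inconclusive +
#' p_negative)` so that the marginal inconclusive rate is preserved without
#' distorting the printed test characteristics.
#'
#' @param config a [screening_config()].
#' @param n number of outcomes to draw.
#' @return character vector in `c("positive", "negative", "inconclusive")`.
#' @export
sample_outcome <- function(config, n = 1) {
  stopifnot(inherits(config, "screening_config"), n >= 0)
  if (n == 0) return(character(0))
  if (config$outcome_mode == "marginal") {
    sample(c("positive", "negative", "inconclusive"), n, replace = TRUE,
           prob = c(config$p_positive, config$p_negative,
                    config$p_inconclusive))
  } else {
    diseased <- stats::runif(n) < config$disease_prevalence
    p_pos <- ifelse(diseased, config$sensitivity, 1 - config$specificity)
    positive <- stats::runif(n) < p_pos
    p_inc_given_nonpos <- config$p_inconclusive /
      (config$p_inconclusive + config$p_negative)
    inconclusive <- !positive & stats::runif(n) < p_inc_given_nonpos
    ifelse(positive, "positive", ifelse(inconclusive, "inconclusive",
                                        "negative"))
  }
}
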