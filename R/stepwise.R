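#' Synthetic call-record generator
#'
#' Generates one row per screening call with the dichotomous adherence
#' outcome and the 21 candidate covariates considered for the decision
#' regression. Only the three screening-history predictors carry true
#' effects (through `model`): percent prior adherence, last screening
#' result, and number of times called. The remaining 18 covariates are
#' outcome-independent demographic/clinical noise, generated with realistic
#' mutual correlation through two latent axes (an age/frailty axis and a
#' socioeconomic axis).
#'
#' @param n number of call records.
#' @param model the true [logistic_model()] generating the outcome; defaults
#'   to [default_logistic_model()].
#' @param null_model if `TRUE` the outcome is drawn independently of every
#'   covariate (Bernoulli(0.5)); used for type-I-error checks.
#' @param seed optional integer seed.
#' @return data frame with column `adhered` (0/1), the three active
#'   predictors (`pct_prior_adherence`, `last_result`, `times_called`) and 18
#'   inactive covariates.
#' @export
simulate_call_records <- function(n = 20000, model = default_logistic_model(),
                                  null_model = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1)

  # latent correlation axes: z1 age/frailty, z2 socioeconomic status
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)

  occ_lin <- cbind(active = 1.0 - 1.8 * z1, retired = -1.2 + 1.8 * z1,
                   other = -0.6)
  occ_p <- exp(occ_lin) / rowSums(exp(occ_lin))
  occ <- vapply(seq_len(n), function(i) {
    sample(colnames(occ_p), 1L, prob = occ_p[i, ])
  }, character(1))

  rec <- data.frame(
    age = round(clamp(62 + 13 * z1 + stats::rnorm(n, 0, 5), 18, 98)),
    gender_male = stats::rbinom(n, 1, 0.45),
    income = round(exp(9.4 + 0.40 * z2 + stats::rnorm(n, 0, 0.20))),
    education_score = clamp(45 + 20 * z2 + stats::rnorm(n, 0, 12), 0, 100),
    urbanization = stats::plogis(0.4 + 1.2 * z2 + stats::rnorm(n, 0, 0.5)),
    occupation_active = as.integer(occ == "active"),
    occupation_retired = as.integer(occ == "retired"),
    has_phone = stats::rbinom(n, 1, stats::plogis(1.4 + 0.5 * z2)),
    family_doctor = stats::rbinom(n, 1, 0.85),
    charge_exemption = stats::rbinom(n, 1, 0.30),
    n_consultations = stats::rpois(n, exp(1.1 + 0.25 * z1)),
    diabetes_type2 = stats::rbinom(n, 1, 0.90),
    bmi = 28 + 2.0 * z1 + stats::rnorm(n, 0, 3),
    hba1c = 7.0 + 0.30 * z1 + stats::rnorm(n, 0, 0.8),
    call_month = sample.int(12, n, replace = TRUE),
    days_between_calls = round(stats::rnorm(n, 380, 40)),
    unit_type_urban = stats::rbinom(n, 1, stats::plogis(0.2 + 1.0 * z2)),
    subregion_metro = stats::rbinom(n, 1, stats::plogis(-0.4 + 1.0 * z2)),
    stringsAsFactors = FALSE
  )

  # screening history (the active block)
  rec$times_called <- 1L + stats::rpois(n, 2)
  prior_calls <- rec$times_called - 1L
  attended_prior <- stats::rbinom(n, prior_calls, 0.66)
  rec$pct_prior_adherence <- ifelse(prior_calls > 0,
                                    100 * attended_prior / prior_calls, 0)
  rec$last_result <- ifelse(
    attended_prior > 0,
    sample(c("negative", "positive", "inconclusive"), n, replace = TRUE,
           prob = c(0.93, 0.04, 0.03)),
    "none")

  p <- if (null_model) rep(0.5, n) else logistic_probability(model, rec)
  rec$adhered <- stats::rbinom(n, 1, p)
  rec
}

#' Candidate covariates of the call-record regression
#'
#' The 21 covariate names tested by [fit_stepwise_logistic()] on
#' [simulate_call_records()] output; `last_result` enters as a single
#' categorical candidate.
#' @return character vector of length 21.
#' @export
call_record_candidates <- function() {
  c("pct_prior_adherence", "last_result", "times_called",
    "age", "gender_male", "income", "education_score", "urbanization",
    "occupation_active", "occupation_retired", "has_phone", "family_doctor",
    "charge_exemption", "n_consultations", "diabetes_type2", "bmi", "hba1c",
    "call_month", "days_between_calls", "unit_type_urban", "subregion_metro")
}

#' Stepwise logistic calibration from call records
#'
#' Forward stepwise selection with backward removal for the dichotomous
#' adherence outcome: at each step the candidate with the smallest
#' likelihood-ratio p-value enters if p < `entry_p`; any entered covariate
#' whose removal LRT p-value exceeds `stay_p` is dropped. Iterates until the
#' model is stable. Accuracy and a rank-based AUC are reported on a held-out
#' split.
#'
#' @param records data frame of call records (e.g.
#'   [simulate_call_records()]); must contain `outcome` and all candidates.
#' @param candidates character vector of candidate covariate names
#'   (default [call_record_candidates()]). Categorical candidates enter as
#'   factors and are tested as a block.
#' @param outcome name of the 0/1 outcome column.
#' @param entry_p,stay_p entry and stay thresholds (defaults 0.05 / 0.10).
#' @param test_fraction fraction of rows held out for accuracy/AUC.
#' @param min_rows minimum number of records required.
#' @param seed optional seed for the holdout split.
#' @return list with elements `selected` (ordered character vector), `fit`
#'   (the final `glm`), `coefficients`, `accuracy`, `auc`, and — when the
#'   selected set is exactly the three screening-history predictors —
#'   `model`, the corresponding [logistic_model()].
#' @export
fit_stepwise_logistic <- function(records,
                                  candidates = call_record_candidates(),
                                  outcome = "adhered",
                                  entry_p = 0.05, stay_p = 0.10,
                                  test_fraction = 0.3, min_rows = 500,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  missing <- setdiff(c(outcome, candidates), names(records))
  if (length(missing)) {
    stop("records lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) < min_rows) {
    stop("need at least ", min_rows, " records, got ", nrow(records),
         call. = FALSE)
  }
  dat <- records[c(outcome, candidates)]
  for (v in candidates) {
    if (is.character(dat[[v]])) {
      dat[[v]] <- factor(dat[[v]])
      if ("none" %in% levels(dat[[v]])) {
        dat[[v]] <- stats::relevel(dat[[v]], ref = "none")
      }
    }
  }
  idx_test <- sample.int(nrow(dat), size = floor(test_fraction * nrow(dat)))
  train <- if (length(idx_test)) dat[-idx_test, ] else dat
  test <- dat[idx_test, ]

  selected <- character(0)
  repeat {
    changed <- FALSE
    # forward step: best remaining candidate by LRT p-value
    remaining <- setdiff(candidates, selected)
    if (length(remaining)) {
      fit0 <- fit_glm_safe(outcome, selected, train)
      addp <- vapply(remaining, function(v) {
        lrt_p(fit0, fit_glm_safe(outcome, c(selected, v), train))
      }, numeric(1))
      if (min(addp) < entry_p) {
        selected <- c(selected, remaining[which.min(addp)])
        changed <- TRUE
      }
    }
    # backward step: drop the worst covariate if it no longer earns its place
    if (length(selected) > 1L) {
      fit1 <- fit_glm_safe(outcome, selected, train)
      dropp <- vapply(selected, function(v) {
        lrt_p(fit_glm_safe(outcome, setdiff(selected, v), train), fit1)
      }, numeric(1))
      if (max(dropp) > stay_p) {
        selected <- setdiff(selected, selected[which.max(dropp)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  fit <- fit_glm_safe(outcome, selected, train)
  p_test <- if (nrow(test)) stats::predict(fit, newdata = test,
                                           type = "response") else numeric(0)
  y_test <- test[[outcome]]
  acc <- if (length(p_test)) mean((p_test > 0.5) == (y_test == 1)) else NA_real_
  auc <- if (length(p_test)) rank_auc(y_test, p_test) else NA_real_

  out <- list(selected = selected, fit = fit,
              coefficients = stats::coef(fit), accuracy = acc, auc = auc)
  if (setequal(selected,
               c("pct_prior_adherence", "last_result", "times_called"))) {
    cf <- stats::coef(fit)
    pick <- function(nm) if (nm %in% names(cf)) unname(cf[nm]) else 0
    out$model <- logistic_model(
      intercept = unname(cf["(Intercept)"]),
      coefficients = c(
        pct_prior_adherence = pick("pct_prior_adherence"),
        times_called = pick("times_called"),
        last_result_negative = pick("last_resultnegative"),
        last_result_positive = pick("last_resultpositive"),
        last_result_inconclusive = pick("last_resultinconclusive")))
  }
  class(out) <- "stepwise_logistic_fit"
  out
}

fit_glm_safe <- function(outcome, covariates, data) {
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  f <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- stats::glm(f, family = stats::binomial(), data = data)
  if (!fit$converged || any(abs(stats::coef(fit)) > 15, na.rm = TRUE)) {
    stop("logistic fit did not converge (possible separation); ",
         "consider regularization or more data", call. = FALSE)
  }
  fit
}

# likelihood-ratio p-value of nested binomial glms (fit0 nested in fit1)
lrt_p <- function(fit0, fit1) {
  dev <- fit0$deviance - fit1$deviance
  df <- fit0$df.residual - fit1$df.residual
  if (df <= 0) return(1)
  stats::pchisq(max(dev, 0), df = df, lower.tail = FALSE)
}

# Mann-Whitney AUC from outcome labels and scores
rank_auc <- function(y, score) {
  y <- as.integer(y == 1)
  n1 <- sum(y); n0 <- sum(1 - y)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.stepwise_logistic_fit <- function(x, ...) {
  cat("<stepwise_logistic_fit>\n  selected:",
      paste(x$selected, collapse = ", "), "\n")
  cat(sprintf("  holdout accuracy: %.4f, AUC: %.4f\n", x$accuracy, x$auc))
  invisible(x)
}
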