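#' Subregions of the simulated screening registry
#'
#' The eight NUTS-III style subregions structuring all reporting, and the
#' published train/test partition used to probe the fuzzy engine's
#' predictive ability in areas it was not calibrated on.
#'
#' @return character vector of subregion names.
#' @export
subregion_names <- function() {
  c("Alto Minho", "Ave", "Cávado", "Douro", "Entre Douro e Vouga",
    "Metropolitan Area of Porto", "Tâmega e Sousa", "Trás-os-Montes")
}

#' @rdname subregion_names
#' @export
train_subregions <- function() {
  c("Tâmega e Sousa", "Cávado", "Douro", "Trás-os-Montes",
    "Metropolitan Area of Porto")
}

#' @rdname subregion_names
#' @export
test_subregions <- function() {
  c("Alto Minho", "Ave", "Entre Douro e Vouga")
}

#' Synthetic population specification
#'
#' Parameterizes the synthetic diabetic population that stands in for the
#' (non-public) regional registry: subregion shares, two demographic
#' clusters (cluster 1 younger and mostly professionally active, cluster 2
#' older and mostly retired), per-subregion income medians and urbanization
#' levels, education, occupation mixes, and initial screening histories.
#' All distributional parameters are editable synthetic stand-ins; the
#' subregion shares are chosen so the five training subregions hold 66.41%
#' of the population and the three test subregions 33.59%, matching the
#' registry split.
#'
#' @param total_size number of agents (default 10,000).
#' @param shares named numeric vector of subregion shares summing to 1.
#' @param cluster1_share fraction of agents in cluster 1 (default 0.509).
#' @param cluster_age list with `mean` and `sd` per cluster for the
#'   truncated-normal age distribution on \[18, 100\] years.
#' @param occupation_probs per-cluster probabilities over
#'   active/retired/student/other.
#' @param education_beta per-cluster `shape1`/`shape2` of the Beta
#'   distribution scaled to the 0-100 education score.
#' @param income_median named vector of per-subregion median incomes in
#'   EUR/year (log-normal, median-parameterized).
#' @param income_sdlog log-scale spread of income.
#' @param urbanization_mean named vector of per-subregion mean degrees of
#'   urbanization in \[0, 1\] (Beta with precision `urbanization_precision`).
#' @param urbanization_precision Beta precision (shape1 + shape2).
#' @param prob_male probability of gender "male".
#' @param frac_never_called fraction of agents starting with no screening
#'   history (default 0.30).
#' @param mean_prior_calls Poisson mean of prior calls beyond the first for
#'   agents with history (times_called ~ 1 + Poisson(mean_prior_calls)).
#' @param prior_adherence_prob per-call probability of having attended a
#'   past call (default 0.66, near the registry-wide adherence level).
#' @return object of class `population_spec`.
#' @export
population_spec <- function(
    total_size = 10000,
    shares = c("Alto Minho" = 0.0700, "Ave" = 0.1250, "Cávado" = 0.1100,
               "Douro" = 0.0500, "Entre Douro e Vouga" = 0.1409,
               "Metropolitan Area of Porto" = 0.3300,
               "Tâmega e Sousa" = 0.1300, "Trás-os-Montes" = 0.0441),
    cluster1_share = 0.509,
    cluster_age = list(`1` = list(mean = 48, sd = 13),
                       `2` = list(mean = 72, sd = 9)),
    occupation_probs = list(
      `1` = c(active = 0.70, retired = 0.06, student = 0.09, other = 0.15),
      `2` = c(active = 0.12, retired = 0.78, student = 0.005, other = 0.095)),
    education_beta = list(`1` = c(shape1 = 3.2, shape2 = 2.2),
                          `2` = c(shape1 = 2.0, shape2 = 3.5)),
    income_median = c("Alto Minho" = 9500, "Ave" = 10000, "Cávado" = 10500,
                      "Douro" = 9000, "Entre Douro e Vouga" = 11000,
                      "Metropolitan Area of Porto" = 12500,
                      "Tâmega e Sousa" = 9200, "Trás-os-Montes" = 8800),
    income_sdlog = 0.45,
    urbanization_mean = c("Alto Minho" = 0.40, "Ave" = 0.55,
                          "Cávado" = 0.60, "Douro" = 0.30,
                          "Entre Douro e Vouga" = 0.60,
                          "Metropolitan Area of Porto" = 0.90,
                          "Tâmega e Sousa" = 0.45,
                          "Trás-os-Montes" = 0.25),
    urbanization_precision = 12,
    prob_male = 0.45,
    frac_never_called = 0.30,
    mean_prior_calls = 2,
    prior_adherence_prob = 0.66) {
  spec <- structure(as.list(environment()), class = "population_spec")
  validate_population_spec(spec)
  spec
}

validate_population_spec <- function(spec) {
  regions <- names(spec$shares)
  if (abs(sum(spec$shares) - 1) > 1e-9) {
    stop_config("population: subregion shares must sum to 1 (got ",
                format(sum(spec$shares)), ")")
  }
  if (any(spec$shares < 0)) stop_config("population: shares must be >= 0")
  for (nm in c("income_median", "urbanization_mean")) {
    missing <- setdiff(regions, names(spec[[nm]]))
    if (length(missing)) {
      stop_config("population: ", nm, " missing subregion(s): ",
                  paste(missing, collapse = ", "))
    }
  }
  if (any(spec$urbanization_mean <= 0 | spec$urbanization_mean >= 1)) {
    stop_config("population: urbanization_mean must be in (0, 1)")
  }
  probs01 <- c(spec$cluster1_share, spec$prob_male, spec$frac_never_called,
               spec$prior_adherence_prob)
  if (any(probs01 < 0 | probs01 > 1)) {
    stop_config("population: probabilities must be in [0, 1]")
  }
  for (cl in c("1", "2")) {
    op <- spec$occupation_probs[[cl]]
    if (abs(sum(op) - 1) > 1e-9 || any(op < 0)) {
      stop_config("population: occupation probabilities of cluster ", cl,
                  " must be non-negative and sum to 1")
    }
  }
  if (spec$total_size < 1) stop_config("population: total_size must be >= 1")
  invisible(spec)
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("<population_spec> %d agents, %d subregions, cluster-1 share %.3f\n",
              x$total_size, length(x$shares), x$cluster1_share))
  invisible(x)
}

# truncated-normal sampler on [lo, hi] via inverse CDF
rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate the synthetic agent population
#'
#' Draws `spec$total_size` agents: subregions multinomially around the
#' configured shares, demographics from the cluster profiles and
#' per-subregion distributions, and initial screening histories (a
#' configurable fraction never called; the rest with `1 + Poisson` prior
#' calls and per-call Bernoulli adherence). Reproducible under a fixed seed.
#'
#' @param spec a [population_spec()].
#' @param seed optional integer seed.
#' @return data frame of agents (one row each) with the documented roster
#'   columns; see [write_population()].
#' @export
generate_population <- function(spec = population_spec(), seed = NULL) {
  validate_population_spec(spec)
  if (!is.null(seed)) set.seed(seed)
  n <- spec$total_size
  regions <- names(spec$shares)

  subregion <- sample(regions, n, replace = TRUE, prob = spec$shares)
  cluster <- ifelse(stats::runif(n) < spec$cluster1_share, 1L, 2L)

  age <- numeric(n)
  education_score <- numeric(n)
  occupation <- character(n)
  for (cl in c(1L, 2L)) {
    idx <- which(cluster == cl)
    prof <- spec$cluster_age[[as.character(cl)]]
    age[idx] <- rtruncnorm(length(idx), prof$mean, prof$sd, 18, 100)
    eb <- spec$education_beta[[as.character(cl)]]
    education_score[idx] <- 100 * stats::rbeta(length(idx), eb[["shape1"]],
                                               eb[["shape2"]])
    op <- spec$occupation_probs[[as.character(cl)]]
    occupation[idx] <- sample(names(op), length(idx), replace = TRUE, prob = op)
  }

  income <- stats::rlnorm(n, log(spec$income_median[subregion]),
                          spec$income_sdlog)
  um <- spec$urbanization_mean[subregion]
  urbanization <- stats::rbeta(n, um * spec$urbanization_precision,
                               (1 - um) * spec$urbanization_precision)
  gender <- ifelse(stats::runif(n) < spec$prob_male, "male", "female")

  never <- stats::runif(n) < spec$frac_never_called
  times_called <- ifelse(never, 0L, 1L + stats::rpois(n, spec$mean_prior_calls))
  times_attended <- stats::rbinom(n, times_called, spec$prior_adherence_prob)
  pct_prior_adherence <- ifelse(times_called > 0,
                                100 * times_attended / times_called, 0)
  last_result <- ifelse(
    times_attended > 0,
    sample(c("negative", "positive", "inconclusive"), n, replace = TRUE,
           prob = c(0.93, 0.04, 0.03)),
    "none")

  data.frame(
    id = seq_len(n),
    subregion = subregion,
    age = round(age, 1),
    gender = gender,
    income = round(income),
    education_score = round(education_score, 1),
    urbanization = round(urbanization, 3),
    occupation = occupation,
    student_flag = occupation == "student",
    cluster = cluster,
    times_called = as.integer(times_called),
    times_attended = as.integer(times_attended),
    pct_prior_adherence = pct_prior_adherence,
    last_result = last_result,
    state = "not_called",
    next_call_week = 0L,
    call_week = NA_integer_,
    stringsAsFactors = FALSE
  )
}

#' Split agents into training and testing subregions
#'
#' @param agents agent roster (data frame from [generate_population()]).
#' @param train,test character vectors of subregion names; together they
#'   must partition the subregions present (defaults: the published 5/3
#'   geographic split).
#' @return list with elements `train` and `test`, each an agent data frame.
#' @export
split_train_test <- function(agents, train = train_subregions(),
                             test = test_subregions()) {
  overlap <- intersect(train, test)
  if (length(overlap)) {
    stop("train and test subregion sets overlap: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  present <- unique(agents$subregion)
  uncovered <- setdiff(present, c(train, test))
  if (length(uncovered)) {
    stop("subregion(s) in neither set: ", paste(uncovered, collapse = ", "),
         call. = FALSE)
  }
  list(train = agents[agents$subregion %in% train, , drop = FALSE],
       test = agents[agents$subregion %in% test, , drop = FALSE])
}

population_columns <- function() {
  c("id", "subregion", "age", "gender", "income", "education_score",
    "urbanization", "occupation", "student_flag", "cluster", "times_called",
    "times_attended", "pct_prior_adherence", "last_result", "state",
    "next_call_week", "call_week")
}

#' Agent-roster CSV input/output
#'
#' One row per agent with the documented header (see
#' [generate_population()] for column semantics). `read_population()`
#' validates the schema and reports missing or unexpected columns.
#' `read_population(write_population(agents, f))` returns the roster
#' unchanged.
#'
#' @param agents agent data frame.
#' @param path CSV file path.
#' @return `write_population()` returns `path` invisibly;
#'   `read_population()` returns the agent data frame.
#' @export
write_population <- function(agents, path) {
  missing <- setdiff(population_columns(), names(agents))
  if (length(missing)) {
    stop("roster lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(agents[population_columns()], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  agents <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(population_columns(), names(agents))
  extra <- setdiff(names(agents), population_columns())
  if (length(missing) || length(extra)) {
    stop("roster schema mismatch",
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ",
                                   paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  agents$student_flag <- as.logical(agents$student_flag)
  agents$cluster <- as.integer(agents$cluster)
  agents$times_called <- as.integer(agents$times_called)
  agents$times_attended <- as.integer(agents$times_attended)
  agents$next_call_week <- as.integer(agents$next_call_week)
  agents$call_week <- as.integer(agents$call_week)
  agents
}
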