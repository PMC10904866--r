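#' Hierarchical run configuration
#'
#' A run is configured from one YAML file with top-level sections
#' `population`, `screening`, `decision`, `scenarios`, plus `seed` and
#' `output_dir`. Every field is optional: unspecified fields take the
#' package defaults, which reproduce the documented screening-strategy
#' parameters (52-week interval, sensitivity 0.96, specificity 0.94,
#' outcome probabilities 0.04/0.93/0.03, 4-week notice, 10-minute wait,
#' 10 cycles, 5 replicates, 10,000 agents). Unknown keys produce a warning,
#' not an error; out-of-range values produce a section-qualified validation
#' error.
#'
#' Scenario entries are either `preset: <name>` (see [scenario_preset()]) or
#' a custom block with `name`, `action` (`set`/`add`/`multiply`), `amount`
#' and a `where` list of conditions, each with `field`, `op` (one of `==`,
#' `!=`, `<`, `<=`, `>`, `>=`, `in`) and `value`; conditions are combined
#' with AND.
#'
#' @param path YAML file path; `NULL` gives the pure defaults.
#' @return list of class `run_config` with elements `population`
#'   ([population_spec()]), `screening` ([screening_config()]), `decision`
#'   ([decision_config()]), `scenarios` (list of [scenario()]s), `seed`,
#'   `output_dir`.
#' @export
load_config <- function(path = NULL) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()  # empty file -> all defaults
  }
  known <- c("population", "screening", "decision", "scenarios", "seed",
             "output_dir")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    warning("ignoring unknown config key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- list(
    population = build_section(population_spec, raw$population, "population",
                               vector_args = c("shares", "income_median",
                                               "urbanization_mean")),
    screening = build_section(screening_config, raw$screening, "screening"),
    decision = build_section(decision_config, raw$decision, "decision"),
    scenarios = lapply(raw$scenarios %||% list(), build_scenario),
    seed = raw$seed %||% 1L,
    output_dir = raw$output_dir %||% "results"
  )
  structure(cfg, class = "run_config")
}

#' @rdname load_config
#' @export
default_config <- function() load_config(NULL)

# call a config-section constructor with the supplied overrides
build_section <- function(constructor, supplied, section,
                          vector_args = character(0)) {
  supplied <- supplied %||% list()
  legal <- names(formals(constructor))
  unknown <- setdiff(names(supplied), legal)
  if (length(unknown)) {
    warning("ignoring unknown ", section, " key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
    supplied <- supplied[intersect(names(supplied), legal)]
  }
  for (v in intersect(vector_args, names(supplied))) {
    supplied[[v]] <- unlist(supplied[[v]])
  }
  do.call(constructor, supplied)
}

build_scenario <- function(entry) {
  if (inherits(entry, "scenario")) return(entry)
  if (is.character(entry) && length(entry) == 1L) {
    return(scenario_preset(entry))
  }
  if (!is.null(entry$preset)) return(scenario_preset(entry$preset))
  for (f in c("name", "action", "amount", "where")) {
    if (is.null(entry[[f]])) {
      stop_config("scenario entry needs '", f, "' (or a 'preset')")
    }
  }
  conditions <- entry$where
  selector <- function(agents) {
    keep <- rep(TRUE, nrow(agents))
    for (cond in conditions) {
      x <- agents[[cond$field]]
      if (is.null(x)) stop_config("scenario condition on unknown field '",
                                  cond$field, "'")
      keep <- keep & switch(cond$op,
        "==" = x == cond$value, "!=" = x != cond$value,
        "<" = x < cond$value, "<=" = x <= cond$value,
        ">" = x > cond$value, ">=" = x >= cond$value,
        "in" = x %in% unlist(cond$value),
        stop_config("unknown scenario operator '", cond$op, "'"))
    }
    keep
  }
  scenario(entry$name, selector, entry$action, entry$amount)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  print(x$population); print(x$screening); print(x$decision)
  cat(sprintf("  %d scenario(s), seed %s, output '%s'\n",
              length(x$scenarios), format(x$seed), x$output_dir))
  invisible(x)
}
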