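#' Default fuzzy decision components
#'
#' Builds the three Mamdani components of the individual adherence decision —
#' access barriers, knowledge of the disease, and quality/strategy of the
#' screening program — with their published membership parameterizations:
#'
#' * access barriers: age (linear easy/difficult over \[0, 100\] years),
#'   income (difficult = gaussian at 50,000 EUR/yr, sd 17,000; easy = max of
#'   gaussians at 0 and 100,000, sd 17,000), screening-location difficulty
#'   score (linear on \[0, 100\]), degree of urbanization (difficult =
#'   gaussian at 0.3, sd 0.1; easy = max of gaussians at 0 and 0.5, sd 0.1);
#' * knowledge of the disease: age (high = gaussian at 65 yr, sd 30; low =
#'   max of gaussians at 18 and 100, sd 30), educational-qualification score
#'   (linear on \[0, 100\]), percent prior adherence (linear on \[0, 100\]);
#' * program quality: reminder-intensity score (linear on \[0, 100\]),
#'   waiting time (linear on \[0, 500\] minutes), call-notice lead time
#'   (high = gaussian at 4 weeks, sd 2; low = max of gaussians at 0 and 8,
#'   sd 2, on \[0, 12\] weeks).
#'
#' Each component's rule base is regenerated from the at-least-half template
#' via [generate_majority_rules()] (16 + 8 + 8 = 32 rules). All components
#' share the output variable "adherence propensity" on \[0, 100\] with terms
#' strong (line through (0,0),(100,1)) and weak (line through (0,1),(100,0)).
#'
#' @return named list of three [fuzzy_component()]s:
#'   `access_barriers`, `disease_knowledge`, `program_quality`.
#' @export
default_fuzzy_components <- function() {
  out <- propensity_output()

  # --- access barriers -------------------------------------------------
  b1 <- fuzzy_variable("age", c(0, 100), units = "years", terms = list(
    difficult = mf_linear(0, 1, 100, 0, c(0, 100)),
    easy      = mf_linear(0, 0, 100, 1, c(0, 100))))
  b2 <- fuzzy_variable("income", c(0, 100000), units = "EUR/year", terms = list(
    difficult = mf_gaussian(50000, 17000, c(0, 100000)),
    easy      = mf_gaussian_max(0, 100000, 17000, c(0, 100000))))
  b3 <- fuzzy_variable("location_score", c(0, 100), units = "score", terms = list(
    difficult = mf_linear(0, 0, 100, 1, c(0, 100)),
    easy      = mf_linear(0, 1, 100, 0, c(0, 100))))
  b4 <- fuzzy_variable("urbanization", c(0, 1), units = "degree", terms = list(
    difficult = mf_gaussian(0.3, 0.1, c(0, 1)),
    easy      = mf_gaussian_max(0, 0.5, 0.1, c(0, 1))))
  barriers_fav <- c(age = "easy", income = "easy",
                    location_score = "easy", urbanization = "easy")
  barriers <- fuzzy_component(
    "access_barriers", list(b1, b2, b3, b4), out,
    generate_majority_rules(list(b1, b2, b3, b4), barriers_fav))

  # --- knowledge of the disease ---------------------------------------
  c1 <- fuzzy_variable("age", c(0, 100), units = "years", terms = list(
    high = mf_gaussian(65, 30, c(0, 100)),
    low  = mf_gaussian_max(18, 100, 30, c(0, 100))))
  c2 <- fuzzy_variable("education_score", c(0, 100), units = "score", terms = list(
    high = mf_linear(0, 0, 100, 1, c(0, 100)),
    low  = mf_linear(0, 1, 100, 0, c(0, 100))))
  c3 <- fuzzy_variable("pct_prior_adherence", c(0, 100), units = "%", terms = list(
    high = mf_linear(0, 0, 100, 1, c(0, 100)),
    low  = mf_linear(0, 1, 100, 0, c(0, 100))))
  knowledge_fav <- c(age = "high", education_score = "high",
                     pct_prior_adherence = "high")
  knowledge <- fuzzy_component(
    "disease_knowledge", list(c1, c2, c3), out,
    generate_majority_rules(list(c1, c2, c3), knowledge_fav))

  # --- quality / strategy of the screening program --------------------
  e1 <- fuzzy_variable("reminder_score", c(0, 100), units = "score", terms = list(
    high = mf_linear(0, 0, 100, 1, c(0, 100)),
    low  = mf_linear(0, 1, 100, 0, c(0, 100))))
  e2 <- fuzzy_variable("waiting_time", c(0, 500), units = "minutes", terms = list(
    high = mf_linear(0, 1, 500, 0, c(0, 500)),
    low  = mf_linear(0, 0, 500, 1, c(0, 500))))
  e3 <- fuzzy_variable("notice_weeks", c(0, 12), units = "weeks", terms = list(
    high = mf_gaussian(4, 2, c(0, 12)),
    low  = mf_gaussian_max(0, 8, 2, c(0, 12))))
  quality_fav <- c(reminder_score = "high", waiting_time = "high",
                   notice_weeks = "high")
  quality <- fuzzy_component(
    "program_quality", list(e1, e2, e3), out,
    generate_majority_rules(list(e1, e2, e3), quality_fav))

  list(access_barriers = barriers, disease_knowledge = knowledge,
       program_quality = quality)
}

propensity_output <- function() {
  fuzzy_variable("propensity", c(0, 100), units = "score", terms = list(
    strong = mf_linear(0, 0, 100, 1, c(0, 100)),
    weak   = mf_linear(0, 1, 100, 0, c(0, 100))))
}

#' Serialize fuzzy components to and from JSON
#'
#' The full definition (variables, membership parameters, rule base) is
#' written as structured JSON so the shipped 32-rule base can be inspected
#' and edited. `read_fuzzy_components(write_fuzzy_components(x, f))`
#' reproduces `x`.
#'
#' @param components named list of [fuzzy_component()]s.
#' @param path file path.
#' @return `write_fuzzy_components()` returns `path` invisibly;
#'   `read_fuzzy_components()` returns the component list.
#' @export
write_fuzzy_components <- function(components, path) {
  enc_mf <- function(mf) list(kind = mf$kind, params = mf$params,
                              domain = mf$domain)
  enc_var <- function(v) list(name = v$name, domain = v$domain,
                              units = v$units, terms = lapply(v$terms, enc_mf))
  enc_comp <- function(cp) list(
    name = cp$name,
    inputs = lapply(unname(cp$inputs), enc_var),
    output = enc_var(cp$output),
    rules = lapply(cp$rules, function(r) list(
      antecedents = as.list(r$antecedents), consequent = r$consequent)))
  json <- jsonlite::toJSON(lapply(unname(components), enc_comp),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_fuzzy_components
#' @export
read_fuzzy_components <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  dec_mf <- function(m) {
    d <- as.numeric(unlist(m$domain))
    p <- m$params
    switch(m$kind,
      linear_two_point = mf_linear(p$x0, p$y0, p$x1, p$y1, d),
      gaussian = mf_gaussian(p$center, p$sd, d),
      max_of_gaussians = mf_gaussian_max(p$center1, p$center2, p$sd, d),
      stop_config("unknown membership kind: ", m$kind))
  }
  dec_var <- function(v) fuzzy_variable(v$name, as.numeric(unlist(v$domain)),
                                        lapply(v$terms, dec_mf),
                                        units = v$units %||% "")
  comps <- lapply(raw, function(cp) {
    fuzzy_component(cp$name,
                    lapply(cp$inputs, dec_var),
                    dec_var(cp$output),
                    lapply(cp$rules, function(r) {
                      fuzzy_rule(unlist(r$antecedents), r$consequent)
                    }))
  })
  stats::setNames(comps, vapply(comps, function(cp) cp$name, character(1)))
}

#' List the generated rule base
#'
#' Returns (and optionally prints) the 32 IF-THEN rules of the default
#' three-component system, or of any supplied component list, in readable
#' form for audit.
#'
#' @param components named list of [fuzzy_component()]s; defaults to
#'   [default_fuzzy_components()].
#' @param print print the rules to the console.
#' @return data frame with columns `component`, `rule` (text) and
#'   `consequent`, invisibly when `print = TRUE`.
#' @export
list_rules <- function(components = default_fuzzy_components(), print = TRUE) {
  rows <- do.call(rbind, lapply(components, function(cp) {
    data.frame(component = cp$name,
               rule = vapply(cp$rules, format, character(1)),
               consequent = vapply(cp$rules, function(r) r$consequent,
                                   character(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  if (print) {
    for (cp in names(components)) {
      sub <- rows[rows$component == cp, ]
      cat(sprintf("%s (%d rules)\n", cp, nrow(sub)))
      cat(sprintf("  %2d. %s\n", seq_len(nrow(sub)), sub$rule), sep = "")
    }
    return(invisible(rows))
  }
  rows
}
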