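#' Linguistic variables, rules, and components of the Mamdani system
#'
#' A `fuzzy_variable` is a named crisp quantity with a closed domain and
#' exactly two linguistic terms (the decision model uses a binary linguistic
#' partition throughout, e.g. "easy"/"difficult" or "high"/"low"), each
#' described by a membership function on the variable's domain.
#'
#' @param name variable identifier; also the key under which crisp inputs
#'   are looked up.
#' @param domain closed interval `c(lo, hi)` in variable units.
#' @param terms named list of exactly two [membership functions][mf_linear],
#'   keyed by linguistic label.
#' @param units optional unit string, for printing.
#' @return A `fuzzy_variable`.
#' @export
fuzzy_variable <- function(name, domain, terms, units = "") {
  stopifnot(is.character(name), length(name) == 1L, is.list(terms))
  if (length(terms) != 2L || is.null(names(terms)) || any(names(terms) == "")) {
    stop_config("variable '", name, "' must have exactly two named terms")
  }
  for (lab in names(terms)) {
    mf <- terms[[lab]]
    if (!inherits(mf, "membership_function")) {
      stop_config("term '", lab, "' of '", name, "' is not a membership function")
    }
    if (!isTRUE(all.equal(mf$domain, as.numeric(domain)))) {
      stop_config("term '", lab, "' of '", name,
                  "' has a domain different from the variable domain")
    }
  }
  structure(list(name = name, domain = as.numeric(domain),
                 terms = terms, units = units),
            class = "fuzzy_variable")
}

#' @rdname fuzzy_variable
#' @param antecedents named character vector mapping input-variable name to
#'   the linguistic label it must carry; combined with the minimum t-norm.
#' @param consequent linguistic label of the output variable.
#' @export
fuzzy_rule <- function(antecedents, consequent) {
  stopifnot(is.character(antecedents), length(antecedents) >= 1L,
            !is.null(names(antecedents)),
            is.character(consequent), length(consequent) == 1L)
  structure(list(antecedents = antecedents, consequent = consequent),
            class = "fuzzy_rule")
}

#' @rdname fuzzy_variable
#' @param inputs list of `fuzzy_variable` inputs.
#' @param output the output `fuzzy_variable` (adherence propensity).
#' @param rules list of `fuzzy_rule`s over the inputs.
#' @export
fuzzy_component <- function(name, inputs, output, rules) {
  stopifnot(is.list(inputs), is.list(rules),
            inherits(output, "fuzzy_variable"))
  in_names <- vapply(inputs, function(v) v$name, character(1))
  names(inputs) <- in_names
  if (length(rules) == 0L) stop_config("component '", name, "' has an empty rule base")
  for (r in rules) {
    bad <- setdiff(names(r$antecedents), in_names)
    if (length(bad)) {
      stop_config("rule references undeclared variable(s): ",
                  paste(bad, collapse = ", "))
    }
    for (v in names(r$antecedents)) {
      if (!r$antecedents[[v]] %in% names(inputs[[v]]$terms)) {
        stop_config("rule references unknown term '", r$antecedents[[v]],
                    "' of variable '", v, "'")
      }
    }
    if (!r$consequent %in% names(output$terms)) {
      stop_config("rule consequent '", r$consequent, "' is not a term of '",
                  output$name, "'")
    }
  }
  structure(list(name = name, inputs = inputs, output = output, rules = rules),
            class = "fuzzy_component")
}

#' @export
print.fuzzy_variable <- function(x, ...) {
  cat(sprintf("<fuzzy_variable> %s on [%g, %g]%s; terms: %s\n", x$name,
              x$domain[1], x$domain[2],
              if (nzchar(x$units)) paste0(" ", x$units) else "",
              paste(names(x$terms), collapse = ", ")))
  invisible(x)
}

#' @export
print.fuzzy_component <- function(x, ...) {
  cat(sprintf("<fuzzy_component> %s: %d inputs (%s), %d rules\n", x$name,
              length(x$inputs), paste(names(x$inputs), collapse = ", "),
              length(x$rules)))
  invisible(x)
}

#' @export
format.fuzzy_rule <- function(x, ...) {
  ants <- paste(sprintf("%s is %s", names(x$antecedents), x$antecedents),
                collapse = " AND ")
  sprintf("IF %s THEN propensity is %s", ants, x$consequent)
}

#' @export
print.fuzzy_rule <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Fire a single fuzzy rule
#'
#' Computes the rule activation as the minimum (the Mamdani AND) of the
#' antecedent term memberships at the supplied crisp inputs.
#'
#' @param rule a [fuzzy_rule()].
#' @param variables named list of [fuzzy_variable()]s covering the
#'   antecedents.
#' @param crisp_inputs named list/vector of crisp values, one per antecedent
#'   variable.
#' @return activation degree in \[0, 1\].
#' @export
fire_rule <- function(rule, variables, crisp_inputs) {
  stopifnot(inherits(rule, "fuzzy_rule"))
  missing <- setdiff(names(rule$antecedents), names(crisp_inputs))
  if (length(missing)) {
    stop("missing crisp input(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  degrees <- vapply(names(rule$antecedents), function(v) {
    mf <- variables[[v]]$terms[[rule$antecedents[[v]]]]
    evaluate_membership(mf, as.numeric(crisp_inputs[[v]]), warn_clamp = FALSE)
  }, numeric(1))
  min(degrees)
}

#' Generate the at-least-half rule base
#'
#' Enumerates one rule per combination of the binary linguistic labels of the
#' input variables (2^n rules). The consequent is "strong" adherence
#' propensity when at least half of the inputs (ceiling of n/2) carry their
#' favorable label, and "weak" otherwise. With 4 inputs this yields 16 rules
#' and with 3 inputs 8 rules, i.e. the 16 + 8 + 8 = 32 rules of the full
#' three-component system.
#'
#' @param inputs list of binary-term [fuzzy_variable()]s.
#' @param favorable_labels named character vector mapping each variable name
#'   to its favorable label (e.g. `c(age = "easy")`).
#' @param strong,weak consequent labels for the output variable.
#' @return list of [fuzzy_rule()]s, length `2^length(inputs)`.
#' @export
generate_majority_rules <- function(inputs, favorable_labels,
                                    strong = "strong", weak = "weak") {
  in_names <- vapply(inputs, function(v) v$name, character(1))
  names(inputs) <- in_names
  if (!setequal(names(favorable_labels), in_names)) {
    stop_config("favorable_labels must name every input variable exactly once")
  }
  label_sets <- lapply(inputs, function(v) {
    if (length(v$terms) != 2L) {
      stop_config("variable '", v$name, "' does not have exactly two terms")
    }
    names(v$terms)
  })
  combos <- expand.grid(label_sets, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  need <- ceiling(length(inputs) / 2)
  lapply(seq_len(nrow(combos)), function(i) {
    labels <- unlist(combos[i, , drop = TRUE])
    names(labels) <- in_names
    n_fav <- sum(labels == favorable_labels[in_names])
    fuzzy_rule(labels, if (n_fav >= need) strong else weak)
  })
}

#' Mamdani inference with centre-of-gravity defuzzification
#'
#' Runs the full Mamdani pipeline for one component: each rule's activation
#' (minimum over antecedent memberships) truncates (clips) its consequent
#' term; the truncated sets are aggregated by pointwise maximum over a
#' discretized output domain; the crisp score is the centroid of the
#' aggregate, computed by the trapezoid rule on `n_grid` evenly spaced
#' points. An identically-zero aggregate returns the domain midpoint.
#'
#' @param component a [fuzzy_component()].
#' @param crisp_inputs named list/vector with one crisp value per input
#'   variable of the component.
#' @param n_grid number of discretization points (default 1001).
#' @return crisp score within the output domain (default \[0, 100\]).
#' @export
defuzzify_component <- function(component, crisp_inputs, n_grid = 1001L) {
  stopifnot(inherits(component, "fuzzy_component"))
  acts <- vapply(component$rules, fire_rule, numeric(1),
                 variables = component$inputs, crisp_inputs = crisp_inputs)
  out <- component$output
  grid <- seq(out$domain[1], out$domain[2], length.out = n_grid)
  term_mu <- lapply(out$terms, evaluate_membership, x = grid, warn_clamp = FALSE)
  agg <- numeric(n_grid)
  for (i in seq_along(component$rules)) {
    mu <- pmin(acts[i], term_mu[[component$rules[[i]]$consequent]])
    agg <- pmax(agg, mu)
  }
  centroid_trapezoid(grid, agg)
}

# trapezoid-rule centroid with midpoint fallback for a zero aggregate
centroid_trapezoid <- function(grid, mu) {
  n <- length(grid)
  w <- rep(1, n); w[c(1, n)] <- 0.5
  den <- sum(w * mu)
  if (den <= .Machine$double.eps * n) {
    return((grid[1] + grid[n]) / 2)
  }
  sum(w * grid * mu) / den
}

#' Evaluate one component for many agents at once
#'
#' Vectorized equivalent of [defuzzify_component()]: crisp inputs are given
#' as equal-length numeric vectors and one score is returned per position.
#' Exploits the binary consequent: the max-aggregate of clipped "strong" and
#' "weak" sets only depends on the maximum activation per consequent label.
#'
#' @param component a [fuzzy_component()].
#' @param crisp_inputs named list of equal-length numeric vectors, one per
#'   input variable.
#' @inheritParams defuzzify_component
#' @return numeric vector of scores, one per input position.
#' @export
component_scores <- function(component, crisp_inputs, n_grid = 1001L) {
  in_names <- names(component$inputs)
  missing <- setdiff(in_names, names(crisp_inputs))
  if (length(missing)) {
    stop("missing crisp input(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n <- max(lengths(crisp_inputs[in_names]))
  # membership of every (variable, term) at the n crisp values
  # (scalar inputs, e.g. program-level settings, are recycled)
  mem <- lapply(component$inputs, function(v) {
    x <- rep_len(as.numeric(crisp_inputs[[v$name]]), n)
    lapply(v$terms, evaluate_membership, x = x, warn_clamp = FALSE)
  })
  out_labels <- names(component$output$terms)
  max_act <- stats::setNames(rep(list(numeric(n)), length(out_labels)), out_labels)
  for (r in component$rules) {
    act <- rep(1, n)
    for (v in names(r$antecedents)) {
      act <- pmin(act, mem[[v]][[r$antecedents[[v]]]])
    }
    max_act[[r$consequent]] <- pmax(max_act[[r$consequent]], act)
  }
  out <- component$output
  grid <- seq(out$domain[1], out$domain[2], length.out = n_grid)
  term_mu <- lapply(out$terms, evaluate_membership, x = grid, warn_clamp = FALSE)
  num <- den <- numeric(n)
  for (i in seq_len(n_grid)) {
    w <- if (i == 1L || i == n_grid) 0.5 else 1
    mu_i <- numeric(n)
    for (lab in out_labels) {
      mu_i <- pmax(mu_i, pmin(max_act[[lab]], term_mu[[lab]][i]))
    }
    num <- num + w * grid[i] * mu_i
    den <- den + w * mu_i
  }
  mid <- (out$domain[1] + out$domain[2]) / 2
  ifelse(den <= .Machine$double.eps * n_grid, mid, num / den)
}
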