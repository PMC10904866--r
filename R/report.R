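#' Reference regional adherence rates
#'
#' Published real adherence rates (%) of the eight subregions, shipped as a
#' comparison-only fixture for report flagging. These are observational
#' reference values, not generator inputs: the synthetic population is not
#' calibrated to reproduce them.
#'
#' @return data frame with columns `subregion` and `real_rate`.
#' @export
reference_adherence <- function() {
  path <- system.file("extdata", "reference_adherence.csv",
                      package = "drscreensim", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Summarize replicate runs
#'
#' Per-subregion (and overall) mean and sample standard deviation of the
#' final cumulative adherence rates across replicates, with Student-t
#' confidence intervals at 95% and 99% (n - 1 degrees of freedom). When a
#' reference table is supplied, the report adds the reference rate, the
#' difference (mean - reference) and flags marking reference values falling
#' outside each interval.
#'
#' @param results list of [run_result][run_simulation] objects (>= 2 for
#'   confidence intervals; with a single replicate the intervals are `NA`
#'   with a warning).
#' @param reference optional data frame with columns `subregion` and
#'   `real_rate` (see [reference_adherence()]).
#' @return data frame of class `adherence_report` with columns `subregion`,
#'   `n_replicates`, `mean`, `sd`, `ci95_lo`, `ci95_hi`, `ci99_lo`,
#'   `ci99_hi`, and, with a reference, `real_rate`, `difference`,
#'   `outside_ci95`, `outside_ci99`.
#' @export
summarize_replicates <- function(results, reference = NULL) {
  if (inherits(results, "run_result")) results <- list(results)
  stopifnot(length(results) >= 1)
  rates <- do.call(rbind, lapply(results, function(r) {
    tab <- adherence_rates(r, by = "subregion")
    tab$replicate <- r$replicate
    tab
  }))
  report <- replicate_rate_report(rates)
  if (!is.null(reference)) {
    report <- merge(report, reference, by = "subregion", all.x = TRUE,
                    sort = FALSE)
    report$difference <- report$mean - report$real_rate
    report$outside_ci95 <- report$real_rate < report$ci95_lo |
      report$real_rate > report$ci95_hi
    report$outside_ci99 <- report$real_rate < report$ci99_lo |
      report$real_rate > report$ci99_hi
  }
  report <- report[order(report$subregion != "overall", report$subregion), ,
                   drop = FALSE]
  rownames(report) <- NULL
  class(report) <- c("adherence_report", "data.frame")
  report
}

# mean/sd/t-CIs from a long table of per-replicate subregion rates
replicate_rate_report <- function(rates) {
  groups <- split(rates$rate, rates$subregion)
  rows <- lapply(names(groups), function(g) {
    x <- groups[[g]]
    n <- length(x)
    m <- mean(x)
    s <- if (n >= 2) stats::sd(x) else NA_real_
    ci <- function(level) {
      if (n < 2) return(c(NA_real_, NA_real_))
      half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * s / sqrt(n)
      c(m - half, m + half)
    }
    c95 <- ci(0.95); c99 <- ci(0.99)
    data.frame(subregion = g, n_replicates = n, mean = m, sd = s,
               ci95_lo = c95[1], ci95_hi = c95[2],
               ci99_lo = c99[1], ci99_hi = c99[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$n_replicates < 2)) {
    warning("fewer than 2 replicates: confidence intervals omitted",
            call. = FALSE)
  }
  out
}

#' @export
print.adherence_report <- function(x, digits = 2, ...) {
  cat("Adherence report (% attended of calls issued)\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Weekly convergence trace
#'
#' Cumulative adherence rate per subregion (and overall) after each week
#' with at least one resolved decision, mirroring the way the simulator's
#' global adherence rises sharply in the first cycles and then converges.
#'
#' @param result a [run_result][run_simulation].
#' @return data frame with columns `week`, `subregion`, `calls`, `attended`,
#'   `rate` (cumulative, percent).
#' @export
convergence_trace <- function(result) {
  ev <- result$events
  if (!nrow(ev)) {
    return(data.frame(week = integer(0), subregion = character(0),
                      calls = integer(0), attended = integer(0),
                      rate = numeric(0)))
  }
  ev$overall <- "overall"
  trace_for <- function(region_col) {
    agg <- stats::aggregate(
      list(calls = rep(1L, nrow(ev)),
           attended = as.integer(ev$event == "attended")),
      by = list(subregion = ev[[region_col]], week = ev$week), FUN = sum)
    agg <- agg[order(agg$subregion, agg$week), ]
    agg$calls <- stats::ave(agg$calls, agg$subregion, FUN = cumsum)
    agg$attended <- stats::ave(agg$attended, agg$subregion, FUN = cumsum)
    agg
  }
  out <- rbind(trace_for("subregion"), trace_for("overall"))
  out$rate <- 100 * out$attended / out$calls
  out[c("week", "subregion", "calls", "attended", "rate")]
}

#' Plot a convergence trace
#'
#' Simple line plot of the cumulative adherence trajectories produced by
#' [convergence_trace()], one line per subregion.
#'
#' @param trace data frame from [convergence_trace()].
#' @param ... passed to [graphics::matplot()].
#' @return the trace, invisibly.
#' @export
plot_convergence <- function(trace, ...) {
  regions <- unique(trace$subregion)
  weeks <- sort(unique(trace$week))
  m <- sapply(regions, function(g) {
    trace$rate[trace$subregion == g][match(weeks,
                                           trace$week[trace$subregion == g])]
  })
  graphics::matplot(weeks, m, type = "l", lty = 1,
                    col = grDevices::hcl.colors(length(regions), "Dark 3"),
                    xlab = "week", ylab = "cumulative adherence (%)", ...)
  graphics::legend("bottomright", legend = regions, lty = 1, cex = 0.7,
                   col = grDevices::hcl.colors(length(regions), "Dark 3"))
  invisible(trace)
}

#' Stacked subgroup report
#'
#' Binds adherence reports of several subgroup runs (e.g. all agents,
#' cluster 1, cluster 2, train, test) into one table with a leading
#' `subgroup` column, mirroring the layout of the published results table.
#'
#' @param results_by_subgroup named list; each element a list of
#'   [run_result][run_simulation] objects for one subgroup.
#' @param reference optional reference table (see [summarize_replicates()]).
#' @return data frame of class `adherence_report` with a `subgroup` column.
#' @export
subgroup_report <- function(results_by_subgroup, reference = NULL) {
  stopifnot(is.list(results_by_subgroup), !is.null(names(results_by_subgroup)))
  parts <- lapply(names(results_by_subgroup), function(g) {
    rep <- summarize_replicates(results_by_subgroup[[g]], reference)
    cbind(subgroup = g, as.data.frame(rep))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  class(out) <- c("adherence_report", "data.frame")
  out
}
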