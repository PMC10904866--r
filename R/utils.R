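# internal helpers

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(
    class = c("drscreensim_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# clamp a crisp input into a variable domain, warning once per call if needed
clamp_to_domain <- function(x, domain, what = "input") {
  out <- clamp(x, domain[1], domain[2])
  n_out <- sum(x < domain[1] | x > domain[2], na.rm = TRUE)
  if (n_out > 0) {
    warning(sprintf("%d %s value(s) outside [%g, %g]; clamped", n_out, what,
                    domain[1], domain[2]), call. = FALSE)
  }
  out
}
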