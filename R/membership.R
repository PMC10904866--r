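#' Fuzzy membership functions
#'
#' Constructors for the three membership-function shapes used by the
#' screening-adherence decision components: a straight line through two
#' anchor points (clamped to \[0, 1\]), a peak-normalized Gaussian, and the
#' pointwise maximum of two Gaussians sharing a spread. The Gaussian shapes
#' are fuzzy memberships normalized to peak value 1, not probability
#' densities.
#'
#' @param x0,y0,x1,y1 anchor points of the linear membership, in variable
#'   units (`x`) and membership degree (`y`).
#' @param center,center1,center2 Gaussian centre(s), in variable units.
#' @param sd shared Gaussian spread (same units as the variable); must be
#'   positive.
#' @param domain closed interval `c(lo, hi)` over which the parent variable
#'   is defined.
#' @return An object of class `membership_function`.
#' @examples
#' mf <- mf_linear(0, 1, 100, 0, domain = c(0, 100))
#' evaluate_membership(mf, 50) # 0.5
#' @seealso [evaluate_membership()], [fuzzy_variable()]
#' @export
mf_linear <- function(x0, y0, x1, y1, domain) {
  stopifnot(is_scalar_number(x0), is_scalar_number(x1),
            is_scalar_number(y0), is_scalar_number(y1))
  if (x0 == x1) stop_config("linear membership anchors must have distinct x")
  new_membership_function("linear_two_point",
                          list(x0 = x0, y0 = y0, x1 = x1, y1 = y1), domain)
}

#' @rdname mf_linear
#' @export
mf_gaussian <- function(center, sd, domain) {
  if (!is_scalar_number(sd) || sd <= 0) {
    stop_config("gaussian membership requires sd > 0")
  }
  new_membership_function("gaussian", list(center = center, sd = sd), domain)
}

#' @rdname mf_linear
#' @export
mf_gaussian_max <- function(center1, center2, sd, domain) {
  if (!is_scalar_number(sd) || sd <= 0) {
    stop_config("gaussian membership requires sd > 0")
  }
  new_membership_function("max_of_gaussians",
                          list(center1 = center1, center2 = center2, sd = sd),
                          domain)
}

new_membership_function <- function(kind, params, domain) {
  if (!is.numeric(domain) || length(domain) != 2L || domain[1] >= domain[2]) {
    stop_config("domain must be c(lo, hi) with lo < hi")
  }
  structure(list(kind = kind, params = params, domain = as.numeric(domain)),
            class = "membership_function")
}

#' Evaluate a membership function
#'
#' Returns the membership degree of crisp values `x`, always in \[0, 1\].
#' Values outside the function's domain are clamped to it (with a warning).
#'
#' @param mf a [mf_linear()], [mf_gaussian()] or [mf_gaussian_max()] object.
#' @param x numeric vector of crisp values in variable units.
#' @param warn_clamp warn when values fall outside the domain.
#' @return numeric vector of degrees in \[0, 1\], same length as `x`.
#' @export
evaluate_membership <- function(mf, x, warn_clamp = TRUE) {
  stopifnot(inherits(mf, "membership_function"), is.numeric(x))
  x <- if (warn_clamp) clamp_to_domain(x, mf$domain) else clamp(x, mf$domain[1], mf$domain[2])
  p <- mf$params
  switch(mf$kind,
    linear_two_point = {
      slope <- (p$y1 - p$y0) / (p$x1 - p$x0)
      clamp(p$y0 + slope * (x - p$x0), 0, 1)
    },
    gaussian = gauss_bump(x, p$center, p$sd),
    max_of_gaussians = pmax(gauss_bump(x, p$center1, p$sd),
                            gauss_bump(x, p$center2, p$sd)),
    stop_config("unknown membership kind: ", mf$kind)
  )
}

# peak-normalized gaussian bump, value 1 at the centre
gauss_bump <- function(x, center, sd) exp(-((x - center)^2) / (2 * sd^2))

#' @export
print.membership_function <- function(x, ...) {
  p <- x$params
  desc <- switch(x$kind,
    linear_two_point = sprintf("line through (%g, %g), (%g, %g)",
                               p$x0, p$y0, p$x1, p$y1),
    gaussian = sprintf("gaussian(center = %g, sd = %g)", p$center, p$sd),
    max_of_gaussians = sprintf("max of gaussians(centers = %g, %g; sd = %g)",
                               p$center1, p$center2, p$sd)
  )
  cat(sprintf("<membership_function> %s on [%g, %g]\n",
              desc, x$domain[1], x$domain[2]))
  invisible(x)
}
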