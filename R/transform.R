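#' Bounded tanh transform for mechanistic parameters
#'
#' Mechanistic rate constants in biochemical models are positive, span orders
#' of magnitude, and usually come with biologically motivated lower and upper
#' bounds. To use unconstrained gradient-based optimisers we estimate each
#' parameter on an unbounded coordinate \eqn{\rho} and map it into its bounds
#' with a scaled hyperbolic tangent,
#' \deqn{\theta = b_l + \frac{\tanh(\rho - a) + 1}{2}\,(b_u - b_l),}
#' which between the bounds behaves like a logarithmic reparameterisation.
#' The offset \eqn{a} is chosen (see [choose_offset()]) so that \eqn{\rho = 0}
#' maps to \eqn{\theta = 1} whenever the bounds bracket 1, mirroring the
#' anchoring of a log-transform.
#'
#' @param rho Numeric vector of unbounded (transformed) coordinates.
#' @param b_l,b_u Numeric lower/upper bounds, recycled to the length of `rho`.
#'   Must satisfy `b_l < b_u` elementwise.
#' @param a Numeric offset(s), typically from [choose_offset()].
#' @return Numeric vector of parameter values strictly inside `(b_l, b_u)`.
#' @seealso [choose_offset()], [inverse_transform()]
#' @examples
#' a <- choose_offset(0.5, 2)
#' transform_parameter(0, 0.5, 2, a)  # exactly 1
#' @export
transform_parameter <- function(rho, b_l, b_u, a = 0) {
  check_bounds(b_l, b_u)
  b_l + (tanh(rho - a) + 1) / 2 * (b_u - b_l)
}

#' Choose the tanh-transform offset anchoring 1 at rho = 0
#'
#' When the bounds bracket 1, returns the offset `a` for which
#' `transform_parameter(0, b_l, b_u, a) == 1`; otherwise the anchor is
#' unattainable and the midpoint convention `a = 0` is used (so `rho = 0`
#' maps to the bound midpoint).
#'
#' @inheritParams transform_parameter
#' @return Numeric offset vector.
#' @export
choose_offset <- function(b_l, b_u) {
  check_bounds(b_l, b_u)
  n <- max(length(b_l), length(b_u))
  b_l <- rep_len(b_l, n)
  b_u <- rep_len(b_u, n)
  a <- numeric(n)
  ok <- b_l < 1 & b_u > 1
  # tanh(-a) = 2 (1 - b_l) / (b_u - b_l) - 1
  a[ok] <- -atanh(2 * (1 - b_l[ok]) / (b_u[ok] - b_l[ok]) - 1)
  a
}

#' Invert the bounded tanh transform
#'
#' Maps a parameter value strictly inside its bounds back to the unbounded
#' coordinate, `transform_parameter(inverse_transform(theta)) == theta`.
#' Needed to initialise the optimiser from parameter values sampled on the
#' natural scale.
#'
#' @param theta Numeric vector of parameter values, strictly inside the bounds.
#' @inheritParams transform_parameter
#' @return Numeric vector of unbounded coordinates.
#' @export
inverse_transform <- function(theta, b_l, b_u, a = 0) {
  check_bounds(b_l, b_u)
  if (any(theta <= b_l | theta >= b_u)) {
    stop("`theta` must lie strictly inside (b_l, b_u)", call. = FALSE)
  }
  a + atanh(2 * (theta - b_l) / (b_u - b_l) - 1)
}

check_bounds <- function(b_l, b_u) {
  if (any(!is.finite(b_l)) || any(!is.finite(b_u)) || any(b_l >= b_u)) {
    stop("malformed parameter bounds: need finite b_l < b_u", call. = FALSE)
  }
  invisible(TRUE)
}

#' Mechanistic parameter set
#'
#' Bundles named parameter values with their bounds and tanh-transform
#' offsets. The offsets default to the anchoring rule of [choose_offset()].
#' A logical `free` marks which parameters are estimated; fixed parameters
#' keep their reference values during training.
#'
#' @param names Character vector of parameter identifiers.
#' @param values Positive reference/current values (model units).
#' @param b_l,b_u Positive bounds, `b_l < b_u`, recycled to length of `names`.
#' @param a Transform offsets; default anchors 1 where bracketed.
#' @param free Logical vector, which parameters are estimated (default all).
#' @return A `parameter_set` object (also a tibble row-per-parameter view via
#'   [tidy()]).
#' @export
parameter_set <- function(names, values, b_l, b_u, a = NULL, free = TRUE) {
  n <- length(names)
  values <- rep_len(values, n)
  b_l <- rep_len(b_l, n)
  b_u <- rep_len(b_u, n)
  check_bounds(b_l, b_u)
  if (any(values < b_l | values > b_u)) {
    stop("parameter values must lie within their bounds", call. = FALSE)
  }
  if (is.null(a)) a <- choose_offset(b_l, b_u)
  a <- rep_len(a, n)
  free <- rep_len(free, n)
  structure(
    list(names = names, values = setNames(values, names),
         b_l = setNames(b_l, names), b_u = setNames(b_u, names),
         a = setNames(a, names), free = setNames(free, names)),
    class = "parameter_set"
  )
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set> ", sum(x$free), " free / ", length(x$names),
      " parameters\n", sep = "")
  print(tidy(x), ...)
  invisible(x)
}

#' @rdname parameter_set
#' @param x A `parameter_set`.
#' @param ... Unused.
#' @export
tidy.parameter_set <- function(x, ...) {
  tibble::tibble(
    term = x$names, value = unname(x$values),
    b_l = unname(x$b_l), b_u = unname(x$b_u),
    a = unname(x$a), free = unname(x$free),
    rho = unname(inverse_transform(x$values, x$b_l, x$b_u, x$a))
  )
}

# rho coordinates of the free parameters
ps_rho <- function(ps, values = ps$values) {
  inverse_transform(values[ps$free], ps$b_l[ps$free], ps$b_u[ps$free],
                    ps$a[ps$free])
}

# full natural-scale value vector from free-parameter rho coordinates
ps_values <- function(ps, rho_free) {
  v <- ps$values
  v[ps$free] <- transform_parameter(rho_free, ps$b_l[ps$free],
                                    ps$b_u[ps$free], ps$a[ps$free])
  v
}

# d theta / d rho for the free parameters, at rho_free
ps_dvalues <- function(ps, rho_free) {
  t2 <- tanh(rho_free - ps$a[ps$free])^2
  (1 - t2) / 2 * (ps$b_u[ps$free] - ps$b_l[ps$free])
}
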