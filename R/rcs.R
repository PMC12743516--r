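#' Restricted cubic spline basis (3 knots, Harrell truncated-power form)
#'
#' Builds the two-column design used throughout the dose-response machinery:
#' a linear term and a single nonlinear term that is, by construction, exactly
#' linear below the first knot and beyond the last knot. With knots
#' \eqn{t_1 < t_2 < t_3} the nonlinear term is
#' \deqn{b_2(x) = \frac{(x-t_1)_+^3 - (x-t_2)_+^3 (t_3-t_1)/(t_3-t_2)
#'   + (x-t_3)_+^3 (t_2-t_1)/(t_3-t_2)}{(t_3-t_1)^2}.}
#' The same basis is shared by the synthetic survival generator and the
#' Poisson dose-response fit, so "true" and fitted dose effects live in the
#' same coefficient space.
#'
#' @param x numeric vector of doses (min/week).
#' @param knots numeric vector of exactly 3 distinct knot locations.
#' @return numeric matrix with columns `dose` and `nonlin`, one row per
#'   element of `x`, with the knots attached as attribute `"knots"`.
#' @export
#' @examples
#' rcs_basis(c(0, 50, 150, 300), knots = c(20, 90, 200))
rcs_basis <- function(x, knots) {
  if (length(knots) != 3L) stop("exactly 3 knots are required")
  if (anyDuplicated(knots)) stop("knots must be distinct")
  knots <- sort(knots)
  t1 <- knots[1L]; t2 <- knots[2L]; t3 <- knots[3L]
  p3 <- function(u) pmax(u, 0)^3
  b2 <- (p3(x - t1) -
           p3(x - t2) * (t3 - t1) / (t3 - t2) +
           p3(x - t3) * (t2 - t1) / (t3 - t2)) / (t3 - t1)^2
  out <- cbind(dose = x, nonlin = b2)
  attr(out, "knots") <- knots
  out
}

#' Evaluate a dose-effect curve on the shared spline basis
#'
#' @param x doses at which to evaluate.
#' @param coef length-2 coefficient vector (linear, nonlinear term).
#' @param knots the 3 spline knots.
#' @return numeric vector of log-rate contributions, one per dose.
#' @export
rcs_effect <- function(x, coef, knots) {
  if (length(coef) != 2L) stop("coef must have length 2 (linear, nonlinear)")
  drop(rcs_basis(x, knots) %*% coef)
}

#' Least-squares projection of a target curve onto the spline basis
#'
#' Convenience for building designed truths (e.g. a steep-then-flat
#' log-hazard) that the generator and recovery tests can share: returns the
#' basis coefficients whose curve best approximates `y` at doses `x` after
#' removing the intercept.
#'
#' @param x doses; `y` target values of the (log-scale) curve at `x`.
#' @param knots the 3 spline knots.
#' @return list with `coef` (length 2) and `intercept`.
#' @export
rcs_project <- function(x, y, knots) {
  X <- cbind(1, rcs_basis(x, knots))
  beta <- qr.solve(X, y)
  list(coef = beta[2:3], intercept = beta[1L])
}
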