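#' Orthogonal natural-spline basis of a score
#'
#' Builds the three-column design used to test linear, quadratic-like and
#' cubic-like (extreme-of-range) effects of a continuous score. The columns
#' live in the natural cubic spline space with boundary knots at the
#' observed range and interior knots at the 33.3/66.7 percentiles, so every
#' column is linear beyond the boundary knots (no diverging tails). Within
#' that space the columns are defined canonically as the projections of
#' \eqn{x}, \eqn{x^2} and \eqn{x^3}, orthonormalised in that order against
#' the intercept and against each other: order 1 is the (centred, scaled)
#' linear trend, orders 2 and 3 capture the curvature directions the spline
#' space allows, ordered by polynomial degree. Orthogonality removes the
#' collinearity that plagues raw polynomial regression, so each order can be
#' tested on its own.
#'
#' @param x numeric vector (the score); needs at least `df + 2` distinct
#'   values.
#' @param df number of spline effect columns (default 3: linear, quadratic,
#'   cubic).
#' @param interior_quantiles quantiles of `x` at which interior knots are
#'   placed; defaults to terciles for `df = 3`.
#' @return an object of class `spline_basis`: a list with `basis` (an
#'   N x df matrix with unit-norm, mutually orthogonal columns, each
#'   orthogonal to the intercept), `knots`, `boundary_knots` and `x`.
#' @examples
#' b <- natural_spline_basis(rnorm(100))
#' round(crossprod(b$basis), 10)  # identity
#' @export
natural_spline_basis <- function(x, df = 3,
                                 interior_quantiles = seq_len(df - 1) / df) {
  if (!is.numeric(x)) stop("x must be numeric")
  ux <- unique(x[is.finite(x)])
  if (length(ux) < df + 2)
    stop("need at least ", df + 2, " distinct finite values to place knots")
  bk <- range(x, na.rm = TRUE)
  ik <- unname(stats::quantile(x, interior_quantiles, na.rm = TRUE, type = 7))
  ik <- ik[ik > bk[1] & ik < bk[2]]
  ns_cols <- splines::ns(x, knots = ik, Boundary.knots = bk)
  n <- length(x)
  # orthonormal basis of the natural-spline function space incl. intercept
  S <- qr.Q(qr(cbind(1, ns_cols)))
  z <- (x - mean(x)) / stats::sd(x)          # conditioning for the powers
  B <- matrix(0, n, df)
  prev <- matrix(rep(1 / sqrt(n), n), n, 1)  # unit-norm intercept
  for (j in seq_len(df)) {
    target <- S %*% crossprod(S, z^j)        # project z^j into the space
    target <- target - prev %*% crossprod(prev, target)
    nrm <- sqrt(sum(target^2))
    if (nrm < 1e-10 * sqrt(n))
      stop("degenerate spline basis: order ", j,
           " carries no variation beyond lower orders")
    B[, j] <- target / nrm
    prev <- cbind(prev, B[, j])
  }
  colnames(B) <- paste0("order", seq_len(df))
  structure(list(basis = B, knots = ik, boundary_knots = bk, x = x),
            class = "spline_basis")
}

#' @export
print.spline_basis <- function(x, ...) {
  cat("Orthogonal natural-spline basis:", ncol(x$basis), "columns,",
      nrow(x$basis), "observations\n")
  cat("  boundary knots:", format(x$boundary_knots, digits = 4),
      "| interior knots:", format(x$knots, digits = 4), "\n")
  invisible(x)
}
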