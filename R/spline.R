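#' Distance-decay B-spline specification
#'
#' Defines the B-spline basis used to model the dependence of contact counts
#' on genomic distance.  The basis is an order-3 (quadratic) B-spline with
#' full boundary-knot multiplicity, so the \code{df} basis functions form a
#' partition of unity over the distance range.  Inner knots default to the
#' 25/50/75\% quantiles of the training distances; boundary knots default to
#' 0 and 2 Mb, the distance cap of the intra-chromosomal model.
#'
#' The number of inner knots equals \code{df} minus the spline order, so the
#' default six degrees of freedom give three inner knots.
#'
#' @param inner_knots Numeric vector of inner knots (bp), strictly inside the
#'   boundary knots, sorted.
#' @param boundary_knots Length-2 numeric vector, default \code{c(0, 2e6)}.
#' @param order Spline order (polynomial degree + 1); default 3.
#' @return An object of class \code{"spline_spec"}: a list with elements
#'   \code{order}, \code{degree}, \code{df}, \code{inner_knots},
#'   \code{boundary_knots} and the full \code{knots} vector (boundary knots
#'   repeated \code{order} times).
#' @examples
#' sp <- spline_spec(c(4e5, 9e5, 1.4e6))
#' sp$df  # 6
#' @export
spline_spec <- function(inner_knots, boundary_knots = c(0, 2e6), order = 3L) {
  order <- as.integer(order)
  if (length(boundary_knots) != 2L || diff(boundary_knots) <= 0)
    stop("'boundary_knots' must be an increasing length-2 vector")
  if (order < 1L) stop("'order' must be >= 1")
  inner_knots <- as.numeric(sort(inner_knots))
  if (length(inner_knots) &&
      (min(inner_knots) <= boundary_knots[1] ||
       max(inner_knots) >= boundary_knots[2]))
    stop("inner knots must lie strictly inside the boundary knots")
  knots <- c(rep(boundary_knots[1], order), inner_knots,
             rep(boundary_knots[2], order))
  structure(list(order = order, degree = order - 1L,
                 df = length(inner_knots) + order,
                 inner_knots = inner_knots, boundary_knots = boundary_knots,
                 knots = knots),
            class = "spline_spec")
}

#' @export
print.spline_spec <- function(x, ...) {
  cat(sprintf("B-spline basis: order %d (degree %d), df %d\n",
              x$order, x$degree, x$df))
  cat("  inner knots: ", paste(format(x$inner_knots), collapse = ", "), "\n")
  cat("  boundary knots: ", paste(format(x$boundary_knots), collapse = ", "),
      "\n")
  invisible(x)
}

#' Compute inner knots from training distances
#'
#' Inner knots are placed at equally spaced quantiles of the linear genomic
#' distance (25/50/75\% for the default three knots).
#'
#' @param d Numeric vector of genomic distances (bp).
#' @param n_inner Number of inner knots (default 3).
#' @param boundary_knots Boundary knots, default \code{c(0, 2e6)}.
#' @return A \code{\link{spline_spec}}.
#' @export
spline_spec_from_distances <- function(d, n_inner = 3L,
                                       boundary_knots = c(0, 2e6)) {
  probs <- seq_len(n_inner) / (n_inner + 1)
  kn <- unname(stats::quantile(d, probs = probs, names = FALSE, type = 7))
  # degenerate distance distributions: nudge ties inward
  eps <- diff(boundary_knots) * 1e-9
  kn <- pmin(pmax(kn, boundary_knots[1] + eps), boundary_knots[2] - eps)
  kn <- kn + seq_along(kn) * eps  # enforce strict ordering under ties
  spline_spec(kn, boundary_knots = boundary_knots)
}

#' Evaluate the distance B-spline basis
#'
#' Returns the full normalized B-spline basis of the specification's knot
#' vector, evaluated by the Cox--de Boor recursion
#' (\code{splines::splineDesign}).  Because the boundary knots carry full
#' multiplicity, the basis functions are non-negative and sum to one at every
#' distance in range, and the basis at the left boundary is
#' \code{(1, 0, ..., 0)}.
#'
#' @param d Numeric vector of distances (bp), all within the boundary knots.
#' @param spec A \code{\link{spline_spec}}.
#' @return Matrix with \code{length(d)} rows and \code{spec$df} columns.
#' @examples
#' sp <- spline_spec(c(4e5, 9e5, 1.4e6))
#' rowSums(bspline_basis(c(0, 1e6, 2e6), sp))  # all 1
#' @export
bspline_basis <- function(d, spec) {
  stopifnot(inherits(spec, "spline_spec"))
  if (any(!is.finite(d)))
    stop("distances must be finite")
  b <- spec$boundary_knots
  if (any(d < b[1] | d > b[2]))
    stop(sprintf("distances outside the boundary knots [%g, %g]", b[1], b[2]))
  splines::splineDesign(spec$knots, d, ord = spec$order, outer.ok = FALSE)
}

#' Spline design columns for the regression model
#'
#' The regression design keeps an explicit intercept, so the first basis
#' function (the only one nonzero at distance 0) is dropped to avoid exact
#' collinearity with the intercept; the spanned function space is unchanged.
#'
#' @inheritParams bspline_basis
#' @return Matrix with \code{spec$df - 1} columns named \code{s1, s2, ...}.
#' @keywords internal
spline_design <- function(d, spec) {
  m <- bspline_basis(d, spec)[, -1L, drop = FALSE]
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  m
}
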