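#' Restricted cubic spline basis (3 knots)
#'
#' Builds a restricted cubic spline basis in the truncated-power
#' parameterization: with knots t1 < ... < tk the basis is the linear term
#' plus k-2 nonlinear terms, each constructed so the fitted function is
#' linear beyond the boundary knots. With the default 3 knots the basis has
#' 2 columns. Knots default to the 10th/50th/90th percentiles of the
#' supplied values.
#'
#' @param values Numeric vector used to place the knots (>= 10 distinct
#'   values required for the default placement).
#' @param n_knots Number of knots (default 3).
#' @param knots Optional explicit knot locations (overrides placement).
#' @return Object of class `ova_spline_basis` with the knots; use
#'   [spline_transform()] to expand new values.
#' @export
build_spline_basis <- function(values, n_knots = 3, knots = NULL) {
  if (is.null(knots)) {
    vals <- values[is.finite(values)]
    if (length(unique(vals)) < max(n_knots, 10)) {
      stop("need at least ", max(n_knots, 10),
           " distinct finite values to place spline knots")
    }
    probs <- switch(as.character(n_knots),
                    "3" = c(0.10, 0.50, 0.90),
                    "4" = c(0.05, 0.35, 0.65, 0.95),
                    "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
                    stop("unsupported n_knots: ", n_knots))
    knots <- unname(stats::quantile(vals, probs, type = 7))
  }
  if (any(diff(knots) <= 0)) stop("spline knots must be strictly increasing")
  structure(list(knots = knots), class = "ova_spline_basis")
}

#' Evaluate a restricted cubic spline basis
#'
#' @param basis An `ova_spline_basis`.
#' @param x Numeric vector to expand.
#' @return Matrix with `length(knots) - 1` columns: the linear term and the
#'   restricted nonlinear term(s).
#' @export
spline_transform <- function(basis, x) {
  t <- basis$knots
  k <- length(t)
  pp3 <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(x), k - 1)
  out[, 1] <- x
  norm <- (t[k] - t[1])^2
  for (j in seq_len(k - 2)) {
    out[, j + 1] <- (pp3(x - t[j]) -
                       pp3(x - t[k - 1]) * (t[k] - t[j]) / (t[k] - t[k - 1]) +
                       pp3(x - t[k]) * (t[k - 1] - t[j]) / (t[k] - t[k - 1])) / norm
  }
  colnames(out) <- c("lin", paste0("rcs", seq_len(k - 2)))
  out
}
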