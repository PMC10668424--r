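#' Flexible (loess-based) calibration curve
#'
#' Smooths the 0/1 event indicator on the predicted probability by local
#' linear regression and evaluates the smooth on a fixed grid restricted to
#' the observed predicted-probability range. Output rates are clipped to
#' \[0, 1\]. The curve carries a weight of sqrt(n) for center-weighted
#' averaging.
#'
#' @param predicted Predicted probabilities for one category (one-vs-rest).
#' @param events 0/1 indicator of that category.
#' @param span Loess span (default 0.75).
#' @param degree Local polynomial degree (default 1).
#' @param grid_size Number of grid points (default 101).
#' @param category Optional outcome level the curve belongs to.
#' @param center_id Center label, or "pooled".
#' @return An `ova_calibration_curve`: list with `grid`, `observed`,
#'   `category`, `center_id`, `weight`, `n`, `span`, `degree`.
#' @export
fit_flexible_curve <- function(predicted, events, span = 0.75, degree = 1,
                               grid_size = 101, category = NULL,
                               center_id = "pooled") {
  if (length(predicted) != length(events)) stop("length mismatch")
  if (length(predicted) < 20) stop("need at least 20 observations for a calibration curve")
  if (!all(events %in% c(0, 1))) stop("events must be coded 0/1")
  if (anyNA(predicted) || anyNA(events)) stop("missing values not allowed")
  rng <- range(predicted)
  if (diff(rng) < sqrt(.Machine$double.eps)) {
    stop("all predictions identical: calibration curve is degenerate (horizontal by construction)")
  }
  grid <- seq(rng[1], rng[2], length.out = grid_size)
  if (stats::var(events) == 0) {
    observed <- rep(mean(events), grid_size)   # loess of a constant is that constant
  } else {
    fit <- stats::loess(events ~ predicted, span = span, degree = degree,
                        family = "gaussian",
                        control = stats::loess.control(statistics = "none",
                                                       trace.hat = "approximate"))
    observed <- stats::predict(fit, newdata = data.frame(predicted = grid))
  }
  observed <- pmin(pmax(observed, 0), 1)
  structure(list(grid = grid, observed = observed, category = category,
                 center_id = center_id, weight = sqrt(length(predicted)),
                 n = length(predicted), span = span, degree = degree),
            class = "ova_calibration_curve")
}

# evaluate a curve at probabilities p, boundary-value extrapolation
eval_curve <- function(curve, p) {
  stats::approx(curve$grid, curve$observed, xout = p, rule = 2)$y
}

#' Average center-specific calibration curves
#'
#' Pointwise weighted mean of center curves for one category, with weights
#' sqrt(n_c) normalized to one. Curves are re-interpolated onto a common
#' grid spanning the union of their ranges; grid points covered by fewer
#' than two centers are dropped (a single input curve is returned as is).
#'
#' @param curves List of `ova_calibration_curve` objects for one category.
#' @param grid_size Grid resolution of the pooled curve.
#' @return A pooled `ova_calibration_curve` with `center_id = "pooled"`.
#' @export
average_center_curves <- function(curves, grid_size = 101) {
  if (!length(curves)) stop("empty curve list")
  cats <- unique(vapply(curves, function(cv) as.character(cv$category %||% NA), ""))
  if (length(cats) > 1) stop("curves belong to different categories: ",
                             paste(cats, collapse = ", "))
  if (length(curves) == 1L) return(curves[[1]])
  lo <- min(vapply(curves, function(cv) min(cv$grid), 0))
  hi <- max(vapply(curves, function(cv) max(cv$grid), 0))
  grid <- seq(lo, hi, length.out = grid_size)
  vals <- vapply(curves, function(cv) {
    v <- stats::approx(cv$grid, cv$observed, xout = grid, rule = 1)$y
    v
  }, numeric(grid_size))
  w <- vapply(curves, function(cv) cv$weight, 0)
  cover <- rowSums(!is.na(vals))
  keep <- cover >= 2
  if (!any(keep)) stop("no grid points covered by >= 2 centers")
  wm <- vapply(which(keep), function(i) {
    ok <- !is.na(vals[i, ])
    sum(vals[i, ok] * w[ok]) / sum(w[ok])
  }, 0)
  structure(list(grid = grid[keep], observed = pmin(pmax(wm, 0), 1),
                 category = curves[[1]]$category, center_id = "pooled",
                 weight = sqrt(sum(vapply(curves, function(cv) cv$n, 0))),
                 n = sum(vapply(curves, function(cv) cv$n, 0)),
                 span = curves[[1]]$span, degree = curves[[1]]$degree),
            class = "ova_calibration_curve")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rescaled Estimated Calibration Index for one category
#'
#' The raw ECI is the mean squared distance between the predictions and the
#' flexible calibration curve evaluated at those predictions. It is
#' rescaled by the mean squared distance between the predictions and the
#' overall event rate, so that a curve coinciding with the diagonal scores
#' 0 and a horizontal curve at the event rate scores 1 (values above 1
#' indicate calibration worse than no predictive ability). Negative values
#' cannot occur; the ratio is floored at 0 against rounding.
#'
#' @param predicted Predicted probabilities for the category.
#' @param events 0/1 indicator of the category.
#' @param curve An `ova_calibration_curve` covering the predicted range
#'   (boundary-value extrapolation beyond its grid).
#' @return The rescaled ECI, a non-negative scalar.
#' @export
rescaled_eci <- function(predicted, events, curve) {
  if (length(predicted) != length(events)) stop("length mismatch")
  ybar <- mean(events)
  denom <- mean((predicted - ybar)^2)
  if (denom < 1e-12) {
    stop("rescaled ECI undefined: all predictions equal the event rate")
  }
  raw <- mean((predicted - eval_curve(curve, predicted))^2)
  max(0, raw / denom)
}

#' Per-category and mean rescaled ECI over five categories
#'
#' @param probabilities n x 5 row-stochastic matrix.
#' @param outcomes True classes aligned to the rows.
#' @param curves Optional named list of five pooled calibration curves; if
#'   omitted, pooled curves are fitted from all patients per category.
#' @param span,degree Smoother settings used when fitting curves here.
#' @return An `ova_eci` list: `per_category_eci` (named 5-vector) and
#'   `mean_eci`.
#' @export
multiclass_eci <- function(probabilities, outcomes, curves = NULL,
                           span = 0.75, degree = 1) {
  outcomes <- factor(as.character(outcomes), levels = outcome_levels())
  validate_probability_matrix(probabilities, n = length(outcomes))
  lev <- outcome_levels()
  eci <- stats::setNames(numeric(5), lev)
  for (k in lev) {
    pk <- probabilities[, k]
    ev <- as.integer(outcomes == k)
    cv <- if (is.null(curves)) {
      fit_flexible_curve(pk, ev, span = span, degree = degree, category = k)
    } else {
      curves[[k]]
    }
    eci[k] <- rescaled_eci(pk, ev, cv)
  }
  structure(list(per_category_eci = eci, mean_eci = mean(eci)),
            class = "ova_eci")
}

#' Center-specific and pooled calibration curves for one category
#'
#' Fits one curve per center with at least `min_n` patients and both
#' outcome levels present, then averages them with sqrt(n) weights.
#' Centers failing the eligibility rule contribute to pooled evaluation
#' only; their exclusion is recorded.
#'
#' @param predicted Predicted probabilities for the category.
#' @param events 0/1 category indicator.
#' @param centers Center ids aligned to patients.
#' @param category Outcome level name.
#' @param min_n Minimum center size for a center-specific curve.
#' @param span,degree Smoother settings.
#' @return List with `pooled` (averaged curve), `center_curves`, and
#'   `excluded` (data frame of center, reason).
#' @export
calibration_curves_by_center <- function(predicted, events, centers, category,
                                         min_n = 20, span = 0.75, degree = 1) {
  curves <- list(); excluded <- list()
  for (c in unique(centers)) {
    idx <- centers == c
    if (sum(idx) < min_n) {
      excluded[[length(excluded) + 1]] <- data.frame(center = c, reason = "too few patients")
      next
    }
    if (stats::var(events[idx]) == 0) {
      excluded[[length(excluded) + 1]] <- data.frame(center = c, reason = "single outcome level")
      next
    }
    cv <- tryCatch(fit_flexible_curve(predicted[idx], events[idx], span = span,
                                      degree = degree, category = category,
                                      center_id = as.character(c)),
                   error = function(e) NULL)
    if (is.null(cv)) {
      excluded[[length(excluded) + 1]] <- data.frame(center = c, reason = "degenerate predictions")
    } else {
      curves[[length(curves) + 1]] <- cv
    }
  }
  pooled <- if (length(curves)) {
    average_center_curves(curves)
  } else {
    fit_flexible_curve(predicted, events, span = span, degree = degree,
                       category = category)
  }
  list(pooled = pooled, center_curves = curves,
       excluded = if (length(excluded)) do.call(rbind, excluded) else NULL)
}

#' Export calibration curves as a long-format table
#'
#' @param curves List of `ova_calibration_curve` objects.
#' @return Data frame with columns category, center, grid_point, observed,
#'   weight.
#' @export
curves_to_table <- function(curves) {
  do.call(rbind, lapply(curves, function(cv) {
    data.frame(category = as.character(cv$category %||% NA),
               center = cv$center_id, grid_point = cv$grid,
               observed = cv$observed, weight = cv$weight)
  }))
}
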