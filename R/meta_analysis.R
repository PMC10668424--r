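#' Random-effects pooling of center-specific statistics
#'
#' DerSimonian-Laird random-effects meta-analysis: the method-of-moments
#' between-center variance tau^2 from Cochran's Q, inverse-variance pooling
#' with weights 1/(v_c + tau^2), a Wald 95% confidence interval, and a
#' Higgins-Thompson 95% prediction interval
#' mu +/- t_{k-2, 0.975} * sqrt(tau^2 + SE(mu)^2) describing the statistic
#' expected in a new center (defined for k >= 3 centers; flagged NA for
#' k = 2). On the logit scale (for proportions and c-statistics) values are
#' transformed in, variances converted by the delta method, and the
#' estimate and intervals transformed back.
#'
#' @param values Center-specific statistic values.
#' @param variances Within-center variances (>= 0), same length.
#' @param scale "identity" or "logit"; logit requires values strictly in
#'   (0, 1).
#' @return An `ova_pooled` list: `mu`, `ci95`, `pi95`, `tau2`, `k`,
#'   `scale`. `tau2` is on the analysis (possibly logit) scale.
#' @export
random_effects_pool <- function(values, variances, scale = c("identity", "logit")) {
  scale <- match.arg(scale)
  if (length(values) != length(variances)) stop("length mismatch")
  if (length(values) < 2) stop("need at least 2 centers to pool")
  if (any(!is.finite(values)) || any(!is.finite(variances))) stop("non-finite inputs")
  if (any(variances < 0)) stop("variances must be >= 0")
  k <- length(values)
  y <- values; v <- pmax(variances, 1e-10)
  if (scale == "logit") {
    if (any(values <= 0 | values >= 1)) {
      stop("logit scale requires values strictly in (0, 1)")
    }
    v <- v / (values * (1 - values))^2
    y <- stats::qlogis(values)
  }
  w <- 1 / v
  ybar <- sum(w * y) / sum(w)
  Q <- sum(w * (y - ybar)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (v + tau2)
  mu <- sum(ws * y) / sum(ws)
  se <- sqrt(1 / sum(ws))
  ci <- mu + c(-1, 1) * stats::qnorm(0.975) * se
  pi <- if (k >= 3) {
    mu + c(-1, 1) * stats::qt(0.975, df = k - 2) * sqrt(tau2 + se^2)
  } else {
    c(NA_real_, NA_real_)
  }
  if (scale == "logit") {
    mu_out <- stats::plogis(mu); ci_out <- stats::plogis(ci)
    pi_out <- stats::plogis(pi)
  } else {
    mu_out <- mu; ci_out <- ci; pi_out <- pi
  }
  structure(list(mu = mu_out, ci95 = ci_out, pi95 = pi_out, tau2 = tau2,
                 k = k, scale = scale, Q = Q),
            class = "ova_pooled")
}

#' @export
print.ova_pooled <- function(x, ...) {
  cat(sprintf("pooled estimate %.4f (95%% CI %.4f-%.4f; 95%% PI %s; tau2=%.3g; k=%d; %s scale)\n",
              x$mu, x$ci95[1], x$ci95[2],
              if (anyNA(x$pi95)) "undefined (k=2)" else sprintf("%.4f-%.4f", x$pi95[1], x$pi95[2]),
              x$tau2, x$k, x$scale))
  invisible(x)
}

#' Map a performance metric over centers
#'
#' Computes a metric per center, with within-center variance by a seeded
#' nonparametric bootstrap (or a user-supplied closed form). Centers where
#' the metric is not computable (e.g. an AUROC with a missing outcome
#' level) are excluded with the reason recorded.
#'
#' @param probabilities n x 5 probability matrix.
#' @param outcomes True classes aligned to the rows.
#' @param centers Center ids aligned to the rows.
#' @param metric_fn Function(probabilities, outcomes) -> scalar.
#' @param B Bootstrap replicates for the variance (default 200).
#' @param seed Seed for the bootstrap.
#' @param variance_fn Optional closed-form function(probabilities,
#'   outcomes) -> variance; skips the bootstrap.
#' @return List with `estimates` (data.frame center_id, value, variance,
#'   n) and `excluded` (data.frame center_id, reason).
#' @export
center_statistics <- function(probabilities, outcomes, centers, metric_fn,
                              B = 200, seed = 1L, variance_fn = NULL) {
  ucenters <- unique(centers)
  est <- list(); excl <- list()
  set.seed(seed)
  for (c in ucenters) {
    idx <- which(centers == c)
    p <- probabilities[idx, , drop = FALSE]
    y <- outcomes[idx]
    val <- tryCatch(metric_fn(p, y), error = function(e) e)
    if (inherits(val, "error")) {
      excl[[length(excl) + 1]] <- data.frame(center_id = c,
                                             reason = conditionMessage(val))
      next
    }
    if (!is.null(variance_fn)) {
      v <- variance_fn(p, y)
    } else {
      boots <- numeric(0)
      for (b in seq_len(B)) {
        ii <- sample.int(length(idx), replace = TRUE)
        bv <- tryCatch(metric_fn(p[ii, , drop = FALSE], y[ii]),
                       error = function(e) NA_real_)
        boots <- c(boots, bv)
      }
      boots <- boots[is.finite(boots)]
      if (length(boots) < B / 4) {
        excl[[length(excl) + 1]] <- data.frame(center_id = c,
                                               reason = "bootstrap variance unstable")
        next
      }
      v <- stats::var(boots)
    }
    est[[length(est) + 1]] <- data.frame(center_id = c, value = val,
                                         variance = v, n = length(idx))
  }
  if (!length(est)) stop("no eligible centers for this metric")
  list(estimates = do.call(rbind, est),
       excluded = if (length(excl)) do.call(rbind, excl) else NULL)
}

#' Pool a metric over centers
#'
#' Convenience wrapper: [center_statistics()] followed by
#' [random_effects_pool()].
#'
#' @inheritParams center_statistics
#' @param scale Pooling scale, see [random_effects_pool()].
#' @return An `ova_pooled`, with the per-center table attached as
#'   attribute `"centers"`; if fewer than 2 centers are eligible, the
#'   single estimate is returned with NA intervals and a warning.
#' @export
pool_center_metric <- function(probabilities, outcomes, centers, metric_fn,
                               scale = "identity", B = 200, seed = 1L,
                               variance_fn = NULL) {
  cs <- center_statistics(probabilities, outcomes, centers, metric_fn,
                          B = B, seed = seed, variance_fn = variance_fn)
  e <- cs$estimates
  if (nrow(e) < 2) {
    warning("only one eligible center; returning its estimate without pooling")
    out <- structure(list(mu = e$value[1], ci95 = c(NA_real_, NA_real_),
                          pi95 = c(NA_real_, NA_real_), tau2 = NA_real_,
                          k = 1L, scale = scale, Q = NA_real_),
                     class = "ova_pooled")
  } else {
    out <- random_effects_pool(e$value, e$variance, scale = scale)
  }
  attr(out, "centers") <- e
  attr(out, "excluded") <- cs$excluded
  out
}
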