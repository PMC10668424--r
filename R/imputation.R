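#' Multiple imputation of missing CA125
#'
#' CA125 is the only incomplete variable by design, so chained equations
#' reduce to repeated draws from a single imputation model: Bayesian
#' linear regression of log CA125 on the eight other predictors plus the
#' outcome class (outcome-inclusive imputation, standard in prediction
#' research), followed by predictive mean matching with a donor pool of 5.
#' For each of the m completed datasets, regression coefficients and the
#' residual variance are drawn from their posterior (normal /
#' scaled-inverse-chi-squared under the usual noninformative prior);
#' each missing cell receives the observed CA125 of a donor sampled among
#' the 5 observed cases whose drawn-coefficient predictions are closest.
#' Imputed values are therefore always observed CA125 values (positive,
#' realistically skewed). Observed cells are never altered.
#'
#' @param cohort An `ova_cohort`; only `ca125` may contain missing values.
#' @param m Number of completed datasets (>= 2).
#' @param seed Integer seed.
#' @param donors Donor pool size for predictive mean matching.
#' @return An `ova_imputation_set`: list with `m`, `tables` (list of m
#'   completed cohorts), `seed`, and `descriptor` (text record of the
#'   imputation model).
#' @export
impute_ca125 <- function(cohort, m = 10, seed = 1L, donors = 5L) {
  if (m < 2) stop("multiple imputation needs m >= 2")
  for (col in setdiff(cohort_columns(), "ca125")) {
    if (anyNA(cohort[[col]])) {
      stop("column '", col, "' has missing values; only ca125 may be imputed")
    }
  }
  mis <- which(is.na(cohort$ca125))
  obs <- which(!is.na(cohort$ca125))
  if (!length(obs)) stop("CA125 is fully missing; nothing to match on")
  descriptor <- paste("predictive mean matching (donors =", donors,
                      ") on log(ca125) ~ center_oncology + age + prop_solid +",
                      "max_diameter + shadows + ascites + gt10_locules +",
                      "papillations + outcome")
  if (!length(mis)) {
    return(structure(list(m = m, tables = replicate(m, cohort, simplify = FALSE),
                          seed = seed, descriptor = descriptor),
                     class = "ova_imputation_set"))
  }
  X <- stats::model.matrix(~ center_oncology + age + prop_solid + max_diameter +
                             shadows + ascites + gt10_locules +
                             papillation_score(papillations) + outcome,
                           data = cohort)
  y <- log(cohort$ca125)
  Xo <- X[obs, , drop = FALSE]; yo <- y[obs]
  qrX <- qr(Xo)
  keep <- qrX$pivot[seq_len(qrX$rank)]           # drop aliased columns
  Xo <- Xo[, keep, drop = FALSE]
  Xm <- X[mis, keep, drop = FALSE]
  fit <- stats::lm.fit(Xo, yo)
  betahat <- fit$coefficients
  res <- fit$residuals
  df <- length(obs) - ncol(Xo)
  XtXinv <- chol2inv(chol(crossprod(Xo)))
  R <- chol(XtXinv)

  set.seed(seed)
  tables <- vector("list", m)
  for (i in seq_len(m)) {
    sigma2 <- sum(res^2) / stats::rchisq(1, df)
    beta <- betahat + sqrt(sigma2) * drop(t(R) %*% stats::rnorm(ncol(Xo)))
    pred_obs <- drop(Xo %*% beta)
    pred_mis <- drop(Xm %*% beta)
    imputed <- vapply(pred_mis, function(pm) {
      d <- abs(pred_obs - pm)
      pool <- order(d)[seq_len(min(donors, length(d)))]
      cohort$ca125[obs[sample(pool, 1)]]
    }, 0)
    tab <- cohort
    tab$ca125[mis] <- imputed
    tables[[i]] <- tab
  }
  structure(list(m = m, tables = tables, seed = seed, descriptor = descriptor),
            class = "ova_imputation_set")
}

#' Pool a statistic across imputations by Rubin's rules
#'
#' The point estimate is the mean across imputations. When within-
#' imputation variances are supplied the total variance is
#' W + (1 + 1/m) B, with W the mean within variance and B the between-
#' imputation variance; the CI uses the Rubin degrees of freedom.
#'
#' @param per_imputation_stats Numeric vector of the statistic, one per
#'   completed dataset (length >= 2).
#' @param per_imputation_variances Optional vector of within-imputation
#'   variances, same length.
#' @return List with `estimate`, `between_var`, and (when variances are
#'   given) `within_var`, `total_var`, `se`, `ci95`, `df`.
#' @export
pool_across_imputations <- function(per_imputation_stats,
                                    per_imputation_variances = NULL) {
  m <- length(per_imputation_stats)
  if (m < 2) stop("pooling requires at least 2 imputations")
  if (!is.null(per_imputation_variances) &&
      length(per_imputation_variances) != m) {
    stop("stats and variances length mismatch")
  }
  est <- mean(per_imputation_stats)
  B <- stats::var(per_imputation_stats)
  out <- list(estimate = est, between_var = B, m = m)
  if (!is.null(per_imputation_variances)) {
    W <- mean(per_imputation_variances)
    total <- W + (1 + 1 / m) * B
    out$within_var <- W
    out$total_var <- total
    out$se <- sqrt(total)
    df <- if (B > 0) (m - 1) * (1 + W / ((1 + 1 / m) * B))^2 else Inf
    out$df <- df
    q <- if (is.finite(df)) stats::qt(0.975, df) else stats::qnorm(0.975)
    out$ci95 <- est + c(-1, 1) * q * out$se
  }
  out
}

#' Write an imputation set to disk
#'
#' One delimited cohort file per completed dataset plus a JSON manifest.
#'
#' @param imputation_set An `ova_imputation_set`.
#' @param dir Output directory (created if absent).
#' @param prefix File name prefix.
#' @export
write_imputation_set <- function(imputation_set, dir, prefix = "imputed") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(imputation_set$m)
  for (i in seq_len(imputation_set$m)) {
    paths[i] <- file.path(dir, sprintf("%s_%02d.csv", prefix, i))
    write_cohort(imputation_set$tables[[i]], paths[i])
  }
  manifest <- list(m = imputation_set$m, seed = imputation_set$seed,
                   model = imputation_set$descriptor, files = basename(paths))
  jsonlite::write_json(manifest, file.path(dir, paste0(prefix, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
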