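#' Specify a five-class risk model
#'
#' Six algorithms are supported: standard multinomial logistic regression
#' (`mlr`), ridge-penalized MLR (`ridge_mlr`), random forest (`rf`),
#' extreme gradient boosting (`xgboost`), a single-hidden-layer neural
#' network (`nn`), and an RBF-kernel support vector machine (`svm`, with
#' per-pair Platt scaling combined by pairwise coupling into multiclass
#' probabilities). Each can be fit with or without CA125. For the MLR
#' variants, continuous predictors (age, log CA125, solid proportion,
#' maximal diameter) enter through restricted cubic splines with 3 knots;
#' papillations enter as an ordinal score for MLR/NN/SVM and as a
#' categorical variable for the tree ensembles.
#'
#' @param algorithm One of "mlr", "ridge_mlr", "rf", "xgboost", "nn",
#'   "svm".
#' @param with_ca125 Include CA125 as a predictor?
#' @param use_splines Spline-expand continuous predictors in the MLR
#'   variants (set `FALSE` for a strictly linear design, e.g. in
#'   parameter-recovery studies).
#' @param grid Hyperparameter candidate grid (data frame, one row per
#'   candidate); defaults to [default_grid()] for the algorithm.
#' @param seed Integer seed governing fold assignment and any stochastic
#'   fitting.
#' @return An `ova_model_spec`.
#' @export
model_spec <- function(algorithm = c("mlr", "ridge_mlr", "rf", "xgboost", "nn", "svm"),
                       with_ca125 = TRUE, use_splines = TRUE, grid = NULL,
                       seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (is.null(grid)) grid <- default_grid(algorithm)
  structure(list(algorithm = algorithm, with_ca125 = with_ca125,
                 use_splines = use_splines, grid = grid,
                 hyperparameters = NULL, tuning = NULL, seed = as.integer(seed)),
            class = "ova_model_spec")
}

#' Default hyperparameter grids
#'
#' Conventional search ranges for tabular clinical data of a few thousand
#' rows; override through the `grid` argument of [model_spec()]. MLR has
#' no tunable hyperparameters (a singleton grid). XGBoost rounds are
#' chosen by early stopping on the cross-validation folds, up to
#' `max_rounds`.
#'
#' @param algorithm Algorithm name as in [model_spec()].
#' @return Data frame of candidates, one row each.
#' @export
default_grid <- function(algorithm) {
  switch(algorithm,
         mlr = data.frame(dummy = 0),
         ridge_mlr = data.frame(lambda = 10^seq(-4, 4, length.out = 25)),
         rf = expand.grid(num_trees = 500, mtry = c(2, 3, 4, 6),
                          min_node = c(1, 5, 10)),
         xgboost = expand.grid(max_depth = c(2, 3, 4, 6),
                               eta = c(0.01, 0.05, 0.1),
                               subsample = c(0.7, 1.0),
                               max_rounds = 500),
         nn = expand.grid(size = c(2, 3, 5, 8), decay = c(0.001, 0.01, 0.1)),
         svm = expand.grid(cost = 2^(-2:6), gamma = 2^(-6:0)),
         stop("unknown algorithm: ", algorithm))
}

# ---- design construction --------------------------------------------------

check_ca125_available <- function(spec, cohort) {
  if (spec$with_ca125 && anyNA(cohort$ca125)) {
    stop("CA125 is missing for ", sum(is.na(cohort$ca125)),
         " patients; run impute_ca125() and fit/predict on completed data, ",
         "or use a without-CA125 model")
  }
}

raw_feature_frame <- function(spec, cohort) {
  df <- data.frame(center_oncology = cohort$center_oncology,
                   age = cohort$age)
  if (spec$with_ca125) df$log_ca125 <- log(cohort$ca125)
  df$prop_solid <- cohort$prop_solid
  df$max_diameter <- cohort$max_diameter
  df$shadows <- cohort$shadows
  df$ascites <- cohort$ascites
  df$gt10_locules <- cohort$gt10_locules
  df
}

continuous_features <- function(spec) {
  c("age", if (spec$with_ca125) "log_ca125", "prop_solid", "max_diameter")
}

# preprocessing state learned on development data (spline knots,
# standardization constants), reapplied verbatim at prediction time
make_preproc <- function(spec, cohort) {
  check_ca125_available(spec, cohort)
  pp <- list(algorithm = spec$algorithm, with_ca125 = spec$with_ca125,
             use_splines = spec$use_splines)
  df <- raw_feature_frame(spec, cohort)
  if (spec$algorithm %in% c("mlr", "ridge_mlr") && spec$use_splines) {
    pp$bases <- lapply(continuous_features(spec), function(v) {
      tryCatch(build_spline_basis(df[[v]]), error = function(e) NULL)
    })
    names(pp$bases) <- continuous_features(spec)
  }
  if (spec$algorithm %in% c("nn", "svm")) {
    X <- build_numeric_matrix(pp, cohort, standardize = FALSE)
    pp$center <- colMeans(X)
    pp$scale <- apply(X, 2, stats::sd)
    pp$scale[pp$scale == 0] <- 1
  }
  pp
}

build_numeric_matrix <- function(pp, cohort, standardize = TRUE) {
  spec_like <- list(with_ca125 = pp$with_ca125)
  df <- raw_feature_frame(spec_like, cohort)
  df$papillations <- papillation_score(cohort$papillations)
  X <- as.matrix(df)
  if (standardize && !is.null(pp$center)) {
    X <- sweep(sweep(X, 2, pp$center), 2, pp$scale, "/")
  }
  X
}

build_spline_matrix <- function(pp, cohort) {
  spec_like <- list(with_ca125 = pp$with_ca125)
  df <- raw_feature_frame(spec_like, cohort)
  cols <- list(center_oncology = df$center_oncology)
  cont <- c("age", if (pp$with_ca125) "log_ca125", "prop_solid", "max_diameter")
  for (v in cont) {
    basis <- if (isTRUE(pp$use_splines)) pp$bases[[v]] else NULL
    if (is.null(basis)) {
      cols[[v]] <- df[[v]]
    } else {
      m <- spline_transform(basis, df[[v]])
      colnames(m) <- paste(v, colnames(m), sep = "_")
      cols[[v]] <- m
    }
  }
  cols$shadows <- df$shadows
  cols$ascites <- df$ascites
  cols$gt10_locules <- df$gt10_locules
  cols$papillations <- papillation_score(cohort$papillations)
  out <- do.call(cbind, cols)
  colnames(out) <- unlist(lapply(names(cols), function(nm) {
    if (is.matrix(cols[[nm]])) colnames(cols[[nm]]) else nm
  }))
  out
}

build_tree_frame <- function(pp, cohort) {
  spec_like <- list(with_ca125 = pp$with_ca125)
  df <- raw_feature_frame(spec_like, cohort)
  df$papillations <- factor(as.character(cohort$papillations),
                            levels = papillation_levels())
  df
}

build_xgb_matrix <- function(pp, cohort) {
  X <- build_numeric_matrix(pp, cohort, standardize = FALSE)
  X <- X[, setdiff(colnames(X), "papillations"), drop = FALSE]
  pap <- factor(as.character(cohort$papillations), levels = papillation_levels())
  onehot <- stats::model.matrix(~ pap - 1)
  colnames(onehot) <- paste0("pap_", papillation_levels())
  cbind(X, onehot)
}

build_design <- function(pp, cohort) {
  if (pp$with_ca125 && anyNA(cohort$ca125)) {
    stop("CA125 is missing at prediction time for a with-CA125 model; ",
         "impute first (impute_ca125)")
  }
  switch(pp$algorithm,
         mlr = build_spline_matrix(pp, cohort),
         ridge_mlr = build_spline_matrix(pp, cohort),
         rf = build_tree_frame(pp, cohort),
         xgboost = build_xgb_matrix(pp, cohort),
         nn = build_numeric_matrix(pp, cohort),
         svm = build_numeric_matrix(pp, cohort))
}

# ---- cross-validation machinery ------------------------------------------

#' Stratified cross-validation folds
#'
#' Fold assignment stratified by outcome class; if the smallest class has
#' fewer members than the requested number of folds, the fold count is
#' reduced (with a warning) so every fold sees every class.
#'
#' @param outcomes Factor of outcome classes.
#' @param n_folds Requested number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold ids, aligned to `outcomes`.
#' @export
stratified_folds <- function(outcomes, n_folds = 10, seed = 1L) {
  outcomes <- factor(as.character(outcomes), levels = outcome_levels())
  min_class <- min(table(outcomes))
  if (min_class < n_folds) {
    n_folds <- max(2, min_class)
    warning("smallest class has ", min_class,
            " members; reducing to ", n_folds, "-fold CV")
  }
  set.seed(seed)
  fold <- integer(length(outcomes))
  for (k in levels(outcomes)) {
    idx <- which(outcomes == k)
    fold[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
  }
  fold
}

mean_loglik <- function(p, y) {
  idx <- cbind(seq_along(y), as.integer(y))
  mean(log(pmax(p[idx], 1e-12)))
}

#' Tune hyperparameters by stratified 10-fold cross-validation
#'
#' Every candidate in the spec's grid is scored by the mean out-of-fold
#' multinomial log-likelihood (a proper scoring rule); the maximizing
#' candidate is selected and the full tuning record (per-candidate CV
#' score, fold count, seed) is retained on the returned spec. For XGBoost
#' the number of boosting rounds is set by early stopping on the CV folds
#' and recorded alongside the selected candidate.
#'
#' @param spec An `ova_model_spec`.
#' @param development Development cohort (complete CA125 if `with_ca125`).
#' @param n_folds Number of folds (default 10).
#' @return The spec with `hyperparameters` and `tuning` filled in.
#' @export
tune_hyperparameters <- function(spec, development, n_folds = 10) {
  stopifnot(inherits(spec, "ova_model_spec"))
  check_ca125_available(spec, development)
  y <- development$outcome
  if (any(table(y) == 0)) stop("development data must contain all five classes")
  fold <- stratified_folds(y, n_folds, seed = spec$seed)
  nf <- max(fold)
  pp <- make_preproc(spec, development)
  X <- build_design(pp, development)
  grid <- spec$grid
  scores <- numeric(nrow(grid))
  extras <- vector("list", nrow(grid))
  if (spec$algorithm == "ridge_mlr") {
    # one glmnet path per fold scores every lambda candidate at once
    lambdas <- sort(grid$lambda, decreasing = TRUE)
    oof <- matrix(NA_real_, nrow(X), length(lambdas))
    for (f in seq_len(nf)) {
      tr <- fold != f
      fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr],
                            family = "multinomial", alpha = 0,
                            lambda = lambdas, standardize = TRUE)
      pr <- predict(fit, newx = X[!tr, , drop = FALSE], type = "response")
      for (j in seq_along(lambdas)) {
        p <- pr[, , j]
        idx <- cbind(seq_len(sum(!tr)), as.integer(y[!tr]))
        oof[which(!tr), j] <- log(pmax(p[idx], 1e-12))
      }
    }
    path_scores <- colMeans(oof)
    scores <- path_scores[match(grid$lambda, lambdas)]
  } else {
    for (g in seq_len(nrow(grid))) {
      hp <- as.list(grid[g, , drop = FALSE])
      ll <- numeric(nrow(X)); rounds <- integer(0)
      for (f in seq_len(nf)) {
        tr <- fold != f
        fitres <- fit_algorithm(spec, hp, X, y, subset = which(tr),
                                eval_subset = which(!tr))
        p <- predict_algorithm(spec$algorithm, fitres$fit,
                               subset_design(X, which(!tr)))
        idx <- cbind(seq_len(sum(!tr)), as.integer(y[!tr]))
        ll[which(!tr)] <- log(pmax(p[idx], 1e-12))
        if (!is.null(fitres$best_rounds)) rounds <- c(rounds, fitres$best_rounds)
      }
      scores[g] <- mean(ll)
      if (length(rounds)) extras[[g]] <- list(nrounds = max(1L, round(mean(rounds))))
    }
  }
  best <- which.max(scores)
  hp <- as.list(grid[best, , drop = FALSE])
  if (!is.null(extras[[best]])) hp <- c(hp, extras[[best]])
  spec$hyperparameters <- hp
  spec$tuning <- list(grid = cbind(grid, cv_loglik = scores),
                      selected = best, n_folds = nf, seed = spec$seed)
  spec
}

subset_design <- function(X, idx) {
  if (is.data.frame(X)) X[idx, , drop = FALSE] else X[idx, , drop = FALSE]
}

# ---- fitting and prediction ----------------------------------------------

fit_algorithm <- function(spec, hp, X, y, subset = NULL, eval_subset = NULL) {
  if (!is.null(subset)) {
    Xtr <- subset_design(X, subset); ytr <- y[subset]
  } else {
    Xtr <- X; ytr <- y
  }
  set.seed(spec$seed)
  alg <- spec$algorithm
  if (alg == "mlr") {
    dat <- data.frame(.y = ytr, Xtr, check.names = FALSE)
    fit <- nnet::multinom(.y ~ ., data = dat, trace = FALSE, maxit = 500,
                          MaxNWts = 5000)
    if (fit$convergence != 0) {
      stop("multinomial logistic regression did not converge (value ",
           format(fit$value), ", ", nrow(Xtr), " rows, ", ncol(Xtr),
           " columns); consider rescaling predictors")
    }
    return(list(fit = fit))
  }
  if (alg == "ridge_mlr") {
    lambdas <- sort(unique(c(spec$grid$lambda, hp$lambda)), decreasing = TRUE)
    fit <- glmnet::glmnet(Xtr, ytr, family = "multinomial", alpha = 0,
                          lambda = lambdas, standardize = TRUE)
    return(list(fit = list(glmnet = fit, s = hp$lambda)))
  }
  if (alg == "rf") {
    fit <- ranger::ranger(x = Xtr, y = ytr, probability = TRUE,
                          num.trees = hp$num_trees,
                          mtry = min(hp$mtry, ncol(Xtr)),
                          min.node.size = hp$min_node,
                          seed = spec$seed, num.threads = 1)
    return(list(fit = fit))
  }
  if (alg == "xgboost") {
    dtr <- xgboost::xgb.DMatrix(as.matrix(Xtr), label = as.integer(ytr) - 1L)
    params <- list(objective = "multi:softprob", num_class = 5,
                   max_depth = hp$max_depth, eta = hp$eta,
                   subsample = hp$subsample, nthread = 1,
                   eval_metric = "mlogloss", seed = spec$seed)
    if (!is.null(eval_subset)) {
      dev <- xgboost::xgb.DMatrix(as.matrix(subset_design(X, eval_subset)),
                                  label = as.integer(y[eval_subset]) - 1L)
      fit <- xgboost::xgb.train(params = params, data = dtr,
                                nrounds = hp$max_rounds,
                                evals = list(val = dev),
                                early_stopping_rounds = 20, verbose = 0)
      best <- as.integer(xgboost::xgb.attr(fit, "best_iteration"))
      return(list(fit = fit, best_rounds = best))
    }
    nrounds <- hp$nrounds %||% hp$max_rounds
    fit <- xgboost::xgb.train(params = params, data = dtr, nrounds = nrounds,
                              verbose = 0)
    return(list(fit = fit))
  }
  if (alg == "nn") {
    fit <- nnet::nnet(x = Xtr, y = nnet::class.ind(ytr), size = hp$size,
                      decay = hp$decay, softmax = TRUE, maxit = 500,
                      trace = FALSE, MaxNWts = 5000)
    return(list(fit = fit))
  }
  if (alg == "svm") {
    fit <- e1071::svm(x = Xtr, y = ytr, probability = TRUE, kernel = "radial",
                      cost = hp$cost, gamma = hp$gamma)
    return(list(fit = fit))
  }
  stop("unknown algorithm: ", alg)
}

predict_algorithm <- function(algorithm, fit, X) {
  lev <- outcome_levels()
  p <- switch(algorithm,
              mlr = {
                pr <- predict(fit, newdata = data.frame(X, check.names = FALSE),
                              type = "probs")
                if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1,
                                                   dimnames = list(NULL, names(pr)))
                pr
              },
              ridge_mlr = {
                pr <- predict(fit$glmnet, newx = as.matrix(X), s = fit$s,
                              type = "response")
                pr[, , 1]
              },
              rf = predict(fit, data = X, num.threads = 1)$predictions,
              xgboost = {
                pr <- predict(fit, xgboost::xgb.DMatrix(as.matrix(X)))
                if (is.null(dim(pr))) pr <- matrix(pr, ncol = 5, byrow = TRUE)
                colnames(pr) <- lev
                pr
              },
              nn = {
                pr <- predict(fit, X)
                pr
              },
              svm = {
                pr <- attr(predict(fit, X, probability = TRUE), "probabilities")
                pr
              },
              stop("unknown algorithm: ", algorithm))
  if (is.null(dim(p))) p <- matrix(p, ncol = 5, dimnames = list(NULL, lev))
  if (!is.null(colnames(p)) && all(lev %in% colnames(p))) {
    p <- p[, lev, drop = FALSE]
  } else {
    colnames(p) <- lev
  }
  p <- pmin(pmax(p, 0), 1)
  p / rowSums(p)
}

#' Fit a tuned model on the full development data
#'
#' @param spec A tuned `ova_model_spec` (see [tune_hyperparameters()]); a
#'   singleton grid may be fit untuned, in which case its only candidate
#'   is used.
#' @param development Development cohort.
#' @return An `ova_model` handle supporting [predict_probabilities()].
#' @export
fit_model <- function(spec, development) {
  stopifnot(inherits(spec, "ova_model_spec"))
  if (is.null(spec$hyperparameters)) {
    if (nrow(spec$grid) == 1L) {
      spec$hyperparameters <- as.list(spec$grid[1, , drop = FALSE])
    } else {
      stop("spec has an untuned multi-candidate grid; run tune_hyperparameters() first")
    }
  }
  check_ca125_available(spec, development)
  pp <- make_preproc(spec, development)
  X <- build_design(pp, development)
  fitres <- fit_algorithm(spec, spec$hyperparameters, X, development$outcome)
  structure(list(spec = spec, preproc = pp, fit = fitres$fit,
                 n_train = nrow(development)),
            class = "ova_model")
}

#' Predict five-class probabilities
#'
#' @param handle An `ova_model` from [fit_model()].
#' @param cohort Cohort to predict for; must carry the predictors the model
#'   was trained on (complete CA125 for with-CA125 models).
#' @return n x 5 row-stochastic probability matrix with outcome-level
#'   column names.
#' @export
predict_probabilities <- function(handle, cohort) {
  stopifnot(inherits(handle, "ova_model"))
  X <- build_design(handle$preproc, cohort)
  p <- predict_algorithm(handle$spec$algorithm, handle$fit, X)
  validate_probability_matrix(p, n = nrow(cohort))
  p
}
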