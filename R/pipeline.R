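#' Configuration for a full model-comparison experiment
#'
#' Describes the whole experiment: data sources (synthetic generator
#' settings or cohort CSV paths) for the separate development and
#' validation cohorts, the algorithms and CA125 variants to fit, the
#' number of imputations, hyperparameter grids, and evaluation settings.
#' All randomness is funneled through the single root `seed`, from which
#' named sub-seeds (generation, imputation, model fitting, bootstrap) are
#' derived and recorded in the output manifest.
#'
#' @param seed Root integer seed.
#' @param dev,val Either a cohort CSV path or a named list of
#'   [cohort_config()] arguments for the synthetic generator.
#' @param algorithms Algorithms to fit (subset of the six).
#' @param with_ca125_variants Logical vector of CA125 variants to run
#'   (default both with and without).
#' @param m Number of imputations for the with-CA125 path.
#' @param grids Optional named list of hyperparameter grids overriding
#'   [default_grid()] per algorithm.
#' @param n_folds CV folds for tuning (default 10).
#' @param thresholds Decision-curve threshold grid.
#' @param nb_threshold Headline Net Benefit threshold (default 0.10).
#' @param bootstrap_B Bootstrap replicates for within-center variances.
#' @return An `ova_experiment_config`.
#' @export
experiment_config <- function(seed = 1L,
                              dev = list(n_patients = 1500, n_centers = 5,
                                         n_oncology = 3),
                              val = list(n_patients = 800, n_centers = 5,
                                         n_oncology = 3),
                              algorithms = c("mlr", "ridge_mlr", "rf",
                                             "xgboost", "nn", "svm"),
                              with_ca125_variants = c(TRUE, FALSE),
                              m = 2L, grids = NULL, n_folds = 10,
                              thresholds = seq(0.05, 0.40, by = 0.01),
                              nb_threshold = 0.10, bootstrap_B = 200) {
  structure(list(seed = as.integer(seed), dev = dev, val = val,
                 algorithms = algorithms,
                 with_ca125_variants = with_ca125_variants, m = as.integer(m),
                 grids = grids, n_folds = n_folds, thresholds = thresholds,
                 nb_threshold = nb_threshold, bootstrap_B = bootstrap_B),
            class = "ova_experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [experiment_config()].
#' @return An `ova_experiment_config`.
#' @export
load_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(experiment_config, raw)
}

derive_seeds <- function(root) {
  set.seed(root)
  s <- sample.int(2^30, 8)
  names(s) <- c("gen_dev", "gen_val", "imp_dev", "imp_val", "models",
                "bootstrap", "folds", "spare")
  s
}

resolve_cohort <- function(source, seed) {
  if (is.character(source)) return(read_cohort(source))
  args <- source
  args$seed <- seed
  generate_cohort(do.call(cohort_config, args))
}

model_label <- function(algorithm, with_ca125) {
  paste0(algorithm, if (with_ca125) "_ca125" else "_noca125")
}

# fit one algorithm/variant across imputations and return the
# imputation-averaged validation probability matrix plus records
fit_and_predict_variant <- function(algorithm, with_ca125, dev_tables,
                                    val_tables, grid, n_folds, seed) {
  spec <- model_spec(algorithm, with_ca125 = with_ca125, grid = grid,
                     seed = seed)
  spec <- tune_hyperparameters(spec, dev_tables[[1]], n_folds = n_folds)
  acc <- NULL; npred <- 0L
  for (dtab in dev_tables) {
    handle <- fit_model(spec, dtab)
    for (vtab in val_tables) {
      p <- predict_probabilities(handle, vtab)
      acc <- if (is.null(acc)) p else acc + p
      npred <- npred + 1L
    }
  }
  prob <- acc / npred
  prob <- prob / rowSums(prob)
  list(spec = spec, prob = prob, n_prediction_sets = npred)
}

evaluate_model <- function(prob, val, nb_threshold, bootstrap_B, boot_seed) {
  y <- val$outcome
  centers <- val$center_id
  pdi_pool <- tryCatch(
    pool_center_metric(prob, y, centers,
                       function(p, yy) pdi(p, yy, estimator = "sorted_exact")$overall_pdi,
                       scale = "logit", B = bootstrap_B, seed = boot_seed),
    error = function(e) NULL)
  cstat_pool <- tryCatch(
    pool_center_metric(prob, y, centers, binary_cstat_any_malignancy,
                       scale = "logit", B = bootstrap_B, seed = boot_seed + 1L),
    error = function(e) NULL)
  curves <- list(); center_curves <- list(); cal_excluded <- list()
  for (k in outcome_levels()) {
    cc <- calibration_curves_by_center(prob[, k], as.integer(y == k),
                                       centers, category = k)
    curves[[k]] <- cc$pooled
    center_curves[[k]] <- cc$center_curves
    if (!is.null(cc$excluded)) {
      cc$excluded$category <- k
      cal_excluded[[length(cal_excluded) + 1]] <- cc$excluded
    }
  }
  eci <- multiclass_eci(prob, y, curves = curves)
  risk <- 1 - prob[, "benign"]
  malignant <- as.integer(y != "benign")
  nb_pool <- if (length(unique(centers)) >= 2) {
    vals <- vars <- numeric(0)
    for (c in unique(centers)) {
      idx <- centers == c
      comp <- nb_components(risk[idx], malignant[idx], nb_threshold)
      vals <- c(vals, comp$nb); vars <- c(vars, comp$var)
    }
    random_effects_pool(vals, vars, scale = "identity")
  } else {
    list(mu = net_benefit(risk, malignant, nb_threshold),
         ci95 = c(NA_real_, NA_real_), pi95 = c(NA_real_, NA_real_),
         tau2 = NA_real_, k = 1L)
  }
  prevalence <- mean(malignant)
  nb_all <- treat_all_nb(prevalence, nb_threshold)
  list(pdi = pdi(prob, y, estimator = "sorted_exact"),
       pdi_pooled = pdi_pool,
       cstat_binary = binary_cstat_any_malignancy(prob, y),
       cstat_binary_pooled = cstat_pool,
       pairwise_cstats = pairwise_cstat_matrix(prob, y),
       eci = eci,
       curves = curves, center_curves = center_curves,
       calibration_excluded = if (length(cal_excluded)) do.call(rbind, cal_excluded) else NULL,
       nb = nb_pool,
       nb_treat_all = nb_all,
       referrals_avoided = referrals_avoided(nb_pool$mu, nb_all, nb_threshold))
}

#' Run the full model-comparison experiment
#'
#' Orchestrates the whole analysis: generate (or load) the development and
#' validation cohorts, multiply impute CA125 for the with-CA125 path, tune
#' and fit every requested algorithm/variant, average validation
#' predictions over all development x validation imputation pairs,
#' evaluate discrimination (PDI and c-statistics with random-effects
#' pooling over centers), calibration (center-averaged flexible curves and
#' rescaled ECI), clinical utility (decision curves and Net Benefit at the
#' headline threshold), and inter-model instability (probability ranges,
#' decision reversal, pairwise prediction exports). Deterministic for a
#' fixed config.
#'
#' @param config An `ova_experiment_config` (or a YAML path).
#' @param output_dir Optional directory; when given, all result tables are
#'   written as CSV plus a JSON manifest.
#' @return (Invisibly) a list with cohorts, per-model specs, probability
#'   matrices, evaluations, and the summary tables.
#' @export
run_experiment <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- load_experiment_config(config)
  stopifnot(inherits(config, "ova_experiment_config"))
  seeds <- derive_seeds(config$seed)
  dev <- resolve_cohort(config$dev, seeds[["gen_dev"]])
  val <- resolve_cohort(config$val, seeds[["gen_val"]])

  need_imputation <- any(config$with_ca125_variants) &&
    (anyNA(dev$ca125) || anyNA(val$ca125))
  if (need_imputation) {
    imp_dev <- impute_ca125(dev, m = config$m, seed = seeds[["imp_dev"]])
    imp_val <- impute_ca125(val, m = config$m, seed = seeds[["imp_val"]])
    dev_tables_ca125 <- imp_dev$tables
    val_tables_ca125 <- imp_val$tables
  } else {
    dev_tables_ca125 <- list(dev)
    val_tables_ca125 <- list(val)
  }

  models <- list()
  mi <- 0L
  for (with_ca125 in config$with_ca125_variants) {
    for (alg in config$algorithms) {
      mi <- mi + 1L
      label <- model_label(alg, with_ca125)
      grid <- config$grids[[alg]]
      if (with_ca125) {
        res <- fit_and_predict_variant(alg, TRUE, dev_tables_ca125,
                                       val_tables_ca125, grid,
                                       config$n_folds,
                                       seed = seeds[["models"]] + mi)
      } else {
        res <- fit_and_predict_variant(alg, FALSE, list(dev), list(val), grid,
                                       config$n_folds,
                                       seed = seeds[["models"]] + mi)
      }
      res$algorithm <- alg; res$with_ca125 <- with_ca125
      models[[label]] <- res
    }
  }

  evaluations <- list()
  for (label in names(models)) {
    evaluations[[label]] <- evaluate_model(models[[label]]$prob, val,
                                           config$nb_threshold,
                                           config$bootstrap_B,
                                           boot_seed = seeds[["bootstrap"]])
  }

  table2 <- do.call(rbind, lapply(names(models), function(label) {
    ev <- evaluations[[label]]
    pp <- ev$pdi_pooled
    eci <- ev$eci$per_category_eci
    data.frame(model = models[[label]]$algorithm,
               with_ca125 = models[[label]]$with_ca125,
               pdi = if (!is.null(pp)) pp$mu else ev$pdi$overall_pdi,
               pdi_ci_low = if (!is.null(pp)) pp$ci95[1] else NA_real_,
               pdi_ci_high = if (!is.null(pp)) pp$ci95[2] else NA_real_,
               pdi_pi_low = if (!is.null(pp)) pp$pi95[1] else NA_real_,
               pdi_pi_high = if (!is.null(pp)) pp$pi95[2] else NA_real_,
               cstat_any_malignancy = ev$cstat_binary,
               eci_benign = eci[["benign"]], eci_borderline = eci[["borderline"]],
               eci_stage_I = eci[["stage_I"]], eci_stage_II_IV = eci[["stage_II_IV"]],
               eci_sec_met = eci[["sec_met"]], eci_mean = ev$eci$mean_eci,
               nb_10 = ev$nb$mu,
               nb_10_ci_low = ev$nb$ci95[1], nb_10_ci_high = ev$nb$ci95[2],
               nb_treat_all = ev$nb_treat_all,
               referrals_avoided = ev$referrals_avoided)
  }))

  variant_tables <- list()
  for (with_ca125 in config$with_ca125_variants) {
    vlab <- if (with_ca125) "with_ca125" else "without_ca125"
    labels <- names(models)[vapply(models, function(mm) mm$with_ca125, TRUE) == with_ca125]
    probs <- lapply(models[labels], function(mm) mm$prob)
    names(probs) <- vapply(models[labels], function(mm) mm$algorithm, "")
    vt <- list()
    if (length(probs) >= 2) {
      t3 <- probability_range_table(probs)
      t3$variant <- vlab
      vt$table3 <- t3
      rev_m <- decision_reversal_matrix(probs, threshold = config$nb_threshold)
      vt$reversal <- rev_m
      vt$scatter <- lapply(stats::setNames(outcome_levels(), outcome_levels()),
                           function(k) pairwise_prediction_export(probs, k,
                                                                  patient_ids = val$patient_id))
    }
    risks <- lapply(probs, function(p) 1 - p[, "benign"])
    dc <- suppressWarnings(decision_curve(risks, as.integer(val$outcome != "benign"),
                                          val$center_id, config$thresholds))
    dc$variant <- vlab
    vt$decision_curve <- dc
    variant_tables[[vlab]] <- vt
  }

  result <- list(config = config, seeds = as.list(seeds), dev = dev, val = val,
                 models = models, evaluations = evaluations,
                 table2 = table2, variant_tables = variant_tables)
  if (!is.null(output_dir)) write_experiment(result, output_dir)
  invisible(result)
}

write_experiment <- function(result, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.csv(df, file.path(output_dir, name),
                                           row.names = FALSE)
  w(result$table2, "table2_performance.csv")
  for (vlab in names(result$variant_tables)) {
    vt <- result$variant_tables[[vlab]]
    if (!is.null(vt$table3)) w(vt$table3, sprintf("table3_probability_range_%s.csv", vlab))
    if (!is.null(vt$reversal)) {
      utils::write.csv(vt$reversal,
                       file.path(output_dir, sprintf("tableS5_decision_reversal_%s.csv", vlab)))
    }
    w(vt$decision_curve, sprintf("decision_curve_%s.csv", vlab))
    if (!is.null(vt$scatter)) {
      for (k in names(vt$scatter)) {
        w(vt$scatter[[k]], sprintf("scatter_%s_%s.csv", vlab, k))
      }
    }
  }
  cal <- do.call(rbind, lapply(names(result$evaluations), function(label) {
    ev <- result$evaluations[[label]]
    tab <- curves_to_table(c(ev$curves, unlist(ev$center_curves, recursive = FALSE)))
    tab$model <- label
    tab
  }))
  w(cal, "calibration_curves.csv")
  excluded <- do.call(rbind, lapply(names(result$evaluations), function(label) {
    ev <- result$evaluations[[label]]
    logs <- list()
    if (!is.null(ev$calibration_excluded)) {
      e1 <- ev$calibration_excluded; e1$what <- "calibration"; e1$model <- label
      names(e1)[names(e1) == "center"] <- "center_id"
      logs[[1]] <- e1[, c("model", "what", "center_id", "reason", "category")]
    }
    pe <- attr(ev$pdi_pooled, "excluded")
    if (!is.null(pe)) {
      pe$what <- "pdi"; pe$model <- label; pe$category <- NA
      logs[[length(logs) + 1]] <- pe[, c("model", "what", "center_id", "reason", "category")]
    }
    if (length(logs)) do.call(rbind, logs) else NULL
  }))
  if (!is.null(excluded)) w(excluded, "excluded_centers.csv")
  manifest <- list(
    seed = result$config$seed,
    sub_seeds = result$seeds,
    algorithms = result$config$algorithms,
    with_ca125_variants = result$config$with_ca125_variants,
    m = result$config$m,
    n_dev = nrow(result$dev), n_val = nrow(result$val),
    nb_threshold = result$config$nb_threshold,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("ovarisk")),
    selected_hyperparameters = lapply(result$models, function(mm) mm$spec$hyperparameters))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(output_dir)
}
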