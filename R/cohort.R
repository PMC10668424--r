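#' Per-class predictor distribution parameters
#'
#' Default marginal distribution parameters for the nine predictors, one
#' set per outcome class. Ages are normal (truncated to 16-95 years, sd 14,
#' means rising from benign to advanced-stage disease); CA125 and maximal
#' lesion diameter are log-normal; proportion of solid tissue is a
#' zero-inflated Beta (many purely cystic masses have no solid component);
#' acoustic shadows, ascites and >10 locules are class-specific Bernoulli;
#' papillary projections are class-specific categorical over
#' `papillation_levels()`. The defaults are calibrated so that a large
#' cohort reproduces the marginal descriptive statistics typical of
#' multicenter adnexal-mass series (median age ~49, median CA125 ~25 U/mL
#' with heavy right skew, median diameter ~70 mm, 25th percentile of solid
#' proportion equal to 0).
#'
#' @return Named list with one parameter list per outcome class.
#' @export
default_class_params <- function() {
  build <- function(age_mean, ca125_median, ca125_sdlog, diam_median,
                    psolid_zero, psolid_a, psolid_b,
                    shadows_p, ascites_p, locules_p, pap_probs) {
    list(age_mean = age_mean, age_sd = 14,
         ca125_meanlog = log(ca125_median), ca125_sdlog = ca125_sdlog,
         diam_meanlog = log(diam_median), diam_sdlog = 0.5,
         psolid_zero = psolid_zero, psolid_a = psolid_a, psolid_b = psolid_b,
         shadows_p = shadows_p, ascites_p = ascites_p, locules_p = locules_p,
         pap_probs = pap_probs)
  }
  list(
    benign      = build(45, 16, 0.95, 65, 0.42, 0.7, 2.2, 0.18, 0.02, 0.10,
                        c(0.90, 0.05, 0.015, 0.010, 0.025)),
    borderline  = build(49, 35, 1.00, 85, 0.12, 1.2, 2.0, 0.08, 0.10, 0.25,
                        c(0.55, 0.15, 0.080, 0.070, 0.150)),
    stage_I     = build(53, 75, 1.10, 95, 0.05, 1.6, 1.4, 0.06, 0.15, 0.18,
                        c(0.70, 0.10, 0.050, 0.040, 0.110)),
    stage_II_IV = build(58, 300, 1.10, 85, 0.02, 2.2, 1.0, 0.04, 0.45, 0.10,
                        c(0.80, 0.07, 0.030, 0.030, 0.070)),
    sec_met     = build(58, 120, 1.20, 75, 0.03, 2.0, 1.2, 0.05, 0.35, 0.12,
                        c(0.85, 0.06, 0.030, 0.020, 0.040))
  )
}

#' Configuration for the synthetic multicenter cohort generator
#'
#' @param n_patients Total number of patients.
#' @param n_centers Number of centers (>= 2).
#' @param n_oncology Number of centers that are oncology referral centers.
#' @param class_prevalences Five global outcome prevalences (sum to 1), in
#'   the order of `outcome_levels()`. Defaults reflect a validation-type
#'   case mix: 62% benign, 8% borderline, 7% stage I, 18% stage II-IV,
#'   5% secondary metastatic.
#' @param dirichlet_concentration Concentration of the Dirichlet from which
#'   center-level prevalences are drawn around the global ones; larger
#'   means more homogeneous centers.
#' @param oncology_malignancy_odds Multiplicative tilt on the malignant
#'   prevalences of oncology centers (case-mix enrichment), applied before
#'   the Dirichlet draw and renormalized.
#' @param class_params Per-class predictor parameters
#'   (see [default_class_params()]).
#' @param latent_mlr_coefficients Optional (n_features + 1) x 4 coefficient
#'   matrix for the known-truth multinomial logistic mechanism used by
#'   [generate_from_latent_mlr()]; benign is the reference class.
#' @param ca125_missing_rate Fraction of patients with CA125 unmeasured.
#' @param suspicion_slope Slope of the logistic model linking a malignancy
#'   suspicion score to the probability of CA125 being *measured*
#'   (suspicious tumors are measured more often).
#' @param seed Integer seed; mandatory for reproducibility.
#' @return An object of class `ova_cohort_config`.
#' @export
cohort_config <- function(n_patients = 3199, n_centers = 25, n_oncology = 15,
                          class_prevalences = c(0.62, 0.08, 0.07, 0.18, 0.05),
                          dirichlet_concentration = 30,
                          oncology_malignancy_odds = 1.6,
                          class_params = default_class_params(),
                          latent_mlr_coefficients = NULL,
                          ca125_missing_rate = 0.30,
                          suspicion_slope = 2,
                          seed = 1L) {
  if (abs(sum(class_prevalences) - 1) > 1e-12) {
    stop("class_prevalences must sum to 1 (got ", sum(class_prevalences), ")")
  }
  if (length(class_prevalences) != 5L) stop("class_prevalences must have length 5")
  if (any(class_prevalences < 0)) stop("class_prevalences must be non-negative")
  if (n_centers < 2) stop("n_centers must be >= 2")
  if (n_patients < n_centers) stop("n_patients must be >= n_centers")
  if (ca125_missing_rate < 0 || ca125_missing_rate >= 1) {
    stop("ca125_missing_rate must be in [0, 1)")
  }
  if (n_oncology > n_centers) stop("n_oncology cannot exceed n_centers")
  structure(list(n_patients = as.integer(n_patients),
                 n_centers = as.integer(n_centers),
                 n_oncology = as.integer(n_oncology),
                 class_prevalences = class_prevalences,
                 dirichlet_concentration = dirichlet_concentration,
                 oncology_malignancy_odds = oncology_malignancy_odds,
                 class_params = class_params,
                 latent_mlr_coefficients = latent_mlr_coefficients,
                 ca125_missing_rate = ca125_missing_rate,
                 suspicion_slope = suspicion_slope,
                 seed = as.integer(seed)),
            class = "ova_cohort_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = pmax(alpha, 1e-8), rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# allocate patients to centers: uneven (log-normal) sizes, every center >= 1
allocate_centers <- function(n_patients, n_centers) {
  w <- stats::rlnorm(n_centers, 0, 0.6)
  sizes <- as.vector(stats::rmultinom(1, n_patients - n_centers, w)) + 1L
  rep(seq_len(n_centers), sizes)
}

draw_class_predictors <- function(cls, params) {
  n <- length(cls)
  age <- numeric(n); ca125 <- numeric(n); psolid <- numeric(n)
  diam <- numeric(n); shadows <- integer(n); ascites <- integer(n)
  locules <- integer(n); pap <- character(n)
  for (k in outcome_levels()) {
    idx <- which(cls == k)
    if (!length(idx)) next
    p <- params[[k]]
    m <- length(idx)
    age[idx] <- rtruncnorm1(m, p$age_mean, p$age_sd, 16, 95)
    ca125[idx] <- stats::rlnorm(m, p$ca125_meanlog, p$ca125_sdlog)
    diam[idx] <- pmax(stats::rlnorm(m, p$diam_meanlog, p$diam_sdlog), 5)
    zero <- stats::runif(m) < p$psolid_zero
    ps <- stats::rbeta(m, p$psolid_a, p$psolid_b)
    ps[zero] <- 0
    psolid[idx] <- pmin(ps, 1)
    shadows[idx] <- stats::rbinom(m, 1, p$shadows_p)
    ascites[idx] <- stats::rbinom(m, 1, p$ascites_p)
    locules[idx] <- stats::rbinom(m, 1, p$locules_p)
    pap[idx] <- sample(papillation_levels(), m, TRUE, prob = p$pap_probs)
  }
  data.frame(age = age, ca125 = ca125, prop_solid = psolid,
             max_diameter = diam, shadows = shadows, ascites = ascites,
             gt10_locules = locules,
             papillations = factor(pap, levels = papillation_levels()),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic multicenter cohort
#'
#' Draws a cohort of adnexal-mass patients across centers. Center sizes are
#' uneven; center-level outcome prevalences are drawn from a Dirichlet
#' around the configured global prevalences, with oncology centers tilted
#' toward malignancy (referral case mix). Predictors are then drawn from
#' the per-class marginal distributions. If `config$ca125_missing_rate > 0`
#' CA125 missingness is injected with measurement probability increasing in
#' a malignancy suspicion score (see [inject_ca125_missingness()]).
#'
#' @param config An [cohort_config()] object.
#' @param apply_missingness Set `FALSE` to keep CA125 complete regardless
#'   of the configured missing rate.
#' @return A `data.frame` (class `ova_cohort`) with columns patient_id,
#'   center_id, center_oncology, the nine predictors, outcome, and the
#'   logical flag ca125_missing.
#' @export
generate_cohort <- function(config, apply_missingness = TRUE) {
  stopifnot(inherits(config, "ova_cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  ctr <- allocate_centers(n, config$n_centers)
  onc_centers <- sort(sample(seq_len(config$n_centers), config$n_oncology))
  oncology <- as.integer(seq_len(config$n_centers) %in% onc_centers)

  # center-level prevalences: Dirichlet around tilted global ones. Oncology
  # centers are tilted toward malignancy; non-oncology centers get the
  # compensating deflation so the cohort-level mixture stays at the
  # configured global prevalences.
  tilt <- function(base, a) {
    base[-1] <- base[-1] * a
    base / sum(base)
  }
  f_onc <- mean(oncology)
  base_onc <- tilt(config$class_prevalences, config$oncology_malignancy_odds)
  base_non <- config$class_prevalences
  if (f_onc > 0 && f_onc < 1 && config$oncology_malignancy_odds != 1) {
    target_mal <- 1 - config$class_prevalences[1]
    g <- function(a) {
      f_onc * (1 - tilt(config$class_prevalences, config$oncology_malignancy_odds)[1]) +
        (1 - f_onc) * (1 - tilt(config$class_prevalences, a)[1]) - target_mal
    }
    comp <- tryCatch(stats::uniroot(g, c(1e-3, 1))$root, error = function(e) 1)
    base_non <- tilt(config$class_prevalences, comp)
  }
  prev_c <- matrix(0, config$n_centers, 5)
  for (c in seq_len(config$n_centers)) {
    base <- if (oncology[c] == 1) base_onc else base_non
    prev_c[c, ] <- rdirichlet1(config$dirichlet_concentration * base)
  }

  cls <- character(n)
  for (c in seq_len(config$n_centers)) {
    idx <- which(ctr == c)
    cls[idx] <- sample(outcome_levels(), length(idx), TRUE, prob = prev_c[c, ])
  }

  pred <- draw_class_predictors(cls, config$class_params)
  cohort <- data.frame(patient_id = seq_len(n),
                       center_id = ctr,
                       center_oncology = oncology[ctr],
                       pred,
                       outcome = factor(cls, levels = outcome_levels()),
                       ca125_missing = FALSE,
                       stringsAsFactors = FALSE)
  class(cohort) <- c("ova_cohort", "data.frame")
  missing_levels <- setdiff(outcome_levels(), unique(cls))
  if (length(missing_levels)) {
    warning("generated cohort lacks outcome classes: ",
            paste(missing_levels, collapse = ", "))
  }
  if (apply_missingness && config$ca125_missing_rate > 0) {
    cohort <- inject_ca125_missingness(cohort, config$ca125_missing_rate,
                                       config$suspicion_slope,
                                       seed = config$seed + 101L)
  }
  cohort
}

# design matrix of the latent multinomial logistic mechanism: intercept +
# the nine predictors on the scale a linear-in-predictors model would use
# (log CA125, papillations as ordinal score 0..4)
latent_feature_matrix <- function(cohort) {
  cbind(intercept = 1,
        center_oncology = cohort$center_oncology,
        age = cohort$age,
        log_ca125 = log(cohort$ca125),
        prop_solid = cohort$prop_solid,
        max_diameter = cohort$max_diameter,
        shadows = cohort$shadows,
        ascites = cohort$ascites,
        gt10_locules = cohort$gt10_locules,
        papillations = papillation_score(cohort$papillations))
}

#' Generate a cohort from a known-truth multinomial logistic mechanism
#'
#' Predictors are drawn from the configured marginal mixture (a latent
#' style class per patient); the outcome is then drawn from the softmax of
#' linear predictors given by `config$latent_mlr_coefficients`, a
#' 10 x 4 matrix (intercept plus nine features; benign is the reference
#' class with linear predictor 0). The features enter as in
#' `latent_feature_matrix()`: CA125 on the log scale, papillations as the
#' ordinal score 0..4. Because the truth is known, every patient's true
#' probability vector is returned, enabling parameter-recovery and
#' oracle-discrimination tests.
#'
#' @param config An [cohort_config()] with `latent_mlr_coefficients` set.
#' @return List with elements `cohort` (complete CA125), `true_probs`
#'   (n x 5 row-stochastic matrix), and `coefficients`.
#' @export
generate_from_latent_mlr <- function(config) {
  stopifnot(inherits(config, "ova_cohort_config"))
  B <- config$latent_mlr_coefficients
  if (is.null(B)) stop("config$latent_mlr_coefficients must be provided")
  B <- as.matrix(B)
  if (nrow(B) != 10L || ncol(B) != 4L) {
    stop("latent_mlr_coefficients must be 10 x 4 (intercept + 9 features; ",
         "4 non-reference classes); got ", nrow(B), " x ", ncol(B))
  }
  set.seed(config$seed)
  n <- config$n_patients
  ctr <- allocate_centers(n, config$n_centers)
  onc_centers <- sort(sample(seq_len(config$n_centers), config$n_oncology))
  oncology <- as.integer(seq_len(config$n_centers) %in% onc_centers)
  style <- sample(outcome_levels(), n, TRUE, prob = config$class_prevalences)
  pred <- draw_class_predictors(style, config$class_params)
  cohort <- data.frame(patient_id = seq_len(n), center_id = ctr,
                       center_oncology = oncology[ctr], pred,
                       outcome = factor(NA_character_, levels = outcome_levels()),
                       ca125_missing = FALSE, stringsAsFactors = FALSE)
  X <- latent_feature_matrix(cohort)
  eta <- cbind(0, X %*% B)            # benign reference
  eta <- eta - apply(eta, 1, max)
  p <- exp(eta) / rowSums(exp(eta))
  colnames(p) <- outcome_levels()
  u <- stats::runif(n)
  cum <- t(apply(p, 1, cumsum))
  ki <- rowSums(u > cum) + 1L
  cohort$outcome <- factor(outcome_levels()[ki], levels = outcome_levels())
  class(cohort) <- c("ova_cohort", "data.frame")
  list(cohort = cohort, true_probs = p, coefficients = B)
}

#' Inject CA125 missingness related to malignancy suspicion
#'
#' CA125 is set to missing with probability decreasing in a malignancy
#' suspicion score (suspicious tumors are *more* often measured). The
#' suspicion score is a standardized combination of solid proportion,
#' ascites and the papillation score; the probability of being measured is
#' `plogis(a + suspicion_slope * score)` with the intercept `a` calibrated
#' so the expected overall missingness equals `rate`.
#'
#' @param cohort An `ova_cohort` with complete CA125.
#' @param rate Target overall missingness fraction, in \[0, 1).
#' @param suspicion_slope Slope on the standardized suspicion score;
#'   0 gives missingness completely at random.
#' @param seed Integer seed.
#' @return The cohort with CA125 set `NA` where unmeasured and the
#'   `ca125_missing` flag updated.
#' @export
inject_ca125_missingness <- function(cohort, rate, suspicion_slope = 2,
                                     seed = 1L) {
  if (rate >= 1) stop("rate must be < 1")
  if (rate < 0) stop("rate must be >= 0")
  if (anyNA(cohort$ca125)) stop("cohort must have complete CA125")
  if (rate == 0) return(cohort)
  set.seed(seed)
  score <- cohort$prop_solid + cohort$ascites +
    papillation_score(cohort$papillations) / 4
  z <- if (stats::sd(score) > 0) (score - mean(score)) / stats::sd(score) else score * 0
  f <- function(a) mean(stats::plogis(a + suspicion_slope * z)) - (1 - rate)
  a <- stats::uniroot(f, c(-30, 30))$root
  measured <- stats::runif(nrow(cohort)) < stats::plogis(a + suspicion_slope * z)
  cohort$ca125[!measured] <- NA_real_
  cohort$ca125_missing <- !measured
  cohort
}
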