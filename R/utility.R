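#' Net Benefit at a risk threshold
#'
#' NB = TP/n - (FP/n) * t/(1-t), where a patient is classified positive
#' when the estimated malignancy risk is greater than or equal to the
#' threshold t (the threshold itself selects).
#'
#' @param risk Estimated risk of malignancy in \[0, 1\] (for a five-class
#'   model, one minus the benign probability).
#' @param malignant 0/1 indicator of malignancy.
#' @param threshold Risk threshold in (0, 1).
#' @return Net Benefit (true positives net of harm-weighted false
#'   positives, per patient).
#' @export
net_benefit <- function(risk, malignant, threshold) {
  if (!length(risk)) stop("empty input")
  if (length(risk) != length(malignant)) stop("length mismatch")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  pos <- risk >= threshold
  n <- length(risk)
  tp <- sum(pos & malignant == 1)
  fp <- sum(pos & malignant == 0)
  tp / n - (fp / n) * threshold / (1 - threshold)
}

#' Net Benefit of referring everyone
#'
#' @param prevalence Malignancy prevalence in (0, 1).
#' @param threshold Risk threshold in (0, 1).
#' @return prevalence - (1 - prevalence) * t / (1 - t).
#' @export
treat_all_nb <- function(prevalence, threshold) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0, 1)")
  prevalence - (1 - prevalence) * threshold / (1 - threshold)
}

#' Net reduction in unnecessary referrals relative to treat-all
#'
#' Expresses a model's Net Benefit advantage over referring everyone as the
#' net proportion of patients in whom a false-positive referral is avoided
#' without missing additional malignancies.
#'
#' @param nb_model Model Net Benefit.
#' @param nb_all Treat-all Net Benefit at the same threshold.
#' @param threshold Risk threshold in (0, 1).
#' @return (nb_model - nb_all) * (1 - t) / t.
#' @export
referrals_avoided <- function(nb_model, nb_all, threshold) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  (nb_model - nb_all) * (1 - threshold) / threshold
}

# center-level NB and its delta-method variance:
# NB = P(TP) - w P(FP); Var = [ptp(1-ptp) + w^2 pfp(1-pfp) + 2 w ptp pfp]/n
nb_components <- function(risk, malignant, threshold) {
  n <- length(risk)
  pos <- risk >= threshold
  tp <- sum(pos & malignant == 1); fp <- sum(pos & malignant == 0)
  w <- threshold / (1 - threshold)
  ptp <- tp / n; pfp <- fp / n
  v <- (ptp * (1 - ptp) + w^2 * pfp * (1 - pfp) + 2 * w * ptp * pfp) / n
  list(nb = ptp - w * pfp, var = v, tp = tp, fp = fp, n = n)
}

#' Decision curve with random-effects pooling over centers
#'
#' For every threshold and strategy (each model, treat all, treat none) the
#' Net Benefit is computed per center and pooled by DerSimonian-Laird
#' random effects ([random_effects_pool()]), with within-center variances
#' from the binomial delta method. With a single center the plain NB is
#' returned with a warning.
#'
#' @param risks Named list of malignancy-risk vectors (or a single vector),
#'   one per model; for a five-class probability matrix use
#'   `1 - p[, "benign"]`.
#' @param malignant 0/1 malignancy indicator.
#' @param centers Center ids aligned to patients.
#' @param thresholds Vector of thresholds in (0, 1); default 5% to 40% in
#'   steps of 1%.
#' @return A `data.frame` (class `ova_decision_curve`) with columns
#'   threshold, strategy, nb, nb_ci_low, nb_ci_high, tau2, k_centers.
#' @export
decision_curve <- function(risks, malignant, centers,
                           thresholds = seq(0.05, 0.40, by = 0.01)) {
  if (is.numeric(risks)) risks <- list(model = risks)
  if (any(thresholds <= 0 | thresholds >= 1)) stop("thresholds must be in (0, 1)")
  strategies <- c(names(risks), "treat_all", "treat_none")
  ucenters <- unique(centers)
  single <- length(ucenters) < 2
  if (single) warning("single center: plain Net Benefit, no meta-analysis")
  rows <- list()
  for (t in thresholds) {
    for (s in strategies) {
      r <- switch(s,
                  treat_all = rep(1, length(malignant)),
                  treat_none = rep(0, length(malignant)),
                  risks[[s]])
      if (s == "treat_none") {
        rows[[length(rows) + 1]] <- data.frame(threshold = t, strategy = s,
                                               nb = 0, nb_ci_low = 0, nb_ci_high = 0,
                                               tau2 = 0, k_centers = length(ucenters))
        next
      }
      if (single) {
        comp <- nb_components(r, malignant, t)
        se <- sqrt(comp$var)
        rows[[length(rows) + 1]] <- data.frame(threshold = t, strategy = s,
                                               nb = comp$nb,
                                               nb_ci_low = comp$nb - 1.96 * se,
                                               nb_ci_high = comp$nb + 1.96 * se,
                                               tau2 = NA_real_, k_centers = 1L)
        next
      }
      vals <- vars <- numeric(0)
      for (c in ucenters) {
        idx <- centers == c
        comp <- nb_components(r[idx], malignant[idx], t)
        vals <- c(vals, comp$nb); vars <- c(vars, comp$var)
      }
      pooled <- random_effects_pool(vals, vars, scale = "identity")
      rows[[length(rows) + 1]] <- data.frame(threshold = t, strategy = s,
                                             nb = pooled$mu,
                                             nb_ci_low = pooled$ci95[1],
                                             nb_ci_high = pooled$ci95[2],
                                             tau2 = pooled$tau2,
                                             k_centers = pooled$k)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ova_decision_curve", "data.frame")
  out
}

#' Decision reversal between two models
#'
#' Percentage of patients whose estimated malignancy risk falls on opposite
#' sides of the threshold under two models ("risk >= t" is the positive
#' side).
#'
#' @param probabilities_a,probabilities_b Aligned n x 5 probability
#'   matrices (or malignancy-risk vectors).
#' @param threshold Risk threshold; default 0.10, the referral threshold in
#'   common clinical use.
#' @return Percentage in \[0, 100\].
#' @export
decision_reversal <- function(probabilities_a, probabilities_b, threshold = 0.10) {
  risk <- function(p) if (is.matrix(p)) 1 - p[, "benign"] else p
  ra <- risk(probabilities_a); rb <- risk(probabilities_b)
  if (length(ra) != length(rb)) stop("row-count mismatch between models")
  100 * mean((ra >= threshold) != (rb >= threshold))
}

#' Decision reversal matrix over a set of models
#'
#' @param probability_list Named list of aligned n x 5 probability
#'   matrices.
#' @param threshold Risk threshold (default 0.10).
#' @return Symmetric matrix of reversal percentages (diagonal 0).
#' @export
decision_reversal_matrix <- function(probability_list, threshold = 0.10) {
  nm <- names(probability_list)
  out <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i < j) {
      out[i, j] <- out[j, i] <-
        decision_reversal(probability_list[[i]], probability_list[[j]], threshold)
    }
  }
  out
}
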