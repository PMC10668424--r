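#' Polytomous Discrimination Index
#'
#' The PDI over K = 5 outcome categories is the probability that, given one
#' patient from each category and a randomly chosen target category k, the
#' model assigns the largest class-k probability to the patient who truly
#' belongs to category k. Ties are split: if the class-k patient is tied
#' with m-1 others at the maximum, the tuple earns credit 1/m, so a model
#' that outputs the same vector for everyone scores exactly 1/K = 0.2.
#'
#' Three estimators are available. `exhaustive` enumerates every one-per-
#' class tuple (only feasible for small classes); `sorted_exact` computes
#' the identical value in O(n log n) per class by counting, for each
#' patient, the fraction of each other class below / tied with them;
#' `monte_carlo` samples tuples and reports a standard error. `auto`
#' selects `exhaustive` when the number of tuples is at most 1e6 and
#' `sorted_exact` otherwise.
#'
#' @param probabilities n x 5 row-stochastic matrix (see
#'   [validate_probability_matrix()]).
#' @param outcomes Factor/character vector of true classes, aligned to rows.
#' @param estimator One of "auto", "exhaustive", "sorted_exact",
#'   "monte_carlo".
#' @param n_mc Number of sampled tuples for the Monte-Carlo estimator.
#' @param seed Seed for the Monte-Carlo estimator.
#' @return An `ova_pdi` list: `overall_pdi`, `category_pdi` (named
#'   5-vector), `estimator`, `n_tuples_evaluated`, `mc_se` (Monte-Carlo
#'   only).
#' @export
pdi <- function(probabilities, outcomes,
                estimator = c("auto", "exhaustive", "sorted_exact", "monte_carlo"),
                n_mc = 1e5, seed = 1L) {
  estimator <- match.arg(estimator)
  outcomes <- factor(as.character(outcomes), levels = outcome_levels())
  validate_probability_matrix(probabilities, n = length(outcomes))
  counts <- table(outcomes)
  absent <- names(counts)[counts == 0]
  if (length(absent)) {
    stop("PDI requires every outcome class; absent: ",
         paste(absent, collapse = ", "))
  }
  idx_by_class <- split(seq_along(outcomes), outcomes)
  n_tuples <- prod(as.numeric(counts))
  if (estimator == "auto") {
    estimator <- if (n_tuples <= 1e6) "exhaustive" else "sorted_exact"
  }
  res <- switch(estimator,
                exhaustive = pdi_exhaustive(probabilities, idx_by_class),
                sorted_exact = pdi_sorted_exact(probabilities, idx_by_class),
                monte_carlo = pdi_monte_carlo(probabilities, idx_by_class, n_mc, seed))
  res$estimator <- estimator
  class(res) <- "ova_pdi"
  res
}

# tuple credit for target class k: 1/(1 + #ties) if the class-k patient is
# at the maximum of the tuple's class-k probabilities, else 0
pdi_exhaustive <- function(p, idx_by_class) {
  K <- length(idx_by_class)
  n_tuples <- prod(lengths(idx_by_class))
  if (n_tuples > 2e6) {
    stop("exhaustive PDI infeasible for ", format(n_tuples),
         " tuples; use sorted_exact")
  }
  tuples <- as.matrix(expand.grid(idx_by_class, KEEP.OUT.ATTRS = FALSE))
  cat_pdi <- numeric(K)
  for (k in seq_len(K)) {
    vals <- matrix(p[tuples, k], nrow(tuples), K)   # class-k prob of each member
    vk <- vals[, k]
    others <- vals[, -k, drop = FALSE]
    n_greater <- rowSums(others > vk)
    n_tied <- rowSums(others == vk)
    credit <- ifelse(n_greater > 0, 0, 1 / (1 + n_tied))
    cat_pdi[k] <- mean(credit)
  }
  names(cat_pdi) <- names(idx_by_class)
  list(overall_pdi = mean(cat_pdi), category_pdi = cat_pdi,
       n_tuples_evaluated = n_tuples, mc_se = NULL)
}

pdi_sorted_exact <- function(p, idx_by_class) {
  K <- length(idx_by_class)
  cat_pdi <- numeric(K)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), K - 1))  # tie pattern over other classes
  for (k in seq_len(K)) {
    own <- p[idx_by_class[[k]], k]
    others <- lapply(idx_by_class[-k], function(i) sort(p[i, k]))
    # per own value v and other class j: a = P(x_j < v), b = P(x_j == v)
    a <- b <- matrix(0, length(own), K - 1)
    for (j in seq_len(K - 1)) {
      x <- others[[j]]
      lo <- findInterval(own, x, left.open = TRUE)   # #{x < v}
      hi <- findInterval(own, x)                     # #{x <= v}
      a[, j] <- lo / length(x)
      b[, j] <- (hi - lo) / length(x)
    }
    credit <- numeric(length(own))
    for (s in seq_len(nrow(subsets))) {
      tied <- as.logical(subsets[s, ])
      term <- rep(1 / (1 + sum(tied)), length(own))
      for (j in seq_len(K - 1)) {
        term <- term * (if (tied[j]) b[, j] else a[, j])
      }
      credit <- credit + term
    }
    cat_pdi[k] <- mean(credit)
  }
  names(cat_pdi) <- names(idx_by_class)
  list(overall_pdi = mean(cat_pdi), category_pdi = cat_pdi,
       n_tuples_evaluated = prod(lengths(idx_by_class)), mc_se = NULL)
}

pdi_monte_carlo <- function(p, idx_by_class, n_mc, seed) {
  set.seed(seed)
  K <- length(idx_by_class)
  draw <- sapply(idx_by_class, function(i) i[sample.int(length(i), n_mc, replace = TRUE)])
  credit_mat <- matrix(0, n_mc, K)
  for (k in seq_len(K)) {
    vals <- matrix(p[draw, k], n_mc, K)
    vk <- vals[, k]
    others <- vals[, -k, drop = FALSE]
    n_greater <- rowSums(others > vk)
    n_tied <- rowSums(others == vk)
    credit_mat[, k] <- ifelse(n_greater > 0, 0, 1 / (1 + n_tied))
  }
  cat_pdi <- colMeans(credit_mat)
  names(cat_pdi) <- names(idx_by_class)
  overall_per_tuple <- rowMeans(credit_mat)
  list(overall_pdi = mean(cat_pdi), category_pdi = cat_pdi,
       n_tuples_evaluated = n_mc,
       mc_se = stats::sd(overall_per_tuple) / sqrt(n_mc))
}

#' Conditional risk for a pair of outcome categories
#'
#' For categories k and l, each patient's conditional risk of l is
#' p_l / (p_k + p_l): the class-l probability renormalized to the pair.
#' When both probabilities are zero the pair carries no information and the
#' conditional risk is set to 0.5.
#'
#' @param probabilities n x 5 row-stochastic matrix.
#' @param class_k,class_l Outcome level names or indices; must differ.
#' @return Numeric vector of conditional risks in \[0, 1\].
#' @export
conditional_risk <- function(probabilities, class_k, class_l) {
  k <- resolve_class(class_k); l <- resolve_class(class_l)
  if (k == l) stop("class_k and class_l must differ")
  pk <- probabilities[, k]; pl <- probabilities[, l]
  denom <- pk + pl
  out <- ifelse(denom > 0, pl / denom, 0.5)
  out
}

resolve_class <- function(x) {
  if (is.numeric(x)) {
    if (!x %in% 1:5) stop("class index out of range: ", x)
    return(as.integer(x))
  }
  i <- match(as.character(x), outcome_levels())
  if (is.na(i)) stop("unknown outcome class: ", x)
  i
}

# binary AUROC with Mann-Whitney 1/2 tie credit
cstat_binary <- function(risk, event) {
  event <- as.logical(event)
  n1 <- sum(event); n0 <- sum(!event)
  if (n1 == 0 || n0 == 0) stop("AUROC needs both event and non-event patients")
  r <- rank(risk, ties.method = "average")
  (sum(r[event]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pairwise c-statistic by the conditional risk method
#'
#' Among patients truly in categories k or l, the AUROC of the conditional
#' risk of l (membership of l as the event), with ties credited 1/2.
#'
#' @inheritParams conditional_risk
#' @param outcomes True classes aligned to the probability rows.
#' @return The pairwise c-statistic in \[0, 1\].
#' @export
pairwise_cstat <- function(probabilities, outcomes, class_k, class_l) {
  k <- resolve_class(class_k); l <- resolve_class(class_l)
  outcomes <- factor(as.character(outcomes), levels = outcome_levels())
  keep <- outcomes %in% outcome_levels()[c(k, l)]
  if (!any(outcomes == outcome_levels()[k]) || !any(outcomes == outcome_levels()[l])) {
    stop("both classes must have at least one patient")
  }
  cr <- conditional_risk(probabilities[keep, , drop = FALSE], k, l)
  cstat_binary(cr, outcomes[keep] == outcome_levels()[l])
}

#' All pairwise c-statistics
#'
#' @inheritParams pairwise_cstat
#' @return 5 x 5 matrix with the upper triangle holding the pairwise
#'   c-statistics (row class = k, column class = l); diagonal NA.
#' @export
pairwise_cstat_matrix <- function(probabilities, outcomes) {
  lev <- outcome_levels()
  out <- matrix(NA_real_, 5, 5, dimnames = list(lev, lev))
  for (k in 1:4) for (l in (k + 1):5) {
    out[k, l] <- tryCatch(pairwise_cstat(probabilities, outcomes, k, l),
                          error = function(e) NA_real_)
  }
  out
}

#' Binary c-statistic for benign versus any malignancy
#'
#' The estimated risk of any malignancy is one minus the estimated benign
#' probability; the four malignant categories are merged into the event.
#'
#' @inheritParams pairwise_cstat
#' @return AUROC in \[0, 1\].
#' @export
binary_cstat_any_malignancy <- function(probabilities, outcomes) {
  outcomes <- factor(as.character(outcomes), levels = outcome_levels())
  validate_probability_matrix(probabilities, n = length(outcomes))
  event <- outcomes != "benign"
  if (!any(event) || all(event)) {
    stop("need both benign and malignant patients")
  }
  cstat_binary(1 - probabilities[, "benign"], event)
}
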