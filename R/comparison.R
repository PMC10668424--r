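#' Between-model probability range summary
#'
#' For every patient and outcome category, the range is the difference
#' between the highest and lowest probability estimated by the models.
#' The summary counts, per category and range threshold, how many patients
#' have a range at least that large — a descriptive measure of how much
#' the choice of algorithm alone changes individual risk estimates.
#'
#' @param probability_matrices Named list (>= 2) of aligned n x 5
#'   probability matrices.
#' @param thresholds Range thresholds (default 0.05, 0.10, 0.20, 0.30).
#' @return Data frame with columns threshold, category, n, pct.
#' @export
probability_range_table <- function(probability_matrices,
                                    thresholds = c(0.05, 0.10, 0.20, 0.30)) {
  if (length(probability_matrices) < 2) stop("need at least 2 models")
  dims <- unique(lapply(probability_matrices, dim))
  if (length(dims) != 1) stop("probability matrices are not aligned")
  n <- dims[[1]][1]
  lev <- outcome_levels()
  rows <- list()
  for (k in seq_along(lev)) {
    vals <- sapply(probability_matrices, function(p) p[, k])
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
    rng <- apply(vals, 1, max) - apply(vals, 1, min)
    for (t in thresholds) {
      cnt <- sum(rng >= t)
      rows[[length(rows) + 1]] <- data.frame(threshold = t, category = lev[k],
                                             n = cnt, pct = 100 * cnt / n)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$threshold, match(out$category, lev)), ]
}

#' Pairwise prediction export for one category
#'
#' Long-format table of estimated probabilities for all unordered model
#' pairs, suitable for scatter plots of inter-model agreement.
#'
#' @param probability_matrices Named list (>= 2) of aligned n x 5
#'   probability matrices.
#' @param category Outcome level name.
#' @param patient_ids Optional patient ids (default row numbers).
#' @return Data frame with columns patient_id, model_a, model_b, p_a, p_b.
#' @export
pairwise_prediction_export <- function(probability_matrices, category,
                                       patient_ids = NULL) {
  if (length(probability_matrices) < 2) stop("need at least 2 models")
  k <- resolve_class(category)
  nm <- names(probability_matrices)
  n <- nrow(probability_matrices[[1]])
  if (is.null(patient_ids)) patient_ids <- seq_len(n)
  rows <- list()
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i >= j) next
    rows[[length(rows) + 1]] <- data.frame(
      patient_id = patient_ids,
      model_a = nm[i], model_b = nm[j],
      p_a = probability_matrices[[i]][, k],
      p_b = probability_matrices[[j]][, k])
  }
  do.call(rbind, rows)
}
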