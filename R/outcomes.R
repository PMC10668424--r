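#' Outcome categories for adnexal masses
#'
#' The five histology-based outcome categories used throughout the package,
#' in their fixed order: benign, borderline, stage I primary invasive,
#' stage II-IV primary invasive, and secondary metastasis.
#'
#' @return Character vector of the five outcome level names.
#' @export
outcome_levels <- function() {
  c("benign", "borderline", "stage_I", "stage_II_IV", "sec_met")
}

#' Papillary projection levels
#'
#' Number of papillary projections as recorded at ultrasound; ">3" is the
#' top category.
#'
#' @return Character vector of the five ordinal levels.
#' @export
papillation_levels <- function() {
  c("0", "1", "2", "3", ">3")
}

# ordinal score 0..4 used when papillations enter a model numerically
papillation_score <- function(x) {
  as.integer(factor(as.character(x), levels = papillation_levels())) - 1L
}

#' Validate a matrix of five-class probability estimates
#'
#' Checks that `p` is an n x 5 row-stochastic matrix (rows sum to 1 within
#' `tol`, all entries in \[0, 1\]) with columns in the fixed outcome order.
#'
#' @param p Numeric matrix of class probabilities.
#' @param n Optional expected number of rows.
#' @param tol Tolerance on row sums (default 1e-8).
#' @return `p`, invisibly, with outcome level column names attached.
#' @export
validate_probability_matrix <- function(p, n = NULL, tol = 1e-8) {
  if (!is.matrix(p) || !is.numeric(p)) stop("probability matrix must be a numeric matrix")
  if (ncol(p) != 5L) stop("probability matrix must have 5 columns, got ", ncol(p))
  if (!is.null(n) && nrow(p) != n) {
    stop("probability matrix has ", nrow(p), " rows; expected ", n)
  }
  if (anyNA(p)) stop("probability matrix contains missing values")
  if (any(p < -tol) || any(p > 1 + tol)) stop("probabilities outside [0, 1]")
  rs <- rowSums(p)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad)) {
    stop("rows do not sum to 1 (first offender: row ", bad[1],
         ", sum ", format(rs[bad[1]]), ")")
  }
  colnames(p) <- outcome_levels()
  invisible(p)
}
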