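# fixture builders shared across test files

# random row-stochastic n x 5 matrix
random_prob_matrix <- function(n, seed = NULL, round_to = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- matrix(rgamma(n * 5, shape = 1), n, 5)
  if (!is.null(round_to)) p <- round(p, round_to) + 1e-9  # induce ties
  p <- p / rowSums(p)
  colnames(p) <- outcome_levels()
  p
}

# balanced outcome vector with n_per patients per class
balanced_outcomes <- function(n_per) {
  factor(rep(outcome_levels(), each = n_per), levels = outcome_levels())
}

# small complete cohort for model tests
small_cohort <- function(n = 400, seed = 1, n_centers = 4) {
  cfg <- cohort_config(n_patients = n, n_centers = n_centers,
                       n_oncology = ceiling(n_centers / 2),
                       ca125_missing_rate = 0, seed = seed)
  generate_cohort(cfg)
}

# coefficients of a linear-truth latent multinomial mechanism, on the scale
# of latent_feature_matrix (intercept + 9 features; benign reference)
latent_coefs <- function() {
  B <- matrix(0, 10, 4,
              dimnames = list(c("intercept", "center_oncology", "age",
                                "log_ca125", "prop_solid", "max_diameter",
                                "shadows", "ascites", "gt10_locules",
                                "papillations"),
                              outcome_levels()[-1]))
  B["intercept", ] <- c(-3.0, -4.0, -5.0, -6.0)
  B["center_oncology", ] <- c(0.2, 0.3, 0.5, 0.4)
  B["age", ] <- c(0.01, 0.02, 0.04, 0.04)
  B["log_ca125", ] <- c(0.3, 0.5, 0.9, 0.6)
  B["prop_solid", ] <- c(1.0, 1.5, 2.0, 1.5)
  B["max_diameter", ] <- c(0.002, 0.004, 0.004, 0.002)
  B["shadows", ] <- c(-0.3, -0.5, -0.7, -0.4)
  B["ascites", ] <- c(0.3, 0.6, 1.2, 0.9)
  B["gt10_locules", ] <- c(0.2, 0.1, 0.2, 0.2)
  B["papillations", ] <- c(0.3, 0.2, 0.2, 0.1)
  B
}

# O(n^2) pair-counting AUROC oracle with half-credit ties
auroc_oracle <- function(risk, event) {
  pos <- risk[event == 1]; neg <- risk[event == 0]
  s <- 0
  for (a in pos) for (b in neg) {
    s <- s + (a > b) + 0.5 * (a == b)
  }
  s / (length(pos) * length(neg))
}

# tiny tuning grids that keep model tests fast
tiny_grids <- function() {
  list(mlr = data.frame(dummy = 0),
       ridge_mlr = data.frame(lambda = c(0.001, 0.1)),
       rf = data.frame(num_trees = 100, mtry = 3, min_node = 5),
       xgboost = data.frame(max_depth = 3, eta = 0.1, subsample = 1,
                            max_rounds = 100),
       nn = data.frame(size = 3, decay = 0.01),
       svm = data.frame(cost = 1, gamma = 0.1))
}
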