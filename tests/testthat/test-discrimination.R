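test_that("PDI endpoints: uniform model scores 0.2, indicator model scores 1", {
  y <- balanced_outcomes(3)
  p_unif <- matrix(0.2, length(y), 5, dimnames = list(NULL, outcome_levels()))
  for (est in c("exhaustive", "sorted_exact")) {
    r <- pdi(p_unif, y, estimator = est)
    expect_identical(r$overall_pdi, 0.2)
    expect_identical(unname(r$category_pdi), rep(0.2, 5))
  }
  r_mc <- pdi(p_unif, y, estimator = "monte_carlo", n_mc = 1000, seed = 1)
  expect_identical(r_mc$overall_pdi, 0.2)

  p_ind <- diag(5)[as.integer(y), ]
  colnames(p_ind) <- outcome_levels()
  for (est in c("exhaustive", "sorted_exact")) {
    expect_identical(pdi(p_ind, y, estimator = est)$overall_pdi, 1)
  }
})

test_that("sorted-exact PDI equals exhaustive tuple enumeration", {
  set.seed(42)
  for (rep in 1:25) {
    n_per <- sample(1:4, 5, replace = TRUE)
    y <- factor(rep(outcome_levels(), times = n_per), levels = outcome_levels())
    p <- random_prob_matrix(length(y), round_to = if (rep %% 2) 1 else NULL)
    a <- pdi(p, y, estimator = "exhaustive")
    b <- pdi(p, y, estimator = "sorted_exact")
    expect_equal(a$overall_pdi, b$overall_pdi, tolerance = 1e-12)
    expect_equal(a$category_pdi, b$category_pdi, tolerance = 1e-12)
  }
})

test_that("overall PDI is the mean of the category components", {
  y <- balanced_outcomes(6)
  p <- random_prob_matrix(length(y), seed = 7)
  r <- pdi(p, y, estimator = "sorted_exact")
  expect_equal(r$overall_pdi, mean(r$category_pdi), tolerance = 1e-10)
  expect_true(all(r$category_pdi >= 0 & r$category_pdi <= 1))
})

test_that("Monte-Carlo PDI converges to the exact value", {
  y <- balanced_outcomes(30)
  p <- random_prob_matrix(length(y), seed = 3)
  exact <- pdi(p, y, estimator = "sorted_exact")$overall_pdi
  mc <- pdi(p, y, estimator = "monte_carlo", n_mc = 1e5, seed = 9)
  expect_lt(abs(mc$overall_pdi - exact), 3 * mc$mc_se)
  mc2 <- pdi(p, y, estimator = "monte_carlo", n_mc = 1e4, seed = 9)
  mc3 <- pdi(p, y, estimator = "monte_carlo", n_mc = 1e4, seed = 9)
  expect_identical(mc2$overall_pdi, mc3$overall_pdi)
})

test_that("PDI under label permutation is near the useless-model value", {
  set.seed(5)
  y <- balanced_outcomes(20)
  p <- random_prob_matrix(length(y))
  vals <- replicate(30, pdi(p, sample(y), estimator = "sorted_exact")$overall_pdi)
  expect_lt(abs(mean(vals) - 0.2), 0.02)
})

test_that("PDI errors name an absent class", {
  y <- factor(rep(c("benign", "borderline"), 5), levels = outcome_levels())
  p <- random_prob_matrix(length(y), seed = 1)
  expect_error(pdi(p, y), "stage_I")
})

test_that("conditional risk follows its closed form with the 0.5 convention", {
  p <- rbind(c(0.5, 0.5, 0, 0, 0),
             c(0.1, 0.3, 0.2, 0.2, 0.2),
             c(0, 0, 0.4, 0.3, 0.3))
  colnames(p) <- outcome_levels()
  cr <- conditional_risk(p, "benign", "borderline")
  expect_equal(cr, c(0.5, 0.75, 0.5))
  expect_error(conditional_risk(p, "benign", "benign"), "must differ")
})

test_that("pairwise c-statistic matches the pair-counting oracle", {
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(20:200, 1)
    y <- factor(sample(outcome_levels()[c(1, 4)], n, replace = TRUE,
                       prob = c(0.6, 0.4)), levels = outcome_levels())
    if (length(unique(y)) < 2) next
    p <- random_prob_matrix(n, round_to = if (rep %% 2) 1 else NULL)
    got <- pairwise_cstat(p, y, "benign", "stage_II_IV")
    cr <- conditional_risk(p, "benign", "stage_II_IV")
    want <- auroc_oracle(cr, as.integer(y == "stage_II_IV"))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("pairwise c-statistic hits its analytic endpoints", {
  y <- factor(c(rep("benign", 4), rep("sec_met", 4)), levels = outcome_levels())
  p <- matrix(0.25 / 4, 8, 5, dimnames = list(NULL, outcome_levels()))
  p[1:4, "benign"] <- 0.9; p[1:4, "sec_met"] <- 0.02
  p[5:8, "sec_met"] <- 0.9; p[5:8, "benign"] <- 0.02
  p <- p / rowSums(p)
  expect_equal(pairwise_cstat(p, y, "benign", "sec_met"), 1)
  p_flat <- matrix(0.2, 8, 5, dimnames = list(NULL, outcome_levels()))
  expect_equal(pairwise_cstat(p_flat, y, "benign", "sec_met"), 0.5)
  y_one <- factor(rep("benign", 8), levels = outcome_levels())
  expect_error(pairwise_cstat(p, y_one, "benign", "sec_met"), "at least one")
})

test_that("pairwise c-statistic is invariant to monotone transforms and matches binary AUROC", {
  set.seed(17)
  n <- 80
  y <- factor(sample(outcome_levels()[1:2], n, replace = TRUE),
              levels = outcome_levels())
  # two populated classes only; conditional risk reduces to p_l renormalized
  p2 <- matrix(runif(n * 2), n, 2); p2 <- p2 / rowSums(p2)
  p <- cbind(p2, matrix(0, n, 3))
  colnames(p) <- outcome_levels()
  got <- pairwise_cstat(p, y, "benign", "borderline")
  want <- auroc_oracle(p[, 2] / rowSums(p[, 1:2]), as.integer(y == "borderline"))
  expect_equal(got, want, tolerance = 1e-12)
  # strictly increasing transform of the conditional risks leaves AUROC unchanged
  cr <- conditional_risk(p, 1, 2)
  ev <- as.integer(y == "borderline")
  expect_equal(auroc_oracle(plogis(5 * cr - 1), ev), auroc_oracle(cr, ev),
               tolerance = 1e-12)
})

test_that("binary any-malignancy c-statistic behaves and matches brute force", {
  y <- factor(c("benign", "benign", "benign", "borderline", "stage_I",
                "stage_II_IV", "sec_met", "benign"), levels = outcome_levels())
  p <- random_prob_matrix(8, seed = 23)
  got <- binary_cstat_any_malignancy(p, y)
  want <- auroc_oracle(1 - p[, "benign"], as.integer(y != "benign"))
  expect_equal(got, want, tolerance = 1e-12)

  p_perfect <- matrix(0, 8, 5, dimnames = list(NULL, outcome_levels()))
  p_perfect[y == "benign", "benign"] <- 1
  p_perfect[y != "benign", "stage_II_IV"] <- 1
  expect_equal(binary_cstat_any_malignancy(p_perfect, y), 1)
  p_const <- matrix(0.2, 8, 5, dimnames = list(NULL, outcome_levels()))
  expect_equal(binary_cstat_any_malignancy(p_const, y), 0.5)
  expect_error(binary_cstat_any_malignancy(p, factor(rep("benign", 8),
                                                     levels = outcome_levels())),
               "both benign and malignant")
})
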