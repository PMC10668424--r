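test_that("homogeneous centers pool to their common value with zero tau2", {
  p <- random_effects_pool(rep(0.9, 5), rep(0.01, 5))
  expect_equal(p$mu, 0.9, tolerance = 1e-12)
  expect_equal(p$tau2, 0, tolerance = 1e-12)
  # PI still wider than CI through the t multiplier
  expect_lt(p$pi95[1], p$ci95[1])
  expect_gt(p$pi95[2], p$ci95[2])
})

test_that("DerSimonian-Laird pooling matches the hand-evaluated formulas", {
  y <- c(0.2, 0.5, 0.8); v <- rep(0.01, 3)
  # hand evaluation: w = 100 each; ybar = 0.5; Q = 100*(0.09+0+0.09) = 18;
  # tau2 = (18 - 2) / (300 - 30000/300) = 16/200 = 0.08;
  # w* = 1/0.09 each -> mu = 0.5, se = sqrt(0.09/3)
  p <- random_effects_pool(y, v)
  expect_equal(p$Q, 18, tolerance = 1e-10)
  expect_equal(p$tau2, 0.08, tolerance = 1e-10)
  expect_equal(p$mu, 0.5, tolerance = 1e-10)
  se <- sqrt(0.09 / 3)
  expect_equal(p$ci95, 0.5 + c(-1, 1) * qnorm(0.975) * se, tolerance = 1e-10)
  expect_equal(p$pi95, 0.5 + c(-1, 1) * qt(0.975, 1) * sqrt(0.08 + se^2),
               tolerance = 1e-10)
})

test_that("pooling agrees with metafor's DL implementation", {
  skip_if_not_installed("metafor")
  set.seed(44)
  y <- runif(8, 0.3, 0.9); v <- runif(8, 0.002, 0.02)
  ours <- random_effects_pool(y, v)
  ref <- metafor::rma(yi = y, vi = v, method = "DL")
  expect_equal(ours$mu, as.numeric(ref$b), tolerance = 1e-8)
  expect_equal(ours$tau2, ref$tau2, tolerance = 1e-8)
  expect_equal(ours$ci95, c(ref$ci.lb, ref$ci.ub), tolerance = 1e-6)
})

test_that("pooling guards its preconditions and ranges", {
  expect_error(random_effects_pool(0.5, 0.1), "at least 2")
  expect_error(random_effects_pool(c(0.2, NA), c(0.1, 0.1)), "non-finite")
  expect_error(random_effects_pool(c(0.2, 1.2), c(0.1, 0.1), scale = "logit"),
               "strictly in")
  # k = 2: PI undefined
  p2 <- random_effects_pool(c(0.4, 0.6), c(0.01, 0.01))
  expect_true(all(is.na(p2$pi95)))
  # logit pooling keeps everything in (0, 1) and mu within the center range
  set.seed(3)
  y <- runif(6, 0.55, 0.95); v <- runif(6, 0.001, 0.01)
  pl <- random_effects_pool(y, v, scale = "logit")
  expect_true(pl$mu > min(y) && pl$mu < max(y))
  expect_true(all(c(pl$ci95, pl$pi95) > 0 & c(pl$ci95, pl$pi95) < 1))
})

test_that("center_statistics maps metrics with eligibility and variance", {
  set.seed(10)
  n <- 600
  centers <- rep(1:4, each = 150)
  y <- factor(sample(outcome_levels(), n, TRUE, prob = c(0.5, 0.15, 0.1, 0.15, 0.1)),
              levels = outcome_levels())
  # center 4 gets only benign patients: ineligible for the binary c-statistic
  y[centers == 4] <- "benign"
  p <- random_prob_matrix(n)
  cs <- center_statistics(p, y, centers, binary_cstat_any_malignancy,
                          B = 100, seed = 2)
  expect_equal(nrow(cs$estimates), 3L)
  expect_equal(cs$excluded$center_id, 4)
  expect_true(all(cs$estimates$variance > 0))

  # closed-form variance path: prevalence with binomial variance
  prev_fn <- function(p, yy) mean(yy != "benign")
  prev_var <- function(p, yy) {
    pr <- mean(yy != "benign"); pr * (1 - pr) / length(yy)
  }
  cs2 <- center_statistics(p, y, centers, prev_fn, variance_fn = prev_var)
  expect_equal(nrow(cs2$estimates), 4L)
  e1 <- cs2$estimates[1, ]
  expect_equal(e1$variance, e1$value * (1 - e1$value) / e1$n, tolerance = 1e-12)

  expect_error(center_statistics(p, factor(rep("benign", n), levels = outcome_levels()),
                                 centers, binary_cstat_any_malignancy),
               "no eligible centers")
})

test_that("bootstrap SEs are consistent with between-center spread", {
  set.seed(12)
  n_per <- 150; k <- 10
  y <- factor(rep(sample(c("benign", "stage_II_IV"), n_per * k, TRUE),),
              levels = outcome_levels())
  risk <- plogis(qlogis(0.4) + 1.2 * (y == "stage_II_IV") + rnorm(n_per * k))
  p <- matrix(0, n_per * k, 5, dimnames = list(NULL, outcome_levels()))
  p[, "benign"] <- 1 - risk; p[, "stage_II_IV"] <- risk
  centers <- rep(1:k, each = n_per)
  cs <- center_statistics(p, y, centers, binary_cstat_any_malignancy,
                          B = 200, seed = 5)
  # centers are exchangeable: observed spread of estimates should be of the
  # same order as the bootstrap SEs (ratio within a broad factor)
  ratio <- sd(cs$estimates$value) / sqrt(mean(cs$estimates$variance))
  expect_gt(ratio, 0.4)
  expect_lt(ratio, 2.5)
})

test_that("pool_center_metric attaches center provenance", {
  set.seed(20)
  n <- 800
  centers <- rep(1:4, each = 200)
  co <- small_cohort(n = n, seed = 33, n_centers = 4)
  p <- random_prob_matrix(n)
  pooled <- pool_center_metric(p, co$outcome, co$center_id,
                               function(pp, yy) pdi(pp, yy, estimator = "sorted_exact")$overall_pdi,
                               scale = "logit", B = 50, seed = 3)
  expect_s3_class(pooled, "ova_pooled")
  expect_true(!is.null(attr(pooled, "centers")))
  # random probabilities: pooled PDI near the useless value
  expect_lt(abs(pooled$mu - 0.2), 0.05)
})
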