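test_that("calibration curve recovers constant and diagonal truths", {
  set.seed(1)
  p <- runif(200, 0.1, 0.9)
  cv1 <- fit_flexible_curve(p, rep(1, 200))
  expect_true(all(cv1$observed == 1))
  expect_equal(length(cv1$grid), length(cv1$observed))
  expect_true(all(diff(cv1$grid) > 0))

  # events drawn from the predictions themselves: curve hugs the diagonal
  n <- 50000
  p <- rbeta(n, 2, 3)
  y <- rbinom(n, 1, p)
  cv <- fit_flexible_curve(p, y)
  expect_lt(max(abs(cv$observed - cv$grid)), 0.03)

  # events independent of predictions: curve near horizontal at the rate
  y_ind <- rbinom(n, 1, 0.3)
  cv_ind <- fit_flexible_curve(p, y_ind)
  expect_lt(max(abs(cv_ind$observed - 0.3)), 0.03)
})

test_that("calibration curve rejects degenerate input", {
  expect_error(fit_flexible_curve(rep(0.4, 50), rbinom(50, 1, 0.5)),
               "degenerate")
  expect_error(fit_flexible_curve(runif(10), rbinom(10, 1, 0.5)), "at least 20")
  expect_error(fit_flexible_curve(runif(30), runif(30)), "0/1")
})

test_that("center-curve averaging uses sqrt-n weights", {
  mk <- function(value, n, center) {
    structure(list(grid = seq(0, 1, length.out = 11),
                   observed = rep(value, 11), category = "benign",
                   center_id = center, weight = sqrt(n), n = n,
                   span = 0.75, degree = 1),
              class = "ova_calibration_curve")
  }
  one <- average_center_curves(list(mk(0.3, 50, "a")))
  expect_equal(one$observed, rep(0.3, 11))

  eq <- average_center_curves(list(mk(0.2, 100, "a"), mk(0.6, 100, "b")))
  expect_equal(unique(eq$observed), 0.4)

  # n = 100 and 400: weights 10 and 20 -> (10*0 + 20*0.3)/30 = 0.2
  wt <- average_center_curves(list(mk(0.0, 100, "a"), mk(0.3, 400, "b")))
  expect_equal(unique(wt$observed), 0.2, tolerance = 1e-12)

  expect_error(average_center_curves(list()), "empty")
  bad <- mk(0.2, 50, "a"); bad$category <- "sec_met"
  expect_error(average_center_curves(list(bad, mk(0.3, 50, "b"))),
               "different categories")

  # ordered center curves bracket the average pointwise
  lo <- mk(0.1, 200, "a"); hi <- mk(0.5, 300, "b")
  avg <- average_center_curves(list(lo, hi))
  expect_true(all(avg$observed >= 0.1 - 1e-12 & avg$observed <= 0.5 + 1e-12))
})

test_that("rescaled ECI hits its endpoints and the hand-computed case", {
  p <- c(0.2, 0.4, 0.6, 0.8)
  y <- c(0, 0, 1, 1)  # event rate 0.5
  diag_curve <- structure(list(grid = seq(0, 1, length.out = 101),
                               observed = seq(0, 1, length.out = 101),
                               category = "benign", center_id = "pooled",
                               weight = 2, n = 4, span = 0.75, degree = 1),
                          class = "ova_calibration_curve")
  expect_equal(rescaled_eci(p, y, diag_curve), 0)

  flat_curve <- diag_curve; flat_curve$observed <- rep(0.5, 101)
  expect_equal(rescaled_eci(p, y, flat_curve), 1)

  # c(p) = p + 0.1: raw = 0.01, denominator = mean((p - 0.5)^2) = 0.05
  shift_curve <- diag_curve; shift_curve$observed <- diag_curve$grid + 0.1
  expect_equal(rescaled_eci(p, y, shift_curve), 0.2, tolerance = 1e-12)

  expect_error(rescaled_eci(rep(0.5, 4), y, diag_curve), "undefined")
})

test_that("rescaled ECI is invariant to patient relabeling", {
  set.seed(4)
  n <- 500
  p <- rbeta(n, 2, 3); y <- rbinom(n, 1, p)
  cv <- fit_flexible_curve(p, y)
  perm <- sample(n)
  expect_equal(rescaled_eci(p, y, cv), rescaled_eci(p[perm], y[perm], cv),
               tolerance = 1e-12)
})

test_that("multiclass ECI separates calibrated from uninformative models", {
  set.seed(6)
  n <- 20000
  p <- matrix(rgamma(n * 5, shape = c(2, 1, 1, 1, 1)), n, 5, byrow = TRUE)
  p <- p / rowSums(p); colnames(p) <- outcome_levels()
  draw_class <- function(prob) {
    u <- runif(nrow(prob)); cum <- t(apply(prob, 1, cumsum))
    factor(outcome_levels()[rowSums(u > cum) + 1], levels = outcome_levels())
  }
  y_cal <- draw_class(p)
  e_cal <- multiclass_eci(p, y_cal)
  expect_lt(e_cal$mean_eci, 0.03)
  expect_equal(e_cal$mean_eci, mean(e_cal$per_category_eci), tolerance = 1e-12)

  y_ind <- factor(sample(outcome_levels(), n, TRUE,
                         prob = c(0.4, 0.2, 0.15, 0.15, 0.1)),
                  levels = outcome_levels())
  e_ind <- multiclass_eci(p, y_ind)
  expect_gt(e_ind$mean_eci, 0.85)
})

test_that("logit-shifted probabilities push the curve off the diagonal one-sidedly", {
  set.seed(8)
  n <- 30000
  p <- rbeta(n, 2, 3)
  y <- rbinom(n, 1, plogis(qlogis(p) + 0.6))  # true rate above stated risk
  cv <- fit_flexible_curve(p, y)
  inner <- cv$grid > 0.1 & cv$grid < 0.9
  expect_true(all(cv$observed[inner] > cv$grid[inner]))
})

test_that("per-center curve construction excludes ineligible centers", {
  set.seed(9)
  n <- 300
  p <- rbeta(n, 2, 3); y <- rbinom(n, 1, p)
  centers <- c(rep("big1", 140), rep("big2", 140), rep("tiny", 10),
               rep("onelevel", 10))
  y[centers == "onelevel"] <- 1
  res <- calibration_curves_by_center(p, y, centers, category = "benign")
  expect_equal(length(res$center_curves), 2L)
  expect_true(all(c("tiny", "onelevel") %in% res$excluded$center))
  expect_s3_class(res$pooled, "ova_calibration_curve")
})
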