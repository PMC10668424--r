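test_that("generator is deterministic and hits configured prevalences", {
  cfg <- cohort_config(seed = 20)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  # default case mix: 62% benign within 3 percentage points at n = 3199
  expect_lt(abs(mean(a$outcome == "benign") - 0.62), 0.03)
  expect_equal(sort(unique(a$center_id)), 1:25)
  expect_true(all(table(a$center_id) >= 1))
})

test_that("generator rejects invalid configurations", {
  expect_error(cohort_config(class_prevalences = c(0.5, 0.2, 0.1, 0.1, 0.05)),
               "sum to 1")
  expect_error(cohort_config(n_patients = 10, n_centers = 25), "n_patients")
  expect_error(cohort_config(ca125_missing_rate = 1), "missing_rate")
  expect_error(cohort_config(n_centers = 1), "n_centers")
})

test_that("degenerate single-class prevalence generates with a warning", {
  cfg <- cohort_config(n_patients = 100, n_centers = 2, n_oncology = 1,
                       class_prevalences = c(1, 0, 0, 0, 0),
                       ca125_missing_rate = 0, seed = 3)
  expect_warning(co <- generate_cohort(cfg), "lacks outcome classes")
  expect_true(all(co$outcome == "benign"))
})

test_that("marginal fidelity at n = 10,000 matches the intended cohort profile", {
  co <- generate_cohort(cohort_config(n_patients = 10000, seed = 11),
                        apply_missingness = FALSE)
  props <- prop.table(table(co$outcome))
  expect_true(all(abs(props - c(0.62, 0.08, 0.07, 0.18, 0.05)) < 0.03))
  expect_lt(abs(median(co$age) - 49), 4)
  expect_gt(median(co$ca125), 15)
  expect_lt(median(co$ca125), 45)
  expect_identical(unname(quantile(co$prop_solid, 0.25)), 0)
  expect_true(all(co$prop_solid >= 0 & co$prop_solid <= 1))
  expect_true(all(co$age > 0) && all(co$max_diameter > 0) && all(co$ca125 > 0))
})

test_that("CA125 missingness hits the target rate and follows suspicion", {
  co <- generate_cohort(cohort_config(seed = 9), apply_missingness = FALSE)
  out <- inject_ca125_missingness(co, rate = 0.30, suspicion_slope = 2, seed = 4)
  expect_lt(abs(mean(is.na(out$ca125)) - 0.30), 0.02)
  expect_identical(out$ca125_missing, is.na(out$ca125))
  # suspicious tumors (high solid proportion) are measured more often
  hi <- out$prop_solid > median(out$prop_solid)
  expect_lt(mean(out$ca125_missing[hi]), mean(out$ca125_missing[!hi]))
  # rate 0 leaves the table untouched
  expect_identical(inject_ca125_missingness(co, 0, seed = 4), co)
  expect_error(inject_ca125_missingness(co, 1.0), "rate")
  # slope 0 is missing completely at random: no association with suspicion
  mcar <- inject_ca125_missingness(co, rate = 0.30, suspicion_slope = 0, seed = 4)
  tab <- table(mcar$ca125_missing, mcar$ascites)
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.001)
})

test_that("latent multinomial mechanism exposes the truth", {
  cfg0 <- cohort_config(n_patients = 500, n_centers = 3, n_oncology = 1,
                        ca125_missing_rate = 0, seed = 8,
                        latent_mlr_coefficients = matrix(0, 10, 4))
  res <- generate_from_latent_mlr(cfg0)
  expect_equal(unname(res$true_probs), matrix(0.2, 500, 5), tolerance = 1e-12)

  # determinism
  res2 <- generate_from_latent_mlr(cfg0)
  expect_identical(res$cohort$outcome, res2$cohort$outcome)

  # average true probability per class matches empirical class frequency
  cfg <- cohort_config(n_patients = 10000, n_centers = 4, n_oncology = 2,
                       ca125_missing_rate = 0, seed = 21,
                       latent_mlr_coefficients = latent_coefs())
  res <- generate_from_latent_mlr(cfg)
  freq <- prop.table(table(res$cohort$outcome))
  mc_se <- sqrt(colMeans(res$true_probs) * (1 - colMeans(res$true_probs)) / 10000)
  expect_true(all(abs(colMeans(res$true_probs) - as.numeric(freq)) < 4 * mc_se + 1e-3))

  # a strong ascites effect raises advanced-stage prevalence among ascites
  B <- matrix(0, 10, 4); B[1, ] <- -2; B[8, 3] <- 3  # ascites -> stage II-IV
  cfg_a <- cohort_config(n_patients = 10000, n_centers = 4, n_oncology = 2,
                         ca125_missing_rate = 0, seed = 22,
                         latent_mlr_coefficients = B)
  res_a <- generate_from_latent_mlr(cfg_a)
  co <- res_a$cohort
  p1 <- mean(co$outcome[co$ascites == 1] == "stage_II_IV")
  p0 <- mean(co$outcome[co$ascites == 0] == "stage_II_IV")
  expect_gt(p1, p0)

  expect_error(generate_from_latent_mlr(
    cohort_config(seed = 1, latent_mlr_coefficients = matrix(0, 3, 4))),
    "10 x 4")
})

test_that("cohort round-trips through the delimited dialect", {
  co <- generate_cohort(cohort_config(n_patients = 300, n_centers = 3,
                                      n_oncology = 2, seed = 14))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back$outcome, co$outcome)
  expect_equal(back$papillations, co$papillations)
  expect_equal(back$ca125, co$ca125, tolerance = 1e-12)
  expect_equal(back$ca125_missing, co$ca125_missing)
})

test_that("schema validation localizes violations", {
  co <- as.data.frame(generate_cohort(cohort_config(n_patients = 60,
                                                    n_centers = 2, n_oncology = 1,
                                                    ca125_missing_rate = 0, seed = 2)))
  bad <- co; bad$prop_solid[7] <- 1.2
  expect_error(validate_cohort(bad), "prop_solid.*row 7")
  bad <- co; bad$age[3] <- NA
  expect_error(validate_cohort(bad), "age.*only ca125")
  bad <- co; bad$outcome <- as.character(bad$outcome); bad$outcome[2] <- "cyst"
  expect_error(validate_cohort(bad), "unknown outcome level")
  bad <- co[, -match("age", names(co))]
  expect_error(validate_cohort(bad), "missing required column")
})
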