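test_that("cohort_spec validates its fields and lists every problem", {
  expect_s3_class(cohort_spec(), "cohort_spec")
  err <- tryCatch(cohort_spec(n_workers = 0, missing_rate = 1.2),
                  error = identity)
  expect_match(conditionMessage(err), "n_workers")
  expect_match(conditionMessage(err), "missing_rate")
  expect_error(cohort_spec(te_choices = c(7, 8), te_weights = 1),
               "te_choices")
  expect_error(generate_cohort(list(n_workers = 5), seed = 1), "cohort_spec")
})

test_that("generation is bit-reproducible and column streams are independent", {
  spec <- cohort_spec(n_workers = 30, missing_rate = 0.1)
  a <- generate_cohort(spec, seed = 123)
  b <- generate_cohort(spec, seed = 123)
  expect_identical(a, b)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_roster(a, f1); write_roster(b, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_false(identical(a$concentration_ppm,
                         generate_cohort(spec, seed = 124)$concentration_ppm))
  # re-parameterising the biomarker layer must not perturb exposure columns
  spec2 <- cohort_spec(n_workers = 30, missing_rate = 0.1,
                       biomarker_links = list(
                         mda = list(intercept = 5, slope = 0.2, sd = 1)))
  c2 <- generate_cohort(spec2, seed = 123)
  expect_identical(a[, 1:6], c2[, 1:6])
  expect_identical(is.na(a$mda), is.na(c2$mda)) # same missingness stream
  # the generator leaves the caller's RNG state untouched
  set.seed(77); before <- .Random.seed
  invisible(generate_cohort(spec, seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("generated marginals match the study's moments on average", {
  m <- t(vapply(1:200, function(s) {
    r <- generate_cohort(cohort_spec(), seed = s)
    c(mean(r$concentration_ppm), mean(r$weight_kg), mean(r$tenure_years))
  }, numeric(3)))
  target <- c(1.653, 59.6, 8.2)
  expect_true(all(abs(colMeans(m) / target - 1) < 0.25))
  r <- generate_cohort(cohort_spec(n_workers = 500), seed = 1)
  expect_true(all(r$weight_kg >= 40))
  expect_true(all(r$tenure_years >= 0.05))
  expect_true(all(r$hours_per_day %in% c(7, 8, 9, 11)))
  expect_true(all(r$days_per_year == 312))
})

test_that("missingness thins biomarkers at the configured binomial rate", {
  spec <- cohort_spec(n_workers = 30, missing_rate = 0.1)
  complete <- vapply(1:200, function(s) {
    r <- generate_cohort(spec, seed = 3000 + s)
    sum(!is.na(r$mda))
  }, numeric(1))
  expect_equal(mean(complete), 27, tolerance = 0.02)
})

test_that("slope calibration induces the requested correlation", {
  expect_equal(slope_for_correlation(0.6, 2, 1), 0.6 / sqrt(0.64) / 2)
  expect_error(slope_for_correlation(1, 1, 1), "< 1")
  # calibrate on the log-RQ scale against a large pilot, then verify
  pilot <- assess_cohort(generate_cohort(cohort_spec(n_workers = 20000),
                                         seed = 1))
  sd_log_rq <- sd(log(pilot$rq))
  beta <- slope_for_correlation(0.6, sd_log_rq, 0.5)
  spec <- cohort_spec(
    n_workers = 5000, link_scale = "log_rq",
    biomarker_links = list(mda = list(intercept = 2, slope = beta, sd = 0.5)))
  a <- assess_cohort(generate_cohort(spec, seed = 2))
  expect_equal(pearson_test(log(a$rq), a$mda)$r, 0.6, tolerance = 0.05)
})

test_that("Fisher-z power behaves analytically at the boundaries", {
  expect_equal(fisher_z_power(0, 27), 0.05, tolerance = 1e-6)
  expect_gt(fisher_z_power(0.9, 27), 0.99)
  expect_true(all(diff(fisher_z_power(seq(0, 0.95, 0.05), 27)) >= 0))
  expect_lt(abs(fisher_z_power(0.266, 27) - 0.27), 0.02)
  expect_error(fisher_z_power(0.5, 3), "exceed 3")
})

test_that("empirical power curve is calibrated at the null and monotone", {
  pc <- power_curve(27, c(0, 0.5, 0.9), reps = 1500, seed = 8)
  expect_equal(pc$power[1], 0.05, tolerance = 0.4) # null: rejection ~ alpha
  expect_true(all(diff(pc$power) > 0))
  expect_gt(pc$power[3], 0.95)
  expect_s3_class(power_curve(cohort_spec(), c(0.5), reps = 100, seed = 1),
                  "data.frame")
  expect_error(power_curve(27, c(0.5, 0.5)), "distinct")
  expect_error(power_curve(27, 0.5, reps = 10), "reps")
})

test_that("any valid spec flows through assessment and screening", {
  set.seed(55)
  for (i in 1:15) {
    spec <- cohort_spec(
      n_workers = sample(5:60, 1),
      weight_mean = runif(1, 45, 90),
      weight_sd = runif(1, 0, 20),
      conc_log_sd = runif(1, 0, 1.5),
      conc_log_mean = runif(1, -2, 2),
      tenure_mean = runif(1, 0.5, 30),
      missing_rate = runif(1, 0, 0.3),
      link_scale = sample(c("rq", "log_rq"), 1),
      biomarker_links = list(
        mda = list(intercept = runif(1, 1, 5), slope = runif(1, -0.1, 0.1),
                   sd = runif(1, 0.1, 2)))
    )
    a <- assess_cohort(generate_cohort(spec, seed = 4000 + i))
    expect_equal(nrow(a), spec$n_workers)
    if (sum(!is.na(a$mda)) >= 3 && sd(a$mda, na.rm = TRUE) > 0) {
      s <- suppressWarnings(correlation_screen(a, biomarkers = "mda"))
      expect_true(all(is.na(s$r) | abs(s$r) <= 1))
    }
  }
})
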