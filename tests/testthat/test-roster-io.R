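test_that("the packaged validation roster loads cleanly", {
  expect_equal(nrow(t3), 27)
  expect_equal(sum(t3$verified), 16)
  expect_true(all(c("worker_id", "concentration_ppm", "weight_kg",
                    "hours_per_day", "days_per_year", "tenure_years",
                    "rfc", "breathing_rate", "intake", "rq") %in% names(t3)))
  expect_type(t3$concentration_ppm, "double")
})

test_that("the reader rejects malformed input with row/column diagnostics", {
  f <- tempfile(fileext = ".csv")
  writeLines("worker_id,concentration_ppm,weight_kg,hours_per_day,days_per_year,tenure_years",
             f)
  expect_error(read_roster(f), "header but no data rows")
  writeLines(c("worker_id,concentration_ppm,weight_kg,hours_per_day,days_per_year,tenure_years",
               "A,0.5,\"63,0\",7,312,5"), f)
  expect_error(read_roster(f), "row 1.*weight_kg.*63,0")
  writeLines(c("worker_id,concentration_ppm,hours_per_day,days_per_year,tenure_years",
               "A,0.5,7,312,5"), f)
  expect_error(read_roster(f), "missing mandatory column.*weight_kg")
  writeLines(c("worker_id,concentration_ppm,weight_kg,hours_per_day,days_per_year,tenure_years",
               "A,-0.5,63,7,312,5"), f)
  expect_error(read_roster(f), "concentration_ppm")
  expect_error(read_roster(tempfile()), "not found")
})

test_that("headers are case-insensitive and optional biomarkers may be sparse", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("Worker_ID,Concentration_PPM,Weight_kg,Hours_per_day,Days_per_year,Tenure_years,MDA",
               "A,0.5,63,7,312,5,1.9",
               "B,1.2,55,8,312,3,"), f)
  r <- read_roster(f)
  expect_equal(names(r)[1:2], c("worker_id", "concentration_ppm"))
  expect_equal(r$mda, c(1.9, NA))
})

test_that("write/read round-trips every value at full precision", {
  r <- generate_cohort(cohort_spec(n_workers = 25, missing_rate = 0.1),
                       seed = 31)
  f <- tempfile(fileext = ".csv")
  write_roster(r, f)
  back <- read_roster(f)
  for (col in names(r)) expect_equal(back[[col]], r[[col]], tolerance = 0)
})

test_that("the report renders the published frequency block and handles no biomarkers", {
  # rendering the published RQ column (the recomputed one differs where the
  # source's RQ cells are scrambled) reproduces the published 25/2 block
  published <- t3_assessed
  published$rq <- t3$rq
  published[c("rq_class", "tlv_class")] <-
    classify_risk(t3$rq, t3$concentration_ppm)
  lines <- render_report(published, quiet = TRUE)
  expect_true(any(grepl("unsafe\\s+25\\s+92.6%", lines)))
  expect_true(any(grepl("safe\\s+2\\s+7.4%", lines)))
  expect_true(any(grepl("above\\s+24", lines)))
  expect_true(any(grepl("insufficient data", lines)))
  # recomputed assessment renders the same blocks
  lines_r <- render_report(t3_assessed, quiet = TRUE)
  expect_true(any(grepl("Risk Quotient classification", lines_r)))
  expect_true(any(grepl("total\\s+27", lines_r)))
  a <- assess_cohort(generate_cohort(cohort_spec(n_workers = 10), seed = 2))
  lines2 <- render_report(a, quiet = TRUE)
  expect_true(any(grepl("Pearson", lines2)))
  expect_error(render_report(t3_assessed[0, ]), "empty")
})

test_that("the lifetime-averaging override collapses RQ to plain intake/RfC", {
  p30 <- risk_params(tavg_rq_years = 30)
  a <- assess_cohort(t3, p30)
  expect_identical(a$rq, a$intake / a$rfc)
})

test_that("the command-line wrapper assesses, correlates and simulates", {
  skip_if(Sys.which("Rscript") == "", "no Rscript on PATH")
  cli <- system.file("cli", "benzrisk.R", package = "benzrisk")
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  out_csv <- tempfile(fileext = ".csv")
  res <- system2("Rscript", c(cli, "assess",
                              "--input", shQuote(system.file(
                                "extdata", "table3.csv", package = "benzrisk")),
                              "--out", shQuote(out_csv)),
                 stdout = TRUE, stderr = TRUE, env = env)
  expect_equal(attr(res, "status"), NULL) # exit 0
  expect_true(file.exists(out_csv))
  expect_equal(nrow(read_roster(out_csv)), 27)
  sim_csv <- tempfile(fileext = ".csv")
  res2 <- system2("Rscript", c(cli, "simulate", "--n", "12", "--seed", "4",
                               "--out", shQuote(sim_csv)),
                  stdout = TRUE, stderr = TRUE, env = env)
  expect_equal(attr(res2, "status"), NULL)
  corr_csv <- tempfile(fileext = ".csv")
  res3 <- system2("Rscript", c(cli, "correlate", "--input", shQuote(sim_csv),
                               "--out", shQuote(corr_csv)),
                  stdout = TRUE, stderr = TRUE, env = env)
  expect_equal(attr(res3, "status"), NULL)
  expect_equal(nrow(utils::read.csv(corr_csv)), 6)
  # a bad roster must exit non-zero
  bad <- tempfile(fileext = ".csv")
  writeLines(c("worker_id,concentration_ppm,weight_kg,hours_per_day,days_per_year,tenure_years",
               "A,oops,63,7,312,5"), bad)
  res4 <- system2("Rscript", c(cli, "assess", "--input", shQuote(bad),
                               "--out", shQuote(tempfile())),
                  stdout = TRUE, stderr = TRUE, env = env)
  expect_equal(attr(res4, "status"), 1)
})
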