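test_that("cohort generation is bit-for-bit reproducible and seed-sensitive", {
  spec <- cohort_spec(n = 5000, seed = 7)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  c <- generate_cohort(cohort_spec(n = 5000, seed = 8))
  expect_false(identical(a, c))
})

test_that("a one-person cohort is a valid person", {
  co <- generate_cohort(cohort_spec(n = 1, seed = 3))
  expect_equal(nrow(co), 1)
  expect_true(co$age >= 30 && co$age <= 89)
  expect_true(co$egfr > 5 && co$egfr <= 150)
  expect_true(co$bmi >= 12 && co$bmi <= 80)
  expect_true(co$albuminuria %in% c("normal", "moderate", "severe"))
})

test_that("generated BMI lies inside its category and creatinine is consistent", {
  co <- generate_cohort(cohort_spec(n = 4000, seed = 11))
  expect_setequal(unique(bmi_category(co$bmi)),
                  c("underweight", "normal", "overweight", "obesity"))
  expect_true(all(co$bmi >= 12 & co$bmi <= 80))
  expect_true(all(co$egfr > 5 & co$egfr <= 150))
  back <- ckd_epi_egfr(co$scr_mg_dl, co$age, co$sex, co$race)
  expect_equal(back, co$egfr, tolerance = 1e-8)
})

test_that("large-sample marginals recover the spec within 99% sampling bounds", {
  n <- 50000
  spec <- cohort_spec(n = n, sex_split = 0.5, seed = 19)
  co <- generate_cohort(spec)
  z99 <- 2.576
  # sex (binomial)
  expect_lt(abs(mean(co$sex == "female") - 0.5), z99 * sqrt(0.25 / n))
  # race (multinomial, per-category binomial bound)
  for (r in names(spec$race_weights)) {
    p <- spec$race_weights[[r]]
    expect_lt(abs(mean(co$race == r) - p), z99 * sqrt(p * (1 - p) / n))
  }
  # age bands
  band <- cut(co$age, c(29, 49, 64, 90), labels = c("30-49", "50-64", "65-90"))
  for (b in levels(band)) {
    p <- spec$age_band_weights[[b]]
    expect_lt(abs(mean(band == b) - p), z99 * sqrt(p * (1 - p) / n))
  }
  # BMI categories within one age band
  idx <- band == "50-64"
  for (cc in colnames(spec$bmi_cat_weights_by_age_band)) {
    p <- spec$bmi_cat_weights_by_age_band["50-64", cc]
    expect_lt(abs(mean(bmi_category(co$bmi[idx]) == cc) - p),
              z99 * sqrt(p * (1 - p) / sum(idx)) + 1e-12)
  }
  # diabetes prevalence in one (band, bmi) cell
  cell <- idx & bmi_category(co$bmi) == "obesity"
  p <- spec$prev_diabetes["50-64", "obesity"]
  expect_lt(abs(mean(co$diabetes[cell]) - p), z99 * sqrt(p * (1 - p) / sum(cell)))
})

test_that("persistent-albuminuria adjustment retains the configured fraction", {
  co <- make_cohort(50000, albuminuria = "moderate")
  # identity and full-reset limits
  expect_identical(adjust_persistent_albuminuria(co, 1, seed = 5), co)
  none <- adjust_persistent_albuminuria(co, 0, seed = 5)
  expect_equal(sum(none$albuminuria == "moderate"), 0)
  expect_true(all(none$albuminuria == "normal"))
  # binomial 99% interval around retain_prob = 0.6
  adj <- adjust_persistent_albuminuria(co, 0.6, seed = 5)
  kept <- sum(adj$albuminuria == "moderate")
  expect_lt(abs(kept - 30000), 2.576 * sqrt(50000 * 0.6 * 0.4))
  # severe untouched
  sev <- make_cohort(100, albuminuria = "severe")
  expect_identical(adjust_persistent_albuminuria(sev, 0, seed = 1), sev)
})

test_that("albuminuria maps onto proteinuria categories as configured", {
  expect_equal(map_albuminuria_to_proteinuria(c("normal", "moderate", "severe")),
               c("p1", "p2", "p3"))
  expect_equal(map_albuminuria_to_proteinuria("severe", p4_fraction = 1), "p4")
  u <- c(0.1, 0.9)
  expect_equal(map_albuminuria_to_proteinuria(c("severe", "severe"),
                                              p4_fraction = 0.5, u = u),
               c("p4", "p3"))
})

test_that("cohort CSV round-trips losslessly and reports schema problems", {
  co <- generate_cohort(cohort_spec(n = 200, seed = 2))
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_equal(back$egfr, co$egfr, tolerance = 1e-12)
  expect_equal(back$diabetes, co$diabetes)
  expect_equal(back$albuminuria, co$albuminuria)
  expect_equal(back$bmi, co$bmi, tolerance = 1e-12)

  # missing column named in the error
  df <- utils::read.csv(path)
  df$bmi <- NULL
  path2 <- tempfile(fileext = ".csv")
  utils::write.csv(df, path2, row.names = FALSE)
  expect_error(read_cohort_csv(path2), "bmi")

  # unparseable cell cites the row
  df2 <- utils::read.csv(path, colClasses = "character")
  df2$bmi[3] <- "abc"
  utils::write.csv(df2, path2, row.names = FALSE, quote = FALSE)
  expect_error(read_cohort_csv(path2), "row 3")

  # eGFR derived from creatinine when the egfr cell is empty
  df3 <- utils::read.csv(path, colClasses = "character")
  df3$egfr[1] <- ""
  utils::write.csv(df3, path2, row.names = FALSE, quote = FALSE)
  back3 <- read_cohort_csv(path2)
  expect_equal(back3$egfr[1], co$egfr[1], tolerance = 1e-6)
  unlink(c(path, path2))
})

test_that("restricting a spec yields single-category cohorts", {
  spec <- restrict_cohort_spec(cohort_spec(n = 500, seed = 4),
                               bmi_category = "obesity", age_band = "50-64")
  co <- generate_cohort(spec)
  expect_true(all(bmi_category(co$bmi) == "obesity"))
  expect_true(all(co$age >= 50 & co$age <= 64))
  expect_error(restrict_cohort_spec(cohort_spec(), bmi_category = "plump"))
})

test_that("degenerate weight vectors are rejected", {
  expect_error(cohort_spec(race_weights = c(nh_white = 0, nh_black = 0,
                                            hispanic = 0, other = 0)),
               "degenerate")
  expect_error(cohort_spec(n = 0), "n must be")
})
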