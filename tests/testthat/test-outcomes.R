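fake_records <- function(highest, bmi = "normal") {
  n <- length(highest)
  df <- data.frame(
    id = seq_len(n),
    baseline_bmi_cat = factor(rep_len(bmi, n),
                              levels = c("underweight", "normal", "overweight", "obesity")),
    baseline_age_band = factor(rep("50-64", n), levels = c("30-49", "50-64", "65+")),
    ever_ckd = highest != "none",
    highest_stage = factor(highest,
                           levels = c("none", "s1", "s2", "s3a", "s3b", "s4", "s5")),
    stringsAsFactors = FALSE
  )
  class(df) <- c("ckd_records", "data.frame")
  df
}

test_that("lifetime risk is the ever-CKD fraction; stage shares partition it", {
  rec <- fake_records(c(rep("none", 6), "s1", "s2", "s3a", "s4"))
  tab <- lifetime_risk(rec)
  row <- tab[tab$baseline_bmi_cat == "normal", ]
  expect_equal(row$risk_any, 0.40)
  expect_equal(row$n, 10)

  rec2 <- fake_records(c("s3a", "s3a", "s4", "none"))
  t2 <- lifetime_risk(rec2)
  r2 <- t2[t2$baseline_bmi_cat == "normal", ]
  expect_equal(r2$risk_any, 0.75)
  expect_equal(r2$risk_s3a, 0.50)
  expect_equal(r2$risk_s4, 0.25)

  t3 <- lifetime_risk(fake_records(rep("none", 5)))
  r3 <- t3[t3$baseline_bmi_cat == "normal", ]
  expect_equal(r3$risk_any, 0)
  expect_equal(r3$risk_s5, 0)

  # empty factor level reported as missing, not zero
  empty <- tab[tab$baseline_bmi_cat == "obesity", ]
  expect_equal(empty$n, 0)
  expect_true(is.na(empty$risk_any))
})

test_that("stage shares sum to risk_any in simulated cohorts (partition identity)", {
  co <- adjust_persistent_albuminuria(generate_cohort(cohort_spec(n = 800, seed = 81)),
                                      0.6, seed = 82)
  rec <- simulate_cohort(co, default_params(), master_seed = 15)
  for (by in list("baseline_bmi_cat", c("baseline_bmi_cat", "baseline_age_band"))) {
    tab <- lifetime_risk(rec, by = by)
    tab <- tab[tab$n > 0, ]
    total <- tab$risk_s1 + tab$risk_s2 + tab$risk_s3a + tab$risk_s3b +
      tab$risk_s4 + tab$risk_s5
    expect_equal(total, tab$risk_any, tolerance = 1e-12)
  }
})

test_that("the percentile rule interpolates linearly between order statistics", {
  x <- (1:100) / 100
  expect_equal(percentile_ci(x), c(0.03475, 0.97525), tolerance = 1e-12)
  expect_equal(percentile_ci(0.42), c(0.42, 0.42))  # B = 1 collapses
})

test_that("bootstrap on a degenerate always-CKD cohort gives CI (1, 1)", {
  co <- make_cohort(40, egfr = 50, albuminuria = "severe", age = 85L)
  boot <- bootstrap_ci(co, default_params(), B = 5, master_seed = 17)
  row <- boot$point[boot$point$baseline_bmi_cat == "normal", ]
  expect_equal(row$risk_any, 1)
  expect_equal(row$ci_low_any, 1)
  expect_equal(row$ci_high_any, 1)
})

test_that("bootstrap replicate array is reproducible and well-shaped", {
  co <- adjust_persistent_albuminuria(generate_cohort(cohort_spec(n = 150, seed = 91)),
                                      0.6, seed = 92)
  p <- default_params()
  b1 <- bootstrap_ci(co, p, B = 3, master_seed = 19)
  b2 <- bootstrap_ci(co, p, B = 3, master_seed = 19)
  expect_identical(b1$replicates, b2$replicates)
  expect_equal(dim(b1$replicates)[1], 3)
  expect_true(all(b1$point$ci_low_any <= b1$point$ci_high_any, na.rm = TRUE))
  # replicate estimates are proportions
  expect_true(all(b1$replicates >= 0 & b1$replicates <= 1, na.rm = TRUE))
})

test_that("bootstrap CIs narrow as the cohort grows", {
  p <- default_params()
  widths <- sapply(c(250, 2250), function(n) {
    co <- adjust_persistent_albuminuria(
      generate_cohort(restrict_cohort_spec(cohort_spec(n = n, seed = 101),
                                           bmi_category = "normal")),
      0.6, seed = 102)
    b <- bootstrap_ci(co, p, B = 25, master_seed = 23)
    row <- b$point[b$point$baseline_bmi_cat == "normal", ]
    row$ci_high_any - row$ci_low_any
  })
  expect_lt(widths[2], widths[1])
})

test_that("paired-replicate comparison follows the normal approximation", {
  expect_equal(compare_groups(rep(0.4, 20), rep(0.4, 20))$p_value, 1)

  # construct replicate differences with mean exactly 2 SE
  set.seed(5)
  d0 <- as.numeric(scale(rnorm(100)))  # mean 0, sd 1
  res <- compare_groups(2 + d0, rep(0, 100))
  expect_equal(res$p_value, 2 * pnorm(-2), tolerance = 1e-9)  # 0.0455
  expect_equal(res$mean_diff, 2, tolerance = 1e-12)

  # clearly separated groups are significant
  a <- 0.5 + d0 * 0.01
  b <- 0.4 + d0 * 0.01
  expect_lt(compare_groups(a, b)$p_value, 0.05)

  # zero bootstrap variance with a real difference: flagged, p < 1/B
  deg <- compare_groups(rep(0.5, 40), rep(0.3, 40))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1 / 40)
})

test_that("sensitivity table has six rows and honours matched seeds", {
  co <- rbind(
    generate_cohort(restrict_cohort_spec(cohort_spec(n = 250, seed = 111),
                                         bmi_category = "normal")),
    generate_cohort(restrict_cohort_spec(cohort_spec(n = 250, seed = 112),
                                         bmi_category = "obesity"))
  )
  co$id <- seq_len(nrow(co))
  class(co) <- c("ckd_cohort", "data.frame")
  p <- default_params()
  sens <- run_sensitivity(co, p, master_seed = 29)
  expect_equal(nrow(sens), 6)
  expect_setequal(unique(sens$parameter),
                  c("rr_diabetes_obesity", "rr_hypertension_obesity", "coef_obesity"))
  expect_setequal(unique(sens$direction), c("-25%", "+25%"))

  # identity factor reproduces the reference difference exactly (same seeds)
  sm <- run_sensitivity(co, p, master_seed = 29, factors = c(1, 1.25))
  ones <- sm[sm$factor == 1, ]
  expect_equal(ones$diff_pp, ones$reference_diff_pp, tolerance = 1e-12)
})

test_that("scaling the diabetes RR only perturbs diabetes pathways", {
  co <- adjust_persistent_albuminuria(generate_cohort(cohort_spec(n = 250, seed = 121)),
                                      0.6, seed = 122)
  p <- default_params()
  q <- scale_param(p, "rr_diabetes_obesity", 1.25)
  ra <- simulate_cohort(co, p, master_seed = 31, trajectory = TRUE)
  rb <- simulate_cohort(co, q, master_seed = 31, trajectory = TRUE)
  # persons who stay diabetes-free in both runs have bit-identical
  # trajectories: the scaled RR never touched any of their draws
  free_a <- tapply(ra$trajectory$diabetes, ra$trajectory$id, function(x) !any(x))
  free_b <- tapply(rb$trajectory$diabetes, rb$trajectory$id, function(x) !any(x))
  ids <- intersect(as.integer(names(free_a))[free_a],
                   as.integer(names(free_b))[free_b])
  expect_gt(length(ids), 0)
  ta <- ra$trajectory[ra$trajectory$id %in% ids, ]
  tb <- rb$trajectory[rb$trajectory$id %in% ids, ]
  expect_identical(ta, tb)
  ia <- ra$records[ra$records$id %in% ids, ]
  ib <- rb$records[rb$records$id %in% ids, ]
  expect_identical(ia, ib)
})
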