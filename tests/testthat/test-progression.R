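test_that("mean annual eGFR change sums the applicable coefficients", {
  p <- default_params()$progression
  ref <- make_person()  # male, nh_white, p1, no conditions, non-obese
  ref$proteinuria <- "p1"
  ref$bmi_cat <- "normal"
  ref$baseline_egfr_band <- "lt60"
  expect_equal(mean_annual_change(ref, p), 0.42)

  # fully loaded profile, baseline eGFR < 60:
  # 0.42 - 0.12 - 0.61 - 4.17 - 0.29 - 0.15 + 0.26
  loaded <- ref
  loaded$sex <- "female"; loaded$race <- "nh_black"; loaded$proteinuria <- "p4"
  loaded$diabetes <- TRUE; loaded$hypertension <- TRUE; loaded$bmi_cat <- "obesity"
  expect_equal(mean_annual_change(loaded, p), -4.66)

  # hispanic male, no conditions, band >= 60: 0.33 + 0.37
  hisp <- ref
  hisp$race <- "hispanic"; hisp$baseline_egfr_band <- "ge60"
  expect_equal(mean_annual_change(hisp, p), 0.70)

  # vectorised over a mixed data frame
  df <- rbind(ref, loaded, hisp)
  expect_equal(mean_annual_change(df, p), c(0.42, -4.66, 0.70))
})

test_that("slope SD applies the variance multiplier on the variance scale", {
  p <- default_params()$progression
  expect_equal(slope_sd("lt60", p), 1.64)
  expect_equal(slope_sd("ge60", p), 1.77 * sqrt(0.5))
  p2 <- p; p2$variance_multiplier_ge60 <- 0.25
  expect_equal(slope_sd("ge60", p2), 1.77 * 0.5)
  expect_equal(slope_sd(c("lt60", "ge60"), p, deterministic_mode = TRUE), c(0, 0))
})

test_that("slope draws collapse to the mean in deterministic mode", {
  p <- default_params()$progression
  person <- make_person()
  person$proteinuria <- "p1"; person$bmi_cat <- "normal"
  person$baseline_egfr_band <- "lt60"
  expect_equal(draw_person_slope(person, p, deterministic_mode = TRUE), 0.42)
})

test_that("slope draws reproduce the model mean and SD (sampling check)", {
  p <- default_params()$progression
  n <- 200000
  person <- make_person()
  person <- person[rep(1, n), ]
  person$proteinuria <- "p1"; person$bmi_cat <- "normal"
  person$baseline_egfr_band <- "lt60"
  set.seed(42)
  draws <- draw_person_slope(person, p)
  expect_lt(abs(mean(draws) - 0.42), 3 * 1.64 / sqrt(n))
  expect_lt(abs(stats::sd(draws) - 1.64), 0.01)
})

test_that("eGFR step adds the slope and floors at 1.0", {
  expect_equal(step_egfr(58, -2.38), 55.62)
  expect_equal(step_egfr(1.5, -4.0), 1.0)
  expect_equal(step_egfr(70, 0.33), 70.33)
  expect_equal(step_egfr(c(58, 1.5, 70), c(-2.38, -4, 0.33)), c(55.62, 1, 70.33))
})

test_that("stage assignment follows the eGFR/damage bands", {
  cases <- list(
    list(95, "moderate", "s1"), list(95, "normal", "none"),
    list(90, "severe", "s1"), list(89.9, "moderate", "s2"),
    list(75, "normal", "none"), list(60, "moderate", "s2"),
    list(59.9, "normal", "s3a"), list(50, "normal", "s3a"),
    list(45, "normal", "s3a"), list(44.9, "severe", "s3b"),
    list(30, "normal", "s3b"), list(29.9, "normal", "s4"),
    list(15, "moderate", "s4"), list(14.9, "normal", "s5"),
    list(1, "normal", "s5")
  )
  for (cs in cases) {
    expect_equal(assign_stage(cs[[1]], cs[[2]]), cs[[3]],
                 label = sprintf("egfr=%s alb=%s", cs[[1]], cs[[2]]))
  }
  expect_error(assign_stage(0, "normal"))
})

test_that("stage history ratchets and records pass-through stages", {
  st <- data.frame(highest_stage = "s3a", att_s3a = TRUE, att_s3b = FALSE,
                   att_s4 = FALSE, att_s5 = FALSE, stringsAsFactors = FALSE)
  up <- update_stage_history(st, "s3b")
  expect_equal(up$highest_stage, "s3b")
  expect_true(up$att_s3b)

  # eGFR rebound never lowers the highest stage
  st2 <- data.frame(highest_stage = "s4", att_s3a = TRUE, att_s3b = TRUE,
                    att_s4 = TRUE, att_s5 = FALSE, stringsAsFactors = FALSE)
  up2 <- update_stage_history(st2, "s3b")
  expect_equal(up2$highest_stage, "s4")
  expect_equal(up2$current_stage, "s3b")

  # a large drop marks the skipped GFR stages when pass-through is on
  st3 <- data.frame(highest_stage = "s3a", att_s3a = TRUE, att_s3b = FALSE,
                    att_s4 = FALSE, att_s5 = FALSE, stringsAsFactors = FALSE)
  up3 <- update_stage_history(st3, "s4", pass_through = TRUE)
  expect_true(up3$att_s3b && up3$att_s4)
  up3b <- update_stage_history(st3, "s4", pass_through = FALSE)
  expect_true(up3b$att_s4)
  expect_false(up3b$att_s3b)
})

test_that("deterministic first-passage ages match the closed form on a grid", {
  thresholds <- c(s3a = 60, s3b = 45, s4 = 30, s5 = 15)
  grid <- expand.grid(egfr0 = c(58, 72, 95, 61.5), slope = c(-1.3, -2, -2.5, -4.1))
  for (i in seq_len(nrow(grid))) {
    e0 <- grid$egfr0[i]; s <- grid$slope[i]
    params <- constant_slope_params(s)
    person <- make_person(age = 30L, egfr = e0)
    res <- simulate_cohort(person, params, master_seed = 1, trajectory = TRUE)
    traj <- res$trajectory
    for (st in names(thresholds)) {
      k_or <- first_passage_cycle(e0, s, thresholds[[st]])
      reached <- which(stage_index(traj$stage) >= stage_index(st))
      k_sim <- if (length(reached)) min(reached) else NA_integer_
      if (k_or == 0) {   # already past the threshold at baseline
        expect_true(res$records[[paste0("att_", st)]])
      } else if (k_or > 60) {   # horizon: person reaches 90 first
        expect_true(is.na(k_sim))
      } else {
        expect_equal(k_sim, k_or,
                     label = sprintf("egfr0=%s slope=%s stage=%s", e0, s, st))
      }
    }
  }
})

test_that("an exact threshold landing stays in the higher band one more year", {
  # 59 - 7*2 = 45 exactly: still stage 3a; stage 3b needs the 8th cycle
  params <- constant_slope_params(-2)
  res <- simulate_cohort(make_person(age = 30L, egfr = 59), params,
                         master_seed = 1, trajectory = TRUE)
  expect_equal(res$trajectory$stage[7], "s3a")
  expect_equal(res$trajectory$stage[8], "s3b")
})
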