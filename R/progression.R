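# eGFR trajectory model: covariate-determined mean annual change, a
# person-level random slope around it, the annual eGFR update, and KDIGO
# staging with sequential (pass-through) stage bookkeeping.

#' Mean annual change in eGFR for a person's current covariates
#'
#' Sum of the base annual change and the applicable additive coefficients
#' (sex, race/ethnicity, proteinuria category, diabetes, hypertension,
#' obesity), using the parameter column selected by the person's *baseline*
#' eGFR band (< 60 vs >= 60, fixed at simulation start). Covariate values
#' are taken from the person's current state, so a person who develops
#' diabetes mid-course picks up that coefficient from the acquisition year
#' onward.
#'
#' @param person data frame (one or more rows) with columns `sex`, `race`,
#'   `proteinuria`, `diabetes`, `hypertension`, `bmi_cat`,
#'   `baseline_egfr_band`.
#' @param params a [progression_params()] object.
#' @return numeric vector, ml/min/1.73m^2 per year (positive = increase).
#' @export
mean_annual_change <- function(person, params) {
  band <- person$baseline_egfr_band
  g <- function(coef) coef[band]
  out <- g(params$base_change)
  out <- out + ifelse(person$sex == "female", g(params$coef_female), 0)
  out <- out + ifelse(person$race == "nh_black", g(params$coef_nh_black), 0)
  out <- out + ifelse(person$race == "hispanic", g(params$coef_hispanic), 0)
  out <- out + ifelse(person$race == "other", g(params$coef_other), 0)
  out <- out + ifelse(person$proteinuria == "p2", g(params$coef_prot_p2), 0)
  out <- out + ifelse(person$proteinuria == "p3", g(params$coef_prot_p3), 0)
  out <- out + ifelse(person$proteinuria == "p4", g(params$coef_prot_p4), 0)
  out <- out + ifelse(person$diabetes, g(params$coef_diabetes), 0)
  out <- out + ifelse(person$hypertension, g(params$coef_hypertension), 0)
  out <- out + ifelse(person$bmi_cat == "obesity", g(params$coef_obesity), 0)
  unname(out)
}

#' Standard deviation of the annual eGFR change distribution
#'
#' `sd_annual_change[band]`, with the >= 60 band deflated by
#' `sqrt(variance_multiplier_ge60)` (the calibration multiplier acts on the
#' variance). Zero in deterministic mode.
#'
#' @param band `"lt60"` or `"ge60"` (vectorised).
#' @param params a [progression_params()] object.
#' @param deterministic_mode logical; `TRUE` collapses the SD to 0.
#' @return numeric vector of SDs.
#' @export
slope_sd <- function(band, params, deterministic_mode = FALSE) {
  if (deterministic_mode) return(rep(0, length(band)))
  sd <- params$sd_annual_change[band]
  mult <- ifelse(band == "ge60", sqrt(params$variance_multiplier_ge60), 1)
  unname(sd * mult)
}

#' Draw a person's annual eGFR slope
#'
#' Normal draw centred on [mean_annual_change()] with SD from
#' [slope_sd()]. Under the default `once_at_baseline` policy the engine
#' calls this once per person and carries the residual (draw minus mean)
#' for life, shifting the slope by coefficient deltas as conditions turn
#' on; under `annual_iid` a fresh draw is taken each cycle.
#'
#' @inheritParams mean_annual_change
#' @param deterministic_mode logical; `TRUE` returns the mean exactly.
#' @param z optional standard-normal deviates (one per person) for callers
#'   managing their own streams; drawn internally when `NULL`.
#' @return numeric vector of slopes, ml/min/1.73m^2 per year.
#' @export
draw_person_slope <- function(person, params, deterministic_mode = FALSE, z = NULL) {
  m <- mean_annual_change(person, params)
  s <- slope_sd(person$baseline_egfr_band, params, deterministic_mode)
  if (is.null(z)) z <- stats::rnorm(length(m))
  m + z * s
}

#' Annual eGFR update
#'
#' `egfr + slope`, floored at 1.0 ml/min/1.73m^2 to keep values physical.
#'
#' @param egfr current eGFR vector.
#' @param slope annual change vector.
#' @param floor lower bound (default 1.0).
#' @return updated eGFR vector.
#' @export
step_egfr <- function(egfr, slope, floor = 1.0) {
  pmax(egfr + slope, floor)
}

#' Assign a CKD stage from eGFR and albuminuria
#'
#' KDIGO bands: stage 1 (eGFR >= 90) and stage 2 (60-89) require kidney
#' damage (moderately or severely increased albuminuria); stages 3a
#' (45-59), 3b (30-44), 4 (15-29) and 5 (< 15) are GFR-defined. Persons
#' with eGFR >= 60 and no damage have no CKD.
#'
#' @param egfr numeric vector (> 0).
#' @param albuminuria character vector over normal/moderate/severe.
#' @return character vector of stage codes.
#' @export
assign_stage <- function(egfr, albuminuria) {
  stopifnot(all(egfr > 0))
  damage <- albuminuria %in% c("moderate", "severe")
  out <- rep("none", length(egfr))
  out[egfr >= 90 & damage] <- "s1"
  out[egfr >= 60 & egfr < 90 & damage] <- "s2"
  out[egfr >= 45 & egfr < 60] <- "s3a"
  out[egfr >= 30 & egfr < 45] <- "s3b"
  out[egfr >= 15 & egfr < 30] <- "s4"
  out[egfr < 15] <- "s5"
  out
}

#' Update stage history after an annual step
#'
#' Ratchets `highest_stage` (never decreases) and maintains per-stage
#' attainment flags for the GFR-defined stages 3a-5. With
#' `pass_through = TRUE` (the default sequential-staging rule) a step that
#' skips bands — e.g. stage 3a directly to stage 4 after a large annual
#' drop — marks the skipped intermediate stages as attained, so reaching
#' stage 4 always implies having attained 3a and 3b.
#'
#' @param state data frame with columns `highest_stage`, `att_s3a`,
#'   `att_s3b`, `att_s4`, `att_s5` (and optionally `current_stage`).
#' @param new_stage stage codes from [assign_stage()], one per row.
#' @param pass_through logical, see above.
#' @return `state` with `current_stage`, `highest_stage` and attainment
#'   flags updated.
#' @export
update_stage_history <- function(state, new_stage, pass_through = TRUE) {
  ni <- stage_index(new_stage)
  hi <- stage_index(state$highest_stage)
  state$current_stage <- new_stage
  state$highest_stage <- stage_code(pmax(hi, ni))
  if (pass_through) {
    state$att_s3a <- state$att_s3a | ni >= 3L
    state$att_s3b <- state$att_s3b | ni >= 4L
    state$att_s4 <- state$att_s4 | ni >= 5L
  } else {
    state$att_s3a <- state$att_s3a | ni == 3L
    state$att_s3b <- state$att_s3b | ni == 4L
    state$att_s4 <- state$att_s4 | ni == 5L
  }
  state$att_s5 <- state$att_s5 | ni == 6L
  state
}
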