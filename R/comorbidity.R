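# Annual comorbidity and vital-status updates: BMI drift, incident
# diabetes/hypertension/CVD with obesity relative risks, incident
# albuminuria, and the mortality draw.

# Vectorised lookup of an annual probability from a (age band x sex) rate
# table. Ages beyond the last band reuse its rate.
rate_lookup <- function(table, age, sex) {
  out <- numeric(length(age))
  for (s in unique(sex)) {
    idx <- sex == s
    sub <- table[table$sex == s, ]
    sub <- sub[order(sub$age_lo), ]
    k <- findInterval(age[idx], sub$age_lo)
    k[k < 1L] <- 1L
    k[k > nrow(sub)] <- nrow(sub)
    out[idx] <- sub$annual_prob[k]
  }
  out
}

#' Annual BMI update
#'
#' Adds the mean annual BMI change for the person's age band (30-49 vs
#' 50+), race group (white/black per the configured mapping) and sex, then
#' recomputes the BMI category.
#'
#' @param person data frame with columns `age`, `race`, `sex`, `bmi`.
#' @param obesity_params an [obesity_params()] object.
#' @return `person` with `bmi` and `bmi_cat` updated.
#' @export
update_bmi <- function(person, obesity_params) {
  band <- ifelse(person$age >= 50, "50+", "30-49")
  grp <- obesity_params$race_to_bmi_group[person$race]
  delta <- obesity_params$bmi_delta[cbind(band, grp, person$sex)]
  person$bmi <- person$bmi + delta
  person$bmi_cat <- bmi_category(person$bmi)
  person
}

#' Apply a relative risk to an annual probability
#'
#' Risk-scale multiplication with a cap at 1: `min(1, base_prob * rr)`.
#' Exact for small probabilities; an approximation to hazard-scale scaling
#' for large ones.
#'
#' @param base_prob annual probability in \[0, 1\] (vectorised).
#' @param rr nonnegative relative risk (vectorised).
#' @return annual probability in \[0, 1\].
#' @export
apply_relative_risk <- function(base_prob, rr) {
  stopifnot(all(base_prob >= 0 & base_prob <= 1), all(rr >= 0))
  pmin(1, base_prob * rr)
}

# RR applicable to one event for each person's current BMI category.
# Categories without a tabulated excess risk (underweight, normal) get 1.
bmi_rr <- function(event, bmi_cat, sex, obesity_params) {
  rr <- rep(1, length(bmi_cat))
  ow <- bmi_cat == "overweight"
  ob <- bmi_cat == "obesity"
  if (event %in% c("diabetes", "hypertension")) {
    m <- obesity_params[[paste0("rr_", event)]]
    rr[ow] <- m["overweight", ][sex[ow]]
    rr[ob] <- m["obesity", ][sex[ob]]
  } else {
    v <- obesity_params[[paste0("rr_", event)]]
    rr[ow] <- v["overweight"]
    rr[ob] <- v["obesity"]
  }
  rr
}

#' Annual incident events
#'
#' Each absent condition (diabetes, hypertension, CHD, stroke, MI)
#' independently becomes present with probability
#' `apply_relative_risk(background rate for age/sex, RR for the current
#' BMI category)`. Albuminuria moves normal -> moderate at the background
#' incidence (times configurable diabetes/hypertension multipliers) and
#' moderate -> severe at a separate constant rate. All conditions are
#' absorbing.
#'
#' @param person data frame of alive persons (columns `age`, `sex`,
#'   `bmi_cat`, condition flags, `albuminuria`).
#' @param background a [background_rates()] object.
#' @param obesity_params an [obesity_params()] object.
#' @param u optional matrix of uniforms with columns `diabetes`,
#'   `hypertension`, `chd`, `stroke`, `mi`, `alb_inc`, `alb_prog` (one row
#'   per person); drawn internally when `NULL`.
#' @return `person` with condition flags and `albuminuria` updated.
#' @export
incident_events <- function(person, background, obesity_params, u = NULL) {
  n <- nrow(person)
  evs <- c("diabetes", "hypertension", "chd", "stroke", "mi", "alb_inc", "alb_prog")
  if (is.null(u)) {
    u <- matrix(stats::runif(n * length(evs)), n, length(evs), dimnames = list(NULL, evs))
  }
  for (ev in c("diabetes", "hypertension", "chd", "stroke", "mi")) {
    absent <- !person[[ev]]
    if (!any(absent)) next
    base <- rate_lookup(background[[paste0("incidence_", ev)]],
                        person$age[absent], person$sex[absent])
    rr <- bmi_rr(ev, person$bmi_cat[absent], person$sex[absent], obesity_params)
    person[[ev]][absent] <- u[absent, ev] < apply_relative_risk(base, rr)
  }
  norm <- person$albuminuria == "normal"
  if (any(norm)) {
    base <- rate_lookup(background$incidence_albuminuria,
                        person$age[norm], person$sex[norm])
    mult <- ifelse(person$diabetes[norm], background$alb_mult_diabetes, 1) *
      ifelse(person$hypertension[norm], background$alb_mult_hypertension, 1)
    hit <- u[norm, "alb_inc"] < pmin(1, base * mult)
    person$albuminuria[norm][hit] <- "moderate"
  }
  mod <- person$albuminuria == "moderate" & !norm  # progression only for prevalent moderate
  if (any(mod)) {
    hit <- u[mod, "alb_prog"] < background$rate_albuminuria_severe
    person$albuminuria[mod][hit] <- "severe"
  }
  person
}

#' Annual mortality draw
#'
#' Death probability is the all-cause life-table value for age and sex,
#' multiplied by the hazard multiplier for the person's current CKD stage
#' and (if any of CHD, stroke or MI is present) the CVD multiplier, capped
#' at 1. BMI enters nowhere: conditional on stage and CVD there is no
#' direct BMI-mortality term.
#'
#' @param person data frame of alive persons (columns `age`, `sex`,
#'   `current_stage`, `chd`, `stroke`, `mi`, `alive`).
#' @param background a [background_rates()] object.
#' @param u optional uniform vector (one per person).
#' @return `person` with `alive` updated.
#' @export
mortality_draw <- function(person, background, u = NULL) {
  n <- nrow(person)
  if (is.null(u)) u <- stats::runif(n)
  p <- death_prob(person, background)
  person$alive <- person$alive & !(u < p)
  person
}

death_prob <- function(person, background) {
  base <- rate_lookup(background$mortality, person$age, person$sex)
  hr <- unname(background$hr_mortality_by_stage[person$current_stage])
  cvd <- person$chd | person$stroke | person$mi
  pmin(1, base * hr * ifelse(cvd, background$hr_mortality_cvd, 1))
}
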