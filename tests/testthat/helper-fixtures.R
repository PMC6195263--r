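# Shared fixtures: all built in code, no stored data.

# Background with every incidence and mortality probability zero: nothing
# happens except eGFR drift and staging.
zero_background <- function() {
  zeros <- function() rate_table_fixture(0)
  background_rates(
    incidence_diabetes = zeros(), incidence_hypertension = zeros(),
    incidence_chd = zeros(), incidence_stroke = zeros(),
    incidence_mi = zeros(), incidence_albuminuria = zeros(),
    mortality = zeros(), rate_albuminuria_severe = 0,
    hr_mortality_by_stage = c(none = 1, s1 = 1, s2 = 1, s3a = 1, s3b = 1,
                              s4 = 1, s5 = 1),
    hr_mortality_cvd = 1
  )
}

# Flat (age- and sex-constant) annual probability table.
rate_table_fixture <- function(p) {
  lo <- seq(30, 85, by = 5)
  data.frame(age_lo = rep(lo, 2), age_hi = rep(lo + 4, 2),
             sex = rep(c("male", "female"), each = length(lo)),
             annual_prob = p, stringsAsFactors = FALSE)
}

# Parameter bundle in which every person's slope is exactly `slope`
# (all covariate coefficients zero, deterministic mode) and nothing else
# ever happens. The workhorse for the analytic first-passage oracle.
constant_slope_params <- function(slope) {
  pp <- progression_params(
    base_change = c(lt60 = slope, ge60 = slope),
    coef_female = c(lt60 = 0, ge60 = 0), coef_nh_black = c(lt60 = 0, ge60 = 0),
    coef_hispanic = c(lt60 = 0, ge60 = 0), coef_other = c(lt60 = 0, ge60 = 0),
    coef_prot_p2 = c(lt60 = 0, ge60 = 0), coef_prot_p3 = c(lt60 = 0, ge60 = 0),
    coef_prot_p4 = c(lt60 = 0, ge60 = 0), coef_diabetes = c(lt60 = 0, ge60 = 0),
    coef_hypertension = c(lt60 = 0, ge60 = 0), coef_obesity = c(lt60 = 0, ge60 = 0)
  )
  ckd_params(progression = pp, background = zero_background(),
             config = sim_config(deterministic_mode = TRUE))
}

# One-row baseline cohort with overridable fields.
make_person <- function(id = 1L, age = 50L, sex = "male", race = "nh_white",
                        egfr = 95, albuminuria = "normal", diabetes = FALSE,
                        hypertension = FALSE, chd = FALSE, stroke = FALSE,
                        mi = FALSE, bmi = 24) {
  co <- data.frame(
    id = id, age = age, sex = sex, race = race,
    scr_mg_dl = NA_real_, egfr = egfr, albuminuria = albuminuria,
    diabetes = diabetes, hypertension = hypertension, chd = chd,
    stroke = stroke, mi = mi, bmi = bmi, stringsAsFactors = FALSE
  )
  class(co) <- c("ckd_cohort", "data.frame")
  co
}

# Multi-person cohort from vectors (recycled).
make_cohort <- function(n, ...) {
  args <- list(...)
  co <- make_person()
  co <- co[rep(1L, n), ]
  co$id <- seq_len(n)
  for (nm in names(args)) co[[nm]] <- rep_len(args[[nm]], n)
  rownames(co) <- NULL
  class(co) <- c("ckd_cohort", "data.frame")
  co
}

# First-passage oracle for a constant negative slope: first cycle k at
# which egfr0 + k*slope < threshold, i.e. the smallest integer exceeding
# (egfr0 - threshold)/|slope| (floor + 1 handles exact threshold hits,
# where the person is still in the band above).
first_passage_cycle <- function(egfr0, slope, threshold) {
  stopifnot(slope < 0)
  if (egfr0 < threshold) return(0L)
  as.integer(floor((egfr0 - threshold) / abs(slope)) + 1L)
}
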