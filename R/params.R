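#' @keywords internal
"_PACKAGE"

# Shared category codes used throughout the package. Stage ordering matters:
# staging logic ratchets along this vector.
STAGE_LEVELS <- c("none", "s1", "s2", "s3a", "s3b", "s4", "s5")
BMI_LEVELS <- c("underweight", "normal", "overweight", "obesity")
SEX_LEVELS <- c("male", "female")
RACE_LEVELS <- c("nh_white", "nh_black", "hispanic", "other")
ALB_LEVELS <- c("normal", "moderate", "severe")
PROT_LEVELS <- c("p1", "p2", "p3", "p4")
EGFR_BANDS <- c("lt60", "ge60")
AGE_BANDS <- c("30-49", "50-64", "65-90")

#' Stage ordering helpers
#'
#' CKD stages are ordered `none < s1 < s2 < s3a < s3b < s4 < s5`.
#' `stage_index()` maps stage codes to 0..6 on that ordering; `stage_code()`
#' is the inverse.
#'
#' @param stage character vector of stage codes.
#' @return integer vector (0 = no CKD, 6 = stage 5).
#' @export
stage_index <- function(stage) {
  i <- match(stage, STAGE_LEVELS) - 1L
  if (anyNA(i)) stop("unknown stage code: ", paste(unique(stage[is.na(i)]), collapse = ", "))
  i
}

#' @rdname stage_index
#' @param index integer vector in 0..6.
#' @export
stage_code <- function(index) {
  stopifnot(all(index >= 0L & index <= 6L))
  STAGE_LEVELS[index + 1L]
}

#' eGFR progression parameters
#'
#' Coefficients of the annual eGFR change model: a base annual change plus
#' additive shifts for sex, race/ethnicity, proteinuria category, diabetes,
#' hypertension and obesity, estimated separately for persons with baseline
#' eGFR < 60 and >= 60 ml/min/1.73m^2, together with the standard deviation
#' of the distribution of annual change in each stratum. Positive values are
#' annual *increases* in eGFR.
#'
#' The defaults are the published estimates from a mixed-effect regression of
#' eGFR slope in a longitudinal CKD cohort. `variance_multiplier_ge60`
#' deflates the *variance* (not the SD) of the >= 60 stratum; the published
#' model over-predicts decline variability for that group relative to a
#' general-population cohort and the exact calibrated multiplier is not
#' public, so the shipped 0.5 is a configurable placeholder (see the
#' vignette).
#'
#' @param base_change,coef_female,coef_nh_black,coef_hispanic,coef_other,coef_prot_p2,coef_prot_p3,coef_prot_p4,coef_diabetes,coef_hypertension,coef_obesity
#'   length-2 named numeric vectors over bands `c(lt60=, ge60=)`,
#'   ml/min/1.73m^2 per year.
#' @param sd_annual_change length-2 named numeric vector, SD of annual change
#'   per band (must be positive).
#' @param variance_multiplier_ge60 scalar in (0, 1].
#' @return an object of class `progression_params`.
#' @export
progression_params <- function(base_change = c(lt60 = 0.42, ge60 = 0.33),
                               coef_female = c(lt60 = -0.12, ge60 = 0.14),
                               coef_nh_black = c(lt60 = -0.61, ge60 = -0.17),
                               coef_hispanic = c(lt60 = -0.40, ge60 = 0.37),
                               coef_other = c(lt60 = -0.65, ge60 = -0.28),
                               coef_prot_p2 = c(lt60 = -0.86, ge60 = -0.26),
                               coef_prot_p3 = c(lt60 = -2.38, ge60 = -1.05),
                               coef_prot_p4 = c(lt60 = -4.17, ge60 = -4.56),
                               coef_diabetes = c(lt60 = -0.29, ge60 = -0.81),
                               coef_hypertension = c(lt60 = -0.15, ge60 = -0.29),
                               coef_obesity = c(lt60 = 0.26, ge60 = -0.15),
                               sd_annual_change = c(lt60 = 1.64, ge60 = 1.77),
                               variance_multiplier_ge60 = 0.5) {
  out <- list(
    base_change = base_change,
    coef_female = coef_female,
    coef_nh_black = coef_nh_black,
    coef_hispanic = coef_hispanic,
    coef_other = coef_other,
    coef_prot_p2 = coef_prot_p2,
    coef_prot_p3 = coef_prot_p3,
    coef_prot_p4 = coef_prot_p4,
    coef_diabetes = coef_diabetes,
    coef_hypertension = coef_hypertension,
    coef_obesity = coef_obesity,
    sd_annual_change = sd_annual_change,
    variance_multiplier_ge60 = variance_multiplier_ge60
  )
  class(out) <- "progression_params"
  out
}

#' Obesity and overweight parameters
#'
#' Relative risks (RR) applied to annual background incidence probabilities
#' of diabetes, hypertension, MI, CHD and stroke for overweight
#' (BMI 25-29.9) and obesity (BMI >= 30), and the mean annual change in BMI
#' by age band, race group and sex. RRs of exactly 1 are stored explicitly
#' so that sensitivity scaling treats every parameter uniformly.
#'
#' BMI drift estimates exist for white and black populations only;
#' `race_to_bmi_group` maps the four modelled race/ethnicity groups onto
#' those two columns (default: hispanic and other use the white estimates).
#'
#' @param rr_diabetes,rr_hypertension 2x2 matrices, rows
#'   `c("overweight","obesity")`, columns `c("male","female")`.
#' @param rr_mi,rr_chd,rr_stroke length-2 named vectors over
#'   `c(overweight=, obesity=)` (sex-invariant).
#' @param bmi_delta 3-d array `[age_band, race_group, sex]` with
#'   `age_band` in `c("30-49","50+")`, `race_group` in `c("white","black")`,
#'   kg/m^2 per year.
#' @param race_to_bmi_group named character vector mapping race codes to
#'   `"white"` or `"black"`.
#' @return an object of class `obesity_params`.
#' @export
obesity_params <- function(rr_diabetes = matrix(c(1, 1.85, 1, 1.36), 2, 2,
                             dimnames = list(c("overweight", "obesity"), SEX_LEVELS)),
                           rr_hypertension = matrix(c(1.48, 2.23, 1.70, 2.63), 2, 2,
                             dimnames = list(c("overweight", "obesity"), SEX_LEVELS)),
                           rr_mi = c(overweight = 1, obesity = 1),
                           rr_chd = c(overweight = 1.43, obesity = 1.58),
                           rr_stroke = c(overweight = 1, obesity = 1),
                           bmi_delta = default_bmi_delta(),
                           race_to_bmi_group = c(nh_white = "white", nh_black = "black",
                                                 hispanic = "white", other = "white")) {
  out <- list(
    rr_diabetes = rr_diabetes,
    rr_hypertension = rr_hypertension,
    rr_mi = rr_mi,
    rr_chd = rr_chd,
    rr_stroke = rr_stroke,
    bmi_delta = bmi_delta,
    race_to_bmi_group = race_to_bmi_group
  )
  class(out) <- "obesity_params"
  out
}

default_bmi_delta <- function() {
  a <- array(NA_real_, dim = c(2, 2, 2),
             dimnames = list(age_band = c("30-49", "50+"),
                             race_group = c("white", "black"),
                             sex = SEX_LEVELS))
  a["30-49", "white", "male"] <- 0.23
  a["30-49", "white", "female"] <- 0.24
  a["30-49", "black", "male"] <- 0.32
  a["30-49", "black", "female"] <- 0.41
  a["50+", "white", "male"] <- 0.073
  a["50+", "white", "female"] <- 0.073
  a["50+", "black", "male"] <- 0.020
  a["50+", "black", "female"] <- 0.020
  a
}

# Annual probability tables indexed by 5-year age band x sex. `values` is a
# list with one numeric vector per sex over the bands; bands run 30-34 ...
# 85-89 (the simulation horizon ends at age 90).
rate_table <- function(male, female, age_lo = seq(30, 85, by = 5)) {
  stopifnot(length(male) == length(age_lo), length(female) == length(age_lo))
  data.frame(
    age_lo = rep(age_lo, 2),
    age_hi = rep(age_lo + 4, 2),
    sex = rep(SEX_LEVELS, each = length(age_lo)),
    annual_prob = c(male, female),
    stringsAsFactors = FALSE
  )
}

#' Background annual incidence and mortality rates
#'
#' Annual probabilities of incident diabetes, hypertension, CHD, stroke, MI
#' and albuminuria (normal to moderately increased) by 5-year age band and
#' sex; all-cause annual mortality by age band and sex; mortality hazard
#' multipliers by CKD stage and for prevalent cardiovascular disease; and
#' the annual rate of albuminuria progression (moderate to severe).
#'
#' The shipped defaults are *synthetic, non-authoritative stand-ins* shaped
#' like contemporary US epidemiology (Gompertz-style mortality, incidence
#' ramps that rise and then plateau with age); the original model's tables
#' are not published. They are ordinary configuration: replace them with
#' your own via [load_params()] for any substantive application. Every
#' incidence/mortality series must be non-decreasing in age.
#'
#' @param incidence_diabetes,incidence_hypertension,incidence_chd,incidence_stroke,incidence_mi,incidence_albuminuria,mortality
#'   data frames with columns `age_lo`, `age_hi`, `sex`, `annual_prob`.
#' @param rate_albuminuria_severe scalar annual probability of moderate to
#'   severe albuminuria progression.
#' @param alb_mult_diabetes,alb_mult_hypertension multipliers on albuminuria
#'   incidence for persons with diabetes / hypertension (defaults 2.5 and
#'   1.5: diabetic and hypertensive nephropathy are the dominant causes of
#'   incident albuminuria, and without them the model cannot carry the
#'   obesity effect through its diabetes/hypertension pathway).
#' @param hr_mortality_by_stage named numeric vector over all seven stage
#'   codes; hazard multipliers on background mortality.
#' @param hr_mortality_cvd scalar hazard multiplier for persons with any of
#'   CHD, stroke or MI.
#' @return an object of class `background_rates`.
#' @export
background_rates <- function(incidence_diabetes = NULL,
                             incidence_hypertension = NULL,
                             incidence_chd = NULL,
                             incidence_stroke = NULL,
                             incidence_mi = NULL,
                             incidence_albuminuria = NULL,
                             mortality = NULL,
                             rate_albuminuria_severe = 0.015,
                             alb_mult_diabetes = 2.5,
                             alb_mult_hypertension = 1.5,
                             hr_mortality_by_stage = c(none = 1, s1 = 1, s2 = 1, s3a = 1.1,
                                                       s3b = 1.3, s4 = 1.8, s5 = 3.0),
                             hr_mortality_cvd = 1.6) {
  mid <- seq(32, 87, by = 5)
  if (is.null(mortality)) {
    mortality <- rate_table(male = 0.0011 * exp(0.083 * (mid - 30)),
                            female = 0.00065 * exp(0.086 * (mid - 30)))
  }
  ramp <- function(lo, hi, plateau_age = 62) {
    v <- lo + (hi - lo) * pmin(1, pmax(0, (mid - 32) / (plateau_age - 32)))
    cummax(v)
  }
  if (is.null(incidence_diabetes)) {
    incidence_diabetes <- rate_table(ramp(0.003, 0.010), ramp(0.003, 0.010))
  }
  if (is.null(incidence_hypertension)) {
    incidence_hypertension <- rate_table(ramp(0.012, 0.035), ramp(0.012, 0.035))
  }
  if (is.null(incidence_chd)) {
    incidence_chd <- rate_table(ramp(0.0010, 0.014, 77), ramp(0.0006, 0.011, 77))
  }
  if (is.null(incidence_stroke)) {
    incidence_stroke <- rate_table(ramp(0.0004, 0.010, 77), ramp(0.0004, 0.010, 77))
  }
  if (is.null(incidence_mi)) {
    incidence_mi <- rate_table(ramp(0.0007, 0.009, 77), ramp(0.0004, 0.007, 77))
  }
  if (is.null(incidence_albuminuria)) {
    incidence_albuminuria <- rate_table(ramp(0.003, 0.009, 72), ramp(0.003, 0.009, 72))
  }
  out <- list(
    incidence_diabetes = incidence_diabetes,
    incidence_hypertension = incidence_hypertension,
    incidence_chd = incidence_chd,
    incidence_stroke = incidence_stroke,
    incidence_mi = incidence_mi,
    incidence_albuminuria = incidence_albuminuria,
    mortality = mortality,
    rate_albuminuria_severe = rate_albuminuria_severe,
    alb_mult_diabetes = alb_mult_diabetes,
    alb_mult_hypertension = alb_mult_hypertension,
    hr_mortality_by_stage = hr_mortality_by_stage,
    hr_mortality_cvd = hr_mortality_cvd
  )
  class(out) <- "background_rates"
  out
}

#' Simulation configuration
#'
#' @param start_year first simulated calendar year (bookkeeping only; no
#'   secular trends are modelled).
#' @param max_age simulation horizon in years (persons are followed to death
#'   or this age; must be <= 90).
#' @param bootstrap_reps number of bootstrap replicates for confidence
#'   intervals.
#' @param ci_percentiles lower/upper percentiles (on 0-100) for the
#'   percentile bootstrap.
#' @param master_seed default master seed for all randomness.
#' @param deterministic_mode logical; when `TRUE` the person-level slope SD
#'   is treated as zero (used by the analytic first-passage oracle tests).
#' @param slope_redraw_policy `"annual_iid"` (default: each year's eGFR
#'   change is a fresh draw around the covariate mean, matching the
#'   within-person error-term reading of the slope model) or
#'   `"once_at_baseline"` (a person-level random slope fixed at baseline;
#'   produces far heavier deep-stage tails).
#' @param pass_through_staging logical; record intermediate GFR-defined
#'   stages as attained when an annual step skips bands (default `TRUE`).
#' @param p4_fraction fraction of severe-albuminuria persons mapped to the
#'   heaviest proteinuria category (>= 1.5 g/24h) instead of 0.50-1.49.
#' @param bootstrap_fresh_sim logical; `TRUE` (default) draws fresh
#'   simulation randomness per bootstrap replicate so both cohort-sampling
#'   and simulation noise propagate into the CIs; `FALSE` keys random
#'   streams to original person ids (resampling-only bootstrap).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(start_year = 2010,
                       max_age = 90,
                       bootstrap_reps = 100,
                       ci_percentiles = c(2.5, 97.5),
                       master_seed = 20100L,
                       deterministic_mode = FALSE,
                       slope_redraw_policy = c("annual_iid", "once_at_baseline"),
                       pass_through_staging = TRUE,
                       p4_fraction = 0,
                       bootstrap_fresh_sim = TRUE) {
  slope_redraw_policy <- match.arg(slope_redraw_policy)
  out <- list(
    start_year = start_year,
    max_age = max_age,
    bootstrap_reps = bootstrap_reps,
    ci_percentiles = ci_percentiles,
    master_seed = as.integer(master_seed),
    deterministic_mode = deterministic_mode,
    slope_redraw_policy = slope_redraw_policy,
    pass_through_staging = pass_through_staging,
    p4_fraction = p4_fraction,
    bootstrap_fresh_sim = bootstrap_fresh_sim
  )
  class(out) <- "sim_config"
  out
}

#' Assemble (or fetch the default) full parameter bundle
#'
#' A bundle holds the four parameter groups the simulator needs:
#' `progression` (eGFR slope model), `obesity` (relative risks and BMI
#' drift), `background` (incidence/mortality tables) and `config`
#' (horizon, seeds, bootstrap settings). `default_params()` returns the
#' bundle that ships with the package.
#'
#' @param progression a [progression_params()] object.
#' @param obesity an [obesity_params()] object.
#' @param background a [background_rates()] object.
#' @param config a [sim_config()] object.
#' @return an object of class `ckd_params`.
#' @export
ckd_params <- function(progression = progression_params(),
                       obesity = obesity_params(),
                       background = background_rates(),
                       config = sim_config()) {
  out <- list(progression = progression, obesity = obesity,
              background = background, config = config)
  class(out) <- "ckd_params"
  validate_params(out)
  out
}

#' @rdname ckd_params
#' @export
default_params <- function() ckd_params()

band_vec_ok <- function(x) {
  is.numeric(x) && length(x) == 2 && !anyNA(x) && all(EGFR_BANDS %in% names(x))
}

#' Validate a parameter bundle
#'
#' Checks presence, types and ranges of every field; all problems are
#' collected and reported together in a single error.
#'
#' @param params a `ckd_params` bundle.
#' @return `params`, invisibly, if valid.
#' @export
validate_params <- function(params) {
  errs <- character(0)
  pp <- params$progression
  band_fields <- c("base_change", "coef_female", "coef_nh_black", "coef_hispanic",
                   "coef_other", "coef_prot_p2", "coef_prot_p3", "coef_prot_p4",
                   "coef_diabetes", "coef_hypertension", "coef_obesity",
                   "sd_annual_change")
  for (f in band_fields) {
    if (is.null(pp[[f]])) {
      errs <- c(errs, sprintf("progression$%s: missing", f))
    } else if (!band_vec_ok(pp[[f]])) {
      errs <- c(errs, sprintf("progression$%s: must be numeric with names lt60, ge60", f))
    }
  }
  if (band_vec_ok(pp$sd_annual_change) && any(pp$sd_annual_change <= 0)) {
    errs <- c(errs, "progression$sd_annual_change: must be > 0")
  }
  vm <- pp$variance_multiplier_ge60
  if (is.null(vm)) {
    errs <- c(errs, "progression$variance_multiplier_ge60: missing")
  } else if (!is.numeric(vm) || length(vm) != 1 || is.na(vm) || vm <= 0 || vm > 1) {
    errs <- c(errs, "progression$variance_multiplier_ge60: must be a scalar in (0, 1]")
  }

  ob <- params$obesity
  for (f in c("rr_diabetes", "rr_hypertension")) {
    m <- ob[[f]]
    if (is.null(m)) {
      errs <- c(errs, sprintf("obesity$%s: missing", f))
    } else if (!is.matrix(m) || !all(c("overweight", "obesity") %in% rownames(m)) ||
               !all(SEX_LEVELS %in% colnames(m)) || any(m < 0)) {
      errs <- c(errs, sprintf("obesity$%s: must be a nonnegative overweight/obesity x male/female matrix", f))
    }
  }
  for (f in c("rr_mi", "rr_chd", "rr_stroke")) {
    v <- ob[[f]]
    if (is.null(v)) {
      errs <- c(errs, sprintf("obesity$%s: missing", f))
    } else if (!is.numeric(v) || !all(c("overweight", "obesity") %in% names(v)) || any(v < 0)) {
      errs <- c(errs, sprintf("obesity$%s: must be nonnegative with names overweight, obesity", f))
    }
  }
  if (is.null(ob$bmi_delta) || !is.array(ob$bmi_delta) || anyNA(ob$bmi_delta) ||
      any(!is.finite(ob$bmi_delta))) {
    errs <- c(errs, "obesity$bmi_delta: must be a finite [age_band, race_group, sex] array")
  }
  if (is.null(ob$race_to_bmi_group) || !all(RACE_LEVELS %in% names(ob$race_to_bmi_group)) ||
      !all(ob$race_to_bmi_group %in% c("white", "black"))) {
    errs <- c(errs, "obesity$race_to_bmi_group: must map every race code to white/black")
  }

  bg <- params$background
  tab_fields <- c("incidence_diabetes", "incidence_hypertension", "incidence_chd",
                  "incidence_stroke", "incidence_mi", "incidence_albuminuria",
                  "mortality")
  for (f in tab_fields) {
    tb <- bg[[f]]
    if (is.null(tb)) {
      errs <- c(errs, sprintf("background$%s: missing", f))
      next
    }
    if (!is.data.frame(tb) || !all(c("age_lo", "age_hi", "sex", "annual_prob") %in% names(tb))) {
      errs <- c(errs, sprintf("background$%s: needs columns age_lo, age_hi, sex, annual_prob", f))
      next
    }
    if (any(tb$annual_prob < 0 | tb$annual_prob > 1)) {
      errs <- c(errs, sprintf("background$%s: annual_prob outside [0, 1]", f))
    }
    for (s in unique(tb$sex)) {
      sub <- tb[tb$sex == s, ]
      sub <- sub[order(sub$age_lo), ]
      if (is.unsorted(sub$annual_prob)) {
        errs <- c(errs, sprintf("background$%s: annual_prob not non-decreasing in age for sex=%s", f, s))
      }
    }
  }
  for (f in c("rate_albuminuria_severe", "alb_mult_diabetes", "alb_mult_hypertension")) {
    v <- bg[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || v < 0) {
      errs <- c(errs, sprintf("background$%s: must be a nonnegative scalar", f))
    }
  }
  if (is.null(bg$rate_albuminuria_severe) || bg$rate_albuminuria_severe > 1) {
    errs <- c(errs, "background$rate_albuminuria_severe: must be a probability in [0, 1]")
  }
  hrs <- bg$hr_mortality_by_stage
  if (is.null(hrs) || !all(STAGE_LEVELS %in% names(hrs)) || any(hrs < 0)) {
    errs <- c(errs, "background$hr_mortality_by_stage: must cover all stages with nonnegative multipliers")
  }
  if (is.null(bg$hr_mortality_cvd) || bg$hr_mortality_cvd < 0) {
    errs <- c(errs, "background$hr_mortality_cvd: must be a nonnegative scalar")
  }

  cf <- params$config
  if (is.null(cf$bootstrap_reps) || cf$bootstrap_reps < 1) {
    errs <- c(errs, "config$bootstrap_reps: must be >= 1")
  }
  if (is.null(cf$max_age) || cf$max_age > 90) {
    errs <- c(errs, "config$max_age: must be <= 90")
  }
  if (!is.null(cf$p4_fraction) && (cf$p4_fraction < 0 || cf$p4_fraction > 1)) {
    errs <- c(errs, "config$p4_fraction: must be in [0, 1]")
  }

  if (length(errs) > 0) {
    stop("invalid parameter bundle:\n  ", paste(errs, collapse = "\n  "), call. = FALSE)
  }
  invisible(params)
}

# ---- serialization -------------------------------------------------------

mat_to_list <- function(m) {
  out <- lapply(seq_len(nrow(m)), function(i) as.list(m[i, ]))
  names(out) <- rownames(m)
  out
}

list_to_mat <- function(l, cols) {
  rows <- names(l)
  m <- matrix(NA_real_, length(rows), length(cols), dimnames = list(rows, cols))
  for (r in rows) for (cc in cols) m[r, cc] <- as.numeric(l[[r]][[cc]])
  m
}

params_to_list <- function(params) {
  pp <- params$progression
  ob <- params$obesity
  bg <- params$background
  cf <- params$config
  bd <- ob$bmi_delta
  bd_list <- lapply(dimnames(bd)$age_band, function(a) {
    g <- lapply(dimnames(bd)$race_group, function(r) {
      stats::setNames(as.list(bd[a, r, ]), dimnames(bd)$sex)
    })
    stats::setNames(g, dimnames(bd)$race_group)
  })
  names(bd_list) <- dimnames(bd)$age_band
  list(
    progression = lapply(unclass(pp), function(x) if (length(x) > 1) as.list(x) else x),
    obesity = list(
      rr_diabetes = mat_to_list(ob$rr_diabetes),
      rr_hypertension = mat_to_list(ob$rr_hypertension),
      rr_mi = as.list(ob$rr_mi),
      rr_chd = as.list(ob$rr_chd),
      rr_stroke = as.list(ob$rr_stroke),
      bmi_delta = bd_list,
      race_to_bmi_group = as.list(ob$race_to_bmi_group)
    ),
    background = c(
      lapply(bg[c("incidence_diabetes", "incidence_hypertension", "incidence_chd",
                  "incidence_stroke", "incidence_mi", "incidence_albuminuria",
                  "mortality")], function(tb) lapply(as.list(tb), as.vector)),
      bg[c("rate_albuminuria_severe", "alb_mult_diabetes", "alb_mult_hypertension")],
      list(hr_mortality_by_stage = as.list(bg$hr_mortality_by_stage),
           hr_mortality_cvd = bg$hr_mortality_cvd)
    ),
    config = unclass(cf)
  )
}

params_from_list <- function(x) {
  num_band <- function(v) {
    if (is.null(v)) return(NULL)
    unlist(v)[EGFR_BANDS]
  }
  p <- x$progression
  pp <- progression_params(
    base_change = num_band(p$base_change),
    coef_female = num_band(p$coef_female),
    coef_nh_black = num_band(p$coef_nh_black),
    coef_hispanic = num_band(p$coef_hispanic),
    coef_other = num_band(p$coef_other),
    coef_prot_p2 = num_band(p$coef_prot_p2),
    coef_prot_p3 = num_band(p$coef_prot_p3),
    coef_prot_p4 = num_band(p$coef_prot_p4),
    coef_diabetes = num_band(p$coef_diabetes),
    coef_hypertension = num_band(p$coef_hypertension),
    coef_obesity = num_band(p$coef_obesity),
    sd_annual_change = num_band(p$sd_annual_change),
    variance_multiplier_ge60 = p$variance_multiplier_ge60
  )
  o <- x$obesity
  bd <- default_bmi_delta()
  for (a in dimnames(bd)$age_band) for (r in dimnames(bd)$race_group) for (s in dimnames(bd)$sex) {
    bd[a, r, s] <- as.numeric(o$bmi_delta[[a]][[r]][[s]])
  }
  ob <- obesity_params(
    rr_diabetes = list_to_mat(o$rr_diabetes, SEX_LEVELS),
    rr_hypertension = list_to_mat(o$rr_hypertension, SEX_LEVELS),
    rr_mi = unlist(o$rr_mi)[c("overweight", "obesity")],
    rr_chd = unlist(o$rr_chd)[c("overweight", "obesity")],
    rr_stroke = unlist(o$rr_stroke)[c("overweight", "obesity")],
    bmi_delta = bd,
    race_to_bmi_group = unlist(o$race_to_bmi_group)[RACE_LEVELS]
  )
  b <- x$background
  tab <- function(nm) {
    tb <- b[[nm]]
    if (is.null(tb)) return(NULL)
    data.frame(age_lo = as.numeric(unlist(tb$age_lo)),
               age_hi = as.numeric(unlist(tb$age_hi)),
               sex = as.character(unlist(tb$sex)),
               annual_prob = as.numeric(unlist(tb$annual_prob)),
               stringsAsFactors = FALSE)
  }
  bg <- background_rates(
    incidence_diabetes = tab("incidence_diabetes"),
    incidence_hypertension = tab("incidence_hypertension"),
    incidence_chd = tab("incidence_chd"),
    incidence_stroke = tab("incidence_stroke"),
    incidence_mi = tab("incidence_mi"),
    incidence_albuminuria = tab("incidence_albuminuria"),
    mortality = tab("mortality"),
    rate_albuminuria_severe = b$rate_albuminuria_severe,
    alb_mult_diabetes = b$alb_mult_diabetes,
    alb_mult_hypertension = b$alb_mult_hypertension,
    hr_mortality_by_stage = unlist(b$hr_mortality_by_stage)[STAGE_LEVELS],
    hr_mortality_cvd = b$hr_mortality_cvd
  )
  cfl <- x$config
  cf <- sim_config(
    start_year = cfl$start_year, max_age = cfl$max_age,
    bootstrap_reps = cfl$bootstrap_reps,
    ci_percentiles = as.numeric(unlist(cfl$ci_percentiles)),
    master_seed = cfl$master_seed,
    deterministic_mode = isTRUE(cfl$deterministic_mode),
    slope_redraw_policy = cfl$slope_redraw_policy,
    pass_through_staging = isTRUE(cfl$pass_through_staging),
    p4_fraction = cfl$p4_fraction %||% 0,
    bootstrap_fresh_sim = isTRUE(cfl$bootstrap_fresh_sim)
  )
  ckd_params(pp, ob, bg, cf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a parameter bundle
#'
#' Bundles are stored as a single human-editable YAML (or JSON) document
#' with one section per parameter group (`progression`, `obesity`,
#' `background`, `config`). `load_params()` validates after reading and
#' reports all problems together; a written bundle reloads field-for-field
#' identical.
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return for `load_params()`, a validated `ckd_params` bundle.
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  params_from_list(x)
}

#' @rdname load_params
#' @param params a `ckd_params` bundle.
#' @export
write_params <- function(params, path) {
  x <- params_to_list(params)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path, precision = 15)
  }
  invisible(path)
}

#' Scale a named obesity-related parameter (one-way sensitivity analysis)
#'
#' Returns a deep copy of the bundle with one parameter (group) multiplied
#' by `factor`; the input bundle is untouched. Valid targets are
#' `"rr_diabetes_obesity"` (both sexes), `"rr_hypertension_obesity"` (both
#' sexes) and `"coef_obesity"` (both eGFR bands).
#'
#' @param params a `ckd_params` bundle.
#' @param target parameter name, see above.
#' @param factor positive scale factor (e.g. 0.75 or 1.25).
#' @return a new `ckd_params` bundle.
#' @export
scale_param <- function(params, target, factor) {
  valid <- c("rr_diabetes_obesity", "rr_hypertension_obesity", "coef_obesity")
  if (!target %in% valid) {
    stop("unknown sensitivity target '", target, "'; valid targets: ",
         paste(valid, collapse = ", "))
  }
  stopifnot(is.numeric(factor), length(factor) == 1, factor > 0)
  out <- params
  if (target == "rr_diabetes_obesity") {
    out$obesity$rr_diabetes["obesity", ] <- out$obesity$rr_diabetes["obesity", ] * factor
  } else if (target == "rr_hypertension_obesity") {
    out$obesity$rr_hypertension["obesity", ] <- out$obesity$rr_hypertension["obesity", ] * factor
  } else {
    out$progression$coef_obesity <- out$progression$coef_obesity * factor
  }
  out
}
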