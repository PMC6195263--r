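# Synthetic baseline cohort generation and the baseline derivations applied
# to survey data (CKD-EPI eGFR, persistent-albuminuria adjustment,
# albuminuria -> proteinuria-category mapping), plus cohort CSV I/O.

COHORT_COLS <- c("id", "age", "sex", "race", "scr_mg_dl", "egfr", "albuminuria",
                 "diabetes", "hypertension", "chd", "stroke", "mi", "bmi")

# Run expr with a private RNG state so generation is reproducible without
# disturbing the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' BMI category from continuous BMI
#'
#' Cutoffs 18.5 / 25 / 30 kg/m^2 (underweight, normal, overweight, obesity).
#'
#' @param bmi numeric vector, kg/m^2.
#' @return character vector of categories.
#' @export
bmi_category <- function(bmi) {
  out <- rep("normal", length(bmi))
  out[bmi < 18.5] <- "underweight"
  out[bmi >= 25 & bmi < 30] <- "overweight"
  out[bmi >= 30] <- "obesity"
  out
}

default_prev <- function(vals) {
  matrix(vals, nrow = 3, ncol = 4, byrow = TRUE,
         dimnames = list(AGE_BANDS, BMI_LEVELS))
}

#' Specification of a synthetic baseline cohort
#'
#' Describes the joint distribution the generator draws from: age-band,
#' sex and race/ethnicity weights; BMI-category weights per age band (with
#' continuous BMI drawn inside each category); a linear-in-age eGFR model;
#' and prevalence tables (age band x BMI category) for diabetes,
#' hypertension, CHD, stroke, MI and moderate/severe albuminuria.
#'
#' The shipped defaults are loosely shaped like the contemporary US adult
#' population (about one third obesity prevalence, diabetes/hypertension
#' prevalence rising with age, eGFR declining about 0.7 per year of age
#' cross-sectionally). They are synthetic, non-authoritative placeholders:
#' a stand-in for restricted survey microdata, not estimates of it.
#'
#' @param n cohort size (>= 1).
#' @param age_band_weights proportions over ages 30-49 / 50-64 / 65-90.
#' @param sex_split proportion female.
#' @param race_weights proportions over nh_white / nh_black / hispanic /
#'   other.
#' @param bmi_cat_weights_by_age_band 3 x 4 matrix of BMI-category
#'   proportions per age band (rows sum to 1).
#' @param egfr_age_model list with `intercept` (mean eGFR at age 30),
#'   `slope` (per year of age) and `sd`; draws are truncated to (5, 150].
#' @param prev_diabetes,prev_hypertension,prev_chd,prev_stroke,prev_mi
#'   3 x 4 prevalence matrices (age band x BMI category).
#' @param prev_alb_moderate,prev_alb_severe 3 x 4 matrices of baseline
#'   albuminuria category probabilities.
#' @param seed integer seed; the cohort is bit-for-bit reproducible from
#'   (spec, seed).
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 10000,
                        age_band_weights = c(`30-49` = 0.45, `50-64` = 0.32, `65-90` = 0.23),
                        sex_split = 0.52,
                        race_weights = c(nh_white = 0.68, nh_black = 0.115,
                                         hispanic = 0.14, other = 0.065),
                        bmi_cat_weights_by_age_band =
                          matrix(c(0.02, 0.31, 0.33, 0.34,
                                   0.01, 0.27, 0.35, 0.37,
                                   0.02, 0.30, 0.36, 0.32),
                                 nrow = 3, byrow = TRUE,
                                 dimnames = list(AGE_BANDS, BMI_LEVELS)),
                        egfr_age_model = list(intercept = 103, slope = -0.7, sd = 12.5),
                        prev_diabetes = default_prev(c(0.015, 0.025, 0.05, 0.09,
                                                       0.05, 0.08, 0.13, 0.20,
                                                       0.08, 0.12, 0.18, 0.25)),
                        prev_hypertension = default_prev(c(0.12, 0.15, 0.21, 0.30,
                                                           0.30, 0.35, 0.45, 0.58,
                                                           0.55, 0.58, 0.65, 0.72)),
                        prev_chd = default_prev(c(0.005, 0.005, 0.008, 0.012,
                                                  0.030, 0.030, 0.045, 0.060,
                                                  0.090, 0.090, 0.110, 0.130)),
                        prev_stroke = default_prev(c(0.002, 0.002, 0.003, 0.004,
                                                     0.015, 0.015, 0.020, 0.025,
                                                     0.050, 0.050, 0.060, 0.070)),
                        prev_mi = default_prev(c(0.003, 0.003, 0.005, 0.007,
                                                 0.018, 0.018, 0.027, 0.036,
                                                 0.055, 0.055, 0.066, 0.078)),
                        prev_alb_moderate = default_prev(c(0.04, 0.05, 0.06, 0.08,
                                                           0.06, 0.07, 0.09, 0.12,
                                                           0.10, 0.12, 0.14, 0.17)),
                        prev_alb_severe = default_prev(c(0.005, 0.006, 0.007, 0.010,
                                                         0.008, 0.010, 0.012, 0.016,
                                                         0.015, 0.017, 0.020, 0.025)),
                        seed = 1L) {
  spec <- list(n = n, age_band_weights = age_band_weights, sex_split = sex_split,
               race_weights = race_weights,
               bmi_cat_weights_by_age_band = bmi_cat_weights_by_age_band,
               egfr_age_model = egfr_age_model,
               prev_diabetes = prev_diabetes, prev_hypertension = prev_hypertension,
               prev_chd = prev_chd, prev_stroke = prev_stroke, prev_mi = prev_mi,
               prev_alb_moderate = prev_alb_moderate, prev_alb_severe = prev_alb_severe,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  errs <- character(0)
  if (spec$n < 1) errs <- c(errs, "n must be >= 1")
  chk_w <- function(w, nm) {
    if (any(w < 0) || sum(w) == 0) {
      errs <<- c(errs, paste0(nm, ": degenerate weights"))
    } else if (abs(sum(w) - 1) > 1e-9) {
      errs <<- c(errs, paste0(nm, ": weights must sum to 1"))
    }
  }
  chk_w(spec$age_band_weights, "age_band_weights")
  chk_w(spec$race_weights, "race_weights")
  for (b in AGE_BANDS) chk_w(spec$bmi_cat_weights_by_age_band[b, ],
                             paste0("bmi_cat_weights_by_age_band[", b, ",]"))
  if (spec$sex_split < 0 || spec$sex_split > 1) errs <- c(errs, "sex_split must be in [0, 1]")
  for (f in grep("^prev_", names(spec), value = TRUE)) {
    if (any(spec[[f]] < 0 | spec[[f]] > 1)) errs <- c(errs, paste0(f, ": probabilities outside [0, 1]"))
  }
  if (length(errs)) stop("invalid cohort spec:\n  ", paste(errs, collapse = "\n  "), call. = FALSE)
  invisible(spec)
}

age_band_of <- function(age) {
  cut(age, breaks = c(29, 49, 64, 90), labels = AGE_BANDS)
}

# Truncated-normal sampler via inverse CDF (exact, vectorised).
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# Continuous BMI within a category: truncated normals centred inside each
# band so the density is not flat against the cutoffs.
BMI_DRAW <- list(
  underweight = c(mean = 17.5, sd = 1.0, lo = 13, hi = 18.5),
  normal      = c(mean = 22.5, sd = 2.0, lo = 18.5, hi = 25),
  overweight  = c(mean = 27.3, sd = 1.5, lo = 25, hi = 30),
  obesity     = c(mean = 33.5, sd = 3.5, lo = 30, hi = 55)
)

#' Generate a synthetic baseline cohort
#'
#' Draws `spec$n` persons from the joint distribution described by a
#' [cohort_spec()]: age (uniform within sampled band), sex, race, BMI
#' category then continuous BMI within the category, comorbidities and
#' albuminuria from the prevalence tables, and eGFR from the linear age
#' model truncated to (5, 150]. A serum creatinine column consistent with
#' the drawn eGFR (inverted through the CKD-EPI equation) is included so
#' both baseline input paths can be exercised.
#'
#' @param spec a [cohort_spec()].
#' @return a `data.frame` of class `ckd_cohort`, one row per person, with
#'   columns `id, age, sex, race, scr_mg_dl, egfr, albuminuria, diabetes,
#'   hypertension, chd, stroke, mi, bmi`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n
  with_seed(spec$seed, {
    band <- sample(AGE_BANDS, n, replace = TRUE, prob = spec$age_band_weights)
    age <- integer(n)
    rng <- list(`30-49` = 30:49, `50-64` = 50:64, `65-90` = 65:89)
    for (b in AGE_BANDS) {
      idx <- band == b
      age[idx] <- sample(rng[[b]], sum(idx), replace = TRUE)
    }
    sex <- ifelse(stats::runif(n) < spec$sex_split, "female", "male")
    race <- sample(RACE_LEVELS, n, replace = TRUE, prob = spec$race_weights)
    bmi_cat <- character(n)
    for (b in AGE_BANDS) {
      idx <- band == b
      bmi_cat[idx] <- sample(BMI_LEVELS, sum(idx), replace = TRUE,
                             prob = spec$bmi_cat_weights_by_age_band[b, ])
    }
    bmi <- numeric(n)
    for (cc in BMI_LEVELS) {
      idx <- bmi_cat == cc
      d <- BMI_DRAW[[cc]]
      bmi[idx] <- rtruncnorm(sum(idx), d["mean"], d["sd"], d["lo"], d["hi"])
    }
    em <- spec$egfr_age_model
    egfr <- rtruncnorm(n, em$intercept + em$slope * (age - 30), em$sd, 5, 150)
    pick <- function(prev) stats::runif(n) < prev[cbind(band, bmi_cat)]
    diabetes <- pick(spec$prev_diabetes)
    hypertension <- pick(spec$prev_hypertension)
    chd <- pick(spec$prev_chd)
    stroke <- pick(spec$prev_stroke)
    mi <- pick(spec$prev_mi)
    u_alb <- stats::runif(n)
    p_sev <- spec$prev_alb_severe[cbind(band, bmi_cat)]
    p_mod <- spec$prev_alb_moderate[cbind(band, bmi_cat)]
    albuminuria <- ifelse(u_alb < p_sev, "severe",
                          ifelse(u_alb < p_sev + p_mod, "moderate", "normal"))
    cohort <- data.frame(
      id = seq_len(n), age = age, sex = sex, race = race,
      scr_mg_dl = scr_from_egfr(egfr, age, sex, race),
      egfr = egfr, albuminuria = albuminuria,
      diabetes = diabetes, hypertension = hypertension,
      chd = chd, stroke = stroke, mi = mi, bmi = bmi,
      stringsAsFactors = FALSE
    )
    class(cohort) <- c("ckd_cohort", "data.frame")
    cohort
  })
}

#' Persistent-albuminuria adjustment
#'
#' Cross-sectional surveys observe albuminuria once, while CKD staging
#' requires *persistent* albuminuria. Each person with moderately increased
#' albuminuria independently retains it with probability `retain_prob`, and
#' is otherwise reset to normal; severe and normal categories are left
#' untouched. This is a probabilistic stand-in for the published
#' persistence-adjustment algorithm, whose exact form is not public.
#'
#' @param cohort a `ckd_cohort`.
#' @param retain_prob probability in \[0, 1\] (default 0.6).
#' @param seed integer seed for the retention draws.
#' @return the adjusted cohort.
#' @export
adjust_persistent_albuminuria <- function(cohort, retain_prob = 0.6, seed = 1L) {
  stopifnot(retain_prob >= 0, retain_prob <= 1)
  mod <- cohort$albuminuria == "moderate"
  if (!any(mod)) return(cohort)
  keep <- with_seed(seed, stats::runif(sum(mod)) < retain_prob)
  cohort$albuminuria[mod][!keep] <- "normal"
  cohort
}

#' Map albuminuria category to 24h-proteinuria category
#'
#' The slope model's proteinuria covariate is categorical in g/24h
#' (p1 < 0.10, p2 0.10-0.49, p3 0.50-1.49, p4 >= 1.50). Default mapping:
#' normal -> p1, moderate -> p2, severe -> p3; optionally a configurable
#' fraction of severe cases is assigned p4 (deterministically the first
#' `p4_fraction` quantile of a per-person uniform if `u` is supplied,
#' otherwise all-or-none at `p4_fraction >= 1`).
#'
#' @param albuminuria character vector over normal/moderate/severe.
#' @param p4_fraction fraction of severe cases mapped to p4 (default 0).
#' @param u optional uniform(0,1) vector (same length) deciding which
#'   severe cases take p4.
#' @return character vector of proteinuria categories.
#' @export
map_albuminuria_to_proteinuria <- function(albuminuria, p4_fraction = 0, u = NULL) {
  out <- c(normal = "p1", moderate = "p2", severe = "p3")[albuminuria]
  if (p4_fraction > 0) {
    sev <- albuminuria == "severe"
    if (is.null(u)) {
      if (p4_fraction >= 1) out[sev] <- "p4"
      else stop("p4_fraction in (0,1) needs per-person uniforms `u`")
    } else {
      out[sev & u < p4_fraction] <- "p4"
    }
  }
  unname(out)
}

#' Cohort CSV input/output
#'
#' One row per person with fixed headers
#' `id, age, sex, race, scr_mg_dl, egfr, albuminuria, diabetes,
#' hypertension, chd, stroke, mi, bmi`; booleans encoded 0/1,
#' categoricals as the documented lowercase codes. `scr_mg_dl` may be
#' empty when `egfr` is supplied; if `egfr` is missing it is derived from
#' creatinine through [ckd_epi_egfr()]. Round-trips are lossless.
#'
#' @param path CSV file path.
#' @return `read_cohort_csv()` returns a `ckd_cohort` data frame.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(setdiff(COHORT_COLS, "scr_mg_dl"), names(raw))
  if (length(missing_cols)) {
    stop("cohort file missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !(raw[[col]] %in% c("", "NA")))
    if (length(bad)) {
      stop(sprintf("cohort file column '%s': unparseable value '%s' at row %d",
                   col, raw[[col]][bad[1]], bad[1]))
    }
    v
  }
  bool <- function(col) {
    v <- raw[[col]]
    bad <- which(!v %in% c("0", "1", "TRUE", "FALSE"))
    if (length(bad)) {
      stop(sprintf("cohort file column '%s': expected 0/1 but found '%s' at row %d",
                   col, v[bad[1]], bad[1]))
    }
    v %in% c("1", "TRUE")
  }
  cat_chk <- function(col, levels) {
    v <- raw[[col]]
    bad <- which(!v %in% levels)
    if (length(bad)) {
      stop(sprintf("cohort file column '%s': unknown code '%s' at row %d",
                   col, v[bad[1]], bad[1]))
    }
    v
  }
  egfr <- if ("egfr" %in% names(raw)) num("egfr") else rep(NA_real_, nrow(raw))
  scr <- if ("scr_mg_dl" %in% names(raw)) num("scr_mg_dl") else rep(NA_real_, nrow(raw))
  sex <- cat_chk("sex", SEX_LEVELS)
  race <- cat_chk("race", RACE_LEVELS)
  age <- num("age")
  need <- is.na(egfr)
  if (any(need & is.na(scr))) {
    stop("cohort file: rows with neither egfr nor scr_mg_dl (first at row ",
         which(need & is.na(scr))[1], ")")
  }
  egfr[need] <- ckd_epi_egfr(scr[need], age[need], sex[need], race[need])
  cohort <- data.frame(
    id = as.integer(num("id")), age = age, sex = sex, race = race,
    scr_mg_dl = scr, egfr = egfr,
    albuminuria = cat_chk("albuminuria", ALB_LEVELS),
    diabetes = bool("diabetes"), hypertension = bool("hypertension"),
    chd = bool("chd"), stroke = bool("stroke"), mi = bool("mi"),
    bmi = num("bmi"), stringsAsFactors = FALSE
  )
  class(cohort) <- c("ckd_cohort", "data.frame")
  cohort
}

#' @rdname read_cohort_csv
#' @param cohort a `ckd_cohort` data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- cohort[, COHORT_COLS]
  for (col in c("diabetes", "hypertension", "chd", "stroke", "mi")) {
    out[[col]] <- as.integer(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict a cohort spec to one BMI category and/or age band
#'
#' Returns a copy of `spec` whose category weights are degenerate on the
#' requested baseline BMI category and/or age band — the device used to
#' build the per-group cohorts (e.g. n = 10,000 persons with baseline
#' obesity) that the lifetime-risk contrasts are computed from.
#'
#' @param spec a [cohort_spec()].
#' @param bmi_category one of underweight/normal/overweight/obesity, or
#'   `NULL` to leave BMI weights unchanged.
#' @param age_band one of `"30-49"`, `"50-64"`, `"65-90"`, or `NULL`.
#' @return a modified `cohort_spec`.
#' @export
restrict_cohort_spec <- function(spec, bmi_category = NULL, age_band = NULL) {
  if (!is.null(bmi_category)) {
    stopifnot(bmi_category %in% BMI_LEVELS)
    w <- matrix(0, 3, 4, dimnames = dimnames(spec$bmi_cat_weights_by_age_band))
    w[, bmi_category] <- 1
    spec$bmi_cat_weights_by_age_band <- w
  }
  if (!is.null(age_band)) {
    stopifnot(age_band %in% AGE_BANDS)
    aw <- stats::setNames(rep(0, 3), AGE_BANDS)
    aw[age_band] <- 1
    spec$age_band_weights <- aw
  }
  validate_cohort_spec(spec)
  spec
}
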