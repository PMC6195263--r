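# The annual-cycle life-course simulator. The cohort is advanced
# year-by-year with vectorised updates; every random number a person
# consumes comes from that person's own pre-drawn stream (seeded from the
# master seed and the person's stream id), so per-id results do not depend
# on cohort order or composition.

# Event channel layout within each person's uniform stream.
EVENT_CHANNELS <- c("mort", "diabetes", "hypertension", "chd", "stroke", "mi",
                    "alb_inc", "alb_prog")

# Deterministic integer hash of one or more integers into [1, 2^31 - 2],
# minstd-style so intermediates stay exactly representable as doubles.
derive_seed <- function(...) {
  xs <- c(...)
  h <- 0
  for (x in xs) h <- (h * 48271 + as.numeric(x) + 1) %% 2147483647
  as.integer(h %% 2147483646 + 1)
}

# Baseline state: derived columns the annual loop needs.
init_state <- function(cohort, params) {
  cf <- params$config
  n <- nrow(cohort)
  state <- as.data.frame(cohort)
  state$age <- as.integer(round(state$age))
  state$alive <- TRUE
  state$bmi_cat <- bmi_category(state$bmi)
  state$baseline_bmi_cat <- state$bmi_cat
  state$baseline_age <- state$age
  state$baseline_egfr_band <- ifelse(state$egfr < 60, "lt60", "ge60")
  state$proteinuria <- map_albuminuria_to_proteinuria(state$albuminuria)
  state$highest_stage <- "none"
  state$att_s3a <- state$att_s3b <- state$att_s4 <- state$att_s5 <- rep(FALSE, n)
  st0 <- assign_stage(state$egfr, state$albuminuria)
  state <- update_stage_history(state, st0, cf$pass_through_staging)
  state$age_at_end <- rep(NA_real_, n)
  done <- state$age >= cf$max_age
  state$age_at_end[done] <- cf$max_age
  state
}

# Pre-draw each person's random numbers from a private stream.
# Returns list(U = n x NY x 8 array, Z = slope deviates, u_p4 = uniforms
# for the baseline severe->p4 assignment).
predraw_streams <- function(state, params, master_seed, stream_ids) {
  cf <- params$config
  n <- nrow(state)
  ny <- pmax(0L, cf$max_age - state$age)
  NY <- max(ny, 1L)
  annual <- cf$slope_redraw_policy == "annual_iid"
  U <- array(NA_real_, c(n, NY, length(EVENT_CHANNELS)))
  Z <- matrix(0, n, if (annual) NY else 1L)
  u_p4 <- numeric(n)
  nch <- length(EVENT_CHANNELS)
  for (i in seq_len(n)) {
    set.seed(derive_seed(master_seed, stream_ids[i]))
    nz <- if (annual) max(ny[i], 1L) else 1L
    Z[i, seq_len(nz)] <- stats::rnorm(nz)
    u_p4[i] <- stats::runif(1)
    if (ny[i] > 0L) {
      U[i, seq_len(ny[i]), ] <- matrix(stats::runif(ny[i] * nch), ny[i], nch)
    }
  }
  list(U = U, Z = Z, u_p4 = u_p4, ny = ny)
}

#' Simulate a cohort to death or the age horizon
#'
#' Runs the annual cycle for every person: (1) mortality draw, (2) BMI
#' drift, (3) incident comorbidities and albuminuria, (4) eGFR step along
#' the person's slope (covariate part re-evaluated each year so newly
#' acquired conditions shift the slope from the acquisition year onward),
#' (5) stage assignment and sequential stage bookkeeping, (6) age
#' increment — until death or `config$max_age`. The within-cycle order is
#' a fixed convention of the model, not a configuration knob.
#'
#' Per-person random streams are derived from `(master_seed, stream id)`,
#' so results for a given id are reproducible and independent of cohort
#' order.
#'
#' @param cohort a `ckd_cohort` data frame (see [generate_cohort()] /
#'   [read_cohort_csv()]).
#' @param params a `ckd_params` bundle.
#' @param master_seed integer master seed (defaults to
#'   `params$config$master_seed`).
#' @param stream_ids integers keying each person's random stream (defaults
#'   to `cohort$id`; the bootstrap passes resample positions instead).
#' @param trajectory logical; also return a per-person-year trajectory log.
#' @return a `data.frame` of class `ckd_records`, one row per person:
#'   baseline descriptors, `ever_ckd`, `highest_stage`, attainment flags
#'   `att_s3a`..`att_s5`, `died` and `age_at_death_or_90`. With
#'   `trajectory = TRUE`, a list `(records, trajectory)`.
#' @export
simulate_cohort <- function(cohort, params, master_seed = NULL,
                            stream_ids = NULL, trajectory = FALSE) {
  stopifnot(nrow(cohort) >= 1)
  validate_params(params)
  cf <- params$config
  if (is.null(master_seed)) master_seed <- cf$master_seed
  if (is.null(stream_ids)) stream_ids <- cohort$id
  state <- init_state(cohort, params)
  rs <- predraw_streams(state, params, master_seed, stream_ids)
  n <- nrow(state)

  # Severe-albuminuria persons optionally mapped to the heaviest
  # proteinuria category at baseline.
  if (cf$p4_fraction > 0) {
    state$proteinuria <- map_albuminuria_to_proteinuria(
      state$albuminuria, cf$p4_fraction, u = rs$u_p4)
  }

  # Person-level random slope: residual around the covariate mean, carried
  # for life under once_at_baseline.
  sdv <- slope_sd(state$baseline_egfr_band, params$progression, cf$deterministic_mode)
  state$slope_resid <- rs$Z[, 1] * sdv

  traj <- if (trajectory) vector("list", max(rs$ny)) else NULL
  prot_rank <- stats::setNames(seq_along(PROT_LEVELS), PROT_LEVELS)

  for (k in seq_len(max(rs$ny, 1L))) {
    A <- which(state$alive & state$age < cf$max_age)
    if (length(A) == 0L) break
    sub <- state[A, ]

    # (1) mortality
    sub <- mortality_draw(sub, params$background, u = rs$U[A, k, 1])
    died <- !sub$alive
    if (any(died)) {
      idx <- A[died]
      state$alive[idx] <- FALSE
      state$age_at_end[idx] <- state$age[idx]
    }
    A <- A[!died]
    if (length(A) == 0L) next
    sub <- sub[!died, ]

    # (2) BMI drift
    sub <- update_bmi(sub, params$obesity)

    # (3) incident comorbidities and albuminuria
    u_ev <- rs$U[A, k, -1, drop = FALSE]
    dim(u_ev) <- c(length(A), length(EVENT_CHANNELS) - 1L)
    colnames(u_ev) <- EVENT_CHANNELS[-1]
    sub <- incident_events(sub, params$background, params$obesity, u = u_ev)
    # proteinuria tracks albuminuria, never downgrading (baseline p4 sticks)
    mapped <- map_albuminuria_to_proteinuria(sub$albuminuria)
    sub$proteinuria <- ifelse(prot_rank[mapped] > prot_rank[sub$proteinuria],
                              mapped, sub$proteinuria)

    # (4) eGFR step
    mu <- mean_annual_change(sub, params$progression)
    slope <- if (cf$slope_redraw_policy == "annual_iid") {
      zk <- rs$Z[A, min(k, ncol(rs$Z))]
      mu + zk * slope_sd(sub$baseline_egfr_band, params$progression, cf$deterministic_mode)
    } else {
      mu + sub$slope_resid
    }
    sub$egfr <- step_egfr(sub$egfr, slope)

    # (5) staging
    ns <- assign_stage(sub$egfr, sub$albuminuria)
    sub <- update_stage_history(sub, ns, cf$pass_through_staging)

    # (6) age
    sub$age <- sub$age + 1L
    reached <- sub$age >= cf$max_age

    for (col in c("bmi", "bmi_cat", "diabetes", "hypertension", "chd", "stroke",
                  "mi", "albuminuria", "proteinuria", "egfr", "current_stage",
                  "highest_stage", "att_s3a", "att_s3b", "att_s4", "att_s5", "age")) {
      state[[col]][A] <- sub[[col]]
    }
    state$age_at_end[A[reached]] <- cf$max_age

    if (trajectory) {
      traj[[k]] <- data.frame(
        id = sub$id, year = cf$start_year + k - 1L, age = sub$age,
        egfr = sub$egfr, stage = sub$current_stage,
        diabetes = sub$diabetes, hypertension = sub$hypertension,
        cvd = sub$chd | sub$stroke | sub$mi,
        bmi = sub$bmi, stringsAsFactors = FALSE
      )
    }
  }
  state$age_at_end[is.na(state$age_at_end)] <- pmin(state$age, cf$max_age)[is.na(state$age_at_end)]

  records <- data.frame(
    id = state$id,
    sex = state$sex,
    race = state$race,
    baseline_age = state$baseline_age,
    baseline_age_band = cut(state$baseline_age, breaks = c(29, 49, 64, Inf),
                            labels = c("30-49", "50-64", "65+")),
    baseline_bmi_cat = factor(state$baseline_bmi_cat, levels = BMI_LEVELS),
    baseline_egfr_band = state$baseline_egfr_band,
    ever_ckd = state$highest_stage != "none",
    highest_stage = factor(state$highest_stage, levels = STAGE_LEVELS),
    att_s3a = state$att_s3a, att_s3b = state$att_s3b,
    att_s4 = state$att_s4, att_s5 = state$att_s5,
    died = !state$alive,
    age_at_death_or_90 = state$age_at_end,
    stringsAsFactors = FALSE
  )
  class(records) <- c("ckd_records", "data.frame")
  if (trajectory) {
    return(list(records = records, trajectory = do.call(rbind, traj)))
  }
  records
}

#' Simulate a single person
#'
#' Convenience wrapper running [simulate_cohort()] on a one-row cohort.
#'
#' @param person a one-row `ckd_cohort` data frame.
#' @param params a `ckd_params` bundle.
#' @param seed integer master seed.
#' @return a one-row `ckd_records` data frame.
#' @export
simulate_person <- function(person, params, seed = NULL) {
  stopifnot(nrow(person) == 1)
  simulate_cohort(person, params, master_seed = seed)
}

#' Write lifetime records to CSV
#'
#' @param records a `ckd_records` data frame.
#' @param path output CSV path.
#' @export
write_records_csv <- function(records, path) {
  out <- as.data.frame(records)
  for (col in c("ever_ckd", "att_s3a", "att_s3b", "att_s4", "att_s5", "died")) {
    out[[col]] <- as.integer(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
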