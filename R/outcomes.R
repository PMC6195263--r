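# Lifetime-risk tabulation, percentile-bootstrap confidence intervals,
# paired bootstrap group comparison, and the one-way +/-25% sensitivity
# analyses.

#' Lifetime risk of CKD by group
#'
#' For each group (default: baseline BMI category, optionally also
#' baseline age band): the share of persons ever reaching any CKD stage
#' (`risk_any`) and the share whose *highest* attained stage is each of
#' s1..s5. Highest-stage categories partition the ever-CKD set, so the
#' stage shares sum to `risk_any` exactly. Groups defined by factor levels
#' with no records are reported as `NA`, not zero.
#'
#' @param records a `ckd_records` data frame from [simulate_cohort()].
#' @param by grouping columns, `"baseline_bmi_cat"` (default) or
#'   `c("baseline_bmi_cat", "baseline_age_band")`.
#' @return a data frame of class `lifetime_risk_table` with columns
#'   `by`, `n`, `risk_any`, `risk_s1` .. `risk_s5`.
#' @export
lifetime_risk <- function(records, by = "baseline_bmi_cat") {
  stopifnot(nrow(records) > 0, all(by %in% names(records)))
  key <- interaction(records[by], drop = FALSE, sep = "|")
  groups <- levels(key)
  rows <- lapply(groups, function(g) {
    r <- records[key == g, ]
    parts <- strsplit(g, "|", fixed = TRUE)[[1]]
    base <- stats::setNames(as.list(parts), by)
    if (nrow(r) == 0) {
      risks <- as.list(rep(NA_real_, 7))
    } else {
      shares <- vapply(c("s1", "s2", "s3a", "s3b", "s4", "s5"),
                       function(s) mean(r$highest_stage == s), numeric(1))
      risks <- c(list(mean(r$ever_ckd)), as.list(shares))
    }
    names(risks) <- c("risk_any", "risk_s1", "risk_s2", "risk_s3a", "risk_s3b",
                      "risk_s4", "risk_s5")
    as.data.frame(c(base, list(n = nrow(r)), risks), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("lifetime_risk_table", "data.frame")
  out
}

#' Percentile of bootstrap replicates
#'
#' Linear interpolation between order statistics (type-7 quantile), the
#' declared percentile convention: with B = 100 replicates the 2.5th/97.5th
#' percentiles are definition-sensitive, so the rule is fixed here.
#'
#' @param x numeric vector of replicate estimates.
#' @param percentiles percentiles on 0-100.
#' @return numeric vector of the requested percentiles.
#' @export
percentile_ci <- function(x, percentiles = c(2.5, 97.5)) {
  stats::quantile(x, probs = percentiles / 100, type = 7, names = FALSE, na.rm = TRUE)
}

#' Percentile-bootstrap confidence intervals for lifetime risk
#'
#' Each replicate resamples persons with replacement from the baseline
#' cohort and re-simulates. By default each replicate also uses fresh
#' simulation randomness (replicate-specific streams keyed by resample
#' position), so both cohort-sampling and simulation noise enter the
#' intervals; with `config$bootstrap_fresh_sim = FALSE` streams are keyed
#' to original person ids (resampling-only). CI bounds are the configured
#' percentiles (default 2.5/97.5) of the replicate estimates per cell.
#'
#' @param cohort a `ckd_cohort` baseline cohort.
#' @param params a `ckd_params` bundle.
#' @param B number of replicates (default `config$bootstrap_reps`).
#' @param percentiles CI percentiles on 0-100 (default
#'   `config$ci_percentiles`).
#' @param master_seed integer master seed.
#' @param by grouping columns as in [lifetime_risk()].
#' @return an object of class `ckd_bootstrap`: a list with `point` (the
#'   full-cohort [lifetime_risk()] table with `ci_low_*`/`ci_high_*`
#'   columns for `risk_any` and each stage), `replicates` (B x group x
#'   metric array) and `B`.
#' @export
bootstrap_ci <- function(cohort, params, B = NULL, percentiles = NULL,
                         master_seed = NULL, by = "baseline_bmi_cat") {
  cf <- params$config
  if (is.null(B)) B <- cf$bootstrap_reps
  if (is.null(percentiles)) percentiles <- cf$ci_percentiles
  if (is.null(master_seed)) master_seed <- cf$master_seed
  stopifnot(B >= 1)
  n <- nrow(cohort)
  point <- lifetime_risk(simulate_cohort(cohort, params, master_seed), by = by)
  metrics <- c("risk_any", "risk_s1", "risk_s2", "risk_s3a", "risk_s3b",
               "risk_s4", "risk_s5")
  key <- do.call(paste, c(point[by], sep = "|"))
  reps <- array(NA_real_, c(B, length(key), length(metrics)),
                dimnames = list(NULL, key, metrics))
  for (b in seq_len(B)) {
    idx <- with_seed(derive_seed(master_seed, 777L, b), sample.int(n, n, replace = TRUE))
    rep_cohort <- cohort[idx, ]
    streams <- if (cf$bootstrap_fresh_sim) seq_len(n) else cohort$id[idx]
    rec <- simulate_cohort(rep_cohort, params,
                           master_seed = derive_seed(master_seed, 999L, b),
                           stream_ids = streams)
    tab <- lifetime_risk(rec, by = by)
    tkey <- do.call(paste, c(tab[by], sep = "|"))
    m <- match(key, tkey)
    for (j in seq_along(metrics)) {
      reps[b, , metrics[j]] <- tab[[metrics[j]]][m]
    }
  }
  for (met in metrics) {
    ci <- apply(reps[, , met, drop = FALSE], 2, percentile_ci, percentiles = percentiles)
    point[[paste0("ci_low_", sub("risk_", "", met))]] <- ci[1, ]
    point[[paste0("ci_high_", sub("risk_", "", met))]] <- ci[2, ]
  }
  # percentile bootstrap does not guarantee containment of the point
  # estimate; flag (never silently "fix") the cells where it falls outside
  point$point_outside_ci <- point$risk_any < point$ci_low_any |
    point$risk_any > point$ci_high_any
  out <- list(point = point, replicates = reps, B = B,
              percentiles = percentiles, by = by)
  class(out) <- "ckd_bootstrap"
  out
}

#' Compare two groups from paired bootstrap replicates
#'
#' Two-sided p-value for the difference in an estimate between groups A
#' and B, from replicate vectors paired by replicate seed:
#' `p = 2 * pnorm(-|mean(d)| / sd(d))` where `d` is the per-replicate
#' difference and `sd(d)` its bootstrap standard error. A normal
#' approximation by declared convention. With zero bootstrap variance and
#' a nonzero difference the p-value is reported as `1/B` with
#' `degenerate = TRUE`.
#'
#' @param reps_a,reps_b equal-length numeric vectors of replicate
#'   estimates for the two groups, same replicate order.
#' @return a list with `p_value`, `mean_diff`, `se_boot`, `degenerate`.
#' @export
compare_groups <- function(reps_a, reps_b) {
  stopifnot(length(reps_a) == length(reps_b), length(reps_a) >= 1)
  d <- reps_a - reps_b
  dbar <- mean(d)
  se <- stats::sd(d)
  if (length(d) == 1 || is.na(se) || se == 0) {
    if (dbar == 0) {
      return(list(p_value = 1, mean_diff = dbar, se_boot = 0, degenerate = FALSE))
    }
    return(list(p_value = 1 / length(d), mean_diff = dbar, se_boot = 0,
                degenerate = TRUE))
  }
  list(p_value = 2 * stats::pnorm(-abs(dbar) / se),
       mean_diff = dbar, se_boot = se, degenerate = FALSE)
}

#' One-way sensitivity analyses (+/- 25%)
#'
#' Re-runs the simulation with each of three obesity-related parameters —
#' the relative risk of diabetes for obesity, the relative risk of
#' hypertension for obesity, and the obesity coefficient of the annual
#' eGFR change — scaled by 0.75 and by 1.25 (six runs), under seeds
#' identical to the reference run, and reports the difference in lifetime
#' risk of any CKD between the obesity and normal-weight baseline groups
#' in percentage points.
#'
#' @param cohort a `ckd_cohort` containing both normal-weight and obesity
#'   baseline groups.
#' @param params a `ckd_params` bundle.
#' @param master_seed integer master seed shared by all runs.
#' @param factors scale factors (default `c(0.75, 1.25)`).
#' @return a data frame of class `sensitivity_table` with 6 rows:
#'   `parameter`, `factor`, `direction`, `diff_pp` (obesity minus normal,
#'   percentage points) and `reference_diff_pp`.
#' @export
run_sensitivity <- function(cohort, params, master_seed = NULL,
                            factors = c(0.75, 1.25)) {
  if (is.null(master_seed)) master_seed <- params$config$master_seed
  diff_pp <- function(p) {
    tab <- lifetime_risk(simulate_cohort(cohort, p, master_seed))
    100 * (tab$risk_any[tab$baseline_bmi_cat == "obesity"] -
             tab$risk_any[tab$baseline_bmi_cat == "normal"])
  }
  ref <- diff_pp(params)
  targets <- c("rr_diabetes_obesity", "rr_hypertension_obesity", "coef_obesity")
  grid <- expand.grid(parameter = targets, factor = factors,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$parameter, grid$factor), ]
  grid$direction <- ifelse(grid$factor < 1, "-25%", "+25%")
  grid$diff_pp <- vapply(seq_len(nrow(grid)), function(i) {
    diff_pp(scale_param(params, grid$parameter[i], grid$factor[i]))
  }, numeric(1))
  grid$reference_diff_pp <- ref
  rownames(grid) <- NULL
  class(grid) <- c("sensitivity_table", "data.frame")
  grid
}
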