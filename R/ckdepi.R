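#' CKD-EPI (2009) estimated glomerular filtration rate
#'
#' The 2009 CKD-EPI creatinine equation with sex-specific creatinine knots
#' (kappa = 0.7 mg/dL for women, 0.9 for men), a two-piece power term and
#' race/sex level constants, in the published per-group form:
#'
#' \deqn{eGFR = C \cdot \min(Scr/\kappa, 1)^{\alpha} \cdot
#'       \max(Scr/\kappa, 1)^{-1.209} \cdot 0.993^{age}}
#'
#' with \eqn{\alpha} = -0.329 (women) / -0.411 (men) and C = 144/166
#' (women, non-black/black) or 141/163 (men). Output is in
#' ml/min/1.73m^2 and strictly decreasing in serum creatinine.
#'
#' @param scr serum creatinine, mg/dL (> 0).
#' @param age age in years (>= 18).
#' @param sex `"male"` or `"female"` (vectorised).
#' @param race race code; `"nh_black"` selects the black coefficient, all
#'   other codes the non-black one.
#' @return numeric vector of eGFR values.
#' @examples
#' ckd_epi_egfr(0.8, 50, "female", "nh_white")
#' @export
ckd_epi_egfr <- function(scr, age, sex, race) {
  if (any(scr <= 0)) stop("serum creatinine must be positive")
  if (any(age < 18)) stop("CKD-EPI is an adult equation: age must be >= 18")
  n <- max(length(scr), length(age), length(sex), length(race))
  scr <- rep_len(scr, n); age <- rep_len(age, n)
  sex <- rep_len(sex, n); race <- rep_len(race, n)
  female <- sex == "female"
  black <- race == "nh_black"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  cons <- ifelse(female, ifelse(black, 166, 144), ifelse(black, 163, 141))
  r <- scr / kappa
  cons * pmin(r, 1)^alpha * pmax(r, 1)^(-1.209) * 0.993^age
}

# Closed-form inverse of ckd_epi_egfr: the serum creatinine consistent with
# a given eGFR. Used by the synthetic generator so cohorts carry a
# creatinine column that reproduces their eGFR through either input path.
scr_from_egfr <- function(egfr, age, sex, race) {
  stopifnot(all(egfr > 0))
  n <- max(length(egfr), length(age), length(sex), length(race))
  egfr <- rep_len(egfr, n); age <- rep_len(age, n)
  sex <- rep_len(sex, n); race <- rep_len(race, n)
  female <- sex == "female"
  black <- race == "nh_black"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  cons <- ifelse(female, ifelse(black, 166, 144), ifelse(black, 163, 141))
  knot_egfr <- cons * 0.993^age           # eGFR at scr == kappa
  ratio <- egfr / knot_egfr
  # egfr >= knot value <=> scr <= kappa (low-creatinine branch)
  ifelse(ratio >= 1, kappa * ratio^(1 / alpha), kappa * ratio^(1 / -1.209))
}
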