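# Synthetic patient cohort: survival-stratified response groups with
# CA 19-9 levels at both draws.

# Inverse-CDF sampling from a truncated normal.  Deterministic under
# set.seed and fails loudly when the truncation window carries essentially
# no probability mass (the analogue of a rejection sampler spinning).
rtruncnorm_inv <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) ms1_abort("truncated-normal `sd` must be positive")
  p_lo <- pnorm(lower, mean, sd)
  p_hi <- pnorm(upper, mean, sd)
  if (p_hi - p_lo < 1e-12) {
    ms1_abort(sprintf(
      "truncation [%g, %g] around Normal(%g, %g) is numerically impossible",
      lower, upper, mean, sd
    ))
  }
  u <- runif(n)
  q <- qnorm(p_lo + u * (p_hi - p_lo), mean, sd)
  pmin(pmax(q, lower), upper)
}

# Clinical CA 19-9 medians (units/ml) by stage, response group and draw,
# used as log-normal location defaults.
CA19_9_MEDIANS <- tibble::tribble(
  ~stage, ~response_group, ~baseline, ~post,
  "III", "Good",     179.5,   25.6,
  "III", "Limited",  447.4,  517.3,
  "IV",  "Good",    1116.8,  250.1,
  "IV",  "Limited", 5532.8, 4642.0
)

#' Simulate a response-stratified patient cohort
#'
#' Generates pancreatic-cancer patients split into Good-responders
#' (overall survival >= 12 months) and Limited-responders (< 12 months).
#' Survival is drawn from a truncated normal per group so that group
#' membership is always consistent with the 12-month rule; CA 19-9 is
#' log-normal around stage/group-specific clinical medians with
#' correlated baseline and post-treatment draws; the gap between the two
#' blood draws is Normal(62, 12) days.
#'
#' @param n_good,n_limited Number of patients per response group.
#' @param stage Tumor stage for the cohort, `"III"` or `"IV"`.
#' @param survival_mean_good,survival_sd_good Survival moments (months)
#'   for Good-responders before truncation at >= 12 months.
#' @param survival_mean_limited,survival_sd_limited Survival moments for
#'   Limited-responders before truncation to (0, 12).
#' @param draw_gap_mean,draw_gap_sd Days between the two blood draws.
#' @param ca19_9_sdlog Log-scale SD of the CA 19-9 log-normal.
#' @param ca19_9_logcor Log-scale correlation between baseline and
#'   post-treatment CA 19-9 within a patient.
#' @param censoring_prob Probability that a patient's survival time is
#'   administratively censored (`event_observed = FALSE`). Default 0: the
#'   source cohort reports no censoring.
#' @param seed Integer seed; identical inputs give identical cohorts.
#' @return A tibble with one row per patient: `patient_id`, `stage`,
#'   `response_group`, `survival_months`, `event_observed`,
#'   `ca19_9_baseline`, `ca19_9_post`, `draw_gap_days`.
#' @examples
#' simulate_patients(n_good = 8, n_limited = 8, seed = 1)
#' @export
simulate_patients <- function(n_good = 8, n_limited = 8, stage = c("IV", "III"),
                              survival_mean_good = 21.6, survival_sd_good = 7.0,
                              survival_mean_limited = 6.9, survival_sd_limited = 3.5,
                              draw_gap_mean = 62, draw_gap_sd = 12,
                              ca19_9_sdlog = 1, ca19_9_logcor = 0.8,
                              censoring_prob = 0, seed = 1) {
  stage <- match.arg(stage)
  if (n_good < 1 || n_limited < 1) ms1_abort("each response group needs >= 1 patient")
  check_positive(survival_sd_good, "survival_sd_good")
  check_positive(survival_sd_limited, "survival_sd_limited")
  check_positive(draw_gap_sd, "draw_gap_sd")
  check_positive(ca19_9_sdlog, "ca19_9_sdlog")
  check_number(ca19_9_logcor, "ca19_9_logcor", lower = -1, upper = 1)
  check_number(censoring_prob, "censoring_prob", lower = 0, upper = 1)

  set.seed(as.integer(seed))
  n <- n_good + n_limited
  group <- c(rep("Good", n_good), rep("Limited", n_limited))

  survival <- numeric(n)
  survival[group == "Good"] <- rtruncnorm_inv(
    n_good, survival_mean_good, survival_sd_good, lower = 12
  )
  survival[group == "Limited"] <- rtruncnorm_inv(
    n_limited, survival_mean_limited, survival_sd_limited,
    lower = .Machine$double.eps, upper = 12 - 1e-9
  )

  medians <- dplyr::filter(CA19_9_MEDIANS, .data$stage == !!stage)
  med_base <- setNames(medians$baseline, medians$response_group)[group]
  med_post <- setNames(medians$post, medians$response_group)[group]
  z_base <- rnorm(n)
  z_post <- ca19_9_logcor * z_base + sqrt(1 - ca19_9_logcor^2) * rnorm(n)
  ca_base <- med_base * exp(ca19_9_sdlog * z_base)
  ca_post <- med_post * exp(ca19_9_sdlog * z_post)

  gap <- rtruncnorm_inv(n, draw_gap_mean, draw_gap_sd, lower = 1)
  censored <- runif(n) < censoring_prob

  tibble::tibble(
    patient_id = sprintf("P%02d", seq_len(n)),
    stage = stage,
    response_group = group,
    survival_months = survival,
    event_observed = !censored,
    ca19_9_baseline = ca_base,
    ca19_9_post = ca_post,
    draw_gap_days = gap
  )
}

# Recompute the response label from survival; used by consistency checks.
response_group_from_survival <- function(survival_months) {
  ifelse(survival_months >= 12, "Good", "Limited")
}
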