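#' Simulate a screening cohort with known ground truth
#'
#' Generates a cohort with the statistical structure the OncoSensi
#' analysis assumes, for testing model fitting and evaluation without
#' patient data. Log growth rate and RT-AUC are drawn bivariate normal
#' with the given correlation (AUC clamped to the attainable 0-800
#' range), HPV status is Bernoulli, features are standardised within
#' the generated cohort, and the 1-year recurrence indicator is drawn
#' from a logistic model on the true linear predictor. Recurrent
#' patients get a truncated-exponential recurrence time inside the
#' 1-year horizon (rate increasing in the linear predictor);
#' non-recurrent patients are administratively censored.
#'
#' Defaults mirror the bundled reference test set: n = 14, log-growth
#' mean 5.16 / SD 0.687, AUC mean 514 / SD 140, correlation -0.7, HPV
#' prevalence 9/14, and the published two-parameter coefficients as the
#' true model.
#'
#' @param n_patients Number of patients (>= 2).
#' @param growth_meanlog,growth_sdlog Mean and SD of log growth rate.
#' @param auc_mean,auc_sd Mean and SD of RT-AUC (percent-Gy).
#' @param correlation Correlation between log growth and RT-AUC, in
#'   `[-1, 1]`.
#' @param hpv_prevalence Probability of HPV positivity, in `[0, 1]`.
#' @param true_model An `oncosensi_model` giving the true coefficients
#'   over `z_growth`, `z_auc` and optionally `z_hpv`.
#' @param rfs_scale_days Baseline exponential scale of recurrence times.
#' @param censor_days Administrative censoring time (> 365).
#' @param seed Optional integer seed; fixed seed gives an identical
#'   table on every call.
#' @return A cohort tibble (schema as [hnscc_cohort()]) with hidden
#'   ground-truth columns `.true_lp` (linear predictor) and
#'   `.true_event_time`.
#' @examples
#' simulate_cohort(20, seed = 1)
#' @export
simulate_cohort <- function(n_patients = 14,
                            growth_meanlog = 5.16, growth_sdlog = 0.687,
                            auc_mean = 514, auc_sd = 140,
                            correlation = -0.7, hpv_prevalence = 9 / 14,
                            true_model = published_model("two_parameter"),
                            rfs_scale_days = 1000, censor_days = 730,
                            seed = NULL) {
  if (n_patients < 2) abort("`n_patients` must be >= 2.")
  if (abs(correlation) > 1) abort("`correlation` must be in [-1, 1].")
  if (hpv_prevalence < 0 || hpv_prevalence > 1) {
    abort("`hpv_prevalence` must be in [0, 1].")
  }
  with_seed_or_not(seed, {
    z1 <- rnorm(n_patients)
    z2 <- correlation * z1 + sqrt(1 - correlation^2) * rnorm(n_patients)
    growth <- exp(growth_meanlog + growth_sdlog * z1)
    auc <- pmin(pmax(auc_mean + auc_sd * z2, 0), 800)
    hpv01 <- rbinom(n_patients, 1, hpv_prevalence)

    feats <- tibble::tibble(
      z_growth = (log(growth) - mean(log(growth))) / sd(log(growth)),
      z_auc = (auc - mean(auc)) / sd(auc)
    )
    if ("z_hpv" %in% true_model$features) {
      s <- sd(hpv01)
      if (s == 0) {
        abort("HPV status is constant; cannot standardise for an HPV model.")
      }
      feats$z_hpv <- (hpv01 - mean(hpv01)) / s
    }
    lp <- linear_predictor(true_model, feats)
    recur <- rbinom(n_patients, 1, plogis(lp))

    rate <- exp(lp) / rfs_scale_days
    horizon <- 365
    event_time <- qexp(runif(n_patients) * stats::pexp(horizon, rate), rate)
    rfs <- ifelse(recur == 1, event_time, censor_days)

    tibble::tibble(
      patient_id = seq_len(n_patients),
      set = "test",
      hpv = ifelse(hpv01 == 1, "positive", "negative"),
      recur = ifelse(recur == 1, "yes", "no"),
      rfs_days = round(rfs, 1),
      rt_auc = auc,
      growth_rate = growth,
      .true_lp = lp,
      .true_event_time = event_time
    )
  })
}
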