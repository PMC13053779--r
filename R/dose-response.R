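#' Trapezoid area under a radiation dose-response curve
#'
#' RT-AUC summarises a dose-response curve of percent viability over the
#' dose grid (default 0/2/4/8 Gy) by the trapezoid rule, in units of
#' percent-Gy. On the standard grid, viability pinned at 100% at every
#' dose gives the maximum of 800; complete kill everywhere gives 0.
#'
#' @param viability_pct Percent viability, one value per dose, >= 0.
#' @param dose_gy Strictly increasing dose grid (>= 2 points).
#' @return RT-AUC in percent-Gy (scalar).
#' @examples
#' auc_trapezoid(c(100, 100, 100, 100)) # 800, fully resistant
#' auc_trapezoid(c(100, 50, 25, 12.5)) # 300
#' @export
auc_trapezoid <- function(viability_pct, dose_gy = c(0, 2, 4, 8)) {
  if (length(dose_gy) < 2) abort("Need at least 2 dose points.")
  if (any(diff(dose_gy) <= 0)) abort("`dose_gy` must be strictly increasing.")
  check_same_length(viability_pct, dose_gy, "viability_pct", "dose_gy")
  check_number(viability_pct, "viability_pct", min = 0)
  sum(diff(dose_gy) * (head(viability_pct, -1) + viability_pct[-1]) / 2)
}

# half-sum of adjacent dose gaps: the weight each dose point carries in
# the trapezoid sum ([1, 2, 3, 2] on the 0/2/4/8 grid)
trapezoid_weights <- function(dose_gy) {
  gaps <- diff(dose_gy)
  (c(0, gaps) + c(gaps, 0)) / 2
}

#' Standard error of a trapezoid RT-AUC
#'
#' Propagates per-dose standard errors of the mean through the trapezoid
#' weights: `SE = sqrt(sum((w_i * sem_i)^2))` with `w_i` the half-sum of
#' the dose gaps adjacent to point `i`. Assumes independent per-dose
#' errors.
#'
#' @param sem Per-dose standard errors of mean viability (>= 0).
#' @inheritParams auc_trapezoid
#' @return AUC standard error in percent-Gy.
#' @examples
#' auc_standard_error(c(2, 2, 2, 2)) # 2 * sqrt(18)
#' @export
auc_standard_error <- function(sem, dose_gy = c(0, 2, 4, 8)) {
  check_number(sem, "sem", min = 0)
  check_same_length(sem, dose_gy, "sem", "dose_gy")
  sqrt(sum((trapezoid_weights(dose_gy) * sem)^2))
}

#' Summarise dose-response curves per sample
#'
#' Takes a long table of per-replicate viabilities and returns, per
#' sample, the trapezoid RT-AUC of the mean curve, its propagated
#' standard error, and the replicate count.
#'
#' @param data Data frame with columns `sample_id`, `dose_gy`,
#'   `viability_pct` (one row per replicate measurement).
#' @return A tibble `sample_id`, `auc`, `se`, `n_replicates`, of class
#'   `drc_summary`.
#' @examples
#' df <- tidyr::expand_grid(sample_id = "s1", dose_gy = c(0, 2, 4, 8),
#'                          rep = 1:3) |>
#'   dplyr::mutate(viability_pct = 100 * exp(-0.2 * dose_gy) + rep - 2)
#' drc_summarise(df)
#' @export
drc_summarise <- function(data) {
  needed <- c("sample_id", "dose_gy", "viability_pct")
  if (!all(needed %in% names(data))) {
    abort("`data` needs columns sample_id, dose_gy, viability_pct.")
  }
  per_dose <- data |>
    dplyr::summarise(
      mean_viab = mean(.data$viability_pct),
      sem = ifelse(dplyr::n() > 1,
                   sd(.data$viability_pct) / sqrt(dplyr::n()), 0),
      n = dplyr::n(),
      .by = c("sample_id", "dose_gy")
    ) |>
    dplyr::arrange(.data$sample_id, .data$dose_gy)
  out <- per_dose |>
    dplyr::summarise(
      auc = auc_trapezoid(.data$mean_viab, .data$dose_gy),
      se = auc_standard_error(.data$sem, .data$dose_gy),
      n_replicates = max(.data$n),
      .by = "sample_id"
    )
  structure(out, class = c("drc_summary", class(out)))
}

#' Concordance (R-squared) between paired viability measurements
#'
#' Coefficient of determination from a simple linear regression of
#' method B on method A, used to check that two irradiation or
#' quantification protocols agree (values above 0.7 are read as high
#' reproducibility).
#'
#' @param a,b Paired numeric vectors (length >= 3); `a` must vary.
#' @return R-squared in `[0, 1]`.
#' @examples
#' replicate_concordance(1:4, c(1.1, 1.9, 3.2, 3.8))
#' @export
replicate_concordance <- function(a, b) {
  check_same_length(a, b, "a", "b")
  if (length(a) < 3) abort("Need at least 3 paired measurements.")
  if (var(a) == 0) abort("`a` has zero variance; R-squared is undefined.")
  summary(lm(b ~ a))$r.squared
}

#' Plot a dose-response curve
#'
#' @param data Data frame with `dose_gy` and `viability_pct` (and
#'   optionally `sample_id` for faceting colour).
#' @return A ggplot.
#' @export
plot_dose_response <- function(data) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$dose_gy,
                                          y = .data$viability_pct))
  if ("sample_id" %in% names(data)) {
    p <- p + ggplot2::aes(colour = factor(.data$sample_id))
  }
  p +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::stat_summary(fun = mean, geom = "point") +
    ggplot2::labs(x = "Dose (Gy)", y = "Viability (%)",
                  colour = "Sample") +
    ggplot2::theme_minimal()
}
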