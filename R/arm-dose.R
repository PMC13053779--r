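#' ARM dose-time calibration
#'
#' The automated radiation modulator (ARM) doses each region of a
#' 384-pillar plate by how long the plate dwells in a fixed radiation
#' slit, so delivered dose is proportional to dwell time. A calibration
#' is a set of measured (dose, dwell) pairs plus the transmission
#' fraction of the tungsten shield that covers the rest of the plate.
#'
#' `arm_reference_calibration()` returns the measured reference
#' calibration for the device this package models: 1, 2, 4 and 8 Gy
#' delivered at dwell times of 51.59, 102.98, 205.96 and 411.92 s, with
#' shield transmission 1/6 (a shielded well receives about 1 Gy while an
#' open well receives about 6 Gy in the same exposure).
#'
#' @param dose_gy Positive doses in Gy.
#' @param dwell_s Positive dwell times in seconds, one per dose.
#' @param shield_transmission Fraction of dose reaching a shielded well,
#'   in `[0, 1]`.
#' @return An `arm_calibration` object: a tibble of calibration points
#'   with the shield transmission as an attribute.
#' @examples
#' arm_reference_calibration()
#' fit_unit_time(arm_reference_calibration())
#' @export
arm_calibration <- function(dose_gy, dwell_s, shield_transmission = 1 / 6) {
  check_number(dose_gy, "dose_gy", min = 0, allow_zero = FALSE)
  check_number(dwell_s, "dwell_s", min = 0, allow_zero = FALSE)
  check_same_length(dose_gy, dwell_s, "dose_gy", "dwell_s")
  if (length(dose_gy) < 1) abort("At least one calibration point is required.")
  if (shield_transmission < 0 || shield_transmission > 1) {
    abort("`shield_transmission` must be in [0, 1].")
  }
  out <- tibble::tibble(dose_gy = as.numeric(dose_gy),
                        dwell_s = as.numeric(dwell_s))
  structure(out, shield_transmission = shield_transmission,
            class = c("arm_calibration", class(out)))
}

#' @rdname arm_calibration
#' @export
arm_reference_calibration <- function() {
  arm_calibration(dose_gy = c(1, 2, 4, 8),
                  dwell_s = c(51.59, 102.98, 205.96, 411.92),
                  shield_transmission = 1 / 6)
}

#' Read an ARM calibration from CSV
#'
#' Expects columns `dose_gy,dwell_s`.
#'
#' @inheritParams arm_calibration
#' @param path CSV file path.
#' @return An [arm_calibration()] object.
#' @export
read_calibration <- function(path, shield_transmission = 1 / 6) {
  df <- readr::read_csv(path, col_types = readr::cols(
    dose_gy = readr::col_double(), dwell_s = readr::col_double()
  ), progress = FALSE)
  arm_calibration(df$dose_gy, df$dwell_s, shield_transmission)
}

#' Fit the per-Gy unit dwell time
#'
#' Least-squares slope of dwell time on dose, constrained through the
#' origin: zero dwell must deliver zero dose. With calibration points
#' \eqn{(D_i, t_i)} the fit is \eqn{\hat u = \sum D_i t_i / \sum D_i^2}
#' seconds per Gy.
#'
#' @param calibration An [arm_calibration()] object (or any data frame
#'   with `dose_gy` and `dwell_s` columns).
#' @return Unit time in seconds per Gy (scalar).
#' @examples
#' fit_unit_time(arm_calibration(c(2, 4), c(102.98, 205.96)))
#' @export
fit_unit_time <- function(calibration) {
  if (nrow(calibration) < 1) abort("Calibration is empty.")
  sum(calibration$dose_gy * calibration$dwell_s) / sum(calibration$dose_gy^2)
}

#' Dwell time needed for a target dose
#'
#' @param dose_gy Target dose (Gy), non-negative.
#' @param unit_time_s_per_gy Seconds of dwell per Gy, from
#'   [fit_unit_time()].
#' @return Dwell time in seconds.
#' @examples
#' dwell_time_for_dose(8, 51.49)
#' @export
dwell_time_for_dose <- function(dose_gy, unit_time_s_per_gy) {
  check_number(dose_gy, "dose_gy", min = 0)
  check_number(unit_time_s_per_gy, "unit_time_s_per_gy", min = 0,
               allow_zero = FALSE)
  dose_gy * unit_time_s_per_gy
}

#' Mean dose rate implied by a dose/dwell pair
#'
#' @param dose_gy Delivered dose (Gy).
#' @param dwell_s Dwell time (seconds), strictly positive.
#' @return Dose rate in Gy/min: `60 * dose_gy / dwell_s`.
#' @examples
#' dose_rate_from_dwell(1, 51.59) # the reference device: 1.163 Gy/min
#' @export
dose_rate_from_dwell <- function(dose_gy, dwell_s) {
  check_number(dose_gy, "dose_gy", min = 0)
  if (any(dwell_s <= 0)) abort("`dwell_s` must be > 0.")
  60 * dose_gy / dwell_s
}

#' Build a dwell-time schedule for per-column-group target doses
#'
#' The ARM exposes the plate one column group at a time; each group's
#' dwell is its target dose times the unit time. Column groups partition
#' the `n_cols` plate columns into `length(target_gy)` contiguous,
#' equal-width blocks.
#'
#' @param target_gy Non-negative target dose per column group, in plate
#'   order (e.g. `c(0, 2, 4, 8)` for the standard dose grid).
#' @param unit_time_s_per_gy Seconds per Gy from [fit_unit_time()].
#' @param n_cols Number of plate columns (default 24).
#' @return A `dose_schedule` tibble with columns `step`, `col_start`,
#'   `col_end`, `target_gy`, `dwell_s`; total exposure time is
#'   `sum(dwell_s)`.
#' @examples
#' build_schedule(c(0, 2, 4, 8), 51.49)
#' @export
build_schedule <- function(target_gy, unit_time_s_per_gy, n_cols = 24) {
  check_number(target_gy, "target_gy", min = 0)
  n_groups <- length(target_gy)
  if (n_groups < 1) abort("`target_gy` must contain at least one group.")
  if (n_cols %% n_groups != 0) {
    abort("`n_cols` must be divisible by the number of column groups.")
  }
  width <- n_cols / n_groups
  out <- tibble::tibble(
    step = seq_len(n_groups),
    col_start = (seq_len(n_groups) - 1L) * width + 1L,
    col_end = seq_len(n_groups) * width,
    target_gy = as.numeric(target_gy),
    dwell_s = as.numeric(target_gy) * unit_time_s_per_gy
  )
  structure(out, class = c("dose_schedule", class(out)))
}

#' Simulate dose delivery over a plate
#'
#' Executes a dwell schedule at a constant dose rate: an open well in a
#' step's column range receives `rate * dwell / 60 * (1 + eps)` Gy with
#' `eps ~ Normal(0, noise_sd)`; a shielded well additionally sees the
#' shield transmission factor. With `noise_sd = 0` the delivered map is
#' exactly the scheduled target map.
#'
#' @param schedule A [build_schedule()] result.
#' @param rate_gy_per_min Dose rate in the open slit (Gy/min), > 0.
#' @param n_rows Number of plate rows (default 16).
#' @param shield Optional logical matrix (`n_rows` x `n_cols`) marking
#'   shielded wells; `NULL` means fully open.
#' @param shield_transmission Fraction of dose reaching shielded wells.
#' @param noise_sd Fractional (relative) SD of multiplicative delivery
#'   noise; 0 for a deterministic map.
#' @param seed Optional integer seed for the noise draw.
#' @return A `dose_map` tibble with columns `row`, `col`, `dose_gy`
#'   covering the full plate grid.
#' @examples
#' sched <- build_schedule(c(0, 2, 4, 8), 51.49)
#' simulate_delivery(sched, rate_gy_per_min = 60 / 51.49)
#' @export
simulate_delivery <- function(schedule, rate_gy_per_min, n_rows = 16,
                              shield = NULL, shield_transmission = 1 / 6,
                              noise_sd = 0, seed = NULL) {
  if (rate_gy_per_min <= 0) abort("`rate_gy_per_min` must be > 0.")
  check_number(noise_sd, "noise_sd", min = 0)
  n_cols <- max(schedule$col_end)
  grid <- tidyr::expand_grid(row = seq_len(n_rows), col = seq_len(n_cols))
  dwell_per_col <- rep(NA_real_, n_cols)
  for (i in seq_len(nrow(schedule))) {
    cols <- schedule$col_start[i]:schedule$col_end[i]
    if (any(!is.na(dwell_per_col[cols]))) {
      abort("Schedule steps overlap: each well must be covered exactly once.")
    }
    dwell_per_col[cols] <- schedule$dwell_s[i]
  }
  if (anyNA(dwell_per_col)) abort("Schedule leaves some columns uncovered.")
  base <- rate_gy_per_min * dwell_per_col[grid$col] / 60
  eps <- with_seed_or_not(seed, rnorm(nrow(grid), 0, noise_sd))
  dose <- base * (1 + if (noise_sd > 0) eps else 0)
  if (!is.null(shield)) {
    if (!is.matrix(shield) || nrow(shield) != n_rows ||
        ncol(shield) != n_cols) {
      abort("`shield` must be an n_rows x n_cols logical matrix.")
    }
    shielded <- shield[cbind(grid$row, grid$col)]
    dose[shielded] <- dose[shielded] * shield_transmission
  }
  out <- tibble::tibble(grid, dose_gy = pmax(dose, 0))
  structure(out, class = c("dose_map", class(out)))
}

#' Delivery-quality statistics for repeated dose measurements
#'
#' Summarises reproducibility of ARM dose delivery: the mean dose rate,
#' the coefficient of variation of repeated measurements (sample SD,
#' n-1 denominator), and the R-squared of a simple linear regression of
#' delivered dose on dwell time.
#'
#' When every measurement shares one dwell time (a uniformity run), the
#' CV is taken over the raw doses and `r_squared` is `NA` (no dwell
#' spread to regress on). With several dwell groups the CV is taken over
#' the implied per-measurement rates `60 * dose / dwell`.
#'
#' @param measurements Data frame with columns `dose_gy` and `dwell_s`
#'   (one row per dosimeter reading), or a bare numeric vector of doses
#'   measured at a single common dwell time.
#' @param dwell_s Dwell time used when `measurements` is a bare vector.
#' @return A one-row tibble: `mean_rate_gy_per_min`, `cv_percent`,
#'   `r_squared`, `n`.
#' @examples
#' delivery_stats(c(1.16, 1.17, 1.16), dwell_s = 60)
#' @export
delivery_stats <- function(measurements, dwell_s = NULL) {
  if (is.numeric(measurements) && is.null(dim(measurements))) {
    if (is.null(dwell_s)) abort("Supply `dwell_s` for a bare dose vector.")
    measurements <- tibble::tibble(dose_gy = measurements, dwell_s = dwell_s)
  }
  if (nrow(measurements) < 2) abort("Need at least 2 measurements.")
  if (all(measurements$dose_gy == 0)) {
    abort("All measurements are zero; CV is undefined.")
  }
  rates <- dose_rate_from_dwell(measurements$dose_gy, measurements$dwell_s)
  single_dwell <- length(unique(measurements$dwell_s)) == 1
  cv_basis <- if (single_dwell) measurements$dose_gy else rates
  r2 <- if (single_dwell) {
    NA_real_ # no dwell spread to regress on
  } else {
    # simple linear regression R^2 = squared Pearson correlation
    stats::cor(measurements$dose_gy, measurements$dwell_s)^2
  }
  tibble::tibble(
    mean_rate_gy_per_min = mean(rates),
    cv_percent = 100 * sd(cv_basis) / mean(cv_basis),
    r_squared = r2,
    n = nrow(measurements)
  )
}
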