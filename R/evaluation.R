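#' ROC analysis by pairwise concordance
#'
#' `roc_auc()` computes the area under the empirical ROC curve as the
#' Mann-Whitney concordance probability: over all (positive, negative)
#' pairs, a pair scores 1 when the positive case has the higher score,
#' 0.5 on a tie, 0 otherwise. Tie half-credit matters: a binary
#' predictor such as HPV status only attains its published AUC with
#' ties counted at 0.5. The concordance equals the trapezoid area under
#' the empirical ROC curve.
#'
#' `roc_curve()` returns the operating points (one per distinct
#' threshold) with sensitivity and specificity.
#'
#' @param scores Numeric risk scores (higher = more likely positive).
#' @param labels Binary labels: 0/1 or `"yes"`/`"no"`.
#' @return `roc_auc()`: a `roc_result` list with `auc`, `n_pos`,
#'   `n_neg` and the operating-point tibble `points`.
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' @export
roc_auc <- function(scores, labels) {
  y <- code_recurrence(labels)
  check_same_length(scores, y, "scores", "labels")
  if (length(unique(y)) < 2) {
    abort("Both classes must be present to compute a ROC curve.")
  }
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  conc <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  structure(
    list(auc = mean(conc), n_pos = length(pos), n_neg = length(neg),
         points = roc_curve(scores, y)),
    class = "roc_result"
  )
}

#' @rdname roc_auc
#' @return `roc_curve()`: a tibble `threshold`, `sensitivity`,
#'   `specificity` including the degenerate all-positive and
#'   all-negative ends.
#' @export
roc_curve <- function(scores, labels) {
  y <- code_recurrence(labels)
  thresholds <- c(-Inf, sort(unique(scores)))
  purrr::map_dfr(thresholds, function(t) {
    tibble::tibble(threshold = t,
                   sensitivity = sensitivity_specificity(scores, y, t)[[1]],
                   specificity = sensitivity_specificity(scores, y, t)[[2]])
  })
}

#' Sensitivity and specificity at a cutoff
#'
#' A case is called positive (resistant) when its score is strictly
#' greater than the cutoff. Sensitivity is TP/(TP+FN) and specificity
#' TN/(TN+FP).
#'
#' @inheritParams roc_auc
#' @param cutoff Score cutoff.
#' @return A named list `sensitivity`, `specificity`.
#' @examples
#' sensitivity_specificity(c(1, 2, 3, 4), c(0, 0, 1, 1), 2.5)
#' @export
sensitivity_specificity <- function(scores, labels, cutoff) {
  y <- code_recurrence(labels)
  called <- scores > cutoff
  list(sensitivity = sum(called & y == 1) / sum(y == 1),
       specificity = sum(!called & y == 0) / sum(y == 0))
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d positive vs %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = 1 - .data$specificity,
                               y = .data$sensitivity)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("ROC AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier recurrence-free survival
#'
#' Product-limit estimator per group: at each distinct event time the
#' survival drops by the factor `1 - d/n` (events over numbers at
#' risk); censored subjects leave the risk set after their time.
#' Survival starts at 1 and is non-increasing.
#'
#' @param time Follow-up times in days (>= 0).
#' @param event Event indicator: 1/TRUE = recurrence observed, 0/FALSE
#'   = censored.
#' @param group Optional group labels (one curve per group).
#' @return A `km_curve` tibble: `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival` (one row per distinct observed time).
#' @examples
#' km_estimate(c(131, 273, 316, 400, 400), c(1, 1, 1, 0, 0))
#' @export
km_estimate <- function(time, event, group = NULL) {
  check_number(time, "time", min = 0)
  ev <- as.integer(event)
  if (!all(ev %in% c(0, 1))) abort("`event` must be 0/1.")
  check_same_length(time, ev, "time", "event")
  if (is.null(group)) group <- rep("all", length(time))
  df <- tibble::tibble(time = time, event = ev, group = as.character(group))
  out <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(g, key) {
      tab <- g |>
        dplyr::summarise(n_event = sum(.data$event),
                         n_censor = sum(1 - .data$event),
                         .by = "time") |>
        dplyr::arrange(.data$time)
      n <- nrow(g)
      at_risk <- n - dplyr::lag(cumsum(tab$n_event + tab$n_censor),
                                default = 0)
      surv <- cumprod(1 - tab$n_event / at_risk)
      tibble::tibble(time = tab$time, n_risk = at_risk,
                     n_event = tab$n_event, n_censor = tab$n_censor,
                     survival = surv)
    }) |>
    dplyr::ungroup()
  structure(out, class = c("km_curve", class(out)))
}

#' Survival probability at a landmark time
#'
#' Reads the product-limit estimate at `at` days (by convention the
#' step function is right-continuous: an event at exactly `at` counts).
#' `at = 365` gives the 1-year recurrence-free survival.
#'
#' @param km A `km_curve` from [km_estimate()].
#' @param at Landmark time in days.
#' @return A tibble `group`, `survival`.
#' @examples
#' km_survival_at(km_estimate(c(131, 273, 316, 400, 400),
#'                            c(1, 1, 1, 0, 0)), 365)
#' @export
km_survival_at <- function(km, at = 365) {
  km |>
    dplyr::summarise(
      survival = if (any(.data$time <= at)) {
        .data$survival[max(which(.data$time <= at))]
      } else {
        1
      },
      .by = "group"
    )
}

#' @export
autoplot.km_curve <- function(object, ...) {
  start <- object |>
    dplyr::distinct(.data$group) |>
    dplyr::mutate(time = 0, survival = 1)
  steps <- dplyr::bind_rows(start,
                            dplyr::select(object, "group", "time",
                                          "survival"))
  ggplot2::ggplot(steps, ggplot2::aes(x = .data$time, y = .data$survival,
                                      colour = .data$group)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Days", y = "Recurrence-free survival",
                  colour = "Group") +
    ggplot2::theme_minimal()
}

#' Two-group log-rank test
#'
#' Standard (asymptotic, 1 d.f.) log-rank test: at each distinct event
#' time, the observed events in group 1 are compared with their
#' hypergeometric expectation given the pooled risk set; the chi-square
#' statistic is the squared standardised difference and the p-value
#' comes from the chi-square distribution.
#'
#' @inheritParams km_estimate
#' @param group Two-level group labels.
#' @return A tibble `chi_square`, `p_value`, `n_1`, `n_2`,
#'   `observed_1`, `expected_1`.
#' @examples
#' log_rank(c(10, 12, 15, 900, 950, 990), c(1, 1, 1, 0, 0, 0),
#'          rep(c("a", "b"), each = 3))
#' @export
log_rank <- function(time, event, group) {
  check_number(time, "time", min = 0)
  ev <- as.integer(event)
  grp <- as.character(group)
  levels <- sort(unique(grp))
  if (length(levels) != 2) abort("`group` must have exactly two levels.")
  if (any(table(grp) == 0)) abort("Both groups must be non-empty.")
  g1 <- grp == levels[1]
  event_times <- sort(unique(time[ev == 1]))
  o_minus_e <- 0
  v <- 0
  observed1 <- 0
  expected1 <- 0
  for (t in event_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(ev == 1 & time == t)
    d1 <- sum(ev == 1 & time == t & g1)
    e1 <- d * n1 / n
    observed1 <- observed1 + d1
    expected1 <- expected1 + e1
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  chi <- if (v > 0) o_minus_e^2 / v else 0
  tibble::tibble(chi_square = chi,
                 p_value = pchisq(chi, df = 1, lower.tail = FALSE),
                 n_1 = sum(g1), n_2 = sum(!g1),
                 observed_1 = observed1, expected_1 = expected1)
}

#' Evaluate an index against recurrence and survival outcomes
#'
#' One-call validation of a risk score on a followed-up cohort: ROC AUC
#' against the 1-year recurrence label, sensitivity/specificity at the
#' cutoff, Kaplan-Meier 1-year recurrence-free survival for the
#' sensitive vs resistant groups, and the log-rank comparison. Times
#' are administratively truncated at the horizon so late recurrences
#' count as recurrence-free at one year.
#'
#' @param data Cohort with score and outcome columns.
#' @param score Name of the score column (default `"index"`).
#' @param cutoff Score cutoff defining the resistant group.
#' @param horizon_days Landmark horizon (default 365).
#' @return A list: `roc` (a `roc_result`), `sensitivity`,
#'   `specificity`, `km` (a `km_curve` by predicted group),
#'   `rfs_at_horizon` tibble, and `log_rank` tibble.
#' @examples
#' cohort <- dplyr::filter(hnscc_cohort(), set == "test")
#' ref <- freeze_reference(cohort)
#' scored <- score_cohort(apply_zscores(cohort, ref))
#' evaluate_cohort(scored)
#' @export
evaluate_cohort <- function(data, score = "index", cutoff = 0,
                            horizon_days = 365) {
  y <- code_recurrence(data$recur)
  s <- data[[score]]
  roc <- roc_auc(s, y)
  ss <- sensitivity_specificity(s, y, cutoff)
  grp <- ifelse(s > cutoff, "resistant", "sensitive")
  time <- pmin(data$rfs_days, horizon_days)
  event <- as.integer(y == 1 & data$rfs_days <= horizon_days)
  km <- km_estimate(time, event, grp)
  list(
    roc = roc,
    sensitivity = ss$sensitivity,
    specificity = ss$specificity,
    km = km,
    rfs_at_horizon = km_survival_at(km, horizon_days),
    log_rank = if (length(unique(grp)) == 2) {
      log_rank(time, event, grp)
    } else {
      NULL
    }
  )
}
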