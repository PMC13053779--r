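test_that("ROC AUC is the tie-aware pairwise concordance", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(2, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "Both classes")
  # half-credit ties: a binary score with 3/1 split of positives
  r <- roc_auc(c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0),
               c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(r$auc, 31 / 40)
})

test_that("single-feature ROC AUCs on the reference cohort are exact", {
  scored <- scored_test_set()
  y <- scored$recur
  expect_equal(roc_auc(scored$z_auc, y)$auc, 26 / 40)
  expect_equal(roc_auc(scored$z_growth, y)$auc, 25 / 40)
  # HPV-negative is the risk-increasing direction
  expect_equal(roc_auc(-scored$z_hpv, y)$auc, 31 / 40)
})

test_that("ROC AUC is invariant under monotone transforms and reverses", {
  set.seed(7)
  for (i in 1:10) {
    s <- rnorm(30)
    y <- rbinom(30, 1, 0.4)
    if (length(unique(y)) < 2) next
    a <- roc_auc(s, y)$auc
    expect_equal(roc_auc(as.numeric(scale(s)), y)$auc, a)
    expect_equal(roc_auc(rank(s), y)$auc, a)
    expect_equal(roc_auc(exp(s), y)$auc, a)
    expect_equal(roc_auc(-s, y)$auc, 1 - a)
  }
})

test_that("concordance AUC equals the trapezoid area under the ROC curve", {
  set.seed(21)
  for (i in 1:5) {
    s <- round(rnorm(40), 1) # rounding forces ties
    y <- rbinom(40, 1, 0.3)
    if (length(unique(y)) < 2) next
    r <- roc_auc(s, y)
    pts <- r$points[order(1 - r$points$specificity, r$points$sensitivity), ]
    x <- 1 - pts$specificity
    trap <- sum(diff(x) * (head(pts$sensitivity, -1) +
                             pts$sensitivity[-1]) / 2)
    expect_equal(r$auc, trap, tolerance = 1e-12)
  }
})

test_that("sensitivity and specificity count calls above the cutoff", {
  expect_equal(sensitivity_specificity(c(1, 2, 3, 4), c(0, 0, 1, 1), 2.5),
               list(sensitivity = 1, specificity = 1))
  expect_equal(sensitivity_specificity(c(1, 2, 3, 4), c(0, 0, 1, 1), 0),
               list(sensitivity = 1, specificity = 0))
  expect_equal(sensitivity_specificity(c(1, 2, 3, 4), c(0, 0, 1, 1), 9),
               list(sensitivity = 0, specificity = 1))
})

test_that("the product-limit estimator handles canonical cases", {
  # no events: survival stays at 1
  km0 <- km_estimate(c(100, 200, 300), c(0, 0, 0))
  expect_true(all(km0$survival == 1))
  # 3 events among 5 with late censoring: S(365) = 4/5 * 3/4 * 2/3 = 0.4
  km <- km_estimate(c(131, 273, 316, 400, 400), c(1, 1, 1, 0, 0))
  expect_equal(km_survival_at(km, 365)$survival, 0.4)
  # single subject: step to zero at the event time
  km1 <- km_estimate(100, 1)
  expect_equal(km_survival_at(km1, 99)$survival, 1)
  expect_equal(km_survival_at(km1, 100)$survival, 0)
  expect_error(km_estimate(-1, 1), "time")
})

test_that("without censoring the estimator is the empirical survival", {
  set.seed(5)
  times <- sample(1:50, 20, replace = TRUE)
  km <- km_estimate(times, rep(1, 20))
  for (t in c(0, 10, 25, 50)) {
    expect_equal(km_survival_at(km, t)$survival, mean(times > t))
  }
})

test_that("log-rank is null on duplicated groups, extreme on separation", {
  times <- c(131, 273, 316, 400, 400)
  events <- c(1, 1, 1, 0, 0)
  dup <- log_rank(rep(times, 2), rep(events, 2),
                  rep(c("a", "b"), each = 5))
  expect_equal(dup$chi_square, 0, tolerance = 1e-12)
  expect_equal(dup$p_value, 1)
  sep <- log_rank(c(rep(10, 20), rep(1000, 20)),
                  c(rep(1, 20), rep(0, 20)),
                  rep(c("a", "b"), each = 20))
  expect_lt(sep$p_value, 0.001)
  expect_error(log_rank(1:3, c(1, 1, 1), c("a", "a", "a")), "two levels")
})

test_that("KM and log-rank agree with the survival package", {
  set.seed(2024)
  for (i in 1:100) {
    n <- sample(10:40, 1)
    times <- round(stats::rexp(n, 1 / 300), 1) + 1
    events <- rbinom(n, 1, 0.7)
    group <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(group)) < 2 || sum(events) == 0) next
    km <- km_estimate(times, events)
    sf <- survival::survfit(survival::Surv(times, events) ~ 1)
    expect_equal(km$survival[km$n_event > 0],
                 summary(sf, times = km$time[km$n_event > 0])$surv,
                 tolerance = 1e-10)
    lr <- log_rank(times, events, group)
    sd_ref <- survival::survdiff(survival::Surv(times, events) ~ group)
    expect_equal(lr$chi_square, sd_ref$chisq, tolerance = 1e-10)
    expect_equal(lr$p_value,
                 pchisq(sd_ref$chisq, 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("concordance ROC agrees with pROC on tied and untied scores", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(12:40, 1)
    s <- round(rnorm(n), sample(0:2, 1)) # varying tie density
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    a <- roc_auc(s, y)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(a, ref, tolerance = 1e-10)
  }
})

test_that("evaluate_cohort reports the full validation summary", {
  scored <- score_cohort(scored_test_set(),
                         published_model("three_parameter"))
  ev <- evaluate_cohort(scored)
  expect_equal(ev$roc$auc, 0.9)
  expect_named(ev$rfs_at_horizon, c("group", "survival"))
  expect_true(all(ev$rfs_at_horizon$survival >= 0 &
                    ev$rfs_at_horizon$survival <= 1))
  expect_true(ev$log_rank$p_value >= 0 && ev$log_rank$p_value <= 1)
  expect_s3_class(autoplot(ev$roc), "ggplot")
  expect_s3_class(autoplot(ev$km), "ggplot")
})

test_that("the top-five published-model grouping reproduces the RFS split", {
  scored <- scored_test_set()
  lp <- linear_predictor(published_model("two_parameter"), scored)
  top5 <- rank(-lp) <= 5
  time <- pmin(scored$rfs_days, 365)
  event <- as.integer(scored$recur == "yes" & scored$rfs_days <= 365)
  km <- km_estimate(time, event, ifelse(top5, "resistant", "sensitive"))
  rfs <- km_survival_at(km, 365)
  expect_equal(rfs$survival[rfs$group == "resistant"], 0.4)
  expect_equal(rfs$survival[rfs$group == "sensitive"], 8 / 9)
  lr <- log_rank(time, event, top5)
  expect_lt(lr$p_value, 0.05)
  expect_equal(lr$chi_square, 3.967, tolerance = 1e-3)
})
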