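#' The published OncoSensi models
#'
#' Coefficients of the published recurrence-prediction logistic models
#' over standardised features, treated as fixed models whose downstream
#' scores are validated (this package does not claim to re-derive the
#' printed coefficients from the 14-patient cohort):
#'
#' * `"two_parameter"`: intercept -1.313, growth 1.324, AUC 1.406.
#' * `"three_parameter"`: intercept -1.739, growth 2.483, AUC 2.411,
#'   HPV -0.5239 (HPV positivity is protective, hence the negative
#'   sign).
#'
#' @param type Which published model.
#' @return An `oncosensi_model` object.
#' @examples
#' published_model("three_parameter")
#' @export
published_model <- function(type = c("two_parameter", "three_parameter")) {
  type <- match.arg(type)
  coefs <- switch(type,
    two_parameter = c(`(Intercept)` = -1.313, z_growth = 1.324,
                      z_auc = 1.406),
    three_parameter = c(`(Intercept)` = -1.739, z_growth = 2.483,
                        z_auc = 2.411, z_hpv = -0.5239)
  )
  new_oncosensi_model(coefs, method = "published", converged = NA,
                      iterations = 0L, ridge = 0, n = NA_integer_,
                      deviance = NA_real_)
}

#' Construct an OncoSensi model from known coefficients
#'
#' Useful for scoring with externally specified coefficients or as the
#' true model of a simulation.
#'
#' @param intercept Model intercept.
#' @param z_growth,z_auc Slopes on the standardised growth and RT-AUC
#'   features.
#' @param z_hpv Optional slope on the standardised HPV feature.
#' @return An `oncosensi_model`.
#' @examples
#' oncosensi_model(-1.3, 1.3, 1.4)
#' @export
oncosensi_model <- function(intercept, z_growth, z_auc, z_hpv = NULL) {
  coefs <- c(`(Intercept)` = intercept, z_growth = z_growth, z_auc = z_auc)
  if (!is.null(z_hpv)) coefs <- c(coefs, z_hpv = z_hpv)
  if (!all(is.finite(coefs))) abort("Coefficients must be finite.")
  new_oncosensi_model(coefs, method = "fixed", converged = NA,
                      iterations = 0L, ridge = 0, n = NA_integer_,
                      deviance = NA_real_)
}

new_oncosensi_model <- function(coefficients, method, converged, iterations,
                                ridge, n, deviance) {
  structure(
    list(coefficients = coefficients, features = names(coefficients)[-1],
         method = method, converged = converged, iterations = iterations,
         ridge = ridge, n = n, deviance = deviance),
    class = "oncosensi_model"
  )
}

#' Fit an OncoSensi recurrence model
#'
#' Fits a (optionally ridge-penalised) logistic regression of 1-year
#' recurrence on standardised cohort features by iteratively reweighted
#' least squares (IRLS), or an ordinary-least-squares linear fit of the
#' 0/1 labels for comparison. Features should already be Z-scored (see
#' [apply_zscores()]); feature order follows the published convention
#' (growth first, then AUC, then HPV).
#'
#' With few events, maximum likelihood can diverge under complete
#' separation; the fitter detects non-convergence or exploding
#' coefficients and warns, suggesting a small ridge penalty
#' (`ridge = 0.5`) which keeps the estimates finite.
#'
#' @param data Data frame containing the feature columns and the label.
#' @param features Feature column names, in order.
#' @param label Label column: 0/1 or `"yes"`/`"no"` recurrence.
#' @param ridge Ridge penalty `lambda` (>= 0) on the slopes (the
#'   intercept is never penalised); 0 for plain maximum likelihood.
#' @param method `"logistic"` (default) or `"ols"`.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on
#'   the coefficient change.
#' @return An `oncosensi_model`; inspect with [tidy()] / [glance()].
#' @examples
#' cohort <- apply_zscores(
#'   dplyr::filter(hnscc_cohort(), set == "test"),
#'   freeze_reference(dplyr::filter(hnscc_cohort(), set == "test"))
#' )
#' fit_oncosensi(cohort, ridge = 0.5)
#' @export
fit_oncosensi <- function(data, features = c("z_growth", "z_auc"),
                          label = "recur", ridge = 0,
                          method = c("logistic", "ols"),
                          max_iter = 100, tol = 1e-10) {
  method <- match.arg(method)
  y <- code_recurrence(data[[label]])
  x <- as.matrix(data[features])
  keep <- stats::complete.cases(x) & !is.na(y)
  if (!all(keep)) {
    warn(sprintf("Dropping %d record(s) with missing features.", sum(!keep)))
    x <- x[keep, , drop = FALSE]
    y <- y[keep]
  }
  if (length(unique(y)) < 2) abort("Both label classes must be present.")
  if (nrow(x) < ncol(x) + 2) abort("Too few records to fit the model.")
  check_number(ridge, "ridge", min = 0)
  xmat <- cbind(`(Intercept)` = 1, x)

  if (method == "ols") {
    fit <- lm.fit(xmat, y)
    coefs <- fit$coefficients
    return(new_oncosensi_model(coefs, method = "ols", converged = TRUE,
                               iterations = 1L, ridge = 0, n = length(y),
                               deviance = sum(fit$residuals^2)))
  }

  # IRLS for penalised logistic regression; intercept unpenalised
  p <- ncol(xmat)
  pen <- diag(c(0, rep(ridge, p - 1)), p)
  beta <- numeric(p)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(xmat %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    xtw <- t(xmat * w)
    beta_new <- tryCatch(
      drop(solve(xtw %*% xmat + pen, xtw %*% z)),
      error = function(e) abort("IRLS normal equations are singular.")
    )
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged || max(abs(beta)) > 50) {
    warn(paste0(
      "Logistic fit did not stabilise (possible complete separation ",
      "with so few events); consider refitting with `ridge = 0.5`."
    ))
  }
  eta <- drop(xmat %*% beta)
  dev <- -2 * sum(y * plogis(eta, log.p = TRUE) +
                    (1 - y) * plogis(-eta, log.p = TRUE))
  names(beta) <- colnames(xmat)
  new_oncosensi_model(beta, method = "logistic", converged = converged,
                      iterations = iter, ridge = ridge, n = length(y),
                      deviance = dev)
}

#' Linear predictor of an OncoSensi model
#'
#' `beta0 + sum(beta_i * Z_i)` over the model's features.
#'
#' @param model An `oncosensi_model`.
#' @param data Data frame carrying the model's feature columns (e.g.
#'   from [apply_zscores()]).
#' @return Numeric linear predictor per row.
#' @examples
#' linear_predictor(published_model("two_parameter"),
#'                  data.frame(z_growth = 0, z_auc = 0)) # the intercept
#' @export
linear_predictor <- function(model, data) {
  missing_cols <- setdiff(model$features, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Data lacks model feature column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- as.matrix(data[model$features])
  if (anyNA(x)) abort("Missing feature values; cannot compute predictor.")
  drop(cbind(1, x) %*% model$coefficients)
}

#' OncoSensi index: Z-scored linear predictor
#'
#' Standardises the linear predictors over the scored cohort (or
#' against frozen statistics from a reference cohort), giving the
#' dimensionless OncoSensi index: higher means predicted
#' radiation-resistant. The index is invariant to any positive affine
#' rescaling of the linear predictor, so it depends only on the ranking
#' and relative spacing of patients.
#'
#' @param lp Numeric linear predictors (length >= 2, non-constant), or
#'   any score to standardise.
#' @param reference Optional two-element list/vector with `mean` and
#'   `sd` frozen from a reference cohort; default standardises within
#'   `lp` itself.
#' @return Z-scored index, same length as `lp`.
#' @examples
#' oncosensi_index(c(-1, 1))
#' @export
oncosensi_index <- function(lp, reference = NULL) {
  if (is.null(reference)) {
    if (length(lp) < 2) abort("Need >= 2 predictors to standardise.")
    s <- sd(lp)
    if (s == 0) abort("Linear predictors are constant; index undefined.")
    (lp - mean(lp)) / s
  } else {
    (lp - reference[["mean"]]) / reference[["sd"]]
  }
}

#' Score a cohort with an OncoSensi model
#'
#' Convenience wrapper: computes linear predictors, the Z-scored
#' OncoSensi index over the cohort, and the sensitive/resistant call at
#' a cutoff.
#'
#' @param data Cohort with standardised feature columns.
#' @param model An `oncosensi_model` (default: the published
#'   two-parameter model).
#' @param cutoff Index cutoff for [classify_index()].
#' @return `data` with `lp`, `index` and `label` columns appended.
#' @examples
#' cohort <- hnscc_cohort()
#' ref <- freeze_reference(dplyr::filter(cohort, set == "test"))
#' score_cohort(apply_zscores(dplyr::filter(cohort, set == "test"), ref))
#' @export
score_cohort <- function(data, model = published_model("two_parameter"),
                         cutoff = 0) {
  out <- tibble::as_tibble(data)
  out$lp <- linear_predictor(model, out)
  out$index <- oncosensi_index(out$lp)
  out$label <- classify_index(out$index, cutoff)
  out
}

#' Classify patients from the OncoSensi index
#'
#' `classify_index()` calls a patient radiation-resistant when the
#' index exceeds the cutoff (ties go to sensitive). The default cutoff
#' of 0 is the scored cohort's mean; the published work does not state
#' its cutoff, so it is configurable.
#'
#' `classify_quadrant()` is the two-axis variant: both standardised AUC
#' and growth positive is *strongly resistant*, both negative *strongly
#' sensitive*, and the mixed quadrants *moderately resistant*.
#'
#' @param index Numeric OncoSensi index.
#' @param cutoff Finite classification cutoff (default 0).
#' @return `classify_index()`: character vector of
#'   `"sensitive"`/`"resistant"`.
#' @examples
#' classify_index(c(-0.5, 0, 0.7))
#' classify_quadrant(c(1, -1), c(1, -1))
#' @export
classify_index <- function(index, cutoff = 0) {
  if (!is.finite(cutoff)) abort("`cutoff` must be finite.")
  ifelse(index > cutoff, "resistant", "sensitive")
}

#' @rdname classify_index
#' @param z_auc,z_growth Standardised RT-AUC and growth values.
#' @return `classify_quadrant()`: character vector of
#'   `"strongly resistant"`, `"moderately resistant"` or
#'   `"strongly sensitive"`.
#' @export
classify_quadrant <- function(z_auc, z_growth) {
  check_same_length(z_auc, z_growth, "z_auc", "z_growth")
  dplyr::case_when(
    z_auc > 0 & z_growth > 0 ~ "strongly resistant",
    z_auc <= 0 & z_growth <= 0 ~ "strongly sensitive",
    .default = "moderately resistant"
  )
}

#' @export
print.oncosensi_model <- function(x, ...) {
  cat("<oncosensi_model>", x$method,
      if (isTRUE(x$converged)) "(converged)" else "", "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.oncosensi_model <- function(object, ...) object$coefficients

#' @export
predict.oncosensi_model <- function(object, newdata,
                                    type = c("link", "response"), ...) {
  type <- match.arg(type)
  lp <- linear_predictor(object, newdata)
  if (type == "response") plogis(lp) else lp
}

#' @export
tidy.oncosensi_model <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @export
glance.oncosensi_model <- function(x, ...) {
  tibble::tibble(method = x$method, n = x$n, deviance = x$deviance,
                 ridge = x$ridge, iterations = x$iterations,
                 converged = x$converged)
}
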