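#' Freeze reference standardisation statistics on a test cohort
#'
#' Computes, per feature, the mean and sample standard deviation (n-1)
#' on the transformed scale, to be frozen and reused: validation cohorts
#' are standardised against the reference (test-set) statistics, never
#' refit. The default transforms — RT-AUC on the raw scale, growth rate
#' on the natural-log scale, HPV as a standardised 0/1 indicator — are
#' the unique combination that reproduces the published Z-score columns
#' of the bundled reference cohort.
#'
#' @param cohort Cohort data frame (typically the test-set rows), with
#'   `rt_auc`, `growth_rate` and optionally `hpv` columns.
#' @param features Named character vector mapping feature columns to
#'   transforms (`"identity"` or `"log"`).
#' @param include_hpv Add a standardised HPV 0/1 feature (rows with
#'   missing HPV status are dropped from that feature's statistics,
#'   with a warning).
#' @return A `cohort_ref` tibble: `feature`, `transform`, `mean`, `sd`,
#'   `n`.
#' @examples
#' ref <- freeze_reference(dplyr::filter(hnscc_cohort(), set == "test"))
#' ref
#' @export
freeze_reference <- function(cohort,
                             features = c(rt_auc = "identity",
                                          growth_rate = "log"),
                             include_hpv = TRUE) {
  if (nrow(cohort) < 2) abort("Need at least 2 reference records.")
  work <- tibble::as_tibble(cohort)
  if (include_hpv && "hpv" %in% names(work)) {
    work$hpv01 <- code_hpv(work$hpv)
    features <- c(features, hpv = "identity")
  }
  rows <- purrr::imap(features, function(transform, feature) {
    col <- if (feature == "hpv") "hpv01" else feature
    x <- work[[col]]
    if (is.null(x)) abort(sprintf("Cohort has no `%s` column.", feature))
    if (anyNA(x)) {
      warn(sprintf("Dropping %d record(s) with missing `%s`.",
                   sum(is.na(x)), feature))
      x <- x[!is.na(x)]
    }
    x <- apply_transform(x, transform, feature)
    s <- sd(x)
    if (s == 0) {
      abort(sprintf("Feature `%s` is constant in the reference cohort; ",
                    feature) |> paste0("its Z-score is undefined."))
    }
    tibble::tibble(feature = feature, transform = transform,
                   mean = mean(x), sd = s, n = length(x))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("cohort_ref", class(out)))
}

apply_transform <- function(x, transform, feature) {
  switch(transform,
    identity = x,
    log = {
      if (any(x <= 0)) {
        abort(sprintf("`%s` must be positive for the log transform.", feature))
      }
      log(x)
    },
    abort(sprintf("Unknown transform '%s'.", transform))
  )
}

#' Z-score values against frozen reference statistics
#'
#' `(transform(value) - mean) / sd` using the statistics frozen by
#' [freeze_reference()]. By construction the reference cohort itself
#' scores to mean 0 and sample SD 1.
#'
#' @param value Numeric vector on the raw feature scale.
#' @param ref A `cohort_ref` from [freeze_reference()].
#' @param feature Feature name within `ref` (e.g. `"rt_auc"`).
#' @return Dimensionless Z-scores.
#' @examples
#' ref <- freeze_reference(dplyr::filter(hnscc_cohort(), set == "test"))
#' zscore(691.1, ref, "rt_auc")
#' @export
zscore <- function(value, ref, feature) {
  row <- ref[ref$feature == feature, ]
  if (nrow(row) != 1) {
    abort(sprintf("Feature '%s' is not in the frozen reference.", feature))
  }
  (apply_transform(value, row$transform, feature) - row$mean) / row$sd
}

#' Attach standardised feature columns to a cohort
#'
#' Adds `z_auc`, `z_growth` and (when HPV is in the reference) `z_hpv`
#' columns, always computed against the *frozen* reference statistics.
#' Use on validation cohorts to score them against the test set; the
#' operation never refits, so it is idempotent and independent of the
#' validation set's composition.
#'
#' @param cohort Cohort data frame with raw feature columns.
#' @param ref A `cohort_ref` from [freeze_reference()].
#' @return `cohort` with standardised columns appended.
#' @examples
#' cohort <- hnscc_cohort()
#' ref <- freeze_reference(dplyr::filter(cohort, set == "test"))
#' apply_zscores(cohort, ref)
#' @export
apply_zscores <- function(cohort, ref) {
  out <- tibble::as_tibble(cohort)
  out$z_auc <- zscore(out$rt_auc, ref, "rt_auc")
  out$z_growth <- zscore(out$growth_rate, ref, "growth_rate")
  if ("hpv" %in% ref$feature && "hpv" %in% names(out)) {
    out$z_hpv <- zscore(code_hpv(out$hpv), ref, "hpv")
  }
  out
}

#' Code HPV status as 0/1
#'
#' HPV-positive is coded 1 and HPV-negative 0; missing status stays
#' `NA` (such records are excluded from HPV-bearing models).
#'
#' @param status Character vector of `"positive"`/`"negative"` (case
#'   insensitive), or an already-numeric 0/1 vector.
#' @return Numeric 0/1/NA vector.
#' @examples
#' code_hpv(c("positive", "negative", NA))
#' @export
code_hpv <- function(status) {
  if (is.numeric(status)) {
    if (!all(status %in% c(0, 1) | is.na(status))) {
      abort("Numeric HPV status must be 0/1.")
    }
    return(as.numeric(status))
  }
  s <- tolower(status)
  bad <- !is.na(s) & !s %in% c("positive", "negative")
  if (any(bad)) abort("HPV status must be 'positive', 'negative' or NA.")
  ifelse(is.na(s), NA_real_, as.numeric(s == "positive"))
}

#' Serialise frozen reference statistics to JSON
#'
#' @param ref A `cohort_ref`.
#' @param path JSON file path.
#' @return `write_reference()` returns `path` invisibly;
#'   `read_reference()` returns a `cohort_ref`.
#' @export
write_reference <- function(ref, path) {
  payload <- purrr::map(split(ref, ref$feature), function(r) {
    list(transform = r$transform, mean = r$mean, sd = r$sd, n = r$n)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- purrr::imap_dfr(payload, function(r, feature) {
    tibble::tibble(feature = feature, transform = r$transform,
                   mean = r$mean, sd = r$sd, n = as.integer(r$n))
  })
  structure(out, class = c("cohort_ref", class(out)))
}

#' @export
tidy.cohort_ref <- function(x, ...) {
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}
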