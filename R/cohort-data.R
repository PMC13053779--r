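#' Reference HNSCC organoid screening cohort
#'
#' The bundled cohort of 20 head and neck squamous cell carcinoma patients
#' whose tumours were screened for radiosensitivity as patient-derived
#' organoids: a 14-patient *test set* with one year of post-radiotherapy
#' follow-up, and a 6-patient *negative validation set* of patients whose
#' recurrent tumours were sampled after recurrence had already occurred
#' (all `recur == "yes"`, no recurrence-free-survival time).
#'
#' Columns `z_auc_printed`, `z_growth_printed` and `oncosensi_printed` are
#' the Z-score and index values as originally published. They are kept as
#' reference annotations only: every function in this package recomputes
#' standardised features from the raw `rt_auc` and `growth_rate` columns
#' and never reads the annotation columns.
#'
#' @param annotations If `TRUE` (default), include the published Z-score and
#'   index columns as reference annotations.
#'
#' @return A tibble with one row per patient and columns
#'   `set` (`"test"` or `"validation"`), `patient_id`, `primary_site`,
#'   `tnm`, `hpv` (`"positive"`, `"negative"` or `NA`), `recur`
#'   (`"yes"`/`"no"`), `rfs_days`, `rt_auc` (percent-Gy, 0-800),
#'   `growth_rate` (percent, day-5 area relative to day 1), plus the
#'   annotation columns unless dropped.
#'
#' @examples
#' hnscc_cohort()
#' dplyr::count(hnscc_cohort(), set, recur)
#' @export
hnscc_cohort <- function(annotations = TRUE) {
  path <- system.file("extdata", "hnscc_cohort.csv", package = "oncosensi",
                      mustWork = TRUE)
  cohort <- read_cohort(path)
  if (!annotations) {
    cohort <- dplyr::select(cohort, -dplyr::ends_with("_printed"))
  }
  cohort
}

cohort_col_types <- function() {
  readr::cols(
    set = readr::col_character(),
    patient_id = readr::col_integer(),
    hpv = readr::col_character(),
    recur = readr::col_character(),
    rfs_days = readr::col_double(),
    rt_auc = readr::col_double(),
    growth_rate = readr::col_double(),
    .default = readr::col_guess()
  )
}

#' Read or write a cohort table
#'
#' Cohort CSVs carry one row per patient with the schema
#' `patient_id,set,primary_site,tnm,hpv,recur,rfs_days,rt_auc,growth_rate`
#' (`set` in `test`/`validation`, `hpv` in `positive`/`negative`/`NA`,
#' `recur` in `yes`/`no`). Extra columns are preserved.
#'
#' @param path File path of a cohort CSV.
#' @param cohort A cohort data frame.
#' @return `read_cohort()` returns a validated tibble; `write_cohort()`
#'   returns `path` invisibly.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' write_cohort(hnscc_cohort(), tmp)
#' read_cohort(tmp)
#' @export
read_cohort <- function(path) {
  cohort <- readr::read_csv(path, col_types = cohort_col_types(),
                            na = c("", "NA"), progress = FALSE)
  validate_cohort(cohort)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  readr::write_csv(cohort, path, na = "NA")
  invisible(path)
}

validate_cohort <- function(cohort) {
  required <- c("patient_id", "set", "hpv", "recur", "rt_auc", "growth_rate")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0("Cohort table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!all(cohort$set %in% c("test", "validation"))) {
    abort("`set` must be 'test' or 'validation'.")
  }
  if (!all(cohort$recur %in% c("yes", "no"))) {
    abort("`recur` must be 'yes' or 'no'.")
  }
  if (!all(is.na(cohort$hpv) | cohort$hpv %in% c("positive", "negative"))) {
    abort("`hpv` must be 'positive', 'negative' or NA.")
  }
  check_number(cohort$rt_auc, "rt_auc", min = 0)
  tibble::as_tibble(cohort)
}

#' Numeric recurrence indicator
#'
#' @param recur Character vector of `"yes"`/`"no"` (or an already-numeric
#'   0/1 vector, returned unchanged).
#' @return Integer vector with 1 for recurrence and 0 otherwise.
#' @examples
#' code_recurrence(c("yes", "no"))
#' @export
code_recurrence <- function(recur) {
  if (is.numeric(recur)) {
    if (!all(recur %in% c(0, 1))) abort("Numeric `recur` must be 0/1.")
    return(as.integer(recur))
  }
  if (!all(recur %in% c("yes", "no"))) abort("`recur` must be 'yes' or 'no'.")
  as.integer(recur == "yes")
}
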