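#' Assemble a pipeline configuration
#'
#' A single configuration object (optionally loaded from YAML or JSON)
#' drives [run_pipeline()]. All randomness in a run flows from the one
#' `seed`, so every artifact is re-derivable from config + seed.
#'
#' @param cohort Path to a cohort CSV, `"bundled"` for the packaged
#'   reference cohort, or `"synthetic"` to generate one with
#'   [simulate_cohort()].
#' @param synthetic Named list of [simulate_cohort()] arguments used
#'   when `cohort = "synthetic"`.
#' @param images `NULL` to skip the image stages, or a named list of
#'   plate-simulation settings: `n_plates`, `targets_gy`, and optional
#'   overrides for [plate_spec()] (`spec`) and [survival_params()]
#'   (`survival`, recycled or one per plate).
#' @param model `"eq1"` (published two-parameter), `"eq2_hpv"`
#'   (published three-parameter) or `"refit"` (fit on the test set with
#'   `ridge`).
#' @param ridge Ridge penalty used when `model = "refit"`.
#' @param cutoff Index cutoff for classification.
#' @param horizon_days Landmark horizon for RFS.
#' @param threshold Intensity threshold for area quantification.
#' @param seed Integer seed.
#' @param output_dir Directory for per-stage artifacts; `NULL` for none.
#' @return A `pipeline_config` list.
#' @examples
#' pipeline_config(model = "eq2_hpv")
#' @export
pipeline_config <- function(cohort = "bundled", synthetic = list(),
                            images = NULL,
                            model = c("eq1", "eq2_hpv", "refit"),
                            ridge = 0.5, cutoff = 0, horizon_days = 365,
                            threshold = 20, seed = 1, output_dir = NULL) {
  model <- match.arg(model)
  structure(
    list(cohort = cohort, synthetic = synthetic, images = images,
         model = model, ridge = ridge, cutoff = cutoff,
         horizon_days = horizon_days, threshold = threshold,
         seed = as.integer(seed), output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON config file whose keys
#'   match [pipeline_config()] arguments.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, raw)
}

#' Run the end-to-end screening pipeline
#'
#' Executes the screening stages in assay order — (optionally) simulate
#' plates and doses, quantify viable areas, build dose-response curves,
#' standardise cohort features, score with the OncoSensi model, and
#' evaluate against recurrence and survival — emitting per-stage CSVs,
#' an evaluation JSON and a run log when `output_dir` is set. A stage
#' failure aborts with the stage name. Two runs with the same config
#' and seed produce byte-identical artifacts.
#'
#' When image stages run, each simulated plate is one sample: growth
#' rate comes from the zero-dose columns (day 5 over day 1) and
#' per-dose viability from day-5 areas normalised to the zero-dose
#' mean, then RT-AUC by the trapezoid rule.
#'
#' @param config A [pipeline_config()] (or path to one).
#' @return A list: `cohort` (scored tibble), `model`, `reference`,
#'   `evaluation` (see [evaluate_cohort()]), `report` (flat summary
#'   list), and when images ran, `areas` and `drc`.
#' @examples
#' res <- run_pipeline(pipeline_config(model = "eq2_hpv"))
#' res$report$roc_auc
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(df, name) {
    if (!is.null(out_dir)) {
      readr::write_csv(df, file.path(out_dir, name), na = "NA")
    }
  }

  areas <- NULL
  drc <- NULL
  truth <- NULL
  if (!is.null(config$images)) {
    img <- stage("simulate", simulate_image_stage(config))
    areas <- img$areas
    drc <- img$drc
    truth <- img$truth
    emit(areas, "areas.csv")
    emit(drc, "drc.csv")
  }

  cohort <- stage("cohort", load_pipeline_cohort(config, drc))
  emit(cohort, "cohort.csv")

  test_set <- dplyr::filter(cohort, .data$set == "test")
  ref <- stage("zscore", freeze_reference(test_set))
  scored_all <- stage("zscore", apply_zscores(cohort, ref))
  emit(dplyr::select(scored_all, -dplyr::starts_with(".")), "zscores.csv")

  model <- stage("score", switch(config$model,
    eq1 = published_model("two_parameter"),
    eq2_hpv = published_model("three_parameter"),
    refit = fit_oncosensi(dplyr::filter(scored_all, .data$set == "test"),
                          ridge = config$ridge)
  ))
  scored_test <- stage("score",
                       score_cohort(dplyr::filter(scored_all,
                                                  .data$set == "test"),
                                    model, cutoff = config$cutoff))
  emit(dplyr::select(scored_test, "patient_id", "lp", "index", "label"),
       "scores.csv")

  evaluation <- stage("evaluate",
                      evaluate_cohort(scored_test, cutoff = config$cutoff,
                                      horizon_days = config$horizon_days))

  rfs <- evaluation$rfs_at_horizon
  report <- list(
    model = config$model,
    coefficients = as.list(model$coefficients),
    n_test = nrow(scored_test),
    roc_auc = evaluation$roc$auc,
    sensitivity = evaluation$sensitivity,
    specificity = evaluation$specificity,
    one_year_rfs_by_group = stats::setNames(as.list(rfs$survival),
                                            rfs$group),
    log_rank_chi_square = evaluation$log_rank$chi_square %||% NA,
    log_rank_p = evaluation$log_rank$p_value %||% NA,
    seed = config$seed,
    config_hash = config_hash(config)
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(c(
      sprintf("oncosensi %s on R %s.%s",
              as.character(utils::packageVersion("oncosensi")),
              R.version$major, R.version$minor),
      sprintf("seed: %d", config$seed),
      sprintf("config_hash: %s", report$config_hash),
      sprintf("stages: %s",
              paste(c(if (!is.null(config$images)) c("simulate", "quantify",
                                                     "drc"),
                      "zscore", "score", "evaluate"), collapse = " -> "))
    ), file.path(out_dir, "run.log"))
  }

  list(cohort = scored_test, full_cohort = scored_all, model = model,
       reference = ref, evaluation = evaluation, report = report,
       areas = areas, drc = drc, truth = truth)
}

# deterministic hash of the config (no external digest dependency:
# serialize to canonical JSON and fold into a hex checksum)
config_hash <- function(config) {
  config <- unclass(config)
  config$output_dir <- NULL # artifact location is not part of the analysis
  json <- jsonlite::toJSON(config[order(names(config))],
                           auto_unbox = TRUE, digits = NA, null = "null",
                           force = TRUE)
  bytes <- as.integer(charToRaw(as.character(json)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", h)
}

simulate_image_stage <- function(config) {
  img_cfg <- config$images
  n_plates <- img_cfg$n_plates %||% 4L
  targets <- img_cfg$targets_gy %||% c(0, 2, 4, 8)
  spec <- do.call(plate_spec, img_cfg$spec %||% list())
  survival_list <- img_cfg$survival %||% list(list())
  if (!is.null(names(survival_list))) survival_list <- list(survival_list)
  survival_list <- rep_len(survival_list, n_plates)

  unit_time <- fit_unit_time(arm_reference_calibration())
  rate <- dose_rate_from_dwell(1, unit_time)
  schedule <- build_schedule(targets, unit_time, n_cols = spec$cols)

  purrr::map(seq_len(n_plates), function(i) {
    dm <- simulate_delivery(schedule, rate, n_rows = spec$rows,
                            noise_sd = img_cfg$dose_noise_sd %||% 0,
                            seed = config$seed + i)
    sim <- simulate_plate_images(
      spec, dm, do.call(survival_params, survival_list[[i]]),
      days = c(1, 5), seed = config$seed + 1000 + i,
      plate_id = sprintf("plate%02d", i)
    )
    dose_by_col <- dm |>
      dplyr::summarise(dose_gy = mean(.data$dose_gy), .by = "col")
    areas <- purrr::imap_dfr(sim$images, function(im, day_name) {
      quantify_green_area(im, spec, threshold = config$threshold,
                          by = "pillar") |>
        dplyr::mutate(day = as.integer(sub("day", "", day_name)))
    }) |>
      dplyr::left_join(dose_by_col, by = c("pillar_col" = "col")) |>
      dplyr::mutate(plate_id = sprintf("plate%02d", i), .before = 1)
    list(areas = areas, truth = sim$truth)
  }) |>
    purrr::transpose() |>
    (\(x) {
      areas <- dplyr::bind_rows(x$areas)
      drc <- plate_areas_to_drc(areas)
      list(areas = areas, drc = drc, truth = dplyr::bind_rows(x$truth))
    })()
}

# collapse per-pillar day-5 areas into per-plate growth + dose-response
plate_areas_to_drc <- function(areas) {
  per_dose <- areas |>
    dplyr::summarise(area = sum(.data$area_px),
                     .by = c("plate_id", "day", "dose_gy"))
  control <- per_dose |>
    dplyr::filter(.data$dose_gy == min(.data$dose_gy)) |>
    dplyr::select("plate_id", "day", control_area = "area")
  growth <- control |>
    tidyr::pivot_wider(names_from = "day", values_from = "control_area",
                       names_prefix = "day") |>
    dplyr::mutate(growth_rate = growth_rate(.data$day5, .data$day1)) |>
    dplyr::select("plate_id", "growth_rate")
  per_dose |>
    dplyr::filter(.data$day == max(.data$day)) |>
    dplyr::left_join(dplyr::select(control[control$day ==
                                             max(per_dose$day), ],
                                   "plate_id", "control_area"),
                     by = "plate_id") |>
    dplyr::mutate(viability_pct = normalize_viability(.data$area,
                                                      .data$control_area)) |>
    dplyr::summarise(
      rt_auc = auc_trapezoid(.data$viability_pct[order(.data$dose_gy)],
                             sort(.data$dose_gy)),
      .by = "plate_id"
    ) |>
    dplyr::left_join(growth, by = "plate_id")
}

load_pipeline_cohort <- function(config, drc) {
  if (identical(config$cohort, "synthetic")) {
    args <- config$synthetic
    args$seed <- args$seed %||% config$seed
    return(do.call(simulate_cohort, args))
  }
  if (identical(config$cohort, "bundled")) {
    return(hnscc_cohort())
  }
  read_cohort(config$cohort)
}
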