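zero_dose_map <- function(spec) {
  simulate_delivery(build_schedule(0, 51.49, n_cols = spec$cols), 60 / 51.49,
                    n_rows = spec$rows)
}

graded_dose_map <- function() {
  simulate_delivery(build_schedule(c(0, 2, 4, 8), 51.49), 60 / 51.49)
}

test_that("no dose and no growth leaves areas unchanged between days", {
  spec <- plate_spec(noise_sd = 0, area_cv = 0)
  sim <- simulate_plate_images(spec, zero_dose_map(spec),
                               survival_params(alpha = 0.3, beta = 0.05,
                                               growth_per_day = 1),
                               days = c(1, 5), seed = 2)
  wide <- tidyr::pivot_wider(sim$truth, names_from = "day",
                             values_from = "true_area_px",
                             names_prefix = "day")
  expect_equal(wide$day5, wide$day1)
})

test_that("zero dose means surviving fraction one for every pillar", {
  spec <- plate_spec(noise_sd = 0, area_cv = 0.2)
  surv <- survival_params(alpha = 0.3, beta = 0.05, growth_per_day = 1.2)
  sim <- simulate_plate_images(spec, zero_dose_map(spec), surv,
                               days = c(1, 5), seed = 3)
  # day-5 areas reflect pure growth (no kill term), up to the pixel
  # discretisation of the two renderings; on small heterogeneous blobs
  # only the plate average is tight
  wide <- tidyr::pivot_wider(sim$truth, names_from = "day",
                             values_from = "true_area_px",
                             names_prefix = "day")
  ratio <- wide$day5 / wide$day1
  expect_equal(mean(ratio), 1.2^4, tolerance = 0.02)
  # with one large uniform blob per pillar the discretisation error is
  # small for every pillar
  spec_big <- plate_spec(noise_sd = 0, area_cv = 0, organoid_lambda = 0,
                         day1_area_px = 250)
  sim_big <- simulate_plate_images(spec_big, zero_dose_map(spec_big), surv,
                                   days = c(1, 5), seed = 3)
  wide_big <- tidyr::pivot_wider(sim_big$truth, names_from = "day",
                                 values_from = "true_area_px",
                                 names_prefix = "day")
  expect_true(all(abs(wide_big$day5 / wide_big$day1 - 1.2^4) < 0.05))
})

test_that("dose-dependent kill follows the linear-quadratic model", {
  # alpha = 0.3, beta = 0: area ratio at 2 Gy vs 0 Gy is exp(-0.6)
  spec <- plate_spec(noise_sd = 0, area_cv = 0, organoid_lambda = 0,
                     day1_area_px = 400)
  surv <- survival_params(alpha = 0.3, beta = 0, growth_per_day = 1)
  sim <- simulate_plate_images(spec, graded_dose_map(), surv,
                               days = 5, seed = 4)
  q <- quantify_green_area(sim$images$day5, spec, by = "pillar")
  merged <- dplyr::left_join(q, sim$truth,
                             by = c("pillar_row", "pillar_col"))
  mean_area <- tapply(merged$area_px, round(merged$dose_gy, 6), mean)
  expect_equal(unname(mean_area["2"] / mean_area["0"]), exp(-0.6),
               tolerance = 0.02)
})

test_that("a fixed seed reproduces images and truth bit-identically", {
  spec <- plate_spec() # defaults include intensity noise and area spread
  dm <- graded_dose_map()
  a <- simulate_plate_images(spec, dm, survival_params(), seed = 123)
  b <- simulate_plate_images(spec, dm, survival_params(), seed = 123)
  expect_identical(a$images, b$images)
  expect_identical(a$truth, b$truth)
})

test_that("emitted truth equals brute-force counting of noiseless images", {
  spec <- plate_spec(noise_sd = 0, area_cv = 0.25)
  sim <- simulate_plate_images(spec, graded_dose_map(), survival_params(),
                               days = c(1, 5), seed = 6)
  for (d in c(1, 5)) {
    img <- sim$images[[paste0("day", d)]]
    q <- quantify_green_area(img, spec, by = "pillar")
    tr <- dplyr::filter(sim$truth, day == !!d)
    expect_identical(as.integer(q$area_px), as.integer(tr$true_area_px))
  }
})

test_that("plate geometry is validated", {
  expect_error(plate_spec(rows = 8, cols = 24), "384")
  expect_error(plate_spec(tile_px = 10, pillar_diameter_px = 18),
               "too small")
  expect_error(plate_spec(background_intensity = 30), "threshold")
})

test_that("plate images survive a TIFF round trip", {
  spec <- plate_spec(noise_sd = 0, area_cv = 0)
  dir <- withr::local_tempdir()
  sim <- simulate_plate_images(spec, zero_dose_map(spec), survival_params(),
                               days = c(1, 5), seed = 8,
                               plate_id = "pltA", dir = dir)
  expect_setequal(list.files(dir),
                  c("pltA_day1.tif", "pltA_day5.tif", "pltA_truth.csv"))
  back <- read_plate_image(file.path(dir, "pltA_day5.tif"))
  expect_equal(round(back), sim$images$day5, ignore_attr = TRUE)
  q <- quantify_image_dir(dir, spec)
  expect_setequal(unique(q$day), c(1, 5))
  expect_equal(sum(q$area_px[q$day == 5]),
               sum(quantify_green_area(sim$images$day5, spec)$area_px))
})
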