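#' Synthetic 384-pillar plate specification
#'
#' Geometry and intensity model for simulated green-fluorescence scans of
#' a 384-pillar organoid plate. Each pillar owns a square tile of pixels;
#' organoid blobs are rendered inside the tile as filled discs whose
#' total area follows the dose/growth model of [survival_params()].
#' Blobs are geometric stand-ins: no organoid morphology or scanner
#' optics are modelled, only the thresholded-area statistics the
#' downstream quantification consumes.
#'
#' @param rows,cols Pillar grid (must multiply to 384).
#' @param tile_px Side of the square pixel tile owned by one pillar; the
#'   image is `rows * tile_px` by `cols * tile_px` pixels.
#' @param pillar_diameter_px Nominal pillar diameter in pixels; must fit
#'   in the tile.
#' @param organoid_lambda Mean of the (zero-truncated) Poisson number of
#'   organoid blobs per pillar.
#' @param day1_area_px Mean day-1 viable area per pillar, in pixels.
#' @param area_cv Lognormal coefficient of variation of day-1 area
#'   across pillars (0 for identical pillars).
#' @param base_intensity Foreground (viable organoid) intensity on the
#'   0-255 scale; must exceed the quantification threshold.
#' @param background_intensity Background intensity on the 0-255 scale;
#'   must not exceed the quantification threshold.
#' @param noise_sd Gaussian intensity noise SD (0-255 scale units).
#' @return A `plate_spec` list.
#' @examples
#' plate_spec()
#' @export
plate_spec <- function(rows = 16, cols = 24, tile_px = 28,
                       pillar_diameter_px = 20, organoid_lambda = 3,
                       day1_area_px = 100, area_cv = 0.2,
                       base_intensity = 120, background_intensity = 10,
                       noise_sd = 3) {
  if (rows * cols != 384) abort("Pillar grid must have 16 x 24 = 384 pillars.")
  if (pillar_diameter_px > tile_px) {
    abort("Image too small to hold the pillar grid: increase `tile_px`.")
  }
  if (background_intensity > 20 || base_intensity <= 20) {
    abort(paste0("Intensities must straddle the quantification threshold: ",
                 "background <= 20 < base."))
  }
  structure(
    list(rows = rows, cols = cols, tile_px = tile_px,
         pillar_diameter_px = pillar_diameter_px,
         organoid_lambda = organoid_lambda, day1_area_px = day1_area_px,
         area_cv = area_cv, base_intensity = base_intensity,
         background_intensity = background_intensity, noise_sd = noise_sd),
    class = "plate_spec"
  )
}

#' Dose-dependent survival model for synthetic plates
#'
#' Linear-quadratic cell survival: the viable area of a pillar exposed
#' to dose \eqn{D} on day \eqn{d} is
#' \eqn{A_1 \, g^{d-1} \exp(-\alpha D - \beta D^2)}, where \eqn{A_1} is
#' its day-1 area and \eqn{g} the per-day growth factor. The surviving
#' fraction at zero dose is exactly 1.
#'
#' @param alpha Linear kill coefficient (per Gy), >= 0.
#' @param beta Quadratic kill coefficient (per Gy squared), >= 0.
#' @param growth_per_day Daily area growth factor (dimensionless).
#' @return A `survival_params` list.
#' @examples
#' survival_params(alpha = 0.3)
#' @export
survival_params <- function(alpha = 0.25, beta = 0.03, growth_per_day = 1.2) {
  check_number(alpha, "alpha", min = 0)
  check_number(beta, "beta", min = 0)
  check_number(growth_per_day, "growth_per_day", min = 0)
  structure(list(alpha = alpha, beta = beta, growth_per_day = growth_per_day),
            class = "survival_params")
}

surviving_fraction <- function(survival, dose_gy) {
  exp(-survival$alpha * dose_gy - survival$beta * dose_gy^2)
}

# render k equal-area discs on an nxn tile without overlap; returns the
# tile mask (logical) -- the discretised pixel count is the ground truth
render_tile <- function(tile_px, n_blobs, total_area) {
  mask <- matrix(FALSE, tile_px, tile_px)
  if (total_area <= 0 || n_blobs < 1) return(mask)
  g <- ceiling(sqrt(n_blobs))
  cell <- tile_px / g
  r <- sqrt(total_area / n_blobs / pi)
  r <- min(r, cell / 2 - 0.5) # cap: blobs stay inside their sub-cell
  if (r <= 0) return(mask)
  centers <- (seq_len(g) - 0.5) * cell
  idx <- seq_len(n_blobs)
  cx <- centers[(idx - 1) %% g + 1]
  cy <- centers[(idx - 1) %/% g + 1]
  px <- seq_len(tile_px) - 0.5
  for (b in seq_len(n_blobs)) {
    dx2 <- outer((px - cy[b])^2, (px - cx[b])^2, `+`)
    mask <- mask | (dx2 <= r^2)
  }
  mask
}

#' Simulate green-fluorescence plate images
#'
#' Renders one image per imaging day for a plate whose per-pillar doses
#' are given by a dose map. Per pillar, the target viable area follows
#' the linear-quadratic model of [survival_params()]; the emitted ground
#' truth is the discretised (rendered) pixel count, which equals a
#' brute-force count of above-threshold pixels in the noiseless image.
#'
#' With a fixed `seed` the output (images and ground truth) is
#' bit-identical across calls.
#'
#' @param spec A [plate_spec()].
#' @param dose_map A `dose_map` tibble (`row`, `col`, `dose_gy`) from
#'   [simulate_delivery()], covering the full pillar grid.
#' @param survival A [survival_params()].
#' @param days Integer imaging days (default `c(1, 5)`).
#' @param seed Optional integer seed.
#' @param plate_id Plate identifier used in filenames.
#' @param dir If non-`NULL`, write one 8-bit grayscale TIFF per day
#'   (`{plate_id}_day{d}.tif`) plus a `{plate_id}_truth.csv` sidecar
#'   (`pillar_row,pillar_col,day,true_area_px,dose_gy`) into this
#'   directory.
#' @return A list with `images` (named list of integer matrices, 0-255,
#'   one per day) and `truth` (tibble `pillar_row`, `pillar_col`, `day`,
#'   `true_area_px`, `dose_gy`).
#' @examples
#' dm <- simulate_delivery(build_schedule(c(0, 2, 4, 8), 51.49), 60 / 51.49)
#' sim <- simulate_plate_images(plate_spec(), dm, survival_params(), seed = 1)
#' sim$truth
#' @export
simulate_plate_images <- function(spec, dose_map, survival = survival_params(),
                                  days = c(1, 5), seed = NULL,
                                  plate_id = "plate01", dir = NULL) {
  if (!inherits(spec, "plate_spec")) abort("`spec` must be a plate_spec().")
  if (max(dose_map$row) != spec$rows || max(dose_map$col) != spec$cols ||
      nrow(dose_map) != spec$rows * spec$cols) {
    abort("`dose_map` dimensions do not match the plate layout.")
  }
  dose <- matrix(NA_real_, spec$rows, spec$cols)
  dose[cbind(dose_map$row, dose_map$col)] <- dose_map$dose_gy

  with_seed_or_not(seed, {
    n_blobs <- matrix(pmax(1L, rpois(384, spec$organoid_lambda)),
                      spec$rows, spec$cols)
    area1 <- if (spec$area_cv > 0) {
      sdlog <- sqrt(log(1 + spec$area_cv^2))
      matrix(spec$day1_area_px *
               exp(rnorm(384, -sdlog^2 / 2, sdlog)), spec$rows, spec$cols)
    } else {
      matrix(spec$day1_area_px, spec$rows, spec$cols)
    }

    h <- spec$rows * spec$tile_px
    w <- spec$cols * spec$tile_px
    images <- list()
    truth <- list()
    for (d in days) {
      img <- matrix(spec$background_intensity, h, w)
      day_truth <- tidyr::expand_grid(pillar_row = seq_len(spec$rows),
                                      pillar_col = seq_len(spec$cols))
      areas <- numeric(nrow(day_truth))
      for (i in seq_len(nrow(day_truth))) {
        r <- day_truth$pillar_row[i]
        cc <- day_truth$pillar_col[i]
        target <- area1[r, cc] * survival$growth_per_day^(d - 1) *
          surviving_fraction(survival, dose[r, cc])
        mask <- render_tile(spec$tile_px, n_blobs[r, cc], target)
        areas[i] <- sum(mask)
        ri <- (r - 1) * spec$tile_px + seq_len(spec$tile_px)
        ci <- (cc - 1) * spec$tile_px + seq_len(spec$tile_px)
        tile <- img[ri, ci]
        tile[mask] <- spec$base_intensity
        img[ri, ci] <- tile
      }
      if (spec$noise_sd > 0) {
        img <- img + rnorm(length(img), 0, spec$noise_sd)
      }
      img <- matrix(as.integer(pmin(pmax(round(img), 0), 255)), h, w)
      images[[paste0("day", d)]] <- img
      truth[[paste0("day", d)]] <- dplyr::mutate(
        day_truth, day = d, true_area_px = areas,
        dose_gy = dose[cbind(.data$pillar_row, .data$pillar_col)]
      )
    }
    truth <- dplyr::bind_rows(truth)

    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      for (d in days) {
        write_plate_image(images[[paste0("day", d)]],
                          file.path(dir, sprintf("%s_day%d.tif", plate_id, d)))
      }
      readr::write_csv(truth,
                       file.path(dir, sprintf("%s_truth.csv", plate_id)))
    }
    list(images = images, truth = truth)
  })
}

#' Read or write a plate image
#'
#' Plate scans are single-channel grayscale TIFFs (8- or 16-bit; PNG is
#' accepted on read if the png package is installed). In memory an image
#' is a numeric matrix on the 0-255 scale; 16-bit files are rescaled to
#' 0-255 on read so the standard intensity threshold applies.
#'
#' @param image Numeric matrix, 0-255 scale.
#' @param path File path (`.tif`/`.tiff` or `.png`).
#' @return `read_plate_image()` returns a numeric matrix on the 0-255
#'   scale; `write_plate_image()` returns `path` invisibly.
#' @export
write_plate_image <- function(image, path) {
  rlang::check_installed("tiff")
  tiff::writeTIFF(image / 255, path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_plate_image
#' @export
read_plate_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    rlang::check_installed("png")
    png::readPNG(path)
  } else {
    rlang::check_installed("tiff")
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3) img <- img[, , 1] # first channel = green
  # readers return [0,1] floats regardless of stored depth
  img * 255
}
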