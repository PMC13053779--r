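#' Quantify viable-cell area on a plate scan
#'
#' Viability on a calcein-stained plate scan is the count of pixels
#' whose green intensity is *strictly greater than* the threshold
#' (default 20 on the 0-255 scale). Counts are reported per 8-pillar
#' strip by default: strips are consecutive groups of `strip_size`
#' pillars along each plate row (24 columns / 8 = 3 strips per row, 48
#' strips on a 384-pillar plate).
#'
#' @param image Numeric intensity matrix on the 0-255 scale (use
#'   [read_plate_image()], which rescales 16-bit scans). Values above
#'   255 are assumed to be raw 16-bit and are rescaled.
#' @param spec A [plate_spec()] describing the pillar geometry; image
#'   dimensions must match `rows * tile_px` by `cols * tile_px`.
#' @param threshold Intensity threshold; pixels must exceed it strictly.
#' @param strip_size Pillars per strip; must divide the plate columns.
#' @param by Granularity: `"strip"` (default), `"pillar"`, or `"plate"`.
#' @return A tibble of integer pixel counts: per strip
#'   (`strip`, `area_px`), per pillar (`pillar_row`, `pillar_col`,
#'   `area_px`), or one row for the whole plate (`area_px`).
#' @examples
#' img <- matrix(10, 16 * 24, 24 * 24)
#' quantify_green_area(img, plate_spec()) # all background: zero areas
#' @export
quantify_green_area <- function(image, spec = plate_spec(), threshold = 20,
                                strip_size = 8,
                                by = c("strip", "pillar", "plate")) {
  by <- match.arg(by)
  if (!inherits(spec, "plate_spec")) abort("`spec` must be a plate_spec().")
  h <- spec$rows * spec$tile_px
  w <- spec$cols * spec$tile_px
  if (nrow(image) != h || ncol(image) != w) {
    abort(sprintf("Image is %d x %d but layout expects %d x %d.",
                  nrow(image), ncol(image), h, w))
  }
  if (max(image) > 255) image <- image * 255 / 65535
  if (spec$cols %% strip_size != 0 && by == "strip") {
    abort("`strip_size` must divide the number of pillar columns.")
  }
  hot <- image > threshold
  # per-pillar counts by summing tile blocks
  pr <- (seq_len(h) - 1L) %/% spec$tile_px + 1L
  pc <- (seq_len(w) - 1L) %/% spec$tile_px + 1L
  counts <- rowsum(t(rowsum(hot + 0, pr)), pc) # cols x rows
  per_pillar <- tibble::tibble(
    pillar_row = rep(seq_len(spec$rows), each = spec$cols),
    pillar_col = rep(seq_len(spec$cols), times = spec$rows),
    area_px = as.integer(t(counts)[cbind(
      rep(seq_len(spec$rows), each = spec$cols),
      rep(seq_len(spec$cols), times = spec$rows))])
  )
  switch(by,
    pillar = per_pillar,
    plate = tibble::tibble(area_px = sum(per_pillar$area_px)),
    strip = per_pillar |>
      dplyr::mutate(strip = (.data$pillar_row - 1L) *
                      (spec$cols %/% strip_size) +
                      (.data$pillar_col - 1L) %/% strip_size + 1L) |>
      dplyr::summarise(area_px = sum(.data$area_px), .by = "strip") |>
      dplyr::arrange(.data$strip)
  )
}

#' Quantify a directory of plate scans
#'
#' Reads every `{plate_id}_day{d}.tif` (or `.png`) in a directory and
#' tabulates per-strip viable areas.
#'
#' @param dir Directory of plate images named `{plate_id}_day{d}.tif`.
#' @inheritParams quantify_green_area
#' @return A tibble `plate_id`, `day`, `strip`, `area_px`.
#' @export
quantify_image_dir <- function(dir, spec = plate_spec(), threshold = 20,
                               strip_size = 8) {
  files <- list.files(dir, pattern = "_day[0-9]+\\.(tif|tiff|png)$",
                      full.names = TRUE)
  if (length(files) == 0) abort("No plate images found in `dir`.")
  purrr::map_dfr(files, function(f) {
    base <- tools::file_path_sans_ext(basename(f))
    day <- as.integer(sub(".*_day([0-9]+)$", "\\1", base))
    plate <- sub("_day[0-9]+$", "", base)
    quantify_green_area(read_plate_image(f), spec, threshold, strip_size) |>
      dplyr::mutate(plate_id = plate, day = day, .before = 1)
  })
}

#' Organoid growth rate between two imaging days
#'
#' The growth rate is the day-5 viable area expressed as a percentage of
#' the day-1 area: `100 * area_day5 / area_day1` (a value of 100 means
#' no net growth; values below 100 mean regression). The alternative
#' percent-increase convention `100 * (area_day5 - area_day1) /
#' area_day1` is available via `convention = "increase"`.
#'
#' @param area_day5,area_day1 Viable areas in pixels; `area_day1` must
#'   be positive.
#' @param convention `"ratio"` (default) or `"increase"`.
#' @return Growth rate in percent.
#' @examples
#' growth_rate(517, 200) # 258.5
#' @export
growth_rate <- function(area_day5, area_day1,
                        convention = c("ratio", "increase")) {
  convention <- match.arg(convention)
  check_number(area_day5, "area_day5", min = 0)
  if (any(area_day1 <= 0)) {
    abort("`area_day1` must be > 0; growth rate is undefined.")
  }
  switch(convention,
         ratio = 100 * area_day5 / area_day1,
         increase = 100 * (area_day5 - area_day1) / area_day1)
}

#' Percent viability relative to an unirradiated control
#'
#' `100 * treated_area / control_area`, floored at 0 and deliberately
#' *not* capped at 100: organoids that keep growing under a low dose can
#' exceed the control.
#'
#' @param treated_area,control_area Viable areas in pixels;
#'   `control_area` must be positive.
#' @return Percent viability.
#' @examples
#' normalize_viability(150, 300) # 50
#' @export
normalize_viability <- function(treated_area, control_area) {
  check_number(treated_area, "treated_area", min = 0)
  if (any(control_area <= 0)) {
    abort("`control_area` must be > 0; viability is undefined.")
  }
  pmax(100 * treated_area / control_area, 0)
}
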