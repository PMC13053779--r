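# shared fixtures: everything is built in code at test time

ref_test_set <- function() {
  dplyr::filter(hnscc_cohort(), set == "test")
}

ref_validation_set <- function() {
  dplyr::filter(hnscc_cohort(), set == "validation")
}

# test set standardised against its own frozen statistics
scored_test_set <- function() {
  cohort <- ref_test_set()
  apply_zscores(cohort, freeze_reference(cohort))
}

# brute-force per-pixel, per-strip area count: the oracle the vectorised
# quantifier must match on every image
naive_strip_count <- function(image, spec, threshold = 20, strip_size = 8) {
  strips_per_row <- spec$cols / strip_size
  counts <- integer(spec$rows * strips_per_row)
  for (i in seq_len(nrow(image))) {
    for (j in seq_len(ncol(image))) {
      if (image[i, j] > threshold) {
        pr <- (i - 1) %/% spec$tile_px + 1
        pc <- (j - 1) %/% spec$tile_px + 1
        strip <- (pr - 1) * strips_per_row + (pc - 1) %/% strip_size + 1
        counts[strip] <- counts[strip] + 1L
      }
    }
  }
  counts
}

# draw a filled disc into an intensity matrix, returning the matrix and
# the exact pixel count (independent of the package's renderer)
draw_disc <- function(image, center_row, center_col, radius, intensity) {
  n <- 0L
  for (i in seq_len(nrow(image))) {
    for (j in seq_len(ncol(image))) {
      if ((i - center_row)^2 + (j - center_col)^2 <= radius^2) {
        image[i, j] <- intensity
        n <- n + 1L
      }
    }
  }
  list(image = image, count = n)
}

blank_plate_image <- function(spec, intensity = 10) {
  matrix(intensity, spec$rows * spec$tile_px, spec$cols * spec$tile_px)
}
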