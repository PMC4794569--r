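# Shared fixtures, built in code and cached for the session.

.cache <- new.env(parent = emptyenv())

# A rasterized disk mask of radius r centred in a (2r+5)^2 frame.
disk_mask <- function(r, pad = 2) {
  n <- 2 * r + 2 * pad + 1
  ctr <- (n + 1) / 2
  d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+")
  d2 <= r^2
}

# Tight-bbox cell_region for a full-frame logical mask.
region_from_mask <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  r0 <- min(px[, 1]); r1 <- max(px[, 1]); c0 <- min(px[, 2]); c1 <- max(px[, 2])
  cell_region(mask[r0:r1, c0:c1, drop = FALSE], c(r0 - 1L, c0 - 1L, r1, c1))
}

# Region + gray image for a generated cell patch (patch coordinates).
cell_as_image <- function(cell) {
  list(image = cell$patch, region = region_from_mask(cell$mask))
}

# A small labeled dataset on disk, generated once per test session.
test_dataset <- function() {
  if (is.null(.cache$dataset_dir)) {
    dir <- file.path(tempdir(), "hep2cad_test_dataset")
    generate_dataset(setNames(rep(3L, 7), hep2_patterns()),
                     negative_fraction = 0.125, seed = 101L, out_dir = dir)
    .cache$dataset_dir <- dir
  }
  .cache$dataset_dir
}

# A CAD bundle trained once on the shared dataset (tuning off for speed).
test_bundle <- function() {
  if (is.null(.cache$bundle)) {
    cfg <- classifier_config(seed = 11L, tune = FALSE, max_cells_per_image = 4L)
    .cache$bundle <- train_cad(file.path(test_dataset(), "manifest.csv"), cfg)
  }
  .cache$bundle
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
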