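#' Well record
#'
#' One serum test unit: a negative well carries exactly one image, a
#' nonnegative well exactly three; the pattern label is `NA` whenever the
#' intensity label is negative.
#'
#' @param well_id Character id.
#' @param images Character vector of image paths (length 1 or 3).
#' @param intensity_label Intensity class, or `NA` when unknown.
#' @param pattern_label Staining pattern, or `NA`.
#' @param reader_id Optional reader id.
#' @return An object of class `hep2_well_record`.
#' @export
well_record <- function(well_id, images, intensity_label = NA,
                        pattern_label = NA, reader_id = NA) {
  if (!length(images) %in% c(1L, 3L)) {
    stop("a well has 1 image (negative serum) or 3 images (nonnegative)")
  }
  if (!is.na(intensity_label)) {
    assert_intensity(intensity_label)
    if (intensity_label == "negative") {
      if (!is.na(pattern_label)) stop("negative wells carry no pattern label")
      if (length(images) != 1L) stop("negative wells have exactly 1 image")
    } else if (length(images) != 3L) {
      stop("nonnegative wells have exactly 3 images")
    }
  }
  if (!is.na(pattern_label)) assert_pattern(pattern_label)
  structure(list(well_id = well_id, images = images,
                 intensity_label = intensity_label,
                 pattern_label = pattern_label, reader_id = reader_id),
            class = "hep2_well_record")
}

#' Generate a labeled synthetic well dataset
#'
#' Writes PNG images, per-image ground-truth JSON sidecars and a manifest
#' CSV for a dataset of synthetic HEp-2 wells. Each requested pattern gets
#' `n_wells_per_class[[pattern]]` nonnegative wells of 3 images each, with
#' the well intensity drawn from {intermediate, positive}; negative wells
#' (one dim image each) are added so they make up `negative_fraction` of all
#' wells. Every nonnegative image contains at least one mitotic cell by
#' default, so the well-discard rule is exercised deliberately; the mitotic
#' fluorescence type alternates across a well's images.
#'
#' @param n_wells_per_class Named integer vector, `pattern -> well count`.
#' @param negative_fraction Fraction of all wells that are negative
#'   (default 0.10, the approximate share of negative sera in routine
#'   screening workloads).
#' @param seed Integer seed; the run is a pure function of its arguments.
#' @param out_dir Output directory (created if missing).
#' @param config Simulator configuration, see [hep2_sim_config()].
#' @return The manifest data.frame (one row per image), invisibly also
#'   written to `file.path(out_dir, "manifest.csv")`.
#' @export
generate_dataset <- function(n_wells_per_class, negative_fraction = 0.10,
                             seed = 1L, out_dir, config = hep2_sim_config()) {
  stopifnot(is.numeric(n_wells_per_class), all(n_wells_per_class >= 0))
  for (p in names(n_wells_per_class)) assert_pattern(p)
  if (negative_fraction < 0 || negative_fraction >= 1) {
    stop("negative_fraction must lie in [0, 1)")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  n_pos <- sum(n_wells_per_class)
  n_neg <- round(n_pos * negative_fraction / (1 - negative_fraction))
  wells <- list()
  for (p in names(n_wells_per_class)) {
    for (i in seq_len(n_wells_per_class[[p]])) {
      wells[[length(wells) + 1]] <- list(pattern = p)
    }
  }
  for (i in seq_len(n_neg)) wells[[length(wells) + 1]] <- list(pattern = NA)
  seeds <- derive_seeds(seed, length(wells) + 1L)
  rows <- list()
  for (wi in seq_along(wells)) {
    w <- wells[[wi]]
    well_id <- sprintf("W%04d", wi)
    negative <- is.na(w$pattern)
    intensity <- if (negative) "negative" else {
      with_seed(seeds[wi], sample(c("intermediate", "positive"), 1))
    }
    n_img <- if (negative) 1L else 3L
    img_seeds <- derive_seeds(seeds[wi] + 1L, n_img)
    for (k in seq_len(n_img)) {
      spec <- image_spec(
        width = config$width, height = config$height,
        n_interphase = config$n_interphase,
        n_mitotic = if (negative) 0L else max(1L, config$n_mitotic),
        pattern = if (negative) "homogeneous" else w$pattern,
        intensity = intensity,
        mitosis_type = hep2_mitosis_types()[(k - 1L) %% 2L + 1L],
        noise_sd = config$noise_sd,
        background_level = config$background_level,
        seed = img_seeds[k])
      img <- generate_image(spec, config)
      stem <- sprintf("%s_%d", well_id, k)
      png_path <- file.path(out_dir, paste0(stem, ".png"))
      write_image_png(img$pixels, png_path)
      write_truth_sidecar(img, file.path(out_dir, paste0(stem, ".json")))
      rows[[length(rows) + 1]] <- data.frame(
        well_id = well_id, image_path = paste0(stem, ".png"),
        image_index = k, intensity_label = intensity,
        pattern_label = if (negative) NA_character_ else w$pattern,
        seed = img_seeds[k], stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = TRUE, eol = "\n")
  invisible(manifest)
}

#' Read and write dataset pieces
#'
#' `read_manifest()` loads a manifest CSV and groups its rows into
#' [well_record()] objects; `read_image()` loads a PNG back to the 0--255
#' integer RGB array; `read_truth_sidecar()` restores the ground-truth cell
#' regions written next to each image.
#'
#' @param path File path.
#' @return See each function.
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well_id", "image_path", "image_index", "intensity_label", "pattern_label")
  if (!all(need %in% names(man))) {
    stop("manifest lacks columns: ", paste(setdiff(need, names(man)), collapse = ", "))
  }
  base <- dirname(path)
  lapply(split(man, man$well_id)[unique(man$well_id)], function(g) {
    g <- g[order(g$image_index), ]
    pat <- g$pattern_label[1]
    well_record(g$well_id[1], file.path(base, g$image_path),
                intensity_label = g$intensity_label[1],
                pattern_label = if (is.na(pat) || pat == "") NA else pat)
  })
}

write_image_png <- function(pixels, path) {
  png::writePNG(pixels / 255, path)
  invisible(path)
}

#' @rdname read_manifest
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("unreadable image path: ", path)
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), dim = c(dim(arr), 3))
  arr <- arr[, , 1:3, drop = FALSE]
  storage.mode(arr) <- "double"
  round(arr * 255)
}

# Ground-truth sidecar: one JSON per image listing each cell's bbox,
# column-major run-length-encoded mask, pattern and mitosis annotation.
write_truth_sidecar <- function(img, path) {
  cells <- lapply(img$truth_cells, function(r) {
    rl <- rle(as.integer(r$mask))
    list(bbox = r$bbox, area = r$area, centroid = r$centroid,
         mask_dims = dim(r$mask), mask_first = rl$values[1],
         mask_runs = rl$lengths,
         pattern = r$pattern, mitosis = r$mitosis)
  })
  jsonlite::write_json(list(width = img$spec$width, height = img$spec$height,
                            cells = cells),
                       path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' @rdname read_manifest
#' @export
read_truth_sidecar <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  cells <- js$cells
  n <- if (is.data.frame(cells)) nrow(cells) else length(cells)
  lapply(seq_len(n), function(i) {
    cl <- if (is.data.frame(cells)) lapply(cells, `[[`, i) else cells[[i]]
    runs <- unlist(cl$mask_runs)
    vals <- rep(c(cl$mask_first, 1 - cl$mask_first), length.out = length(runs))
    mask <- matrix(as.logical(inverse.rle(structure(
      list(lengths = as.integer(runs), values = as.integer(vals)), class = "rle"))),
      nrow = cl$mask_dims[1], ncol = cl$mask_dims[2])
    reg <- cell_region(mask, unlist(cl$bbox))
    reg$pattern <- cl$pattern
    reg$mitosis <- if (is.null(cl$mitosis) || is.na(cl$mitosis)) NA_character_ else cl$mitosis
    reg
  })
}
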