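#' Simulator configuration
#'
#' Parameters controlling the synthetic HEp-2 image generator. Textures are
#' synthesized as relative brightness fields in \[0, 1\] and scaled by the
#' per-intensity-class amplitude, so mean cell brightness is strictly
#' increasing over negative < intermediate < positive. Fluorescence lives in
#' the green channel; red and blue carry a small bleed fraction, matching
#' FITC imagery.
#'
#' @param amplitude Named vector of peak gray levels (0--255 scale) per
#'   intensity class. Negative cells stay under `negative_ceiling`.
#' @param negative_ceiling Maximum mean interior gray level of a
#'   negative-intensity cell.
#' @param background_level Constant background gray level added to images.
#' @param noise_sd Standard deviation of the additive Gaussian camera noise,
#'   in gray levels.
#' @param bleed Fraction of the green signal copied to red and blue.
#' @param width,height Default image size in pixels.
#' @param n_interphase,n_mitotic Default cell counts per generated image.
#' @param radius_range Interphase nucleus radius range (pixels).
#' @param mitotic_radius Mitotic cell body radius (pixels).
#' @param max_place_attempts Rejection-sampling attempts per cell before a
#'   density error is raised.
#' @param pattern_params Per-pattern texture parameters; see Details.
#'
#' @details Each staining pattern keys on one visual trait: homogeneous is a
#' uniform fill; fine speckled is dense 1--2 px granules; coarse speckled is
#' sparser 3--6 px granules; nucleolar is 1--5 large bright round blobs on a
#' dark interior; centromere is 30--60 discrete 2--3 px dots; nuclear dots is
#' 2--10 dots; nuclear pore complex is a bright rim with a dim interior. The
#' `lo`/`hi` entries are the two relative amplitude levels of each texture.
#'
#' @return A list of simulator parameters.
#' @export
hep2_sim_config <- function(amplitude = c(negative = 40, intermediate = 110, positive = 185),
                            negative_ceiling = 50,
                            background_level = 8,
                            noise_sd = 4,
                            bleed = 0.05,
                            width = 256, height = 256,
                            n_interphase = 6, n_mitotic = 1,
                            radius_range = c(13, 17),
                            mitotic_radius = 15,
                            max_place_attempts = 200,
                            pattern_params = NULL) {
  stopifnot(all(amplitude > 0), noise_sd >= 0, background_level >= 0)
  if (is.null(pattern_params)) {
    pattern_params <- list(
      homogeneous          = list(lo = 1.00, hi = 1.00),
      fine_speckled        = list(lo = 0.45, hi = 1.00, r_gran = c(0.5, 1.0), per_px = 1 / 5),
      coarse_speckled      = list(lo = 0.40, hi = 1.00, r_gran = c(1.5, 3.0), per_px = 1 / 40),
      nucleolar            = list(lo = 0.40, hi = 1.00, n = c(1, 5),  r_gran = c(4.0, 6.0)),
      centromere           = list(lo = 0.30, hi = 1.00, n = c(30, 60), r_gran = c(1.0, 1.5)),
      nuclear_dots         = list(lo = 0.32, hi = 1.00, n = c(2, 10), r_gran = c(1.5, 2.5)),
      nuclear_pore_complex = list(lo = 0.35, hi = 1.00, rim_width = 2.5)
    )
  }
  list(amplitude = amplitude, negative_ceiling = negative_ceiling,
       background_level = background_level, noise_sd = noise_sd, bleed = bleed,
       width = width, height = height,
       n_interphase = n_interphase, n_mitotic = n_mitotic,
       radius_range = radius_range, mitotic_radius = mitotic_radius,
       max_place_attempts = max_place_attempts,
       pattern_params = pattern_params)
}

#' Image specification
#'
#' Describes one synthetic image: size, cell counts, the staining pattern and
#' intensity class shared by its interphase cells, the mitotic fluorescence
#' type, noise parameters and the seed that makes generation reproducible.
#'
#' @param width,height Image size in pixels (at least 64).
#' @param n_interphase,n_mitotic Non-negative cell counts.
#' @param pattern Staining pattern label, see [hep2_patterns()].
#' @param intensity Intensity class label, see [hep2_intensities()].
#' @param mitosis_type Mitotic fluorescence type for the mitotic cells.
#' @param noise_sd,background_level Noise model, gray levels.
#' @param seed Integer seed.
#' @return An object of class `hep2_image_spec`.
#' @export
image_spec <- function(width, height, n_interphase, n_mitotic,
                       pattern = "homogeneous", intensity = "positive",
                       mitosis_type = "negative_mitosis",
                       noise_sd = 4, background_level = 8, seed = 1L) {
  if (width < 64 || height < 64) stop("width and height must be >= 64 pixels")
  if (n_interphase < 0 || n_mitotic < 0) stop("cell counts must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  assert_pattern(pattern); assert_intensity(intensity)
  assert_mitosis_type(mitosis_type)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_interphase = as.integer(n_interphase),
                 n_mitotic = as.integer(n_mitotic),
                 pattern = pattern, intensity = intensity,
                 mitosis_type = mitosis_type,
                 noise_sd = noise_sd, background_level = background_level,
                 seed = as.integer(seed)),
            class = "hep2_image_spec")
}

# Stamp disks of relative level `value` centred at `centers` (k x 2, row/col)
# onto `tex`, restricted to `mask`.
stamp_disks <- function(tex, mask, centers, radii, value) {
  n <- nrow(tex); m <- ncol(tex)
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 2)
  for (i in seq_len(nrow(centers))) {
    r0 <- centers[i, 1]; c0 <- centers[i, 2]; rad <- radii[i]
    rr <- max(1, floor(r0 - rad)):min(n, ceiling(r0 + rad))
    cc <- max(1, floor(c0 - rad)):min(m, ceiling(c0 + rad))
    d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
    hit <- d2 <= rad^2 & mask[rr, cc]
    sub <- tex[rr, cc]
    sub[hit] <- value
    tex[rr, cc] <- sub
  }
  tex
}

# Relative-brightness texture for one pattern over an elliptical mask.
# `u` is the normalized elliptical radius (1 on the nucleus boundary).
pattern_texture <- function(pattern, mask, u, cfg) {
  pp <- cfg$pattern_params[[pattern]]
  area <- sum(mask)
  tex <- matrix(0, nrow(mask), ncol(mask))
  tex[mask] <- pp$lo
  inside <- which(mask & u < 0.9, arr.ind = TRUE)   # keep structures off the rim
  pick_centers <- function(k) inside[sample.int(nrow(inside), min(k, nrow(inside))), , drop = FALSE]
  if (pattern %in% c("fine_speckled", "coarse_speckled")) {
    k <- max(1L, round(area * pp$per_px))
    tex <- stamp_disks(tex, mask, pick_centers(k),
                       stats::runif(k, pp$r_gran[1], pp$r_gran[2]), pp$hi)
  } else if (pattern %in% c("centromere", "nuclear_dots")) {
    k <- if (pattern == "centromere") {
      min(pp$n[2], max(pp$n[1], round(area / 11)))
    } else sample(pp$n[1]:pp$n[2], 1)
    tex <- stamp_disks(tex, mask, pick_centers(k),
                       stats::runif(k, pp$r_gran[1], pp$r_gran[2]), pp$hi)
  } else if (pattern == "nucleolar") {
    k <- sample(pp$n[1]:pp$n[2], 1)
    amax <- max(u[mask]) # ~1; blob centres drawn from the deep interior
    deep <- which(mask & u < 0.55, arr.ind = TRUE)
    if (nrow(deep) == 0) deep <- inside
    ctr <- deep[sample.int(nrow(deep), min(k, nrow(deep))), , drop = FALSE]
    tex <- stamp_disks(tex, mask, ctr,
                       stats::runif(nrow(ctr), pp$r_gran[1], pp$r_gran[2]), pp$hi)
  } else if (pattern == "nuclear_pore_complex") {
    rim <- mask & u > (1 - pp$rim_width / sqrt(area / pi))
    tex[rim] <- pp$hi
  }
  # homogeneous: flat fill at lo == hi
  tex
}

# Multiplicative shot-noise texture roughness, clipped to [0, 1].
roughen <- function(tex, mask, sd = 0.05) {
  tex[mask] <- pmin(1, pmax(0, tex[mask] * (1 + stats::rnorm(sum(mask), 0, sd))))
  tex
}

# Negative sera show faint, flattened staining: compress the texture contrast
# upward so even dark-interior patterns stay visible but dim.
apply_intensity <- function(tex, mask, intensity, cfg) {
  t <- tex
  if (identical(intensity, "negative")) t[mask] <- 0.6 + 0.4 * t[mask]
  t * unname(cfg$amplitude[[intensity]])
}

#' Generate one interphase cell patch
#'
#' Renders an elliptical nucleus whose interior texture follows the rule for
#' the requested staining pattern, scaled to the requested intensity class.
#' Deterministic given `seed`.
#'
#' @param pattern Staining pattern label.
#' @param intensity Intensity class label.
#' @param radius Nucleus semi-major axis in pixels (>= 8).
#' @param seed Integer seed.
#' @param config Simulator configuration, see [hep2_sim_config()].
#' @return A list with `patch` (gray-level matrix, 0 outside the nucleus),
#'   `mask` (logical matrix), and the generating arguments.
#' @examples
#' cell <- generate_cell("centromere", "positive", radius = 20, seed = 1)
#' mean(cell$patch[cell$mask])
#' @export
generate_cell <- function(pattern, intensity, radius, seed, config = hep2_sim_config()) {
  assert_pattern(pattern); assert_intensity(intensity)
  if (radius < 8) stop("radius must be >= 8 pixels")
  with_seed(seed, {
    n <- 2L * ceiling(radius + 2) + 1L
    ctr <- (n + 1) / 2
    a <- radius
    b <- radius * stats::runif(1, 0.8, 1)
    th <- stats::runif(1, 0, pi)
    dr <- row(matrix(0, n, n)) - ctr
    dc <- col(matrix(0, n, n)) - ctr
    x <- dc * cos(th) + dr * sin(th)
    y <- -dc * sin(th) + dr * cos(th)
    u <- sqrt((x / a)^2 + (y / b)^2)
    mask <- u <= 1
    tex <- pattern_texture(pattern, mask, u, config)
    tex <- roughen(tex, mask)
    patch <- apply_intensity(tex, mask, intensity, config)
    list(patch = patch, mask = mask, pattern = pattern, intensity = intensity,
         radius = radius, seed = as.integer(seed))
  })
}

#' Generate one mitotic cell patch
#'
#' A mitotic cell is a rounded fluorescent body with a compact collapsed
#' chromosome mass at its centre. In a negative mitosis the body is bright
#' and the chromosome mass dark; in a positive mitosis the roles are
#' reversed. Deterministic given `seed`.
#'
#' @param mitosis_type `"positive_mitosis"` or `"negative_mitosis"`.
#' @param pattern Staining pattern of the well (mildly modulates the body
#'   texture roughness; the body/mass contrast is what defines the type).
#' @param seed Integer seed.
#' @param radius Cell body radius in pixels.
#' @param intensity Intensity class used for amplitude scaling.
#' @param config Simulator configuration.
#' @return A list with `patch`, `mask` (whole cell), `body_mask`
#'   (cell minus chromosome mass) and `mass_mask`.
#' @export
generate_mitotic_cell <- function(mitosis_type, pattern, seed, radius = 15,
                                  intensity = "positive",
                                  config = hep2_sim_config()) {
  assert_mitosis_type(mitosis_type); assert_pattern(pattern)
  assert_intensity(intensity)
  with_seed(seed, {
    n <- 2L * ceiling(radius + 2) + 1L
    ctr <- (n + 1) / 2
    b <- radius * stats::runif(1, 0.85, 1)
    dr <- row(matrix(0, n, n)) - ctr
    dc <- col(matrix(0, n, n)) - ctr
    u <- sqrt((dc / radius)^2 + (dr / b)^2)
    mask <- u <= 1
    # chromosome mass: compact central blob, slightly jittered
    mr <- 0.45 * radius
    joff <- stats::runif(2, -0.1 * radius, 0.1 * radius)
    md <- sqrt((dr - joff[1])^2 + (dc - joff[2])^2)
    mass_mask <- mask & md <= mr
    body_mask <- mask & !mass_mask
    lv <- if (identical(mitosis_type, "negative_mitosis")) c(body = 0.90, mass = 0.15)
          else c(body = 0.35, mass = 1.00)
    tex <- matrix(0, n, n)
    tex[body_mask] <- lv[["body"]]
    tex[mass_mask] <- lv[["mass"]]
    tex <- roughen(tex, mask)
    patch <- apply_intensity(tex, mask, intensity, config)
    list(patch = patch, mask = mask, body_mask = body_mask,
         mass_mask = mass_mask, mitosis_type = mitosis_type,
         pattern = pattern, seed = as.integer(seed))
  })
}

#' Generate one synthetic HEp-2 image
#'
#' Places the requested interphase and mitotic cells at non-overlapping
#' positions (rejection sampling with a bounded number of attempts), adds
#' the constant background and Gaussian camera noise, and records the
#' ground truth of every placed cell. Fluorescence is written to the green
#' channel; red and blue receive a small bleed fraction.
#'
#' @param spec An [image_spec()].
#' @param config Simulator configuration.
#' @return An object of class `hep2_synthetic_image`: a list with `pixels`
#'   (height x width x 3 integer array, 0--255), `truth_cells` (list of
#'   [cell_region()] objects annotated with `pattern` and `mitosis`) and
#'   `spec`.
#' @export
generate_image <- function(spec, config = hep2_sim_config()) {
  stopifnot(inherits(spec, "hep2_image_spec"))
  h <- spec$height; w <- spec$width
  n_cells <- spec$n_interphase + spec$n_mitotic
  seeds <- if (n_cells > 0) derive_seeds(spec$seed, n_cells + 1L) else derive_seeds(spec$seed, 1L)
  green <- matrix(spec$background_level, h, w)
  occupied <- matrix(FALSE, h, w)
  truth <- list()
  place <- function(green, occupied, patch, mask, seed_i) {
    n <- nrow(mask)
    rad <- (n - 1) / 2
    ok <- FALSE
    for (att in seq_len(config$max_place_attempts)) {
      # keep a 3-px margin so cells never touch the frame border
      r0 <- sample.int(h - n - 5L, 1L) + 3L
      c0 <- sample.int(w - n - 5L, 1L) + 3L
      rr <- r0:(r0 + n - 1L); cc <- c0:(c0 + n - 1L)
      if (!any(occupied[rr, cc] & mask)) { ok <- TRUE; break }
    }
    if (!ok) {
      stop(sprintf(paste0("could not place a cell after %d attempts: the ",
                          "requested cell density exceeds what fits in a ",
                          "%dx%d frame"), config$max_place_attempts, w, h))
    }
    g <- green[rr, cc]
    g[mask] <- g[mask] + patch[mask]
    green[rr, cc] <- g
    occupied[rr, cc] <- occupied[rr, cc] | mask
    list(green = green, occupied = occupied, rows = rr, cols = cc)
  }
  with_seed(seeds[length(seeds)], {
    idx <- 0L
    for (i in seq_len(spec$n_interphase)) {
      idx <- idx + 1L
      radius <- stats::runif(1, config$radius_range[1], config$radius_range[2])
      cell <- generate_cell(spec$pattern, spec$intensity, radius, seeds[idx], config)
      pl <- place(green, occupied, cell$patch, cell$mask, seeds[idx])
      green <- pl$green; occupied <- pl$occupied
      reg <- region_from_placed_mask(cell$mask, pl$rows, pl$cols)
      reg$pattern <- spec$pattern; reg$mitosis <- NA_character_
      truth[[idx]] <- reg
    }
    for (i in seq_len(spec$n_mitotic)) {
      idx <- idx + 1L
      mc <- generate_mitotic_cell(spec$mitosis_type, spec$pattern, seeds[idx],
                                  radius = config$mitotic_radius,
                                  intensity = spec$intensity, config = config)
      pl <- place(green, occupied, mc$patch, mc$mask, seeds[idx])
      green <- pl$green; occupied <- pl$occupied
      reg <- region_from_placed_mask(mc$mask, pl$rows, pl$cols)
      reg$pattern <- spec$pattern; reg$mitosis <- spec$mitosis_type
      truth[[idx]] <- reg
    }
    if (spec$noise_sd > 0) green <- green + stats::rnorm(h * w, 0, spec$noise_sd)
    green <- matrix(pmin(255, pmax(0, round(green))), h, w)
    bleed <- round(config$bleed * green)
    pixels <- array(0L, dim = c(h, w, 3))
    pixels[, , 1] <- bleed
    pixels[, , 2] <- green
    pixels[, , 3] <- bleed
    storage.mode(pixels) <- "integer"
    structure(list(pixels = pixels, truth_cells = truth, spec = spec),
              class = "hep2_synthetic_image")
  })
}

# Build a cell_region from a patch-local mask placed at full-frame rows/cols.
region_from_placed_mask <- function(mask, rows, cols) {
  hit <- which(mask, arr.ind = TRUE)
  rr <- rows[hit[, 1]]; cc <- cols[hit[, 2]]
  r0 <- min(rr); r1 <- max(rr); c0 <- min(cc); c1 <- max(cc)
  crop <- mask[rows %in% r0:r1, cols %in% c0:c1, drop = FALSE]
  cell_region(crop, bbox = c(r0 - 1L, c0 - 1L, r1, c1))
}

#' @export
print.hep2_synthetic_image <- function(x, ...) {
  cat(sprintf("synthetic HEp-2 image %dx%d, %d truth cells (%s, %s)\n",
              x$spec$width, x$spec$height, length(x$truth_cells),
              x$spec$pattern, x$spec$intensity))
  invisible(x)
}
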