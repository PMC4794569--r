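#' Gray-level quantization
#'
#' Re-bins a gray-level raster with values in \[0, 255\] to one of the four
#' descriptor quantization levels. The bin index is
#' `floor(v * levels / 256)`; at 256 levels the mapping is the identity for
#' integer input.
#'
#' @param gray Numeric matrix with values in \[0, 255\].
#' @param levels One of 256, 128, 64, 32.
#' @return Integer matrix with values in `[0, levels)`.
#' @examples
#' quantize(matrix(100, 2, 2), 32)   # all 12
#' @export
quantize <- function(gray, levels) {
  if (!levels %in% quantization_levels()) {
    stop("levels must be one of ", paste(quantization_levels(), collapse = ", "))
  }
  if (any(gray < 0 | gray > 255)) stop("gray values must lie in [0, 255]")
  q <- floor(gray * levels / 256)
  storage.mode(q) <- "integer"
  q
}

#' @rdname quantize
#' @export
quantization_levels <- function() c(256L, 128L, 64L, 32L)

# Shannon entropy (bits) of a count/weight vector; empty bins contribute 0.
shannon_entropy <- function(counts) {
  s <- sum(counts)
  if (s <= 0) return(0)
  p <- counts[counts > 0] / s
  -sum(p * log2(p))
}

# Central-difference gradients with one-sided differences at the borders.
raster_gradients <- function(m) {
  n <- nrow(m); k <- ncol(m)
  gr <- matrix(0, n, k); gc <- matrix(0, n, k)
  if (n >= 2) {
    gr[2:(n - 1), ] <- (m[3:n, , drop = FALSE] - m[1:(n - 2), , drop = FALSE]) / 2
    gr[1, ] <- m[2, ] - m[1, ]
    gr[n, ] <- m[n, ] - m[n - 1, ]
  }
  if (k >= 2) {
    gc[, 2:(k - 1)] <- (m[, 3:k, drop = FALSE] - m[, 1:(k - 2), drop = FALSE]) / 2
    gc[, 1] <- m[, 2] - m[, 1]
    gc[, k] <- m[, k] - m[, k - 1]
  }
  list(dr = gr, dc = gc, mag = sqrt(gr^2 + gc^2))
}

# Boundary pixels of a mask: foreground pixels with fewer than four
# 4-connected foreground neighbours.
mask_boundary <- function(mask) {
  n <- nrow(mask); k <- ncol(mask)
  pad <- matrix(FALSE, n + 2, k + 2)
  pad[2:(n + 1), 2:(k + 1)] <- mask
  full <- pad[1:n, 2:(k + 1)] & pad[3:(n + 2), 2:(k + 1)] &
          pad[2:(n + 1), 1:k] & pad[2:(n + 1), 3:(k + 2)]
  mask & !full
}

#' Intensity-based features (9)
#'
#' Statistics of the quantized gray levels over a cell mask: mean, standard
#' deviation, their ratio, Shannon entropy of the level histogram (bits),
#' moment of inertia of the intensity distribution about its weighted
#' centroid, skewness, excess kurtosis, entropy of the gradient-magnitude
#' histogram restricted to the mask boundary pixels, and the median level.
#' Skewness and kurtosis are defined as 0 for a constant region; the
#' standard-deviation/mean ratio is 0 when the mean is 0.
#'
#' @param quantized Integer raster (a quantized patch).
#' @param mask Logical matrix, same size, with at least one `TRUE` pixel.
#' @param grad_bins Number of bins of the boundary-gradient histogram.
#' @return Named numeric vector of length 9.
#' @export
intensity_features <- function(quantized, mask, grad_bins = 16L) {
  if (!any(mask)) stop("empty mask")
  x <- as.numeric(quantized[mask])
  mu <- mean(x)
  sdev <- stats::sd(x)
  if (is.na(sdev)) sdev <- 0
  m2 <- mean((x - mu)^2)
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 - 3 else 0
  ent <- shannon_entropy(table(x))
  # moment of inertia about the intensity-weighted centroid
  px <- which(mask, arr.ind = TRUE)
  wsum <- sum(x)
  moi <- if (wsum > 0) {
    rc <- sum(x * px[, 1]) / wsum
    cc <- sum(x * px[, 2]) / wsum
    sum(x * ((px[, 1] - rc)^2 + (px[, 2] - cc)^2)) / wsum
  } else 0
  bnd <- mask_boundary(mask)
  gmag <- raster_gradients(quantized)$mag[bnd]
  cge <- gradient_histogram_entropy(gmag, grad_bins)
  c(mean = mu, sd = sdev, sd_over_mean = if (mu > 0) sdev / mu else 0,
    entropy = ent, moment_inertia = moi, skewness = skew, kurtosis = kurt,
    contour_gradient_entropy = cge, median = stats::median(x))
}

gradient_histogram_entropy <- function(mags, bins) {
  if (length(mags) == 0) return(0)
  mx <- max(mags)
  if (mx <= 0) return(0)
  idx <- pmin(floor(mags / mx * bins), bins - 1)
  shannon_entropy(tabulate(idx + 1, nbins = bins))
}

#' Geometry-based features (8)
#'
#' Radial and elliptical description of a single connected region: mean,
#' standard deviation and maximum of the centroid-to-contour radii and the
#' sd/mean ratio; circularity `4*pi*A/P^2`; anisotropy
#' `1 - minor/major` axis ratio of the second-moment ellipse; the
#' box-counting (fractal) index of the contour (box sizes 2, 4, 8, 16, 32);
#' and the eccentricity of the fitted ellipse.
#'
#' @param mask Logical matrix holding one connected region of area >= 4 px.
#' @param contour Optional ordered contour (n x 2, 0-based); traced from the
#'   mask when missing.
#' @return Named numeric vector of length 8.
#' @export
geometry_features <- function(mask, contour = NULL) {
  if (sum(mask) < 4) stop("degenerate region: area < 4 px")
  if (is.null(contour)) contour <- trace_contour(mask)
  px <- which(mask, arr.ind = TRUE) - 1  # 0-based to match the contour
  ctr <- colMeans(px)
  radii <- sqrt((contour[, 1] - ctr[1])^2 + (contour[, 2] - ctr[2])^2)
  rmean <- mean(radii)
  rsd <- stats::sd(radii); if (is.na(rsd)) rsd <- 0
  per <- contour_length(contour)
  area <- nrow(px)
  mom <- second_moment_ellipse(px)
  c(radius_mean = rmean, radius_sd = rsd, radius_max = max(radii),
    radius_sd_over_mean = if (rmean > 0) rsd / rmean else 0,
    circularity = if (per > 0) 4 * pi * area / per^2 else 0,
    anisotropy = 1 - mom$axis_ratio,
    fractal_index = box_counting_dimension(contour),
    eccentricity = mom$eccentricity)
}

# Closed path length of an ordered contour; diagonal steps count sqrt(2).
contour_length <- function(contour) {
  n <- nrow(contour)
  if (n < 2) return(0)
  nxt <- rbind(contour[-1, , drop = FALSE], contour[1, , drop = FALSE])
  sum(sqrt(rowSums((nxt - contour)^2)))
}

# Second-moment (best-fit) ellipse of a pixel set: axis ratio minor/major
# and eccentricity. Half-pixel variance regularization keeps 1-px-thin
# shapes finite.
second_moment_ellipse <- function(px) {
  v <- stats::cov(px) * (nrow(px) - 1) / nrow(px) + diag(1 / 12, 2)
  ev <- eigen(v, symmetric = TRUE)$values
  ratio <- sqrt(ev[2] / ev[1])
  list(axis_ratio = ratio, eccentricity = sqrt(1 - ev[2] / ev[1]),
       major_axis = 4 * sqrt(ev[1]))
}

# Least-squares slope of log N(s) over log(1/s) for grid sizes s.
box_counting_dimension <- function(points, sizes = c(2, 4, 8, 16, 32)) {
  if (nrow(points) < 2) return(0)
  anchor <- apply(points, 2, min)
  n_boxes <- vapply(sizes, function(s) {
    nrow(unique(floor(sweep(points, 2, anchor) / s)))
  }, 0)
  stats::coef(stats::lm(log(n_boxes) ~ log(1 / sizes)))[[2]]
}

#' Shape and morphology features (8)
#'
#' Whole-mask morphology: area, perimeter (sum of 8-connected outer contour
#' lengths, diagonal steps counting sqrt(2)), convex area (pixels inside the
#' convex hull of the mask), convex deficiency, solidity, compactness
#' `P^2/A`, roundness `4A/(pi * major_axis^2)` with the major axis from the
#' second-moment ellipse, and the Euler number (8-connected components minus
#' 4-connected holes).
#'
#' @param mask Logical matrix, nonempty.
#' @return Named numeric vector of length 8.
#' @export
shape_features <- function(mask) {
  if (!any(mask)) stop("empty mask")
  area <- sum(mask)
  px <- which(mask, arr.ind = TRUE)
  per <- total_perimeter(mask)
  ca <- convex_pixel_area(px)
  mom <- second_moment_ellipse(px - 1)
  c(area = area, perimeter = per, convex_area = ca,
    convex_deficiency = (ca - area) / ca, solidity = area / ca,
    compactness = if (area > 0) per^2 / area else 0,
    roundness = 4 * area / (pi * mom$major_axis^2),
    euler_number = euler_number(mask))
}

# Sum of outer-contour path lengths over all connected components.
total_perimeter <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  ocs <- EBImage::ocontour(EBImage::Image(lab))
  sum(vapply(ocs, contour_length, 0))
}

# Pixel count of the convex hull of a pixel set (centers inside or on the
# hull polygon), via half-plane tests on the hull edges.
convex_pixel_area <- function(px) {
  if (nrow(px) <= 2) return(nrow(px))
  hull <- grDevices::chull(px[, 2], px[, 1])   # chull takes x = col, y = row
  hv <- px[hull, , drop = FALSE]
  nh <- nrow(hv)
  if (nh <= 2) return(nrow(unique(px)))
  rr <- min(px[, 1]):max(px[, 1]); cc <- min(px[, 2]):max(px[, 2])
  cand <- cbind(rep(rr, times = length(cc)), rep(cc, each = length(rr)))
  inside <- rep(TRUE, nrow(cand))
  nxt <- c(2:nh, 1)
  orient <- sign(sum(hv[, 1] * hv[nxt, 2] - hv[nxt, 1] * hv[, 2]))
  if (orient == 0) orient <- 1
  for (i in seq_len(nh)) {
    a <- hv[i, ]; b <- hv[nxt[i], ]
    cross <- (b[1] - a[1]) * (cand[, 2] - a[2]) - (b[2] - a[2]) * (cand[, 1] - a[1])
    inside <- inside & orient * cross >= -1e-9
    if (!any(inside)) break
  }
  sum(inside)
}

# Euler number via 2x2 quad counts (Gray's formula for 8-connected
# foreground / 4-connected background): E = (Q1 - Q3 - 2*Qd) / 4.
euler_number <- function(mask) {
  n <- nrow(mask); k <- ncol(mask)
  pad <- matrix(0L, n + 2, k + 2)
  pad[2:(n + 1), 2:(k + 1)] <- mask * 1L
  a <- pad[1:(n + 1), 1:(k + 1)]
  b <- pad[1:(n + 1), 2:(k + 2)]
  d <- pad[2:(n + 2), 1:(k + 1)]
  e <- pad[2:(n + 2), 2:(k + 2)]
  s <- a + b + d + e
  q1 <- sum(s == 1)
  q3 <- sum(s == 3)
  qd <- sum(s == 2 & ((a == 1 & e == 1) | (b == 1 & d == 1)))
  (q1 - q3 - 2 * qd) / 4
}

#' Gradient-descriptor features (2)
#'
#' Entropy (bits) of two gradient histograms over the masked pixels: a
#' 9-bin unsigned-orientation histogram (0--180 degrees) weighted by
#' gradient magnitude (HOG), and a 16-bin histogram of gradient magnitudes
#' scaled to \[0, max magnitude\] (HAG). Both are 0 by convention when every
#' gradient vanishes.
#'
#' @param quantized Integer raster.
#' @param mask Logical matrix with an extent of at least 2 x 2.
#' @param hog_bins,hag_bins Histogram resolutions.
#' @return Named numeric vector `c(hog_entropy, hag_entropy)`.
#' @export
descriptor_features <- function(quantized, mask, hog_bins = 9L, hag_bins = 16L) {
  px <- which(mask, arr.ind = TRUE)
  if (nrow(px) == 0 || diff(range(px[, 1])) < 1 || diff(range(px[, 2])) < 1) {
    stop("mask must span at least a 2x2 extent")
  }
  g <- raster_gradients(quantized)
  mag <- g$mag[mask]
  hag <- gradient_histogram_entropy(mag, hag_bins)
  live <- mag > 0
  hog <- if (!any(live)) 0 else {
    ang <- (atan2(g$dr[mask][live], g$dc[mask][live]) * 180 / pi) %% 180
    bin <- pmin(floor(ang / (180 / hog_bins)), hog_bins - 1)
    w <- vapply(seq_len(hog_bins) - 1, function(b) sum(mag[live][bin == b]), 0)
    shannon_entropy(w)
  }
  c(hog_entropy = hog, hag_entropy = hag)
}

#' Names of the 108 descriptor entries
#'
#' Quantization-level-major ordering (256, 128, 64, 32); within a level the
#' groups run intensity (9), geometry (8), shape (8), descriptors (2), each
#' in its documented internal order. Names follow
#' `"L{levels}.{group}.{feature}"`.
#'
#' @return Character vector of length 108.
#' @export
hep2_feature_names <- function() {
  int <- paste0("int.", c("mean", "sd", "sd_over_mean", "entropy",
                          "moment_inertia", "skewness", "kurtosis",
                          "contour_gradient_entropy", "median"))
  geo <- paste0("geom.", c("radius_mean", "radius_sd", "radius_max",
                           "radius_sd_over_mean", "circularity", "anisotropy",
                           "fractal_index", "eccentricity"))
  shp <- paste0("shape.", c("area", "perimeter", "convex_area",
                            "convex_deficiency", "solidity", "compactness",
                            "roundness", "euler_number"))
  des <- paste0("desc.", c("hog_entropy", "hag_entropy"))
  unlist(lapply(quantization_levels(), function(L) {
    paste0("L", L, ".", c(int, geo, shp, des))
  }))
}

#' Extract the 108-value cell descriptor
#'
#' The cell's green-channel patch is quantized at 256, 128, 64 and 32 gray
#' levels; at each level the 27 features (9 intensity, 8 geometry, 8 shape,
#' 2 descriptor) are computed. Geometry and shape use the level-dependent
#' mask — the region mask restricted to pixels quantized above level 0 — so
#' they legitimately vary across quantizations; if that mask degenerates
#' (fewer than 8 pixels) the full region mask is used instead. Geometry is
#' computed on the largest connected component of the level mask.
#'
#' @param image RGB array (0--255), gray matrix or `hep2_synthetic_image`.
#' @param region A [cell_region()] inside the image bounds.
#' @return Named numeric vector of length 108 (see [hep2_feature_names()]).
#' @export
extract_cell_features <- function(image, region) {
  g <- as_green_matrix(image)
  b <- region$bbox
  if (b[1] < 0 || b[2] < 0 || b[3] > nrow(g) || b[4] > ncol(g)) {
    stop("region lies outside the image bounds")
  }
  patch <- g[(b[1] + 1):b[3], (b[2] + 1):b[4], drop = FALSE]
  mask <- region$mask
  out <- unlist(lapply(quantization_levels(), function(L) {
    q <- quantize(patch, L)
    lmask <- mask & q > 0
    if (sum(lmask) < 8) lmask <- mask
    lab <- EBImage::bwlabel(lmask * 1)
    areas <- tabulate(lab[lab > 0])
    comp <- lab == which.max(areas)
    c(intensity_features(q, lmask),
      geometry_features(comp),
      shape_features(lmask),
      descriptor_features(q, lmask))
  }))
  names(out) <- hep2_feature_names()
  if (!all(is.finite(out))) stop("non-finite feature value produced")
  out
}

#' Write a per-cell feature table
#'
#' One row per cell: `well_id`, `image`, `region_id`, then the 108 named
#' descriptor columns.
#'
#' @param rows A data.frame in that layout (see [extract_cell_features()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(rows, path) {
  stopifnot(all(c("well_id", "image", "region_id") %in% names(rows)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
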