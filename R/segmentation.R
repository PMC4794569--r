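#' Cell region
#'
#' One segmented (or ground-truth) cell: a binary mask stored cropped to its
#' tight bounding box, the box itself in 0-based half-open image coordinates
#' `(row0, col0, row1, col1)`, the mask centroid in fractional 0-based
#' `(row, col)` pixels, the ordered closed outer contour, and the pixel area.
#'
#' @param mask Logical matrix cropped to the bounding box (all-`FALSE` rows
#'   or columns are not allowed: the box must be tight).
#' @param bbox Integer vector `(row0, col0, row1, col1)`, 0-based, half-open,
#'   locating the mask in the full image frame.
#' @return An object of class `hep2_cell_region`.
#' @export
cell_region <- function(mask, bbox) {
  stopifnot(is.matrix(mask), any(mask))
  bbox <- as.integer(bbox)
  stopifnot(length(bbox) == 4, bbox[3] - bbox[1] == nrow(mask),
            bbox[4] - bbox[2] == ncol(mask))
  rs <- rowSums(mask); cs <- colSums(mask)
  if (rs[1] == 0 || rs[length(rs)] == 0 || cs[1] == 0 || cs[length(cs)] == 0) {
    stop("bbox does not tightly bound the mask")
  }
  px <- which(mask, arr.ind = TRUE)
  centroid <- c(mean(px[, 1]) - 1 + bbox[1], mean(px[, 2]) - 1 + bbox[2])
  contour <- trace_contour(mask, offset = bbox[c(1, 2)])
  structure(list(mask = mask, bbox = bbox, centroid = centroid,
                 contour = contour, area = sum(mask)),
            class = "hep2_cell_region")
}

#' @export
print.hep2_cell_region <- function(x, ...) {
  cat(sprintf("cell region: area %d px, bbox [%d,%d)x[%d,%d), centroid (%.1f, %.1f)\n",
              x$area, x$bbox[1], x$bbox[3], x$bbox[2], x$bbox[4],
              x$centroid[1], x$centroid[2]))
  invisible(x)
}

# Ordered closed outer contour (0-based, full-frame (row, col)) of the
# largest connected component of a binary mask, via EBImage boundary
# tracing. Returns an n x 2 matrix.
trace_contour <- function(mask, offset = c(0L, 0L)) {
  lab <- EBImage::bwlabel(mask * 1)
  if (max(lab) == 0) return(matrix(numeric(0), 0, 2))
  if (max(lab) > 1) {
    areas <- tabulate(lab[lab > 0])
    keep <- which.max(areas)
  } else keep <- 1L
  oc <- EBImage::ocontour(EBImage::Image((lab == keep) * 1))[[1]]
  # ocontour yields 0-based (dim1, dim2) = (row, col) for a plain matrix
  sweep(oc, 2, offset, "+")
}

# Full-frame logical mask of a region within an h x w frame.
region_full_mask <- function(region, h, w) {
  m <- matrix(FALSE, h, w)
  b <- region$bbox
  m[(b[1] + 1):b[3], (b[2] + 1):b[4]] <- region$mask
  m
}

#' Segment cells in a fluorescence image
#'
#' Classical pipeline on the green channel: Gaussian smoothing, Otsu
#' thresholding, morphological opening, and watershed on the distance
#' transform to split touching cells. Regions smaller than `min_area` or
#' (optionally) touching the image border are dropped. Output is sorted by
#' the `(row0, col0)` corner of the bounding box.
#'
#' @param image Either an `hep2_synthetic_image`, an `h x w x 3` RGB array
#'   (values 0--255 or 0--1), or a gray-level matrix.
#' @param config List of parameters: `sigma` (smoothing sd, px), `min_area`
#'   (px), `drop_border` (logical), `opening_radius` (px), `watershed_tol`.
#' @return A list of [cell_region()] objects (empty for a featureless image).
#' @examples
#' img <- generate_image(image_spec(128, 128, 3, 0, seed = 1))
#' length(segment_cells(img))
#' @export
segment_cells <- function(image, config = segmentation_config()) {
  g <- as_green_matrix(image)
  if (length(g) == 0) stop("empty image")
  if (diff(range(g)) < 1e-9) return(list())
  g01 <- g / 255
  sm <- EBImage::gblur(g01, sigma = config$sigma)
  th <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  bin <- sm > th
  # featureless scenes: smoothed noise yields a weak Otsu split; require a
  # minimum foreground/background contrast (gray levels) to proceed
  if (!any(bin) || all(bin) ||
      (mean(sm[bin]) - mean(sm[!bin])) * 255 < config$min_contrast) {
    return(list())
  }
  if (config$opening_radius > 0) {
    brush <- EBImage::makeBrush(2 * config$opening_radius + 1, shape = "disc")
    bin <- EBImage::opening(bin, brush)
  }
  bin <- as_pixel_data(bin) > 0
  if (!any(bin)) return(list())
  dm <- EBImage::distmap(EBImage::Image(bin * 1))
  lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = config$watershed_tol, ext = 1))
  regions <- list()
  for (k in seq_len(max(lab))) {
    px <- which(lab == k, arr.ind = TRUE)
    if (nrow(px) < config$min_area) next
    r0 <- min(px[, 1]); r1 <- max(px[, 1]); c0 <- min(px[, 2]); c1 <- max(px[, 2])
    if (config$drop_border &&
        (r0 == 1 || c0 == 1 || r1 == nrow(g) || c1 == ncol(g))) next
    crop <- matrix(FALSE, r1 - r0 + 1, c1 - c0 + 1)
    crop[cbind(px[, 1] - r0 + 1, px[, 2] - c0 + 1)] <- TRUE
    regions[[length(regions) + 1]] <- cell_region(crop, c(r0 - 1L, c0 - 1L, r1, c1))
  }
  if (length(regions) > 1) {
    ord <- order(vapply(regions, function(r) r$bbox[1], 0),
                 vapply(regions, function(r) r$bbox[2], 0))
    regions <- regions[ord]
  }
  regions
}

#' @rdname segment_cells
#' @param sigma,min_area,drop_border,opening_radius,watershed_tol,min_contrast
#'   See above.
#' @export
segmentation_config <- function(sigma = 2, min_area = 200, drop_border = TRUE,
                                opening_radius = 2, watershed_tol = 2,
                                min_contrast = 12) {
  list(sigma = sigma, min_area = min_area, drop_border = drop_border,
       opening_radius = opening_radius, watershed_tol = watershed_tol,
       min_contrast = min_contrast)
}

as_pixel_data <- function(x) if (inherits(x, "Image")) EBImage::imageData(x) else x

# Accept synthetic images, RGB arrays (0-255 or 0-1) or plain matrices and
# return the green channel on the 0-255 scale.
as_green_matrix <- function(image) {
  if (inherits(image, "hep2_synthetic_image")) image <- image$pixels
  if (is.array(image) && length(dim(image)) == 3) image <- image[, , 2]
  if (!is.matrix(image)) stop("image must be a matrix, RGB array or hep2_synthetic_image")
  if (max(image) <= 1 && min(image) >= 0 && !all(image %in% c(0, 1))) image <- image * 255
  image
}

#' Match predicted regions to ground truth
#'
#' Greedy one-to-one matching by decreasing mask overlap; a pair matches when
#' its intersection-over-union is at least `iou_threshold`.
#'
#' @param predicted,truth Lists of [cell_region()] from the same image frame.
#' @param iou_threshold Minimum IoU for a match (default 0.5).
#' @return A list with `pairs` (matrix of predicted index, truth index, IoU),
#'   `matched`, `missed`, `spurious` counts.
#' @export
match_regions <- function(predicted, truth, iou_threshold = 0.5) {
  np <- length(predicted); nt <- length(truth)
  if (np == 0 || nt == 0) {
    return(list(pairs = matrix(numeric(0), 0, 3,
                               dimnames = list(NULL, c("predicted", "truth", "iou"))),
                matched = 0L, missed = nt, spurious = np))
  }
  iou <- matrix(0, np, nt)
  for (i in seq_len(np)) for (j in seq_len(nt)) {
    iou[i, j] <- region_iou(predicted[[i]], truth[[j]])
  }
  pairs <- NULL
  used_p <- logical(np); used_t <- logical(nt)
  repeat {
    iou2 <- iou
    iou2[used_p, ] <- -1; iou2[, used_t] <- -1
    best <- which.max(iou2)
    if (iou2[best] < iou_threshold) break
    i <- (best - 1) %% np + 1; j <- (best - 1) %/% np + 1
    pairs <- rbind(pairs, c(i, j, iou[i, j]))
    used_p[i] <- TRUE; used_t[j] <- TRUE
    if (all(used_p) || all(used_t)) break
  }
  if (is.null(pairs)) {
    pairs <- matrix(numeric(0), 0, 3)
  }
  colnames(pairs) <- c("predicted", "truth", "iou")
  list(pairs = pairs, matched = nrow(pairs),
       missed = nt - nrow(pairs), spurious = np - nrow(pairs))
}

# IoU of two regions via their bounding boxes (no full-frame allocation).
region_iou <- function(a, b) {
  r0 <- max(a$bbox[1], b$bbox[1]); c0 <- max(a$bbox[2], b$bbox[2])
  r1 <- min(a$bbox[3], b$bbox[3]); c1 <- min(a$bbox[4], b$bbox[4])
  if (r1 <= r0 || c1 <= c0) return(0)
  sub <- function(reg) {
    reg$mask[(r0 - reg$bbox[1] + 1):(r1 - reg$bbox[1]),
             (c0 - reg$bbox[2] + 1):(c1 - reg$bbox[2]), drop = FALSE]
  }
  inter <- sum(sub(a) & sub(b))
  inter / (a$area + b$area - inter)
}
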