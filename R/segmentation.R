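# Segmentation of spread cells in phase-contrast frames:
# Sobel gradient -> threshold -> dilate/fill/erode -> convex hull per component.
#
# Pixel coordinate convention (fixed; required for bit-exact tests):
# 0-based, x rightward (matrix column - 1), y downward (matrix row - 1),
# pixel centers at integer coordinates. Matrices are indexed [y + 1, x + 1].

#' Construct a frame image
#'
#' A single grayscale frame plus the acquisition metadata needed to convert
#' pixel measurements to physical units.
#'
#' @param pixels Numeric matrix of grayscale intensities (arbitrary units),
#'   at least 16 x 16.
#' @param pixel_size Pixel size in micrometres per pixel (default 0.65, a
#'   typical 10x phase-contrast setup).
#' @param frame_index Non-negative integer frame index.
#' @return An object of class `frame_image`.
#' @export
frame_image <- function(pixels, pixel_size = 0.65, frame_index = 0L) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix (2-D grayscale image)",
         call. = FALSE)
  }
  if (any(dim(pixels) < 16L)) {
    stop("frame must have at least 16 x 16 extent", call. = FALSE)
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number", call. = FALSE)
  }
  if (frame_index < 0) stop("`frame_index` must be >= 0", call. = FALSE)
  structure(
    list(pixels = pixels, pixel_size = pixel_size,
         frame_index = as.integer(frame_index)),
    class = "frame_image"
  )
}

#' @export
print.frame_image <- function(x, ...) {
  cat(sprintf("<frame_image> %d x %d px, %.3g um/px, frame %d\n",
              ncol(x$pixels), nrow(x$pixels), x$pixel_size, x$frame_index))
  invisible(x)
}

#' Segmentation configuration
#'
#' Parameters of the edge-based segmentation chain. Defaults follow the
#' reference protocol for 10x phase-contrast images at 0.65 um/px: octagonal
#' dilation of radius 3 px, hole filling, then two erosions with a diamond
#' of radius 5 px, and rejection of components smaller than 200 um^2
#' (an order of magnitude below a spread fibroblast).
#'
#' @param edge_threshold Gradient-magnitude cutoff (same units as the
#'   intensity gradient); pixels with magnitude strictly greater are kept.
#'   The threshold is tuned once per acquisition setup; see
#'   [suggest_edge_threshold()] for an automatic starting point.
#' @param dilation_radius_px Octagon radius in pixels (origin to side,
#'   measured along the axes). Default 3.
#' @param erosion_radius_px Diamond radius in pixels (origin to vertex).
#'   Default 5.
#' @param erosion_repeats Number of erosion passes. Default 2.
#' @param min_area_um2 Minimum component area in um^2. Default 200.
#' @param centroid_mode `"pixel"` (centroid rounded to the nearest integer
#'   pixel, half away from zero) or `"subpixel"`. Default `"pixel"`,
#'   matching centroid tables quantized to the pixel grid.
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(edge_threshold,
                       dilation_radius_px = 3L,
                       erosion_radius_px = 5L,
                       erosion_repeats = 2L,
                       min_area_um2 = 200,
                       centroid_mode = c("pixel", "subpixel")) {
  centroid_mode <- match.arg(centroid_mode)
  if (!is.numeric(edge_threshold) || length(edge_threshold) != 1L ||
      edge_threshold < 0) {
    stop("`edge_threshold` must be a single number >= 0", call. = FALSE)
  }
  if (dilation_radius_px < 1L || erosion_radius_px < 1L) {
    stop("structuring-element radii must be >= 1", call. = FALSE)
  }
  if (erosion_repeats < 1L) stop("`erosion_repeats` must be >= 1", call. = FALSE)
  if (min_area_um2 <= 0) stop("`min_area_um2` must be > 0", call. = FALSE)
  structure(
    list(edge_threshold = edge_threshold,
         dilation_radius_px = as.integer(dilation_radius_px),
         erosion_radius_px = as.integer(erosion_radius_px),
         erosion_repeats = as.integer(erosion_repeats),
         min_area_um2 = min_area_um2,
         centroid_mode = centroid_mode),
    class = "seg_config"
  )
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Structuring elements
#'
#' Frozen pixel footprints used by [refine_mask()]. The octagon of radius
#' `r` contains all offsets with `max(|dx|, |dy|) <= r` and
#' `|dx| + |dy| <= floor(4 * r / 3)` (origin-to-side distance `r` along the
#' axes, corners cut at 45 degrees); for the default r = 3 this is
#' `|dx| + |dy| <= 4`. The diamond of radius `r` contains all offsets with
#' `|dx| + |dy| <= r` (origin-to-vertex distance `r`).
#'
#' @param r Radius in pixels (>= 1).
#' @return A (2r+1) x (2r+1) 0/1 matrix.
#' @export
octagon_kernel <- function(r) {
  r <- as.integer(r)
  stopifnot(r >= 1L)
  d <- seq.int(-r, r)
  off <- expand.grid(dy = d, dx = d)
  cut <- floor(4L * r / 3L)
  k <- matrix(as.numeric(pmax(abs(off$dx), abs(off$dy)) <= r &
                           (abs(off$dx) + abs(off$dy)) <= cut),
              nrow = 2L * r + 1L)
  k
}

#' @rdname octagon_kernel
#' @export
diamond_kernel <- function(r) {
  r <- as.integer(r)
  stopifnot(r >= 1L)
  d <- seq.int(-r, r)
  off <- expand.grid(dy = d, dx = d)
  matrix(as.numeric(abs(off$dx) + abs(off$dy) <= r), nrow = 2L * r + 1L)
}

#' Sobel gradient magnitude
#'
#' First-order differential edge detector: the image is convolved with the
#' two 3 x 3 Sobel kernels and the L2 norm of the horizontal and vertical
#' responses is returned. Borders are handled by edge replication.
#'
#' @param image A [frame_image()] or a numeric matrix.
#' @return Non-negative numeric matrix of the same extent.
#' @export
compute_edge_magnitude <- function(image) {
  px <- if (inherits(image, "frame_image")) image$pixels else image
  if (!is.matrix(px) || !is.numeric(px)) {
    stop("input must be a 2-D numeric image", call. = FALSE)
  }
  ny <- nrow(px); nx <- ncol(px)
  # pad by 1 with edge replication
  p <- px[c(1L, seq_len(ny), ny), c(1L, seq_len(nx), nx)]
  s <- function(dy, dx) p[seq_len(ny) + 1L + dy, seq_len(nx) + 1L + dx]
  # Sobel x-derivative: [-1 0 1; -2 0 2; -1 0 1] (rows = y, cols = x)
  gx <- (s(-1L, 1L) + 2 * s(0L, 1L) + s(1L, 1L)) -
        (s(-1L, -1L) + 2 * s(0L, -1L) + s(1L, -1L))
  gy <- (s(1L, -1L) + 2 * s(1L, 0L) + s(1L, 1L)) -
        (s(-1L, -1L) + 2 * s(-1L, 0L) + s(-1L, 1L))
  sqrt(gx^2 + gy^2)
}

#' Binarize a gradient map
#'
#' @param gradmap Non-negative numeric matrix from [compute_edge_magnitude()].
#' @param edge_threshold Cutoff; pixels strictly greater are edge pixels.
#' @return Logical matrix.
#' @export
binarize_edges <- function(gradmap, edge_threshold) {
  if (!is.numeric(edge_threshold) || length(edge_threshold) != 1L ||
      edge_threshold < 0) {
    stop("`edge_threshold` must be a single number >= 0", call. = FALSE)
  }
  gradmap > edge_threshold
}

#' Suggest an edge threshold from the gradient histogram
#'
#' Convenience extension for unattended runs: Otsu's criterion applied to
#' the gradient-magnitude map. The reference protocol tunes the threshold
#' manually once per acquisition setup; this function only provides a
#' starting value.
#'
#' @param gradmap Gradient-magnitude matrix.
#' @return A single threshold on the gradient scale.
#' @export
suggest_edge_threshold <- function(gradmap) {
  rng <- range(gradmap)
  if (diff(rng) <= 0) return(0)
  g <- (gradmap - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(g), range = c(0, 1))
  th * diff(rng) + rng[1]
}

#' Morphological refinement of an edge mask
#'
#' Applies, in order: dilation by an octagon structuring element, filling of
#' enclosed holes, then `erosion_repeats` erosions by a diamond structuring
#' element (see [octagon_kernel()] for the exact pixel sets). Border
#' convention: dilation treats pixels outside the image as background,
#' erosion treats them as foreground.
#'
#' @param edge_mask Logical (or 0/1 numeric) matrix.
#' @param config A [seg_config()].
#' @return Logical matrix of the smoothed solid regions.
#' @export
refine_mask <- function(edge_mask, config) {
  stopifnot(inherits(config, "seg_config"))
  m <- matrix(as.numeric(edge_mask), nrow = nrow(edge_mask))
  m <- EBImage::dilate(m, octagon_kernel(config$dilation_radius_px))
  m <- EBImage::fillHull(m)
  dk <- diamond_kernel(config$erosion_radius_px)
  for (i in seq_len(config$erosion_repeats)) m <- EBImage::erode(m, dk)
  m > 0
}

# 8-connected labeling: EBImage::bwlabel (4-connected flood fill) followed by
# union-find over diagonally adjacent label pairs.
label_components8 <- function(mask) {
  m <- matrix(as.numeric(mask), nrow = nrow(mask))
  lbl <- EBImage::bwlabel(m)
  n <- max(lbl)
  if (n <= 1L) return(lbl)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  ny <- nrow(lbl); nx <- ncol(lbl)
  for (d in list(c(1L, 1L), c(1L, -1L))) {  # diagonal neighbor offsets (dy, dx)
    dy <- d[1]; dx <- d[2]
    ys <- seq_len(ny - 1L)
    xs <- if (dx > 0L) seq_len(nx - 1L) else seq.int(2L, nx)
    a <- lbl[ys, xs, drop = FALSE]
    b <- lbl[ys + dy, xs + dx, drop = FALSE]
    sel <- which(a > 0 & b > 0 & a != b)
    if (length(sel)) {
      pr <- unique(cbind(a[sel], b[sel]))
      for (k in seq_len(nrow(pr))) union2(pr[k, 1], pr[k, 2])
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lbl
  out[lbl > 0] <- relab[lbl[lbl > 0]]
  out
}

# filled convex hull of a pixel set; returns list(hull = n x 2 (x, y),
# mask = logical matrix of the given extent)
fill_convex_hull <- function(xs, ys, dim_yx) {
  mask <- matrix(FALSE, dim_yx[1], dim_yx[2])
  pts <- unique(cbind(xs, ys))
  if (nrow(pts) < 3L || length(unique(xs)) == 1L || length(unique(ys)) == 1L) {
    # degenerate hull (point or line): support is the pixel set itself
    mask[cbind(ys + 1L, xs + 1L)] <- TRUE
    h <- pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
    return(list(hull = h, mask = mask))
  }
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  hull <- pts[idx, , drop = FALSE]
  nh <- nrow(hull)
  # signed area decides which side of each edge is the interior
  jnext <- c(seq.int(2L, nh), 1L)
  a2 <- sum(hull[, 1] * hull[jnext, 2] - hull[jnext, 1] * hull[, 2])
  sgn <- if (a2 >= 0) 1 else -1
  # candidate pixels: bounding box of the hull
  xr <- range(hull[, 1]); yr <- range(hull[, 2])
  gx <- rep(seq.int(xr[1], xr[2]), times = yr[2] - yr[1] + 1L)
  gy <- rep(seq.int(yr[1], yr[2]), each = xr[2] - xr[1] + 1L)
  inside <- rep(TRUE, length(gx))
  tol <- 1e-9
  for (i in seq_len(nh)) {
    j <- jnext[i]
    ex <- hull[j, 1] - hull[i, 1]; ey <- hull[j, 2] - hull[i, 2]
    cr <- sgn * (ex * (gy - hull[i, 2]) - ey * (gx - hull[i, 1]))
    inside <- inside & (cr >= -tol)
  }
  mask[cbind(gy[inside] + 1L, gx[inside] + 1L)] <- TRUE
  list(hull = hull, mask = mask)
}

# second-central-moment ellipse of a pixel set (0-based x, y vectors)
pixel_moments_axis <- function(xs, ys, pixel_size) {
  n <- length(xs)
  if (n < 2L) {
    stop2("degenerate_region", "major axis undefined for a single-pixel region")
  }
  mx <- mean(xs); my <- mean(ys)
  cxx <- mean((xs - mx)^2); cyy <- mean((ys - my)^2)
  cxy <- mean((xs - mx) * (ys - my))
  tr <- cxx + cyy; det <- cxx * cyy - cxy^2
  disc <- sqrt(max((tr / 2)^2 - det, 0))
  l1 <- tr / 2 + disc  # major eigenvalue
  # eigenvector of the larger eigenvalue
  if (abs(cxy) > 1e-12) {
    vx <- l1 - cyy; vy <- cxy
  } else if (cxx >= cyy) {
    vx <- 1; vy <- 0
  } else {
    vx <- 0; vy <- 1
  }
  ang <- atan2(vy, vx) * 180 / pi
  if (ang >= 90) ang <- ang - 180
  if (ang < -90) ang <- ang + 180
  list(length_um = 4 * sqrt(l1) * pixel_size, orientation_deg = ang)
}

stop2 <- function(class, msg) {
  stop(structure(class = c(class, "motrack_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Extract cell regions from a solid mask
#'
#' Finds 8-connected components of the refined mask, drops those below the
#' minimum area, and smooths each with its convex hull: the region's mask is
#' the filled hull interior, on which centroid, area, equivalent diameter
#' and major axis are computed. Regions are returned sorted by descending
#' area.
#'
#' @param solid_mask Logical matrix from [refine_mask()].
#' @param image The source [frame_image()] (for pixel size and frame index).
#' @param config A [seg_config()].
#' @return A list of `cell_region` objects (possibly empty). Each has
#'   fields `mask`, `hull` (polygon vertices, 0-based x/y pixel coords),
#'   `centroid_px`, `centroid_um`, `area_um2`, `equivalent_diameter_um`,
#'   `major_axis_length_um`, `major_axis_orientation_deg`, `n_px`.
#' @export
extract_cells <- function(solid_mask, image, config) {
  stopifnot(inherits(config, "seg_config"))
  ps <- if (inherits(image, "frame_image")) image$pixel_size else 0.65
  lbl <- label_components8(solid_mask)
  n <- max(lbl)
  regions <- list()
  if (n >= 1L) {
    for (i in seq_len(n)) {
      idx <- which(lbl == i, arr.ind = TRUE)
      xs <- idx[, 2] - 1L; ys <- idx[, 1] - 1L
      comp_area <- nrow(idx) * ps^2
      if (comp_area < config$min_area_um2) next
      fh <- fill_convex_hull(xs, ys, dim(lbl))
      hidx <- which(fh$mask, arr.ind = TRUE)
      hx <- hidx[, 2] - 1L; hy <- hidx[, 1] - 1L
      cx <- mean(hx); cy <- mean(hy)
      if (config$centroid_mode == "pixel") {
        cx <- round_half_away(cx); cy <- round_half_away(cy)
      }
      area <- length(hx) * ps^2
      ax <- if (length(hx) >= 2L) pixel_moments_axis(hx, hy, ps) else
        list(length_um = NA_real_, orientation_deg = NA_real_)
      regions[[length(regions) + 1L]] <- structure(
        list(mask = fh$mask,
             hull = fh$hull,
             centroid_px = c(x = cx, y = cy),
             centroid_um = c(x = cx * ps, y = cy * ps),
             area_um2 = area,
             equivalent_diameter_um = 2 * sqrt(area / pi),
             major_axis_length_um = ax$length_um,
             major_axis_orientation_deg = ax$orientation_deg,
             n_px = length(hx),
             pixel_size = ps),
        class = "cell_region")
    }
  }
  if (length(regions) > 1L) {
    regions <- regions[order(vapply(regions, function(r) r$area_um2,
                                    numeric(1)), decreasing = TRUE)]
  }
  regions
}

#' Centroid of a segmented region
#'
#' Arithmetic mean of the filled-hull pixel coordinates; in `"pixel"` mode
#' the mean is rounded to the nearest integer pixel (half away from zero).
#'
#' @param region A `cell_region`.
#' @param centroid_mode `"pixel"` or `"subpixel"`.
#' @return Named vector `c(x = , y = )` in pixel coordinates.
#' @export
centroid_of_region <- function(region, centroid_mode = c("pixel", "subpixel")) {
  centroid_mode <- match.arg(centroid_mode)
  stopifnot(inherits(region, "cell_region"))
  idx <- which(region$mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop2("degenerate_region", "empty region has no centroid")
  cx <- mean(idx[, 2] - 1L); cy <- mean(idx[, 1] - 1L)
  if (centroid_mode == "pixel") {
    cx <- round_half_away(cx); cy <- round_half_away(cy)
  }
  c(x = cx, y = cy)
}

#' Major axis of a segmented region
#'
#' Length and orientation of the major axis of the ellipse with the same
#' second central moments as the filled-hull pixel set.
#'
#' @param region A `cell_region`.
#' @return List with `length_um` and `orientation_deg` (in \[-90, 90)).
#' @export
major_axis <- function(region) {
  stopifnot(inherits(region, "cell_region"))
  idx <- which(region$mask, arr.ind = TRUE)
  pixel_moments_axis(idx[, 2] - 1L, idx[, 1] - 1L, region$pixel_size)
}

#' Segment one frame end to end
#'
#' Convenience wrapper running [compute_edge_magnitude()],
#' [binarize_edges()], [refine_mask()] and [extract_cells()] in sequence.
#'
#' @inheritParams extract_cells
#' @param image A [frame_image()].
#' @return A list of `cell_region` objects.
#' @export
segment_frame <- function(image, config) {
  g <- compute_edge_magnitude(image)
  bw <- binarize_edges(g, config$edge_threshold)
  solid <- refine_mask(bw, config)
  extract_cells(solid, image, config)
}

#' Tabulate segmented regions
#'
#' @param regions List of `cell_region` objects.
#' @param frame_index Frame index recorded in the table.
#' @return Data frame with one row per region: `frame`, `region_id`,
#'   `x_px`, `y_px`, `x_um`, `y_um`, `area_um2`, `equiv_diam_um`,
#'   `major_axis_um`, `orientation_deg`.
#' @export
regions_to_table <- function(regions, frame_index = 0L) {
  if (length(regions) == 0L) {
    return(data.frame(frame = integer(), region_id = integer(),
                      x_px = numeric(), y_px = numeric(),
                      x_um = numeric(), y_um = numeric(),
                      area_um2 = numeric(), equiv_diam_um = numeric(),
                      major_axis_um = numeric(), orientation_deg = numeric()))
  }
  do.call(rbind, lapply(seq_along(regions), function(i) {
    r <- regions[[i]]
    data.frame(frame = as.integer(frame_index), region_id = i,
               x_px = r$centroid_px[["x"]], y_px = r$centroid_px[["y"]],
               x_um = r$centroid_um[["x"]], y_um = r$centroid_um[["y"]],
               area_um2 = r$area_um2,
               equiv_diam_um = r$equivalent_diameter_um,
               major_axis_um = r$major_axis_length_um,
               orientation_deg = r$major_axis_orientation_deg)
  }))
}
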