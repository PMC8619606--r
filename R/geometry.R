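#' Parametric five-lobed leaf geometry
#'
#' A vine leaf lamina is realized in a 2-D plane from its descriptors: the
#' lamina base sits at the origin, the midrib runs along +y, and the right
#' side of the leaf occupies +x. Vein tips are placed at their measured
#' lengths along directions set by the angles alpha and beta; sinus bases are
#' placed on the angular bisector between adjacent vein directions at their
#' measured distances. The outline is the closed 10-vertex polygon
#' base -> VR2 tip -> right sinus 2 -> VR1 tip -> right sinus 1 -> MR tip ->
#' left sinus 1 -> VL1 tip -> left sinus 2 -> VL2 tip -> base.
#'
#' @name leaf-geometry
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Build a leaf shape from descriptors
#'
#' Places the vein-tip and sinus-base landmarks and assembles the closed
#' outline polygon. The right-side vein directions are `alpha` (first order)
#' and `alpha + beta` (second order) clockwise from the midrib; left-side
#' directions mirror them with angles scaled by `left_angle_factor`, which
#' lets callers introduce structural asymmetry. The tip distances DV1/DV2
#' emerge from the construction and are stored back into the landmark record
#' (the generating DV values are not used to place any point).
#'
#' @param descriptors a [leaf_descriptors] object.
#' @param left_angle_factor multiplier applied to the left-side vein angles;
#'   1 gives a mirror-symmetric angular skeleton.
#' @param smoothing if `TRUE`, each outline vertex is replaced by a sampled
#'   quadratic arc that still passes through the landmark, rounding the
#'   lobes and sinuses; default `FALSE` (piecewise-linear outline).
#' @param smooth_points number of sampled points per arc when smoothing.
#' @return An object of class `leaf_shape`: a list with `landmarks` (named
#'   2-column matrix, cm), `outline` (closed polygon, first row == last row),
#'   `descriptors` (the generating descriptors with DV1/DV2 replaced by the
#'   emergent tip distances) and `left_angle_factor`.
#' @examples
#' d <- leaf_descriptors(9.21, 7.54, 7.92, 10.82, 5.80, 5.94, 11.52,
#'                       3.69, 3.49, 3.52, 3.57, 44.46, 54.91)
#' sh <- build_leaf_shape(d)
#' polygon_area(sh)
#' @export
build_leaf_shape <- function(descriptors, left_angle_factor = 1,
                             smoothing = FALSE, smooth_points = 8) {
  d <- validate_descriptors(unclass(descriptors))
  if (!is.numeric(left_angle_factor) || left_angle_factor <= 0)
    stop("left_angle_factor must be positive")
  laf <- left_angle_factor
  a <- d[["alpha"]]; b <- d[["beta"]]
  if (laf * (a + b) >= 180)
    stop("left_angle_factor folds the left veins past the leaf base (",
         "left second-order direction ", laf * (a + b),
         " degrees from the midrib)")

  # direction angles measured counterclockwise from +x; midrib at 90 deg
  dir <- c(MR   = 90,
           VR1  = 90 - a,
           VR2  = 90 - a - b,
           VL1  = 90 + a * laf,
           VL2  = 90 + (a + b) * laf,
           SR1  = 90 - a / 2,
           SR2  = 90 - a - b / 2,
           SL1  = 90 + (a / 2) * laf,
           SL2  = 90 + (a + b / 2) * laf)
  len <- c(MR = d[["MR"]], VR1 = d[["VR1"]], VR2 = d[["VR2"]],
           VL1 = d[["VL1"]], VL2 = d[["VL2"]],
           SR1 = d[["DSR1"]], SR2 = d[["DSR2"]],
           SL1 = d[["DSL1"]], SL2 = d[["DSL2"]])
  th <- deg2rad(dir[names(len)])
  pts <- cbind(x = len * cos(th), y = len * sin(th))
  landmarks <- rbind(base = c(0, 0), pts)
  colnames(landmarks) <- c("x", "y")

  order_names <- c("base", "VR2", "SR2", "VR1", "SR1", "MR",
                   "SL1", "VL1", "SL2", "VL2")
  outline <- landmarks[order_names, , drop = FALSE]
  outline <- rbind(outline, outline[1, , drop = FALSE])

  bad <- polygon_self_intersection(outline)
  if (!is.null(bad)) {
    stop("descriptor combination is geometrically infeasible: outline edge ",
         bad[1], "-", bad[2], " crosses edge ", bad[3], "-", bad[4],
         " (check the named sinus/vein landmarks)")
  }

  d2 <- d
  d2[["DV1"]] <- sqrt(sum((landmarks["VL1", ] - landmarks["VR1", ])^2))
  d2[["DV2"]] <- sqrt(sum((landmarks["VL2", ] - landmarks["VR2", ])^2))

  if (isTRUE(smoothing))
    outline <- smooth_outline(outline, smooth_points)

  structure(list(landmarks = landmarks, outline = outline,
                 descriptors = structure(d2, class = "leaf_descriptors"),
                 left_angle_factor = laf, smoothed = isTRUE(smoothing)),
            class = "leaf_shape")
}

# Quadratic-arc smoothing that keeps every landmark on the outline: the arc
# around vertex L runs between the midpoints of its two incident edges with
# control point 2L - (m1+m2)/2, so B(1/2) == L exactly.
smooth_outline <- function(outline, k = 8) {
  v <- outline[-nrow(outline), , drop = FALSE]  # open ring
  n <- nrow(v)
  t <- seq(0, 1, length.out = k + 1)[-(k + 1)]
  pieces <- vector("list", n)
  for (i in seq_len(n)) {
    prev <- v[if (i == 1) n else i - 1, ]
    cur <- v[i, ]
    nxt <- v[if (i == n) 1 else i + 1, ]
    m1 <- (prev + cur) / 2
    m2 <- (cur + nxt) / 2
    ctrl <- 2 * cur - (m1 + m2) / 2
    bx <- (1 - t)^2 * m1[1] + 2 * t * (1 - t) * ctrl[1] + t^2 * m2[1]
    by <- (1 - t)^2 * m1[2] + 2 * t * (1 - t) * ctrl[2] + t^2 * m2[2]
    pieces[[i]] <- cbind(bx, by)
  }
  out <- do.call(rbind, pieces)
  out <- rbind(out, out[1, , drop = FALSE])
  colnames(out) <- c("x", "y")
  rownames(out) <- NULL
  out
}

# Returns NULL if the closed polygon is simple, else the landmark names of
# the first pair of non-adjacent edges that properly intersect.
polygon_self_intersection <- function(outline) {
  v <- outline[-nrow(outline), , drop = FALSE]
  n <- nrow(v)
  nm <- rownames(v)
  if (is.null(nm)) nm <- as.character(seq_len(n))
  seg_from <- seq_len(n)
  seg_to <- c(seq_len(n)[-1], 1)
  cross2 <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  intersects <- function(p1, p2, p3, p4) {
    d1 <- cross2(p3, p4, p1); d2 <- cross2(p3, p4, p2)
    d3 <- cross2(p1, p2, p3); d4 <- cross2(p1, p2, p4)
    (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
  }
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      # skip adjacent edges (share a vertex), incl. the wrap-around pair
      if (j == i + 1 || (i == 1 && j == n)) next
      if (intersects(v[seg_from[i], ], v[seg_to[i], ],
                     v[seg_from[j], ], v[seg_to[j], ]))
        return(c(nm[seg_from[i]], nm[seg_to[i]], nm[seg_from[j]], nm[seg_to[j]]))
    }
  }
  NULL
}

outline_of <- function(shape) {
  if (inherits(shape, "leaf_shape")) shape$outline
  else if (is.matrix(shape) && ncol(shape) == 2) shape
  else stop("expected a leaf_shape or a 2-column vertex matrix")
}

#' Exact polygon area (shoelace formula)
#'
#' Orientation-independent area of a simple closed polygon, in the square of
#' the coordinate unit (cm^2 for leaf shapes).
#'
#' @param shape a `leaf_shape` or a 2-column vertex matrix (closed or open).
#' @return area, strictly positive.
#' @export
polygon_area <- function(shape) {
  v <- outline_of(shape)
  if (all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  if (nrow(unique(v)) < 3) stop("degenerate polygon: fewer than 3 distinct vertices")
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  a <- abs(sum(x * yn - xn * y)) / 2
  if (a <= 0) stop("degenerate polygon: zero area")
  a
}

#' Rasterize a leaf shape onto a binary pixel grid
#'
#' Emulates a flatbed scan of the lamina: a pixel is occupied when its
#' centre falls inside the outline under the even-odd rule (implemented as
#' a scanline fill with the half-open vertex convention, so shared vertices
#' are counted once). The grid's bounding box covers the polygon with a
#' one-pixel margin on every side.
#'
#' @param shape a `leaf_shape` (or 2-column closed vertex matrix).
#' @param pixel_pitch pixel side length in cm.
#' @return An object of class `leaf_raster`: list with `grid` (logical
#'   matrix, rows = y from bottom, columns = x), `pixel_pitch` and `origin`
#'   (bottom-left corner of the grid, cm).
#' @export
rasterize <- function(shape, pixel_pitch) {
  if (!is.numeric(pixel_pitch) || length(pixel_pitch) != 1 ||
      !is.finite(pixel_pitch) || pixel_pitch <= 0)
    stop("pixel_pitch must be a single positive number")
  v <- outline_of(shape)
  if (!all(v[1, ] == v[nrow(v), ])) v <- rbind(v, v[1, , drop = FALSE])
  xr <- range(v[, 1]); yr <- range(v[, 2])
  if (pixel_pitch > min(diff(xr), diff(yr)))
    stop("pixel_pitch (", pixel_pitch, " cm) exceeds the polygon's smallest ",
         "extent (", signif(min(diff(xr), diff(yr)), 4), " cm)")
  origin <- c(xr[1] - pixel_pitch, yr[1] - pixel_pitch)
  nc <- ceiling(diff(xr) / pixel_pitch) + 2
  nr <- ceiling(diff(yr) / pixel_pitch) + 2
  xc <- origin[1] + (seq_len(nc) - 0.5) * pixel_pitch
  yc <- origin[2] + (seq_len(nr) - 0.5) * pixel_pitch

  grid <- matrix(FALSE, nrow = nr, ncol = nc)
  x1 <- v[-nrow(v), 1]; y1 <- v[-nrow(v), 2]
  x2 <- v[-1, 1];       y2 <- v[-1, 2]
  keep <- y1 != y2
  x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  # per scanline, collect edge crossings under the half-open rule
  # [min(y), max(y)) and fill between sorted crossing pairs
  crossings <- vector("list", nr)
  for (e in seq_along(x1)) {
    ylo <- min(y1[e], y2[e]); yhi <- max(y1[e], y2[e])
    rows <- which(yc >= ylo & yc < yhi)
    if (length(rows) == 0) next
    xcr <- x1[e] + (yc[rows] - y1[e]) * (x2[e] - x1[e]) / (y2[e] - y1[e])
    for (k in seq_along(rows))
      crossings[[rows[k]]] <- c(crossings[[rows[k]]], xcr[k])
  }
  for (r in seq_len(nr)) {
    cr <- crossings[[r]]
    if (is.null(cr) || length(cr) < 2) next
    cr <- sort(cr)
    for (p in seq(1, length(cr) - 1, by = 2))
      grid[r, xc > cr[p] & xc < cr[p + 1]] <- TRUE
  }
  structure(list(grid = grid, pixel_pitch = pixel_pitch, origin = origin),
            class = "leaf_raster")
}

#' Pixel-count area of a rasterized leaf
#'
#' The scanned-area analogue: number of occupied pixels times the pixel
#' area. This is the package's stand-in for scanned leaf area (SLA) when
#' leaves are synthesized rather than scanned.
#'
#' @param raster a `leaf_raster`.
#' @return area in cm^2 (zero for an empty raster).
#' @export
pixel_area <- function(raster) {
  if (!inherits(raster, "leaf_raster")) stop("expected a leaf_raster")
  sum(raster$grid) * raster$pixel_pitch^2
}

#' Re-measure descriptors from a leaf shape
#'
#' Recomputes all thirteen descriptors from the landmark coordinates:
#' lengths as Euclidean distances from the lamina base, DV1/DV2 as tip-to-tip
#' distances, and alpha/beta as the angles between the midrib and right-vein
#' directions. A round trip through [build_leaf_shape()] reproduces the
#' generating lengths and angles to floating-point accuracy, with DV1/DV2 as
#' the emergent tip distances.
#'
#' @param shape a `leaf_shape` carrying its landmark record.
#' @return a [leaf_descriptors] object.
#' @export
measure_descriptors <- function(shape) {
  if (!inherits(shape, "leaf_shape") || is.null(shape$landmarks))
    stop("shape does not carry a landmark record")
  L <- shape$landmarks
  base <- L["base", ]
  dist_to_base <- function(nm) sqrt(sum((L[nm, ] - base)^2))
  ang <- function(nm) rad2deg(atan2(L[nm, "y"] - base["y"], L[nm, "x"] - base["x"]))
  alpha <- ang("MR") - ang("VR1")
  beta <- ang("VR1") - ang("VR2")
  leaf_descriptors(
    MR = dist_to_base("MR"),
    VL1 = dist_to_base("VL1"), VR1 = dist_to_base("VR1"),
    DV1 = sqrt(sum((L["VL1", ] - L["VR1", ])^2)),
    VL2 = dist_to_base("VL2"), VR2 = dist_to_base("VR2"),
    DV2 = sqrt(sum((L["VL2", ] - L["VR2", ])^2)),
    DSL1 = dist_to_base("SL1"), DSR1 = dist_to_base("SR1"),
    DSL2 = dist_to_base("SL2"), DSR2 = dist_to_base("SR2"),
    alpha = alpha, beta = beta)
}

#' Export a leaf outline as a CSV vertex list
#'
#' Writes columns `x_cm`, `y_cm`, `landmark_name` (empty for interpolated
#' smoothing points).
#'
#' @param shape a `leaf_shape`.
#' @param path output CSV path.
#' @export
write_shape_csv <- function(shape, path) {
  v <- outline_of(shape)
  nm <- rownames(v)
  if (is.null(nm)) nm <- rep("", nrow(v))
  utils::write.csv(data.frame(x_cm = v[, 1], y_cm = v[, 2],
                              landmark_name = nm),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a leaf raster as a 1-bit PNG with a JSON sidecar
#'
#' The PNG stores the occupancy grid (leaf = black on white, row 1 at the
#' top); the sidecar `<path>.json` records `pixel_pitch_cm` and the grid
#' origin so the physical scale is recoverable. Requires the `png` and
#' `jsonlite` packages.
#'
#' @param raster a `leaf_raster`.
#' @param path output PNG path.
#' @export
write_raster_png <- function(raster, path) {
  if (!requireNamespace("png", quietly = TRUE) ||
      !requireNamespace("jsonlite", quietly = TRUE))
    stop("write_raster_png requires the 'png' and 'jsonlite' packages")
  img <- 1 - raster$grid[rev(seq_len(nrow(raster$grid))), , drop = FALSE]
  png::writePNG(img, path)
  jsonlite::write_json(
    list(pixel_pitch_cm = raster$pixel_pitch,
         origin_x_cm = raster$origin[1], origin_y_cm = raster$origin[2]),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.leaf_shape <- function(x, ...) {
  cat("Five-lobed leaf shape:", nrow(x$outline) - 1, "outline vertices,",
      "midrib", round(x$descriptors[["MR"]], 2), "cm,",
      "area", round(polygon_area(x), 2), "cm^2\n")
  invisible(x)
}

#' @export
print.leaf_raster <- function(x, ...) {
  cat("Leaf raster:", nrow(x$grid), "x", ncol(x$grid), "pixels at",
      x$pixel_pitch, "cm/pixel;", sum(x$grid), "occupied (",
      round(pixel_area(x), 2), "cm^2 )\n")
  invisible(x)
}
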