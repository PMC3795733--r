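#' Per-vessel shape and size descriptors
#'
#' A segmented vessel profile is characterised by its endothelial, luminal
#' and vascular (endothelium + lumen) areas, the length of its outer
#' boundary, the diameter of the largest inscribable circle (its width),
#' the solidity of the filled profile relative to its convex hull, the
#' length and branching of its skeleton, and its centre of mass. All
#' length-like outputs are in micrometres, areas in square micrometres;
#' the pixel pitch converts between the raster grid and physical units.
#'
#' @name morphometry
NULL

#' Measure endothelial, luminal and vascular areas
#'
#' Areas are pixel counts scaled by the squared pixel pitch, so the
#' identity `vascular = endothelial + luminal` holds exactly.
#'
#' @param profile A `vessel_profile` (see [segment_field()]).
#' @param pitch_um Pixel pitch in micrometres per pixel.
#' @return Named numeric vector with `endothelial_um2`, `luminal_um2`,
#'   `vascular_um2`.
#' @export
measure_areas <- function(profile, pitch_um) {
  stopifnot(inherits(profile, "vessel_profile"), pitch_um > 0)
  n_lum <- sum(vapply(profile$lumens, sum, numeric(1)), 0)
  n_end <- sum(profile$endothelium)
  c(endothelial_um2 = n_end * pitch_um^2,
    luminal_um2 = n_lum * pitch_um^2,
    vascular_um2 = (n_end + n_lum) * pitch_um^2)
}

# Outer Moore contour(s) of a mask as 1-based (row, col) coordinates.
outer_contours <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)))
  lapply(EBImage::ocontour(lab), function(o) o + 1)
}

# Chain-length perimeter of one closed contour, in pixels.
# Corner-calibrated weights (0.948 straight, 1.340 diagonal) are close to
# unbiased for pixel-centre digitizations of smooth outlines; objects whose
# contour degenerates to <= 4 points fall back on the exposed pixel-edge
# (crack) length so a single pixel measures 4.
contour_length_px <- function(contour, mask = NULL) {
  n <- nrow(contour)
  if (n <= 4 && !is.null(mask)) return(crack_length_px(mask))
  p <- rbind(contour, contour[1, , drop = FALSE])
  dr <- diff(p[, 1]); dc <- diff(p[, 2])
  straight <- sum(abs(dr) + abs(dc) == 1)
  diagonal <- sum(abs(dr) == 1 & abs(dc) == 1)
  0.948 * straight + 1.340 * diagonal
}

# Number of pixel edges between the set and its complement (border counts).
crack_length_px <- function(mask) {
  m <- mask != 0
  sum(m & !mat_shift(m, 1, 0)) + sum(m & !mat_shift(m, -1, 0)) +
    sum(m & !mat_shift(m, 0, 1)) + sum(m & !mat_shift(m, 0, -1))
}

#' Outer perimeter of a vessel profile
#'
#' Length of the traced outer boundary of the filled profile (endothelium
#' plus lumens); internal lumen boundaries are excluded, so an annulus and
#' its filled disc report the same perimeter.
#'
#' @inheritParams measure_areas
#' @return Perimeter in micrometres.
#' @export
outer_perimeter <- function(profile, pitch_um) {
  stopifnot(inherits(profile, "vessel_profile"), pitch_um > 0)
  mask_perimeter_um(profile$filled, pitch_um)
}

# Perimeter of the outer boundary of a single-object mask, in um.
mask_perimeter_um <- function(mask, pitch_um) {
  stopifnot(sum(mask) > 0)
  ct <- outer_contours(mask)
  # a single profile has one outer contour; if labelling ever splits it,
  # sum the pieces
  sum(vapply(ct, contour_length_px, numeric(1), mask = mask)) * pitch_um
}

#' Largest-inscribed-circle width of a pixel set
#'
#' Width is the diameter of the largest circle inscribable in the set:
#' twice the maximum over pixels of the Euclidean distance to the nearest
#' complement pixel (the image border counts as complement).
#'
#' @param mask Logical/numeric matrix, the pixel set.
#' @param pitch_um Pixel pitch in micrometres per pixel.
#' @return Width in micrometres.
#' @export
object_width <- function(mask, pitch_um) {
  stopifnot(pitch_um > 0)
  if (sum(mask != 0) == 0) stop("object_width() is undefined for an empty pixel set")
  2 * max(distance_to_background(mask)) * pitch_um
}

#' Convex solidity of a vessel profile
#'
#' Filled (vascular) area divided by the area of the convex hull of the
#' filled set. The hull is taken over pixel *corners*, so pixel squares are
#' fully contained and solidity never exceeds 1 by more than numerical
#' noise. A degenerate hull is floored at the filled area (solidity 1).
#'
#' @inheritParams measure_areas
#' @return Solidity in (0, 1].
#' @export
convex_solidity <- function(profile) {
  stopifnot(inherits(profile, "vessel_profile"))
  mask_solidity(profile$filled)
}

mask_solidity <- function(mask) {
  area <- sum(mask != 0)
  stopifnot(area > 0)
  m <- mask != 0
  # hull over mid-crack points (midpoints of exposed pixel edges): exact
  # for axis-aligned outlines and nearly unbiased for smooth ones
  pts <- rbind(
    shift_edge_pts(m, -1, 0), shift_edge_pts(m, 1, 0),
    shift_edge_pts(m, 0, -1), shift_edge_pts(m, 0, 1))
  h <- grDevices::chull(pts)
  hull <- pts[h, , drop = FALSE]
  hull_area <- polygon_area(hull[, 1], hull[, 2])
  area / max(hull_area, area)
}

# midpoints of pixel edges exposed towards direction (dr, dc)
shift_edge_pts <- function(m, dr, dc) {
  idx <- which(m & !mat_shift(m, -dr, -dc), arr.ind = TRUE)
  cbind(idx[, 1] + dr / 2, idx[, 2] + dc / 2)
}

# Shoelace area of a simple polygon.
polygon_area <- function(x, y) {
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Skeletonize a pixel set
#'
#' Topology-preserving Zhang-Suen thinning to one-pixel-wide strokes.
#'
#' @param mask Logical/numeric matrix.
#' @return Logical matrix of the same dimensions.
#' @export
skeletonize <- function(mask) {
  m <- mask != 0
  if (!any(m)) return(m)
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  m <- pad
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours clockwise from north (north = row - 1)
      p2 <- mat_shift(m, -1, 0); p3 <- mat_shift(m, -1, 1)
      p4 <- mat_shift(m, 0, 1);  p5 <- mat_shift(m, 1, 1)
      p6 <- mat_shift(m, 1, 0);  p7 <- mat_shift(m, 1, -1)
      p8 <- mat_shift(m, 0, -1); p9 <- mat_shift(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (step == 1) {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) { m <- m & !cond; changed <- TRUE }
    }
    if (!changed) break
  }
  m[2:(nr + 1), 2:(nc + 1), drop = FALSE]
}

# Length of a 1-px skeleton: orthogonal links weigh 1, diagonal links
# sqrt(2); a diagonal link is skipped when either shared 4-neighbour is on
# the skeleton (the path is already counted by two orthogonal links).
skeleton_length_px <- function(skel) {
  s <- skel != 0
  n_orth <- sum(s & mat_shift(s, -1, 0)) + sum(s & mat_shift(s, 0, -1))
  se <- s & mat_shift(s, -1, -1) &
    !(mat_shift(s, -1, 0) | mat_shift(s, 0, -1))
  sw <- s & mat_shift(s, -1, 1) &
    !(mat_shift(s, -1, 0) | mat_shift(s, 0, 1))
  n_orth + sqrt(2) * (sum(se) + sum(sw))
}

# Branch points: skeleton pixels with >= 3 skeleton 8-neighbours, merged
# into clusters of centre-to-centre distance <= merge_radius_px.
skeleton_branch_points <- function(skel, merge_radius_px = 2) {
  s <- skel != 0
  nb <- mat_shift(s, -1, 0) + mat_shift(s, 1, 0) + mat_shift(s, 0, -1) +
    mat_shift(s, 0, 1) + mat_shift(s, -1, -1) + mat_shift(s, -1, 1) +
    mat_shift(s, 1, -1) + mat_shift(s, 1, 1)
  idx <- which(s & nb >= 3, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) return(0L)
  if (n == 1) return(1L)
  d <- as.matrix(stats::dist(idx))
  adj <- d <= merge_radius_px
  # count connected clusters (single linkage)
  seen <- rep(FALSE, n); k <- 0L
  for (i in seq_len(n)) {
    if (seen[i]) next
    k <- k + 1L
    queue <- i
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      if (seen[j]) next
      seen[j] <- TRUE
      queue <- c(queue, which(adj[j, ] & !seen))
    }
  }
  k
}

#' Skeleton length and branch points of a vessel profile
#'
#' The filled profile is thinned to minimum connected strokes; length is
#' the sum of inter-pixel steps (1 or sqrt(2) pixels) times the pitch, and
#' branch points are skeleton pixels with at least three skeleton
#' neighbours, with adjacent triple-points (within 2 px) merged.
#'
#' @inheritParams measure_areas
#' @return List with `skeleton_length_um`, `n_branch_points` and the
#'   skeleton mask (`skeleton`).
#' @export
skeleton_metrics <- function(profile, pitch_um) {
  stopifnot(inherits(profile, "vessel_profile"), pitch_um > 0)
  sk <- skeletonize(profile$filled)
  list(skeleton_length_um = skeleton_length_px(sk) * pitch_um,
       n_branch_points = skeleton_branch_points(sk),
       skeleton = sk)
}

#' Centre of mass of a vessel profile
#'
#' Arithmetic mean of the filled pixel coordinates, reported as
#' `(x = col, y = row)` in the full-image frame. The centroid of a concave
#' profile may fall outside the filled set.
#'
#' @inheritParams measure_areas
#' @return Numeric `c(x, y)` in pixels.
#' @export
centroid <- function(profile) {
  stopifnot(inherits(profile, "vessel_profile"))
  idx <- which(profile$filled != 0, arr.ind = TRUE)
  c(x = mean(idx[, 2]) + profile$offset[2],
    y = mean(idx[, 1]) + profile$offset[1])
}

#' Compute all descriptors for a vessel profile
#'
#' Fills the measurement slots of a `vessel_profile` in place: areas,
#' outer perimeter, width, solidity, skeleton length, branch points,
#' lumen flag and centroid.
#'
#' @inheritParams measure_areas
#' @return The profile with measurement fields populated.
#' @export
measure_vessel <- function(profile, pitch_um) {
  ar <- measure_areas(profile, pitch_um)
  sk <- skeleton_metrics(profile, pitch_um)
  profile$endothelial_area_um2 <- unname(ar["endothelial_um2"])
  profile$luminal_area_um2 <- unname(ar["luminal_um2"])
  profile$vascular_area_um2 <- unname(ar["vascular_um2"])
  profile$perimeter_um <- outer_perimeter(profile, pitch_um)
  profile$width_um <- object_width(profile$filled, pitch_um)
  profile$solidity <- convex_solidity(profile)
  profile$skeleton_length_um <- sk$skeleton_length_um
  profile$n_branch_points <- sk$n_branch_points
  profile$skeleton <- sk$skeleton
  profile$has_lumen <- length(profile$lumens) > 0
  profile$centroid_px <- centroid(profile)
  profile
}

#' Tabulate vessel profiles
#'
#' @param profiles List of measured `vessel_profile`s.
#' @param field_id Field identifier recycled into the table.
#' @return A data frame with one row per vessel.
#' @export
vessel_table <- function(profiles, field_id = "field") {
  if (!length(profiles)) {
    return(data.frame(field_id = character(), vessel_id = integer(),
                      endothelial_area_um2 = numeric(), luminal_area_um2 = numeric(),
                      vascular_area_um2 = numeric(), perimeter_um = numeric(),
                      width_um = numeric(), solidity = numeric(),
                      skeleton_length_um = numeric(), n_branch_points = integer(),
                      has_lumen = logical(), centroid_x = numeric(),
                      centroid_y = numeric()))
  }
  do.call(rbind, lapply(profiles, function(p) data.frame(
    field_id = field_id, vessel_id = p$vessel_id,
    endothelial_area_um2 = p$endothelial_area_um2,
    luminal_area_um2 = p$luminal_area_um2,
    vascular_area_um2 = p$vascular_area_um2,
    perimeter_um = p$perimeter_um, width_um = p$width_um,
    solidity = p$solidity, skeleton_length_um = p$skeleton_length_um,
    n_branch_points = p$n_branch_points, has_lumen = p$has_lumen,
    centroid_x = p$centroid_px[["x"]], centroid_y = p$centroid_px[["y"]])))
}
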