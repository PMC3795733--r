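#' Synthetic hot-spot fields with continuum ground truth
#'
#' The generator renders calibrated RGB rasters that emulate
#' CD34-immunostained hot-spot photomicrographs: vessel walls carry the
#' brown DAB chromogen, scattered nuclei carry the blue haematoxylin
#' counterstain, lumens and background are near-white, and sub-threshold
#' DAB specks emulate staining noise. Four vessel archetypes are drawn -
#' annuli, elliptical rings, wavy ribbons and branched profiles, with or
#' without lumens - and every vessel's continuum geometry (area,
#' perimeter, solidity, width, centre) is recorded analytically (or by a
#' dense 10x-resolution oracle for the branched family), so that the
#' segmentation and morphometry stages can be validated against exact
#' truth.
#'
#' @name synthetic_fields
NULL

#' Specify one synthetic vessel
#'
#' @param shape_family One of `"annulus"`, `"elliptical_ring"`,
#'   `"ribbon"`, `"branched"`.
#' @param centre Numeric `c(x, y)` centre in pixels.
#' @param outer_radius_px Outer radius (annulus) in pixels.
#' @param axis_lengths_px Semi-axes `c(a, b)` (elliptical ring).
#' @param wall_thickness_px Stained wall thickness (>= 1 px); for ribbons
#'   and branched profiles this is the full stroke thickness.
#' @param has_lumen Render an interior opening (annulus/elliptical ring).
#' @param orientation_deg Rotation of the shape, degrees.
#' @param length_px Centreline length (ribbon) or branch length
#'   (branched).
#' @param waviness_amplitude_px Transverse sinusoidal amplitude (ribbon).
#' @param wavelength_px Wavelength of the transverse wave (ribbon).
#' @param n_branches Number of branches (branched family, >= 2).
#' @param branch_angles_deg Optional explicit branch directions.
#' @return A `vessel_spec` list.
#' @export
vessel_spec <- function(shape_family, centre, outer_radius_px = NULL,
                        axis_lengths_px = NULL, wall_thickness_px = 4,
                        has_lumen = FALSE, orientation_deg = 0,
                        length_px = NULL, waviness_amplitude_px = 0,
                        wavelength_px = NULL, n_branches = 3,
                        branch_angles_deg = NULL) {
  shape_family <- match.arg(shape_family,
    c("annulus", "elliptical_ring", "ribbon", "branched"))
  stopifnot(wall_thickness_px >= 1, length(centre) == 2)
  structure(list(shape_family = shape_family, centre = centre,
                 outer_radius_px = outer_radius_px,
                 axis_lengths_px = axis_lengths_px,
                 wall_thickness_px = wall_thickness_px,
                 has_lumen = has_lumen, orientation_deg = orientation_deg,
                 length_px = length_px,
                 waviness_amplitude_px = waviness_amplitude_px,
                 wavelength_px = wavelength_px, n_branches = n_branches,
                 branch_angles_deg = branch_angles_deg),
            class = "vessel_spec")
}

#' Specify a synthetic field
#'
#' @param height_px,width_px Field dimensions in pixels. The defaults
#'   reproduce the acquisition geometry the package targets: a 0.38 mm^2
#'   field at 0.34 um/px (1814 x 1814 px).
#' @param pixel_pitch_um Pixel pitch, micrometres per pixel.
#' @param vessels List of [vessel_spec()]s.
#' @param stain_colour_model List with `dab` and `haematoxylin` HSV
#'   components (`h` degrees, `s`, `v`) and `background` RGB.
#' @param noise List: `n_specks` and `speck_size_px` (range); all specks
#'   are rendered below the minimum vessel width.
#' @param nuclei List: `n` counterstained nuclei and their `radius_px`
#'   range.
#' @param allow_overlap Permit vessel masks to touch or overlap (default
#'   `FALSE`; rendering then fails if they do, keeping per-vessel ground
#'   truth unambiguous).
#' @param seed Integer seed; the same spec renders bit-identically.
#' @return A `field_spec` list.
#' @export
field_spec <- function(height_px = 1814, width_px = 1814,
                       pixel_pitch_um = 0.34, vessels = list(),
                       stain_colour_model = default_stain_colours(),
                       noise = list(n_specks = 40, speck_size_px = c(1, 3)),
                       nuclei = list(n = 250, radius_px = c(2, 5)),
                       allow_overlap = FALSE, seed = 1L) {
  stopifnot(height_px > 0, width_px > 0, pixel_pitch_um > 0)
  structure(list(height_px = as.integer(height_px),
                 width_px = as.integer(width_px),
                 pixel_pitch_um = pixel_pitch_um, vessels = vessels,
                 stain_colour_model = stain_colour_model, noise = noise,
                 nuclei = nuclei, allow_overlap = allow_overlap,
                 seed = as.integer(seed)),
            class = "field_spec")
}

#' @rdname field_spec
#' @export
default_stain_colours <- function() {
  list(dab = list(h = 30, s = 0.55, v = 0.42, v_jitter = 0.04),
       haematoxylin = list(h = 230, s = 0.45, v = 0.42, v_jitter = 0.05),
       background = c(0.93, 0.92, 0.94))
}

# ---- shape rasterizers -----------------------------------------------------
# Each returns list(wall, lumens, filled, offset, truth) with cropped masks;
# truth holds continuum vascular/endothelial area (px^2), perimeter (px),
# solidity, width (px), centre and the lumen flag.

pixel_grid <- function(r0, r1, c0, c1) {
  list(r = matrix(r0:r1, r1 - r0 + 1, c1 - c0 + 1),
       c = matrix(c0:c1, r1 - r0 + 1, c1 - c0 + 1, byrow = TRUE))
}

shape_bbox <- function(centre, reach, dims) {
  # centre is (x, y) = (col, row)
  r0 <- max(1L, floor(centre[2] - reach)); r1 <- min(dims[1], ceiling(centre[2] + reach))
  c0 <- max(1L, floor(centre[1] - reach)); c1 <- min(dims[2], ceiling(centre[1] + reach))
  list(r0 = r0, r1 = r1, c0 = c0, c1 = c1, offset = c(r0 - 1L, c0 - 1L))
}

raster_annulus <- function(spec, dims) {
  R <- spec$outer_radius_px; t <- spec$wall_thickness_px
  bb <- shape_bbox(spec$centre, R + 2, dims)
  g <- pixel_grid(bb$r0, bb$r1, bb$c0, bb$c1)
  d <- sqrt((g$c - spec$centre[1])^2 + (g$r - spec$centre[2])^2)
  outer <- d <= R
  lumens <- list()
  wall <- outer
  r_in <- R - t
  if (isTRUE(spec$has_lumen) && r_in > 0.5) {
    lum <- d <= r_in
    wall <- outer & !lum
    if (any(lum)) lumens <- list(lum)
  } else r_in <- 0
  truth <- list(
    vascular_area_px2 = pi * R^2,
    endothelial_area_px2 = pi * (R^2 - r_in^2),
    perimeter_px = 2 * pi * R,
    solidity = 1, width_px = 2 * R,
    centre_px = spec$centre, has_lumen = length(lumens) > 0)
  list(wall = wall, lumens = lumens, filled = outer, offset = bb$offset,
       truth = truth)
}

# circumference of an ellipse with semi-axes a >= b, by quadrature
ellipse_perimeter <- function(a, b) {
  4 * a * stats::integrate(function(th)
    sqrt(1 - (1 - (b / a)^2) * sin(th)^2), 0, pi / 2,
    rel.tol = 1e-10)$value
}

raster_elliptical_ring <- function(spec, dims) {
  ab <- spec$axis_lengths_px; a <- ab[1]; b <- ab[2]
  t <- spec$wall_thickness_px
  th <- spec$orientation_deg * pi / 180
  bb <- shape_bbox(spec$centre, max(a, b) + 2, dims)
  g <- pixel_grid(bb$r0, bb$r1, bb$c0, bb$c1)
  xr <- (g$c - spec$centre[1]) * cos(th) + (g$r - spec$centre[2]) * sin(th)
  yr <- -(g$c - spec$centre[1]) * sin(th) + (g$r - spec$centre[2]) * cos(th)
  outer <- (xr / a)^2 + (yr / b)^2 <= 1
  lumens <- list()
  wall <- outer
  ai <- a - t; bi <- b - t
  if (isTRUE(spec$has_lumen) && bi > 0.5) {
    lum <- (xr / ai)^2 + (yr / bi)^2 <= 1
    wall <- outer & !lum
    if (any(lum)) lumens <- list(lum)
  } else { ai <- 0; bi <- 0 }
  truth <- list(
    vascular_area_px2 = pi * a * b,
    endothelial_area_px2 = pi * (a * b - ai * bi),
    perimeter_px = ellipse_perimeter(max(a, b), min(a, b)),
    solidity = 1, width_px = 2 * min(a, b),
    centre_px = spec$centre, has_lumen = length(lumens) > 0)
  list(wall = wall, lumens = lumens, filled = outer, offset = bb$offset,
       truth = truth)
}

# sample the ribbon centreline densely; returns n x 2 (x, y) points
ribbon_centreline <- function(spec, spacing = 0.25) {
  L <- spec$length_px
  A <- spec$waviness_amplitude_px
  lam <- if (is.null(spec$wavelength_px)) L / 1.5 else spec$wavelength_px
  th <- spec$orientation_deg * pi / 180
  u <- seq(-L / 2, L / 2, by = spacing)
  off <- if (A > 0) A * sin(2 * pi * u / lam) else rep(0, length(u))
  dir <- c(cos(th), sin(th)); nrm <- c(-sin(th), cos(th))
  cbind(spec$centre[1] + u * dir[1] + off * nrm[1],
        spec$centre[2] + u * dir[2] + off * nrm[2])
}

polyline_length <- function(p) sum(sqrt(rowSums(diff(p)^2)))

# min distance from pixels (px, py) to a point chain, blockwise
dist_to_points <- function(px, py, pts, block = 5000L) {
  n <- length(px)
  out <- rep(Inf, n)
  for (i0 in seq(1L, n, by = block)) {
    i1 <- min(n, i0 + block - 1L)
    dx <- outer(px[i0:i1], pts[, 1], `-`)
    dy <- outer(py[i0:i1], pts[, 2], `-`)
    out[i0:i1] <- sqrt(do.call(pmin, c(
      lapply(seq_len(ncol(dx)), function(j) dx[, j]^2 + dy[, j]^2))))
  }
  out
}

raster_ribbon <- function(spec, dims) {
  t <- spec$wall_thickness_px
  cl <- ribbon_centreline(spec, spacing = 0.25)
  reach <- spec$length_px / 2 + spec$waviness_amplitude_px + t / 2 + 2
  bb <- shape_bbox(spec$centre, reach, dims)
  g <- pixel_grid(bb$r0, bb$r1, bb$c0, bb$c1)
  d <- dist_to_points(as.vector(g$c), as.vector(g$r), cl)
  wall <- matrix(d <= t / 2, nrow(g$r), ncol(g$r))
  # continuum truth from a finer sampling of the generating curve
  fine <- ribbon_centreline(spec, spacing = 0.02)
  len <- polyline_length(fine)
  # hull of the offset outline (sides plus end caps)
  seg <- diff(fine)
  tang <- seg / sqrt(rowSums(seg^2))
  nrm <- cbind(-tang[, 2], tang[, 1])
  mid <- fine[-1, , drop = FALSE]
  side1 <- mid + nrm * t / 2; side2 <- mid - nrm * t / 2
  caps <- lapply(list(c(1, -1), c(nrow(fine), 1)), function(e) {
    p <- fine[e[1], ]; tg <- tang[if (e[1] == 1) 1 else nrow(tang), ] * e[2]
    ang <- atan2(tg[2], tg[1]) + seq(-pi / 2, pi / 2, length.out = 40)
    cbind(p[1] + cos(ang) * t / 2, p[2] + sin(ang) * t / 2)
  })
  outline <- rbind(side1, side2, caps[[1]], caps[[2]])
  h <- grDevices::chull(outline)
  hull_area <- polygon_area(outline[h, 1], outline[h, 2])
  area <- len * t + pi * (t / 2)^2
  truth <- list(
    vascular_area_px2 = area, endothelial_area_px2 = area,
    perimeter_px = 2 * len + pi * t,
    solidity = min(1, area / hull_area), width_px = t,
    centre_px = spec$centre, has_lumen = FALSE)
  list(wall = wall, lumens = list(), filled = wall, offset = bb$offset,
       truth = truth)
}

# distance from points to a segment p0-p1
dist_to_segment <- function(px, py, p0, p1) {
  vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]
  len2 <- vx^2 + vy^2
  tt <- pmin(1, pmax(0, ((px - p0[1]) * vx + (py - p0[2]) * vy) / len2))
  sqrt((px - (p0[1] + tt * vx))^2 + (py - (p0[2] + tt * vy))^2)
}

branch_segments <- function(spec) {
  k <- max(2L, spec$n_branches)
  ang <- if (!is.null(spec$branch_angles_deg)) spec$branch_angles_deg else
    seq(0, 360, length.out = k + 1)[seq_len(k)]
  ang <- (ang + spec$orientation_deg) * pi / 180
  L <- rep_len(if (is.null(spec$length_px)) 30 else spec$length_px, k)
  lapply(seq_len(k), function(i)
    list(p0 = spec$centre,
         p1 = spec$centre + L[i] * c(cos(ang[i]), sin(ang[i]))))
}

branched_distance <- function(px, py, segs) {
  d <- rep(Inf, length(px))
  for (s in segs) d <- pmin(d, dist_to_segment(px, py, s$p0, s$p1))
  d
}

raster_branched <- function(spec, dims, oracle_scale = 10L) {
  t <- spec$wall_thickness_px
  segs <- branch_segments(spec)
  reach <- max(vapply(segs, function(s)
    sqrt(sum((s$p1 - spec$centre)^2)), numeric(1))) + t / 2 + 2
  bb <- shape_bbox(spec$centre, reach, dims)
  g <- pixel_grid(bb$r0, bb$r1, bb$c0, bb$c1)
  d <- branched_distance(as.vector(g$c), as.vector(g$r), segs)
  wall <- matrix(d <= t / 2, nrow(g$r), ncol(g$r))
  # continuum oracle at 10x resolution on the generating capsule union
  k <- oracle_scale
  rr <- seq(bb$r0 - 0.5 + 1 / (2 * k), bb$r1 + 0.5 - 1 / (2 * k), by = 1 / k)
  cc <- seq(bb$c0 - 0.5 + 1 / (2 * k), bb$c1 + 0.5 - 1 / (2 * k), by = 1 / k)
  gg <- list(r = matrix(rr, length(rr), length(cc)),
             c = matrix(cc, length(rr), length(cc), byrow = TRUE))
  dd <- branched_distance(as.vector(gg$c), as.vector(gg$r), segs)
  hi <- matrix(dd <= t / 2, length(rr), length(cc))
  area <- sum(hi) / k^2
  per <- mask_perimeter_um(hi, 1) / k
  truth <- list(
    vascular_area_px2 = area, endothelial_area_px2 = area,
    perimeter_px = per,
    solidity = sum(hi) / max(sum(hi), hull_area_px(hi)),
    width_px = t, centre_px = spec$centre, has_lumen = FALSE)
  list(wall = wall, lumens = list(), filled = wall, offset = bb$offset,
       truth = truth)
}

hull_area_px <- function(mask) {
  m <- mask != 0
  interior <- m & mat_shift(m, 1, 0) & mat_shift(m, -1, 0) &
    mat_shift(m, 0, 1) & mat_shift(m, 0, -1)
  idx <- which(m & !interior, arr.ind = TRUE)
  pts <- rbind(cbind(idx[, 1] - 0.5, idx[, 2] - 0.5),
               cbind(idx[, 1] - 0.5, idx[, 2] + 0.5),
               cbind(idx[, 1] + 0.5, idx[, 2] - 0.5),
               cbind(idx[, 1] + 0.5, idx[, 2] + 0.5))
  h <- grDevices::chull(pts)
  polygon_area(pts[h, 1], pts[h, 2])
}

raster_vessel <- function(spec, dims) {
  switch(spec$shape_family,
         annulus = raster_annulus(spec, dims),
         elliptical_ring = raster_elliptical_ring(spec, dims),
         ribbon = raster_ribbon(spec, dims),
         branched = raster_branched(spec, dims))
}

# ---- rendering -------------------------------------------------------------

hsv_pixels <- function(n, h, s, v, v_jitter) {
  vv <- pmin(1, pmax(0.05, v + stats::runif(n, -v_jitter, v_jitter)))
  grDevices::col2rgb(grDevices::hsv(h / 360, s, vv)) / 255
}

#' Render a synthetic field
#'
#' Renders the field described by a [field_spec()] into a calibrated RGB
#' image together with its ground truth: per-vessel filled and lumen
#' masks, continuum geometry per vessel, and the exact stain mask (vessel
#' walls plus noise specks). Rendering is bit-deterministic in the spec's
#' seed. Vessels may not overlap unless the spec allows it; an overlap
#' raises an error so per-vessel truth stays unambiguous.
#'
#' @param spec A [field_spec()].
#' @return List with `image` (an [image_field()]) and `gt` (a
#'   `ground_truth` object).
#' @export
render_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  dims <- c(spec$height_px, spec$width_px)
  with_seed(spec$seed, {
    vessels <- lapply(spec$vessels, raster_vessel, dims = dims)
    # overlap guard: dilated union must not intersect the next vessel
    occupied <- matrix(FALSE, dims[1], dims[2])
    for (v in vessels) {
      m <- v$filled
      if (!any(m)) next
      rows <- (v$offset[1] + 1):(v$offset[1] + nrow(m))
      cols_ <- (v$offset[2] + 1):(v$offset[2] + ncol(m))
      if (!isTRUE(spec$allow_overlap)) {
        dil <- m | mat_shift(m, 1, 0) | mat_shift(m, -1, 0) |
          mat_shift(m, 0, 1) | mat_shift(m, 0, -1) |
          mat_shift(m, 1, 1) | mat_shift(m, 1, -1) |
          mat_shift(m, -1, 1) | mat_shift(m, -1, -1)
        region <- occupied[rows, cols_, drop = FALSE]
        if (any(region & dil))
          stop("vessel masks overlap or touch; set allow_overlap or respace")
        occupied[rows, cols_] <- region | dil
      } else {
        occupied[rows, cols_] <- occupied[rows, cols_, drop = FALSE] | m
      }
    }
    cols <- spec$stain_colour_model
    # channel matrices are composed at top level (in-place assignment)
    # and assembled into the RGB array at the end
    red <- pmin(1, pmax(0, cols$background[1] +
      stats::rnorm(prod(dims), 0, 0.012)))
    grn <- pmin(1, pmax(0, cols$background[2] +
      stats::rnorm(prod(dims), 0, 0.012)))
    blu <- pmin(1, pmax(0, cols$background[3] +
      stats::rnorm(prod(dims), 0, 0.012)))
    dim(red) <- dims; dim(grn) <- dims; dim(blu) <- dims
    # haematoxylin nuclei (drawn first; walls paint over them)
    if (spec$nuclei$n > 0) {
      nuc_idx <- vector("list", spec$nuclei$n)
      for (i in seq_len(spec$nuclei$n)) {
        rad <- stats::runif(1, spec$nuclei$radius_px[1], spec$nuclei$radius_px[2])
        ctr <- c(stats::runif(1, 1 + rad, dims[2] - rad),
                 stats::runif(1, 1 + rad, dims[1] - rad))
        bb <- shape_bbox(ctr, rad + 1, dims)
        g <- pixel_grid(bb$r0, bb$r1, bb$c0, bb$c1)
        ecc <- stats::runif(1, 0.6, 1)
        m <- ((g$c - ctr[1]) / rad)^2 + ((g$r - ctr[2]) / (rad * ecc))^2 <= 1
        idx <- which(m, arr.ind = TRUE)
        if (!nrow(idx)) next
        nuc_idx[[i]] <- cbind(idx[, 1] + bb$offset[1], idx[, 2] + bb$offset[2])
      }
      idx <- do.call(rbind, nuc_idx)
      if (!is.null(idx) && nrow(idx)) {
        hx <- cols$haematoxylin
        cc <- hsv_pixels(nrow(idx), hx$h, hx$s, hx$v, hx$v_jitter)
        red[idx] <- cc[1, ]; grn[idx] <- cc[2, ]; blu[idx] <- cc[3, ]
      }
    }
    # vessel walls
    stain <- matrix(FALSE, dims[1], dims[2])
    dab <- cols$dab
    wall_idx <- lapply(vessels, function(v) {
      idx <- which(v$wall, arr.ind = TRUE)
      cbind(idx[, 1] + v$offset[1], idx[, 2] + v$offset[2])
    })
    idx <- do.call(rbind, wall_idx)
    if (!is.null(idx) && nrow(idx)) {
      stain[idx] <- TRUE
      cc <- hsv_pixels(nrow(idx), dab$h, dab$s, dab$v, dab$v_jitter)
      red[idx] <- cc[1, ]; grn[idx] <- cc[2, ]; blu[idx] <- cc[3, ]
    }
    # lumens show background plasma, not counterstain
    lum_idx <- do.call(rbind, lapply(vessels, function(v) {
      do.call(rbind, lapply(v$lumens, function(lum) {
        li <- which(lum, arr.ind = TRUE)
        cbind(li[, 1] + v$offset[1], li[, 2] + v$offset[2])
      }))
    }))
    if (!is.null(lum_idx) && nrow(lum_idx)) {
      nl <- nrow(lum_idx)
      red[lum_idx] <- pmin(1, pmax(0, cols$background[1] +
        stats::rnorm(nl, 0, 0.012)))
      grn[lum_idx] <- pmin(1, pmax(0, cols$background[2] +
        stats::rnorm(nl, 0, 0.012)))
      blu[lum_idx] <- pmin(1, pmax(0, cols$background[3] +
        stats::rnorm(nl, 0, 0.012)))
    }
    # noise specks: DAB-coloured, all below the minimum vessel width,
    # placed clear of vessels so they never merge with a profile
    n_specks <- spec$noise$n_specks
    if (n_specks > 0) {
      placed <- 0L; tries <- 0L
      speck_idx <- list()
      while (placed < n_specks && tries < n_specks * 50L) {
        tries <- tries + 1L
        sz <- sample(seq(spec$noise$speck_size_px[1],
                         spec$noise$speck_size_px[2]), 1)
        r <- sample(seq(3L, dims[1] - sz - 2L), 1)
        c <- sample(seq(3L, dims[2] - sz - 2L), 1)
        win_r <- max(1, r - 3):min(dims[1], r + sz + 2)
        win_c <- max(1, c - 3):min(dims[2], c + sz + 2)
        if (any(occupied[win_r, win_c]) || any(stain[win_r, win_c])) next
        idx <- as.matrix(expand.grid(r:(r + sz - 1L), c:(c + sz - 1L)))
        stain[idx] <- TRUE
        speck_idx[[length(speck_idx) + 1]] <- idx
        placed <- placed + 1L
      }
      idx <- do.call(rbind, speck_idx)
      if (!is.null(idx) && nrow(idx)) {
        cc <- hsv_pixels(nrow(idx), dab$h, dab$s, dab$v, dab$v_jitter)
        red[idx] <- cc[1, ]; grn[idx] <- cc[2, ]; blu[idx] <- cc[3, ]
      }
      if (placed < n_specks)
        warning(sprintf("placed %d of %d noise specks", placed, n_specks))
    }
    img <- array(c(red, grn, blu), c(dims, 3L))
    truth_table <- if (length(vessels)) do.call(rbind, lapply(
      seq_along(vessels), function(i) {
        tr <- vessels[[i]]$truth
        p <- spec$pixel_pitch_um
        data.frame(vessel_id = i,
                   vascular_area_um2 = tr$vascular_area_px2 * p^2,
                   endothelial_area_um2 = tr$endothelial_area_px2 * p^2,
                   luminal_area_um2 = (tr$vascular_area_px2 -
                                       tr$endothelial_area_px2) * p^2,
                   perimeter_um = tr$perimeter_px * p,
                   solidity = tr$solidity,
                   width_um = tr$width_px * p,
                   centre_x = tr$centre_px[1], centre_y = tr$centre_px[2],
                   has_lumen = tr$has_lumen)
      })) else data.frame(
        vessel_id = integer(), vascular_area_um2 = numeric(),
        endothelial_area_um2 = numeric(), luminal_area_um2 = numeric(),
        perimeter_um = numeric(), solidity = numeric(), width_um = numeric(),
        centre_x = numeric(), centre_y = numeric(), has_lumen = logical())
    gt <- structure(list(
      vessels = vessels, truth = truth_table, stain_mask = stain,
      dims = dims, pixel_pitch_um = spec$pixel_pitch_um,
      n_vessels = length(vessels)), class = "ground_truth")
    list(image = image_field(img, spec$pixel_pitch_um,
                             field_id = sprintf("synthetic-%d", spec$seed)),
         gt = gt)
  })
}

#' Sample a random field specification
#'
#' Draws vessel shapes, sizes and non-overlapping placements from the
#' generator's distributions. Sizes are drawn in micrometres and converted
#' by the pitch, so the rendered population is pitch-invariant. All
#' intended vessels render at least the minimum vessel width wide and all
#' noise specks below it.
#'
#' @param params List of generator parameters; see Details. Any subset may
#'   be supplied, the rest keep their defaults: `height_px`/`width_px`
#'   (1814), `pixel_pitch_um` (0.34), `n_vessels` (25), `shape_mix`
#'   (annulus 0.45, elliptical ring 0.20, ribbon 0.20, branched 0.15),
#'   `mean_outer_radius_um` (5.1), `radius_sdlog` (0.30),
#'   `wall_thickness_um` (1.7), `lumen_prob` (0.6), `n_specks` (40),
#'   `n_nuclei` (250), `min_separation_px` (6).
#' @param seed Integer seed.
#' @return A [field_spec()].
#' @export
sample_field_spec <- function(params = list(), seed = 1L) {
  p <- utils::modifyList(list(
    height_px = 1814L, width_px = 1814L, pixel_pitch_um = 0.34,
    n_vessels = 25L,
    shape_mix = c(annulus = 0.45, elliptical_ring = 0.20,
                  ribbon = 0.20, branched = 0.15),
    mean_outer_radius_um = 5.1, radius_sdlog = 0.30,
    wall_thickness_um = 1.7, lumen_prob = 0.6,
    n_specks = 40L, n_nuclei = 250L, min_separation_px = 6), params)
  pitch <- p$pixel_pitch_um
  min_w_px <- 3.5 / pitch           # minimum vessel width in px
  with_seed(seed, {
    fams <- sample(names(p$shape_mix), p$n_vessels, replace = TRUE,
                   prob = p$shape_mix)
    specs <- vector("list", p$n_vessels)
    reach <- numeric(p$n_vessels)
    for (i in seq_len(p$n_vessels)) {
      fam <- fams[i]
      R <- max(min_w_px / 2 + 1.5,
               stats::rlnorm(1, log(p$mean_outer_radius_um / pitch),
                             p$radius_sdlog))
      t <- max(2, stats::rnorm(1, p$wall_thickness_um / pitch, 0.8))
      lum <- stats::runif(1) < p$lumen_prob
      if (fam == "annulus") {
        if (lum) t <- min(t, R - 2)
        specs[[i]] <- vessel_spec("annulus", c(0, 0), outer_radius_px = R,
                                  wall_thickness_px = t, has_lumen = lum)
        reach[i] <- R + 2
      } else if (fam == "elliptical_ring") {
        a <- R * stats::runif(1, 1.3, 2.1)
        b <- max(min_w_px / 2 + 1, R * stats::runif(1, 0.7, 1.0))
        if (lum) t <- min(t, b - 1.5)
        specs[[i]] <- vessel_spec("elliptical_ring", c(0, 0),
                                  axis_lengths_px = c(a, b),
                                  wall_thickness_px = max(2, t), has_lumen = lum,
                                  orientation_deg = stats::runif(1, 0, 180))
        reach[i] <- max(a, b) + 2
      } else if (fam == "ribbon") {
        tt <- stats::runif(1, min_w_px + 0.8, min_w_px + 5)
        L <- stats::runif(1, 3, 6) * tt
        A <- stats::runif(1, 0, 0.08 * L)
        lam <- L / stats::runif(1, 1.0, 1.8)
        # keep the offset curve simple: curvature radius > thickness
        max_a <- lam^2 / (4 * pi^2 * (tt / 2 + 1.5))
        A <- min(A, max_a)
        specs[[i]] <- vessel_spec("ribbon", c(0, 0), wall_thickness_px = tt,
                                  orientation_deg = stats::runif(1, 0, 180),
                                  length_px = L, waviness_amplitude_px = A,
                                  wavelength_px = lam)
        reach[i] <- L / 2 + A + tt / 2 + 2
      } else {
        tt <- stats::runif(1, min_w_px + 0.8, min_w_px + 4)
        L <- stats::runif(1, 1.8, 3.5) * tt
        ang <- c(0, 120, 240) + stats::runif(3, -25, 25)
        specs[[i]] <- vessel_spec("branched", c(0, 0), wall_thickness_px = tt,
                                  orientation_deg = stats::runif(1, 0, 360),
                                  length_px = L, n_branches = 3,
                                  branch_angles_deg = ang)
        reach[i] <- L + tt / 2 + 2
      }
    }
    # rejection-sample non-overlapping centres (bounding-disc separation)
    centres <- matrix(NA_real_, p$n_vessels, 2)
    for (i in seq_len(p$n_vessels)) {
      ok <- FALSE
      for (try in seq_len(400)) {
        ctr <- c(stats::runif(1, reach[i] + 1, p$width_px - reach[i] - 1),
                 stats::runif(1, reach[i] + 1, p$height_px - reach[i] - 1))
        if (i == 1 || all(sqrt(rowSums((centres[seq_len(i - 1), , drop = FALSE] -
              matrix(ctr, i - 1, 2, byrow = TRUE))^2)) >
              reach[seq_len(i - 1)] + reach[i] + p$min_separation_px)) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("placement failure: field too crowded for requested vessels")
      centres[i, ] <- ctr
      specs[[i]]$centre <- ctr
    }
    field_spec(height_px = p$height_px, width_px = p$width_px,
               pixel_pitch_um = pitch, vessels = specs,
               noise = list(n_specks = p$n_specks, speck_size_px = c(1, 3)),
               nuclei = list(n = p$n_nuclei, radius_px = c(2, 5)),
               seed = sample.int(.Machine$integer.max, 1))
  })
}

#' Field markers from continuum ground truth
#'
#' Computes the marker vector from the generating geometry: sizes, shapes
#' and centres come from the continuum truth; `MVA_rx4` and `MV_scale`,
#' which are defined on the rasterized field, are computed from the
#' ground-truth masks with the same definitions as the measurement module.
#'
#' @param gt A `ground_truth` from [render_field()].
#' @param pitch_um Pixel pitch; defaults to the ground truth's.
#' @param cfg A [scale_config()] for `MV_scale`.
#' @return One-row data frame matching [compute_field_markers()].
#' @export
true_markers <- function(gt, pitch_um = gt$pixel_pitch_um,
                         cfg = scale_config()) {
  stopifnot(inherits(gt, "ground_truth"))
  tr <- gt$truth
  n <- nrow(tr)
  area_mm2 <- prod(gt$dims) * pitch_um^2 / 1e6
  out <- data.frame(
    field_id = "truth", n_vessels = n, MVD = n / area_mm2,
    MVA_sigma = if (n >= 1) sum(tr$vascular_area_um2) else NA_real_,
    MVA_mu = if (n >= 1) mean(tr$vascular_area_um2) else NA_real_,
    MVA_CV = if (n >= 2)
      stats::sd(tr$vascular_area_um2) / mean(tr$vascular_area_um2)
    else NA_real_,
    MVP_mu = if (n >= 1) mean(tr$perimeter_um) else NA_real_,
    MVP_sigma = if (n >= 1) sum(tr$perimeter_um) else NA_real_,
    MVE_mu = if (n >= 1) mean(tr$endothelial_area_um2) else NA_real_,
    MVL_mu = NA_real_,
    MVS_mu = if (n >= 1) mean(tr$solidity) else NA_real_,
    MV_luminal = if (n >= 1) mean(tr$has_lumen) else NA_real_)
  vasc <- matrix(FALSE, gt$dims[1], gt$dims[2])
  skel <- matrix(FALSE, gt$dims[1], gt$dims[2])
  skel_len <- numeric(n)
  for (i in seq_len(n)) {
    v <- gt$vessels[[i]]
    idx <- which(v$filled, arr.ind = TRUE)
    vasc[cbind(idx[, 1] + v$offset[1], idx[, 2] + v$offset[2])] <- TRUE
    sk <- skeletonize(v$filled)
    skel_len[i] <- skeleton_length_px(sk) * pitch_um
    idx <- which(sk, arr.ind = TRUE)
    if (nrow(idx))
      skel[cbind(idx[, 1] + v$offset[1], idx[, 2] + v$offset[2])] <- TRUE
  }
  out$MVL_mu <- if (n >= 1) mean(skel_len) else NA_real_
  out$MVA_rx4 <- if (n >= 1) mva_rx4(vasc) else NA_real_
  out$MV_scale <- if (n >= 1) mv_scale(skel, cfg) else NA_real_
  out$ICD <- if (n >= 2)
    icd_mean_points(as.matrix(tr[, c("centre_x", "centre_y")]), pitch_um)
  else NA_real_
  out
}
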