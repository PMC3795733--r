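#' Field-level angiogenesis markers
#'
#' Per-vessel descriptors are aggregated into a per-field marker vector.
#' The validated panel comprises the mean outer perimeter (`MVP_mu`), the
#' coefficient of variation of vessel areas (`MVA_CV`), the luminal
#' fraction (`MV_luminal`), the mass-scaling slope of skeleton content
#' versus window size (`MV_scale`), the hot-spot concentration ratio
#' (`MVA_rx4`), the mean solidity (`MVS_mu`) and the Gabriel-graph mean
#' intercapillary distance (`ICD`); the related density/size family
#' (`MVD`, `MVA_sigma`, `MVA_mu`, `MVP_sigma`, `MVE_mu`, `MVL_mu`) is
#' reported alongside. Markers whose preconditions are not met (too few
#' vessels) are reported as `NA`, never as zero.
#'
#' @name field_markers
NULL

#' Configuration for the mass-scaling slope
#'
#' Square windows of `n_sizes` geometrically spaced side lengths, from
#' `min_size_px` up to the image height, are dropped uniformly at random
#' over the field; the mean skeleton content of the *non-empty* windows at
#' each size is regressed (OLS) on size in log-log coordinates.
#'
#' @param n_sizes Number of window sizes (default 50).
#' @param min_size_px Smallest window side in pixels (default 3).
#' @param max_size_px Largest window side; `NULL` means the image height.
#' @param placements_per_size Random placements per size (default 200).
#' @param seed Integer seed making window placement reproducible.
#' @return A `scale_config` list.
#' @export
scale_config <- function(n_sizes = 50, min_size_px = 3, max_size_px = NULL,
                         placements_per_size = 200, seed = 1L) {
  stopifnot(n_sizes >= 2, min_size_px >= 1, placements_per_size >= 1)
  structure(list(n_sizes = n_sizes, min_size_px = min_size_px,
                 max_size_px = max_size_px,
                 placements_per_size = placements_per_size,
                 seed = as.integer(seed)),
            class = "scale_config")
}

#' Density and size summary of a field
#'
#' @param profiles List of measured `vessel_profile`s.
#' @param field_area_mm2 Field area in square millimetres (for `MVD`).
#' @return One-row data frame with `n_vessels`, `MVD` (vessels/mm^2),
#'   `MVA_sigma`, `MVA_mu`, `MVA_CV`, `MVP_mu`, `MVP_sigma`, `MVE_mu`,
#'   `MVL_mu`. `MVA_CV` uses the sample (n-1) standard deviation and needs
#'   at least two vessels; means need at least one.
#' @export
size_summary <- function(profiles, field_area_mm2) {
  n <- length(profiles)
  areas <- vapply(profiles, function(p) p$vascular_area_um2, numeric(1))
  per <- vapply(profiles, function(p) p$perimeter_um, numeric(1))
  endo <- vapply(profiles, function(p) p$endothelial_area_um2, numeric(1))
  skel <- vapply(profiles, function(p) p$skeleton_length_um, numeric(1))
  data.frame(
    n_vessels = n,
    MVD = n / field_area_mm2,
    MVA_sigma = if (n >= 1) sum(areas) else NA_real_,
    MVA_mu = if (n >= 1) mean(areas) else NA_real_,
    MVA_CV = if (n >= 2) stats::sd(areas) / mean(areas) else NA_real_,
    MVP_mu = if (n >= 1) mean(per) else NA_real_,
    MVP_sigma = if (n >= 1) sum(per) else NA_real_,
    MVE_mu = if (n >= 1) mean(endo) else NA_real_,
    MVL_mu = if (n >= 1) mean(skel) else NA_real_)
}

#' Shape summary of a field
#'
#' @inheritParams size_summary
#' @return One-row data frame with `MVS_mu` (unweighted mean solidity) and
#'   `MV_luminal` (fraction of profiles with at least one lumen).
#' @export
shape_summary <- function(profiles) {
  n <- length(profiles)
  data.frame(
    MVS_mu = if (n >= 1)
      mean(vapply(profiles, function(p) p$solidity, numeric(1))) else NA_real_,
    MV_luminal = if (n >= 1)
      mean(vapply(profiles, function(p) isTRUE(p$has_lumen), logical(1)))
    else NA_real_)
}

#' Hot-spot concentration ratio
#'
#' Ratio of the field's total vascular area to the vascular area of the
#' highest-scoring subfield whose linear dimensions are one quarter of the
#' field's (four times higher magnification). The subfield window slides
#' over the field with stride `max(1, window/8)`. A uniformly vascular
#' field scores ~16; vasculature concentrated in one window-aligned
#' subfield scores 1.
#'
#' @param vascular_mask Logical/numeric matrix marking vascular (filled)
#'   pixels of the whole field.
#' @return The ratio (>= 1 up to window discretization), or `NA` for an
#'   empty mask.
#' @export
mva_rx4 <- function(vascular_mask) {
  total <- sum(vascular_mask != 0)
  if (total == 0) return(NA_real_)
  nr <- nrow(vascular_mask); nc <- ncol(vascular_mask)
  wr <- max(1L, nr %/% 4L); wc <- max(1L, nc %/% 4L)
  sat <- integral_image(vascular_mask != 0)
  stride <- max(1L, wr %/% 8L)
  rs <- unique(c(seq(0L, nr - wr, by = stride), nr - wr))
  cs <- unique(c(seq(0L, nc - wc, by = stride), nc - wc))
  best <- 0
  for (c0 in cs) {
    v <- sat[rs + wr + 1, c0 + wc + 1] - sat[rs + 1, c0 + wc + 1] -
      sat[rs + wr + 1, c0 + 1] + sat[rs + 1, c0 + 1]
    best <- max(best, v)
  }
  total / best
}

#' Mass-scaling slope of the skeleton pattern
#'
#' For each window size, square windows are placed uniformly at random
#' fully inside the field and the skeleton content (number of skeleton
#' pixels) of each is recorded; the mean over non-empty windows is fitted
#' against size by OLS in log-log coordinates. Sizes at which every window
#' is empty are dropped; fewer than two usable sizes yields `NA`. The
#' slope is ~2 for a space-filling pattern, ~1 for a single line, ~0 for
#' an isolated point.
#'
#' @param skeleton_mask Logical/numeric matrix: union of all vessels'
#'   skeleton strokes.
#' @param cfg A [scale_config()].
#' @return The fitted slope (dimensionless).
#' @export
mv_scale <- function(skeleton_mask, cfg = scale_config()) {
  if (sum(skeleton_mask != 0) == 0) return(NA_real_)
  nr <- nrow(skeleton_mask); nc <- ncol(skeleton_mask)
  max_s <- min(if (is.null(cfg$max_size_px)) nr else cfg$max_size_px, nr, nc)
  sizes <- unique(round(exp(seq(log(cfg$min_size_px), log(max_s),
                                length.out = cfg$n_sizes))))
  sat <- integral_image(skeleton_mask != 0)
  with_seed(cfg$seed, {
    mean_content <- vapply(sizes, function(s) {
      r0 <- sample.int(nr - s + 1L, cfg$placements_per_size, replace = TRUE) - 1L
      c0 <- sample.int(nc - s + 1L, cfg$placements_per_size, replace = TRUE) - 1L
      v <- window_sum_at(sat, r0, c0, s)
      v <- v[v > 0]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    ok <- is.finite(mean_content)
    if (sum(ok) < 2) return(NA_real_)
    stats::coef(stats::lm(log(mean_content[ok]) ~ log(sizes[ok])))[[2]]
  })
}

#' Gabriel graph of a point set
#'
#' Two points are Gabriel neighbours iff the closed disc whose diameter is
#' their connecting segment contains no third point (a point exactly on
#' the circle blocks the edge). Coincident points are jittered by 1e-6 px
#' with a seeded RNG so the graph is well defined.
#'
#' @param points Numeric matrix `n x 2` of point coordinates.
#' @param jitter_seed Seed for the duplicate-breaking jitter.
#' @return Integer matrix `m x 2` of point-index pairs (undirected, each
#'   edge once, i < j); zero rows for fewer than two points.
#' @export
gabriel_edges <- function(points, jitter_seed = 1L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2) return(matrix(integer(0), 0, 2))
  if (anyDuplicated(points)) {
    dup <- duplicated(points)
    points[dup, ] <- points[dup, , drop = FALSE] +
      with_seed(jitter_seed, matrix(stats::runif(2 * sum(dup), -1e-6, 1e-6),
                                    ncol = 2))
  }
  d2 <- as.matrix(stats::dist(points))^2
  edges <- matrix(integer(0), 0, 2)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # k blocks (i,j) iff d2[i,k] + d2[j,k] <= d2[i,j]  (closed disc)
      others <- setdiff(seq_len(n), c(i, j))
      if (!length(others) ||
          all(d2[i, others] + d2[j, others] > d2[i, j])) {
        edges <- rbind(edges, c(i, j))
      }
    }
  }
  edges
}

#' Mean intercapillary distance
#'
#' Mean Euclidean centre-to-centre distance over the Gabriel edges of the
#' vessel centroids, converted to micrometres. Distances use vessel centre
#' points, not boundary-to-boundary distances.
#'
#' @inheritParams size_summary
#' @param pitch_um Pixel pitch in micrometres per pixel.
#' @return Mean distance in micrometres, or `NA` with fewer than two
#'   vessels.
#' @export
icd_mean <- function(profiles, pitch_um) {
  if (length(profiles) < 2) return(NA_real_)
  pts <- t(vapply(profiles, function(p) p$centroid_px, numeric(2)))
  icd_mean_points(pts, pitch_um)
}

icd_mean_points <- function(pts, pitch_um) {
  if (nrow(pts) < 2) return(NA_real_)
  e <- gabriel_edges(pts)
  d <- sqrt(rowSums((pts[e[, 1], , drop = FALSE] -
                     pts[e[, 2], , drop = FALSE])^2))
  mean(d) * pitch_um
}

#' Compute the full field-marker vector
#'
#' @param profiles List of measured `vessel_profile`s, typically from
#'   [segment_field()].
#' @param dims Field dimensions `c(rows, cols)` in pixels; defaults to the
#'   `"dims"` attribute of `profiles`.
#' @param pitch_um Pixel pitch in micrometres per pixel; defaults to the
#'   `"pixel_pitch_um"` attribute of `profiles`.
#' @param cfg A [scale_config()] for the mass-scaling slope.
#' @param field_id Field identifier; defaults to the attribute.
#' @return One-row data frame with `field_id`, the size family, `MVS_mu`,
#'   `MV_luminal`, `MVA_rx4`, `MV_scale` and `ICD`. Undefined markers are
#'   `NA`.
#' @export
compute_field_markers <- function(profiles, dims = attr(profiles, "dims"),
                                  pitch_um = attr(profiles, "pixel_pitch_um"),
                                  cfg = scale_config(),
                                  field_id = attr(profiles, "field_id")) {
  stopifnot(length(dims) == 2, pitch_um > 0)
  if (is.null(field_id)) field_id <- "field"
  area_mm2 <- prod(dims) * pitch_um^2 / 1e6
  out <- cbind(data.frame(field_id = field_id),
               size_summary(profiles, area_mm2), shape_summary(profiles))
  vasc <- matrix(FALSE, dims[1], dims[2])
  skel <- matrix(FALSE, dims[1], dims[2])
  for (p in profiles) {
    idx <- which(p$filled, arr.ind = TRUE)
    vasc[cbind(idx[, 1] + p$offset[1], idx[, 2] + p$offset[2])] <- TRUE
    sk <- if (!is.null(p$skeleton)) p$skeleton else skeletonize(p$filled)
    idx <- which(sk, arr.ind = TRUE)
    if (nrow(idx))
      skel[cbind(idx[, 1] + p$offset[1], idx[, 2] + p$offset[2])] <- TRUE
  }
  out$MVA_rx4 <- if (length(profiles)) mva_rx4(vasc) else NA_real_
  out$MV_scale <- if (length(profiles)) mv_scale(skel, cfg) else NA_real_
  out$ICD <- icd_mean(profiles, pitch_um)
  out
}
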