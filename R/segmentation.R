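#' Segmentation of immunostained hot-spot fields
#'
#' A calibrated RGB field is converted into microvessel profiles in four
#' steps: (1) stain detection by a dynamically computed darkness threshold
#' combined with rejection of the haematoxylin (blue) hue band; (2)
#' grouping of stain pixels into 8-connected candidate objects; (3)
#' classification of fully enclosed stain gaps into lumens (wider than the
#' minimum lumen width) or noise gaps (filled back into the stain); and
#' (4) a minimum-width filter that keeps only objects whose filled
#' profile, lumens included, is at least the minimum vessel width wide.
#'
#' @name segmentation
NULL

#' Construct a calibrated image field
#'
#' @param rgb Numeric array `height x width x 3` with values in `[0, 1]`.
#' @param pixel_pitch_um Pixel pitch in micrometres per pixel.
#' @param field_id Identifier carried into output tables.
#' @return An `image_field` object.
#' @export
image_field <- function(rgb, pixel_pitch_um, field_id = "field") {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3,
            all(dim(rgb)[1:2] > 0), pixel_pitch_um > 0)
  structure(list(rgb = rgb, pixel_pitch_um = pixel_pitch_um,
                 field_id = field_id), class = "image_field")
}

#' @export
print.image_field <- function(x, ...) {
  d <- dim(x$rgb)
  cat(sprintf("<image_field '%s': %d x %d px, %.3g um/px (%.3g mm^2)>\n",
              x$field_id, d[1], d[2], x$pixel_pitch_um,
              prod(d[1:2]) * x$pixel_pitch_um^2 / 1e6))
  invisible(x)
}

#' Segmentation configuration
#'
#' @param min_lumen_width_um Minimum largest-inscribed-circle width for an
#'   enclosed stain gap to count as a lumen (default 1.0).
#' @param min_vessel_width_um Minimum width, lumens included, for a
#'   stained object to count as a microvessel (default 3.5).
#' @param haematoxylin_hue_deg Hue interval (degrees) rejected as
#'   counterstain.
#' @param darkness_method `"otsu"` (dynamic, parameter-free) or
#'   `"percentile"`.
#' @param darkness_percentile Percentile of the intensity histogram used
#'   when `darkness_method = "percentile"`.
#' @param retain_border Keep vessels touching the field border (hot-spot
#'   fields crop vessels; discarding them would bias size markers down).
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(min_lumen_width_um = 1.0,
                                min_vessel_width_um = 3.5,
                                haematoxylin_hue_deg = c(180, 280),
                                darkness_method = c("otsu", "percentile"),
                                darkness_percentile = 0.25,
                                retain_border = TRUE) {
  darkness_method <- match.arg(darkness_method)
  stopifnot(min_lumen_width_um > 0,
            min_lumen_width_um < min_vessel_width_um,
            length(haematoxylin_hue_deg) == 2)
  structure(list(min_lumen_width_um = min_lumen_width_um,
                 min_vessel_width_um = min_vessel_width_um,
                 haematoxylin_hue_deg = haematoxylin_hue_deg,
                 darkness_method = darkness_method,
                 darkness_percentile = darkness_percentile,
                 retain_border = retain_border),
            class = "segmentation_config")
}

#' Detect stain pixels
#'
#' A pixel is stain iff its intensity (mean of the RGB channels) lies
#' below a dynamically computed darkness threshold *and* its hue falls
#' outside the haematoxylin band. The darkness threshold is recomputed per
#' image (Otsu's method by default).
#'
#' @param image An [image_field()].
#' @param cfg A [segmentation_config()].
#' @return Logical matrix (the stain mask), with the threshold attached as
#'   attribute `"threshold"`.
#' @export
detect_stain <- function(image, cfg = segmentation_config()) {
  stopifnot(inherits(image, "image_field"))
  r <- image$rgb[, , 1]; g <- image$rgb[, , 2]; b <- image$rgb[, , 3]
  intensity <- (r + g + b) / 3
  thr <- switch(cfg$darkness_method,
    otsu = otsu_threshold(intensity),
    percentile = stats::quantile(intensity, cfg$darkness_percentile,
                                 names = FALSE))
  if (is.na(thr) || diff(range(intensity)) < 1e-12) {
    warning("degenerate intensity histogram; returning an empty stain mask")
    mask <- matrix(FALSE, nrow(intensity), ncol(intensity))
    attr(mask, "threshold") <- NA_real_
    return(mask)
  }
  dark <- intensity < thr
  mask <- dark
  if (any(dark)) {
    hsv <- grDevices::rgb2hsv(rbind(as.vector(r)[dark], as.vector(g)[dark],
                                    as.vector(b)[dark]), maxColorValue = 1)
    hue <- hsv[1, ] * 360
    blue <- hue >= cfg$haematoxylin_hue_deg[1] &
      hue <= cfg$haematoxylin_hue_deg[2]
    mask[dark][blue] <- FALSE
  }
  attr(mask, "threshold") <- thr
  mask
}

#' Classify the enclosed gaps of a candidate object
#'
#' Gaps are 4-connected background components fully enclosed by the
#' object; background touching the crop border is never a gap. A gap whose
#' largest-inscribed-circle width reaches the minimum lumen width is a
#' lumen; narrower gaps are noise and are filled into the stain.
#'
#' @param obj A candidate object as returned internally by
#'   [segment_field()]: a list with a cropped logical `mask` and integer
#'   `offset`.
#' @param cfg A [segmentation_config()].
#' @param pitch_um Pixel pitch in micrometres per pixel.
#' @return A `vessel_profile` (unmeasured): `endothelium` (stain plus
#'   filled noise gaps), `lumens` (list of lumen masks), `filled`, and the
#'   crop `offset`.
#' @export
classify_gaps <- function(obj, cfg = segmentation_config(), pitch_um) {
  m <- obj$mask != 0
  nr <- nrow(m); nc <- ncol(m)
  # pad so outside background forms one border-touching component
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  bg <- label_components(!pad, connectivity = 4)
  border_labels <- unique(c(bg[1, ], bg[nr + 2, ], bg[, 1], bg[, nc + 2]))
  border_labels <- border_labels[border_labels > 0]
  gap_labels <- setdiff(unique(bg[bg > 0]), border_labels)
  endo <- m
  lumens <- list()
  for (lb in gap_labels) {
    gap <- (bg == lb)[2:(nr + 1), 2:(nc + 1), drop = FALSE]
    if (object_width(gap, pitch_um) >= cfg$min_lumen_width_um) {
      lumens[[length(lumens) + 1]] <- gap
    } else {
      endo <- endo | gap
    }
  }
  structure(list(endothelium = endo, lumens = lumens,
                 filled = Reduce(`|`, lumens, endo),
                 offset = obj$offset, vessel_id = obj$vessel_id),
            class = "vessel_profile")
}

#' Apply the minimum-width microvessel filter
#'
#' Keeps gap-classified objects whose filled profile (lumens included) is
#' at least `min_vessel_width_um` wide; narrower objects are discarded as
#' noise or artefacts.
#'
#' @param profiles List of `vessel_profile`s from [classify_gaps()].
#' @inheritParams classify_gaps
#' @return List of retained profiles, renumbered consecutively; the number
#'   discarded is attached as attribute `"n_discarded"`.
#' @export
filter_candidates <- function(profiles, cfg = segmentation_config(), pitch_um) {
  keep <- vapply(profiles, function(p)
    object_width(p$filled, pitch_um) >= cfg$min_vessel_width_um, logical(1))
  out <- profiles[keep]
  for (i in seq_along(out)) out[[i]]$vessel_id <- i
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Segment a field into microvessel profiles
#'
#' Deterministic composition of [detect_stain()], 8-connected component
#' extraction, [classify_gaps()] and [filter_candidates()]. Border-touching
#' objects are retained by default (configurable).
#'
#' @inheritParams detect_stain
#' @param measure Also compute the per-vessel descriptors
#'   ([measure_vessel()]) for each retained profile.
#' @return List of `vessel_profile`s, with attributes `"n_discarded"`
#'   (objects removed by the width filter) and `"dims"` (field size).
#' @export
segment_field <- function(image, cfg = segmentation_config(), measure = TRUE) {
  stopifnot(inherits(image, "image_field"))
  pitch <- image$pixel_pitch_um
  stain <- detect_stain(image, cfg)
  lab <- label_components(stain, connectivity = 8)
  n <- max(lab)
  profiles <- list()
  if (n > 0) {
    idx <- which(lab > 0, arr.ind = TRUE)
    labs <- lab[lab > 0]
    for (k in seq_len(n)) {
      sel <- idx[labs == k, , drop = FALSE]
      if (!isTRUE(cfg$retain_border) &&
          (any(sel[, 1] %in% c(1L, nrow(stain))) ||
           any(sel[, 2] %in% c(1L, ncol(stain))))) next
      r0 <- max(1L, min(sel[, 1]) - 1L); c0 <- max(1L, min(sel[, 2]) - 1L)
      sub <- matrix(FALSE, max(sel[, 1]) - r0 + 2L, max(sel[, 2]) - c0 + 2L)
      sub[cbind(sel[, 1] - r0 + 1L, sel[, 2] - c0 + 1L)] <- TRUE
      obj <- list(mask = sub, offset = c(r0 - 1L, c0 - 1L), vessel_id = k)
      profiles[[length(profiles) + 1]] <- classify_gaps(obj, cfg, pitch)
    }
  }
  profiles <- filter_candidates(profiles, cfg, pitch)
  n_disc <- attr(profiles, "n_discarded")
  if (measure) profiles <- lapply(profiles, measure_vessel, pitch_um = pitch)
  attr(profiles, "n_discarded") <- n_disc
  attr(profiles, "dims") <- dim(stain)
  attr(profiles, "field_id") <- image$field_id
  attr(profiles, "pixel_pitch_um") <- pitch
  profiles
}
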