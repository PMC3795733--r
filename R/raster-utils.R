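# Internal raster helpers.
#
# All masks are logical/numeric matrices indexed [row, col]; pixel centres sit
# on the integer grid, so a pixel is the unit square centred on (row, col).
# Coordinates reported to users are (x = col, y = row).

# Shift a matrix by (dr, dc), zero-filling exposed cells.
mat_shift <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Restore the RNG state on exit; make `expr` deterministic under `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Connected-component labelling. EBImage::bwlabel() is 4-connected; for
# 8-connectivity, diagonal-adjacent 4-labels are merged by union-find.
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  n <- max(lab)
  if (connectivity == 4 || n < 2) return(lab)
  # pairs of distinct labels meeting diagonally
  pairs <- rbind(
    cbind(as.vector(lab[-nrow(lab), -ncol(lab)]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-1, -ncol(lab)]), as.vector(lab[-nrow(lab), -1]))
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  keep <- lab > 0
  lab[keep] <- relab[lab[keep]]
  lab
}

# Euclidean distance from each foreground pixel to the nearest background
# pixel centre, with the image border treated as background (pad-and-crop).
distance_to_background <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- as.numeric(mask != 0)
  d <- EBImage::distmap(pad, metric = "euclidean")
  matrix(as.numeric(d), nr + 2, nc + 2)[2:(nr + 1), 2:(nc + 1)]
}

# Summed-area table with a zero first row/col: sat[r+1, c+1] holds the sum
# of m[1..r, 1..c].
integral_image <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr + 1, nc + 1)
  out[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  out
}

# Sum of the s x s window with 0-based top-left offset (a, b), i.e.
# covering rows a+1..a+s and cols b+1..b+s; a and b may be vectors.
window_sum_at <- function(sat, a, b, s) {
  sat[cbind(a + s + 1, b + s + 1)] - sat[cbind(a + 1, b + s + 1)] -
    sat[cbind(a + s + 1, b + 1)] + sat[cbind(a + 1, b + 1)]
}

# Otsu threshold on values in [0, 1]; returns the threshold or NA when the
# histogram is degenerate (single occupied bin).
otsu_threshold <- function(v, n_bins = 256) {
  v <- v[is.finite(v)]
  if (!length(v)) return(NA_real_)
  brk <- seq(0, 1, length.out = n_bins + 1)
  h <- as.numeric(tabulate(pmin(pmax(findInterval(v, brk,
    rightmost.closed = TRUE), 1L), n_bins), nbins = n_bins))
  if (sum(h > 0) < 2) return(NA_real_)
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  n <- w[n_bins]; mu_t <- mu[n_bins]
  w1 <- w[-n_bins]; mu1 <- mu[-n_bins]
  # between-class variance, up to a constant factor
  between <- (mu1 - w1 * (mu_t / n))^2 / (w1 * (n - w1))
  between[!is.finite(between)] <- -Inf
  # threshold sits at the upper edge of the maximizing bin
  brk[which.max(between) + 1]
}

# Bounding box (rows, cols) of a mask, or NULL if empty.
mask_bbox <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  list(r = range(idx[, 1]), c = range(idx[, 2]))
}

# Crop a mask to its bbox plus `pad` background pixels; returns the cropped
# matrix and the offset such that full coords = cropped coords + offset.
crop_mask <- function(mask, pad = 1) {
  bb <- mask_bbox(mask)
  r0 <- max(1, bb$r[1] - pad); r1 <- min(nrow(mask), bb$r[2] + pad)
  c0 <- max(1, bb$c[1] - pad); c1 <- min(ncol(mask), bb$c[2] + pad)
  list(m = mask[r0:r1, c0:c1, drop = FALSE], offset = c(r0 - 1L, c0 - 1L))
}
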