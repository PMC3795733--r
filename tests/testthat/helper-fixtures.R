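# Shared fixtures: digital shapes, tiny rendered fields and brute-force
# oracles used to cross-check the geometry implementations.

# digital disc; strict = pixel centres with d < r (the digitization whose
# inscribed-circle width is exactly 2r)
disc_mask <- function(r, strict = FALSE, pad = 3) {
  n <- 2 * ceiling(r) + 2 * pad + 1
  ctr <- ceiling(r) + pad + 1
  g <- expand.grid(r_ = 1:n, c_ = 1:n)
  d <- sqrt((g$r_ - ctr)^2 + (g$c_ - ctr)^2)
  matrix(if (strict) d < r else d <= r, n, n)
}

annulus_mask <- function(r_out, r_in, pad = 3) {
  n <- 2 * ceiling(r_out) + 2 * pad + 1
  ctr <- ceiling(r_out) + pad + 1
  g <- expand.grid(r_ = 1:n, c_ = 1:n)
  d <- sqrt((g$r_ - ctr)^2 + (g$c_ - ctr)^2)
  matrix(d <= r_out & d > r_in, n, n)
}

# plus-pentomino, each unit scaled to `u` px per side
plus_mask <- function(u = 15, pad = 2) {
  n <- 3 * u + 2 * pad
  m <- matrix(FALSE, n, n)
  b <- function(i) (pad + (i - 1) * u + 1):(pad + i * u)
  m[b(2), b(1)] <- TRUE; m[b(2), b(2)] <- TRUE; m[b(2), b(3)] <- TRUE
  m[b(1), b(2)] <- TRUE; m[b(3), b(2)] <- TRUE
  m
}

# wrap a mask as an unmeasured vessel_profile
as_profile <- function(filled, lumens = list(), offset = c(0L, 0L), id = 1L) {
  endo <- Reduce(function(a, b) a & !b, lumens, filled)
  structure(list(endothelium = endo, lumens = lumens, filled = filled,
                 offset = offset, vessel_id = id),
            class = "vessel_profile")
}

# brute-force largest-inscribed-circle width: exhaustive per-pixel
# maximization of the distance to the nearest complement pixel (image
# border counts as complement)
brute_force_width <- function(mask, pitch_um = 1) {
  idx <- which(mask != 0, arr.ind = TRUE)
  nr <- nrow(mask); nc <- ncol(mask)
  comp <- which(mask == 0, arr.ind = TRUE)
  # border ring one pixel outside the image
  ring <- rbind(cbind(0, 0:(nc + 1)), cbind(nr + 1, 0:(nc + 1)),
                cbind(1:nr, 0), cbind(1:nr, nc + 1))
  comp <- rbind(comp, ring)
  best <- 0
  for (k in seq_len(nrow(idx))) {
    d <- sqrt((comp[, 1] - idx[k, 1])^2 + (comp[, 2] - idx[k, 2])^2)
    best <- max(best, min(d))
  }
  2 * best * pitch_um
}

# O(n^3) Gabriel-graph definition check with the closed-disc tie rule
brute_force_gabriel <- function(points) {
  n <- nrow(points)
  edges <- matrix(integer(0), 0, 2)
  if (n < 2) return(edges)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      mid <- (points[i, ] + points[j, ]) / 2
      rad2 <- sum((points[i, ] - points[j, ])^2) / 4
      blocked <- FALSE
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        if (sum((points[k, ] - mid)^2) <= rad2 + 1e-12) { blocked <- TRUE; break }
      }
      if (!blocked) edges <- rbind(edges, c(i, j))
    }
  }
  edges
}

# random 8-connected-ish blob grown from a seed pixel
random_blob <- function(n_px = 60, dim = 40, seed = 1) {
  vesselmorph:::with_seed(seed, {
    m <- matrix(FALSE, dim, dim)
    r <- dim %/% 2; c <- dim %/% 2
    m[r, c] <- TRUE
    frontier <- matrix(c(r, c), 1, 2)
    while (sum(m) < n_px && nrow(frontier)) {
      k <- sample.int(nrow(frontier), 1)
      p <- frontier[k, ]
      step <- sample(c(-1L, 0L, 1L), 2, replace = TRUE)
      q <- pmin(pmax(p + step, 2L), dim - 1L)
      if (!m[q[1], q[2]]) {
        m[q[1], q[2]] <- TRUE
        frontier <- rbind(frontier, q)
      }
    }
    m
  })
}

# a small synthetic field spec used across tests (fast to render)
small_field_spec <- function(seed = 42, n_vessels = 8, dim = 512L,
                             n_specks = 20L, n_nuclei = 30L, ...) {
  sample_field_spec(c(list(height_px = dim, width_px = dim,
                           n_vessels = n_vessels, n_specks = n_specks,
                           n_nuclei = n_nuclei), list(...)), seed = seed)
}

# paint simple DAB-coloured rectangles on a white background; rects is a
# list of c(r0, r1, c0, c1)
rect_image <- function(dim, rects, pitch_um = 0.34) {
  arr <- array(0.94, c(dim, dim, 3))
  dab <- c(0.42, 0.33, 0.19)
  for (rc in rects) for (ch in 1:3)
    arr[rc[1]:rc[2], rc[3]:rc[4], ch] <- dab[ch]
  image_field(arr, pitch_um, "rects")
}
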