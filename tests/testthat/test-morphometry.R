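test_that("areas are additive pixel counts scaled by the squared pitch", {
  filled <- matrix(FALSE, 20, 20)
  filled[5:14, 5:14] <- TRUE             # 100 px
  p <- as_profile(filled)
  a <- measure_areas(p, 0.34)
  expect_equal(unname(a["vascular_um2"]), 100 * 0.34^2)
  expect_equal(unname(a["luminal_um2"]), 0)

  ann <- annulus_mask(8, 5)
  lum <- disc_mask(5, pad = 6)           # same grid as annulus_mask(8,...)
  # build lumen aligned with the annulus interior
  n <- nrow(ann)
  g <- expand.grid(r_ = 1:n, c_ = 1:n)
  ctr <- (n + 1) / 2
  lum <- matrix(sqrt((g$r_ - ctr)^2 + (g$c_ - ctr)^2) <= 5, n, n)
  p <- as_profile(ann | lum, lumens = list(lum))
  a <- measure_areas(p, 0.34)
  expect_equal(unname(a["vascular_um2"]),
               unname(a["endothelial_um2"] + a["luminal_um2"]))
  expect_equal(unname(a["endothelial_um2"]), sum(ann) * 0.34^2)
})

test_that("outer perimeter tracks the continuum circle and excludes lumens", {
  for (r in c(30, 50, 80)) {
    p <- as_profile(disc_mask(r))
    expect_lt(abs(outer_perimeter(p, 1) / (2 * pi * r) - 1), 0.03)
  }
  # annulus and its filled disc share the outer boundary
  ann <- annulus_mask(30, 20)
  filled <- disc_mask(30)
  stopifnot(dim(ann)[1] == dim(filled)[1])
  n <- nrow(ann); g <- expand.grid(r_ = 1:n, c_ = 1:n); ctr <- (n + 1) / 2
  lum <- matrix(sqrt((g$r_ - ctr)^2 + (g$c_ - ctr)^2) <= 20, n, n)
  expect_equal(outer_perimeter(as_profile(ann | lum, list(lum)), 1),
               outer_perimeter(as_profile(filled), 1))
  # single pixel reads as a unit pixel square
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_equal(outer_perimeter(as_profile(single), 0.34), 4 * 0.34)
})

test_that("width equals exhaustive per-pixel maximization on random blobs", {
  for (s in 1:20) {
    blob <- random_blob(n_px = 40 + 5 * s, dim = 36, seed = s)
    expect_equal(object_width(blob, 1), brute_force_width(blob),
                 tolerance = 1e-8)
  }
  # rectangle and disc conventions
  rect <- matrix(FALSE, 30, 50); rect[6:17, 6:45] <- TRUE   # 12 x 40
  expect_lt(abs(object_width(rect, 1) - 12), 1 + 1e-9)
  d <- disc_mask(10, strict = TRUE)
  expect_lt(abs(object_width(d, 1) - 20), 1 + 1e-9)
  expect_error(object_width(matrix(FALSE, 4, 4), 1), "empty")
})

test_that("solidity is exact for convex shapes and the plus-pentomino", {
  rect <- matrix(FALSE, 30, 50); rect[6:25, 6:45] <- TRUE
  expect_equal(convex_solidity(as_profile(rect)), 1)
  expect_equal(convex_solidity(as_profile(plus_mask(15))), 5 / 7,
               tolerance = 0.02 * 7 / 5)
  # carving a concave notch strictly decreases solidity
  d <- disc_mask(20)
  notched <- d
  notched[1:ceiling(nrow(d) / 2), (ncol(d) %/% 2 - 2):(ncol(d) %/% 2 + 2)] <- FALSE
  expect_lt(convex_solidity(as_profile(notched)),
            convex_solidity(as_profile(d)))
  # solidity uses the filled set: annulus equals its filled disc
  ann <- annulus_mask(25, 18)
  n <- nrow(ann); g <- expand.grid(r_ = 1:n, c_ = 1:n); ctr <- (n + 1) / 2
  lum <- matrix(sqrt((g$r_ - ctr)^2 + (g$c_ - ctr)^2) <= 18, n, n)
  expect_equal(convex_solidity(as_profile(ann | lum, list(lum))),
               convex_solidity(as_profile(disc_mask(25))))
})

test_that("skeleton length and branch points match simple constructions", {
  bar <- matrix(FALSE, 20, 120); bar[9:11, 6:105] <- TRUE  # 3 x 100 bar
  p <- as_profile(bar)
  sk <- skeleton_metrics(p, 1)
  expect_equal(sk$skeleton_length_um, 100, tolerance = 0.05)
  expect_equal(sk$n_branch_points, 0)
  # Y-shaped union of three bars: one branch-point cluster
  y <- matrix(FALSE, 80, 80)
  y[40:42, 10:40] <- TRUE                       # horizontal arm
  for (k in 0:30) {                              # two diagonal arms
    y[pmin(80, 40 + k + 0:2), pmin(80, 40 + k)] <- TRUE
    y[pmax(1, 40 - k + 0:2), pmin(80, 40 + k)] <- TRUE
  }
  expect_equal(skeleton_metrics(as_profile(y), 1)$n_branch_points, 1)
  # a disc thins to something point-like: no branch points
  expect_equal(skeleton_metrics(as_profile(disc_mask(15)), 1)$n_branch_points, 0)
})

test_that("centroid is the mean of filled pixels, offset-aware", {
  d <- matrix(FALSE, 9, 9); d[4:6, 4:6] <- TRUE
  p <- as_profile(d, offset = c(10L, 20L))
  expect_equal(unname(centroid(p)), c(25, 15))   # (x = col+20, y = row+10)
  two <- matrix(FALSE, 5, 5); two[2, c(2, 4)] <- TRUE
  expect_equal(unname(centroid(as_profile(two))), c(3, 2))
})

test_that("descriptors are rotation-robust and scale-covariant", {
  base <- matrix(FALSE, 60, 90); base[21:40, 16:75] <- TRUE  # 20 x 60 rect
  p0 <- as_profile(base)
  p90 <- as_profile(t(base))
  expect_equal(outer_perimeter(p90, 1), outer_perimeter(p0, 1))
  expect_equal(convex_solidity(p90), convex_solidity(p0))
  expect_equal(object_width(t(base), 1), object_width(base, 1))
  # 45-degree rotation: perimeter within 3%
  n <- 121
  g <- expand.grid(r_ = 1:n, c_ = 1:n)
  u <- (g$r_ - 61 + g$c_ - 61) / sqrt(2); v <- (g$r_ - 61 - g$c_ + 61) / sqrt(2)
  rot <- matrix(abs(u) <= 10 & abs(v) <= 30, n, n)
  expect_lt(abs(outer_perimeter(as_profile(rot), 1) /
                outer_perimeter(p0, 1) - 1), 0.03)
  # 2x supersampling doubles perimeter and quadruples area within 2%
  big <- base[rep(seq_len(nrow(base)), each = 2), rep(seq_len(ncol(base)), each = 2)]
  expect_lt(abs(outer_perimeter(as_profile(big), 1) /
                (2 * outer_perimeter(p0, 1)) - 1), 0.02)
  expect_equal(sum(big), 4 * sum(base))
})
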