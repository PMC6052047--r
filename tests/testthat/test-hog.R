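test_that("binarization is a strict threshold against the background mean", {
  expect_true(all(binarize_patch(matrix(60, 10, 10), 60) == 0))
  expect_true(all(binarize_patch(matrix(61, 10, 10), 60) == 1))
  set.seed(3)
  p <- matrix(sample(0:255, 400, TRUE), 20, 20)
  b <- binarize_patch(p, 117.5)
  oracle <- matrix(0L, 20, 20)
  for (y in 1:20) for (x in 1:20) if (p[y, x] > 117.5) oracle[y, x] <- 1L
  expect_identical(b, oracle)
  # dark-on-bright polarity flips the comparison
  expect_identical(binarize_patch(p, 117.5, "dark"),
                   matrix(as.integer(p < 117.5), 20, 20))
})

test_that("cell histograms match a naive per-pixel accumulation", {
  cfg <- zf_config()
  expect_true(all(hog_map(matrix(80, 100, 100), cfg)$cell_hist == 0))

  set.seed(11)
  p <- matrix(runif(100 * 100, 0, 255), 100, 100)
  m <- hog_map(p, cfg)
  expect_equal(dim(m$cell_hist), c(11, 11, 9))
  expect_equal(dim(m$blocks), c(10, 10, 36))
  # naive oracle: same gradient convention, pixel loops
  H <- 100; W <- 100
  oracle <- array(0, c(11, 11, 9))
  for (y in 1:H) for (x in 1:W) {
    xl <- p[y, max(x - 1, 1)]; xr <- p[y, min(x + 1, W)]
    yu <- p[max(y - 1, 1), x]; yd <- p[min(y + 1, H), x]
    gx <- xr - xl; gy <- -(yd - yu)
    mag <- sqrt(gx^2 + gy^2)
    if (mag == 0) next
    ang <- atan2(gy, gx)
    if (ang < 0) ang <- ang + pi
    bin <- min(floor(ang / (pi / 9)), 8) + 1
    cy <- (y - 1) %/% 9 + 1; cx <- (x - 1) %/% 9 + 1
    if (cy > 11 || cx > 11) next
    oracle[cy, cx, bin] <- oracle[cy, cx, bin] + mag
  }
  expect_equal(m$cell_hist, oracle, tolerance = 1e-6)
  # every block vector is unit-normalized (or zero)
  nrm <- apply(m$blocks, c(1, 2), function(v) sqrt(sum(v^2)))
  expect_true(all(abs(nrm - 1) < 1e-9 | nrm == 0))
})

test_that("a vertical step edge votes into the horizontal-gradient bin", {
  p <- matrix(0, 100, 100)
  p[, 51:100] <- 200
  m <- hog_map(p, zf_config())
  # edge between columns 50/51 straddles cell column 6
  hist <- m$cell_hist[5, 6, ]
  expect_gt(hist[1], 0)            # bin 1 = orientations around 0 degrees
  expect_equal(sum(hist[-1]), 0)
  expect_equal(sum(m$cell_hist[5, 2, ]), 0)  # flat region, no gradient
})

test_that("relevance masks count foreground pixels per cell", {
  cfg <- zf_config()
  z <- matrix(0L, 100, 100)
  rm0 <- relevance_mask(z, cfg)
  expect_true(all(rm0$cell_mask == 0))
  expect_true(all(rm0$block_mask == 0))

  # exactly P_c = 10 foreground pixels in cell (3, 4)
  p <- matrix(0L, 100, 100)
  p[19:23, 28:29] <- 1L
  rm1 <- relevance_mask(p, cfg)
  expect_equal(sum(rm1$cell_mask), 1)
  expect_equal(rm1$cell_mask[3, 4], 1L)
  expect_equal(sum(rm1$block_mask), 4)   # the four blocks containing it
  expect_true(all(rm1$block_mask[2:3, 3:4] == 1L))
  # one pixel fewer falls below the threshold
  p[19, 28] <- 0L
  expect_equal(sum(relevance_mask(p, cfg)$cell_mask), 0)

  set.seed(5)
  r <- matrix(as.integer(runif(1e4) < 0.15), 100, 100)
  rmr <- relevance_mask(r, cfg)
  counts <- matrix(0L, 11, 11)
  for (cy in 1:11) for (cx in 1:11) {
    counts[cy, cx] <- sum(r[((cy - 1) * 9 + 1):(cy * 9),
                            ((cx - 1) * 9 + 1):(cx * 9)])
  }
  expect_identical(rmr$cell_mask, matrix(as.integer(counts >= 10), 11, 11))
  for (by in 1:10) for (bx in 1:10) {
    expect_equal(rmr$block_mask[by, bx],
                 as.integer(any(rmr$cell_mask[by:(by + 1), bx:(bx + 1)] == 1L)))
  }
})

test_that("the mask is invariant to a uniform illumination shift", {
  set.seed(6)
  p <- matrix(runif(1e4, 0, 255), 100, 100)
  b1 <- binarize_patch(p, 117)
  b2 <- binarize_patch(p + 15, 117 + 15)   # shift below Thr_g, model follows
  expect_identical(b1, b2)
})

test_that("spiral enumeration starts centre-out, right then clockwise", {
  # frozen 3x3 order, worked out by hand
  expect_equal(spiral_order(3, 3),
               matrix(c(2, 2, 2, 3, 3, 3, 3, 2, 3, 1, 2, 1, 1, 1, 1, 2, 1, 3),
                      ncol = 2, byrow = TRUE, dimnames = list(NULL, c("row", "col"))))
  # frozen first positions of the even 4x4 grid (centre = upper-left of the
  # central 2x2)
  o44 <- spiral_order(4, 4)
  expect_equal(o44[1:8, ],
               matrix(c(2, 2, 2, 3, 3, 3, 3, 2, 3, 1, 2, 1, 1, 1, 1, 2),
                      ncol = 2, byrow = TRUE, dimnames = list(NULL, c("row", "col"))))
  for (dims in list(c(5, 5), c(10, 10), c(4, 7), c(7, 4), c(1, 6))) {
    o <- spiral_order(dims[1], dims[2])
    expect_equal(nrow(o), prod(dims))
    expect_false(any(duplicated(o)))
    expect_equal(o, oracle_spiral(dims[1], dims[2]))
  }
})

test_that("spiral selection emits fixed-length, zero-padded descriptors", {
  cfg <- zf_config()
  set.seed(12)
  p <- matrix(runif(1e4, 0, 255), 100, 100)
  map <- hog_map(p, cfg)

  all1 <- list(cell_mask = matrix(1L, 11, 11), block_mask = matrix(1L, 10, 10))
  f <- spiral_select(map, all1, 34)
  expect_length(f$vector, 34 * 4 * 9)
  expect_false(f$padded)
  expect_equal(f$n_blocks_found, 100)

  all0 <- list(cell_mask = matrix(0L, 11, 11), block_mask = matrix(0L, 10, 10))
  f0 <- spiral_select(map, all0, 34)
  expect_true(all(f0$vector == 0))
  expect_equal(f0$n_blocks_found, 0)
  expect_true(f0$padded)

  # random mask: selected coordinates equal the masked spiral prefix
  set.seed(13)
  bm <- matrix(as.integer(runif(100) < 0.4), 10, 10)
  fr <- spiral_select(map, list(cell_mask = NULL, block_mask = bm), 20)
  ord <- oracle_spiral(10, 10)
  keep <- ord[bm[ord] == 1L, , drop = FALSE]
  expect_equal(fr$coords, keep[1:min(20, nrow(keep)), , drop = FALSE],
               ignore_attr = TRUE)
  k <- min(20, nrow(keep))
  expect_equal(fr$vector[1:36], map$blocks[keep[1, 1], keep[1, 2], ])
  expect_equal(fr$n_blocks_found, nrow(keep))
})

test_that("the descriptor is deterministic and pose-stable per fish", {
  cfg <- zf_config()
  f1 <- feature_at(1, 137)
  f2 <- feature_at(1, 137)
  expect_identical(f1$feature$vector, f2$feature$vector)

  f0 <- feature_at(1, 0)
  same_fish <- cosine_similarity(f0$feature$vector, f1$feature$vector)
  expect_gte(same_fish, 0.9)
  g0 <- feature_at(2, 0)
  cross_fish <- cosine_similarity(f0$feature$vector, g0$feature$vector)
  expect_lt(cross_fish, same_fish)
  expect_equal(length(f0$feature$vector), cfg$P_b * 4 * cfg$n_bins)
  expect_equal(length(g0$feature$vector), length(f1$feature$vector))
})
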