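#' Binarize an ROI patch against the background mean
#'
#' A pixel is foreground (1) when its intensity strictly exceeds the average
#' intensity of the background model; the comparison is flipped when the fish
#' are darker than the background.
#'
#' @param patch grayscale matrix.
#' @param mean_level scalar mean of the background model.
#' @param polarity `"bright"` (default) or `"dark"`.
#' @return integer 0/1 matrix of the same size.
#' @export
binarize_patch <- function(patch, mean_level, polarity = "bright") {
  if (polarity == "bright") {
    (patch > mean_level) + 0L
  } else {
    (patch < mean_level) + 0L
  }
}

#' Gradient-orientation histogram map of a patch
#'
#' Standard histogram-of-oriented-gradients front end: centered [-1, 0, 1]
#' gradients (edge-replicated at the borders), unsigned orientations binned
#' into `n_bins` bins of 180/n_bins degrees with magnitude-weighted votes,
#' per-cell histograms over non-overlapping `cell_px` squares (the pixel
#' remainder beyond the last full cell is ignored), and blocks of
#' `block_cells^2` cells at one-cell stride whose concatenated histograms are
#' L2-normalized jointly. For a 100 px patch with 9 px cells this gives an
#' 11 x 11 cell grid and a 10 x 10 block grid.
#'
#' @param patch grayscale matrix, at least one block wide and tall.
#' @param cfg a [zf_config()].
#' @return list of class `zf_hogmap`: `cell_hist` (array cells_r x cells_c x
#'   n_bins), `blocks` (array blocks_r x blocks_c x (block_cells^2 * n_bins)),
#'   `n_bins`, `cell_px`, `block_cells`.
#' @export
hog_map <- function(patch, cfg = zf_config()) {
  H <- nrow(patch); W <- ncol(patch)
  cell <- cfg$cell_px; bc <- cfg$block_cells; nb <- cfg$n_bins
  n_cr <- H %/% cell; n_cc <- W %/% cell
  if (n_cr < bc || n_cc < bc)
    stop("patch smaller than one block", call. = FALSE)
  # centered gradients with edge replication; y points down, so gy is negated
  # to measure orientations in the y-up sense
  xl <- patch[, c(1, seq_len(W - 1))]; xr <- patch[, c(seq_len(W - 1) + 1, W)]
  yu <- patch[c(1, seq_len(H - 1)), ]; yd <- patch[c(seq_len(H - 1) + 1, H), ]
  gx <- xr - xl
  gy <- -(yd - yu)
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  bin <- pmin(floor(ang / (pi / nb)), nb - 1) + 1L
  bin[mag == 0] <- 0L
  storage.mode(bin) <- "integer"
  ch <- cpp_cell_hist(mag, bin, as.integer(cell), n_cr, n_cc, nb)
  cell_hist <- array(ch, c(n_cr, n_cc, nb))
  n_br <- n_cr - bc + 1L; n_bc <- n_cc - bc + 1L
  blk_len <- bc * bc * nb
  blocks <- array(0, c(n_br, n_bc, blk_len))
  for (r in seq_len(n_br)) {
    for (c in seq_len(n_bc)) {
      v <- as.numeric(cell_hist[r:(r + bc - 1), c:(c + bc - 1), ])
      nv <- sqrt(sum(v^2))
      if (nv > 0) v <- v / nv
      blocks[r, c, ] <- v
    }
  }
  out <- list(cell_hist = cell_hist, blocks = blocks, n_bins = nb,
              cell_px = cell, block_cells = bc)
  class(out) <- "zf_hogmap"
  out
}

#' Mark descriptor cells and blocks relevant to the body texture
#'
#' A cell is relevant (1) when it contains at least `P_c` foreground pixels
#' of the binarized patch; a block is relevant when any of its member cells
#' is. Only relevant blocks carry back-texture information and enter the
#' final descriptor.
#'
#' @param bin_patch 0/1 matrix from [binarize_patch()], aligned with the cell
#'   grid of the patch.
#' @param cfg a [zf_config()].
#' @return list of class `zf_relevance`: `cell_mask`, `block_mask` (0/1
#'   matrices matching the cell and block grids).
#' @export
relevance_mask <- function(bin_patch, cfg = zf_config()) {
  cell <- cfg$cell_px; bc <- cfg$block_cells
  n_cr <- nrow(bin_patch) %/% cell; n_cc <- ncol(bin_patch) %/% cell
  ones <- matrix(1L, nrow(bin_patch), ncol(bin_patch))
  ones[bin_patch == 0] <- 0L
  counts <- cpp_cell_hist(ones + 0, ones, as.integer(cell), n_cr, n_cc, 1L)
  cell_mask <- matrix(as.integer(counts >= cfg$P_c), n_cr, n_cc)
  n_br <- n_cr - bc + 1L; n_bc <- n_cc - bc + 1L
  block_mask <- matrix(0L, n_br, n_bc)
  for (r in seq_len(n_br)) {
    for (c in seq_len(n_bc)) {
      block_mask[r, c] <-
        as.integer(any(cell_mask[r:(r + bc - 1), c:(c + bc - 1)] == 1L))
    }
  }
  out <- list(cell_mask = cell_mask, block_mask = block_mask)
  class(out) <- "zf_relevance"
  out
}

#' Centre-out spiral enumeration of a grid
#'
#' Enumerates all positions of an `nr x nc` grid in a deterministic outward
#' spiral: start at the grid centre (for even dimensions, the upper-left
#' element of the central 2x2), first step to the right, turning clockwise
#' on screen (right, down, left, up).
#'
#' @param nr,nc grid dimensions.
#' @return integer matrix with columns `row`, `col`, one grid position per
#'   row, in spiral order.
#' @export
spiral_order <- function(nr, nc) {
  r <- ceiling(nr / 2); c <- ceiling(nc / 2)
  dirs <- rbind(c(0, 1), c(1, 0), c(0, -1), c(-1, 0))  # right, down, left, up
  out <- matrix(NA_integer_, nr * nc, 2)
  n_found <- 0L
  if (r >= 1 && r <= nr && c >= 1 && c <= nc) {
    n_found <- 1L
    out[1, ] <- c(r, c)
  }
  d <- 1L; run <- 1L
  while (n_found < nr * nc) {
    for (rep in 1:2) {
      for (s in seq_len(run)) {
        r <- r + dirs[d, 1]; c <- c + dirs[d, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc) {
          n_found <- n_found + 1L
          out[n_found, ] <- c(r, c)
          if (n_found == nr * nc) break
        }
      }
      d <- d %% 4L + 1L
      if (n_found == nr * nc) break
    }
    run <- run + 1L
    if (run > 4L * max(nr, nc)) break   # safety; cannot trigger for valid grids
  }
  colnames(out) <- c("row", "col")
  out
}

#' Spiral selection of relevant blocks into the final descriptor
#'
#' Walks the block grid in the centre-out spiral order and collects the
#' normalized vectors of the first `P_b` blocks marked relevant. The output
#' length is always `P_b * block_cells^2 * n_bins`; when fewer relevant
#' blocks exist the vector is zero-padded and `padded` is set.
#'
#' @param map a `zf_hogmap` from [hog_map()].
#' @param mask a `zf_relevance` from [relevance_mask()].
#' @param P_b number of blocks to emit.
#' @return list of class `zf_hogfeature`: `vector`, `n_blocks_found`,
#'   `padded`, `coords` (selected block positions, in order).
#' @export
spiral_select <- function(map, mask, P_b) {
  bm <- mask$block_mask
  stopifnot(identical(dim(bm), dim(map$blocks)[1:2]), P_b >= 1)
  ord <- spiral_order(nrow(bm), ncol(bm))
  keep <- ord[bm[ord] == 1L, , drop = FALSE]
  n_take <- min(nrow(keep), P_b)
  blk_len <- dim(map$blocks)[3]
  vec <- numeric(P_b * blk_len)
  for (k in seq_len(n_take)) {
    vec[((k - 1) * blk_len + 1):(k * blk_len)] <-
      map$blocks[keep[k, 1], keep[k, 2], ]
  }
  out <- list(vector = vec, n_blocks_found = nrow(keep),
              padded = nrow(keep) < P_b,
              coords = keep[seq_len(n_take), , drop = FALSE])
  class(out) <- "zf_hogfeature"
  out
}

#' Extract the improved-HOG feature of an accepted ROI
#'
#' Composition of [binarize_patch()], [hog_map()], [relevance_mask()] and
#' [spiral_select()]: the back-texture descriptor of one head-normalized
#' body sample. Deterministic.
#'
#' @param roi an accepted `zf_roi` from [extract_roi()].
#' @param bg a `zf_background` (its mean level drives binarization).
#' @param cfg a [zf_config()].
#' @return a `zf_hogfeature`.
#' @export
extract_feature <- function(roi, bg, cfg = zf_config()) {
  if (!identical(roi$quality, "accepted"))
    stop("feature extraction requires an accepted ROI", call. = FALSE)
  bp <- binarize_patch(roi$patch, bg$mean_level, cfg$polarity)
  map <- hog_map(roi$patch, cfg)
  mask <- relevance_mask(bp, cfg)
  spiral_select(map, mask, cfg$P_b)
}

#' Plain HOG baseline descriptor
#'
#' The unmasked, orientation-naive baseline: the full block grid of
#' [hog_map()] computed on an axis-aligned crop (no head-right rotation, no
#' relevance masking, no spiral selection), concatenated in grid order. Used
#' to contrast the orientation robustness of the improved descriptor.
#'
#' @param patch grayscale matrix (e.g. an axis-aligned crop rescaled to
#'   `P_r`).
#' @param cfg a [zf_config()].
#' @return numeric vector of all block descriptors.
#' @export
plain_hog_feature <- function(patch, cfg = zf_config()) {
  map <- hog_map(patch, cfg)
  as.numeric(map$blocks)
}

#' Cosine similarity of two feature vectors
#'
#' @param a,b numeric vectors of equal length.
#' @return cosine similarity in [-1, 1]; 0 if either vector is all zero.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}
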