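#' Build the static background model
#'
#' Averages the first `f` frames pixel-wise: `Bm(x, y) = sum_t G_t(x, y) / f`.
#' A static model suffices because the imaging arena is stable; the model's
#' overall mean intensity (`mean_level`) is also the reference used when
#' binarizing ROI patches for the relevance mask.
#'
#' @param frames list of numeric matrices with identical dimensions.
#' @param f number of leading frames to average (default `min(100, length)`).
#' @return An object of class `zf_background`: `Bm` (matrix), `f`,
#'   `mean_level`.
#' @export
build_background <- function(frames, f = min(100L, length(frames))) {
  if (length(frames) == 0) stop("empty frame sequence", call. = FALSE)
  f <- as.integer(f)
  if (f < 1 || f > length(frames))
    stop("f must be between 1 and the number of frames", call. = FALSE)
  dims <- dim(frames[[1]])
  acc <- matrix(0, dims[1], dims[2])   # double accumulator, no overflow
  for (t in seq_len(f)) {
    if (!identical(dim(frames[[t]]), dims))
      stop("frames have mismatched dimensions", call. = FALSE)
    acc <- acc + frames[[t]]
  }
  out <- list(Bm = acc / f, f = f, mean_level = mean(acc) / f)
  class(out) <- "zf_background"
  out
}

#' Fit the second-moment ellipse of a pixel component
#'
#' Returns the ellipse whose second central moments equal those of the pixel
#' set, the standard blob-orientation estimate. The tilt angle is measured
#' from the horizontal image axis to the major axis, counter-clockwise
#' positive in the (x right, y up) sense (the y pixel axis points down), and
#' normalized to [-90, 90). For degenerate (collinear) components the
#' bounding-box axis is used instead, with a warning.
#'
#' @param xs,ys 0-based pixel coordinates of the component.
#' @return list: `centre` (x, y), `theta_raw` (deg), `major`, `minor`
#'   (semi-axes, px), `aspect_ratio`.
#' @export
fit_ellipse <- function(xs, ys) {
  n <- length(xs)
  stopifnot(n == length(ys), n >= 1)
  cx <- mean(xs); cy <- mean(ys)
  bb <- function() {
    w <- max(xs) - min(xs) + 1; h <- max(ys) - min(ys) + 1
    list(centre = c(cx, cy), theta_raw = if (w >= h) 0 else -90,
         major = max(w, h) / 2, minor = min(w, h) / 2,
         aspect_ratio = max(w, h) / min(w, h))
  }
  if (n < 5) {
    warning("component with < 5 pixels: bounding-box fallback")
    return(bb())
  }
  dx <- xs - cx; dy <- ys - cy
  mu20 <- mean(dx * dx); mu02 <- mean(dy * dy); mu11 <- mean(dx * dy)
  disc <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- (mu20 + mu02) / 2 + disc
  l2 <- (mu20 + mu02) / 2 - disc
  if (l2 <= 1e-9) {
    warning("degenerate (collinear) component: bounding-box fallback")
    return(bb())
  }
  # y points down, so negate mu11 for a counter-clockwise (y-up) angle
  theta <- 0.5 * atan2(-2 * mu11, mu20 - mu02) * 180 / pi
  if (theta >= 90) theta <- theta - 180
  if (theta < -90) theta <- theta + 180
  list(centre = c(cx, cy), theta_raw = theta,
       major = 2 * sqrt(l1), minor = 2 * sqrt(l2),
       aspect_ratio = sqrt(l1 / l2))
}

#' Segment the fish blobs of one frame
#'
#' Background subtraction: pixels whose absolute difference from the
#' background model exceeds `Thr_g` are foreground; 8-connected components
#' smaller than `Thr_s` px^2 are discarded; each surviving component yields
#' one detection with second-moment ellipse geometry. Detections are ordered
#' by component label (raster order of first pixel), which makes the output
#' deterministic.
#'
#' @param frame numeric matrix matching the background dimensions.
#' @param bg a `zf_background`.
#' @param cfg a [zf_config()].
#' @param frame_index frame number stored on each detection.
#' @return list of detections; each is a list with `frame_index`, `centroid`
#'   (0-based x, y), `theta_raw`, `rect` (centre, width, height, angle),
#'   `area`, `aspect_ratio`, `mask_id`, and the component pixel coordinates
#'   `xs`, `ys` (0-based).
#' @export
segment_frame <- function(frame, bg, cfg = zf_config(), frame_index = NA_integer_) {
  stopifnot(inherits(bg, "zf_background"))
  if (!identical(dim(frame), dim(bg$Bm)))
    stop("frame dimensions do not match the background model", call. = FALSE)
  fg <- abs(frame - bg$Bm) > cfg$Thr_g
  lab <- cpp_label8(fg)
  if (max(lab) == 0L) return(list())
  H <- nrow(frame)
  idx <- which(lab > 0L)
  comp <- split(idx, lab[idx])
  out <- list()
  for (ci in seq_along(comp)) {
    pix <- comp[[ci]]
    if (length(pix) < cfg$Thr_s) next
    xs <- (pix - 1L) %/% H
    ys <- (pix - 1L) %% H
    e <- fit_ellipse(xs, ys)
    out[[length(out) + 1L]] <- list(
      frame_index = frame_index, centroid = e$centre,
      theta_raw = e$theta_raw,
      rect = list(centre = e$centre, width = 2 * e$major,
                  height = 2 * e$minor, angle = e$theta_raw),
      area = length(pix), aspect_ratio = e$aspect_ratio,
      mask_id = as.integer(names(comp)[ci]), xs = xs, ys = ys)
  }
  out
}
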