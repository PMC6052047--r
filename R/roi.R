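#' Resolve the head side of a detected fish
#'
#' The fitted body axis splits the enclosing rectangle across its minor axis;
#' the head lies on the half with the larger foreground-pixel count (the
#' anterior body is wider than the tail). The body is classed as left-right
#' oriented when `theta_raw` is within (-45, 45) degrees and up-down
#' otherwise, and the resolved side is reported as one of four quadrant
#' regions: 1 = up, 2 = down, 3 = left, 4 = right.
#'
#' Exact pixel-count ties are broken toward the direction of recent motion
#' when `velocity` is supplied, else toward the half with the larger
#' intensity sum.
#'
#' @param frame the frame image (used only for tie-breaking).
#' @param det a detection from [segment_frame()].
#' @param velocity optional c(dx, dy) of recent motion for tie-breaking
#'   (y down).
#' @return list: `region` (1-4), `sign` (+1 if the head lies along the
#'   +theta_raw axis direction, -1 otherwise).
#' @export
resolve_head <- function(frame, det, velocity = NULL) {
  th <- det$theta_raw * pi / 180
  dx <- det$xs - det$centroid[1]
  dy <- det$ys - det$centroid[2]
  proj <- dx * cos(th) - dy * sin(th)   # y down: -sin gives the y-up sense
  n_pos <- sum(proj > 0); n_neg <- sum(proj < 0)
  if (n_pos != n_neg) {
    s <- if (n_pos > n_neg) 1 else -1
  } else if (!is.null(velocity)) {
    s <- if (velocity[1] * cos(th) - velocity[2] * sin(th) >= 0) 1 else -1
  } else {
    vals <- frame[cbind(det$ys + 1, det$xs + 1)]
    s <- if (sum(vals[proj > 0]) >= sum(vals[proj < 0])) 1 else -1
  }
  region <- head_region(det$theta_raw, s)
  list(region = region, sign = s)
}

# Quadrant region label from the axis angle and the head sign.
head_region <- function(theta_raw, s) {
  if (theta_raw > -45 && theta_raw < 45) {
    if (s > 0) 4L else 3L                 # right / left
  } else if (theta_raw >= 45) {
    if (s > 0) 1L else 2L                 # axis points up on screen
  } else {
    if (s > 0) 2L else 1L                 # axis points down on screen
  }
}

#' Full body angle from tilt angle and head side
#'
#' Combines the ellipse tilt angle `theta_raw` in [-90, 90) with the resolved
#' head region into the full pointing direction in [0, 360). The mapping is
#' total and single-valued: the head direction is the +axis direction when the
#' head region lies on that side, and the opposite direction otherwise, so
#' rotating the patch by the result always puts the head to the right.
#'
#' @param theta_raw ellipse tilt angle in degrees, [-90, 90).
#' @param pHead head region label (1-4) from [resolve_head()].
#' @return the full angle in degrees, [0, 360).
#' @export
full_angle <- function(theta_raw, pHead) {
  stopifnot(theta_raw >= -90, theta_raw < 90, pHead %in% 1:4)
  lr <- theta_raw > -45 & theta_raw < 45
  if (lr && !pHead %in% 3:4)
    stop("head region ", pHead, " inconsistent with a left-right body axis",
         call. = FALSE)
  if (!lr && !pHead %in% 1:2)
    stop("head region ", pHead, " inconsistent with an up-down body axis",
         call. = FALSE)
  s <- if (lr) {
    if (pHead == 4L) 1 else -1
  } else if (theta_raw >= 45) {
    if (pHead == 1L) 1 else -1
  } else {
    if (pHead == 2L) 1 else -1
  }
  wrap360(if (s > 0) theta_raw else theta_raw + 180)
}

#' Extract the head-right normalized ROI sample
#'
#' Rejects detections whose enclosing-rectangle aspect ratio falls below
#' `Thr_e` (bent or overlapping bodies). Otherwise samples the head-side
#' portion of the rotated body box — a square of side `2 * major *
#' head_fraction` anchored at the head end, bilinearly interpolated so the
#' head points right — and rescales it to `P_r x P_r`. Samples falling
#' outside the frame are filled with the background mean level.
#'
#' @param frame the frame image.
#' @param det a detection from [segment_frame()].
#' @param theta_full full body angle from [full_angle()].
#' @param cfg a [zf_config()].
#' @param fill fill intensity for out-of-frame samples (background mean).
#' @return list of class `zf_roi`: `patch` (`P_r x P_r` matrix or NULL),
#'   `frame_index`, `detection_ref`, `theta_full`, `quality`
#'   (`"accepted"` or `"rejected_aspect"`).
#' @export
extract_roi <- function(frame, det, theta_full, cfg = zf_config(), fill = NULL) {
  out <- list(patch = NULL, frame_index = det$frame_index,
              detection_ref = det$mask_id, theta_full = theta_full,
              quality = "accepted")
  class(out) <- "zf_roi"
  if (det$aspect_ratio < cfg$Thr_e) {
    out$quality <- "rejected_aspect"
    return(out)
  }
  if (is.null(fill)) fill <- mean(frame)
  a <- det$rect$width / 2
  side <- 2 * a * cfg$head_fraction
  u_lo <- a - side
  v_lo <- -side / 2
  h <- theta_full * pi / 180
  scale <- side / cfg$P_r
  cx <- det$centroid[1]; cy <- det$centroid[2]
  # target (x, y) -> body (u, v) -> frame (xs, ys); y axis points down
  aff <- c(scale * cos(h), scale * sin(h),
           cx + cos(h) * (u_lo + 0.5 * scale) + sin(h) * (v_lo + 0.5 * scale),
           -scale * sin(h), scale * cos(h),
           cy - sin(h) * (u_lo + 0.5 * scale) + cos(h) * (v_lo + 0.5 * scale))
  patch <- cpp_affine_sample(frame, cfg$P_r, cfg$P_r, aff, fill)
  # the ROI is magnified several-fold, so bilinear resampling leaves
  # orientation-dependent aliasing; a small fixed smoothing removes it
  if (cfg$roi_smooth_sigma > 0) patch <- gauss_blur(patch, cfg$roi_smooth_sigma)
  out$patch <- patch
  out
}

# Separable Gaussian smoothing with edge replication.
gauss_blur <- function(m, sigma) {
  r <- ceiling(2.5 * sigma)
  k <- stats::dnorm(-r:r, 0, sigma)
  k <- k / sum(k)
  conv_rows <- function(mm) {
    mp <- rbind(matrix(rep(mm[1, ], each = r), r),
                mm,
                matrix(rep(mm[nrow(mm), ], each = r), r))
    out <- matrix(0, nrow(mm), ncol(mm))
    for (i in -r:r) {
      out <- out + k[i + r + 1] * mp[(1 + r + i):(nrow(mm) + r + i), , drop = FALSE]
    }
    out
  }
  t(conv_rows(t(conv_rows(m))))
}
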