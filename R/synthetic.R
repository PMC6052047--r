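#' Describe a synthetic shoal scene
#'
#' Defines the conditions of a synthetic top-view video: `n_fish` elongated
#' textured bodies move smoothly by a heading random walk with roughly
#' constant speed inside a rectangular arena with reflective walls, and
#' occasionally overlap. Each fish carries a fixed, seeded spot texture
#' painted in body coordinates on its anterior half, which rotates rigidly
#' with the heading — an idealization of the individual back-texture pattern
#' that identity classification relies on.
#'
#' The body silhouette is a half-ellipse head joined to a narrower tail
#' (`tail_factor`), so the anterior half holds the majority of the pixels and
#' head-side resolution behaves as it does for real fish. `bend` curves the
#' midline (px of lateral tip deflection) to emulate body deformation, which
#' lowers the fitted aspect ratio.
#'
#' @param n_fish number of fish.
#' @param n_frames number of frames.
#' @param frame_size c(height, width) in px.
#' @param arena_margin wall margin in px.
#' @param fish_axes c(semi-major, semi-minor) of the body in px.
#' @param texture_seed integer seed; the same seed reproduces the video and
#'   ground truth bit for bit.
#' @param speed_mean,speed_sd per-frame speed distribution in px/frame.
#' @param heading_diffusion sd of the per-frame heading increment in radians.
#' @param background_level,fish_level 8-bit background and body intensities.
#' @param crossing_bias 0-1 factor steering fish toward their nearest
#'   neighbour; higher values produce more crossings.
#' @param tail_factor width of the tail half relative to the head half.
#' @param n_spots,spot_sigma,spot_delta texture spots per fish, their
#'   Gaussian radius in px, and their (signed) intensity offset.
#' @param body_floor minimum intensity lift of a body pixel over the
#'   background (default 50, above twice the default grey threshold), so
#'   dark texture spots never punch detection holes through the body.
#' @param bend midline deflection in px at the body ends (0 = rigid).
#' @param noise_sd sd of additive pixel noise (0 = none; frames are then a
#'   deterministic function of the poses alone).
#' @return An object of class `zf_scene`.
#' @export
synth_scene <- function(n_fish = 4, n_frames = 600, frame_size = c(360, 480),
                        arena_margin = 30, fish_axes = c(27, 8.5),
                        texture_seed = 1L, speed_mean = 3, speed_sd = 0.8,
                        heading_diffusion = 0.12, background_level = 60,
                        fish_level = 190, crossing_bias = 0.3,
                        tail_factor = 0.6, n_spots = 10, spot_sigma = 2.5,
                        spot_delta = -70, body_floor = 50, bend = 0, noise_sd = 0) {
  scene <- list(n_fish = as.integer(n_fish), n_frames = as.integer(n_frames),
                frame_size = as.integer(frame_size),
                arena_margin = arena_margin, fish_axes = fish_axes,
                texture_seed = as.integer(texture_seed),
                speed_mean = speed_mean, speed_sd = speed_sd,
                heading_diffusion = heading_diffusion,
                background_level = background_level, fish_level = fish_level,
                crossing_bias = crossing_bias, tail_factor = tail_factor,
                n_spots = as.integer(n_spots), spot_sigma = spot_sigma,
                spot_delta = spot_delta, body_floor = body_floor,
                bend = bend, noise_sd = noise_sd)
  class(scene) <- "zf_scene"
  if (scene$n_fish < 1 || scene$n_frames < 1)
    stop("scene must have at least one fish and one frame", call. = FALSE)
  if (length(scene$frame_size) != 2 || any(scene$frame_size <= 0))
    stop("frame_size must be positive c(height, width)", call. = FALSE)
  need <- 2 * (scene$arena_margin + 2 * scene$fish_axes[1])
  if (any(scene$frame_size < need))
    stop(sprintf(
      "frame_size %dx%d too small: fish of semi-major %g px need at least %g px inside the %g px margins",
      scene$frame_size[1], scene$frame_size[2], scene$fish_axes[1], need,
      scene$arena_margin), call. = FALSE)
  if (scene$fish_axes[1] <= scene$fish_axes[2])
    stop("fish_axes must satisfy semi-major > semi-minor", call. = FALSE)
  scene
}

#' @export
print.zf_scene <- function(x, ...) {
  cat(sprintf("Synthetic scene: %d fish, %d frames, %dx%d px, seed %d\n",
              x$n_fish, x$n_frames, x$frame_size[1], x$frame_size[2],
              x$texture_seed))
  cat(sprintf("  body %gx%g px, contrast %g vs %g, crossing_bias %g\n",
              2 * x$fish_axes[1], 2 * x$fish_axes[2], x$fish_level,
              x$background_level, x$crossing_bias))
  invisible(x)
}

# Per-fish texture spot tables, a deterministic function of the scene seed.
make_textures <- function(scene) {
  a <- scene$fish_axes[1]; b <- scene$fish_axes[2]
  with_seed(scene$texture_seed, {
    lapply(seq_len(scene$n_fish), function(i) {
      data.frame(u = runif(scene$n_spots, 0.12 * a, 0.92 * a),
                 v = runif(scene$n_spots, -0.6 * b, 0.6 * b),
                 sigma = runif(scene$n_spots, 0.8, 1.2) * scene$spot_sigma,
                 delta = scene$spot_delta *
                   runif(scene$n_spots, 0.7, 1.3))
    })
  })
}

# Paint one fish into `frame` (modified in place semantics via return).
# Returns list(frame, pixels) where pixels are the 1-based linear indices of
# body pixels (alpha > 0.5), used for ground-truth centroids and overlap.
paint_fish <- function(frame, scene, tex, x, y, heading_deg) {
  H <- nrow(frame); W <- ncol(frame)
  a <- scene$fish_axes[1]; b <- scene$fish_axes[2]
  h <- heading_deg * pi / 180
  R <- ceiling(a + 3 * scene$spot_sigma)
  x0 <- max(1, floor(x + 1 - R)); x1 <- min(W, ceiling(x + 1 + R))
  y0 <- max(1, floor(y + 1 - R)); y1 <- min(H, ceiling(y + 1 + R))
  if (x0 > x1 || y0 > y1) return(list(frame = frame, pixels = integer()))
  px <- seq(x0, x1) - 1; py <- seq(y0, y1) - 1
  dx <- matrix(px, length(py), length(px), byrow = TRUE) - x
  dy <- matrix(py, length(py), length(px)) - y
  # body frame: u along the heading (head u > 0), v lateral; y axis points
  # down, heading measured counter-clockwise in the (x right, y up) sense
  u <- dx * cos(h) - dy * sin(h)
  v <- dx * sin(h) + dy * cos(h)
  if (scene$bend != 0) v <- v - scene$bend * (u / a)^2
  w <- b * sqrt(pmax(0, 1 - (u / a)^2)) * ifelse(u >= 0, 1, scene$tail_factor)
  # soft 1-px outline for rotation-stable edge gradients
  alpha <- pmin(1, pmax(0, w - abs(v) + 0.5)) *
    pmin(1, pmax(0, a - abs(u) + 0.5))
  alpha[w <= 0] <- 0
  val <- matrix(scene$fish_level, length(py), length(px))
  for (k in seq_len(nrow(tex))) {
    val <- val + tex$delta[k] *
      exp(-((u - tex$u[k])^2 + (v - tex$v[k])^2) / (2 * tex$sigma[k]^2))
  }
  # dark spots never pull a body pixel close to the background level, so
  # texture cannot punch detection holes through the body
  val <- pmax(val, scene$background_level + scene$body_floor)
  sub <- frame[y0:y1, x0:x1]
  frame[y0:y1, x0:x1] <- sub + alpha * (val - sub)
  idx <- which(alpha > 0.5)
  pixels <- (rep(seq(y0, y1), times = length(px))[idx]) +
    (rep(seq(x0, x1), each = length(py))[idx] - 1) * H
  list(frame = frame, pixels = pixels)
}

#' Render one frame of a scene at given poses
#'
#' Low-level renderer used by [generate_video()] and by tests that need a
#' fish at an exact pose. Poses are recycled over fish.
#'
#' @param scene a [synth_scene()] object.
#' @param x,y,heading_deg pose vectors (one entry per fish).
#' @param fish which fish (texture identities) to render; default all.
#' @return list with `frame` (numeric matrix, 0-255 integers), `pixels`
#'   (per-fish body pixel indices) and `centroid` (per-fish true body
#'   centroid, n x 2 matrix of 0-based x, y).
#' @export
render_pose <- function(scene, x, y, heading_deg, fish = seq_len(scene$n_fish)) {
  tex <- make_textures(scene)
  H <- scene$frame_size[1]; W <- scene$frame_size[2]
  frame <- matrix(scene$background_level, H, W)
  pixels <- vector("list", length(fish))
  centroid <- matrix(NA_real_, length(fish), 2)
  for (k in seq_along(fish)) {
    p <- paint_fish(frame, scene, tex[[fish[k]]], x[k], y[k], heading_deg[k])
    frame <- p$frame
    pixels[[k]] <- p$pixels
    if (length(p$pixels)) {
      centroid[k, ] <- c(mean((p$pixels - 1) %/% H), mean((p$pixels - 1) %% H))
    }
  }
  list(frame = round(pmin(pmax(frame, 0), 255)), pixels = pixels,
       centroid = centroid)
}

#' Generate a synthetic video with ground truth
#'
#' Simulates the motion model of the scene and renders every frame. Fish
#' reflect off the arena walls; when two fish overlap, their blobs merge into
#' one connected component, as in real crossings. The ground truth records
#' each fish's true body centroid and heading on every frame, and
#' `visible = FALSE` where its pixels overlap another fish.
#'
#' @param scene a [synth_scene()] object.
#' @return list of class `zf_video`: `frames` (list of 0-255 integer
#'   matrices), `truth` (data.frame frame, fish, x, y, heading_deg, visible),
#'   `n_components` (per-frame count of connected body components; below
#'   `n_fish` exactly on the frames where blobs merged) and `scene`.
#' @export
generate_video <- function(scene) {
  stopifnot(inherits(scene, "zf_scene"))
  n <- scene$n_fish
  H <- scene$frame_size[1]; W <- scene$frame_size[2]
  a <- scene$fish_axes[1]
  lo_x <- scene$arena_margin + a; hi_x <- W - 1 - scene$arena_margin - a
  lo_y <- scene$arena_margin + a; hi_y <- H - 1 - scene$arena_margin - a
  tex <- make_textures(scene)
  frames <- vector("list", scene$n_frames)
  truth <- vector("list", scene$n_frames)
  n_components <- integer(scene$n_frames)
  with_seed(scene$texture_seed + 1L, {
    # initial poses: rejection-sample centres at least 3 semi-major apart
    x <- numeric(n); y <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        xi <- runif(1, lo_x, hi_x); yi <- runif(1, lo_y, hi_y)
        if (i == 1 || all(sqrt((x[seq_len(i - 1)] - xi)^2 +
                               (y[seq_len(i - 1)] - yi)^2) > 3 * a)) break
      }
      x[i] <- xi; y[i] <- yi
    }
    h <- runif(n, 0, 2 * pi)
    for (t in seq_len(scene$n_frames)) {
      frame <- matrix(scene$background_level, H, W)
      pix <- vector("list", n)
      cen <- matrix(NA_real_, n, 2)
      for (i in seq_len(n)) {
        p <- paint_fish(frame, scene, tex[[i]], x[i], y[i], h[i] * 180 / pi)
        frame <- p$frame
        pix[[i]] <- p$pixels
        if (length(p$pixels))
          cen[i, ] <- c(mean((p$pixels - 1) %/% H), mean((p$pixels - 1) %% H))
      }
      if (scene$noise_sd > 0)
        frame <- frame + matrix(stats::rnorm(H * W, 0, scene$noise_sd), H, W)
      frames[[t]] <- round(pmin(pmax(frame, 0), 255))
      all_pix <- unlist(pix)
      shared <- unique(all_pix[duplicated(all_pix)])
      visible <- vapply(pix, function(p) !any(p %in% shared), TRUE)
      # merged-component truth: connected components of the visible
      # footprint (pixels raised above background by more than the default
      # grey threshold), the same sets background subtraction segments when
      # the background model is exact
      n_components[t] <-
        max(cpp_label8(abs(frames[[t]] - scene$background_level) > 20))
      truth[[t]] <- data.frame(frame = t, fish = seq_len(n),
                               x = cen[, 1], y = cen[, 2],
                               heading_deg = wrap360(h * 180 / pi),
                               visible = visible)
      # motion update
      spd <- pmax(0, stats::rnorm(n, scene$speed_mean, scene$speed_sd))
      dh <- stats::rnorm(n, 0, scene$heading_diffusion)
      if (n > 1 && scene$crossing_bias > 0) {
        # steer toward the nearest neighbour only while beyond a standoff
        # distance, so overlaps are transient crossings rather than contact
        standoff <- 3 * scene$fish_axes[1]
        for (i in seq_len(n)) {
          d2 <- (x - x[i])^2 + (y - y[i])^2
          d2[i] <- Inf
          j <- which.min(d2)
          if (d2[j] > standoff^2) {
            bearing <- atan2(-(y[j] - y[i]), x[j] - x[i])
            dh[i] <- dh[i] + scene$crossing_bias * 0.2 * sin(bearing - h[i])
          }
        }
      }
      h <- h + dh
      x <- x + spd * cos(h)
      y <- y - spd * sin(h)
      for (i in seq_len(n)) {
        if (x[i] < lo_x) { x[i] <- 2 * lo_x - x[i]; h[i] <- pi - h[i] }
        if (x[i] > hi_x) { x[i] <- 2 * hi_x - x[i]; h[i] <- pi - h[i] }
        if (y[i] < lo_y) { y[i] <- 2 * lo_y - y[i]; h[i] <- -h[i] }
        if (y[i] > hi_y) { y[i] <- 2 * hi_y - y[i]; h[i] <- -h[i] }
      }
    }
  })
  out <- list(frames = frames, truth = do.call(rbind, truth), scene = scene,
              n_components = n_components)
  class(out) <- "zf_video"
  out
}

#' @export
print.zf_video <- function(x, ...) {
  merged <- sum(!tapply(x$truth$visible, x$truth$frame, all))
  cat(sprintf("Synthetic video: %d fish, %d frames (%d with overlap)\n",
              x$scene$n_fish, x$scene$n_frames, merged))
  invisible(x)
}

#' Write a synthetic video to disk
#'
#' Writes numbered 8-bit grayscale PNG frames (`frame_000001.png`, ...) and a
#' `truth.csv` ground-truth table into `dir`.
#'
#' @param video a `zf_video` from [generate_video()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_video <- function(video, dir) {
  stopifnot(inherits(video, "zf_video"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (t in seq_along(video$frames)) {
    png::writePNG(video$frames[[t]] / 255,
                  file.path(dir, sprintf("frame_%06d.png", t)))
  }
  write.csv(video$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
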