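# Shared fixtures, generated in code and cached across test files.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache))
    assign(key, force(expr), envir = fixture_cache)
  get(key, envir = fixture_cache)
}

# A flat background model matching a scene's arena.
flat_background <- function(scene) {
  build_background(list(matrix(scene$background_level,
                               scene$frame_size[1], scene$frame_size[2])), 1)
}

# Reference scene for single-fish pose renders (feature tests).
pose_scene <- function() {
  cached("pose_scene", synth_scene(n_fish = 5, n_frames = 1, texture_seed = 7))
}

# Render one fish at an exact pose and run detection on the frame.
pose_detection <- function(fish, heading, scene = pose_scene(),
                           cfg = zf_config(), x = 240, y = 180) {
  rp <- render_pose(scene, x = x, y = y, heading_deg = heading, fish = fish)
  bg <- flat_background(scene)
  dets <- segment_frame(rp$frame, bg, cfg, 1L)
  stopifnot(length(dets) == 1)
  list(frame = rp$frame, det = dets[[1]], bg = bg, truth_centroid = rp$centroid[1, ])
}

# Head-normalized ROI and improved-HOG feature of one posed fish.
feature_at <- function(fish, heading, scene = pose_scene(), cfg = zf_config()) {
  pd <- pose_detection(fish, heading, scene, cfg)
  ph <- resolve_head(pd$frame, pd$det)
  tf <- full_angle(pd$det$theta_raw, ph$region)
  roi <- extract_roi(pd$frame, pd$det, tf, cfg, fill = pd$bg$mean_level)
  stopifnot(roi$quality == "accepted")
  list(feature = extract_feature(roi, pd$bg, cfg), roi = roi,
       theta_full = tf, det = pd$det, frame = pd$frame, bg = pd$bg)
}

# Plain (orientation-naive, unmasked) HOG of the same posed fish: an
# axis-aligned square crop about the centroid, rescaled to P_r.
plain_feature_at <- function(fish, heading, scene = pose_scene(),
                             cfg = zf_config()) {
  pd <- pose_detection(fish, heading, scene, cfg)
  side <- 2 * scene$fish_axes[1]
  sc <- side / cfg$P_r
  aff <- c(sc, 0, pd$det$centroid[1] - side / 2 + 0.5 * sc,
           0, sc, pd$det$centroid[2] - side / 2 + 0.5 * sc)
  patch <- zebratrack:::cpp_affine_sample(pd$frame, cfg$P_r, cfg$P_r, aff,
                                          pd$bg$mean_level)
  plain_hog_feature(patch, cfg)
}

# Small two-fish video with staged crossings, reused by several files
# (generation is the expensive step). The roomier arena keeps the mean
# background model clean over this short clip.
two_fish_video <- function() {
  cached("two_fish_video", {
    generate_video(synth_scene(n_fish = 2, n_frames = 260,
                               frame_size = c(420, 560), texture_seed = 5,
                               crossing_bias = 0.8))
  })
}

# Hand-built toy for the evaluation formulas: 2 fish x 10 frames. Truth
# keeps the fish 200 px apart; trajectory 2 sits at fish 1's position
# ("mislabelled") on frames 8-10, and the detector saw one blob on frame 5.
toy_truth <- function() {
  rbind(data.frame(frame = 1:10, fish = 1, x = 10 * (1:10), y = 0,
                   heading_deg = 0, visible = TRUE),
        data.frame(frame = 1:10, fish = 2, x = 10 * (1:10), y = 200,
                   heading_deg = 0, visible = TRUE))
}

toy_traj <- function() {
  tr <- rbind(data.frame(frame = 1:10, fish_id = 1, x = 10 * (1:10), y = 0),
              data.frame(frame = 1:10, fish_id = 2, x = 10 * (1:10), y = 200))
  tr$y[tr$fish_id == 2 & tr$frame >= 8] <- 0   # wrong fish on 3 frames
  tr
}

# A detection stub for constructed tracklet scenarios.
stub_det <- function(x, y, area = 600) {
  list(centroid = c(x, y), area = area)
}

# Literal brute-force frame matcher: nearest-neighbour claims, conflict
# cancellation, distance-gap rescue — written independently of match_frame.
oracle_match <- function(prev, curr, thr_d) {
  np <- nrow(prev); nc <- nrow(curr)
  m <- matrix(0L, np, nc)
  if (np == 0 || nc == 0) return(m)
  for (i in seq_len(np)) {
    d <- sqrt((curr[, 1] - prev[i, 1])^2 + (curr[, 2] - prev[i, 2])^2)
    m[i, which.min(d)] <- 1L
  }
  for (j in seq_len(nc)) {
    cl <- which(m[, j] == 1L)
    if (length(cl) < 2) next
    d <- sqrt((curr[j, 1] - prev[cl, 1])^2 + (curr[j, 2] - prev[cl, 2])^2)
    m[cl, j] <- 0L
    ord <- order(d, cl)
    if (d[ord[2]] - d[ord[1]] > thr_d) m[cl[ord[1]], j] <- 1L
  }
  m
}

# Spiral enumeration oracle using complex arithmetic (turn = multiply by i,
# i.e. clockwise on a y-down grid), independent of spiral_order().
oracle_spiral <- function(nr, nc) {
  start <- complex(real = ceiling(nc / 2), imaginary = ceiling(nr / 2))
  pos <- start
  dir <- 1 + 0i
  out <- matrix(NA_integer_, 0, 2)
  add <- function(p) {
    r <- Im(p); c <- Re(p)
    if (r >= 1 && r <= nr && c >= 1 && c <= nc)
      out <<- rbind(out, c(r, c))
  }
  add(pos)
  run <- 1
  while (nrow(out) < nr * nc) {
    for (leg in 1:2) {
      for (s in seq_len(run)) {
        pos <- pos + dir
        add(pos)
        if (nrow(out) == nr * nc) break
      }
      dir <- dir * 1i
      if (nrow(out) == nr * nc) break
    }
    run <- run + 1
  }
  storage.mode(out) <- "integer"
  colnames(out) <- c("row", "col")
  out
}

# Brute-force maximum assignment by permutation enumeration (rows <= cols).
oracle_assign <- function(p) {
  r <- nrow(p); c <- ncol(p)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- -Inf; best_sel <- NULL
  for (pm in perms(seq_len(c))) {
    sel <- pm[seq_len(r)]
    val <- sum(p[cbind(seq_len(r), sel)])
    if (val > best + 1e-12) { best <- val; best_sel <- sel }
  }
  list(labels = best_sel, objective = best)
}
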