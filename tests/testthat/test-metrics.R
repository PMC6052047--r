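test_that("the six evaluation formulas reproduce hand-computed values", {
  rep <- evaluate_tracking(toy_traj(), toy_truth(), total_fish = 2,
                           detected_counts = c(2, 2, 2, 2, 1, 2, 2, 2, 2, 2))
  expect_equal(rep$ErrorRate, 3 / 20)
  expect_equal(rep$CrossFrequency, 1 / 10)
  expect_equal(rep$AccuracyRate, 1 - 3 / 10)
  expect_equal(rep$CA, 17 / 20)
  expect_equal(rep$MissRate, 0)
  expect_equal(rep$IA, 1)        # majority overlap still identifies both
})

test_that("perfect tracking scores perfectly and gaps count as misses", {
  truth <- toy_truth()
  traj <- data.frame(frame = rep(1:10, 2), fish_id = rep(1:2, each = 10),
                     x = rep(10 * (1:10), 2), y = rep(c(0, 200), each = 10))
  rep <- evaluate_tracking(traj, truth, total_fish = 2)
  expect_equal(rep$IA, 1)
  expect_equal(rep$AccuracyRate, 1)
  expect_equal(rep$MissRate, 0)
  expect_equal(rep$ErrorRate, 0)
  expect_equal(rep$CrossFrequency, 0)   # all fish present on all frames

  traj2 <- traj
  traj2$x[traj2$fish_id == 2 & traj2$frame > 6] <- NA
  traj2$y[traj2$fish_id == 2 & traj2$frame > 6] <- NA
  rep2 <- evaluate_tracking(traj2, truth, total_fish = 2)
  expect_equal(rep2$MissRate, 4 / 20)
  expect_equal(rep2$AccuracyRate, 1)

  expect_warning(rep0 <- evaluate_tracking(traj[0, ], truth, total_fish = 2),
                 "no tracked")
  expect_equal(rep0$AccuracyRate, 0)
})

test_that("crossing frequency equals the generator's merged-frame fraction", {
  v <- two_fish_video()
  cfg <- zf_config()
  bg <- flat_background(v$scene)   # exact background isolates the property
  counts <- vapply(seq_along(v$frames), function(t)
    length(segment_frame(v$frames[[t]], bg, cfg, t)), 0L)
  truth_frac <- mean(v$n_components < v$scene$n_fish)
  expect_gt(truth_frac, 0)
  rep <- evaluate_tracking(
    data.frame(frame = v$truth$frame, fish_id = v$truth$fish,
               x = v$truth$x, y = v$truth$y),
    v$truth, total_fish = 2, detected_counts = counts)
  expect_equal(rep$CrossFrequency, truth_frac)
})

test_that("shoaling distances match hand geometry", {
  # 2 fish at fixed distance d: both statistics equal d at every sample
  traj <- data.frame(frame = rep(1:40, 2), fish_id = rep(1:2, each = 40),
                     x = c(rep(0, 40), rep(24, 40)),
                     y = c(rep(0, 40), rep(7, 40)))
  st <- shoal_stats(traj, sampling_interval = 1, frame_rate = 10)
  expect_true(all(st$per_fish$nnd == 25))
  expect_true(all(st$per_frame$avg_iid == 25))
  expect_equal(unname(st$summary), c(25, 25))

  # 3-4-5 triangle: average inter-individual distance 4, NND (3, 3, 4)
  tri <- data.frame(frame = 1, fish_id = 1:3,
                    x = c(0, 0, 4), y = c(0, 3, 0))
  st3 <- shoal_stats(tri, sampling_interval = 1, frame_rate = 1)
  expect_equal(st3$per_frame$avg_iid, 4)
  expect_equal(sort(st3$per_fish$nnd), c(3, 3, 4))

  # fixture trajectories equal a direct pairwise-distance loop
  v <- two_fish_video()
  tt <- data.frame(frame = v$truth$frame, fish_id = v$truth$fish,
                   x = v$truth$x, y = v$truth$y)
  stf <- shoal_stats(tt, sampling_interval = 2, frame_rate = 10)
  for (i in seq_len(nrow(stf$per_frame))) {
    t <- stf$per_frame$frame[i]
    d <- tt[tt$frame == t, ]
    expect_equal(stf$per_frame$avg_iid[i],
                 sqrt(diff(d$x)^2 + diff(d$y)^2), tolerance = 1e-12)
  }
})

test_that("locomotion statistics handle paths, wraps and gaps", {
  # stationary fish
  still <- data.frame(frame = 1:20, x = 5, y = 5, heading_deg = 90)
  ls <- locomotion_stats(still, frame_rate = 1)
  expect_equal(ls$total_distance, 0)
  expect_equal(ls$average_velocity, 0)
  expect_equal(ls$turn_angle, 0)

  # square path of side 10 at 1 px/frame, 1 fps: 40 px and three 90-degree turns
  xs <- c(0:10, rep(10, 10), 9:0, rep(0, 10))
  ys <- c(rep(0, 11), 1:10, rep(10, 10), 9:0)
  hd <- c(rep(0, 11), rep(270, 10), rep(180, 10), rep(90, 10))
  sq <- data.frame(frame = seq_along(xs), x = xs, y = ys, heading_deg = hd)
  lsq <- locomotion_stats(sq, frame_rate = 1)
  expect_equal(lsq$total_distance, 40)
  expect_equal(lsq$turn_angle, 270)
  expect_equal(lsq$average_velocity, 40 / 40)

  # heading wrap: 350 -> 10 is a 20-degree turn, not 340
  wrap <- data.frame(frame = 1:2, x = c(0, 1), y = 0,
                     heading_deg = c(350, 10))
  expect_equal(locomotion_stats(wrap, frame_rate = 1)$turn_angle, 20)

  # a gap splits segments; the gap span adds no distance and no duration
  gap <- data.frame(frame = c(1:5, 50:54), x = c(1:5, 105:109), y = 0,
                    heading_deg = 0)
  lg <- locomotion_stats(gap, frame_rate = 1)
  expect_equal(lg$total_distance, 8)
  expect_equal(lg$duration, 8)
})
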