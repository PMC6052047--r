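# Gaussian feature clouds: separable multi-class data for classifier tests
# without the cost of rendering.
gauss_features <- function(n, centre, sd = 0.05, dim = 40) {
  matrix(rep(centre, each = n) + rnorm(n * dim, 0, sd), n, dim)
}

test_that("the group with the longer shortest tracklet trains", {
  expect_equal(select_training_group(c(120, 200), c(40, 300)), "A")
  expect_equal(select_training_group(c(50, 60), c(50, 90)), "A")   # tie
  expect_equal(select_training_group(c(20, 60), c(30, 90)), "B")
  set.seed(2)
  for (i in 1:25) {
    a <- sample(10:300, sample(2:5, 1))
    b <- sample(10:300, sample(2:5, 1))
    expect_equal(select_training_group(a, b),
                 if (min(a) >= min(b)) "A" else "B")
  }
})

test_that("the SVM separates distinct feature pools and is deterministic", {
  cfg <- zf_config()
  set.seed(31)
  dim <- 40
  c1 <- runif(dim); c2 <- runif(dim)
  pools <- list(a = gauss_features(100, c1, dim = dim),
                b = gauss_features(100, c2, dim = dim))
  clf <- train_group_classifier(pools, cfg)
  P <- classify_features(clf, rbind(pools$a, pools$b))
  pred <- clf$classes[max.col(P)]
  truth <- rep(c("a", "b"), each = 100)
  expect_gte(mean(pred == truth), 0.95)
  expect_true(all(abs(rowSums(P) - 1) < 1e-9))
  # deterministic retrain + reclassify
  clf2 <- train_group_classifier(pools, cfg)
  expect_identical(P, classify_features(clf2, rbind(pools$a, pools$b)))
})

test_that("degenerate and invalid training inputs are handled", {
  cfg <- zf_config()
  set.seed(7)
  x <- gauss_features(30, runif(10), dim = 10)
  # identical pools for both classes: probabilities stay near chance and the
  # 1/N rule then rejects the assignment
  clf <- train_group_classifier(list(a = x, b = x), cfg)
  P <- classify_features(clf, x[1:5, ])
  expect_true(all(abs(P - 0.5) < 0.01))   # chance-level probabilities
  # a chance-level row sits at the 1/N boundary, which rejects (strict >)
  asg <- match_groups(rbind(c(0.5, 0.5)), N = 2)
  expect_false(asg$accepted)

  expect_error(train_group_classifier(list(a = x), cfg), "two classes")
  expect_error(train_group_classifier(
    list(a = x, b = x[0, , drop = FALSE]), cfg), "zero accepted")
})

test_that("tracklet probabilities aggregate per-frame rows as stated", {
  P <- rbind(c(0.7, 0.2, 0.1), c(0.5, 0.3, 0.2), c(0.9, 0.05, 0.05))
  expect_equal(aggregate_probs(P, "mean"), colMeans(P))
  expect_equal(aggregate_probs(P, "vote"), c(1, 0, 0))
  u <- matrix(1 / 3, 4, 3)
  expect_equal(aggregate_probs(u, "mean"), rep(1 / 3, 3))
  # resubstitution: the training fish is its own argmax
  cfg <- zf_config()
  set.seed(9)
  pools <- list(a = gauss_features(50, runif(20), dim = 20),
                b = gauss_features(50, runif(20), dim = 20))
  clf <- train_group_classifier(pools, cfg)
  row <- classify_tracklet(clf, pools$a[1:20, ], "mean")
  expect_equal(unname(which.max(row$prob)), 1)
  # zero features give a flagged uniform row
  empty <- classify_tracklet(clf, matrix(numeric(), 0, 20))
  expect_true(empty$uniform)
  expect_equal(unname(empty$prob), c(0.5, 0.5))
})

test_that("group matching maximizes total probability under the 1/N rule", {
  asg <- match_groups(diag(3))
  expect_equal(asg$labels, 1:3)
  expect_true(asg$accepted)
  expect_equal(asg$unmatched_classes, integer())

  # a selected probability exactly at 1/N flips acceptance off (strict >)
  P <- rbind(c(0.5, 0.5), c(0.4, 0.6))
  asg2 <- match_groups(P, N = 2)
  expect_equal(asg2$prob[1], 0.5)
  expect_false(asg2$accepted)

  # low-confidence selections are flagged against Thr_p
  P3 <- rbind(c(0.55, 0.45), c(0.1, 0.9))
  asg3 <- match_groups(P3, N = 2, Thr_p = 0.6)
  expect_true(asg3$accepted)
  expect_equal(asg3$flagged_low_confidence, 1L)

  expect_error(match_groups(matrix(numeric(), 0, 0)), "empty")
  expect_error(match_groups(matrix(0.5, 3, 2)), "rows")
})

test_that("assignments equal brute-force permutation search up to 6x6", {
  for (s in 1:100) {
    set.seed(s)
    r <- sample(2:6, 1)
    cpad <- sample(0:1, 1)
    p <- matrix(runif(r * (r + cpad)), r, r + cpad)
    p <- p / rowSums(p)
    asg <- match_groups(p, N = ncol(p))
    o <- oracle_assign(p)
    expect_equal(sum(p[cbind(seq_len(r), asg$labels)]), o$objective,
                 tolerance = 1e-12)
  }
})

test_that("stitching is a no-op when every assignment is rejected", {
  cfg <- zf_config()
  set.seed(4)
  x <- gauss_features(30, runif(15), dim = 15)
  mk <- function(id, frames, feats) {
    list(id = id, frames = frames, det_idx = seq_along(frames),
         merged = FALSE, parents = integer(),
         entries = data.frame(frame = frames, x = 0, y = 0, heading_deg = 0),
         features = feats)
  }
  # identical pools on every tracklet: 2-class probabilities ~0.5 fail 1/N
  tl <- structure(list(
    tracklets = list(mk(1L, 1:40, x), mk(2L, 1:40, x),
                     mk(3L, 45:80, x), mk(4L, 45:80, x)),
    events = list(list(frame_index = 45L, frame_before = 40L,
                       frame_after = 45L, groups_before = c(1L, 2L),
                       groups_after = c(3L, 4L))),
    counts = rep(2L, 80)), class = "zf_tracklets")
  st <- stitch_and_accumulate(tl, cfg, n_fish = 2)
  expect_length(st$tracklets, 4)
  expect_false(any(vapply(st$stitch_log, function(l) l$accepted, TRUE)))
})

test_that("stitching joins same-identity tracklets across a crossing", {
  cfg <- zf_config()
  set.seed(14)
  dim <- 30
  cA <- runif(dim); cB <- runif(dim)
  mk <- function(id, frames, centre) {
    list(id = id, frames = frames, det_idx = seq_along(frames),
         merged = FALSE, parents = integer(),
         entries = data.frame(frame = frames, x = id, y = 0, heading_deg = 0),
         features = gauss_features(length(frames), centre, dim = dim))
  }
  tl <- structure(list(
    tracklets = list(mk(1L, 1:50, cA), mk(2L, 1:50, cB),
                     mk(3L, 61:100, cB), mk(4L, 61:100, cA)),
    events = list(list(frame_index = 61L, frame_before = 50L,
                       frame_after = 61L, groups_before = c(1L, 2L),
                       groups_after = c(3L, 4L))),
    counts = rep(2L, 100)), class = "zf_tracklets")
  st <- stitch_and_accumulate(tl, cfg, n_fish = 2)
  expect_length(st$tracklets, 2)
  spans <- lapply(st$tracklets, function(tr) range(tr$frames))
  expect_true(all(vapply(spans, function(s) s[1] == 1 && s[2] == 100, TRUE)))
  # pools accumulated: each stitched tracklet holds both parts' samples
  expect_true(all(vapply(st$tracklets, function(tr) nrow(tr$features), 0L) == 90))
})

test_that("the final reference group maximizes the shortest member length", {
  cfg <- zf_config()
  set.seed(21)
  dim <- 25
  cents <- replicate(2, runif(dim), simplify = FALSE)
  mk <- function(id, frames, centre) {
    list(id = id, frames = frames, det_idx = seq_along(frames),
         merged = FALSE, parents = integer(),
         entries = data.frame(frame = frames, x = id, y = 0, heading_deg = 0),
         features = gauss_features(length(frames), centre, dim = dim))
  }
  # two candidate frames with full groups: around frame 30 (min len 60) and
  # frame 90 (min len 20); max(min(NF)) picks the earlier group
  tl <- structure(list(
    tracklets = list(mk(1L, 1:60, cents[[1]]), mk(2L, 1:80, cents[[2]]),
                     mk(3L, 81:100, cents[[1]]), mk(4L, 61:100, cents[[2]])),
    events = list(), counts = rep(2L, 100)), class = "zf_tracklets")
  fin <- final_trajectories(tl, n_fish = 2, cfg, n_frames = 100)
  expect_true(fin$reference_frame <= 60)
  # max-of-min oracle over frames
  lens <- c(60, 80, 20, 40)
  cover <- function(t) which(vapply(tl$tracklets, function(tr) t %in% tr$frames, TRUE))
  mins <- vapply(1:100, function(t) {
    cv <- cover(t)
    if (length(cv) == 2) min(lens[cv]) else -1
  }, 0)
  expect_equal(min(lens[cover(fin$reference_frame)]), max(mins))
})

test_that("a crossing-free video yields trajectories equal to its tracklets", {
  cfg <- zf_config()
  mk <- function(id, frames) {
    list(id = id, frames = frames, det_idx = seq_along(frames),
         merged = FALSE, parents = integer(),
         entries = data.frame(frame = frames, x = id * 10 + frames / 100,
                              y = id, heading_deg = 0),
         features = matrix(numeric(), 0, 0))
  }
  tl <- structure(list(tracklets = list(mk(1L, 1:50), mk(2L, 1:50)),
                       events = list(), counts = rep(2L, 50)),
                  class = "zf_tracklets")
  fin <- final_trajectories(tl, n_fish = 2, cfg, n_frames = 50)
  expect_null(fin$classifier)
  for (i in 1:2) {
    d <- fin$table[fin$table$fish_id == i, ]
    expect_equal(d$x, tl$tracklets[[i]]$entries$x)
    expect_equal(d$y, rep(i, 50))
  }
})
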