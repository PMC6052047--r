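#' Choose the training group flanking a crossing
#'
#' Of the two tracklet groups before and after a crossing, the one whose
#' shortest member is longer carries more reliable samples and is used to
#' train the crossing classifier; the other group is classified. Ties go to
#' the earlier (before) group.
#'
#' @param nf_a,nf_b numeric vectors of tracklet lengths (frames) in the
#'   before and after groups.
#' @return `"A"` if the before group trains, else `"B"`.
#' @export
select_training_group <- function(nf_a, nf_b) {
  stopifnot(length(nf_a) > 0, length(nf_b) > 0)
  if (min(nf_a) >= min(nf_b)) "A" else "B"
}

# Deterministic per-class subsample: evenly spaced row indices.
cap_rows <- function(n, cap) {
  if (n <= cap) seq_len(n) else unique(round(seq(1, n, length.out = cap)))
}

#' Train a multi-class SVM on tracklet feature pools
#'
#' One class per tracklet identity; samples are the improved-HOG features of
#' the tracklet's accepted ROIs. RBF kernel; probabilities are produced
#' deterministically from the one-vs-one decision values via a fixed-slope
#' sigmoid and pairwise coupling (see [classify_features()]), so repeated
#' training on the same pools gives identical results.
#'
#' @param features_by_class named list of feature matrices (rows = samples);
#'   at least two classes, each with at least one row.
#' @param cfg a [zf_config()]; supplies `svm_cost`, `svm_gamma` and the
#'   per-class sample cap.
#' @return list of class `zf_classifier`: `model`, `classes`, `dim`.
#' @export
train_group_classifier <- function(features_by_class, cfg = zf_config()) {
  k <- length(features_by_class)
  if (k < 2) stop("need at least two classes to train", call. = FALSE)
  nr <- vapply(features_by_class, nrow, 0L)
  if (any(nr == 0))
    stop("class with zero accepted-ROI samples: ",
         paste(names(features_by_class)[nr == 0], collapse = ", "),
         call. = FALSE)
  if (is.null(names(features_by_class)))
    names(features_by_class) <- as.character(seq_len(k))
  xs <- lapply(features_by_class, function(m) m[cap_rows(nrow(m), cfg$max_train_samples), , drop = FALSE])
  x <- do.call(rbind, xs)
  y <- factor(rep(names(xs), vapply(xs, nrow, 0L)), levels = names(xs))
  gamma <- if (is.na(cfg$svm_gamma)) 1 / ncol(x) else cfg$svm_gamma
  model <- e1071::svm(x, y, kernel = "radial", cost = cfg$svm_cost,
                      gamma = gamma, scale = FALSE)
  out <- list(model = model, classes = levels(y), dim = ncol(x))
  class(out) <- "zf_classifier"
  out
}

# Pairwise coupling of one-vs-one probabilities into class probabilities
# (least-squares coupling, solved by the usual fixed-point iteration).
couple_probs <- function(q) {
  k <- nrow(q)
  if (k == 2) {
    p <- c(q[1, 2], q[2, 1])
    return(p / sum(p))
  }
  Q <- matrix(0, k, k)
  for (i in seq_len(k)) {
    Q[i, i] <- sum(q[-i, i]^2)
    for (j in seq_len(k)) if (j != i) Q[i, j] <- -q[j, i] * q[i, j]
  }
  p <- rep(1 / k, k)
  for (it in 1:100) {
    pQp <- as.numeric(t(p) %*% Q %*% p)
    p_new <- p
    for (i in seq_len(k)) {
      p_new[i] <- (-sum(Q[i, -i] * p_new[-i]) + pQp) / Q[i, i]
      p_new <- pmax(p_new, 0)
      p_new <- p_new / sum(p_new)
      pQp <- as.numeric(t(p_new) %*% Q %*% p_new)
    }
    if (max(abs(p_new - p)) < 1e-10) { p <- p_new; break }
    p <- p_new
  }
  p
}

#' Per-sample class probabilities from a trained classifier
#'
#' Maps each one-vs-one SVM decision value through a fixed-slope sigmoid
#' (slope 2) and couples the pairwise probabilities into a class probability
#' vector per sample. Deterministic, unlike cross-validated probability
#' calibration.
#'
#' @param clf a `zf_classifier`.
#' @param X feature matrix (rows = samples).
#' @return matrix of probabilities, rows = samples, columns = `clf$classes`;
#'   rows sum to 1.
#' @export
classify_features <- function(clf, X) {
  stopifnot(inherits(clf, "zf_classifier"))
  X <- as.matrix(X)
  if (ncol(X) != clf$dim) stop("feature dimension mismatch", call. = FALSE)
  pred <- predict(clf$model, X, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  classes <- clf$classes
  k <- length(classes)
  pairs <- strsplit(colnames(dv), "/", fixed = TRUE)
  P <- matrix(0, nrow(X), k, dimnames = list(NULL, classes))
  for (s in seq_len(nrow(X))) {
    q <- matrix(0.5, k, k)
    for (pi in seq_along(pairs)) {
      i <- match(pairs[[pi]][1], classes)
      j <- match(pairs[[pi]][2], classes)
      sig <- 1 / (1 + exp(-2 * dv[s, pi]))   # dv > 0 favors class i
      q[i, j] <- sig
      q[j, i] <- 1 - sig
    }
    P[s, ] <- couple_probs(q)
  }
  P
}

#' Aggregate per-frame probabilities over a tracklet
#'
#' Pools the per-frame class probability rows of one tracklet into a single
#' probability row, either as the arithmetic mean (default) or as the
#' majority-vote proportions of per-frame argmax labels. A tracklet with
#' zero feature rows yields a uniform row, flagged.
#'
#' @param clf a `zf_classifier`.
#' @param features feature matrix of the tracklet's accepted ROIs (may have
#'   zero rows).
#' @param aggregation `"mean"` or `"vote"`.
#' @return list: `prob` (named probability row), `n_frames` used, `uniform`
#'   (TRUE when there were no features).
#' @export
classify_tracklet <- function(clf, features, aggregation = "mean") {
  k <- length(clf$classes)
  if (is.null(features) || nrow(features) == 0) {
    return(list(prob = stats::setNames(rep(1 / k, k), clf$classes),
                n_frames = 0L, uniform = TRUE))
  }
  P <- classify_features(clf, features)
  row <- aggregate_probs(P, aggregation)
  list(prob = stats::setNames(row, clf$classes), n_frames = nrow(P),
       uniform = FALSE)
}

#' Pool per-frame probability rows into one tracklet row
#'
#' @param P matrix of per-frame class probabilities (rows sum to 1).
#' @param aggregation `"mean"` (arithmetic mean of rows) or `"vote"`
#'   (proportions of per-frame argmax labels).
#' @return a probability vector summing to 1.
#' @export
aggregate_probs <- function(P, aggregation = "mean") {
  P <- as.matrix(P)
  row <- if (aggregation == "vote") {
    tab <- tabulate(max.col(P, ties.method = "first"), ncol(P))
    tab / sum(tab)
  } else {
    colMeans(P)
  }
  row / sum(row)
}

#' Stitch initial tracklets across crossings
#'
#' Processes crossing events in chronological order. For each event the
#' groups before and after are compared by their shortest member
#' ([select_training_group()]); the longer group trains a crossing
#' classifier ([train_group_classifier()]), the other group is classified
#' ([classify_tracklet()]) and matched ([match_groups()]). On an accepted
#' assignment, same-label tracklets are merged: frame spans concatenate
#' (with a gap across the crossing) and sample pools accumulate, so later
#' classifiers train on more data. Sweeps repeat until no merge occurs.
#' Events whose groups have fewer than two usable members (a member may have
#' zero accepted ROIs, or have been discarded as too short) are skipped and
#' left to the final classifier.
#'
#' Only events where the training side covers all `n_fish` identities are
#' stitched: with every class present, each test tracklet has its true class
#' among the candidates, which makes the assignment sound. Crossings without
#' a full flanking group are left to the final classifier.
#'
#' @param tl a `zf_tracklets` whose tracklets carry `entries` (data.frame
#'   with columns frame, x, y, heading_deg) and `features` (matrix), as
#'   produced by the pipeline.
#' @param cfg a [zf_config()].
#' @param n_fish number of identities; defaults to the modal per-frame
#'   detection count.
#' @return `tl` with merged tracklets replacing their parts; each stitched
#'   tracklet keeps `member_ids` of the initial tracklets it unites. A log of
#'   event outcomes is attached as `stitch_log`.
#' @export
stitch_and_accumulate <- function(tl, cfg = zf_config(), n_fish = NULL) {
  if (is.null(n_fish)) {
    tab <- table(tl$counts[tl$counts > 0])
    n_fish <- as.integer(names(tab)[which.max(tab)])
  }
  tracklets <- tl$tracklets
  log <- list()
  repeat {
    merged_any <- FALSE
    for (ev in tl$events) {
      # groups = usable tracklets covering the flanking reference frames
      covering <- function(f) {
        if (is.null(f) || f < 1) return(integer())
        which(vapply(tracklets, function(tr) {
          !tr$merged && !is.null(tr$features) && nrow(tr$features) > 0 &&
            f %in% tr$frames
        }, TRUE))
      }
      before <- covering(ev$frame_before)
      after <- covering(ev$frame_after)
      if (identical(before, after)) next   # crossing already resolved
      if (length(before) < 2 || length(after) < 2) next
      # the training side must hold all identities, else a test tracklet's
      # true class could be absent and the assignment unsound
      full_a <- length(before) == n_fish
      full_b <- length(after) == n_fish
      if (!full_a && !full_b) next
      nf_a <- vapply(before, function(ix) length(tracklets[[ix]]$frames), 0L)
      nf_b <- vapply(after, function(ix) length(tracklets[[ix]]$frames), 0L)
      side <- if (full_a && full_b) select_training_group(nf_a, nf_b)
              else if (full_a) "A" else "B"
      train_ix <- if (side == "A") before else after
      test_ix <- if (side == "A") after else before
      pools <- lapply(train_ix, function(ix) tracklets[[ix]]$features)
      names(pools) <- as.character(train_ix)
      clf <- train_group_classifier(pools, cfg)
      P <- do.call(rbind, lapply(test_ix, function(ix) {
        classify_tracklet(clf, tracklets[[ix]]$features,
                          cfg$prob_aggregation)$prob
      }))
      if (nrow(P) > ncol(P)) next
      asg <- match_groups(P, N = ncol(P), Thr_p = cfg$Thr_p)
      log[[length(log) + 1L]] <- list(
        frame = ev$frame_index, accepted = asg$accepted, prob = asg$prob,
        train_ids = vapply(train_ix, function(ix) tracklets[[ix]]$id, 0L),
        test_ids = vapply(test_ix, function(ix) tracklets[[ix]]$id, 0L),
        labels = asg$labels)
      if (!asg$accepted) next
      # merge each test tracklet into its matched training tracklet
      did_merge <- FALSE
      for (r in seq_len(nrow(P))) {
        a <- tracklets[[test_ix[r]]]
        b <- tracklets[[train_ix[asg$labels[r]]]]
        if (length(intersect(a$frames, b$frames)) > 0) next
        merged_any <- TRUE
        did_merge <- TRUE
        b$frames <- sort(c(b$frames, a$frames))
        b$entries <- rbind(b$entries, a$entries)
        b$entries <- b$entries[order(b$entries$frame), , drop = FALSE]
        b$features <- rbind(b$features, a$features)
        b$member_ids <- c(b$member_ids %||% b$id, a$member_ids %||% a$id)
        tracklets[[train_ix[asg$labels[r]]]] <- b
        tracklets[[test_ix[r]]]$dead <- TRUE
      }
      if (!did_merge) next
      tracklets <- Filter(function(tr) is.null(tr$dead), tracklets)
      break   # indices changed; restart the sweep
    }
    if (!merged_any) break
  }
  tl$tracklets <- tracklets
  tl$stitch_log <- log
  tl
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Final per-identity trajectories
#'
#' Selects the reference frame whose tracklet group has the longest shortest
#' member (max over frames t of min tracklet length among the tracklets
#' covering t, requiring all `n_fish` identities present), trains the single
#' final classifier on that group, classifies every remaining tracklet, and
#' assigns labels group-wise with [match_groups()] under the constraint that
#' a label never appears twice on one frame. Tracklets whose assignment is
#' rejected by the 1/N rule, and merged-blob tracklets, contribute gaps.
#'
#' @param tl a stitched `zf_tracklets` (see [stitch_and_accumulate()]).
#' @param n_fish number of identities.
#' @param cfg a [zf_config()].
#' @param n_frames total frames (defaults to `length(tl$counts)`).
#' @return list of class `zf_trajectories`: `table` (data.frame frame,
#'   fish_id, x, y, heading_deg, confidence, flagged; one row per fish and
#'   frame, NA positions at gaps), `labels` (per tracklet), `classifier`.
#' @export
final_trajectories <- function(tl, n_fish, cfg = zf_config(),
                               n_frames = length(tl$counts)) {
  tracklets <- Filter(function(tr) !tr$merged, tl$tracklets)
  if (length(tracklets) < n_fish)
    stop("fewer than n_fish tracklets available", call. = FALSE)
  if (length(tracklets) == n_fish) {
    # one tracklet per identity: nothing to resolve, no classifier needed
    tab <- traj_table(tracklets, seq_len(n_fish), rep(1, n_fish),
                      rep(FALSE, n_fish), n_fish, n_frames)
    out <- list(table = tab, labels = seq_len(n_fish), classifier = NULL,
                reference_frame = NA_integer_)
    class(out) <- "zf_trajectories"
    return(out)
  }
  lens <- vapply(tracklets, function(tr) length(tr$frames), 0L)
  has_feat <- vapply(tracklets, function(tr) !is.null(tr$features) &&
                       nrow(tr$features) > 0, TRUE)
  # reference group: maximize min member length over frames covered by
  # exactly n_fish feature-bearing tracklets
  cover <- matrix(FALSE, length(tracklets), n_frames)
  for (i in seq_along(tracklets)) cover[i, tracklets[[i]]$frames] <- TRUE
  cover[!has_feat, ] <- FALSE
  n_cov <- colSums(cover)
  cand <- which(n_cov == n_fish)
  if (length(cand) == 0) {
    stop(sprintf(
      "no frame is covered by %d concurrent tracklets (largest usable group: %d)",
      n_fish, max(n_cov)), call. = FALSE)
  }
  min_len <- vapply(cand, function(t) min(lens[cover[, t]]), 0)
  t_ref <- cand[which.max(min_len)]
  train_ix <- which(cover[, t_ref])
  pools <- lapply(train_ix, function(ix) tracklets[[ix]]$features)
  names(pools) <- as.character(seq_len(n_fish))
  clf <- train_group_classifier(pools, cfg)
  labels <- rep(NA_integer_, length(tracklets))
  conf <- rep(NA_real_, length(tracklets))
  flagged <- rep(FALSE, length(tracklets))
  labels[train_ix] <- seq_len(n_fish)
  conf[train_ix] <- 1
  rest <- setdiff(which(has_feat), train_ix)
  if (length(rest) > 0) {
    # classify every remaining tracklet, then assign labels in order of
    # decreasing confidence under the constraint that a label never appears
    # twice on one frame; a tracklet is labeled only if its (constrained)
    # best probability clears the 1/N rule, and flagged below Thr_p
    P <- do.call(rbind, lapply(rest, function(ix) {
      classify_tracklet(clf, tracklets[[ix]]$features,
                        cfg$prob_aggregation)$prob
    }))
    for (r in order(apply(P, 1, max), decreasing = TRUE)) {
      ix <- rest[r]
      p <- P[r, ]
      fr <- tracklets[[ix]]$frames
      for (jx in which(!is.na(labels))) {
        if (length(intersect(fr, tracklets[[jx]]$frames)) > 0)
          p[labels[jx]] <- 0
      }
      if (max(p) <= 1 / n_fish) next   # rejected by the 1/N rule: gap
      labels[ix] <- which.max(p)
      conf[ix] <- max(p)
      flagged[ix] <- max(p) < cfg$Thr_p
    }
  }
  tab <- traj_table(tracklets, labels, conf, flagged, n_fish, n_frames)
  out <- list(table = tab, labels = labels, classifier = clf,
              reference_frame = t_ref)
  class(out) <- "zf_trajectories"
  out
}

# Assemble the per-identity trajectory grid from labeled tracklets.
traj_table <- function(tracklets, labels, conf, flagged, n_fish, n_frames) {
  tab <- expand.grid(frame = seq_len(n_frames), fish_id = seq_len(n_fish))
  tab$x <- NA_real_; tab$y <- NA_real_; tab$heading_deg <- NA_real_
  tab$confidence <- NA_real_; tab$flagged <- FALSE
  for (i in seq_along(tracklets)) {
    if (is.na(labels[i])) next
    e <- tracklets[[i]]$entries
    rows <- e$frame + (labels[i] - 1L) * n_frames
    tab$x[rows] <- e$x
    tab$y[rows] <- e$y
    tab$heading_deg[rows] <- e$heading_deg
    tab$confidence[rows] <- conf[i]
    tab$flagged[rows] <- flagged[i]
  }
  tab
}
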