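#' Crossing determination from object counts
#'
#' The detected object count changes when fish blobs merge or split, so a
#' transition is flagged as a crossing (1) whenever the counts on two
#' consecutive frames differ, and 0 otherwise.
#'
#' @param n_prev,n_curr detection counts on frames t-1 and t.
#' @return 0 or 1.
#' @export
crossing_flag <- function(n_prev, n_curr) {
  stopifnot(n_prev >= 0, n_curr >= 0)
  as.integer(n_prev != n_curr)
}

#' Minimum-distance frame-to-frame matching
#'
#' Each object on frame t-1 claims its nearest object on frame t (Euclidean
#' centroid distance). When two or more prior objects claim the same current
#' object, all claims are cancelled — unless the distance gap between the
#' two closest claimants exceeds `Thr_d`, in which case the closer claimant
#' is reinstated (a conflict caused by a stationary fish or a special
#' matching distance rather than a genuine crossing, which is why the
#' crossing indicator of such a conflict counts as 0). Claims farther than
#' `max_dist` are never made. Distance ties break toward the lower current
#' index.
#'
#' @param prev,curr numeric matrices of centroids (rows = objects, cols =
#'   x, y).
#' @param cfg a [zf_config()] supplying `Thr_d`.
#' @param max_dist maximum claim distance in px (`Inf` disables the gate).
#' @return 0/1 match matrix of dimension `nrow(prev)` x `nrow(curr)`; each
#'   row and each column contains at most one 1.
#' @export
match_frame <- function(prev, curr, cfg = zf_config(),
                        max_dist = cfg$max_match_dist) {
  np <- if (is.null(prev)) 0L else nrow(prev)
  nc <- if (is.null(curr)) 0L else nrow(curr)
  m <- matrix(0L, np, nc)
  if (np == 0L || nc == 0L) return(m)
  D <- sqrt(outer(prev[, 1], curr[, 1], "-")^2 +
            outer(prev[, 2], curr[, 2], "-")^2)
  claim <- apply(D, 1, which.min)   # ties -> lowest index
  ok <- D[cbind(seq_len(np), claim)] <= max_dist
  for (i in seq_len(np)) if (ok[i]) m[i, claim[i]] <- 1L
  for (j in seq_len(nc)) {
    claimants <- which(m[, j] == 1L)
    if (length(claimants) < 2L) next
    m[claimants, j] <- 0L
    d <- D[claimants, j]
    o <- order(d, claimants)
    if (d[o[2]] - d[o[1]] > cfg$Thr_d) m[claimants[o[1]], j] <- 1L
  }
  m
}

#' Build initial tracklets from per-frame detections
#'
#' Chains detections into gap-free tracklets with [match_frame()]. Every
#' unmatched transition terminates and/or starts tracklets. A current
#' detection claimed by two or more prior objects without resolution is a
#' merged blob: the tracklet started on it is marked `merged` and remembers
#' its parent tracklets, and when the blob later splits (the detection count
#' rises) the merged tracklet is cut rather than allowed to continue into a
#' single fish, which keeps every ordinary tracklet pure. Crossing events
#' pair the tracklets that ended at a merge with those that started at the
#' corresponding split. Tracklets shorter than `min_tracklet_len` frames are
#' discarded as crossing debris.
#'
#' @param dets list over frames; each element a list of detections from
#'   [segment_frame()].
#' @param cfg a [zf_config()].
#' @return list of class `zf_tracklets`: `tracklets` (each with `id`,
#'   `frames`, `det_idx`, `merged`, `parents`), `events` (each with
#'   `frame_index`, `groups_before`, `groups_after`), `counts` (per-frame
#'   detection counts).
#' @export
build_tracklets <- function(dets, cfg = zf_config()) {
  n_frames <- length(dets)
  counts <- vapply(dets, length, 0L)
  # overlap detections: blobs much larger than the typical single body merge
  # two or more fish, and matches never cross the single/blob boundary
  areas <- unlist(lapply(dets, function(dl) vapply(dl, function(d) d$area, 0)))
  area_cut <- cfg$overlap_area_factor * stats::median(areas)
  big <- lapply(dets, function(dl) vapply(dl, function(d) d$area > area_cut, TRUE))
  tracklets <- list()
  events <- list()
  new_tracklet <- function(t, j, merged = FALSE, parents = integer()) {
    id <- length(tracklets) + 1L
    tracklets[[id]] <<- list(id = id, frames = t, det_idx = j,
                             merged = merged, parents = parents)
    id
  }
  centroids <- function(t, idx) {
    if (length(idx) == 0) return(matrix(numeric(), 0, 2))
    do.call(rbind, lapply(dets[[t]][idx], function(d) d$centroid))
  }
  active <- if (counts[1] > 0) {
    vapply(seq_len(counts[1]), function(j) new_tracklet(1L, j), 0L)
  } else integer()
  active_det <- seq_len(counts[1])
  for (t in seq_len(n_frames)[-1]) {
    np <- length(active); ncur <- counts[t]
    m <- if (np > 0 && ncur > 0) {
      match_frame(centroids(t - 1L, active_det), centroids(t, seq_len(ncur)),
                  cfg)
    } else matrix(0L, np, ncur)
    # detect merged blobs from the raw nearest-neighbour claims
    claim_cnt <- integer(ncur)
    cl <- integer(); okd <- logical()
    if (np > 0 && ncur > 0) {
      prev_xy <- centroids(t - 1L, active_det)
      cur_xy <- centroids(t, seq_len(ncur))
      D <- sqrt(outer(prev_xy[, 1], cur_xy[, 1], "-")^2 +
                outer(prev_xy[, 2], cur_xy[, 2], "-")^2)
      cl <- apply(D, 1, which.min)
      okd <- D[cbind(seq_len(np), cl)] <= cfg$max_match_dist
      claim_cnt <- tabulate(cl[okd], ncur)
    }
    # purity guard: a match may not cross the single/blob boundary, so every
    # tracklet is cut at the moment fish merge into a blob and at the moment
    # the blob splits again
    if (np > 0 && ncur > 0) {
      for (k in seq_len(np)) {
        j <- which(m[k, ] == 1L)
        if (length(j) != 1) next
        cut <- big[[t]][j] != big[[t - 1L]][active_det[k]]
        if (!cut && tracklets[[active[k]]]$merged) {
          # a blob whose area stayed near one body (fish passing on top of
          # each other) is cut at any count increase or sharp area drop
          cut <- ncur > np ||
            dets[[t]][[j]]$area < 0.78 * dets[[t - 1L]][[active_det[k]]]$area
        }
        if (cut) m[k, j] <- 0L
      }
    }
    matched_prev <- if (np > 0) rowSums(m) > 0 else logical()
    matched_curr <- if (ncur > 0) colSums(m) > 0 else logical()
    ended <- active[!matched_prev]
    # extend matched tracklets
    new_active <- integer(); new_active_det <- integer()
    if (np > 0 && ncur > 0) {
      for (k in which(matched_prev)) {
        j <- which(m[k, ] == 1L)
        id <- active[k]
        tracklets[[id]]$frames <- c(tracklets[[id]]$frames, t)
        tracklets[[id]]$det_idx <- c(tracklets[[id]]$det_idx, j)
        new_active <- c(new_active, id)
        new_active_det <- c(new_active_det, j)
      }
    }
    started <- integer()
    for (j in seq_len(ncur)) {
      if (matched_curr[j]) next
      is_merged <- claim_cnt[j] >= 2L || big[[t]][j]
      parents <- integer()
      if (is_merged && np > 0) {
        cls <- which(cl == j & okd)                      # conflicting claimants
        near <- which(!matched_prev &                    # enders near the blob
          sqrt((prev_xy[, 1] - dets[[t]][[j]]$centroid[1])^2 +
               (prev_xy[, 2] - dets[[t]][[j]]$centroid[2])^2) <=
            cfg$max_match_dist)
        parents <- unique(unlist(lapply(active[union(cls, near)], function(id) {
          tr <- tracklets[[id]]
          if (tr$merged) tr$parents else id
        })))
      }
      id <- new_tracklet(t, j, merged = is_merged, parents = parents)
      started <- c(started, id)
      new_active <- c(new_active, id)
      new_active_det <- c(new_active_det, j)
    }
    # crossing events: when a merged blob dies (its fish separated again),
    # bridge the crossing by pairing the last pre-merge frame with the
    # post-split frame; the groups themselves are resolved at stitch time as
    # the tracklets covering those frames
    for (id in ended) {
      tr <- tracklets[[id]]
      if (tr$merged) {
        events[[length(events) + 1L]] <- list(
          frame_index = t, frame_before = tr$frames[1] - 1L,
          frame_after = t, groups_before = tr$parents,
          groups_after = setdiff(started, id))
      }
    }
    # conflict cut without a surviving blob (stationary-fish case): pair the
    # two sides of the cut transition directly
    plain_ended <- ended[!vapply(ended, function(id) tracklets[[id]]$merged, TRUE)]
    merged_started <- started[vapply(started, function(id) tracklets[[id]]$merged, TRUE)]
    if (length(plain_ended) >= 2 && length(merged_started) == 0 &&
        length(started) >= 2) {
      events[[length(events) + 1L]] <- list(
        frame_index = t, frame_before = t - 1L, frame_after = t,
        groups_before = plain_ended, groups_after = started)
    }
    active <- new_active
    active_det <- new_active_det
  }
  keep <- vapply(tracklets, function(tr) length(tr$frames) >= cfg$min_tracklet_len,
                 TRUE)
  kept_ids <- which(keep)
  tracklets <- tracklets[keep]
  events <- lapply(events, function(ev) {
    ev$groups_before <- intersect(ev$groups_before, kept_ids)
    ev$groups_after <- intersect(ev$groups_after, kept_ids)
    ev
  })
  out <- list(tracklets = tracklets, events = events, counts = counts)
  class(out) <- "zf_tracklets"
  out
}

#' @export
print.zf_tracklets <- function(x, ...) {
  lens <- vapply(x$tracklets, function(tr) length(tr$frames), 0L)
  cat(sprintf("%d tracklets over %d frames (lengths %s), %d crossing events\n",
              length(lens), length(x$counts),
              if (length(lens)) paste(range(lens), collapse = "-") else "-",
              length(x$events)))
  invisible(x)
}
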