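#' Evaluate tracking results against ground truth
#'
#' Fixes the trajectory-to-truth identity correspondence by majority frame
#' overlap (Hungarian assignment on per-pair overlap counts), then computes
#' the six evaluation metrics:
#' \itemize{
#'   \item IA — correctly identified fish / identified fish;
#'   \item CA — correct predicted labels summed over fish / classified
#'     (tracked) frames summed over fish;
#'   \item CrossFrequency — frames where the detected fish count falls below
#'     the total fish count / tracked frames;
#'   \item AccuracyRate — 1 - wrong tracked frames summed over fish /
#'     tracked frames;
#'   \item MissRate — missed frames summed over fish / (fish x frames);
#'   \item ErrorRate — wrong tracked frames summed over fish /
#'     (fish x frames).
#' }
#' "Tracked frames" in the CrossFrequency and AccuracyRate denominators is
#' the total number of processed frames. A tracked position is correct when
#' it lies within `match_radius` of its mapped true fish; a truth frame is
#' missed when its mapped trajectory has no position there.
#'
#' @param traj a `zf_trajectories`, a `zf_track`, or a data.frame with
#'   columns frame, fish_id, x, y (NA positions mark gaps).
#' @param truth data.frame with columns frame, fish, x, y (the ground-truth
#'   table of [generate_video()]).
#' @param total_fish total number of fish; default `max(truth$fish)`.
#' @param detected_counts optional per-frame detection counts used for
#'   CrossFrequency; when absent, the per-frame number of tracked
#'   trajectory positions is used instead.
#' @param match_radius correctness radius in px (default 30, about one body
#'   semi-axis).
#' @return list of class `zf_report` with the six metrics, `per_fish`
#'   breakdowns, and the identity `mapping`.
#' @export
evaluate_tracking <- function(traj, truth, total_fish = max(truth$fish),
                              detected_counts = NULL, match_radius = 30) {
  if (inherits(traj, "zf_track")) {
    if (is.null(detected_counts)) detected_counts <- traj$counts
    traj <- traj$trajectories
  }
  if (inherits(traj, "zf_trajectories")) traj <- traj$table
  n_frames <- max(truth$frame)
  ids <- sort(unique(traj$fish_id))
  fish <- sort(unique(truth$fish))
  pos <- function(df, id_col, id) {
    d <- df[df[[id_col]] == id, ]
    x <- rep(NA_real_, n_frames); y <- rep(NA_real_, n_frames)
    x[d$frame] <- d$x; y[d$frame] <- d$y
    cbind(x, y)
  }
  tp <- lapply(ids, function(i) pos(traj, "fish_id", i))
  gp <- lapply(fish, function(j) pos(truth, "fish", j))
  tracked <- vapply(tp, function(p) sum(!is.na(p[, 1])), 0)
  if (sum(tracked) == 0) {
    warning("no tracked frames: all-zero report")
    out <- list(IA = 0, CA = 0, CrossFrequency = 0, AccuracyRate = 0,
                MissRate = 0, ErrorRate = 0, per_fish = NULL, mapping = NULL)
    class(out) <- "zf_report"
    return(out)
  }
  overlap <- matrix(0, length(ids), length(fish))
  for (i in seq_along(ids)) {
    for (j in seq_along(fish)) {
      d <- sqrt((tp[[i]][, 1] - gp[[j]][, 1])^2 +
                (tp[[i]][, 2] - gp[[j]][, 2])^2)
      overlap[i, j] <- sum(d <= match_radius, na.rm = TRUE)
    }
  }
  mapping <- if (length(ids) <= length(fish)) {
    assign_max(overlap)
  } else {
    stop("more trajectories than true fish", call. = FALSE)
  }
  correct <- wrong <- numeric(length(ids))
  for (i in seq_along(ids)) {
    d <- sqrt((tp[[i]][, 1] - gp[[mapping[i]]][, 1])^2 +
              (tp[[i]][, 2] - gp[[mapping[i]]][, 2])^2)
    correct[i] <- sum(d <= match_radius, na.rm = TRUE)
    wrong[i] <- tracked[i] - correct[i]
  }
  missed <- numeric(length(fish))
  for (j in seq_along(fish)) {
    i <- match(j, mapping)
    missed[j] <- if (is.na(i)) n_frames else sum(is.na(tp[[i]][, 1]))
  }
  identified <- which(tracked > 0)
  majority <- apply(overlap, 1, which.max)
  IA <- if (length(identified)) {
    mean(majority[identified] == mapping[identified])
  } else 0
  if (is.null(detected_counts)) {
    detected_counts <- vapply(seq_len(n_frames), function(t) {
      sum(vapply(tp, function(p) !is.na(p[t, 1]), TRUE))
    }, 0)
  }
  out <- list(
    IA = IA,
    CA = sum(correct) / sum(tracked),
    CrossFrequency = sum(detected_counts < total_fish) / n_frames,
    AccuracyRate = 1 - sum(wrong) / n_frames,
    MissRate = sum(missed) / (total_fish * n_frames),
    ErrorRate = sum(wrong) / (total_fish * n_frames),
    per_fish = data.frame(trajectory = ids, truth_fish = fish[mapping],
                          tracked = tracked, correct = correct,
                          wrong = wrong),
    missed_per_fish = missed,
    mapping = mapping)
  class(out) <- "zf_report"
  out
}

#' @export
print.zf_report <- function(x, ...) {
  cat("Tracking evaluation\n")
  cat(sprintf("  IA  = %.4f   CA = %.4f   CrossFrequency = %.4f\n",
              x$IA, x$CA, x$CrossFrequency))
  cat(sprintf("  AccuracyRate = %.4f   MissRate = %.4f   ErrorRate = %.4f\n",
              x$AccuracyRate, x$MissRate, x$ErrorRate))
  invisible(x)
}

#' Shoaling statistics: nearest-neighbour and inter-individual distance
#'
#' Samples the trajectories every `sampling_interval` seconds. At each
#' sampled frame the nearest-neighbour distance of every present fish and
#' the mean distance over all unordered pairs are computed; frames with
#' fewer than two tracked fish are skipped.
#'
#' @param traj trajectory data.frame (frame, fish_id, x, y) or a
#'   `zf_track`/`zf_trajectories`.
#' @param sampling_interval seconds between samples (default 5).
#' @param frame_rate frames per second.
#' @return list: `per_fish` (frame, fish_id, nnd), `per_frame` (frame,
#'   avg_iid, n_present), `summary` (time-mean nnd and avg_iid).
#' @export
shoal_stats <- function(traj, sampling_interval = 5, frame_rate = 30) {
  if (inherits(traj, "zf_track")) traj <- traj$trajectories
  if (inherits(traj, "zf_trajectories")) traj <- traj$table
  step <- max(1L, round(sampling_interval * frame_rate))
  frames <- seq(1L, max(traj$frame), by = step)
  per_fish <- list(); per_frame <- list()
  for (t in frames) {
    d <- traj[traj$frame == t & !is.na(traj$x), ]
    if (nrow(d) < 2) next
    D <- as.matrix(stats::dist(d[, c("x", "y")]))
    diag(D) <- Inf
    per_fish[[length(per_fish) + 1L]] <-
      data.frame(frame = t, fish_id = d$fish_id, nnd = apply(D, 1, min))
    per_frame[[length(per_frame) + 1L]] <-
      data.frame(frame = t, avg_iid = mean(D[upper.tri(D)]),
                 n_present = nrow(d))
  }
  per_fish <- do.call(rbind, per_fish)
  per_frame <- do.call(rbind, per_frame)
  list(per_fish = per_fish, per_frame = per_frame,
       summary = c(nnd = if (is.null(per_fish)) NA_real_ else mean(per_fish$nnd),
                   avg_iid = if (is.null(per_frame)) NA_real_ else mean(per_frame$avg_iid)))
}

#' Locomotion statistics of one trajectory
#'
#' Total distance travelled, average velocity, cumulative turn angle
#' (absolute heading changes, wrapped to (-180, 180]) and angular velocity.
#' Gaps split the trajectory into segments that are measured independently
#' and summed; gap spans contribute no distance and no duration.
#'
#' @param traj data.frame with columns frame, x, y and optionally
#'   heading_deg for a single fish (filter a multi-fish table first).
#' @param frame_rate frames per second.
#' @return list: `total_distance` (px), `average_velocity` (px/s),
#'   `turn_angle` (deg), `angular_velocity` (deg/s), `duration` (s).
#' @export
locomotion_stats <- function(traj, frame_rate = 30) {
  traj <- traj[!is.na(traj$x), ]
  traj <- traj[order(traj$frame), ]
  if (nrow(traj) < 2)
    return(list(total_distance = 0, average_velocity = 0, turn_angle = 0,
                angular_velocity = 0, duration = 0))
  seg <- cumsum(c(1, diff(traj$frame) != 1))
  dist <- 0; turn <- 0; dur <- 0
  for (s in unique(seg)) {
    d <- traj[seg == s, ]
    if (nrow(d) < 2) next
    dist <- dist + sum(sqrt(diff(d$x)^2 + diff(d$y)^2))
    dur <- dur + (nrow(d) - 1) / frame_rate
    hd <- if ("heading_deg" %in% names(d) && !anyNA(d$heading_deg)) {
      d$heading_deg
    } else {
      atan2(-diff(d$y), diff(d$x)) * 180 / pi
    }
    if (length(hd) >= 2) turn <- turn + sum(abs(wrap180(diff(hd))))
  }
  list(total_distance = dist,
       average_velocity = if (dur > 0) dist / dur else 0,
       turn_angle = turn,
       angular_velocity = if (dur > 0) turn / dur else 0,
       duration = dur)
}
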