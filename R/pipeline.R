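#' Read a frame sequence from a directory
#'
#' Reads numbered 8-bit grayscale PNG (or TIFF, if the tiff package is
#' installed) frames in lexicographic order and converts them to 0-255
#' intensity matrices; colour images are averaged over channels.
#'
#' @param path directory containing the frames.
#' @param pattern filename regular expression (default PNG/TIFF extensions).
#' @return list of numeric matrices.
#' @export
read_frames <- function(path, pattern = "\\.(png|tif|tiff)$") {
  files <- sort(list.files(path, pattern = pattern, ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0) stop("no frames found in ", path, call. = FALSE)
  lapply(files, function(f) {
    img <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
      png::readPNG(f)
    } else {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the tiff package is required for TIFF input", call. = FALSE)
      tiff::readTIFF(f)
    }
    if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
    round(img * 255)
  })
}

#' Track multiple fish through a video
#'
#' Runs the full pipeline: background model, per-frame segmentation,
#' head-right ROI extraction and improved-HOG features, minimum-distance
#' tracklet building, crossing-classifier stitching, and final identity
#' assignment. Deterministic for a given configuration.
#'
#' @param frames list of grayscale matrices, a directory path (passed to
#'   [read_frames()]), or a `zf_video` from [generate_video()].
#' @param cfg a [zf_config()].
#' @param n_fish number of identities; default the maximum per-frame
#'   detection count.
#' @return object of class `zf_track`: `trajectories` (data.frame frame,
#'   fish_id, x, y, heading_deg, confidence, flagged), `counts` (per-frame
#'   detection counts), `tracklets` (stitched `zf_tracklets`), `stage_log`
#'   (per-stage tallies), `config`, `n_fish`.
#' @export
track_video <- function(frames, cfg = zf_config(), n_fish = NULL) {
  if (is.character(frames)) frames <- read_frames(frames)
  if (inherits(frames, "zf_video")) frames <- frames$frames
  bg <- build_background(frames, min(cfg$f_background, length(frames)))
  n_frames <- length(frames)
  dets <- vector("list", n_frames)
  rois <- vector("list", n_frames)
  n_rejected <- 0L
  for (t in seq_len(n_frames)) {
    dl <- segment_frame(frames[[t]], bg, cfg, frame_index = t)
    ri <- vector("list", length(dl))
    for (k in seq_along(dl)) {
      ph <- resolve_head(frames[[t]], dl[[k]])
      tf <- full_angle(dl[[k]]$theta_raw, ph$region)
      roi <- extract_roi(frames[[t]], dl[[k]], tf, cfg, fill = bg$mean_level)
      feat <- if (roi$quality == "accepted") {
        extract_feature(roi, bg, cfg)$vector
      } else {
        n_rejected <- n_rejected + 1L
        NULL
      }
      dl[[k]]$theta_full <- tf
      ri[k] <- list(feat)   # keep NULL placeholders for rejected ROIs
    }
    dets[[t]] <- dl
    rois[[t]] <- ri
  }
  if (sum(lengths(dets)) == 0)
    stop("no detections in the entire video; check Thr_g/Thr_s and polarity",
         call. = FALSE)
  if (is.null(n_fish)) {
    # modal per-frame detection count: robust to transient merges/splits
    cnt <- lengths(dets)
    tab <- table(cnt[cnt > 0])
    n_fish <- as.integer(names(tab)[which.max(tab)])
  }
  tl <- with_seed(cfg$seed, {
    tl <- build_tracklets(dets, cfg)
    # attach per-tracklet entries and feature pools
    tl$tracklets <- lapply(tl$tracklets, function(tr) {
      ent <- data.frame(
        frame = tr$frames,
        x = vapply(seq_along(tr$frames), function(i)
          dets[[tr$frames[i]]][[tr$det_idx[i]]]$centroid[1], 0),
        y = vapply(seq_along(tr$frames), function(i)
          dets[[tr$frames[i]]][[tr$det_idx[i]]]$centroid[2], 0),
        heading_deg = vapply(seq_along(tr$frames), function(i)
          dets[[tr$frames[i]]][[tr$det_idx[i]]]$theta_full, 0))
      feats <- Filter(Negate(is.null), lapply(seq_along(tr$frames), function(i)
        rois[[tr$frames[i]]][[tr$det_idx[i]]]))
      tr$entries <- ent
      tr$features <- if (length(feats)) do.call(rbind, feats) else
        matrix(numeric(), 0, 0)
      tr
    })
    stitch_and_accumulate(tl, cfg, n_fish = n_fish)
  })
  traj <- with_seed(cfg$seed + 1L, final_trajectories(tl, n_fish, cfg, n_frames))
  out <- list(
    trajectories = traj$table,
    counts = tl$counts,
    tracklets = tl,
    final = traj,
    stage_log = list(
      n_frames = n_frames,
      detections = sum(tl$counts),
      rejected_rois = n_rejected,
      tracklets = length(tl$tracklets),
      crossing_events = length(tl$events),
      stitch_accepted = sum(vapply(tl$stitch_log, function(l) l$accepted, TRUE)),
      flagged_frames = sum(traj$table$flagged, na.rm = TRUE)),
    config = cfg,
    n_fish = n_fish)
  class(out) <- "zf_track"
  out
}

#' @export
print.zf_track <- function(x, ...) {
  sl <- x$stage_log
  cat(sprintf("zf_track: %d fish over %d frames\n", x$n_fish, sl$n_frames))
  cat(sprintf("  %d detections, %d ROIs rejected, %d tracklets, %d crossing events (%d stitched)\n",
              sl$detections, sl$rejected_rois, sl$tracklets,
              sl$crossing_events, sl$stitch_accepted))
  tracked <- sum(!is.na(x$trajectories$x))
  cat(sprintf("  %d/%d fish-frames tracked, %d flagged low-confidence\n",
              tracked, nrow(x$trajectories), sl$flagged_frames))
  invisible(x)
}

#' @export
summary.zf_track <- function(object, ...) {
  tab <- object$trajectories
  per <- aggregate(!is.na(tab$x), list(fish_id = tab$fish_id), sum)
  names(per)[2] <- "tracked_frames"
  res <- list(stage_log = object$stage_log, per_fish = per,
              n_fish = object$n_fish)
  class(res) <- "summary.zf_track"
  res
}

#' @export
print.summary.zf_track <- function(x, ...) {
  cat("Pipeline stages:\n")
  for (nm in names(x$stage_log)) cat(sprintf("  %s: %s\n", nm, x$stage_log[[nm]]))
  cat("Tracked frames per fish:\n")
  print(x$per_fish, row.names = FALSE)
  invisible(x)
}

#' @export
plot.zf_track <- function(x, ...) {
  tab <- x$trajectories
  cols <- grDevices::hcl.colors(x$n_fish, "Dark 3")
  graphics::plot(NA, xlim = range(tab$x, na.rm = TRUE),
                 ylim = rev(range(tab$y, na.rm = TRUE)),
                 xlab = "x (px)", ylab = "y (px)", asp = 1,
                 main = "Tracked trajectories", ...)
  for (i in seq_len(x$n_fish)) {
    d <- tab[tab$fish_id == i, ]
    graphics::lines(d$x, d$y, col = cols[i])
  }
  graphics::legend("topright", legend = paste("fish", seq_len(x$n_fish)),
                   col = cols, lty = 1, cex = 0.8)
  invisible(x)
}

#' Write trajectories (and a flagged-frames sidecar) to CSV
#'
#' @param x a `zf_track` or trajectory data.frame.
#' @param path output CSV path; the low-confidence sidecar is written next
#'   to it as `<path>.flagged.csv`.
#' @param sidecar write the flagged-frames sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(x, path, sidecar = TRUE) {
  tab <- if (inherits(x, "zf_track")) x$trajectories else x
  write.csv(tab, path, row.names = FALSE)
  if (sidecar && "flagged" %in% names(tab)) {
    fl <- tab[tab$flagged & !is.na(tab$x), ]
    write.csv(fl, paste0(path, ".flagged.csv"), row.names = FALSE)
  }
  invisible(path)
}
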