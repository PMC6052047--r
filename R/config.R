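#' Tracking configuration
#'
#' Bundles every threshold and parameter of the tracking pipeline. The
#' defaults are the settings used throughout: area threshold `Thr_s` and grey
#' threshold `Thr_g` for background subtraction (the only two knobs that
#' normally need adjusting between arenas), ROI scale `P_r`, aspect-ratio
#' threshold `Thr_e` rejecting deformed/overlapping bodies, match-redundancy
#' distance `Thr_d`, cell relevance pixel count `P_c`, spiral block count
#' `P_b`, and the low-confidence probability threshold `Thr_p`.
#'
#' @param Thr_s minimum blob area in px^2 (default 500).
#' @param Thr_g grey-level threshold for background subtraction (default 20).
#' @param P_r side of the square, rescaled ROI sample in px (default 100).
#' @param Thr_e minimum enclosing-rectangle aspect ratio of an accepted ROI
#'   (default 3); lower ratios indicate a bent or overlapping body.
#' @param Thr_d distance margin in px that rescues the closer of two
#'   detections competing for the same match (default 30).
#' @param P_c minimum foreground pixel count for a descriptor cell to be
#'   marked body-relevant (default 10).
#' @param P_b number of relevant blocks emitted spirally (default 34).
#' @param Thr_p probability below which an accepted match is flagged as a
#'   possible error (default 0.60).
#' @param n_bins unsigned orientation bins per cell histogram (default 9).
#' @param cell_px cell side in pixels (default 9).
#' @param block_cells block side in cells (default 2).
#' @param f_background number of leading frames averaged into the background
#'   model, capped at the number of available frames (default 400; long
#'   enough that a fish passing over a pixel leaves no ghost above `Thr_g`).
#' @param polarity `"bright"` for fish brighter than the background,
#'   `"dark"` for the opposite contrast.
#' @param head_fraction fraction of the rotated body box, measured from the
#'   head end, kept as the ROI crop (default 0.5, i.e. the anterior half).
#' @param roi_smooth_sigma sd (px) of the Gaussian that smooths the rescaled
#'   ROI patch against resampling aliasing (default 1.5 at patch scale,
#'   well under one source pixel after magnification; 0 disables).
#' @param svm_cost,svm_gamma RBF-SVM hyperparameters; `svm_gamma = NA` means
#'   1/feature-dimension.
#' @param max_match_dist maximum centroid displacement in px considered for
#'   frame-to-frame matching (default 45, under one body length; a vanished
#'   detection then ends its tracklet instead of grabbing a neighbour).
#' @param event_window frames over which tracklet endpoints are grouped into
#'   one crossing event (default 5).
#' @param min_tracklet_len tracklets shorter than this many frames are
#'   discarded as crossing debris (default 10).
#' @param overlap_area_factor a detection whose area exceeds this multiple of
#'   the median detection area is treated as an overlapping (merged) blob
#'   (default 1.45, between one and two body areas).
#' @param max_train_samples per-class cap on SVM training samples (default 150).
#' @param prob_aggregation how per-frame class probabilities are pooled over a
#'   tracklet: `"mean"` or `"vote"`.
#' @param seed integer seed controlling all randomized steps.
#' @return An object of class `zf_config` (a validated named list).
#' @export
zf_config <- function(Thr_s = 500, Thr_g = 20, P_r = 100, Thr_e = 3,
                      Thr_d = 30, P_c = 10, P_b = 34, Thr_p = 0.60,
                      n_bins = 9, cell_px = 9, block_cells = 2,
                      f_background = 400, polarity = c("bright", "dark"),
                      head_fraction = 0.5, roi_smooth_sigma = 1.5,
                      svm_cost = 10, svm_gamma = NA,
                      max_match_dist = 45, event_window = 5,
                      min_tracklet_len = 10, overlap_area_factor = 1.45,
                      max_train_samples = 150,
                      prob_aggregation = c("mean", "vote"), seed = 1L) {
  cfg <- list(
    Thr_s = Thr_s, Thr_g = Thr_g, P_r = P_r, Thr_e = Thr_e, Thr_d = Thr_d,
    P_c = P_c, P_b = P_b, Thr_p = Thr_p, n_bins = n_bins, cell_px = cell_px,
    block_cells = block_cells, f_background = f_background,
    polarity = match.arg(polarity), head_fraction = head_fraction,
    roi_smooth_sigma = roi_smooth_sigma,
    svm_cost = svm_cost, svm_gamma = as.numeric(svm_gamma),
    max_match_dist = max_match_dist, event_window = event_window,
    min_tracklet_len = min_tracklet_len,
    overlap_area_factor = overlap_area_factor,
    max_train_samples = max_train_samples,
    prob_aggregation = match.arg(prob_aggregation), seed = as.integer(seed))
  class(cfg) <- "zf_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk <- function(ok, name, msg) {
    if (!isTRUE(ok)) stop(sprintf("invalid config value `%s`: %s", name, msg),
                          call. = FALSE)
  }
  pos <- c("Thr_s", "Thr_g", "P_r", "Thr_e", "Thr_d", "P_c", "P_b", "n_bins",
           "cell_px", "block_cells", "f_background", "head_fraction",
           "svm_cost", "max_match_dist", "event_window", "min_tracklet_len",
           "overlap_area_factor", "max_train_samples")
  for (p in pos) {
    chk(is.numeric(cfg[[p]]) && length(cfg[[p]]) == 1 && cfg[[p]] > 0,
        p, "must be a positive number")
  }
  chk(is.numeric(cfg$Thr_p) && cfg$Thr_p > 0 && cfg$Thr_p < 1,
      "Thr_p", "must lie in (0, 1)")
  chk(cfg$head_fraction <= 1, "head_fraction", "must lie in (0, 1]")
  chk(is.numeric(cfg$roi_smooth_sigma) && cfg$roi_smooth_sigma >= 0,
      "roi_smooth_sigma", "must be non-negative")
  chk(cfg$polarity %in% c("bright", "dark"), "polarity",
      "must be 'bright' or 'dark'")
  n_cells <- floor(cfg$P_r / cfg$cell_px)
  n_blocks <- (n_cells - cfg$block_cells + 1)^2
  chk(cfg$P_b <= n_blocks, "P_b",
      sprintf("exceeds the %d block positions available at P_r=%d, cell=%d",
              n_blocks, cfg$P_r, cfg$cell_px))
  cfg
}

#' @export
print.zf_config <- function(x, ...) {
  cat("Tracking configuration (zf_config)\n")
  cat(sprintf("  segmentation: Thr_s=%g px^2, Thr_g=%g, polarity=%s\n",
              x$Thr_s, x$Thr_g, x$polarity))
  cat(sprintf("  ROI: P_r=%gx%g px, Thr_e=%g, head_fraction=%g\n",
              x$P_r, x$P_r, x$Thr_e, x$head_fraction))
  cat(sprintf("  descriptor: cell=%g px, block=%g cells, n_bins=%g, P_c=%g, P_b=%g\n",
              x$cell_px, x$block_cells, x$n_bins, x$P_c, x$P_b))
  cat(sprintf("  matching: Thr_d=%g px, max_match_dist=%g px, Thr_p=%g\n",
              x$Thr_d, x$max_match_dist, x$Thr_p))
  invisible(x)
}

#' Read or write a configuration file
#'
#' The file format is flat `key = value` text, one pair per line; `#` starts
#' a comment. All keys are optional and default to [zf_config()] defaults.
#' Unknown keys are rejected. `profile` applies a tank preset before the file
#' overrides: `"small_tank"` keeps the defaults, `"large_tank"` raises the
#' area and grey thresholds (`Thr_s = 800`, `Thr_g = 50`) for the coarser
#' fish-to-arena scale of a large tank.
#'
#' @param path file path; `load_config(NULL)` returns pure defaults.
#' @param profile optional preset, `"small_tank"` or `"large_tank"`.
#' @return `load_config()` returns a `zf_config`; `save_config()` writes
#'   `cfg` and returns `path` invisibly.
#' @export
load_config <- function(path = NULL, profile = NULL) {
  args <- list()
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("small_tank", "large_tank"))
    if (profile == "large_tank") args <- list(Thr_s = 800, Thr_g = 50)
  }
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("malformed config line: ", ln, call. = FALSE)
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (!key %in% names(formals(zf_config)))
        stop("unknown config key: ", key, call. = FALSE)
      args[[key]] <- if (key %in% c("polarity", "prob_aggregation")) val
                     else if (identical(val, "NA")) NA_real_
                     else as.numeric(val)
    }
  }
  do.call(zf_config, args)
}

#' @param cfg a `zf_config` object.
#' @rdname load_config
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "zf_config"))
  fmt <- function(v) if (is.character(v)) v else format(v, digits = 15)
  writeLines(sprintf("%s = %s", names(cfg), vapply(cfg, fmt, "")), path)
  invisible(path)
}
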