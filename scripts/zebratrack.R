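#!/usr/bin/env Rscript
# Command-line front end for the zebratrack pipeline.
#
#   Rscript scripts/zebratrack.R simulate --n-fish 4 --n-frames 600 --seed 1 --out frames/
#   Rscript scripts/zebratrack.R track <frames-dir> [--config cfg.txt] --out traj.csv
#   Rscript scripts/zebratrack.R evaluate <traj.csv> <truth.csv> [--out report.json]

suppressPackageStartupMessages({
  library(zebratrack)
  library(optparse)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) {
  cat("usage: zebratrack.R <simulate|track|evaluate> [options]\n")
  quit(status = 1)
}
cmd <- args[1]
rest <- args[-1]

if (cmd == "simulate") {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--n-fish", type = "integer", default = 4, dest = "n_fish"),
    make_option("--n-frames", type = "integer", default = 600, dest = "n_frames"),
    make_option("--seed", type = "integer", default = 1L),
    make_option("--crossing-bias", type = "double", default = 0.3,
                dest = "crossing_bias"),
    make_option("--out", type = "character", default = "frames"))),
    args = rest)
  sc <- synth_scene(n_fish = opts$n_fish, n_frames = opts$n_frames,
                    texture_seed = opts$seed,
                    crossing_bias = opts$crossing_bias)
  v <- generate_video(sc)
  write_video(v, opts$out)
  cat(sprintf("wrote %d frames + truth.csv to %s\n", opts$n_frames, opts$out))
} else if (cmd == "track") {
  src <- rest[1]
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--config", type = "character", default = NULL),
    make_option("--n-fish", type = "integer", default = NULL, dest = "n_fish"),
    make_option("--out", type = "character", default = "trajectories.csv"))),
    args = rest[-1])
  cfg <- load_config(opts$config)
  tr <- track_video(src, cfg, n_fish = opts$n_fish)
  print(tr)
  write_trajectories(tr, opts$out)
  cat("wrote", opts$out, "\n")
} else if (cmd == "evaluate") {
  traj <- utils::read.csv(rest[1])
  truth <- utils::read.csv(rest[2])
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--out", type = "character", default = NULL))),
    args = rest[-(1:2)])
  rep <- evaluate_tracking(traj, truth)
  print(rep)
  if (!is.null(opts$out)) {
    jsonlite::write_json(rep[c("IA", "CA", "CrossFrequency", "AccuracyRate",
                               "MissRate", "ErrorRate")],
                         opts$out, auto_unbox = TRUE, digits = NA)
    cat("wrote", opts$out, "\n")
  }
} else {
  cat("unknown command:", cmd, "\n")
  quit(status = 1)
}
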