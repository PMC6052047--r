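# zebratrack

Identity-preserving tracking of multiple zebrafish in top-view grayscale
video, for behavioural researchers who need per-individual trajectories of
visually similar animals — shoaling structure, locomotion of a treated fish
inside a group, long observation sessions — without physical marking.

The hard part of multi-fish tracking is not finding the fish but keeping
their identities across crossings, when two bodies merge into one image
blob. zebratrack solves it with a pose-normalized back-texture descriptor
and classifier-based tracklet association:

* **Detection.** Static background model `Bm(x,y) = (1/f) Σ_t G_t(x,y)`;
  foreground where `|G_t − Bm| > Thr_g`; 8-connected components with area
  ≥ `Thr_s`; per blob a second-moment ellipse (centroid, tilt angle
  θ ∈ [−90°, 90°), axes).
* **Head-right ROI.** The head lies on the rectangle half with the larger
  pixel sum; θ plus the head side gives the full angle in [0°, 360°); the
  anterior half of the body box is rotated head-right and rescaled to
  `P_r × P_r`. Samples with aspect ratio < `Thr_e` (bent or overlapping
  bodies) are rejected.
* **Masked spiral gradient descriptor.** Unsigned gradient-orientation
  histograms (9 bins) in 9×9 px cells, 2×2-cell blocks at one-cell stride
  with L2 normalization; cells with fewer than `P_c` foreground pixels of
  the binarized body (`Bi = 1` iff `G > mean(Bm)`) are irrelevant, a block
  is relevant if any member cell is; the first `P_b` relevant blocks in a
  fixed centre-out spiral form the descriptor (length `P_b·4·9`).
* **Tracklets.** Nearest-centroid matching `m(O_i,t−1, O_j,t) = 1` iff
  `j = argmin_j D(O_i, O_j)`; conflicting claims cancel unless the distance
  gap exceeds `Thr_d`; tracklets shorter than 10 frames are discarded; blobs
  much larger than the median detection are treated as merged and cut
  tracklets at merge and split.
* **Identity.** Around each crossing, the flanking tracklet group with the
  longer shortest member trains a multi-class RBF-SVM on the descriptors;
  the other group's tracklets are classified (per-frame probabilities
  averaged) and matched by the Hungarian algorithm, accepting only if every
  selected probability exceeds `1/N`; matches below `Thr_p` are flagged. A
  final classifier trained on the group maximizing `min(NF)` labels all
  remaining tracklets. Unmatched training classes in rectangular problems
  identify an individual missing from the test video (e.g. a treated fish).
* **Metrics.** IA, CA, CrossFrequency, AccuracyRate, MissRate, ErrorRate
  against ground truth, plus shoaling (nearest-neighbour and average
  inter-individual distance) and locomotion (distance, velocity, turn
  angle, angular velocity) statistics.

A built-in synthetic video generator renders textured fish with exact
ground truth, so the whole pipeline is testable without recorded data.

## Worked example

```r
library(zebratrack)

scene <- synth_scene(n_fish = 2, n_frames = 260, frame_size = c(420, 560),
                     texture_seed = 5, crossing_bias = 0.8)
video <- generate_video(scene)
video
#> Synthetic video: 2 fish, 260 frames (64 with overlap)

tr <- track_video(video, zf_config())
tr
#> zf_track: 2 fish over 260 frames
#>   454 detections, 40 ROIs rejected, 7 tracklets, 5 crossing events (3 stitched)
#>   388/520 fish-frames tracked, 0 flagged low-confidence

evaluate_tracking(tr, video$truth)
#> Tracking evaluation
#>   IA  = 1.0000   CA = 1.0000   CrossFrequency = 0.2538
#>   AccuracyRate = 1.0000   MissRate = 0.2538   ErrorRate = 0.0000
```

Reading the output: the two fish overlap on 64 of 260 frames
(CrossFrequency 0.25 — a quarter of the video is a crossing), which breaks
the detections into 7 tracklets around 5 crossing events; the crossing
classifiers stitch 3 of them and the final classifier labels the rest. Both
identities are recovered (IA = 1) with no wrongly tracked frame
(AccuracyRate = 1, ErrorRate = 0); the frames during full occlusion have no
per-fish position and appear as gaps (MissRate 0.25 mirrors the crossing
fraction).

Behaviour statistics from the same trajectories:

```r
shoal_stats(tr, sampling_interval = 1, frame_rate = 25)$summary
#>     nnd avg_iid
#>    93.6    93.6          # px; identical because N = 2

locomotion_stats(tr$trajectories[tr$trajectories$fish_id == 1, ],
                 frame_rate = 25)
#> $total_distance 597.3 px   $average_velocity 79 px/s
#> $turn_angle 1531.3 deg     $angular_velocity 202.6 deg/s
```

`plot(tr)` draws the trajectories; `write_trajectories(tr, "traj.csv")`
exports the per-frame table plus a `.flagged.csv` sidecar of low-confidence
frames for manual review.

A command-line wrapper is provided:

```sh
Rscript scripts/zebratrack.R simulate --n-fish 4 --n-frames 600 --seed 1 --out frames/
Rscript scripts/zebratrack.R track frames/ --out traj.csv
Rscript scripts/zebratrack.R evaluate traj.csv frames/truth.csv
```

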