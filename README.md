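# pigbyte

Behavior tracking and time budgets for group-housed pigs.

Commercial pens house 6–15 pigs whose welfare shows up in how they divide
their time between lying, standing, eating and everything else. A
behavior-classifying detector turns pen video into per-frame boxes with a
confidence and a behavior class — but no identities. `pigbyte` is the part
of the pipeline after the detector, for farm-monitoring researchers and
engineers who need identities and per-animal statistics:

* **Tracking-by-detection** with the BYTE two-stage association cascade:
  high-confidence detections (conf > τ_high = 0.6) are matched to tracks
  first by gated Hungarian assignment on 1 − IoU; low-confidence
  detections (0.1 < conf ≤ 0.6) then rescue the tracks left unmatched —
  typically partially occluded pigs — while low-confidence detections that
  match nothing are discarded as background. Track motion is a
  constant-velocity Kalman filter on (cx, cy, aspect, height). New tracks
  are born from unmatched detections with conf > η = 0.75; tracks lost for
  more than 30 frames are removed.
* **Occlusion repair** by linear trajectory interpolation: an internal gap
  between matched frames t₁ < t₂ is filled with
  Bt = Bt₁ + (Bt₂ − Bt₁)·(t − t₁)/(t₂ − t₁) on the box corners, for gaps
  up to `max_gap` (default 20 frames).
* **Behavior time budgets**: each track keeps a 4-slot counter
  A = (A_lie, A_stand, A_eat, A_other) incremented by the matched
  detection's one-hot class every frame it is matched; seconds per class
  are A / fps.
* **Evaluation**: HOTA (single-threshold ratio form
  Σ_c A(c) / (TP + FN + FP), with the benchmark-standard sqrt/averaged
  variant available), MOTA = 1 − (ΣFP + ΣFN + ΣIDS)/Σgt,
  IDF1 = 2·IDTP/(2·IDTP + IDFP + IDFN), and identity switches, plus
  multi-sequence aggregation (IDs by sum, ratios by pooled counts).
* **A seeded pen simulator** (day/night activity and confidence regimes,
  pairwise-occlusion dropout, box jitter) so the whole pipeline runs and
  is tested without any video data.

Detections, ground truth and tracks all use a MOT-dialect CSV
(`frame,id,left,top,width,height,conf,class[,interp]`, classes 1=lie,
2=stand, 3=eat, 4=other) with a small YAML sidecar for sequence metadata.

## Worked example

Simulate a 1-minute medium-activity pen of 6 pigs at 5 fps, track it,
compute budgets, and score against the simulator's ground truth:

```r
library(pigbyte)

sc    <- sim_preset("day_medium", n_pigs = 6, n_frames = 300, seed = 7)
scene <- simulate_scene(sc)

res <- run_sequence(scene$dets, n_frames = 300)
res
#> <pig_tracks> 6 tracks over 300 frames, 1800 rows (63 interpolated)

behavior_summary(res, scene$meta)
#>   track_id lie_frames stand_frames eat_frames other_frames lie_s stand_s eat_s other_s
#> 1        1         66          108         74           42  13.2    21.6  14.8     8.4
#> 2        2        117          102         62           11  23.4    20.4  12.4     2.2
#> 3        3        126           65         70           22  25.2    13.0  14.0     4.4
#> 4        4        146           80         42           26  29.2    16.0   8.4     5.2
#> 5        5        220           25         24           19  44.0     5.0   4.8     3.8
#> 6        6        148           50         37           55  29.6    10.0   7.4    11.0

evaluate_tracking(scene$gt, res$records)
#> <metrics_report> seq: HOTA 1.000  MOTA 1.000  IDF1 1.000  IDs 0
```

Each of the 6 pigs keeps one identity for the whole minute (zero identity
switches, all metrics at 1 to three decimals), and every pig's four
budgets sum to its matched time — e.g. pig 5 lay for 44 of its 58 matched
seconds, a typical low-activity individual. The 63 interpolated rows are
occlusion gaps refilled by the linear form above; rerunning with
`interpolate = FALSE` leaves those frames as misses.

The same flow is available from a shell via the bundled entry point
(`inst/cli/pigbyte`): `simulate`, `track`, `stats`, `eval`, and `demo`
(the full pipeline from one seed, with a run log).

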