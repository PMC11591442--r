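---
title: "Tracking and behavior time budgets for group-housed pigs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking and behavior time budgets for group-housed pigs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigbyte)
```

## The problem

Monitoring welfare in group-housed pigs requires knowing, per animal, how
much time it spends lying, standing, eating, or doing something else. A
behavior-classifying detector applied to pen video gives per-frame boxes
with a confidence and a behavior class, but no identities. pigbyte links
those detections into identity-labeled trajectories, repairs the gaps that
occlusion between pen mates leaves, turns matched frames into per-pig time
budgets, and scores tracking quality against ground truth.

The package deliberately starts *after* detection: detector training and
inference are out of scope, and detections are consumed from MOT-dialect
CSV files (`frame,id,left,top,width,height,conf,class[,interp]`) or from
the built-in pen simulator.

## Two-stage association over a Kalman motion model

Each live track carries a constant-velocity Kalman filter on the state
$(c_x, c_y, a, h, \dot c_x, \dot c_y, \dot a, \dot h)$ — box center, aspect
ratio $w/h$, height, and their per-frame velocities — with measurement
$(c_x, c_y, a, h)$ and noise standard deviations proportional to box
height (position weight $1/20$, velocity weight $1/160$ per frame; both
configurable through `kf_pars()`). These are the conventions of the
SORT/BYTE tracker family; nothing in the method depends on their exact
values, and they can be overridden wherever a detector's noise
characteristics differ.

Per frame the tracker:

1. **predicts** every non-removed track one frame forward — including lost
   tracks, so re-association after an occlusion uses the extrapolated
   position;
2. **splits** detections by confidence: above $\tau_{high} = 0.6$ high
   score, in $(\tau_{low}, \tau_{high}] = (0.1, 0.6]$ low score, the rest
   discarded;
3. **stage 1** matches all candidate tracks to high-score detections by
   gated Hungarian assignment on $1 - \mathrm{IoU}$ (gate: IoU $\ge$ 0.2);
4. **stage 2** matches the remaining tracks to low-score detections at the
   stricter gate IoU $\ge$ 0.5 — this is the step that keeps partially
   occluded, low-confidence pigs on their own track; low-score detections
   that still match nothing are background and are dropped, never born;
5. **births** a new track for each stage-1 unmatched detection with
   confidence above the tracking threshold $\eta = 0.75$;
6. **ages** unmatched tracks as lost and removes them once lost for more
   than 30 consecutive frames.

Behavior classes never gate the association: a pig may stand up between
two frames, and forcing class agreement would split its identity. The
matched detection's class simply overwrites the track's current class.
Matching ties inside the assignment are broken toward the lowest
(track, detection) pair, so runs are bit-reproducible.

The assignment itself is an $O(n^3)$ Hungarian solve (shortest augmenting
paths with potentials) written in R; pen-scale matrices are at most a few
dozen rows, so this costs microseconds per frame. Gated pairs are priced
prohibitively so the solver first maximizes the number of admissible
matches, then minimizes cost — the test suite checks this against an
exhaustive bitmask-DP oracle on hundreds of random instances.

## Occlusion gaps and linear interpolation

When a pig reappears within the 30-frame lost window and is re-associated,
its trajectory has a hole. As post-processing, every internal gap between
matched frames $t_1 < t_2$ with $t_2 - t_1 \le \texttt{max\_gap} + 1$ is
filled with

$$B_t = B_{t_1} + (B_{t_2} - B_{t_1})\,\frac{t - t_1}{t_2 - t_1},
\qquad t_1 < t < t_2,$$

applied to the corner coordinates $(l, t, r, b)$. Endpoints are left
untouched, nothing is extrapolated outside a track's matched span, and
interpolation never creates tracks or reassigns identities — it only adds
rows flagged `interp = 1`.

Design choices made here, where the linear form itself fixes only the
geometry:

* `max_gap` defaults to 20 frames (4 s at 5 fps). Unbounded interpolation
  across the full 30-frame deletion window would fabricate long unseen
  segments for fast-moving pigs; 4 s keeps the filled segment short
  relative to how quickly a walking pig changes direction.
* Interpolated rows take the behavior class of the nearest matched
  endpoint (the earlier one on ties) and a linearly interpolated
  confidence; a box equation says nothing about behavior, and the nearest
  observation is the least committal imputation.
* Interpolated rows do **not** increment behavior counters by default —
  the counting procedure keys on successful detector matches — but
  `behavior_summary(..., count_interpolated = TRUE)` includes them for
  users who prefer wall-clock budgets over evidence-backed budgets.

## Behavior time budgets

Every track carries a counter $A = (A_{lie}, A_{stand}, A_{eat},
A_{other})$. On each successful match (stage 1 or stage 2 — the counting
rule does not distinguish them) the matched detection's class is one-hot
encoded and added: $A \leftarrow A + a$. A new track starts from
$A = (0,0,0,0)$ and immediately accumulates its creating detection, so
$\sum_c A_c$ always equals the track's number of matched (non-interpolated)
rows. Budgets in seconds are $A_c / \mathrm{fps}$.

One upstream description of this procedure contains a branch that could be
read as zeroing an *existing* track's counters whenever it fails to match.
Zeroing accumulated statistics on every missed detection would destroy the
time budget that the procedure exists to report, so the package reads the
branch as zero-initialization of newly created tracks. The literal reading
remains available as `run_sequence(..., strict_reset = TRUE)`, under which
a track's budget reflects only its current uninterrupted matched run.

The slot order (lie, stand, eat, other) is fixed package-wide — types,
files, plots — because upstream descriptions of the class set disagree
among themselves about ordering; a single documented convention beats
guessing.

## Evaluation

`evaluate_tracking()` scores a track file against ground truth:

* **Frame matching** follows the CLEAR protocol: a ground-truth/predicted
  pairing made in the previous frame is kept while both sides are present
  and still overlap at IoU $\ge$ 0.5; the remaining boxes are matched by
  gated Hungarian assignment. Pure per-frame re-assignment was tried first
  and rejected: with jittered boxes, near-ties between two overlapping
  pigs flip almost every frame, inflating identity switches with artifacts
  of the evaluator rather than of the tracker. An identity switch (IDs) is
  counted when a ground-truth identity's matched predicted id differs from
  the last predicted id it was ever matched to.
* **MOTA** $= 1 - (\sum FP + \sum FN + \sum IDS)/\sum g_t$, which may be
  negative.
* **IDF1** $= 2\,IDTP / (2\,IDTP + IDFP + IDFN)$ with the identity-level
  bijection chosen to maximize $IDTP$, solved as an assignment problem
  over ground-truth-id $\times$ predicted-id overlap counts.
* **HOTA** is implemented in its single-threshold ratio form
  $\sum_{c \in TP} A(c) / (TP + FN + FP)$, where for a matched identity
  pair $c = (g, p)$, $A(c)$ is the sequence-level Jaccard overlap of the
  frames on which $g$ and $p$ are matched to each other. Benchmark tooling
  usually reports the square root of this ratio averaged over the gates
  $0.05, 0.10, \ldots, 0.95$; `evaluate_tracking(..., hota_standard =
  TRUE)` computes that variant alongside, and the two should not be
  compared to each other numerically.

Across sequences, identity switches aggregate by summation and ratio
metrics by pooling counts (sums of numerators over sums of denominators),
never by averaging per-sequence ratios. Published multi-sequence tables
generally follow the same convention: their IDs averages are exact column
sums, while their ratio averages are not arithmetic means of the rows.
When a report is built from printed values alone (`metrics_report()`),
the pooled ratios are undefined and returned as `NA` — only the IDs sum
is recomputable without the per-frame counts.

## The pen simulator

`simulate_scene()` produces a ground-truth/detections pair with the
statistical structure the tracker assumes, so the full pipeline is
testable without video:

* pigs are axis-aligned boxes with class-dependent size (lying pigs
  project wider and flatter than standing ones); no rotation, since the
  tracker operates on axis-aligned boxes;
* behavior evolves per pig by a 4-state Markov chain; three preset chains
  encode high day activity, medium mixed activity, and lie-dominated night
  activity (the low chain's stationary distribution puts over 90% of time
  on lying, so night pens are mostly static);
* position follows a class-dependent random walk with persistent heading,
  reflected at the pen walls (lying $\approx$ 0.3 px/frame, walking
  $\approx$ 3 px/frame at 5 fps in a 1280 x 720 pen);
* detections drop at random (day presets detect 97% of visible pigs,
  night 93%); in any pair overlapping above an IoU threshold the smaller
  pig counts as occluded and is dropped with an extra probability, and
  when kept gets confidence from a degraded regime (day visible
  $\mathcal N(0.88, 0.04)$ vs. occluded $\mathcal N(0.45, 0.08)$; night
  visible $\mathcal N(0.78, 0.06)$); surviving boxes get Gaussian
  corner jitter (sd 1.5 px);
* all randomness derives from per-pig substreams seeded deterministically
  from the scenario seed, so adding a pig never perturbs the others and
  every scene is byte-reproducible.

The occlusion model is pairwise-overlap dropout, not depth rendering: it
is sufficient to exercise the lost buffer, stage-2 rescue and gap
interpolation, which is what the tests need. What the simulator does *not*
emulate — deformable pig shapes, lighting drift within a sequence,
correlated detector failures, crowding beyond simple overlap — bounds what
passing tests prove: they validate the tracking, interpolation, counting
and scoring machinery, not detector-facing robustness on real video.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run pens of 6–15 pigs for
120–300 frames (up to one simulated minute at 5 fps) and a few seeds per
property; these sizes give stable metric estimates while keeping a full
suite run under a minute, and the pipeline scales linearly in frames so
longer sequences change nothing structurally. Other numerical choices:
covariance symmetry is enforced after every filter step (Joseph-form
update); the assignment solver prices gated pairs at $10^6$ so gate
feasibility dominates cost; evaluation gates use a $10^{-9}$ tolerance so
boxes at exactly the threshold IoU count as matched; degenerate boxes
(non-positive width or height) are rejected at every interface rather than
silently clipped.

## Known limitations

* Identity swaps during prolonged deep crossings of two similar-sized pigs
  are possible even with perfect detections; motion-plus-IoU association
  carries no appearance information, by design.
* Track fragments are not stitched: a pig lost for more than the 30-frame
  buffer returns as a new identity, exactly as the lifecycle rules
  prescribe.
* Interpolation is offline post-processing; the online pass emits only
  matched boxes.
* The literal single-threshold HOTA and the benchmark-standard variant are
  different quantities; cross-package comparisons should state which one
  they use.
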