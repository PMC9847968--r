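---
title: "Pass-possibility networks and graph visual rhythms: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pass-possibility networks and graph visual rhythms: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`passrhythm` asks a concrete tactical question of player tracking data:
given only the first five seconds after a team wins the ball, will that
possession reach the attacking zone — the final quarter of the pitch —
before the ball is lost? The pipeline answers it in five stages:

1. **Possession segmentation.** The match is cut into ball-possession
   intervals (BPIs), maximal runs of frames with one team in control.
   Each interval at least 10 s long is split into the feature-extraction
   time window (FETW, first 5 s), a flexible middle Lag, and the Target
   (last 5 s). The label is computed from the Target only: success iff
   the ball's x-coordinate reaches `0.75 * length` (inclusive) in at
   least one Target frame, after normalizing the attacking direction
   to +x.
2. **Pass-possibility graphs.** For every sampled frame and each team, an
   undirected graph on the team's players: candidate edges are the
   Delaunay edges of the player positions (no teammate geometrically
   interposed), and every edge incident to a *marked* player — one with
   an opponent within 0.5 m, inclusive — is removed. Marked players stay
   in the vertex set, so per-player rows remain aligned over time.
3. **Per-vertex network metrics.** Eight metrics per player per frame:
   normalized betweenness, clustering coefficient, eccentricity, h-step
   random-walk entropy, per-vertex global efficiency, local efficiency,
   PageRank, and vulnerability.
4. **Visual rhythms and classification.** Each metric's player-by-time
   matrix over the FETW becomes one image channel (rows = roster
   players, columns = frames, intensity = min–max-normalized value).
   Sixteen channels (8 metrics x 2 teams, attacking block first) stack
   into an `11 x T x 16` tensor classified by a small convolutional
   network.
5. **Attribution.** KernelSHAP-style Shapley estimates, aggregated as
   absolute sums per metric channel over the success class, yield the
   percentage contribution of each metric for each team.

# Graph construction details

Delaunay triangulation is computed by Bowyer–Watson insertion with
symbolic handling of the bounding triangle (its vertices are treated as
points at infinity, so the incircle test for triangles touching them
reduces to orientation tests; this avoids the classical failure where a
huge circumcircle of a near-degenerate sliver swallows a bounding
vertex). Degenerate inputs never fail: fewer than three points give the
complete graph, collinear sets the coordinate-sorted chain, and
coincident points receive a deterministic 1e-6 m jitter keyed by point
index. Graphs must exist for every frame; these conventions make that
true.

Marking suppresses a player's edges at the vertex level — a marked
player can neither give nor receive a pass — rather than only the edges
whose *pair* is jointly marked. The vertex-level reading keeps
"unable to receive the ball" equivalent to isolation and keeps the
per-player metric rows meaningful.

Only teammates enter the triangulation; opponents influence the graph
solely through marking.

# Metric conventions

With sigma(s,t) the number of shortest s–t paths and sigma(s,t|v) those
through v:

* **Betweenness** sums sigma(s,t|v)/sigma(s,t) over *ordered* pairs of
  distinct vertices and divides by (n-1)(n-2), which maps it into
  [0, 1]. Graphs with n < 3 return zeros (the normalization is
  undefined). Unreachable pairs contribute nothing.
* **Eccentricity** is the maximum hop distance to a *reachable* vertex;
  isolated vertices score 0. Restricting to the component keeps the
  metric finite on the disconnected graphs that marking produces.
* **Global efficiency** of v is `sum_j 1/d(v,j) / (n-1)` with
  `1/Inf = 0`.
* **Local efficiency** of v averages, over the neighbours of v, their
  global efficiency computed *within the neighbour-induced subgraph*
  (v excluded). This follows the nested per-vertex form rather than the
  more common Latora–Marchiori average-of-pairs variant; a degree-0
  vertex scores 0 and a singleton neighbour subgraph contributes 0.
* **Vulnerability** is `1 - Eloc(v)/E(v)`, 0 when `E(v) = 0`. It can be
  negative when a neighbourhood is locally more efficient than the
  graph around v.
* **Clustering** is `2 T(v) / (deg(v)(deg(v)-1))`, 0 below degree 2.
* **Walk entropy** is the Shannon entropy (natural log — the base is a
  convention; nats are used throughout) of row v of `P^h`, where
  `P = D^{-1} A` is the simple random walk. `h` defaults to 3: `h = 1`
  degenerates to log-degree and carries no information beyond degree,
  while h around the graph diameter saturates; 3 probes the 2–3 pass
  horizon that short passing sequences span. Isolated vertices score 0.
* **PageRank** iterates `p(i) = (1-q)/n + q sum_{j in nei(i)} p(j)/deg(j)`
  with q = 0.85 from the uniform vector. As written the recurrence does
  not conserve probability mass when isolated vertices are present, so
  the vector is renormalized to sum 1 after every sweep — a documented
  deviation that keeps the output a distribution; convergence is an L1
  change below 1e-10, with an error (not a silent result) at 1000
  iterations.

All eight are verified against independent brute-force oracles (shortest
-path enumeration, igraph BFS distances, triple enumeration, recursive
walk expansion, an independent power iteration) on randomized graphs of
up to 8 vertices.

# Windows, rates, and image geometry

Tracking data is consumed at 30 Hz. The graph-sampling rate for rhythm
images is configurable and defaults to 5 Hz here, giving `T = 25`
columns for a 5 s FETW; per-frame graphs at 30 Hz change slowly (players
move ~25 cm between frames), so the decimation loses little while
cutting compute six-fold. Possessions shorter than
`fetw + target = 10 s` are discarded (with a count) rather than
zero-padded or allowed to overlap; partial windows would make the FETW
and the Target share frames and leak the label.

Channel normalization is per-channel min–max, fitted on the *training*
images of each evaluation round only and then applied unchanged to
validation and test images; values outside the training range clip to
[0, 1] and a degenerate channel (min = max) maps to 0. Row order is
roster order; the attacking team occupies channels 1–8 and the defending
team 9–16, each in the fixed metric order: centrality (betweenness),
clustering, eccentricity, entropy, global efficiency, local efficiency,
PageRank, vulnerability.

# Classifier

Two 3x3 adapter convolutions (16 -> 8 -> 3 channels, ReLU after the
first) reduce the 16 channels to 3; the result is bilinearly resized to
`32 x 32` (the smallest size the backbone contract allows — the rhythm
tensor is only `11 x 25`, so upsampling further adds cost without
information) and fed to a pluggable backbone:

* `efficientnet_b0_topology` (default): stem plus depthwise-separable
  stages with the EfficientNet-B0 stage widths
  (32, 16, 24, 40, 80, 112, 192, 320) and a 1280-channel 1x1 head with
  swish activations and global average pooling — a 1280-dimensional
  feature vector. No pretrained weights ship with the package; the
  backbone is seeded-random and frozen, and training fits the dense head
  only, transfer-learning style.
* `tiny_cnn`: three 3x3 conv/ReLU/max-pool blocks
  (3 -> 8 -> 16 -> 32 channels) trained end to end with the adapter and
  head. This is the desk-scale backbone used by the whole test-suite.

The head is four fully connected ReLU layers (width 32) and a 2-way
softmax decision layer. Balanced accuracy is not differentiable, so the
optimized loss is class-weighted cross-entropy (weights inversely
proportional to class frequency) under Adam, with balanced accuracy on
the validation split used for model selection and early stopping — the
selection criterion, not the loss. Defaults: learning rate 1e-3, batch
size 8, up to 100 epochs, patience 25. Training is deterministic given
the seed. All tensor operations are batched pure-R matrix algebra; the
backward pass is verified against central finite differences.

# Evaluation protocol

BPIs are grouped into 20 half-match groups. Each evaluation round draws
6 test groups; of the remaining 14, 4 are held out as the validation
split and 10 train the model. Hyperparameters come from a small grid
(learning rates 1e-3 and 2e-3 at fixed head width) selected by
validation balanced accuracy; a full k-fold grouped cross-validation
(e.g. k = 7) times the grid would multiply training cost several-fold
for little selection benefit at these sample sizes, so a single grouped
validation split per grid point is used. The min–max normalizer is
refitted inside every round on that round's training groups, so no test
statistics leak through pixel scaling. Reports carry balanced accuracy
and the confusion matrix laid out `[TP, FN; FP, TN]` with success
positive.

The comparison against a coin-flip baseline uses a one-sided exact
Wilcoxon signed-rank test implemented by generating-function enumeration
over sign assignments (average ranks under ties, zeros dropped, p = 1
when all differences vanish); `stats::wilcox.test` silently switches to
a normal approximation under ties, which the exact enumeration avoids,
and the two agree wherever the stats version is exact.

# Attribution

Shapley values are estimated with a kernel-weighted local linear
surrogate. Coalition features are (player-row, channel) groups — 176 for
an 11-row, 16-channel image — not raw pixels: group-level coalitions
keep the constrained weighted least-squares problem exactly solvable and
match the granularity of the question ("which metric of which player
mattered"). The background is the elementwise mean of the training
images. All singleton and all-but-one coalitions are enumerated, the
rest sampled from the Shapley kernel; the efficiency constraint
`base + sum(phi) = f(x)` is eliminated analytically, so local accuracy
holds to solver precision. For a linear model the estimate equals the
closed-form Shapley value, which the tests check. Aggregation mirrors
the two per-team figures: absolute Shapley mass summed over the
success-class samples, players and frames, normalized to 100% within
each team's eight channels.

One property of this aggregation deserves emphasis: the eight metric
channels are deterministic functions of the same per-frame graphs and
therefore strongly correlated. A classifier needs only a sufficient
subset of them, and which subset it relies on varies with the training
seed; Shapley values faithfully report the *model's* reliance, not the
generator's mechanism. On the synthetic data the consequence is
measurable and reproduced by the acceptance checks: the top-ranked
defending channel always falls inside the planted availability cluster
(walk entropy, global efficiency, local efficiency), but which member of
the cluster ranks first is seed-dependent, and no single metric wins a
majority of seeds. Interpreting per-metric Shapley shares on real data
should respect the same caveat: clusters of correlated metrics are
trustworthy units of attribution; fine rankings within a cluster are
not.

# Synthetic data generator

Real tracking data cannot ship with the package, so the generator
produces matches with the statistical structure the pipeline assumes:
two 11-player rosters in 4-4-2 formations, possession alternating
between teams, possession durations uniform on 10–15 s, and players
moving by Ornstein–Uhlenbeck dynamics around formation anchors
(mean-reversion 0.5 /s, diffusion 1 m/sqrt(s), stationary spread about
1 m), clipped to the pitch and to 8 m/s. The ball advances smoothly
towards a per-interval objective and its attacking-zone crossing (or
not) during the Target is enforced by construction, so the pipeline's
own Target-window labeling reproduces the planted outcome exactly.

The planted class signal lives in the defending team's marking
behaviour. The baseline (failure-class) defence man-marks tightly: each
outfield defender stands 0.8 m goal-side of his counterpart, so under
the motion noise opponents continually cross the 0.5 m marking radius
and defenders (and the attackers they shadow) flicker in and out of
isolation in the pass graphs. In success intervals the defence drops
off: every defender retreats `0.2 * effect_size` metres goal-side, the
block dilates mildly, and one midfielder drifts out of his zone —
which takes the defenders out of marking range almost entirely.
Isolation events are the cleanest fingerprint in the walk-entropy
channel (a connected vertex's entropy concentrates near the log of its
degree while an isolated vertex scores exactly zero), so walk entropy is
the generator's nominal marker metric; but the same events also sever
distances for every row, so the per-vertex global and local efficiencies
shift at least as strongly (see the attribution discussion below).
The attacking formation is identical in both classes; attacking-channel
signal arises only through the same marking interactions. With
`effect_size = 0` the classes are exchangeable by construction, which is
what the label-shuffle and null-effect guards exploit.

What the generator does *not* emulate: realistic tactics, set pieces,
player substitutions or identity switches, measurement noise of real
tracking systems, or the metric distributions of real matches. Passing
the planted-signal tests therefore shows the pipeline recovers a known
spacing-driven signal end to end — not that real matches are predictable
at any particular accuracy.

# Problem sizes and numerical choices

The test-suite and the acceptance script run the full protocol at desk
scale, chosen once: 200 generated possessions in 20 groups, graph rate
5 Hz (T = 25), tiny_cnn backbone, 5 evaluation rounds for the planted-
signal check, 10 for the label-shuffle null, 5 seeds x 6 explained
samples for attribution, 1000 random graphs and 500 random point sets
for the oracle-equivalence suites. Oracle tolerances are 1e-6 to 1e-10
(brute-force and implementation arithmetic differ only by accumulation
order); the PageRank oracle runs to 1e-13. Ties in max-pooling resolve
to the first position in scan order; coincident-point jitter is keyed by
point index; all stochastic steps (initialisation, batching, splits,
coalition sampling, the generator) consume explicit seeds and restore
the RNG state afterwards.

# Known limitations

* The marking radius (0.5 m) and the attack-zone fraction (0.75) are
  fixed conventions of the method, not fitted quantities.
* Vertex-level marking suppression is one reading of the construction;
  an edge-level reading (suppress only edges both of whose endpoints
  are within the radius of some opponent) would yield denser graphs.
* The efficientnet-style backbone ships untrained; results with it
  reflect random-feature transfer learning unless the user supplies
  training at scale. The tiny_cnn backbone is the supported desk-scale
  path.
* Players missing longer than 1 s simply drop out of their frames;
  their image rows are zero-filled rather than interpolated.
* The generator's planted effect is a single spacing mechanism; it
  cannot probe metrics that respond only to features it does not vary.
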