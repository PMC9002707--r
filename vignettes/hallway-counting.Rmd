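---
title: "Counting hallway traffic by tracking: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting hallway traffic by tracking: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigcount)
```

This vignette is the package's own account of the science it implements:
the motion and association model behind the tracker, the counting state
machine, the filter-clustering pruning rule, what the synthetic scenes do
and do not emulate, and the numerical conventions chosen where the design
was genuinely open.

## The tracking model

The tracker follows the tracking-by-detection paradigm: an external
detector supplies per-frame bounding boxes, and the tracker's only job is
to stitch them into identities. Its state model is the standard
constant-velocity Kalman filter over
$(c_x, c_y, a, h, \dot c_x, \dot c_y, \dot a, \dot h)$, where $(c_x, c_y)$
is the box center, $a = w/h$ the aspect ratio, and $h$ the height; the
measurement is $(c_x, c_y, a, h)$. The time step is one frame — the
camera streams at a fixed rate and no frame-drop compensation is
attempted.

Noise scales are tied to the object height, the convention of reference
implementations of this filter family: per-step position/size standard
deviation $h/20$, velocity $h/160$, with fixed small constants ($10^{-2}$,
$10^{-5}$, and $10^{-1}$ in the measurement model) for the dimensionless
aspect terms. Track initiation inflates these (2× position, 10× velocity)
because velocity is unobserved at birth. These constants are inherited
tracker folklore, not estimates from data; the covariance tests
(symmetry and positive semi-definiteness over 1000 predict/update cycles)
guard their numerical behaviour, not their calibration.

Association runs as an age cascade. Confirmed tracks are offered the
frame's detections tier by tier, most recently updated first, so a track
seen last frame always outranks one coasting for five frames — this is
what keeps identities stable through brief occlusions without letting
stale tracks steal detections. Within a tier the cost is the cosine
distance between the detection's appearance feature and the track's
feature gallery (minimum over the gallery, up to 100 stored features),
with pairs whose squared Mahalanobis distance exceeds the
$\chi^2$ 0.95 quantile at 4 degrees of freedom (`chi2_gate()`, about
9.4877) forced infeasible, and matches above a cosine distance of 0.9
rejected. Unconfirmed tracks and confirmed tracks that missed exactly one
frame get a final IOU-distance stage gated at 0.7. Assignment inside each
stage is minimum-cost Hungarian; among equal-cost optima the solver
returns the lexicographically smallest assignment by (row, column), a
deliberate tie-break that makes runs byte-reproducible. No installed R
package provides min-cost linear assignment, so the solver (a shortest
augmenting path formulation) is implemented here and checked against
exhaustive permutation search in the tests.

The appearance descriptor is the package's deliberately minimal stand-in
for a learned embedding: crop, bilinear-resize to 10×10, flatten to a
100-vector. Two choices here were open and are worth recording. First,
the vector is scaled to unit Euclidean norm (an all-black crop stays
zero); raw intensities would make the cosine distance depend on scene
gain, and normalization makes it bounded and gain-invariant. Second, when
no pixels are available at all (detections from a file without frames),
every detection receives the same constant unit vector (`flat_feature()`),
which makes all appearance distances zero and degrades the cascade
gracefully to motion gating plus assignment order — the right behaviour
for visually near-identical animals, and a tested invariant: on scenes
whose objects never gate-overlap, real and flat features produce identical
tracks.

Track lifecycle: a new track is tentative, confirmed after `init_hits = 3`
consecutive matched frames, and deleted either on its first miss (while
tentative) or after more than `max_age = 20` consecutive misses (while
confirmed). The boundary is strict: a confirmed track unseen for exactly
20 frames survives; the 21st miss deletes it. Track ids count up from 1
and are never reused.

## The counting state machine

A vertical line — by default the hallway center — splits the view into an
entrance zone (status 0, by default the right half) and an exit zone
(status 1). Each track records `start_status`, the zone of its first
detection, written once and never rewritten, and `end_status`, refreshed
from the box center at every successful update (never from coasted
predictions: the status is a property of evidence, not extrapolation).
The signed counting result is recomputed every frame as

$$ CR = \sum_{\text{ended tracks}} c + \sum_{\text{live pig tracks}} c,
\qquad c(0,1) = +1,\; c(1,0) = -1,\; c(s,s) = 0. $$

Recomputation from statuses — rather than accumulating increments at
crossing moments — is a deliberate semantic choice. It makes the count of
a track that wanders back and forth across the line depend only on its
endpoints, so a pig that crosses and returns nets zero regardless of how
many times it dithered on the line; it also makes the total robust to
identity fragmentation, because contributions telescope across track
breaks (a broken track's end status is the next track's start status,
provided no crossing happened while untracked). An event-accumulation
reading would double-count a forward–back–forward excursion; the
recomputation semantics gives +1, which matches the worked net-count
arithmetic (10 crossers, 2 returners, net 8) that the pipeline reproduces
end to end.

Boundary conventions: a center exactly on the line keeps its previous
status (avoiding chatter from sub-pixel jitter), and a track born exactly
on the line takes the entrance status. All pig tracks contribute,
tentative ones included — a one-frame spurious track necessarily has
`start == end` and contributes 0, so no confirmation filter is needed.
Person-class detections are excluded from counting entirely; a
`track_persons` flag exists for visualization and evaluation only.
Mirroring the entrance side negates `CR` on any scene, a tested property.

## Filter-clustering pruning

The pruning module compresses 3×3 convolution layers by clustering
filters that respond to the same coarse spatial structure. The pattern
bank is all $2^9 - 1 = 511$ nonzero binary 3×3 patterns, enumerated in
ascending 9-bit integer order (bit $j$, least significant first, is cell
$j$ row-major). A filter's response to a pattern is the inner product of
its channel-summed 3×3 kernel with the pattern; each filter joins the
cluster of its maximum-response pattern and each non-empty cluster keeps
its best-scoring filter.

Three conventions were open and are fixed as follows. Multi-channel
filters are reduced by summing across input channels before scoring —
the cheapest reduction that preserves linearity (doubling the weights
doubles every score, a tested invariant). Filters are not normalized
before scoring; a config-free raw-max rule keeps the representative
choice scale-covariant. Ties go to the lowest pattern index and lowest
filter index; since any superset of a pattern's support has a strictly
larger integer code, a filter that *is* a scaled pattern is assigned to
exactly that pattern, which the tests exploit to build duplicate-free
fixtures.

Channel bookkeeping is where the real complexity lives. When a layer
loses filters, every consumer drops the corresponding input channels.
Concatenating routes offset the surviving indices; channel-splitting
routes (darknet group routing, which forwards the last
$\lfloor C/2 \rfloor$ channels of a source — the floor convention is
forced by the odd 45 → 22 split in the printed architecture) record an
explicit surviving-channel selection in the pruned graph, so that a
second pruning pass is well-defined and removes nothing (idempotence is
tested, as is forward-pass equivalence of a pruned toy network against a
direct convolution oracle). Pruning never merges duplicate filters'
downstream weights — recovering lost accuracy is the job of fine-tuning,
which is out of scope here along with detector training and inference.

Shape propagation over the 38-layer detector graph uses
$H_\text{out} = \lfloor (H + 2 - k)/s \rfloor + 1$ for padded
convolutions, halving for 2×2/2 maxpools, doubling for upsample, channel
sums for concatenations and the floor rule for splits. Declared shapes
from the printed table are cross-checked and disagreements are reported,
not fatal: exactly two rows of the printed table declare input channel
counts (128 and 256) inconsistent with the computed concatenations (103
and 120), and the propagation flags precisely those. The computed values
are carried forward. The 18 output channels of the two detection heads
are likewise taken as printed, although 3 anchors × (5 + 2 classes)
would give 21; the graph encodes what the table states.

## Synthetic scenes and what they do (not) show

The generator scripts rectangular actors with per-actor constant speed,
entry frame, entry side, optional velocity reversals, and a lane; frames
(when rendered) are a fixed textured background with each actor drawn at
a distinct intensity. Detections are the true boxes with independent
dropout and truncated Gaussian jitter. Everything derives from one seed.
Default geometry: a 320×240 view, 36×24 boxes, speeds of 4–9 px/frame,
the counting line at mid-width — proportions comparable to a downscaled
hallway camera view with adult pigs crossing in a few seconds.

The ground-truth signed count is computed by an independent sweep over
each actor's center trajectory using the same on-line-keeps-status rule
as the counter. The headline property test runs 200 randomized noise-free
scenarios (1–4 actors, reversals, occasional persons) and requires the
pipeline `CR` to equal that oracle exactly; a robustness suite requires
single-crosser scenes to stay correct over 50 seeds at 15% detection
dropout. Test problem sizes (70–160 frames, up to 30 actors in the dense
preset) were chosen to exercise every code path while keeping the default
suite around a minute of compute.

What passing these tests does *not* show: real hallway video has
perspective distortion, pigs are deformable and overlap heavily when
bunched, detector errors are correlated in time rather than independent,
and a pig riding over another can suppress detections of those beneath —
the known failure mode of this class of counter, which the generator
deliberately does not simulate. The synthetic scenes validate the
*logic* of tracking and counting, not detector quality.

## Parameters at a glance

| Parameter | Default | Unit | Role |
|---|---|---|---|
| `init_hits` | 3 | frames | consecutive matches before confirmation |
| `max_age` | 20 | frames | allowed misses before a confirmed track dies |
| `max_distance` | 0.9 | cosine distance | appearance acceptance threshold |
| IOU gate | 0.7 | IOU distance | final-stage acceptance threshold |
| Mahalanobis gate | 9.4877 | squared distance | $\chi^2_{4}$ 0.95 quantile |
| `gallery_size` | 100 | features | per-track appearance memory |
| `line_x` | width/2 | px | counting-line position |
| `entrance_side` | right | — | which half is the entrance zone |
| MOT IOU threshold | 0.5 | IOU | CLEAR-MOT correspondence cutoff |

## Known limitations

- No re-identification: a pig that leaves the field of view and returns is
  a new track (the counting semantics absorb this as long as no crossing
  happens while untracked).
- The Kalman noise constants are conventions, not calibrated values.
- The CLEAR-MOT scorer implements MOTA and identity switches only (no
  MOTP/IDF1/HOTA), matching what the pipeline's evaluation needs.
- Counting supports a single vertical line with two orientations; oblique
  or polyline gates are out of scope.
- Timing/throughput claims are hardware-bound and outside what this
  package measures.
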