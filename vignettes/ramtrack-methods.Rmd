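---
title: "Tracking and scoring rats in radial arm maze video: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking and scoring rats in radial arm maze video: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

An eight-arm radial maze (RAM) test quantifies a rodent's spatial memory:
food is placed at the distal ends of a subset of "baited" arms and the
animal's visits are scored. A re-entry into an arm already visited in the
same session is a working-memory (short-term) error; the first entry into
an arm that was never baited is a reference-memory (long-term) error. The
session ends when every baited arm has been emptied, and the elapsed time
is the latency. Trajectory-level quantities — path length, average speed,
time shares per maze region, the number and duration of "S spots" where
the animal stays still — complete the picture.

Scoring these by hand is slow, so the maze is filmed from above with an
infrared night-vision camera in a dark room. Under IR the rat's body is
the bright object on a dark background, which permits a deliberately
simple per-frame localization scheme — fixed-threshold binarization plus
binary morphology — instead of background subtraction, adaptive
thresholding or a learned detector. Two practical noise sources drive the
design: rat droppings, which appear as small persistent bright spots, and
an experimenter stepping over an arm, which appears as a large bright
shape entering from the image edge.

`ramtrack` implements that pipeline end to end: maze geometry, the image
primitives, per-frame localization, the arm-entry state machine, the
trajectory metrics — plus a ground-truthed synthetic IR scene generator so
the whole chain can be exercised and evaluated without any recordings.

## Maze geometry and the 89-piece partition

The maze model is a circular central platform with `n` rectangular arms
(default 8, one every 45°), each 70 cm long and 10 cm wide. All geometry
lives in pixel space: x = column, y = row, 0-based, origin at the
top-left pixel, with a single `cm_per_px` scale. The default working
image is the 480 x 480 subimage containing the maze.

For occupancy statistics every arm is divided into 10 equal segments of
exactly 70 cm² (7 cm x 10 cm), and the platform into 9 pieces of
approximately 70 cm², giving `10 n + 9` zones — 89 for the default maze.
Two derived choices deserve justification:

* **Platform radius.** No platform diameter is part of the published maze
  dimensions, but requiring nine platform pieces of ≈70 cm² fixes the
  platform area at ≈630 cm², i.e. a radius of `sqrt(630 / pi)` ≈ 14.16 cm.
  That is the default, and with `cm_per_px = 0.36` the full
  2·(70 + 14.16) cm footprint fits the 480-pixel subimage with margin.
* **Platform partition.** The pieces are formed by a 3 x 3 grid clipped
  to the platform disc. Grid lines at the naive cell thirds (±r/3) give a
  center piece 27% above and corner pieces 30% below the 70 cm² target.
  Instead the grid lines sit at ±0.279 r, the (numerically) minimax
  choice for the relative area deviation: all nine disc pieces then fall
  within about ±13% of 70 cm². This is a deterministic, shape-simple
  partition; any other equal-area construction would serve equally well.

The footprint mask is the *filled* platform-plus-arms region (it is used
as an intersection operand, which requires an areal region, not a 1-px
outline). Zone classification is analytic — disc test for the platform,
arm-frame coordinates for the arms — and the zone raster is its
evaluation at pixel centers, so the zones are pairwise disjoint and tile
the mask exactly by construction. Each arm's *entry line* is the segment
across its proximal end at the platform rim; the same segment serves the
entry and the exit test.

## Image primitives

Frames are converted to gray as `0.299 R + 0.589 G + 0.114 B` — the
printed green coefficient (0.589, not the broadcast-standard 0.587) is
kept as printed, so the weights sum to 1.002 and a uniform white pixel
maps to 255.51. The gray value is kept unrounded and thresholded
strictly: a pixel is foreground iff `gray > 127`. (Rounding before
thresholding could flip pixels that land exactly between 127 and 128;
binarizing the unrounded value avoids that edge entirely.)

Erosion and dilation are implemented from their set definitions with the
*reflected* structuring element B̂:

* erosion: `{ z : (B̂)z ⊆ A }`
* dilation: `{ z : (B̂)z ∩ A ≠ ∅ }`

For the default element — a 5 x 5 all-ones square with centered anchor —
the reflection is immaterial, but the implementation honors it for
asymmetric elements, and with these two forms the duality
`dilate(A, B) = ¬ erode(¬A, B)` holds with the *same* element. Pixels
outside the image are treated as background for both operations; this
keeps opening anti-extensive at the borders (at the price of breaking
the duality identity within one element radius of the frame edge, which
the tests account for). Opening is erosion followed by dilation with the
same element; it removes every isolated bright component too small to
contain a translate of the element — precisely the dropping-sized spots —
while restoring the extent of the survivors.

Connected components are 8-connected (robust to diagonal pixel chains in
thresholded blobs); each component carries its pixel count and real-valued
centroid, ordered by descending area with ties broken by the topmost-
leftmost pixel.

## Per-frame localization

Each frame is cropped, grayed, binarized, and duplicated:

1. copy 1 is intersected with the maze mask, then opened ("Image 1″");
2. copy 2 is opened directly ("Image 2′");
3. the two results are intersected, giving the candidate image.

Candidate components must have area ≥ `min_component_area` (default 25 px,
the area of the 5 x 5 element — the smallest shape that can survive the
opening) and centroid inside the mask. One candidate is the rat; among
several, the largest wins, because after masking and opening the residual
noise is smaller than the rat's body (≈350 px at the default scale). If
the intersection yields nothing the masked-and-opened image alone is
consulted, and failing that the previous position is carried forward,
flagged as such.

Two remarks on this composition. First, because opening is increasing and
`A ∩ M ⊆ A`, the intersection of steps 1–3 mathematically equals Image 1″
alone; the pipeline computes it anyway to mirror the described dual-image
procedure, and the fallback branch is consequently unreachable. Second,
the largest-in-maze rule is what tolerates an intruder: a bright shape
entering from outside loses everything beyond the footprint to the mask,
and its in-maze trace — in the conditions this scheme is designed for — is
smaller than the rat. A shape that covered most of an arm would defeat
the rule; that failure mode is outside the method's stated operating
conditions and is discussed under Limitations.

Positions are logged every `sample_period` seconds (default 0.05 s),
taking the nearest frame at or before each tick; the logging period and
the camera frame rate are deliberately independent.

## The arm-entry state machine

Scoring walks the trajectory once, holding the current arm (`maze_state`,
0 = platform), per-arm food flags, per-arm entry counters, the two error
counters and the clocks.

* **Entry** fires when the state is 0 and the center is on the arm side
  of an arm's entry line — within `entry_distance_px` of the line
  (default: half the arm width) *or* anywhere inside the arm. The second
  clause matters at coarse sampling: a fast crossing may simply never
  produce a sample inside the threshold band.
* **Exit** is the symmetric test toward the platform. A sample inside a
  *different* arm (possible only across a sampling gap) closes the
  current visit and opens the new one.
* **Scoring at entry:** if the arm's entry counter is already positive,
  one short-term error; otherwise, if the arm was never baited, one
  long-term error. The counter then increments. An aborted visit — line
  crossed, immediate retreat — counts as an entry once the center is on
  the arm side, and a re-entry into an emptied baited arm counts as a
  short-term error.
* **Food** is inferred from position alone (no sensor exists): while
  inside baited arm k, the first sample in the distal segment clears that
  arm's flag. When the last flag clears, the session is complete, the end
  time is recorded and the state freezes.

Entry counting follows the standard RAM convention — every completed
entry event increments the counter, whether or not food was taken — since
re-entry scoring everywhere relies on the counter reflecting visits, not
rewards. Errors are scored at entry rather than exit time; the counts are
identical, and entry-time scoring keeps aborted-visit semantics explicit.

## Trajectory metrics

* **Path length** is the sum of consecutive-sample distances, in meters.
  Carried-forward samples repeat the last fix and so add no displacement.
* **Average speed** is path length over elapsed time (cm/s).
* **Region time fractions** use the *total* session sample count as the
  denominator (so platform + baited + non-baited ≤ 100%; out-of-footprint
  samples — possible only for a mistracked fix — count in none).
* **S spots** formalize "staying still within a specified range" as a
  greedy anchored scan: a spot opens at sample i if every sample within
  the next `min_duration_s` stays within `radius_cm` of the position at
  i, extends while samples remain within that radius of the anchor, and
  the scan resumes after it ends. Spots are therefore non-overlapping and
  deterministic. Note that a spot's duration covers every moment the
  animal is within the radius of the anchor — including a slow approach
  to and departure from a resting place — so it slightly exceeds the
  motionless time itself. The radius (2.5 cm ≈ a quarter body length) and minimum
  duration (2 s) are unpublished constants of the original system,
  exposed as parameters.
* **Zone histogram** counts samples per zone — the "rainfall" dot
  statistics; the dots are the logged samples themselves.
* The session report truncates the trajectory at the completion time
  before computing trajectory metrics, so post-completion frames do not
  dilute the session quantities.

## The synthetic scene generator

The generator renders 8-bit gray frames of: a dark background (gray 30);
a bright rat — a filled ellipse, default 30 x 15 px (~11 x 5 cm) at gray
200, oriented along its direction of motion and driven at constant speed
(default 12 cm/s, a typical healthy-rat pace) along scripted waypoints
with dwell times; persistent droppings (default 10 squares of 2–8 px at
gray 180, deposited along the rat's path over the first 60% of the
session, kept ≥15 px apart so separate droppings never pile into a
rat-sized blob); bright static clutter outside the footprint; and
optionally an intruder. Waypoints — and every interpolated position —
must stay inside the footprint: rats do not leave the maze, and the
generator refuses scripts that cut corners across the void between arms.

The dropping size range deliberately straddles the structuring element:
2–4 px spots vanish under the 5 x 5 opening, 5–8 px spots survive it and
exercise the largest-area rule.

The intruder models an experimenter's leg crossing over an arm: a bright
40-px-wide rectangle entering from the image edge whose tip steps a few
pixels (default 6) onto the edge of one arm, present for a contiguous
block of frames (22% of the session in the standard Case-2 scene). It is
placed over the arm's distal half, from where its path to the image edge
crosses no other arm — so its only in-maze trace is the small tip patch.
The standard Case-2 scene baits the diagonal arms and targets the first
axis-aligned non-baited arm: on an axis-aligned arm the tip patch
survives the opening as a genuine ≈240 px competing candidate below the
rat's area — exactly the regime the largest-in-maze rule is designed to
reject. (On a 45° arm the 6-px-deep patch cannot contain the 5 × 5
element and is simply erased, which would leave nothing to reject.) A
half-plane "occluder" variant is available for harsher experiments; it
defeats the largest-area rule by construction and is excluded from the
accuracy claims.

Ground truth carries the per-frame true center, body axes and heading, so
detection can be scored as "reported center inside the true body
ellipse". The scripted event log (entries, exits, food-zone arrivals,
pauses) is derived from region transitions of the true path —
independently of the scoring state machine — and the two are required to
agree in the tests.

What the generator does *not* emulate: fur texture and body articulation
(the rat is a rigid ellipse), shadows and illumination gradients, motion
blur, camera noise above the threshold, partial occlusion of the rat by
the intruder, and sensor-level artifacts. Passing the synthetic suites
therefore demonstrates the algorithm's logic — noise-spot removal, mask
discipline, candidate selection, scoring — not its performance on any
particular camera.

## Problem sizes and numerical choices

The standard evaluation scenes are 5-minute sessions at 10 fps — 3000
frames of 480 x 480 pixels — with the logging period set to one frame so
the detection rate is scored once per frame; the determinism check uses a
2-minute scene. Morphology oracle comparisons run on 200 random images up to
32 x 32 against direct evaluation of the set definitions at every
translation. Timestamp-to-frame mapping uses a 1e-9 s guard against
floating-point tick drift; trajectory CSVs serialize coordinates with 17
significant digits so a written trajectory reads back bit-identical.

## Limitations

* A single fixed threshold presumes IR imaging in darkness; daylight or
  uneven illumination would need the adaptive methods this scheme
  deliberately avoids.
* One animal only; two rats merge into one component.
* An intruder (or any bright in-maze object) larger than the rat's body
  after masking and opening captures the largest-area rule for the frames
  involved.
* A rat pressed against the arm end is clipped by the mask; with the
  default scale the body stays ≥2 px inside, but tighter geometries could
  shave its area.
* The entry/exit rule is evaluated per sample; at very low sample rates
  (≳ arm length per sample) visits can be missed outright.
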