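---
title: "Relational measures, joints and attribution: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relational measures, joints and attribution: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewmnr)
```

# The model

`ewmnr` treats each animal as a planar longitudinal axis: an ordered
polyline through its tracked midline keypoints, anterior to posterior. All
inter-animal measures are functions of the two axes and nothing else — body
width, limbs and vertical posture are outside the model, because planar
multi-animal pose tracking observes none of them reliably. Three simplified
horizontal-plane EWMN measures describe the dyad per frame:

**Partnerwise orientation.** Headings are measured in degrees clockwise
from the arena's reference direction (+y, "up the page"), from the
posterior-most to the anterior-most midline point by default. The relative
heading of partner versus focal is discretized on a ring of `n_sectors`
(8 or 16) half-open bins *centred* on the sector directions, so the
anti-parallel configuration (relative heading 180°) sits in the middle of
sector 4 and a partner pointing at the focal animal's right side is sector
2. Centred bins mean small heading noise never flips a configuration that
is exactly on a canonical sector.

**Opposition.** The closest pair of points between the two axes is found by
exact segment-to-segment minimisation (for non-crossing segments the
minimum is attained at a segment endpoint, so four point-segment
projections plus a crossing test are exhaustive). Each animal's body
surface is then coded at that pair: arc position along the axis plus the
side given by the sign of the 2-D cross product of the local facing
direction with the offset vector — code 2 right, 6 left, with the region
letter from `region_bounds`. The front (0) and rear (4) tips require both
an arc position within `tip_fraction` of the end *and* the opposing point
lying inside a 45° cone around the axis extension: a point alongside the
head is a side-of-head opposition, not a frontal one. The boundary between
"front" and "side of head" is not anatomically observable from midline
keypoints, so the cone angle matches the sector half-width.

**Relative distance.** The closest-pair gap divided by a reference body
length — the median per-frame midline arc length, robust to flexion. By
default the focal animal's own length is the unit (configurable to the
partner's or the pair mean); distances are therefore comparable across
videos with no metric calibration.

Per animal, the notated-score rows are **Front** (the heading's sector,
allocentric) and **Weight** (the sector of the frame-to-frame centroid
displacement measured clockwise from the animal's own heading, egocentric):
a step to the animal's own left is `S[6]`, an oblique left-rear step
`S[5]`. Weight is suppressed below `step_floor` so tracking jitter does not
masquerade as locomotion.

All measures are invariant under global translation, rotation and uniform
scaling (headings are equivariant, their differences invariant), and
mirror-flipping the arena swaps codes 2 and 6 — these are tested
properties, not aspirations.

# Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `n_sectors` | 8 | sectors | angular grain (45°; 16 gives 22.5°) |
| `tip_fraction` | 0.05 | arc fraction | extent of the 0/4 tips |
| `region_bounds` | H .25, S .5, T 1 | arc fraction | region letters on side codes |
| `step_floor` | 0.02 | body lengths/frame | minimum step for a Weight code |
| `contact_tau`, `tau_contact` | 0.10 | body lengths | contact threshold |
| `min_duration` | 5 | frames | shortest reportable joint |
| `motion_floor` | 0.02 | BL + sector widths, per frame | static-vs-dynamic floor |
| `window` | 3 (attribution), ~2× reaction lag (maintenance) | frames | counterfactual look-back |
| `tau` | 0.25 | fraction | necessity threshold for "mutual" |
| `n_min`, `merge_gap` | 3, 2 | frames | contact event length / merge rules |

The region fractions are a convention, not a species fact: where a head
ends and a shoulder begins must be set per species. `tau` likewise has no
principled value; it is exposed, logged into outputs, and reported
alongside the necessity fractions it thresholds. Combined motion is always
measured in commensurable units — step length in body lengths plus heading
change in sector widths — so one floor value works across both channels.

# Joints, compensation and attribution

A **joint** is a maximal run (≥ `min_duration` frames) of a constant
discretized code — partnerwise sector, opposition pair, or their tuple.
Undefined frames break runs. An optional mode filter (`smooth_k`) may be
applied before run detection; it is the only place the discretized series
is ever altered. A joint is *dynamic* (an attractor) when the pair's summed
motion averages at least `motion_floor` per frame; two frozen animals in a
stable configuration are a static posture, not an attractor. Whether static
mutual postures should count as joints at all is left to this flag rather
than decided for the user.

The **compensation index** of an interval is `ci = 1 − min(1, R/M)`: `R`
sums the absolute frame-to-frame changes of relative heading (in sector
widths) and relative distance (in body lengths); `M` sums both animals'
per-frame motion in the same units. Exactly mirrored motion gives `ci = 1`
(the relational state never moves); a single mover whose motion appears
relationally in full gives `ci = 0`; the index is undefined for zero-motion
intervals. This index is this package's operationalisation of compensatory
movement — the underlying idea (movements by one animal negated by the
other's) is qualitative, and the specific ratio should be read as a
measurement device with the stated units, not a canonical quantity.

**Attribution** of a code change at frame `t` evaluates two counterfactual
freezes over a `window`-frame look-back: the code with the focal animal
current and the partner frozen, and the mirror. A change is attributed to
the animal whose motion alone reproduces the new code while the other's
freeze retains the old one; to `both` when either animal's motion alone
suffices; and to `ambiguous` otherwise — including whenever the implied
mover's motion over the window is below `motion_floor`, so sub-floor jitter
flips are never attributed. Single-frame counterfactuals are
noise-dominated at typical frame rates, hence the 3-frame default.

**Maintenance classification** applies the same freezes inside a joint: a
frame is "A-necessary" if freezing A while B plays back would change the
code. Both necessity fractions ≥ `tau` ⇒ `mutual`; otherwise the dominant
animal; `static` if neither. Playback counterfactuals have a structural
bias worth understanding: when maintenance is *exact mutual compensation of
the same geometric degree of freedom*, freezing either animal breaks the
code and the verdict is `mutual` — correctly so. A one-sided verdict
requires the maintained code to be robust to the maintainer's own staleness
over the window but not to the evader's; this is the case when the
maintainer tracks a body target with a short reaction lag. The
classification window should therefore be of the order of twice the
expected reaction lag: long enough that freezing the maintainer visibly
breaks the code, short enough that the evader's playback alone does not.

# The simulator and what it emulates

The generator produces rigid-midline dyads: per frame a centroid and a
heading per animal, keypoints laid along the heading, i.i.d. Gaussian noise
(`noise_sd`, as a fraction of body length) added to every keypoint.
Controllers are first-order heading relaxation toward a goal bearing
(`gains`, default 0.3 pursuer / 0.5 blocker); travel speed defaults to
0.05 body lengths/frame (about 1.5 body lengths/s at 30 fps, a brisk
interactive pace); default runs are 500 frames with noise at 0.5 % of body
length, a tracking accuracy good pose estimation reaches on clean video.
These defaults are the package's validation conditions; the seeded-run
tests use 50 replicates.

Scenario design notes:

- `CIRCLE_MAINTAIN` circles both agents on a common ring (chord-exact
  angular step, so the per-frame step equals the configured speed exactly at zero noise)
  with the relative configuration locked, and switches configurations via
  scripted 90° in-place turns by one animal at a time. The baseline
  relative heading is offset 10° from anti-parallel so the two bodies are
  never exactly parallel (exactly parallel overlapping segments make the
  closest pair degenerate). Turns are eased (7.5°, 15°×5, 7.5°) and
  preceded by a 3-frame hold so that discretized sector crossings land
  mid-bin and attribution windows never mix turning with circling — without
  this, crossings sit 2.5° from a bin edge and attribution degrades for a
  scenario-geometry reason rather than an algorithmic one.
- `BILL_TO_HEAD` scripts one-sided maintenance as rotational evasion: the
  defender swings its heading in place (±60°, 80-frame period) while the
  attacker shadows the rear target at a 3-frame reaction lag. A
  translational pure pursuit cannot serve here: its exact compensation
  makes both freezes break the code symmetrically (see above), which is a
  property of playback counterfactuals, not of the detector.
- `FPD_MUTUAL_BLOCK` co-rotates an anti-parallel pair in place (±40°),
  the canonical mutually maintained stand-off.
- `APPROACH_CONTACT` drives the attacker's head onto a scripted target
  segment of a static recipient, dwells (optionally sliding to a second
  segment), and retreats; contact truth comes from the scripted geometry.
- `EVADE_ZIGZAG` and `RANDOM_WALK` supply escaping and null dynamics.

The simulator deliberately does **not** emulate body flexion, occlusion,
identity swaps, heteroscedastic or autocorrelated tracking error, arena
walls, or 3-D postures. Passing tests therefore demonstrate that the
measures, detectors and attributions are correct on planar rigid-body
geometry with white keypoint noise — they do not certify performance on
flexible-bodied animals or on pose-estimation failure modes, for which the
cleaning stage (confidence gating, gap interpolation, median smoothing) and
the `mask_dropouts()` post-step provide the first line of defence.

# Numerical choices

- Angles: degrees, clockwise from +y; wrapped differences in (−180, 180];
  sector binning via `floor(angle/w + 0.5) mod n` so the lower bin edge is
  inclusive and exact ties never hit banker's rounding.
- Video pixel input (y increasing downward) is flipped by `image_coords`
  (on by default for DLC dialects); EWMN side codes are chirality-sensitive
  and silently mirrored data would swap every 2 and 6.
- Nearest-segment ties on a polyline break toward the more anterior
  segment, deterministically.
- Cleaning is off by default (no confidence floor, no interpolation, no
  smoothing): no threshold is assumed where none is knowable, and cleaning
  with neutral parameters is the identity. Interpolation is per-coordinate
  linear and only for interior gaps ≤ `max_gap`; smoothing is a centred
  moving median (robust to tracking flips) that never invents points.
- Tidy track CSVs are written at 17 significant digits and parsed with
  base-R numeric conversion, so a write/read round trip is bit-exact for
  non-missing coordinates (the fast vectorised CSV float parser is off by
  one ulp on some values).
- Frame indices are 0-based with half-open `[start, end)` ranges
  everywhere; degenerate inputs (missing bodyparts, zero-length heading
  vectors, < 2 midline points) mark the frame undefined rather than
  erroring, and undefined frames propagate as flags.
- Validation problem sizes: brute-force geometry oracles run on 1000 random
  polyline pairs (400-point dense sampling) and 200 nearest-point cases
  (10⁴ samples); joint/mover recovery on 50 seeded 500-frame runs; contact
  recovery on 200 scripted events. These sizes give the binomial and
  interval-overlap checks the precision their tolerances assume while
  keeping the suite quick to run.

# Known limitations

- Only dyads are analysed; more animals would need pairwise enumeration
  (the measure definitions extend unchanged, the interfaces currently do
  not).
- Opposition is computed midline-to-midline; for wide-bodied animals the
  true skin-to-skin closest pair can differ near the flanks, biasing gaps
  upward by up to half a body width.
- Attribution and maintenance rest on playback counterfactuals: they
  cannot re-simulate reactive policies, so "what the partner would have
  done" is always "what it actually did, delayed". The mutual-vs-one-sided
  distinction is meaningful exactly to the extent that the window is tuned
  to the interaction's reaction timescale.
- The compensation index compares path lengths, not causal influence; a
  high `ci` says the relational state was conserved while both moved, not
  who conserved it — that question belongs to the maintenance classifier.
- DLC HDF5 files are not readable in this installation; use the CSV
  dialects.
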