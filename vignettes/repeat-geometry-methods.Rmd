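---
title: "Methods: circle-fitted repeat geometry and Tait–Bryan angle decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circle-fitted repeat geometry and Tait–Bryan angle decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RepeatGeometry)
```

## The model

A structured tandem repeat protein is treated as an ordered chain of
units, each reduced to its Cα trace, each summarized by its centroid.
Locally — within a window of a few consecutive units — the centroids are
assumed to lie near a circular arc in a plane. This is the central
modeling assumption: it holds well for solenoids and exactly for closed
rings, and it degrades gracefully to a straight line for rod-like
repeats, which the pipeline detects and handles separately rather than
forcing a circle through them.

Given the fitted circle, the motion from unit i to unit i+1 is described
the way aircraft attitude is: the **yaw** (heading change, measured as
curvature at the circle center), the **roll** about the direction of
travel (reported as twist), and the **pitch** about the radial axis. The
key design point is that yaw is *not* taken from the unit-to-unit
superposition: curvature is measured once, robustly, from the circle
geometry, and the superposition rotation is only trusted for its roll and
pitch components. The yaw that falls out of the decomposition is kept as
a per-row diagnostic (`yaw_diagnostic`); on well-behaved input it is
close to zero because the canonical frames already absorb the heading
change.

### Local frames and canonicalization

Unit i's frame is anchored at its centroid cᵢ: y = (cᵢ − center)/‖·‖,
x = orthogonalized travel (cᵢ₊₁ − cᵢ), z = x × y. Both units of a pair
use the *pair's* travel vector, each orthogonalized against its own
radial axis; this yields the tangent exactly on ideal arcs and remains
defined for the last pair of the region. Units are expressed in their own
frames (p ↦ Fᵀ(p − anchor)) before superposition, so that a pure
heading rotation between units cancels out and the residual rotation
carries only roll and pitch.

### Decomposition conventions

The superposition rotation is factored as R = R_z(yaw)·R_y(pitch)·R_x(roll),
the intrinsic z–y′–x″ Tait–Bryan sequence, with yaw, roll ∈ (−π, π] and
pitch ∈ [−π/2, π/2]. Twist is reported clockwise-positive: the reported
value is `twistSign * roll` with `twistSign = -1` by default, and the
constant is a configuration switch (`geomConfig(twistSign = +1)`) for
users who prefer the raw mathematical sign. Pitch handedness is "up =
positive": when the unit's displacement along the continuity-oriented
window normal is decisive (|d| > `dispTol`, default 0.5 Å), the pitch
sign is reconciled with that displacement. The threshold matters: on
flat (zero-rise) regions the normal displacement is pure noise, and an
unconditional reconciliation would randomize the pitch sign; below the
threshold the decomposition's own sign is kept.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `window` | 6 | units | enough centroids to stabilize the plane/circle fit while staying local; the whole region is used when it has fewer units |
| `linearEvalRatio` | 1e-4 | — | windows whose centroid principal-variance ratio λ₂/λ₁ falls below this are treated as straight |
| `radiusCap` | 1e4 | Å | a fitted radius above this is indistinguishable from a line at protein scale |
| `twistSign` | −1 | — | clockwise-positive twist convention |
| `dispTol` | 0.5 | Å | minimum normal displacement that can override the pitch sign |
| `refineCenter` | FALSE | — | optionally re-fit the circle (center included) to all projected Cα atoms |
| `wrap` | FALSE | — | traverse the closing (last, first) pair of a ring |
| `workers` | 1 | — | batch parallelism; results are defined to be identical to serial |

## Numerical choices

**Initial circle.** The algebraic (Kåsa) least-squares circle: linear,
deterministic, and exact when the points lie exactly on a circle. Its
known bias toward smaller radii on short noisy arcs is acceptable here
because the crown step refines the radius and curvature depends only on
the center direction, not the radius itself.

**Widest crown.** Points are labeled in/out by the initial circle; the
crown is the gap between the innermost wall maximum and outermost wall
minimum. When the walls interleave, the widest empty interval among
sorted radial distances is used, ties broken by the interval whose
midpoint is closest to the initial radius. With no points on one side the
initial circle is kept and the row flagged (`crown_fallback`).

**Center refinement.** The crown refines only the radius; the center from
the centroid fit is kept. Re-estimating the center from all Cα atoms is
exposed as `refineCenter = TRUE`, but on short arcs the full-atom cloud
(a thick annulus sector) pulls the center markedly off-axis — our test
suite demonstrates curvature errors of tens of percent on ideal
solenoids — so the conservative default stands.

**Window centering.** For pair (i, i+1): units i−2 … i+3, clamped at the
region ends and extended toward the interior to keep the window full.
One circle per pair (the pair's own window); no averaging across the two
units' windows.

**Normal continuity.** The PCA normal has an arbitrary sign. The first
(non-linear) window is oriented so that travel agrees with the
counterclockwise tangent (travel · (n × y) > 0); every subsequent window
is flipped if it disagrees with its predecessor. Only the pitch
displacement convention depends on this sign; curvature and the fitted
circle do not.

**Near-linear windows.** Curvature is reported as 0 (flag `linear`,
radius ∞) and the pitch axis is taken from the third principal direction,
which keeps twist well-defined on straight rods. For an exactly straight
rod the second and third principal directions are individually arbitrary
(any orthonormal pair in the normal plane), but twist is invariant to
that choice because it is a rotation about the travel axis.

**Gimbal lock.** |pitch| within 1e-7 of π/2 sets yaw = 0, absorbs the
remainder into roll and flags the row (`gimbal`); the recomposed matrix
still reproduces the input.

**Unequal-length units.** The internal backend trims the longer unit's
termini equally (the odd residue off the C-terminus) to get a 1:1
sequence-order-preserving correspondence before the Kabsch fit. A
TM-align-compatible external backend can replace this behind the same
interface when such an executable is on the PATH; the default path never
requires it.

**Degenerate inputs.** Identical centroids, travel parallel to the radial
axis, units with fewer than 3 Cα after insertion removal, and
unresolvable spans all flag the affected pair row (null angles + reason)
without aborting the region; a region fails only when every row fails.

## The synthetic generator

`generateSolenoid()` is the package's ground-truth oracle. It defines
truth *operationally*, in the same terms the pipeline measures: unit
centroids are placed exactly on a circle of the prescribed radius with an
arc of `yaw0` radians between consecutive units, and each unit's body
accumulates the prescribed per-unit roll and pitch as rotations expressed
in the local tangent/radial/normal frame at its centroid (parameters are
given in the *reported* sign conventions). By construction the rotation
measured between canonicalized consecutive units is exactly
R_y(pitch₀)·R_x(roll₀-as-raw-roll) and the centroid circle is the circle
the pipeline fits, so noiseless recovery is exact to numerical precision
— which is precisely what makes it a useful oracle. A screw construction
whose translation couples to pitch was considered and rejected: with
nonzero pitch its centroids leave every plane circle, and the generator
parameters would then no longer *be* the quantities the method defines.

What the generator emulates: identical units, exact circular centroid
paths, optional isotropic Gaussian coordinate noise (`noiseSd`, seeded,
bit-reproducible), closed rings (`closed = TRUE` forces yaw₀ = 2π/N and
requires pitch₀ = 0), straight rods with optional accumulated twist
(`generateLinearRod()`). What it does not emulate: unit-to-unit
conformational variability, insertions/deletions between units, unit
length variation, non-circular (e.g. superhelical with large rise)
centroid paths, and real backbone chemistry beyond the Cα trace. Passing
the recovery tests therefore shows the measurement machinery is exact on
its own model class and unbiased under coordinate noise; it does not by
itself certify accuracy on irregular natural repeats, where unit
annotation quality dominates.

Validation problem sizes used by the test-suite and acceptance checks —
chosen to exercise every code path at desk scale: 8–12 unit regions of
10-residue ideal α-helix units; a 3 × 3 × 3 grid over
(yaw₀, pitch₀, roll₀) ∈ {0.05, 0.3, 1.0} × {−0.3, 0, 0.3} × {−0.5, 0, 0.5};
noise studies at σ = 0.3 Å over 50 seeds.

## Open design points, resolved

- **Per-pair rows.** Descriptors are emitted per consecutive pair,
  indexed by the left unit (N − 1 rows for N units); region summaries are
  the arithmetic mean and standard deviation of the signed per-pair
  values. Circular statistics are unnecessary at the observed angle
  ranges (far from ±π wraparound) — a documented limitation for exotic
  inputs.
- **Open traversal.** Rings are traversed N→C without the closing pair;
  `wrap = TRUE` adds it for users studying closed topologies.
- **Altlocs** resolve to the highest-occupancy conformer (ties: first
  encountered); **models** default to the first, selectable by number.

## Known limitations

- Curvature is per-window planar curvature; a genuine superhelical axis
  (helix-on-helix) is not modeled, so strongly rising solenoids fold
  their rise partly into pitch rather than into a helix pitch parameter.
- The internal correspondence for unequal-length units is terminal
  trimming, not structure-aware alignment; grossly different unit lengths
  are better served by the external-aligner backend.
- The pitch-sign reconciliation is displacement-based and deliberately
  inert below `dispTol`; perfectly flat regions report the decomposition
  sign, which for near-zero pitch is noise-signed (magnitude remains
  meaningful).
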