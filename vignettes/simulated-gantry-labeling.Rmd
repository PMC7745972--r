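---
title: "Geometric labeling with a simulated gantry camera: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric labeling with a simulated gantry camera}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantgantry)
```

## The problem and the approach

Supervised plant-classification models need labeled images in quantities
that manual annotation cannot supply. A gantry-mounted camera photographing
plants at *measured* floor positions sidesteps annotation entirely: if the
camera's position and orientation and every plant's world position are
known, the plant's location in each photograph is a deterministic function
of geometry, and labels come for free. `plantgantry` simulates such a rig
end to end so that the labeling pipeline — transforms, route planning,
cropping, metadata, segmentation, statistics — can be developed and
validated against exact ground truth.

## The camera model

**Frames.** The world frame is the gantry's fixed coordinate system:
millimetres, origin at the base corner of the travel volume (default
1150 × 840 × 718 mm), z up. The camera frame puts the optical center at the
origin with the optical axis along +x, y left, z up. The image frame is
fractional: (0, 0) top-left, u rightward, v downward, (0.5, 0.5) on the
optical axis.

**Extrinsics.** `world_to_camera()` translates by minus the optical-center
position, then undoes the pan rotation about the vertical axis, then the
tilt rotation about the camera's transverse axis. Pan = 0 points the
optical axis along world +x; tilt is measured from the horizontal,
positive downward. These senses are a deliberate choice — a standard
pan-tilt head over a camera whose reference orientation is "forward along
+x" — made because only the existence of pan/tilt, not their zero points,
is fixed by the rig's construction. The polar angle a metadata consumer
expects is `tilt + 90` ∈ [0°, 180°], and that is what the metadata writer
emits.

**Intrinsics.** The sole projection model is rectilinear:
`u = 0.5 − f·(y/x)/W`, `v = 0.5 − f·(z/x)/H`, with the focal length in
pixels `f = (diag/2)/tan(FOV/2)` derived from the diagonal field of view
(default 98.7°, the camera's no-zoom "linear" mode) and the pixel diagonal
of the 4000 × 3000 sensor. Whether a quoted FOV is diagonal or horizontal
is often ambiguous; we interpret it as diagonal (the convention for action
cameras) and leave it configurable. No lens-distortion model is fitted:
instead, boxes that come within a configurable margin (default 3% of
image width/height) of the border are excluded, since the border zone is
where a physical lens distorts most and where crops are least reliable.

**Bounding boxes.** A plant is replaced by a bounding sphere centred at its
position. From distance *D*, a sphere of radius *R* subtends the half-angle
`asin(R/D)`; its silhouette is the tangent cone about the center direction,
and under rectilinear projection the cone boundary maps to a conic in the
image plane. `project_sphere()` computes the *exact* axis-aligned extremes
of that conic in closed form (per image axis, eliminating one variable via
the tangency condition leaves a quadratic whose roots are the extremes).
This is the tightest axis-aligned box containing the whole projected
sphere. Simpler four-extreme-ray constructions under-cover for oblique
spheres — the projected conic bulges beyond the four sampled rays — which
is why the exact extremes are used. If the conic is unbounded (the cone
grazes the image plane at 90° off-axis), the affected side falls back to
the image border; after clamping to [0, 1], an empty box is reported as
"absent" rather than an error, since a plant that is merely out of frame
is not an exceptional condition.

**Inverse.** For objects on a known horizontal plane (plants stand on the
floor, z = 0), the projection inverts: `image_to_ground()` intersects the
pixel ray with the plane, recovering world positions from a single image.
Round-trip error is at floating-point level (≈ 10⁻¹³ mm over the travel
volume; the test suite requires < 10⁻⁶ mm).

## Route planning and timing

**Axis speed.** One controller pulse advances an axis by
`d · s · r · m` mm — distance per actuator revolution *d* = 105 mm, step
fraction *s* = 1.8°/360°, gearbox reduction *r* = 0.2, stepping-mode factor
*m* (1 full, 0.5 half) — i.e. 0.105 mm/pulse at full step, giving
`v = p_r · 0.105 · m` mm/s at pulse rate `p_r` (420 mm/s at the 4000 pulses/s
controller maximum; 157.5 mm/s at the production setting of 3000 pulses/s,
half-stepping).

**Leg times.** Moves ramp linearly at `a` pulses/s² to the peak rate and
back: a move of *D* pulses takes `D/p_r + p_r/a` when the peak is reached
(`D ≥ p_r²/a`), else the triangular `2·sqrt(D/a)`. The two regimes meet
continuously at the boundary. The three axes move sequentially by default
(the production configuration); a `parallel_axes` flag switches the leg
time from the sum to the maximum. Pan/tilt motion runs concurrently with
the axis moves and is faster, so it is neglected in scheduling.

**Routing.** Visiting thousands of poses in optimal order is a 3-D
travelling-salesman problem; the rig instead uses a nested zig-zag: the
volume is cut into slabs along x and columns along y, slabs are visited in
+x order, columns serpentine in y (direction alternating per slab), and
within each column poses are visited in z order, the sweep direction
alternating between consecutive non-empty columns, starting upward from
the bottom near corner. Two rules are under-determined by that prose and
fixed here deterministically: ties in z break by (y, x) ascending, and the
z-sweep direction carries across slab boundaries (the first column of a
new slab continues the alternation rather than resetting). Slab and column
widths default to a quarter of the volume extent per axis.

**Production rates.** A run producing `N_m` master images in imaging time
`t_p` with bulk-download time `t_d` and cropping time `t_c` for `N_s`
subimages has average costs `t_m = (t_p + t_d)/N_m` and
`t_s = (t_p + t_d + t_c)/N_s`. At the reference settings (t_p = 3 h 25 min,
t_d = 46 min, t_c = 34 min, N_m = 2149, N_s = 3494) these evaluate to
7.01 and 4.89 s/image. Inside the simulation, `t_p` comes from the
scheduled route; `t_d` and `t_c` are simulated at per-image constants
defaulting to the reference runs' ratios (≈ 1.28 s per master download,
≈ 0.58 s per crop), so the accounting exercises the same arithmetic on
self-consistent inputs.

## The synthetic scenes

The generator emulates the rig's study conditions: up to 12 marked floor
positions in the travel volume — 4 on the edge (imageable from half a
cylinder of poses) and 8 in the interior (full circles) — with plants
drawn from a table of eight weed species (three grasses, five dicots).
Plants are rendered as seeded 2.5-D sprites: flat lobed rosettes on the
floor plane, with 4–9 leaves, per-plant rotation, lobe sharpness, and a
greenish base color, all deterministic functions of the scene seed. The
sprite's maximal extent is strictly inside its bounding sphere (95% of
radius × an extent fraction ≤ 0.95), so box containment is guaranteed by
construction *if and only if the projection code is right* — which is
exactly what makes the renderer a useful oracle. The default bounding
sphere is 100 mm: generous for a seedling, and small relative to the
≥ 240 mm marked-position spacing, matching a rig operated with plants well
separated. A `tight_packing` mode instead clusters plants at 1.4 sphere
radii so that boxes overlap, for exercising the overlap-reporting path.

Rendering is by inverse projection: each pixel ray is intersected with the
floor plane and tested against every sprite's footprint; ties go to the
nearest plant center, so per-plant masks are disjoint and their union is
exactly the non-background pixel set. Everything else — including the
floor, which the keying fabric covers on the physical rig — is the uniform
keying blue (default RGB 0.05/0.22/0.80, chosen to sit clearly low on the
CIELAB b axis). A background-only render is pixel-identical with the
plants removed, which makes background subtraction exact on lossless
rasters.

What the sprites do *not* model: botanical realism, self-occlusion in 3-D,
leaves extending above the floor plane, shadows, lighting variation, or
JPEG noise. Passing tests therefore demonstrate the correctness of the
*geometry and labeling pipeline*, not segmentation robustness on real
foliage; on real images the b-channel threshold interacts with soil color,
shadows, and compression artifacts that the simulation deliberately omits.

## Labeling and metadata

Crops use the half-open pixel rule `[floor(min·dim), ceil(max·dim))` per
axis, so crops never lose covered pixels to rounding and differ in size
from box to box. Each master image gets a v1.5 JSON metadata record:
identity (`yyyymmddhhmmss-pose#.jpg`), capture date/time, room/institute/
camera/lens strings from configuration, the camera pose (x, y, z, polar
and azimuthal angles), and one entry per labeled box (plant id, label,
scientific name, position id, subimage file name, planting date, and the
box fractions). Records are schema-validated on both write and read.

The box-coordinate convention deserves a note: the production datasets'
documented convention puts (0, 0) at the image's upper *right* corner —
despite a claimed equivalence to a popular vision library whose actual
convention is upper-left. Rather than guessing which one any given
consumer expects, the writer emits the literal upper-right convention by
default, a flag switches to upper-left, and every record *declares* its
convention in a `box_origin` field that the reader honors. Timestamps come
from a clock abstraction seeded by the configured start time and advanced
by the scheduled capture intervals, so runs are byte-stable for a fixed
configuration and seed.

Subimages are filed into `interior/` and `edge/` subfolders by position
class; filing is idempotent, and a run validator checks that the manifest
exists, every record validates, and every subimage file on disk is
referenced by exactly one record.

## Segmentation

The CIELAB b axis (blue–yellow opponent channel) is the natural separator
for plant-on-blue images: the fabric sits far down the blue end, plant
matter well above it. `b_channel()` converts sRGB (D65) to Lab and rescales
b by +128 into 0–255 levels, so neutral gray is 128. The threshold is not
fixed anywhere authoritative, so the default is Otsu's method on the
channel histogram — robust across sprite palettes — with a numeric
override for the fixed-threshold workflow. Cleanup defaults to dilate(3) →
fill holes → erode(3) → Gaussian blur(σ = 1) + re-binarize at 0.5, all
configurable and applied strictly in the given order. Morphology, blur,
hole filling, Otsu, and raster I/O are delegated to `EBImage`; the
colorimetry to `grDevices::convertColor` (the test suite cross-checks it
against an independently hand-written sRGB→XYZ→Lab conversion).
Background subtraction marks pixels whose maximal per-channel difference
from the plant-free capture exceeds a tolerance (0 is exact on lossless
rasters; ±2 levels is a sensible floor for JPEG inputs).

## Statistics

`accuracy_percent()` and `binomial_se_percent()` return `100·k/n` and
`100·sqrt(p(1−p)/n)` rounded half-up at the printed precision (the raw
values are one `round()` away; half-up matches how evaluation tables are
typically typeset). The binomial standard error is adopted because it
reproduces every printed table value we recompute. `clopper_pearson()` is
the exact interval via beta quantiles, with the conventional closed ends
(lower = 0 at k = 0, upper = 1 at k = n). `class_weights()` returns
`total/count` per class, so the weighted class masses are equal exactly.
`dataset_summary()` tallies subimage labels across a directory of records,
reporting and skipping unreadable files rather than aborting a summary
over thousands of records.

## Numerical choices and degenerate inputs

- `project_sphere` errors when the camera is inside the sphere (D ≤ R) or
  the center is behind the camera (x_f ≤ 0); a zero-radius sphere gives a
  zero-area box at the projected center.
- `image_to_ground` errors when the pixel ray is parallel to or points
  away from the ground plane.
- The conic-extreme quadratic is recovered by evaluating the (provably
  quadratic) substituted polynomial at −1, 0, 1 — no symbolic expansion to
  get wrong — and a non-negative leading coefficient (non-elliptical
  conic) falls back to the full image extent before clamping.
- `leg_time` is continuous at the trapezoid/triangle boundary
  `D = p_r²/a` by construction; tests verify it to 10⁻⁹ s.
- Crop requests that round to zero area raise an error rather than
  returning an empty raster.
- Scene generation saves and restores the global RNG state, so seeded
  scenes do not perturb a caller's random stream.

## Problem sizes used in the checks

The test suite renders at 400 × 300 and the end-to-end labeling check at
800 × 600 over 50 seeded scenes — small enough to run in seconds, large
enough that one pixel is ≈ 0.1% of image width, well inside every
tolerance asserted. The acceptance script measures round trips on 1000
ground-plane points, sphere containment on 100 spheres × 10⁴ surface
samples, and labeling/segmentation on 25 scenes at 800 × 600.

## Known limitations

- Sprites are flat; a tall plant leaning outside its bounding sphere would
  break the containment guarantee on a real rig — choosing the sphere
  "large enough" remains the operator's responsibility.
- The pan-tilt head offset between gantry attachment and optical center is
  modeled (a configurable 3-vector) but defaults to zero; with a nonzero
  offset the *commanded* gantry position differs from the optical center,
  which the simulation does not separately track.
- Scheduling ignores pan/tilt time entirely; on a rig with slow servos and
  short legs that approximation degrades.
- The segmentation defaults are tuned for synthetic palettes; real
  deployments should expect to re-tune threshold and cleanup sizes.
- Conversion to third-party annotation formats (COCO, Pascal VOC) is an
  extension point, not implemented.
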