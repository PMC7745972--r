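# plantgantry

Machine-learning work in agriculture is chronically short of labeled plant
images: every crop, weed, and growth stage needs its own training data, and
manual annotation does not scale. One answer is a camera rig that *knows
where its plants are*: a gantry-mounted pan-tilt camera images plants placed
at measured floor positions against a blue keying background, and because
the scene geometry is fully known, every photograph can be labeled
automatically — no human annotation, no pretrained detector.

`plantgantry` is a software-only simulation of such a rig, for R. It
provides:

- **Geometry.** The transform chain `T = T_w2c · T_c2i` from world
  coordinates to image coordinates: a rigid world→camera transform
  parameterized by the gantry position and the pan/tilt angles, followed by
  a rectilinear (pinhole) projection derived from the camera's resolution
  and diagonal field of view. Each plant is replaced by a bounding sphere of
  radius *R*; at distance *D* it subtends the half-angle `asin(R/D)`, and
  the projection of that tangent cone yields an image-space bounding box.
  The chain inverts for objects of known height (ray–ground-plane
  intersection), so floor positions can be recovered from a single image.
- **Route planning.** A nested zig-zag (serpentine) traversal of the travel
  volume — slabs along x, columns along y, alternating z sweeps — plus a
  trapezoidal stepper-motion timing model: axis speed
  `v = p_r · d · s · r · m` (0.105 mm/pulse at the default drive-train
  constants) with linear acceleration ramps, and production-rate accounting
  `t_m = (t_p + t_d)/N_m`, `t_s = (t_p + t_d + t_c)/N_s`.
- **Scene simulation.** A seeded generator that places parametric plant
  sprites at the rig's marked floor positions and renders master images
  through the virtual camera with exact per-plant ground-truth masks.
- **Labeling.** Cropping of per-plant subimages, bounding-box overlay
  copies, and a v1.5 JSON metadata record per master image (capture time,
  camera pose, and one labeled box per plant), filed by position class
  (edge / interior).
- **Segmentation.** Chroma keying in CIELAB: the *b* (blue–yellow) channel
  separates plant matter from the blue fabric; thresholding (fixed or
  Otsu), morphological cleanup, background replacement, and background
  subtraction against a plant-free capture.
- **Statistics.** Inverse-frequency class weights, binomial accuracy and
  standard error, exact Clopper–Pearson confidence intervals, and dataset
  summaries from metadata directories.

## Worked example

```r
library(plantgantry)

# a run: 9 plants at marked positions, 4 ring poses each, rendered small
cfg <- run_config(n_locations = 9, seed = 42, downscale = 0.1)
res <- run_pipeline(cfg, "demo-run")
run_report("demo-run")
```

```
Production report
Routing Algorithm       Nested Zig-Zag
Locations Imaged        9
Total Images            36
Total Subimages         82
Time for Imaging t_p    268.6 s
Download Time t_d       46.2 s
Cropping Time t_c       47.9 s
Rate (Images) t_m       8.74 s/image
Rate (Subimages) t_s    4.42 s/image

Label                          Images
BarnyardGrass                       6
Dandelion                          19
Smartweed                           8
WildBuckwheat                      12
WildOat                            23
YellowFoxtail                      14
Total                              82
```

36 master images were captured (9 locations × 4 poses); 82 labeled
subimages survived the margin filter. `t_m` is the average wall-clock cost
per master image (movement + settle pause + exposure + download), `t_s` the
cost per labeled subimage — the number that tells you how fast the rig
turns time into training data. Each master image in `demo-run/` has a
`-bb.jpg` overlay copy and a `.json` metadata record; subimages are filed
under `interior/` and `edge/`.

The production-rate arithmetic at the reference settings:

```r
production_rates(production_log(t_p = 12300, t_d = 2760, t_c = 2040,
                                n_master = 2149, n_sub = 3494))
#>      t_m      t_s
#> 7.007911 4.894104
```

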