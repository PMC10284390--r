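---
title: "Quantifying cytoplasmic reorganization in maturing zebrafish oocytes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cytoplasmic reorganization in maturing zebrafish oocytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oomat)
```

## The biology being measured

During the last stage of zebrafish oogenesis the oocyte reorganizes its
cytoplasm in preparation for fertilization. Germinal vesicle breakdown
(GVBD) at the animal pole sets off several coupled processes:

* **Yolk granules (Yg)** — large (radius 8–20 µm), Lysotracker-positive
  storage organelles — undergo repeated pairwise fusion and compact
  towards the oocyte center. Fusion roughly doubles their mean 2D
  cross-sectional area over maturation.
* **Cortical granules (Cg)** — small secretory vesicles, dark in both the
  ooplasm and Lysotracker channels — are advected radially outward by the
  ooplasmic flows that Yg compaction induces, accumulate at the cortex,
  and are exocytosed upon egg activation (driving chorion elevation).
* The **microtubule network** collapses into acentrosomal asters in a
  wave that travels from the animal to the vegetal pole; asters drift
  outward and carry Rab11-positive vesicles to the surface.
* **K⁺-filled vesicles** appear after GVBD and fuse with Ygs, reflecting
  the Na⁺/K⁺-ATPase-dependent ion changes that trigger Yg fusion.

`oomat` implements the image-quantification side of this biology: granule
segmentation and tracking, radial phase-fraction profiles, kymograph
velocimetry, aster detection, and the Voronoi contraction-domain
analysis, together with a synthetic time-lapse generator that emulates
the imaged processes so every stage of the pipeline can be tested
quantitatively without microscope data.

## The synthetic scene

`scene_params()` fixes the simulated imaging conditions; `generate_timelapse()`
renders them and emits ground-truth tables.

```{r params}
p <- scene_params()
p
```

Geometry and defaults:

* Oocyte diameter 600 µm (stage III oocytes are 500–690 µm), imaged at
  1 µm/pixel, 60 s between frames, 60 frames.
* GV diameter 148 µm, tangent to the animal pole: this makes the GV
  exactly 1.5% of the oocyte volume, the fraction such stage III
  oocytes devote to their nucleus. `scene_volume_stacks()` digitizes both spheres for the
  voxel-count volume pipeline.
* 300 Yg (8–20 µm) and 600 Cg (2–5 µm) packed at ~75% areal coverage.
  Granules are seeded largest-first and tightened by deterministic
  push-apart relaxation; pairwise overlap is capped at 10% of the
  smaller radius, two cortical granules always keep a clear gap, and
  every granule starts at least 3 µm clear of the cortex.
* `fusion_rounds_mean = 1.5`: with 3D-volume-conserving pairwise fusion
  (`r_child = (r1^3 + r2^3)^(1/3)`) the expected mean-area factor is
  `2^(2 * 1.5 / 3) = 2`, the observed doubling. This is a calibration,
  not a fit: the per-pair fusion probability is re-derived every step
  from the count schedule `n(t) = n0 * 2^(-1.5 * tau)`.
* Compaction and outward Cg speeds 0.3 µm/min; aster wave 20 µm/min
  along the nucleation circumference (0.75 R); aster drift 0.5 µm/min;
  GVBD at 600 s. Speeds are prescribed kinematics — the imaged flows are
  not solved from fluid mechanics, so the generator advects granules at
  the constant speeds the analyses must later recover.

### What the generator emulates, and what it does not

The renderer reproduces the *statistical structure* the analyses rely
on: channel semantics (Cg dark in both ooplasm and Lysotracker; Yg
Lysotracker-positive; asters as Gaussian foci), a Gaussian PSF, photon
shot noise plus read noise, and granule crowding. Yolk granules are
drawn with a ~1.6 µm dark membrane rim (the lumen dye does not label the
bounding membrane), which is what keeps touching granules separable in
the real images too. It does **not** emulate textured granule interiors,
z-sectioning artifacts, bleaching, or the mechanical coupling between
granules and flows: granules follow prescribed velocities, cortical
granules slide around yolk granules rather than being advected by a
resolved flow field, and overlaps deeper than 25% of the smaller radius
(fusion children landing on a neighbor) are relaxed back to that depth.
Passing tests therefore demonstrate that the *analysis* recovers known
inputs under realistic imaging statistics — not that the generator is a
mechanistic model of ooplasmic flow.

Two presentation choices matter downstream. First, all dynamics are
gated on GVBD: before `gvbd_time` the scene is static, so "GVBD onset"
is a known frame rather than something detected from the images
(reference frames for normalization are explicit arguments throughout).
Second, the mean Yg distance to the center decreases monotonically up to
small fusion-induced jumps: replacing two granules by their
volume-weighted centroid can move the *mean* outward by a small amount
within a single step, which is why the compaction test allows per-step
upticks of a few percent of the oocyte radius.

## Segmentation

Granules in such data are often segmented with interactively trained
classifiers; `oomat` instead uses a classical, fully reproducible
pipeline: Gaussian
smoothing (1 µm) → global Otsu threshold (overridable) → distance-
transform watershed split → minimum-area filter (yolk 20 µm², cortical
3 µm²). Cortical granules are the blobs dark in *both* the ooplasm and
Lysotracker channels, restricted to the oocyte mask eroded by 2 µm
(unclipped masks produce a spurious Cg depletion at the cortex) and away
from the dilated yolk mask (yolk membrane rims are dark in both channels
too and would otherwise masquerade as Cg).

The watershed split is seeded: seeds are local maxima of the smoothed
distance transform under scale-adaptive non-maximum suppression — a peak
of distance value *v* (a granule of radius ≈ *v*) suppresses weaker
maxima within 1.2 *v*. A fixed suppression radius cannot serve both a
stage III frame (hundreds of touching 8–20 µm granules) and a
post-fusion frame (granules up to ~35 µm with noisy boundaries); tying
the radius to the peak value handles both, and components too small to
reach the seed floor keep a label of their own. On noiseless renders
this recovers ground-truth granule counts exactly.

```{r segment, eval = FALSE}
run <- generate_timelapse(scene_params(pixel_size = 1.25))  # 512 x 512
tl <- run$timelapse
mask <- segment_oocyte(tl_frame(tl, 1, "ooplasm"), tl$pixel_size)
labs <- lapply(1:60, function(f)
  segment_granules(list(lysotracker = tl_frame(tl, f, "lysotracker")),
                   "yolk", tl$pixel_size, oocyte_mask = mask,
                   frame_index = f))
tracks <- track_labels(labs, frame_interval = 60)
mean_area_series(labs)$area_factor   # ~2: the fusion-driven doubling
```

Tracking links labels across frames by maximal pixel overlap (granules
are large and slow relative to the frame interval); a label receiving
two or more links is a merge, i.e. a fusion event, with the larger
overlap surviving and ties broken towards the smaller track id.

## Radial profiles

`fit_geometry()` measures the oocyte radius along 72 rays at 5°
increments from the mask center of mass; every pixel is then assigned a
normalized radius r/R(θ) using **its own angle's** radius rather than a
mean radius, so non-circular outlines do not smear the profiles.
`phase_fractions()` normalizes the per-bin ooplasm/yolk/cortical counts
to the total phase, on 20 equal bins by default (the Cg density
histogram uses the conventional 0.05 bin width, which
`radial_histogram()` adopts); bins with zero occupancy report `NA`, never 0, so an empty bin
cannot masquerade as depletion. `delta_phase()` between a post-GVBD and
a late frame reproduces the maturation signature: cortical fraction up
near the cortex, yolk fraction up centrally and down at the cortex.

## Kymograph velocimetry

`build_kymograph()` averages bilinear samples across the line width
(radially, for circumferential arcs). Where the original analysis fitted
lines by hand in an image viewer, `extract_slope()` localizes the
feature per column — half-maximum crossing in `edge` mode (robust to
intensity scaling), intensity maximum with a repeated-median (Siegel)
fit in `ridge` mode — and reports the fit R² so trajectory quality is
explicit. Conventions: radially inward speeds are negative, outward
positive; trajectory start/end frames and positions are explicit
arguments, mirroring how such trajectories are chosen by eye in an
image viewer. In practice, candidate
trajectories whose fit R² falls below ~0.9 are trajectories crossed by
another granule and are discarded, mirroring the manual choice of clean
trajectories. `wave_speed()` fits onset time against arc position and
returns the inverse slope, with an infinite-speed sentinel (`Inf` plus a
warning) for simultaneous onset.

## Asters and contraction domains

`detect_asters()` is multi-scale Laplacian-of-Gaussian blob detection
with a relative threshold (invariant to intensity rescaling) and
non-maximum suppression; `aster_counts()` normalizes to oocyte area
(per 10⁵ µm²) when sizes differ. `temporal_projection()` records the
per-pixel maximum and its time, the quantitative counterpart of a
temporal color-code.

`contraction_domains()` assigns every pixel of the initial network mask
to the nearest final cluster (the exact Voronoi partition, computed by
1-nearest-neighbor search against cluster pixels) and measures each
domain's linear size ξ. The sizes of the two largest domains, ξ₁ and
ξ₂, read out the contraction mode: similar magnitudes mean local
contraction, ξ₁ near the system size means large-scale contraction.
**Definition of ξ:** the maximum caliper extent measured along the image
axes (the larger of the domain's x- and y-extent over the initial mask).
A domain filling the square patch then reports the system size itself —
the length ξ₁ is compared against — whereas a diagonal Feret diameter
would report 1.41× the patch side for the same domain and could never
be "close to the system size" on a square field. Classification uses a
fixed, documented threshold (large-scale iff ξ₁ ≥ 0.7 × field size,
closed boundary), and the numeric (ξ₁, ξ₂) pair always accompanies the
call; a third qualitative category used for scoring abnormal asters is
not auto-classified.

```{r contraction, eval = FALSE}
p <- scene_params(seed = 1)
glob <- generate_contraction_series(p, mode = "global")
init <- network_mask(tl_frame(glob$timelapse, 1, "network"))
fin <- segment_network_clusters(tl_frame(glob$timelapse, 60, "network"))
contraction_domains(init, fin, field_size = p$field_size)
#> xi1 = 200 um on the 200 um patch -> large_scale
```

## Event metrics

`fusion_histogram()` bins merge events (10-minute bins by default, a
coarseness matched to the few-per-hour event rate) with an
optional seeded granule subsample emulating the 10–20-granules-per-
oocyte scoring. `depletion_ratio()` is the percentage of pre-activation
Cg with no overlapping post-activation granule — pixel overlap without
registration, since the egg is immobilized between the two frames, and
both frames are explicit inputs because "completion of activation" is
operator-defined. `chorion_ratio()` detects the two concentric
boundaries by edge detection plus radial Hough-style voting and returns
outer/inner diameter; coincident boundaries return 1.0.

## Numerical choices and problem sizes

* Determinism: every stochastic step draws from an RNG stream seeded by
  `scene_params(seed=)`; the scene carries its RNG state, and rendering
  is seeded per frame, so identical parameters give bit-identical
  frames and tables.
* Packing: rejection seeding falls back to push-apart relaxation;
  residual pairwise violation above 0.05 µm raises a packing-failure
  error (infeasible density).
* 16-bit TIFF I/O is exact for integer counts; calibration lives in a
  JSON sidecar, and a missing sidecar falls back to 1 µm / 60 s with a
  warning.
* Test problem sizes: the suite exercises a 150 µm miniature oocyte
  (25 Yg, 60 Cg, 30 frames at 160×160) for per-operation checks, and
  one full-scale 600 µm run at 1.25 µm/pixel (512×512, 60 frames) for
  the end-to-end fusion benchmark; the contraction analysis runs on the
  default 200 µm patch. These sizes keep a complete run of the suite in
  the minutes range while preserving the default granule densities and
  speeds.

## Known limitations

* Granules are homogeneous disks; segmentation parameters tuned here
  may need adjustment for textured real granules (thresholds and
  minimum areas are exposed as arguments).
* The Lysotracker intensity cut-off separating Yg from Cg is not
  specified by the imaging protocol; the defaults are calibrated on the
  generator's channel semantics.
* Tracking assumes merges only (fusion); granule splitting is not
  modelled and would be recorded as a new track.
* The flow profile and slope extraction assume roughly linear
  trajectories within the fitted window; strongly curved trajectories
  need narrower frame ranges.
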