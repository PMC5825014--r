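---
title: "Fuzzy-distance morphometry of dendritic spines: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy-distance morphometry of dendritic spines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinemorph)
```

## The problem

Dendritic spines are micrometre-scale protrusions on neuronal dendrites;
their shape (a bulbous head on a thin neck, a stubby dome, a thin
filopodium) tracks synaptic function, and shape changes are the readout
in structural-plasticity experiments.  Confocal z-stacks of
fluorescently labelled dendrites resolve spines only marginally: the
in-plane pixel is typically 70 nm but the axial step is 200 nm, the
point-spread function smears structures near the resolution limit, and
spine necks image far dimmer than the dendrite shaft.  Segmenting an
individual spine therefore means separating two *fused, fuzzy* objects
-- the bright dendrite and the dim spine -- whose boundary is not a
visible edge, and then measuring geometry on the resulting voxel set.

`spinemorph` implements this as three layers:

1. **Fuzzy-distance machinery.**  A fuzzy object carries a per-voxel
   membership $\mu \in [0,1]$.  A 26-adjacent link from $p$ to $q$ has
   length $\tfrac12(\mu(p)+\mu(q))\,\lVert p-q\rVert$ with
   $\lVert\cdot\rVert$ the physical (anisotropic) step; the fuzzy
   distance between voxels is the minimal path length; the fuzzy
   distance transform (FDT) $\Omega(p)$ is the minimal path length from
   $p$ to the background, a depth map inside the object.
2. **Multi-scale opening (MSO).**  Seeded separation of the spine and
   dendrite objects by descending depth scales: coarse cores are claimed
   first, fine peripheral detail last, and within each scale the two
   objects race outward from what they have already claimed.
3. **Morphometry and rules.**  Landmarks (base, central base point, head
   centre, tip), central paths, the feature set (neck length, minimum
   neck width, average head width, spine length, volume) and a fixed
   rule cascade assigning one of four shape classes.

## Membership model and foreground extraction

Foreground extraction is a threshold $\theta$ plus connectivity
filtering (`threshold_foreground()`).  The default $\theta$ is the
*lower* threshold of a two-level Otsu split: the volume histogram of a
spiny dendrite is trimodal (background / dim spine band / bright
dendrite band), and a single Otsu threshold lands between the spine and
dendrite bands, deleting the dim necks that connect spines to the
shaft.  A single-Otsu option (`theta = "otsu"`) and a numeric $\theta$
remain available.

Intensities inside the foreground are mapped to two memberships by
linear ramps between a spine level $I_{\mathrm{Spine}}$ and a dendrite
level $I_{\mathrm{Dendrite}}$: below $I_{\mathrm{Spine}}$ a voxel is
purely spine-like, at or above $I_{\mathrm{Dendrite}}$ purely
dendrite-like, and in between the two memberships are complementary
ramps summing to one (`membership_spine()`, `membership_dendrite()`).
The band limits default to a two-level Otsu on the foreground
intensities and can be set explicitly.

## The opening algorithm

`multi_scale_opening()` receives the composite object (fuzzy union of
the two memberships) and the user's seed sets.  Initial depth maps
$\Omega_{\mathrm{Spine},0}$ and $\Omega_{\mathrm{Dendrite},0}$ are FDTs
of the composite membership with the rival's seeds and all separator
voxels pushed into the background.  The composite membership (rather
than each class's own ramp) is used deliberately: the blurred boundary
shell of the dendrite has spine-band intensities, and an object whose
membership vanished there could never claim its own partial-volume
shell.

Growth proceeds over scales $s$ descending from the deepest value to
zero in steps of one minimal voxel size.  At scale $s$ an object may
claim unclaimed voxels whose own initial depth is at least $s$; within
the scale the two objects expand as competing Dijkstra fronts from
their already-claimed sets, with the usual fuzzy link lengths, so a
voxel goes to whichever object reaches it first *geodesically* (a
hop-synchronous race would be metrically wrong on anisotropic grids,
where an axial hop is three times an in-plane hop).  An exact
simultaneous arrival falls back to the geodesic distance from the seed
sets, and a full tie goes to the dendrite.  Bright voxels at or above
$I_{\mathrm{Dendrite}}$ are pre-claimed by the dendrite -- nothing else
in these images mimics the brightest band -- but dim voxels are *not*
pre-claimed by the spine object, precisely because the dendrite's
partial-volume shell shares that band.  Separator voxels are never
claimed; whatever remains unclaimed after the final scale is assigned
to the dendrite and counted.

Connected components of the spine label that contain no spine seed are
merged back into the dendrite (`extract_spine_components()`), so every
reported region holds at least one seed and the labels always partition
the foreground.

A property worth stating: on phantoms the split this produces agrees
with an independent erosion-until-disconnection oracle to within a few
percent of voxels, but both procedures place the spine/dendrite
boundary *inside the neck* (the fronts meet mid-neck), whereas solid
ground-truth labels place it at the shaft surface.  For the smallest
spines that half-neck is several percent of the volume; it bounds the
achievable Dice against solid truth at roughly 0.93-0.98 even without
noise.

## Morphometry

Each region is measured in isolation (`measure_spine()`):

* $\Omega_i$, the region's own FDT (everything outside the region,
  including the dendrite, is background) defines depth landmarks.
* The **base** is the set of dendrite voxels 26-adjacent to the region;
  its centroid is the **central base point** (CBP), snapped to the
  nearest base-or-region voxel for path computations and reported
  unsnapped.
* **Locally deepest points** are voxels whose depth is maximal over the
  $(2l+1)^3$ neighbourhood ($l = 2$ by default, suppressing noise
  maxima); the **head centre** (CH) is the deepest of them, tied
  maxima resolved by their centroid.  Because a uniform tube is a depth
  plateau, *every* centreline voxel of a clean neck is locally deepest;
  statistics that intend "head points" therefore use the *significant*
  subset with depth at least `depth_frac` (default 0.6) of the maximum.
  Setting `depth_frac = 0` recovers the unfiltered set.
* The **tip** is the region voxel geodesically farthest from the CBP.

Two path notions coexist and serve different purposes:

* **Central paths** (`central_paths()`) minimise a node-weight sum over
  the region FDT.  The default weight is the medialness form
  $\max\Omega_i + s/2 - \Omega_i(p)$ (with $s$ the minimal voxel size),
  which drives the path through the deepest voxels -- the anatomical
  centre of the neck and head.  Minimising the *plain* depth sum
  (`mode = "sum"`) is mathematically tempting but selects
  surface-crawling paths: many shallow voxels cost less than a few deep
  ones, which doubles apparent neck lengths even on clean rasterized
  solids.  The central path carries the **minimum neck width** reading.
* **Length features** are unit-membership geodesic distances between
  the landmarks: base-to-head $BH$, head-to-tip $HT$, spine length
  $L = BH + HT$.  The geodesic is the taut realization of "length of
  the path joining the landmarks"; a walking path's voxel count picks
  up meander inside wide heads.

Derived features (all widths are *diameters*, twice the FDT depth,
matching the biological reading of "width"):

* neck length $NL = BH - \Omega_i(CH)$, clamped at zero (a head sitting
  directly on the shaft has no neck);
* minimum neck width $MNW = 2\min \Omega^{\mathrm{ref}}$ along the
  central path restricted to region voxels, where $\Omega^{\mathrm{ref}}$
  is the FDT of the *full* foreground (region plus dendrite).  On the
  isolated-region map every voxel near the spine/dendrite cut face has
  near-zero depth because the cut is treated as background even though
  it is not an anatomical surface; widths are a property of the tissue
  boundary, so they are read on the map that knows the dendrite is
  tissue;
* average head width $AHW = 2\,\mathrm{avg}\,\Omega_i$ over the
  significant deepest points;
* volume = voxel count times the physical voxel volume.

Detached regions (no base) report neck features as missing and skip
classification.

## Classification

The cascade (`classify_spine()`) fires in a fixed order and records a
decision trace:

1. $NL \le \tau_{\mathrm{stubby}}$ (default 0.2 um, one axial sampling
   step -- a neck shorter than the coarsest voxel is not measurable)
   gives **Stubby**.
2. spread $\ge \tau_{\mathrm{spread}}$ (default 0.6) gives
   **Filopodia**.  The spread statistic is the extent of the
   significant deepest points' geodesic positions along the spine,
   divided by $L$: a uniform tube's depth plateau covers its whole
   axis, while heads concentrate depth.
3. $BH/L \le \tau_{\mathrm{ratio}}$ (default 0.65) gives **Mushroom**,
   otherwise **Spine-head protrusion**.  Geometrically
   $BH/L \approx (n + r)/(n + 2r)$ for neck length $n$ and head radius
   $r$, so the ratio starts just above one half for short-necked heads
   and grows towards one with the neck; the default is the empirical
   split point of the phantom suite, where segmentation halo shifts
   both populations slightly.
4. Branched spines -- at least two depth-significant clusters that pass
   a bulge test (cluster depth at least $\tau_{\mathrm{branch}} = 1.5$
   times the narrowest depth on its path to the base, read on
   $\Omega^{\mathrm{ref}}$) and are geodesically separated by more than
   the sum of their depths -- bypass the cascade and are flagged only.

"Thin" is deliberately not a class: it is an intermediate form without
a crisp geometric definition, and forcing it would only blur the
mushroom/filopodia boundary.

## The phantom generator

`make_phantom()` renders a bright tubular dendrite (radius 0.5 um)
along the y axis with attached protrusions -- spheres on cylindrical
necks, neckless domes, capped thin tubes -- at the acquisition geometry
of a typical confocal experiment: voxels of 0.2 x 0.07 x 0.07 um, 8-bit
intensities with background 10, spine band 120, dendrite band 220, a
0.15-um linear intensity ramp at the spine-dendrite junction (creating
the shared band), Gaussian blur of sigma (0.1, 0.07, 0.07) um standing
in for the point-spread function, and additive Gaussian noise
(sd 4).  Everything is configurable; rendering is deterministic given
the seed.  Ground truth is the noiseless solid labelling plus the exact
per-spine geometry and one seed per structure at its deepest point.

Geometry ranges are chosen to be *resolvable at the stated optics*: a
0.2-um-calibre neck peaks at roughly a tenth of its band intensity
after blur and denoising -- below any defensible threshold -- so
phantoms carry necks of 0.26-0.32 um diameter.  Validating against
structures the imaging model itself erases would test nothing.

What the phantoms do **not** emulate: a real (Gibson-Lanni) PSF with
depth-dependent axial smear, photon-counting (Poisson) noise, uneven
labelling, dendrite curvature and taper, and touching or overlapping
spines.  Passing the phantom suite therefore demonstrates correctness
of the algorithms under a faithful geometry-and-contrast model, not
performance parity on arbitrary real acquisitions.

## Numerical choices

* 26-adjacency throughout; physical spacing enters every link length,
  so path lengths and widths are in micrometres and volumes in cubic
  micrometres.
* Space outside the image array counts as background for every FDT.
* All shortest-path computations are exact Dijkstra runs (compiled);
  FDT values match an exhaustive graph oracle to numerical precision.
* Ties are broken deterministically everywhere: minimum-weight paths
  prefer fewer voxels then a fixed predecessor order; landmark snapping
  prefers the lexicographically smallest voxel; the opening race
  resolves simultaneous arrivals by seed distance, then dendrite.
  Repeated runs are bit-identical.
* The opening's scale step defaults to one minimal voxel size; results
  on phantoms are insensitive to finer steps.

## Problem sizes used in the shipped validation

The test-suite and acceptance checks run on 6x6x6 random fuzzy fields
against an exhaustive shortest-path oracle (50 fields), binary balls of
radius 3-8 voxels against a brute-force Euclidean distance transform,
twenty shallowly fused two-ball scenes against an
erosion-until-disconnection oracle, twenty renderings of a five-spine
dendrite phantom (20 x 92 x 64 voxels) for geometry recovery, and a
forty-instance single-spine suite (ten per category) for
classification.  These sizes keep a full validation run in the order
of a minute while every check remains exhaustive at its scale.

## Known limitations

* The spine/dendrite boundary lands mid-neck, not at the shaft surface
  (inherent to erosion-style separation); volumes of small spines are
  correspondingly conservative near the base and inflated by the
  partial-volume halo elsewhere.
* Head depth is axially truncated on anisotropic grids (a 0.4-um head
  spans only four z-slices), which biases the head radius low by up to
  one axial step; neck length inherits part of that bias.
* Reproducibility with respect to seed placement is essentially perfect
  on phantoms because seeds enter only through tie-breaking; real
  inter-rater variation also includes ROI and threshold choices that
  the phantom protocol does not model.
* Branched spines are flagged, never classified; spine density is out
  of scope.

## A minimal session

```{r example, eval = FALSE}
ph <- make_phantom(five_spine_phantom(seed = 1))
res <- run_pipeline(ph$volume, ph$seeds, out_dir = "run1")
res$features[, c("spine_id", "volume_um3", "neck_length_um",
                 "min_neck_width_um", "avg_head_width_um",
                 "spine_length_um", "class")]
```
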