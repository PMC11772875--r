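---
title: "Methods: quantifying condensates and their organelle association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying condensates and their organelle association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

condensatr quantifies membrane-less condensates (P-bodies and similar
ribonucleoprotein granules) in multi-channel 3D(+time) fluorescence stacks
and classifies their association with a membrane-bound organelle (the ER or
its exit sites, ERES). The pipeline is the open counterpart of a
commercial "Surface"/"Spot" object-statistics workflow:

1. **Surface detection.** Per channel: Gaussian pre-smoothing (σ = 1 XY
   pixel, matched in physical units along Z), median background
   subtraction, Otsu thresholding on a 256-bin relative histogram,
   26-connected 3D component labeling, and a strict volume gate —
   components with volume ≤ 0.05 µm³ are discarded. The relative
   histogram makes detection invariant under uniform intensity rescaling.
2. **Morphometry.** Volume V = voxel count × voxel volume. Surface area A
   comes from a triangulated isosurface (marching tetrahedra at level 0.5)
   of the object mask resampled to an isotropic grid at the finest voxel
   pitch and lightly smoothed. Sphericity is Wadell's
   Ψ = π^(1/3)·(6V)^(2/3)/A, 1 for a ball. Aspect ratio is the square root
   of the extreme-eigenvalue ratio of the binary mask's second central
   moment tensor in physical units (intensity-independent by design, so
   shape and texture stay decoupled).
3. **Association.** The organelle mask's signed Euclidean distance field is
   anisotropy-corrected and sampled at voxel centers (positive outside,
   negative inside). A condensate is *associated* iff its shortest surface
   distance is ≤ 0 µm — touch or overlap — and *cytoplasmic* otherwise.
4. **Colocalization.** Spot–spot: center distance strictly < 0.2 µm
   (spots are 0.2 µm diameter, 0.1 µm radius). Spot–surface: distance from
   the surface to the spot center strictly < 0.1 µm; a spot inside a
   surface has negative distance. Surface–surface: ≤ 0 µm. All thresholds
   live in the run configuration and are echoed into the run manifest.
5. **Dynamics.** Frame-to-frame linking by optimal assignment (Hungarian
   algorithm) in 3D physical coordinates with a hard gate (default
   2 µm/frame) and gap closing (default 1 missing frame). Readouts: track
   linearity (net displacement ÷ path length), instantaneous speeds, track
   duration, ensemble MSD at lags that are multiples of the 15 s cadence
   (default up to 45 s), and fission/fusion events from label-map overlap
   between consecutive frames.
6. **Statistics.** The sampling unit is the image: per-object measurements
   are collapsed to per-image means before testing. Group comparisons use
   two-sided Mann–Whitney tests — exact (dynamic-programming enumeration of
   the rank-sum null) for combined n ≤ 20 without ties, midranks with
   tie-corrected normal approximation otherwise. Percent differences state
   their denominator convention explicitly, because summary prose
   legitimately alternates between "percent of the larger value" and
   "percent of the control".

## Geometric conventions

Arrays are ordered `(T, C, Z, Y, X)`; voxel sizes are `(z, y, x)` in µm
(default 0.3 × 0.1 × 0.1 µm: confocal stacks with 0.3 µm optical
sections). Physical coordinates are voxel centers: voxel `i` (1-based)
along an axis of pitch `h` sits at `(i − 0.5)·h`. The canonical on-disk
format is uncompressed 16-bit OME-TIFF; intensities are floating point in
memory.

Two distance conventions coexist and are both exposed deliberately:

* The stored distance **field** is center-to-center (the value at a voxel
  adjacent to a mask voxel is one pitch), matching how a voxelized field
  can actually be sampled; linear interpolation of the signed field crosses
  zero at the mask boundary.
* **Rule-critical queries** — the ≤ 0 µm touch rule and the < 0.1 µm
  spot–surface rule — use exact mask adjacency and point-to-voxel-box
  distances, so sub-voxel offsets (a spot 0.05 µm outside a face) are
  resolved correctly rather than being at the mercy of half-voxel bias.

"Touch" is operationalized as voxel-box contact: overlapping or
26-adjacent voxels (boxes meeting at a face, an edge or a corner) give
distance ≤ 0. This is slightly more inclusive than a face-only reading;
geometrically, boxes do touch at edges and corners.

## Numerical choices

* **Surface-area smoothing (σ = 0.75 isotropic voxels).** Meshing the raw
  binary mask overestimates area by 25–40 % (staircase artifacts); heavy
  smoothing (σ = 1) under-estimates it for small objects by eroding
  curvature. σ = 0.75 was calibrated against analytic spheres: digital
  balls of radius ≥ 3 voxels mesh to within ~1 % (isotropic grid) and
  ~1–4.5 % (0.3/0.1/0.1 µm grid) of 4πr². Sphericity is clipped at 1.05;
  values between 1 and 1.05 occur for small, Z-thin segmented masks where
  the mesh slightly underestimates A, and such objects carry a `thin`
  flag.
* **Spot detection floor (5 × MAD of the LoG response).** Spots are found
  as local maxima of the negative Laplacian-of-Gaussian response at the
  scale matched to the nominal 0.2 µm diameter, with subpixel centers by
  local center of mass. The classical "3 robust SDs" floor is defined on
  intensities; on the heavy-tailed LoG response it over-detects, while
  recall/precision are flat between 4 and 16 MADs on planted scenes — 5 is
  used and logged.
* **MSD fitting with an intercept.** Localization error adds a constant
  2dσ² offset to every MSD lag and biases a through-origin slope upward;
  the default fit therefore carries an intercept (`msd_fit(...,
  intercept = FALSE)` recovers the textbook form). Recovering a diffusion
  coefficient to within 10 % needs roughly 150 tracks; thin (3 µm) Z
  fields additionally confine Z diffusion and depress 3D MSD by ~5–10 %,
  which is a property of slab geometry, not of the estimator.
* **Mann–Whitney exactness.** The exact two-sided p is computed from the
  full rank-sum null distribution via a subset-sum dynamic programme
  (equivalent to enumerating all C(m+n, m) labelings); it matches R's
  `wilcox.test(exact = TRUE)` to 1e-12 on all combined n ≤ 12 and keeps
  simulated type-I error at α = 0.05 within [0.035, 0.065].

## The synthetic world

Because the study images are not deposited, every stage is validated by
parameter recovery on synthetic scenes with complete ground truth
(`generate_scene()`, `generate_timeseries()`, `generate_probe_scene()`).
A scene is an ideal noise-free rendering corrupted by a Gaussian PSF
(default σ = 0.25/0.08/0.08 µm in z/y/x) and Poisson–Gaussian noise
(`Poisson(scale·I)/scale + N(0, sd)`).

What the generator emulates, and the choices behind it:

* **Condensates** are solid prolate spheroids with log-normal volumes
  (default mean 0.3 µm³, truncated to 0.06–1 µm³, matching the 0.05–1 µm³
  working range) and log-normal aspect ratios ≥ 1. Masks are rasterized by
  exact-count selection — the `round(V/voxel volume)` voxels with the
  smallest ellipsoid quadratic form — so ground-truth voxel volumes track
  planted volumes to half a voxel regardless of how the surface cuts the
  grid. Internal texture is multiplicative band-limited speckle with
  amplitude `texture_roughness`, reproducing the smooth-vs-rough contrast
  with one knob.
* **Organelles** are either hard spheres at random positions (ERES-like
  puncta) or random-walk tubes of fixed radius (ER-like network); only the
  mask geometry matters downstream. Exactly
  `round(association_fraction·n)` condensates are planted touching the
  mask; non-associated ones keep a clearance of at least one long
  semi-axis plus two voxels.
* **Motion** mixes ballistic transport (fixed speed along a fixed random
  in-plane direction — the emulated stacks are 10 × 0.3 µm optical
  sections, and ballistic motion along Z would exit the slab within a
  frame) and isotropic 3D diffusion with per-axis step variance 2DΔt at a
  15 s cadence. Objects whose extent would leave the field are truncated
  and flagged, never an error.
* **Fission** occurs at `fission_rate` per object-frame for objects large
  enough that both half-volume daughters stay well above the 0.05 µm³ gate
  (parent ≥ 0.3 µm³). Daughters split along the parent's in-plane long
  axis, start just resolvable (~0.45 µm surface gap, which survives the
  PSF) while each still overlaps the parent footprint, and one daughter
  departs ballistically. In fission worlds a volume-exclusion rule rejects
  any step that would bring two surfaces within blur-merge range: these
  condensates never coalesce (no fusion is ever planted), so an apparent
  fusion is always an error of the detector, never of the world. Pure
  motion worlds omit the exclusion so planted speeds stay exact.
* **Probe pairs** plant a recorded multinomial draw of
  intact / orphan-5′ / orphan-3′ transcripts; an intact transcript puts one
  spot per channel within 0.1 µm of a shared center (always below the
  0.2 µm pairing threshold), orphans put a single spot. Orphan 5′ spots
  read out 3′→5′ decay intermediates and vice versa.
* **Bleaching** multiplies the condensate-channel intensity of objects
  inside the ROI at the bleach frame by a residual factor (default 0.05)
  for all later frames; "recovery" is re-entry of unbleached mobile
  objects, and the FRAP readout is object counts per class in the ROI, not
  an intensity-recovery curve.

What the generator does **not** emulate: vectorial/aberrated PSFs,
spectral bleed-through, depth-dependent attenuation, nurse-cell anatomy
(nuclei, membranes, ring canals), cytoplasmic autofluorescence gradients,
or condensate coalescence. A green test therefore establishes that each
stage recovers its planted parameter under realistic blur, shot noise and
anisotropy — not that the pipeline is robust to every optical artifact of
real tissue.

One free parameter has no published value: the number density of
condensates. The default (≈ 0.05 objects/µm³, i.e. `n_condensates = 40`
in the 20 × 20 × 3 µm default field) was chosen once as a realistic
nurse-cell-like density and is not revisited; tests that need sparser or
denser fields say so explicitly in their scene specs.

## Degenerate inputs and tie-breaks

Flat channels segment to an empty set with a warning, never an error. An
empty organelle mask classifies everything cytoplasmic at distance +∞
(warned). Tracks with a single point have undefined linearity (`NA`,
flagged); zero-motion tracks define linearity 0/0 := 0. Track class ties
resolve to "associated" (the conservative choice). Assignment ties in the
tracker are broken by the LSAP solver's canonical order; all stochastic
draws flow from one seed and the caller's RNG state is restored.

## Known limitations

* Absolute sphericities are not comparable to the commercial tool's
  (its formula is unpublished); only relative comparisons are meaningful.
  Wadell sphericity is used and stated.
* Threshold segmentation of blurred objects biases measured volumes
  upward for objects near the PSF scale; comparisons between conditions
  processed identically remain valid, absolute volumes carry the bias.
* The tracker has no motion model (no Kalman prediction); it is accurate
  when per-frame displacement is well under the gate, which holds at the
  emulated speeds (≤ 0.05 µm/s at 15 s cadence).
* Fission detection requires daughters to be resolvable one frame after
  the split; events below the PSF scale are invisible by construction.
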