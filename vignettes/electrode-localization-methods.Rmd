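---
title: "Photogrammetric EEG electrode localization: models, parameters and design choices"
author: "headgeo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photogrammetric EEG electrode localization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Source reconstruction from EEG benefits from knowing where each electrode
actually sat on the participant's scalp, in the coordinate frame of their
structural MRI. Photogrammetry offers a fast way to get there: photograph
the head wearing the cap, reconstruct a textured 3D mesh with
structure-from-motion software, and read the electrode positions off the
mesh texture. Two computational problems remain, and they are what
`headgeo` implements:

1. **Coregistration.** The photogrammetric mesh lives in an arbitrary
   coordinate frame at an arbitrary scale. It must be mapped into MRI
   space using only geometry shared by both surfaces — the rigid parts of
   the face (forehead, brow, nose ridge, cheekbones), since caps and hair
   are not present in the MRI scalp surface.
2. **Electrode identification and labeling.** Electrode patches are
   visible in the mesh texture as high-contrast circular targets. They
   must be found, lifted from the 2D texture back to 3D surface points,
   and assigned standard montage labels.

# Coregistration model

Let $v_i^{MRI}$ be the points of a facial segment selected on the MRI
scalp surface and $v_i^{model}$ the corresponding segment on the
photogrammetric mesh, with centroids $C^{MRI}$ and $C^{model}$ (per-axis
means). The isotropic scale is estimated as the ratio of mean centroid
distances,

$$ s \;=\; \frac{\tfrac{1}{N_{MRI}}\sum_i \lVert v_i^{MRI}-C^{MRI}\rVert}
                {\tfrac{1}{N_{model}}\sum_i \lVert v_i^{model}-C^{model}\rVert}, $$

the whole model is multiplied by $s$, and a rigid transform is then
estimated by iterative closest point (ICP): alternate nearest-neighbour
correspondence with a least-squares rotation/translation solve (Kabsch,
via SVD), which makes the summed squared point-to-closest-point distance
non-increasing across iterations. The composition (scale, then rigid fit)
maps the full model — and any electrode coordinates expressed in its
frame — into MRI space.

Two design choices here were genuinely open:

* **Initialization.** Interactive pre-orientation is replaced by an
  automatic coarse init: the principal axes of the two segments are
  aligned (centroids matched), trying the four proper axis-sign
  combinations and keeping the lowest nearest-neighbour RMS. Point-to-point
  ICP on smooth surface patches can otherwise stall in a sliding local
  minimum; the package's own tests document this (a 10° rotation of a
  facial patch is not always recovered from an identity init, and is
  always recovered from the principal-axes init). `coregister_model_to_mri()`
  always applies the coarse init.
* **Reflections.** The least-squares rotation is constrained to
  determinant $+1$. An anatomical surface must never be mirrored, so a
  reflection is treated as a degenerate-geometry error, not a solution.

ICP defaults: `max_iter = 100`, `tol = 1e-6` mm RMS change, trimming off.
Trimming (`trim_frac`) drops the worst fraction of correspondences per
iteration and stands in for manually deleting mismatching mesh regions;
it is off by default because the synthetic fixtures have no such regions.

`fiducial_transform()` implements the baseline used by electromagnetic
digitizers: both point sets are expressed in the canonical head frame
(origin at the midpoint of the preauricular points, $x$ toward RPA, $y$
toward the nasion within the fiducial plane, $z = x \times y$) and the
frames are composed. It is exact on noiseless fiducials, which is why the
coregistration-error simulation injects per-fiducial Gaussian placement
noise (default SD 2 mm, configurable): a noiseless baseline would carry
no information about digitization error. The noise level is a repository
assumption; digitization repeatability of a few millimetres is typical
for landmark-based workflows.

# Electrode detection model

Detection works entirely on the textured mesh:

1. **Binarization.** The texture is converted to luminance and thresholded.
   The automatic threshold maximizes between-class variance (Otsu's
   criterion), the standard formalization of "maximize the contrast
   between electrodes and cap". Polarity is configurable; the default
   expects electrode patches brighter than the cap fabric.
2. **Views.** The binary-textured mesh is rasterized orthographically
   with a z-buffer from 10 viewpoints: azimuths
   $\{0°, 72°, 144°, 216°, 288°\}$ at elevations $\{20°, 55°\}$ above the
   horizontal, relative to the head's vertical axis. The literature the
   package follows states the view count but not the directions; this
   grid covers the cap area with overlap so that every electrode is seen
   nearly face-on in at least two views. Default pixel pitch is
   0.6 mm/px.
3. **Circular Hough transform.** In each binary view, Sobel edge pixels
   vote along their gradient direction across the radius search range;
   the accumulator is perimeter-normalized so scores are comparable
   across radii, local maxima above `sensitivity` (default 0.3, the
   fraction of a full perimeter's vote) are kept, with non-maximum
   suppression of centers closer than `r_min` or inside an accepted
   stronger circle. Radii are specified in millimetres (default 2–8 mm,
   bracketing real electrode patches) and converted to pixels per view —
   physical electrode size is scale-invariant, pixels are not.
4. **Back-projection.** Each detected center is mapped through the
   render's per-pixel face + barycentric record to the 3D surface point
   that produced it.
5. **Merging.** Candidates from all views are merged by single-linkage
   clustering at `merge_radius` (default 10 mm, about half the minimum
   inter-electrode spacing of dense caps); each cluster becomes its
   centroid. Clusters supported by fewer than `min_views = 2` views are
   discarded as spurious (typically half-occluded patches at silhouette
   boundaries). Averaging across views is also what makes the final
   positions more accurate than any single view's pixel quantization.

The detected set is an ordinary `electrode_set`; the caller may add,
remove or move rows before labeling — the manual-correction hook, kept
because a few percent of electrodes on real textures need adjustment.

# Labeling model

Labeling assumes the electrode count matches the montage (sets with
missing or extra electrodes are rejected, deliberately). Seven labeled
template sets are aligned onto the unlabeled cloud; each electrode takes
the label of its nearest template electrode per template, and the final
label is the majority over the seven proposals (ties to the lowest
template index; duplicate winners resolved by a minimum-total-distance
one-to-one assignment over the freed labels).

The alignment anchor is the pair of landmark electrodes Fpz and Oz. How
they are "automatically detected" was left open by the source material;
the package's heuristic is documented as its own choice:

* fit a sphere to the cloud; the vertical axis is the direction from the
  sphere centre to the cloud centroid (a hemispheric cap's centroid sits
  above its centre of curvature);
* find the best reflection-symmetry plane containing that axis by
  scanning azimuths (3° grid, then local refinement). Because an
  electrode grid is nearly symmetric about the coronal plane too, *both*
  orthogonal symmetry minima are kept as hypotheses;
* in each hypothesis plane, the two midsagittal electrodes at extreme
  anterior/posterior positions within the lower cap band (lowest 50% of
  cap height — wide enough to survive anisotropic heads, narrow enough to
  exclude the next midline row) are the landmark candidates;
* every orientation hypothesis (2 planes × 2 directions) is trial-aligned
  against the templates (landmark-anchored similarity init + short
  similarity ICP) and scored by a greedy one-to-one matching cost. Plain
  nearest-neighbour cost is *not* sufficient here: a front/back flip
  still leaves most electrodes near *some* electrode of the regular grid,
  whereas one-to-one matching exposes the pile-ups the flip produces on
  the asymmetric rows. The hypothesis preferred across templates wins.

Per template the final alignment is a 12-parameter affine ICP restricted
to positive determinant (a mirror flip would silently exchange left/right
labels). The seven default templates are generated from one canonical
68-electrode layout by fixed-seed 3 mm jitter and stored normalized
(centred, unit RMS radius); real deployments should replace them with
curated digitized sets via `build_template()`/`write_templates()`.

The canonical layout itself is a 10-10-style construction: rows Fp
through O placed by spherical-arc interpolation between midline anchors
and outer-ring endpoints, plus an inferior 9/10 row. To keep exactly 68
unique labels while preserving the property the landmark detector needs —
Fpz and Oz being the extreme midsagittal electrodes of the lower band —
the layout omits AFz and Iz and includes the lateral pairs F9/F10,
FT9/FT10, TP9/TP10 and P9/P10. The real cap the method was validated on
is not published; this layout is a stand-in with the same count and the
same qualitative geometry.

# Scalp extraction and capture preparation

`scalp_mesh_from_volume()` derives a scalp surface from an MRI-like
volume: binarize at `threshold_frac` (default 0.10) of the robust maximum
(99th percentile), morphological closing with a 2-voxel spherical
element, keep the largest 6-connected component, fill internal holes, and
extract the 0.5 isosurface by marching tetrahedra (six tetrahedra per
cube sharing the main diagonal, face-consistent between neighbours, hence
watertight). A light Gaussian on the binary mask (`smooth_sigma = 0.6`
voxels) suppresses voxel staircase; on a synthetic 50 mm ball the
extracted radius is correct to well under one voxel. These defaults are
the package's own: the upstream workflow delegated scalp extraction to
external segmentation tools without stating parameters.

`chroma_mask()` computes color distance to the key in a
luminance-separated chroma plane (Cb/Cr), so shading gradients on the
green screen stay background; the automatic threshold is the Otsu valley
of the bimodal chroma-distance histogram, then the largest connected
foreground component is kept and hole-filled. `downsampling_rate()` is
the bookkeeping identity $1 - (n \cdot MP)/(56 \cdot 24)$ of the capture
study it mirrors.

# Evaluation machinery

`mesh_deviation()` measures, for every test vertex, the offset to the
*nearest vertex* of the truth mesh — per-axis absolute components and the
Euclidean distance — exactly as the workflow it reproduces describes;
true point-to-triangle distance is available as an option
(`mode = "surface"`). `electrode_deviation()` matches by label (with an
exclusion list for electrodes known to be unreliable on a reference
object) and `pure_position_deviation()` first removes the best rigid
transform between the matched sets. With correspondences known, the
least-squares rigid fit *is* the fixed point that correspondence-based
ICP converges to, so the package solves it directly.

`coreg_error_simulation()` is the package's central accuracy experiment:
apply a random similarity perturbation — per-axis rotations uniform on
[1°, 360°] composed as $R_z R_y R_x$ (the composition order is fixed and
documented because only "per orthogonal direction" was specified),
per-axis translations uniform on [1, 100] mm, scale uniform on [1, 5] —
to the model, its electrodes and (for the fiducial method) its
fiducials; re-coregister; and pool the Euclidean distances between
original and recovered electrode positions. The arbitrary scale is
applied only in the surface-matching arm: a digitized fiducial set has no
reconstruction scale to recover. Every repetition derives its own
sub-seed from the master seed, so reports are exactly reproducible.

`wilcoxon_signed_rank()` drops zero differences and mid-ranks ties; for
$n \le 12$ retained pairs it enumerates all $2^n$ sign assignments of the
observed ranks (exact even under ties, which the standard exact routine
refuses), otherwise it uses the normal approximation with continuity and
tie corrections. The exact/approximate switch and tie handling were
unspecified upstream; these are the package's documented defaults, and
the approximation branch is cross-checked against `stats::wilcox.test`
in the test suite.

# The synthetic data generator

Real inputs to this pipeline (photogrammetric meshes, MRIs, digitized
ground truth) cannot ship with a package, so every fixture is generated
with known ground truth:

* `make_head()` radially displaces a subdivided icosahedron (2562
  vertices at the default subdivision 4): an ellipsoidal base with
  semi-axes ≈ 78 × 96 × 92 mm (left-right × anterior-posterior ×
  vertical, adult-head scale), plus a protruding nose ridge, brow bulge,
  cheekbones and chin — precisely the rigid features surface matching
  relies on — plus smooth seeded lumps outside the facial region so heads
  differ between seeds. Radial displacement of a star-shaped surface
  cannot self-intersect, and the mesh stays watertight by construction.
  Fiducials (nasion, LPA, RPA) and the facial-segment vertex list are
  returned as ground truth; the nasion lies exactly on the midline.
* `paint_electrodes()` rasterizes the mesh into texture space to get a
  per-texel 3D position map, then paints filled discs of 4 mm default
  radius by *surface* distance around each electrode's surface
  projection, so discs stay circular on the curved head. Default texture
  2048 × 1024 (≈ 0.3 mm/texel at the equator). The texture seam sits at
  azimuth 189°, between electrode columns, so no disc is split across it.
* `make_mri_like()` voxelizes the head interior (parity ray casting),
  smooths, and places the volume in a world frame offset by a known rigid
  transform — so scalp-extraction round trips have exact ground truth.
* `make_chroma_photo()` renders a Lambertian-shaded head over a uniform
  key background together with its exact silhouette.
* `jitter_electrodes()` adds seeded isotropic Gaussian displacement; its
  mean displacement matches the chi(3) closed form in the tests.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: photogrammetric reconstruction artifacts
(holes, smearing, texture ghosting), hair and cap fabric geometry,
specular skin reflectance, non-circular or partially occluded electrode
prints, and anatomical realism of the head shape. The generator
demonstrates geometric correctness of the algorithms, not field
performance.

# Problem sizes and numerical choices

The shipped experiments run at sizes chosen to exercise the full
pipeline while staying comfortable on a laptop-class single core: heads
at subdivision 4 (2562 vertices, 5120 faces; facial segments of ~370
points), textures of 2048 × 1024, ten ~370² rasters per detection pass,
100 coregistration repetitions, and 50 labeling repetitions. The
coregistration simulation takes a few seconds, the full detection pass
under ten seconds.

Degenerate inputs are rejected rather than patched: empty segments,
coincident or collinear point sets (where the rotation solve loses rank),
constant-intensity textures, zero-spread scaling denominators, fiducials
with the nasion on the preauricular line, and label inventories that do
not match between templates all raise errors naming the problem. Tie
breaks are deterministic everywhere (lowest template index in votes;
descending cluster size then ascending z in merging; fixed composition
order in sampled rotations), so fixed seeds reproduce byte-identical
results.

# Known limitations

* Point-to-point ICP only; point-to-plane and non-rigid variants are out
  of scope, as is GPU acceleration.
* The landmark heuristic assumes a roughly hemispheric, roughly
  left-right-symmetric montage covering the scalp with ≥ 10 electrodes;
  exotic montages may need the manual landmark override that
  `label_majority_vote(landmarks = ...)` accepts.
* Labeling requires electrode counts to match the templates exactly —
  montages with missing electrodes are refused by design.
* The perspective camera model is not implemented; rendering is
  orthographic, which is what surface lookup needs but is not
  photorealistic.
* Structure-from-motion reconstruction itself is out of scope: the
  package consumes meshes, it does not build them from photographs.
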