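---
title: "Methods and design notes: 3D radial-glia morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes: 3D radial-glia morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the models and
procedures, the parameters that matter, what the synthetic phantoms do and
do not emulate, numerical choices, and the design decisions made where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The problem

Müller glia stretch radially across the retina — apical processes among the
photoreceptors, a cell body in the inner nuclear layer, lateral branches in
the plexiform layers, and a basal endfoot on the inner limiting membrane.
Quantifying their 3D morphology from confocal stacks requires four things
this package provides: (i) geometric standardization so that stacks from
different eyes are comparable voxel-for-voxel; (ii) quantitative quality
control; (iii) segmentation into a binary glia mask; and (iv) morphometrics
on that mask, including skeleton topology and apicobasal texture.

## Conventions

* Arrays are indexed `(z, y, x)`; calibration is carried as `(dx, dy, dz)`
  in µm and every µm-scaled output uses it explicitly. The source protocol
  never fixes an axis convention; this one is asserted throughout the code.
* After standardization the **apicobasal axis is the row (y) axis**, basal
  at row 0, apical at the last row. Zonation profiles carry an
  `orientation` field so apical-first plots are a presentation flip, not a
  recomputation.
* Masks are `{0,1}` in memory and written as 0/255 8-bit TIFFs for viewer
  compatibility.

## Quality metrics

`CNR = (µ_s − µ_ns)/σ_bg` with means measured in oval ROIs on a single
slice (inclusive ellipse inequality at pixel centres — deterministic raster
semantics), and `SNR = µ_s − µ_ns`. The SNR is implemented **verbatim as a
difference**: conventional SNR divides by a noise term, but the defining
protocol prints the plain difference and silently "fixing" it would make
results incomparable with the original tool. The suggested ROI sizes (cell
body 5×5 µm, protrusion 2×5 µm, endfoot 5×3 µm) ship as presets converted
to pixels via the calibration.

`z_profile()` additionally fits `log(mean_z) ~ z` by least squares and
reports `τ = −1/slope` (µm). The fit is an addition of this package — the
original workflow inspects decay visually — and is labelled as such.

## Subregion standardization

A line ROI drawn basal→apical defines a rigid in-plane transform mapping
the ROI onto a vertical segment. The output is
`ceil((L+σ)/dy)` rows × `ceil(width/dx)` columns × `ceil(depth/dz)` slices,
a pure function of parameters, calibration and ROI length — which is the
point: every stack in a batch comes out the same size. Open choices,
decided as follows:

* **Sigma side.** The σ extension (default 10 µm) exists to catch retinal
  curvature and the vasculature *under the endfeet*, i.e. basal tissue, so
  it is appended beyond the basal ROI end only: the ROI start sits
  `σ/dy` rows into the output, with rows 0…σ/dy covering the extension.
* **Rotation pivot.** Any pivot on the ROI line yields the same output
  window given the contract above (start at row σ/dy, line at the centre
  column); the implementation parameterizes by the ROI start. Flagged for
  comparison runs against the original macros, which do not state a pivot.
* **z window.** The standard (projection-drawn) variant takes slices from
  0; only the within-stack variant centres the window on the ROI's slice,
  shifting minimally to fit. Inferred from the existence of a separate
  within-stack tool.
* **Interpolation.** Bilinear with zero fill by default; nearest available
  so oracle tests can demand exactness. In-plane rotation assumes
  `dx == dy` (warned otherwise), the universal case for confocal rasters.
* A single image is paired with a single ROI; the original GUI's
  "add the ROI twice" workaround is not reproduced. Pairing is by
  lexicographic filename order and a count mismatch is an error, replacing
  the manual open-order convention, which is not reproducible headlessly.

## Theoretical PSF and Richardson–Lucy

The PSF is scalar-diffraction, paraxial (Born–Wolf):
`I(u,v) = |∫₀¹ J₀(vρ) exp(−iuρ²/2) ρ dρ|²` with `v = 2πNAr/λ` and
`u = 2πNA²z/(nλ)`, evaluated by 129-point Simpson quadrature and normalized
to sum 1. At focus this reduces to the squared Airy pattern, and the test
suite checks the lateral FWHM against `0.51 λ/NA` within 15%. The original
plugin's exact defocus model is unpublished; paraxial Born–Wolf is a
documented approximation of "theoretical PSF from Fraunhofer diffraction".

Richardson–Lucy uses the standard multiplicative update, default **1
iteration** (the protocol's setting for confocal data), FFT convolution
with reflective padding by half the PSF extent (avoids edge ringing on
cropped subregions, deterministic), non-negativity clipping and clipping to
the input bit range. A user-supplied PSF TIFF is accepted and renormalized
to sum 1 (`load_psf()`). Deconvolution of a small (PSF-scale) structure
measurably raises CNR after one iteration; on large structures with added
noise one iteration can *lower* CNR because noise sharpens too — the
method-comparison harness exists precisely to check such trade-offs per
dataset.

## Segmentation

All histogram methods operate on the whole-stack 256-bin histogram (8-bit
conversion first if needed): the data are treated as 3D throughout, not
slice-wise. Criteria: Otsu (between-class variance), Moments
(moment-preserving / Tsai), Percentile (cumulative fraction closest to the
target, default 0.5), Max-Entropy (Kapur–Sahoo–Wong). **Tie-break:** flat
criterion plateaus (e.g. an empty gap between two modes) resolve to the
plateau midpoint, so a two-value image thresholds strictly between its
modes; the oracle tests therefore check *criterion optimality* of the
returned threshold, which is tie-robust. A constant image has no valid
threshold and errors explicitly.

Hysteresis defaults are histogram-derived: high = Otsu, low = 0.5·high
(recorded in provenance, configurable); voxels above low survive only if
26-connected to a voxel above high. Connectivity is fixed at 26 everywhere
in 3D because glial processes are thin and diagonal. Rolling-ball
background is slice-wise grayscale opening with a non-flat ball structuring
element (not the classic paraboloid approximation), subtracted and clipped
at 0.

The `cytosol` and `membrane` reference pipelines correspond to macros whose
internal parameter values are not published; the defaults here are this
package's own, set on phantoms and versioned:

* `cytosol`: median radius `(0,1,1)` (z,y,x) → Otsu → speckles < 27 vox
  removed. The median is **in-plane only**: with `dz ≫ dx`, fine processes
  can be a single voxel thick in z and an isotropic-in-voxels median erases
  them.
* `membrane`: median `(0,1,1)` → hysteresis (Otsu/0.5) → speckles < 27 vox.

## Quantification

* **Surface** voxels have ≥ 1 of 6 face neighbours background or lie on the
  image border. `S_N` is reported in µm³ (count × voxel volume) —
  dimensionally a volume, kept because that is the convention of the
  feature table it reproduces — with a conventional µm² column emitted
  alongside so no information is lost.
* **EDT** uses the separable parabolic-envelope algorithm per axis with the
  physical `(dz, dy, dx)` metric (not voxel indices): with `dz ≫ dx`,
  index-metric distances would be badly wrong. Foreground infinities are
  seeded with a large finite sentinel (1e18 squared µm) because true
  infinities corrupt the envelope-intersection arithmetic.
* **Thickness** `T_N` is the mean EDT value over skeleton voxels — a local
  *radius* (centreline to surface). No factor 2 is applied; the maximum is
  reported as well.
* **Skeletonization** is homotopy-preserving layer-by-layer thinning:
  six directional subiterations per pass, deleting *simple points*
  (foreground 26-connectivity / background 6-connectivity, checked by
  explicit component analysis of the 3×3×3 neighbourhood) with endpoint
  preservation, candidates re-checked sequentially at deletion time. This
  is the same family as the published Lee-style thinning the original tool
  uses, without reproducing that plugin's Euler-LUT implementation detail.
  Two consequences worth knowing:
  * a cylinder's centreline is shorter than the solid by roughly one radius
    per flat cap (cap erosion) — the 10% length tolerances in the tests
    absorb this for the thin, elongated shapes the package targets;
  * small surface bumps can spawn spurious terminal branchlets; optional
    pruning (`prune_below_um`) removes terminal branches below a length
    threshold. **Default off**, matching the original default; the
    recovery tests run with 2 µm pruning, the standard advisory for
    spur removal.
* **Skeleton graph**: junctions are maximal 26-connected clusters of voxels
  with > 2 skeleton neighbours, counted once (naive per-voxel counting
  double-counts thick junctions); triple/quadruple points are clusters with
  3/4 incident branches; branch lengths are anisotropic step sums
  `√((Δx·dx)² + (Δy·dy)² + (Δz·dz)²)`, including the attachment step into
  each junction cluster; closed cycles (e.g. a torus skeleton) are single
  branches with no endpoints.
* Whether the original stats count junction voxels or clusters is unstated;
  cluster counting was chosen and is flagged for cross-validation.

## Zonation

Profiles average over the full 3D stack (`mean over (z, x)` per row),
consistent with "1D vector from 3D stack"; whether the original averages
the projection instead is flagged for cross-validation. The profile mean
therefore equals the stack mean exactly — a conservation law the tests
assert. Scale normalization is linear resampling with endpoints mapped to
endpoints. Mixed-length profile batches export with padded empty cells
(plus a warning) rather than erroring, because comparing unequal stacks
*before* normalization is a stated use of the tool.

## The phantom: a stated world

`phantom_spec()` defaults describe one fixed scene, chosen once:

* grid `12 × 160 × 140` voxels at `0.5 × 0.5 × 1.0` µm — an 80 µm tall,
  70 µm wide, 12 µm deep standardized tile, typical of a zebrafish larval
  retina subregion at confocal resolution;
* 2 cells (the defining group-comparability setup uses 2 cells at stalk
  radius 1.5 µm), vertical stalks spanning rows 6–94% of the height, an
  ellipsoidal soma at mid-height (2.5 × 4 × 2.5 µm radii), a conical basal
  endfoot widening to 3 µm, and one branch zone at 25–45% height with 3
  lateral branches of 5 µm × 1 µm radius per cell — a plexiform-layer-like
  arrangement;
* intensities 200 (foreground) over 10 (background), Gaussian read noise
  SD 5, exponential z decay τ = 50 µm, Poisson and PSF blur off by
  default; one seed fixes every stochastic stage.

Ground truth derives from the voxelized (not continuous) geometry, so mask
volume equality is exact and testable; skeleton length/junction/endpoint
truths are construction counts (stalk span + branch lengths; one triple
point and one tip endpoint per branch).

What the phantom does **not** emulate: curved tissue (curvature handling is
exactly what σ exists for), tiled cell packing, intensity heterogeneity
within cells, antibody-staining speckle, refractive-index aberrations. A
green recovery test therefore establishes that the algorithms are correct
on ideal radial geometry at realistic noise — not that any particular
microscope's data will segment well.

At the stated noise level (SD 5 against a 190-unit contrast), thresholding
margins are so wide that every noise realization produces the identical
mask: the group CoV of volume across eight replicates computed by
`scripts/acceptance.R` is 0%, comfortably inside the ≤ 20% comparability
guideline. This is the honest value of the stated world, not a tuned one;
raising the noise or enabling Poisson/PSF degradation makes the CoV move.

## Infrastructure choices forced by the environment

* No TIFF/image package exists in the supported R dependency set, so the
  format layer is a minimal baseline TIFF reader/writer (uncompressed,
  grayscale 8/16-bit and 32-bit float, both byte orders on read,
  resolution tags + ImageJ-style description). Tests cross-validate it
  against an independent Python reader/writer. Resolution tags are only
  trusted when a unit is actually declared (ImageJ `unit=micron`, inch or
  cm codes); a bare "resolution 1, unit none" is treated as uncalibrated.
* ImageJ `.roi` records are read and written directly per the published
  binary layout (magic `Iout`, type byte, big-endian bounding box, float
  line endpoints, stack position); archives are store-only ZIPs written
  with an in-package CRC32.
* Pipeline configuration is JSON (no YAML parser in the dependency set).

## Known limitations

* Thinning-based skeleton lengths under-measure blob-ended structures (cap
  erosion, above).
* The EDT of a mask with *no* background voxels is meaningless (sentinel
  distances); real masks always have background.
* `simple_3d` and the global thresholds use strict `>` for foreground;
  methods that define `≥` will differ by at most the threshold bin.
* Richardson–Lucy with many iterations amplifies noise; no regularization
  is provided (out of scope, as in the original).
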