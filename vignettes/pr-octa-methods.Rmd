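---
title: "Projection-resolved OCTA: methods, phantom design and validation"
author: "octapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projection-resolved OCTA: methods, phantom design and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

OCT angiography (OCTA) detects blood flow as inter-B-scan signal
decorrelation, but depth discrimination is corrupted by the *projection
(tailing) artifact*: the flickering shadow of a superficial vessel modulates
the OCT signal of every reflective structure beneath it, so the
decorrelation estimator reports spurious "flow" all the way down the axial
scan line. En-face images of deep slabs then duplicate the superficial
vascular pattern, and the intermediate and deep capillary plexuses (ICP,
DCP) cannot be separated from the superficial vasculature.

`octapr` implements the projection-resolved (PR) rule that removes this
artifact, the fractional anatomic slab scheme that separates the four
retinal plexuses (RPCP, SVP, ICP, DCP) and two complexes (SVC, DVC), the
registration steps that make depth profiles comparable across subjects,
and three capillary-density representations. Because no instrument data
ship with the package, a synthetic volumetric phantom with per-voxel
ground truth exercises every stage.

## The projection-resolution rule

Let $D(x,y,z) \in [0,1]$ be the SSADA-scale decorrelation and $R(x,y,z)$
the reflectance, with $z$ increasing from the vitreous downward. The
reflectance-normalized decorrelation is

$$\bar D = \frac{D}{\max(R/R_{\mathrm{ref}},\ \varepsilon)},$$

with $R_{\mathrm{ref}}$ the median reflectance over the inner retina
(ILM to OPL/ONL). A voxel is classified as *in-situ* flow iff

$$\bar D(x,y,z) \ge \theta \quad\text{and}\quad
  \bar D(x,y,z) > \max_{z' < z} \bar D(x,y,z'),$$

i.e. it is suprathreshold and strictly higher than **all** shallower
voxels of its axial line; all other voxels are set to zero. Consequences
that the tests assert as invariants: retained $\bar D$ values strictly
increase with depth in every axial line; the first suprathreshold voxel
of a line is always retained (the maximum over the empty set is
$-\infty$); ties with the running maximum are artifact (a shadow can at
most replicate its source); the operation is idempotent; and the output
is everywhere $\le D$ with support inside the suprathreshold set.

Numerical choices:

* **Normalization floor** $\varepsilon = 0.5$ (of $R_{\mathrm{ref}}$).
  The floor bounds the noise amplification that division by reflectance
  produces in optically empty or dark tissue. A small floor (e.g. 0.1)
  lets vitreous noise — reflectance near zero — be amplified tenfold in
  $\bar D$, poisoning the per-line running maximum and erasing genuine
  flow beneath; 0.5 keeps the amplification at most twofold while still
  boosting flow in the darker nuclear layers. The functional form sits
  behind a parameter object so alternatives are pluggable.
* **Threshold** $\theta = \text{mean} + m\cdot\text{SD}$ of $\bar D$ in
  an avascular noise region, the outer nuclear layer band restricted to
  columns without inner-retinal flow (so projection tails do not inflate
  the statistics). $m = 2.33$ (the default, $\approx$ the 99th Gaussian
  percentile) is used for the threshold function itself; the pipeline
  passes $m = 3$ because the phantom's clamped, floored noise is
  heavier-tailed in normalized space than the Gaussian the 2.33 z-score
  presumes, and the per-window false-positive load must stay below the
  peak-detection prominence.

## Slab geometry

Boundaries (inner to outer): ILM, NFL/GCL, IPL/INL (= outer limit of the
ganglion cell complex, GCC = NFL + GCL + IPL), INL/OPL, OPL/ONL, RPE.
The plexus slabs are fractional bands between boundaries:

| slab | inner | outer |
|------|-------|-------|
| RPCP | ILM | NFL/GCL |
| SVP | NFL/GCL | inner 80% of GCC |
| ICP | inner 80% of GCC | inner 50% of INL |
| DCP | inner 50% of INL | OPL/ONL |
| SVC | ILM | inner 80% of GCC |
| DVC | inner 80% of GCC | OPL/ONL |

Bands are half-open $[z_{in}, z_{out})$ with voxel-center membership, so
the four plexus bands tile $[\mathrm{ILM}, \mathrm{OPL/ONL})$ exactly —
an asserted invariant. One-voxel inter-plexus slabs are centred midway
between the SVP limit and IPL/INL (the IPL space) and at the INL
midpoint; the depth rule for "through the inter-plexus space" is this
package's choice since only the intent is anatomically fixed.

## Registration

Volumes are aligned at the RPE by integer per-column shifts (idempotent;
the deepest rounded RPE is the common target so nothing shifts out the
top). Depth is then rescaled piecewise-linearly per column so each major
structural layer (ILM+NFL, GCL+IPL, INL, OPL, and the outer retina)
matches a reference subject's thickness. Flow is resampled by **forward
nearest-neighbour splatting** — each source flow voxel lands in exactly
one reference plane — because gather-style interpolation would inflate
flow-voxel counts by the thickness ratio and smear values across the
threshold; reflectance uses linear interpolation. The transverse axis is
scaled by a 1-D affine map sending disc and fovea centers to the
reference positions, nearest-neighbour for flow.

## The phantom

The generator emulates a 70 kHz spectral-domain acquisition: 3.1 µm
axial voxels and 15 µm transverse sampling at full scale (304 × 304 ×
512 supported). The default study conditions are desk-scale:

* `widefield`: 456 × 28 × 192 voxels at (30, 30, 3.1) µm — a thin swath
  along the maculopapillary axis from nasal of the disc (x = −5 mm) to
  8.65 mm temporal, covering all four anatomic regions. Used for depth
  profiles, plexus detection, merge-locus recovery and the demo.
* `macula`: 160 × 96 × 192 at (15, 15, 3.1) µm, fovea-centred.
* `flat`: 200 × 200 × 160 at (15, 15, 3.1) µm, 3 × 3 mm, no pit, no
  disc effects, no FAZ, no large vessels — the calibration bench for
  area-fraction recovery.

**Anatomy.** Boundary surfaces are built bottom-up from a flat RPE with
layer base thicknesses 31 (NFL), 93 (GCL+IPL), 43.4 (INL), 34.1 (OPL)
and 155 µm (outer retina) under 80.6 µm of vitreous — voxel multiples of
3.1 µm so the flat periphery has reproducible integer boundary planes. A
Gaussian foveal pit (default 100 µm deep, σ = 0.35 mm) thins the four
inner layers proportionally; peripapillary NFL thickening adds a
Gaussian 62 µm (σ = 1 mm) around the disc center at (−4, 0) mm.

**Vasculature.** Each plexus is a single-voxel-thick capillary sheet
hosted in its anatomic band (real plexuses occupy thicker, 1–24-voxel
slabs; one voxel is the cleanest geometry for recovery testing and is
stated as a phantom simplification). Capillary meshes are the ridge
sets of Voronoi tessellations of jittered-grid (blue-noise) seeds — the
"lobular" texture — with the lobule size chosen from the capillary width
(15 µm) and target fraction, and the achieved area fraction calibrated
essentially exactly by thresholding the ridge coordinate at its
empirical quantile (per radial-density bin where the target varies).
Table-scale defaults: SVP 0.30 (declining to 55% of that by 7 mm), ICP
0.21, DCP 0.14, RPCP 0.30 over the peripapillary annulus. The RPCP is
drawn as arcuate streamlines fanned from the disc edge, so its density
falls off ~1/r by geometry; large-vessel trees (width 0.1 mm, tapering,
branching) leave the disc obliquely like the real arcades. ICP and DCP
centerlines sit at the inner and outer INL borders at the fovea and
approach mid-INL linearly with eccentricity, coalescing at the
configured merge eccentricity (default 6.5 mm); voxelized sheets are
clamped to stay inside their half-open host bands, so fully merged
sheets occupy adjacent planes while the continuous centerline separation
is exactly zero. A foveal avascular zone (radius 0.3 mm) excludes all
retinal flow, rimmed by a one-pixel perifoveal ring; sparse vertical
interconnecting segments join the SVP to ICP and DCP; a homogeneous
choriocapillaris slab (fraction 0.65, two planes) sits below the RPE.
Quantitative capillary geometry (width, lobule size) is not constrained
by published densitometry; the values are plausible placeholders.

**Rendering.** Reflectance is a per-layer base level (NFL 1.0, GCL+IPL
0.65, INL 0.45, OPL 0.60, ONL 0.28, RPE 1.15, choroid 0.5, vitreous
0.04, arbitrary units) under multiplicative log-normal speckle (contrast
0.25). In-situ decorrelation draws U[0.20, 0.35] for capillaries and
U[0.45, 0.60] for large-vessel trees — both above the 0.12 large-vessel
threshold voxel-wise, with vessels brighter than capillaries as in real
SSADA data; this separation is what lets a smoothed 0.12 threshold
isolate large vessels at realistic capillary densities. Projection
tails: each voxel below an in-situ voxel whose local reflectance exceeds
the gate (0.15) receives the source's normalized decorrelation
attenuated by $\alpha^{\Delta z}$ ($\alpha = 0.8$ per mm), converted
back to stored decorrelation by the local normalization factor. The
attenuation acting in *normalized* space encodes the physical fact that
a shadow's decorrelation scales with the reflectance of the tissue it
falls on; under uniform reflectance the stored tail is exactly
`source × alpha^gap`. Gaussian background noise (SD 0.02) is added and
the result clamped to [0, 1]. An `increasing` flow mode assigns each
axial line's in-situ voxels strictly increasing normalized targets — the
construction under which PR provably retains 100% of in-situ flow.

**What the phantom does not emulate.** Optics and speckle physics, raw
spectrum SSADA statistics, eye motion, vessel-diameter continua,
capillary tortuosity in depth, flow pulsatility, and the choroid beyond
a homogeneous slab. Passing tests show the *pipeline machinery* is
correct under known geometry; they are not evidence about instrument
noise regimes.

## Measurement calibration at desk scale

The depth-density sampling window defaults to the 0.1 × 0.8 mm of the
sampling scheme it implements. At the 30 µm wide-field grid such a
window holds only ~80 columns, so counting noise alone is ±0.045 — the
pipeline therefore samples 0.4 × 0.8 mm windows (~340 columns), matching
the ~355 columns a 0.1 mm window holds at full 15 µm sampling. For the
same reason the density-recovery experiment measures a 1.5 × 1.5 mm
window on the flat phantom. Peak detection uses prominence 0.02 by
default; the pipeline passes 0.05, which sits between the phantom's
artifact-survivor noise floor (~0.03, from shadows immediately below
vessels that noise pushes past their source) and the smallest true
plexus peak (~0.09). The recall guarantee — every plexus with area
fraction ≥ 0.10 detected — holds at 0.02 and is tested there.

The merge-locus estimator reports the smallest eccentricity from which
all more peripheral profiles show a single DVC peak. With 3.1 µm voxels
the last ~0.5 mm of the linear separation ramp is sub-voxel, so the
first *detectable* merged profile sits one 0.5 mm step inside the
configured locus: a 6.5 mm configuration is recovered as 6.0–6.5 mm.

## Degenerate inputs and tie-breaks

Zero-thickness slabs project to flagged-absent values, not zeros; depth
planes with no unmasked columns are NA, not zero. Peak plateaus count
once, at the central plane. Equality with the running maximum is
artifact. Columns whose layer thickness vanishes where the reference's
does not are flagged and excluded from profiles. The large-vessel mask
keeps components strictly larger than 50 pixels under 8-connectivity;
the conventional 20 × 20 smoothing window has no centre pixel, so the
kernel is built on the 20 × 20 support inside a 21 × 21 array, with
σ = 5 px (window/4).

## Known limitations

* In-situ retention on noisy phantoms is ~70%: where vessels of
  different plexuses overlap transversely, noise can flip the normalized
  ordering and the deeper vessel is zeroed. This mirrors the method's
  real behaviour (deep flow directly beneath strong superficial flow is
  the hard case) and is reported, not hidden.
* The peripapillary window is partially covered by the large-vessel
  mask (arcade exits plus the near-threshold smoothed background of the
  very dense peripapillary SVC), so its profile is noisier than the
  macular ones.
* Layer segmentation of real scans is out of scope: layer models come
  from phantom truth or an external surface file, keeping the geometry
  module pure.
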