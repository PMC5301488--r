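# octapr

Projection-resolved OCT angiography (PR-OCTA) in R: flow-projection
artifact removal, anatomic slab segmentation of the four retinal
vascular plexuses, and depth-resolved capillary density analysis —
exercised end-to-end on a synthetic volumetric retinal phantom with
per-voxel ground truth.

## The problem

OCTA images blood flow as inter-B-scan signal decorrelation, without
dye. Superficial vessels, however, cast flickering shadows on every
reflective layer beneath them, so the decorrelation estimator reports
spurious "flow" in a long tail under each vessel. This projection
artifact duplicates the superficial vascular pattern onto deeper slabs
and defeats attempts to image the intermediate and deep capillary
plexuses (ICP, DCP) separately.

The projection-resolution rule removes the artifact per axial scan
line. With reflectance-normalized decorrelation
`Dbar = D / max(R / R_ref, eps)`, a voxel is retained as in-situ flow
iff

```
Dbar(x, y, z) >= theta   and   Dbar(x, y, z) > max_{z' < z} Dbar(x, y, z')
```

— suprathreshold and strictly higher than **all** shallower voxels of
its axial line (`theta` = mean + k·SD of an avascular noise band); all
other voxels are zeroed. A shadow is always weaker than its source
after reflectance normalization, so it can never beat the running
maximum; real flow in deeper plexuses can.

On top of the resolved volumes the package provides:

* **Slab geometry** — fractional anatomic bands: RPCP (ILM–NFL/GCL),
  SVP (NFL/GCL–inner 80% of the ganglion cell complex), ICP (outer 20%
  of GCC–mid-INL), DCP (mid-INL–OPL/ONL), the SVC/DVC complexes, and
  single-voxel inter-plexus slabs. The plexus bands provably tile the
  inner retina.
* **Registration** — RPE flattening, per-layer depth rescaling to a
  reference subject (flow mass preserved by forward splatting), and
  disc–fovea transverse scaling.
* **Density analysis** — depth-resolved capillary density profiles in
  0.1 × 0.8 mm windows, a cross-sectional super-voxel
  (0.1 × 0.8 × 0.01 mm) density map, transverse per-plexus profiles
  along the maculopapillary axis, a Gaussian-smoothed / 0.12-threshold /
  >50-pixel-component large-vessel mask, and repeatability CoV.
* **Plexus detection** — prominence-based peaks/troughs, labeling by
  anatomic band, and estimation of the eccentricity where ICP and DCP
  merge into one layer.
* **Synthetic phantom** — 70 kHz SD-OCT geometry (3.1 µm axial voxels),
  layered anatomy with foveal pit and peripapillary NFL thickening,
  lobular Voronoi-ridge capillary meshes with calibrated area
  fractions, radial peripapillary capillaries, arcade trees, a foveal
  avascular zone, ICP/DCP merging at a configurable eccentricity,
  exponential projection tails, and full per-voxel ground truth.

## Worked example

```r
library(octapr)

cfg <- phantom_config("widefield", seed = 1)   # disc-to-periphery swath
sim <- simulate_phantom(cfg)
pr  <- pr_resolve(sim$volume, sim$truth$layer_model, multiplier = 3)

art <- sim$truth$artifact_flow
ins <- sim$truth$in_situ_flow
kept <- pr$volume$decorrelation > 0
round(100 * c(artifact_survival = sum(kept & art) / sum(art),
              insitu_retention  = sum(kept & ins) / sum(ins)), 1)
#> artifact_survival  insitu_retention
#>               5.0              70.4
```

Of about 1.1 million artifact-only voxels, 5% survive on this noisy
phantom (0% on a noise-free one); the in-situ flow lost sits where
vessels of different plexuses overlap transversely. Depth profiles then
recover the plexus architecture:

```r
fl <- flatten_to_rpe(pr$volume, sim$truth$layer_model)
nd <- normalize_depth(fl$volume, fl$layers, fl$layers)
band <- resolve_slab(standard_plexus_specs()$SVP, nd$layers)
lvm <- build_large_vessel_mask(project_flow_max(nd$volume, band)$image)

prof <- depth_density_profile(nd$volume, c(1.5, 0), "parafoveal",
                              mask = lvm, window = c(0.4, 0.8))
f <- assign_plexus_labels(find_peaks_troughs(prof, 0.05), nd$layers,
                          center = c(1.5, 0), volume = nd$volume)
subset(f$peaks, plexus != "unassigned")
#>     z    height prominence plexus
#>    48 0.3005780 0.30057803    SVP
#>    69 0.1878613 0.17919075    ICP
#>    80 0.1040462 0.07225434    DCP
```

Three peaks — SVP in the GCL, ICP at the inner INL border, DCP at the
outer INL border — with densities ordered SVP > ICP > DCP, as in healthy
maculae. At 7 mm eccentricity the same call returns two labeled peaks
(SVP and a merged ICP/DCP), and scanning profiles every 0.5 mm puts the
merge locus at 6.0 mm for the configured 6.5 mm (the last half
millimetre of separation is below one 3.1 µm voxel).

`run_demo(out_dir, seed)` runs the whole pipeline (simulate → resolve →
register → density → plexus → en-face → report) and writes profile and
findings CSVs, en-face TIFFs and a composite cross-section; the
`analysis/01…05` scripts are the same workflow as a narrated sequence
with figures under `results/`.

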