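# vmir — vascular and metabolic imaging from 3D autofluorescence volumes

Whole-organ fluorescence cryo-imaging captures the intrinsic NADH and FAD
signals of frozen rodent organs. Hemoglobin quenches that autofluorescence,
so blood vessels appear as a connected *dark* network inside the bright
tissue foreground. `vmir` turns that observation into a label-free 3D
vascular imaging tool for researchers quantifying vascular injury and
remodeling (radiation damage, hypertension, angiogenesis) in kidney, heart,
liver and lung, alongside the mitochondrial redox state from the very same
volumes — no contrast agents, fillers, or clearing solvents.

## What it computes

**Segmentation** (dark-vessel mode): intensities are remapped to the full
16-bit range over the whole volume, each slice is inverted so vessels become
bright, a rolling-ball background subtraction (grayscale opening by a
spherical element of radius at least the largest vessel radius) removes the
remaining illumination field per slice, contrast is stretched again, and the
volume is binarized (triangle threshold by default) with small-component
filtering and optional region exclusion (heart cavities, renal medulla).
Bright structures (FITC-filled airways, endothelial reporter red channel)
use the identical pipeline without the inversion step.

**Tracing**: the mask is thinned to a curve skeleton by distance-ordered
homotopic thinning, contracted into a junction/segment graph, rooted at the
fattest vessel origin ("largest starting point"), and reported as branches
with depth (root = 1, +1 per bifurcation), mean diameter (twice the mean
inscribed radius from the anisotropy-aware Euclidean distance transform
along the centerline) and length.

**Quantification**:

- Dice overlap `Dice = 2|A∩B| / (|A|+|B|)` between two segmentations;
- Murray's-law branching analysis: for each depth *k*, the summed cubed
  diameters of parents, `Σ_p (D_p^k)³`, against daughters,
  `Σ_d (D_d^{k+1})³`; a minimum-work-compliant tree falls on the identity
  line (slope 1, intercept 0) under ordinary least squares;
- voxelwise redox ratio RR = NADH/FAD with flat-field calibration and
  tissue-masked summary statistics;
- vascular volume fraction as a density biomarker.

**Phantoms**: a synthetic generator produces Murray-compliant vascular
trees (daughter diameters satisfy `d₁^m + d₂^m = D^m` exactly,
minimum-work bifurcation angles, optional asymmetry, tortuosity and calibre
cutoff) rasterized as dark capsules in a noisy, unevenly illuminated
foreground, with ground-truth masks and trees — the validation surface for
the whole pipeline.

## Worked example

```r
library(vmir)

ph  <- make_phantom(phantom_spec(seed = 1))       # 128^3, 10 um voxels
par <- segmentation_params(rolling_ball_radius_um = 60)
seg <- segment_vasculature(ph$volume, par)
dice(seg, ph$mask)
#> Dice = 0.9984  (|A| = 4640, |B| = 4625, |A ∩ B| = 4625)

tree <- build_tree(seg)
tree
#> <vmi_tree> 15 branches in 1 component(s), max depth 4
#>   diameters 26.6-56.7 um, total length 4031 um
head(branch_table(tree), 3)
#>   id parent_id depth mean_diameter_um length_um is_terminal
#> 1  1        NA     1         56.65433  420.7107       FALSE
#> 2  2         1     2         45.09253  364.0154       FALSE
#> 3  3         1     2         44.51608  356.8070       FALSE
```

The Dice of 0.998 says the dark-voxel segmentation recovered essentially
every ground-truth vessel voxel; the traced tree recovers all 15 generated
branches with per-depth mean diameters within ~7% of the generating tree
(the residual bias comes from voxelization and the junction-adjacent
centerline points). On a Murray-compliant tree the branching analysis
returns the identity line:

```r
fit <- murray_fit(murray_depth_sums(generate_tree(
  phantom_spec(levels = 5, asymmetry = 0.3, min_diameter = 20, seed = 3)),
  exclude_terminal_parents = TRUE), TRUE)
fit
#> Murray's-law fit over 4 depth pairs: slope = 1.0000, intercept = 0 um^3, r^2 = 1.00000
#>   (identity line slope 1, intercept 0 = perfect compliance)
```

## Command line

A single entry point (installed at `exec/vmi`, or call `vmir::vmi_run()`):

```
vmi segment  --in stack.tif --spacing 10,10,10 --radius-um 300 --out mask.tif
vmi trace    --mask mask.tif --spacing 10,10,10 --out tree.swc --table branches.csv
vmi dice     --a a.tif --b b.tif
vmi murray   --table branches.csv [--exclude-terminal] --out murray.csv
vmi redox    --nadh n.tif --fad f.tif --spacing 10,10,10 --out rr.tif
vmi phantom  --spec spec.json --seed 1 --out-dir phantom/
vmi pipeline --in stack.tif --spacing 10,10,10 --radius-um 300 --out-dir out/
```

Spacing is always supplied explicitly (never parsed from TIFF tags); every
run writes a `provenance.json` with its inputs, parameters and version.
I/O is plain multi-page TIFF (8/16-bit unsigned or 32-bit float) plus SWC
and CSV for trees.

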