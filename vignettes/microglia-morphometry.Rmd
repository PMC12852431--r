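---
title: "Measuring microglial morphology: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring microglial morphology: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microgliaMorph)
```

## The measurement problem

Microglia are the resident immune cells of the retina and brain. Their
morphology tracks their activation state: surveillant ("ramified") cells
have a small, round soma and a wide territory of thin branching processes;
activated cells retract processes and show enlarged, often elongated or
rod-like somas, with increased Iba-1 expression. A morphometric pipeline
therefore needs five per-cell quantities from a calibrated 2-D
fluorescence field: soma area, a summary of process extent
(skeletonization), the territory the processes span (arborization), a soma
shape descriptor (Feret's Diameter Ratio), and soma fluorescence intensity
comparable across images.

This vignette explains how each quantity is defined here, which parameters
matter, what the synthetic-data generator does and does not emulate, and
the numerical choices a maintainer should know about.

## Data model and calibration

A field is a numeric matrix on a 0--255 working intensity scale with a
pixel pitch in µm/px (`field_image()`, `pixel_calibration()`). Multi-plane
TIFF stacks are collapsed by maximum-intensity projection by default
(`project_zstack()`): fields are optical sections through specific retinal
layers, and max projection preserves thin processes that appear in only one
section. 16-bit input is rescaled linearly so full scale maps to 255.

The study design samples fields of 0.1502 mm². The raster convention here
is 1024 × 1024 px with

```{r}
default_field_geometry()$calibration$microns_per_pixel
```

µm/px, chosen so that the physical field area is exactly 0.1502 mm². The
pitch (~0.38 µm/px) is ordinary for high-NA fluorescence imaging and keeps
pixel-quantization error small relative to a ~10 µm soma; coarser sampling
(e.g. ~0.76 µm/px) measurably degrades Feret diameters of small somas. Any
consistent (width, height, pitch) triple is accepted everywhere.

Coordinates are 0-based pixel centres, origin top-left; areas are pixel
counts × (µm/px)² unless stated otherwise.

## Segmentation

Soma detection (`segment_somas()`) is deliberately simple and fully
parameterized (`segmentation_params()`):

1. optional Gaussian smoothing (`smoothing_sigma_px`, default 0);
2. a global threshold (Otsu by default, or fixed);
3. morphological opening with a disk (`soma_opening_radius_px`, default
   3 px) to erase thin processes;
4. 8-connected components, an inclusive physical-area filter
   (15--300 µm² by default), and a border policy.

Two defaults deserve comment. *Smoothing is off by default*: a global Otsu
threshold already sits several noise standard deviations above background
on typical fields, while pre-smoothing spreads the blur halo around cells
into a continuum that biases the global threshold upward — on simulated
fields an extra 1 px of smoothing raised the threshold above the
thin-process intensity and erased the processes entirely. *The opening
radius is 3 px*, about half a small soma radius at the default pitch: it
removes structures a few pixels wide (processes) while leaving somas with
semi-minor axes down to ~3 µm essentially intact (the osculating radius at
the tip of a 5.5 × 3 µm soma is ~4.3 px, safely above the disk radius).

Full-cell masks (`extract_cell_masks()`) re-threshold without the opening
and partition the foreground among the detected somas by nearest-seed
geodesic propagation (8-connected wavefronts; the lowest label wins on
equidistant ridges, making the partition deterministic). Foreground
components containing no soma — debris, specks — stay unlabelled. Because
the point spread and noise fragment thin processes at threshold, a
morphological closing (`gap_closing_radius_px`, default 2 px) is applied
*for connectivity only* before the partition: without it roughly a quarter
of the process pixels on realistic simulated fields end up in soma-free
fragments and would be dropped; reported masks still contain only
thresholded foreground pixels.

Border policy: somas touching the field border are excluded from
morphometry by default (partial cells bias every shape metric) but kept for
counting (a partial cell still occupies the counting frame). Both policies
are explicit arguments and are recorded in the per-run configuration.

## The five measurements

**Soma area** is the soma mask pixel count × pixel area.

**Feret diameters and FDR.** F_max and F_min are the longest and shortest
distances between parallel tangents to the soma contour. Both are
support-function quantities, so they are computed exactly on the convex
hull of the traced contour: F_max as the largest antipodal vertex distance
and F_min as the least width over directions normal to hull edges. The
contour vertices are boundary *pixel centres*: centres sample the
underlying contour essentially without bias, whereas pixel corners would
inflate both diameters by ~1 px and bias the ratio of a 3:1 ellipse
downward by ~3%. FDR = F_max/F_min ≥ 1 by construction; somas with
FDR ≥ 3 are classified rod/amoeboid (inclusive boundary), below 3
ramified. Note the quantization floor: for a rasterized circle of radius
30 px the measured FDR is 1.010, because the integer radius places lattice
points exactly on the circle along some axes (F_max = 60.000 exactly)
while the minimum lattice width is 59.40 px. No contour-based estimator
beats this at that sampling; it shrinks with radius.

**Skeletonization** (`skeletonize_cell()`) thins the full-cell mask to
1-px-wide centrelines with the Zhang–Suen algorithm, which preserves
8-connected topology (the skeleton has exactly as many components as the
mask). The study's "skeletonization area" is reported as skeleton pixel
count × pixel area (µm²); a path length (µm) is exported alongside — the
pixel count with diagonal-only adjacencies weighted √2 — so either
interpretation of "skeleton extent" is recoverable from the same table.

**Arborization area** (`arborization_area()`) is the shoelace area of the
convex hull of the full-cell mask's pixel-corner point set. Corners are
used here (unlike for Feret) because the hull must dominate the mask's own
pixel area — the territory containing the cell cannot be smaller than the
cell.

**Intensity.** The raw value is the arithmetic mean grayscale value of the
soma pixels; pixels within 2 px (dilated) of *other* cells' masks are
excluded first, so a bright neighbour cannot bleed into the measurement.
Cross-image normalization (`fit_normalization()`) estimates a robust
background (median outside all dilated cell masks) and a robust bright
anchor (99.5th percentile inside cell masks) and maps them affinely onto
fixed targets (10 and 240 by default; all four knobs are configurable).
Because medians and quantiles are equivariant under increasing affine
maps, any gain/offset change of the acquisition that does not clip leaves
normalized soma means invariant up to segmentation jitter (< 1% in tests).
The functional form is a package reconstruction: the normalization goal is
part of the method, the algorithm is not published, so the two-anchor
affine model was chosen as the simplest model that exactly cancels the
acquisition model it is tested against. Raw and normalized means are both
exported, since published intensity figures do not state which scale they
use.

## The synthetic-field generator

`generate_field()` renders what the segmentation stage needs to be tested
against: elliptical somas (semi-axes 3.0--5.5 µm, i.e. soma areas
~28--95 µm²) at intensity 200, 3--6 primary processes per cell (random
walks of 3--6 segments, 15--40 µm total, 3 px wide, optional one
bifurcation) at intensity 120, on background 20; then Gaussian PSF blur
(σ = 1 px), additive Gaussian noise (sd 8), an affine gain/offset, and a
clip to [0, 255]. Somas and branches are composited by per-pixel maximum,
so soma interiors stay exactly at the soma intensity before blur — which
is what makes the exact mean-intensity ground truth possible. One integer
seed fully determines placement, trees and noise.

Planted cells are *territorial*: soma centres keep a minimum spacing
(55 µm by default), each cell's branches are confined to a territory
radius of half its nearest-neighbour distance and kept outside the soma
ellipse, and primary branches radiate at jittered regular angles. Real
microglia tile the tissue in exactly this way; the choice also keeps
per-cell ground-truth comparisons meaningful, because heavily
interdigitated branches would be assigned to whichever soma is
geodesically nearer — a property of the tissue, not a measurement error.

Ground truth records, per cell: centre, semi-axes and orientation, soma
area πab, Feret diameters 2a and 2b, FDR a/b, all branch polylines with
total length, the hull area of soma boundary plus branch vertices
(shoelace), and the pre-acquisition mean soma intensity.

What the generator does **not** emulate: photoreal PSFs, vignetting and
illumination gradients, Poisson (signal-dependent) noise, overlapping or
touching cells, 3-D structure, and intensity heterogeneity within a cell.
Passing the recovery tests therefore shows the measurement chain is
correct and stable under simple noise — not that segmentation will be
reliable on arbitrary real material, where contrast, clutter and cell
density can be far worse.

### What recovery tests can resolve

On noise-free, blur-free fields the pipeline recovers the planted count
exactly, soma areas within a few percent, and centroids within a pixel.
FDR and hull area are compared with ground truth at the per-field *median*
absolute error (< 5%): at realistic soma sizes (~8--15 px semi-axes) pixel
quantization alone contributes 3--4% per-cell scatter to F_min, so a
per-cell 5% band is not a meaningful target at this sampling, while the
median tests the same recovery claim without loosening the band. On noisy,
blurred fields the count is still recovered and hulls are typically within
a few percent, but branch *tips* blur below threshold, so skeleton length
and arborization are mildly conservative there.

## Study design, counting and statistics

`sampling_plan()`/`enumerate_fields()` encode the sampling frame: four
quadrants × three eccentricity zones = 12 fields per retina; six retinas
per group give 72 fields per group per time point and 144 per age with two
groups. Counts convert to densities by dividing by the physical field area;
both the raw per-field count and cells/mm² are emitted, since published
figures use both presentations. For the OS and NFL/GCL layers the
summaries carry counts only (those layers are counted, not systematically
measured); OPL and IPL carry the full variable set.

`run_study_contrasts()` runs, per (layer, variable): one-way ANOVA across
ages within each group with Tukey–Kramer post hoc pairs (valid under
unequal group sizes), and a two-sided Mann–Whitney U test between
genotypes at each age with the percent change of the test-group mean
relative to control. The Mann–Whitney p-value is exact by enumeration when
the samples are tie-free and small (arrangement count under a configurable
cap), otherwise a midrank normal approximation with continuity correction;
U_a + U_b = n_a·n_b always holds. Stars follow strict thresholds
(p < 0.05 `*`, < 0.01 `**`, < 0.001 `***`, < 0.0001 `****`; a p exactly at
a threshold gets the weaker label). Degenerate inputs resolve by limits:
all values identical gives F = 0, p = 1; zero within-group variance with
unequal means gives p = 0.

Two design points are worth making explicit. First, the *unit of
analysis*: the default pools individual cells within (group, age, layer),
matching figures in which each data point is one cell; pooled cells are
pseudo-replicates with respect to animals, so a per-field pooling mode
(`pooling = "field"`, per-field medians) is provided as the conservative
alternative. Second, *multiplicity*: no correction is applied across
layers and variables by default, mirroring the study design; a
Benjamini–Hochberg flag (`fdr_adjust`) appends an adjusted-p column when
wanted. Calibration is checked by simulation (`simulate_study()`): under a
null generator the rejection rate of the nominal-α tests (ANOVA omnibus
and Mann–Whitney) stays inside binomial bounds of 5%; Tukey-adjusted pairs
are excluded from that pooled rate because they control their family-wise
rate by design and would deflate it. A planted 30% soma-area shift at 60
cells/group is detected with power above 0.9 — per-cell variability is
simulated at a coefficient of variation of ~0.25, typical of soma-area
distributions.

Schematic intensity panels use `gray_tone()`: intensities on the 0--255
working scale are clipped onto a 0--250 display range (whiter = brighter),
matching the grayscale convention of published schematic figures; 0--250
is display-only and never enters measurement.

## Pipeline orchestration

`cmd_simulate()`, `cmd_measure()` and `cmd_stats()` (and the
`inst/cli/microglia-morph` wrapper) bind the stages together behind one
YAML configuration (`pipeline_config()`), and every run writes its
resolved configuration next to its outputs, so each of the reconstruction
choices above is auditable per run. Simulation is governed by one seed;
measurement is seed-free and deterministic; the statistics stage records
whether each Mann–Whitney p was exact or approximate. Problem sizes used
by the test-suite simulations — a dozen 1024² fields, null studies of 200
cells per stratum, 200 power replicates at 60 cells/group — were chosen as
the smallest sizes at which the checked properties are statistically
resolvable.

## Known limitations

- Soma delineation after opening can retain 1--2 px nubs where a thick
  process joins the soma; on small somas this adds a few percent of
  scatter to F_max. Opening radius and area bounds are the knobs to tune
  per dataset.
- FDR of near-circular somas carries the lattice quantization floor
  described above (~1% at 30 px diameter-equivalent radius, larger for
  smaller somas).
- The watershed-free geodesic partition assigns contested process pixels
  by distance only; intensity ridges between touching cells are ignored.
- No interactive curation: batch mode exports label TIFFs
  (`write_label_tiff()`) for external review instead.
- Statistics treat cells (or fields) as exchangeable within strata; there
  is no animal-level mixed model.
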