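---
title: "Quantifying meiotic spindle pole focus: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying meiotic spindle pole focus: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindlemorph)
```

## The biological problem

Plant meiocytes build their division spindles without centrosomes.
Minus-end-directed kinesin-14A motors gather microtubule minus ends into
focused poles; when such a motor is lost — as in the classic maize
*divergent spindle 1* (*dv1*) mutant — metaphase I spindles remain splayed,
with broad, unfocused poles, sometimes fragmenting into multiple or
tripolar spindles. spindlemorph quantifies this phenotype from two-channel
3D immunofluorescence stacks (tubulin + DNA) and from 4D live-imaging
series, and carries the downstream statistics (ANOVA letter groups,
proportions, qPCR relative expression) and the CAPS genotyping assays used
to track the mutant alleles in segregating material.

## The morphometric model

Spindle shape is summarized by three lengths measured per half-spindle and
one derived ratio:

* **W~C~** — width of the metaphase plate, the chromosome mass at the
  spindle equator (µm);
* **L** — half-spindle length, from the plate centre to the pole (µm);
* **W~S~** — spindle width at a fraction *f* of L from the plate (default
  *f* = 0.75, i.e. three quarters of the way to the pole);
* **focus ratio W~S~/W~C~** — near 0 for a tightly focused (conical)
  half-spindle, near 1 when the fiber bundle never converges (a cylinder).

For an ideal cone the width tapers linearly, W(*f*) = (1 − *f*)·W~C~, so
the expected focus ratio at *f* = 0.75 is 0.25; for an ideal cylinder it
is 1 at every *f*. These two closed forms anchor the acceptance tests.

### Operational definitions

Manual measurements with a line tool do not define "width" operationally,
so the package had to choose:

* **Widths are FWHM** of intensity profiles — the full width at half
  maximum of the profile along a line through the measurement point,
  perpendicular to the spindle axis, maximized over in-plane directions
  (12 by default). FWHM is robust to the segmentation threshold; the
  half-max crossings of a blurred symmetric plateau sit on the true edge,
  which makes the estimate nearly PSF-independent. A mask-extent
  alternative is available (`width_method = "mask"`).
* **W~C~ is measured on the DNA channel** (the metaphase plate is the
  chromosome mass). The tubulin-channel interpretation is supported via
  `width_channel = "tubulin"`.
* **The axis** is the principal eigenvector of the intensity-weighted
  second moments of the tubulin signal inside its mask, computed in
  physical µm so anisotropic voxels cannot bias it. If the two leading
  eigenvalues agree within 5% the direction is meaningless and a classed
  anisotropy error is raised.
* **The pole point** is the farthest masked tubulin voxel on the
  requested side, projected onto the axis; intensity, then lowest
  (z, y, x) index, break ties.
* **Per-cell summaries** average the two half-spindles, which are always
  measured independently and reported per side first.

### Segmentation

The default mask is a global histogram threshold computed by Otsu's
method **on log1p intensity**, followed by removal of 26-connected
components below 27 voxels. Fluorescence histograms are heavy-tailed —
converging fiber bundles concentrate signal near the poles by an order of
magnitude — and raw-intensity Otsu then drifts into the signal tail,
eating the dimmer plate region and splitting one spindle into two
half-spindle islands. The log transform restores a near-bimodal
histogram; on noiseless phantoms the resulting mask covers >99% of the
true fiber envelope. Raw Otsu (`method = "otsu"`) and fixed thresholds
remain available, and every segmentation records the threshold used.

### Spindle and pole counting

Spindle components are 26-connected components of the tubulin mask;
components separated by less than `min_gap` (default 2 µm) are bridged by
a box dilation of half the gap so that genuinely separate spindles (e.g.
two parallel spindles with ≥5 µm of clear space) stay distinct while
threshold nicks do not split one spindle. Poles are counted per component
as the connected clusters of mask voxels in the outer radial shell
(beyond `pole_frac` = 0.7 of the maximal centre distance) — the peaks of
the radial extent function. A bipolar spindle yields two such clusters,
a tripolar one three.

## Kinematics

Live series are reduced to centroid tracks: per frame and channel,
intensity-weighted centroids of labeled objects in physical µm, linked
across frames by nearest-centroid matching within a maximum displacement
(intensity similarity breaks ties). From the DNA-channel track:

* **chromosome offset** — Euclidean 3D distance between the chromosome
  mass centroid and the spindle centroid at metaphase (a congression
  metric);
* **anaphase distance** — 3D distance between a mass's centroid at the
  window start and end;
* **anaphase rate** — that distance divided by elapsed time, exactly.

The measurement window is not fixed by convention, so the default picks
`t_start` as the first frame where the inter-mass separation exceeds its
first-frame baseline by 2 µm and `t_end` as the last frame; both are
overridable. Rates from a constant-velocity series are insensitive to the
window choice (checked to 10% under rendering noise). Reporting is per
mass plus the cell mean of the two masses.

## Statistics

* **ANOVA letter groups**: one-way `aov`, with Tukey HSD pairwise
  comparisons by default (unadjusted LSD-style t tests available, since
  field software defaults vary). The compact letter display is built from
  the maximal cliques of the pairwise non-significance graph, which is
  valid by construction: a clique contains only mutually non-significant
  groups, and every non-significant pair shares a clique. Cliques are
  lettered in order of their best group mean.
* **Proportions** use the Wilson score interval (`prop.test` without
  continuity correction); it behaves sensibly at the small counts of rare
  phenotypes such as mininucleate tetrads (3 of 434).
* **Relative expression** follows the 2^−ΔΔCt^ scheme: per-sample
  ΔCt = Ct~target~ − Ct~reference~, ΔΔCt against the **mean calibrator
  ΔCt** (a per-replicate pairing is a documented alternative), and
  genotype means of 2^−ΔΔCt^ with t intervals. Samples missing a gene are
  excluded with a logged message rather than failing the table.

## CAPS genotyping

Both bundled assays rest on palindromic recognition sites — MseI (T^TAA)
for the 235-bp *dv1-1* amplicon (cut: 152 + 83 bp; wild type uncut) and
NsiI (ATGCA^T) for the 533-bp *dv1-IG* amplicon (wild type cut: 272 +
261 bp; mutant uncut) — so scanning the forward strand suffices and
non-palindromic enzymes are out of scope. Cut positions are 0-based
top-strand offsets; fragments of a linear molecule satisfy
Σ fragments = length and k cuts → k + 1 fragments. Allele calls match
observed fragment multisets against the cut pattern, the uncut pattern,
and their union (the heterozygote, as expected in segregating F2
material) within a per-fragment size tolerance; anything else is
`unknown`, a value rather than an error. IUPAC ambiguity codes are
rejected explicitly.

## The synthetic-data generator

Real *dv1* specimens are not available, so every quantitative claim is
exercised on synthetic data with known ground truth. The generator
renders what the measurements need and no more:

* **Geometry.** Fibers run from points sampled uniformly on the
  metaphase-plate disc toward each pole; the lateral spread at axial
  fraction *f* is the plate radius times (1 − *f*) + *f*·*d*, where the
  **divergence** *d* ∈ [0, 1] interpolates linearly between a cone
  (*d* = 0, focused wild-type-like pole) and a cylinder (*d* = 1, fully
  divergent pole). The chromosome mass is a uniform ellipsoid of diameter
  `plate_width_true` at the plate. Multi-spindle cells place parallel
  spindles offset laterally; tripolar cells add a third pole at right
  angles.
* **Defaults** (chosen once, as plausible study conditions): plate width
  10 µm, half-length 12 µm, voxel size (1, 0.2, 0.2) µm matching a 1-µm
  z-step with finer lateral sampling as in widefield stacks, anisotropic
  Gaussian PSF σ = (0.6, 0.25, 0.25) µm, 5-min frame interval for live
  series. `fiber_count` defaults to 2000: real meiocyte spindles contain
  thousands of microtubules, and at a few hundred rendered fibers the
  speckle of individually resolved fibers measurably tilts the principal
  axis.
* **Noise.** Signal is PSF-blurred, scaled to photons, given Poisson
  shot noise, and topped with Gaussian read noise (clipped at zero);
  `optics_noiseless()` switches everything off for closed-form checks.
  Every generator is a pure function of parameters and seed — identical
  calls are bitwise identical.
* **Live series** move two chromosome masses (5-µm balls, initial
  centre separation 8 µm so both are resolvable from the first frame)
  apart at ±`speed` from `anaphase_onset`, over a static spindle.
* **Tables and sequences.** Ct tables encode expression as
  −log2(e) cycle offsets plus Gaussian cycle noise; count tables are
  per-plant binomial draws; amplicons are random sequences with
  recognition sites planted so cleavage falls exactly on the requested
  positions and no accidental site survives (violations are mutated
  away, with a bounded-retry error for impossible placements).

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: chromosome substructure (individual
bivalents, kinetochores), spindle curvature and cell-wall confinement,
photobleaching and focus drift over time, spatially varying background,
and optical aberrations beyond a Gaussian PSF. Recovery results on
phantoms bound algorithmic error, not biological measurement error.

## Numerical choices and degenerate inputs

* All geometry is computed at voxel centres, index × voxel size, 0-based.
* FWHM crossings are linearly interpolated, scanning from the profile
  ends inward (robust to interior dips from fiber texture).
* Recovery tolerances on phantoms are set by the coarsest sampling step:
  the 1-µm z step exceeds every PSF σ, so plate width and half-length are
  required to come back within 1 µm. The pole's blur tail biases L
  upward by a few tenths of a µm on bright converging tips — visible,
  accepted, and far below the between-genotype differences of interest.
* Constant-intensity images raise a classed degenerate-input error from
  segmentation; empty half-spindle sides raise a missing-pole error;
  near-isotropic tubulin distributions raise an anisotropy error. Batch
  stages log such per-cell failures and continue, erroring only when no
  cell succeeds.
* Test problem sizes: phantoms are ~17 × 71 × 191 voxels; the divergence
  sweep uses 20 phantoms per level across five levels; digestion
  properties run on 1000 random sequences; the Wilson coverage check uses
  1000 binomial replicates.

## Known limitations

* Pole counting assumes poles are radial extrema; exotic topologies
  (rings, strongly bent spindles) would need a different detector.
* The FWHM width of very dim cross-sections near a cone tip is noise
  sensitive; measurements there are dominated by the PSF.
* Linking is greedy nearest-neighbour and intended for the two or three
  large masses of meiotic anaphase, not for dense particle fields.
* The 2^−ΔΔCt^ model assumes perfect amplification efficiency for both
  genes; efficiency-corrected variants are out of scope.
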