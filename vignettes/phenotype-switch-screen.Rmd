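---
title: "Quantifying the VSMC phenotype switch: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the VSMC phenotype switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsmcscreen)
```

## The problem

Vascular smooth muscle cells (VSMCs) switch between a quiescent,
spindle-shaped *contractile* phenotype and a proliferative, rounded
*synthetic* phenotype; the switch underlies several vascular pathologies
and can be driven well-by-well by transfecting miRNA mimics. `vsmcscreen`
implements the computational side of a microscopy-based switch assay: it
turns two-channel well images into per-cell shape descriptors, aggregates
them into a screen readout, calls differentially expressed miRNAs from
count data, and integrates both evidence streams into target/hub/drug
networks. Every stage is exercised on synthetic data with planted ground
truth, so the pipeline's statistical behavior is measurable.

## Shape model and morphometry

Each segmented cell is reduced to two dimensionless descriptors:

* **Elongation** `E = major / minor`, the axis ratio of the ellipse whose
  second central moments match the cell's pixel distribution
  (axis length = 4 x the square root of the corresponding covariance
  eigenvalue). `E >= 1` always.
* **Cell shape index** `CSI = 4 * pi * area / perimeter^2`, 1 for a circle
  and decreasing towards 0 with elongation. Area is the pixel count;
  the perimeter uses a four-direction Cauchy–Crofton transition-count
  estimator, which is unbiased on smooth convex shapes — naive boundary
  counting overestimates the perimeter and can push the CSI of digitized
  circles above 1. Residual overshoot is clamped so `CSI <= 1` is a hard
  contract.

Two numerical details matter at cell scale (widths of 10–16 px):

* moments carry the `1/12` pixel-as-unit-square term, without which thin
  axis-aligned objects read systematically too narrow;
* when the cell-body intensity channel is available, moments are
  intensity-weighted, recovering sub-pixel boundary information from
  partially covered edge pixels. With the generator's anti-aliased
  rendering this keeps `E` rotation-invariant to well under 2 % and
  accurate to ~3 % at the default cell sizes; binary-mask moments alone
  wobble by several percent at grid-aligned orientations.

Segmentation is nucleus-seeded: Otsu threshold + morphological opening +
connected components on the nuclear channel provide one seed per cell,
and `EBImage::propagate()` grows each seed over the body channel restricted
to its Otsu foreground (a watershed-style split at ridges between touching
cells). Both channels are pre-smoothed with a Gaussian of sigma 1 px —
the scale of the simulated optics — before thresholding: less smoothing
leaves noise-jagged boundaries that inflate the Crofton perimeter of round
cells, more fattens thin cells and biases `E` low. A minimum-contrast guard
(0.1 on the unit intensity scale) declares blank or noise-only wells empty
instead of thresholding noise. Objects touching the border or outside
[25, 50000] px^2 are removed; one-pixel-wide objects are flagged
`degenerate` and classified `unclassified` rather than dropped.

## Classification

The published decision rules are applied with strict inequalities:
contractile iff `E > 3` and `0 < CSI < 0.4`; synthetic iff `1 < E < 3` and
`0.6 < CSI`; undecided iff `0.4 < CSI < 0.6`. Two choices were open:

* **Conflicting combinations** (e.g. `E > 3` with `CSI > 0.6`) belong to no
  published class; they are labeled `unclassified` and excluded from the
  contractile/synthetic ratio rather than forced into a class.
* **The CSI upper bound** is treated as inclusive (`CSI <= 1`) because
  measured CSI is clamped to 1; a digitized circle would otherwise be
  unclassifiable. Boundary values (`E = 3`, `CSI = 0.4` or `0.6`) fall
  through to `unclassified`.

## Screen aggregation and hit calling

The well readout is `ratio_con_syn = (n_con + 0.5) / (n_syn + 0.5)`; the
Haldane–Anscombe pseudocount keeps wells without synthetic cells finite and
is symmetric in both classes. Wells with neither contractile nor synthetic
cells are flagged `low_information`. Fold changes are taken against the
mean negative-control ratio *of the same replicate* (per-plate
normalization absorbs plate effects). Hit rules: strong contractile iff
average FC > 1.5 **and** every replicate FC > 1 (the directional clause
formalizes "in all three replicates"); weak contractile iff not strong and
average FC > 1.2; strong synthetic iff every replicate FC < 1 and average
FC < 1/1.2 — the down-threshold mirrors the weak up-threshold since no
numeric down-threshold is published. Averaging happens before
thresholding; per-replicate thresholding enters only through the
directional clauses.

## Differential expression

Counts are transformed to `logCPM = log2((count + 0.5)/(lib + 1) * 1e6)`
and tested gene-wise with a two-group moderated t: pooled variance `s2_g`
with `d_g = n1 + n2 - 2` df, prior `(d0, s0^2)` fitted by matching the
log-scale moments of a scaled-F distribution (the trigamma-inverse Newton
iteration), posterior variance `(d0 s0^2 + d_g s2_g)/(d0 + d_g)`, and
`d0 + d_g` df for the p-value; BH adjustment across the panel. When the
moment estimate of `d0` is non-positive the prior df goes to infinity
(full shrinkage) with a warning; when every gene has zero within-group
variance the fit falls back to the ordinary t. The implementation is
authored here and cross-checked in the test suite against the established
empirical-Bayes reference to ~1e-10.

Design choices: precision weights tied to a mean–variance trend are
omitted — the calls operate on log2FC and p, and the moderated-t core is
what the thresholds exercise. Two significance modes are exposed because
volcano legends print raw `p < 0.05` while pipeline-level control uses
BH-FDR 0.05: `call_de(use_fdr = FALSE)` is the volcano mode and the
default; the pipeline demo runs with `use_fdr = TRUE`. The log2FC cutoff is
0.6 (the printed fold-change cutoff of 1.5 corresponds to 0.585; the
rounder printed log2 value is used).

## Network integration

Screen hits and up-regulated miRNAs are intersected after name
normalization (species prefix stripped, `miR` capitalization fixed, arm
suffixes preserved); if one list carries -3p/-5p arms and the other none,
the intersection errors instead of part-matching. Shared targets are
stratified by the exact number k of distinct miRNAs predicting them.

Hub genes are scored by Maximal Clique Centrality: all maximal cliques are
enumerated with Bron–Kerbosch with pivoting (budgeted; the default aborts
beyond 1e5 cliques) and `MCC(v)` sums `(|C|-1)!` over maximal cliques of
size >= 2 containing `v`; isolated nodes score 0 (a degree-based fallback
is deliberately not used). MCC is computed per miRNA on the subgraph
induced by that miRNA's own targets — mirroring per-miRNA interaction
analysis — with a global-graph mode behind a flag. Ties are broken by MCC,
then degree, then lexicographically, and the top 3 per miRNA form the hub
set after deduplication (a gene may be hub for several miRNAs). The merged
network (shared targets at k >= 4 plus hubs, annotated with role, k,
targeting miRNAs and MCC) exports to GraphML and TSV, and an inner join
with a drug–gene table yields (miRNA, target, drug) triples plus the
fraction of hub genes with at least one drug.

## The synthetic-data generator

The generator emulates the assay's study conditions rather than
photorealistic cytology:

* **Plates**: 3 replicates (screens A/B/C), each with at least one
  negative-control well; per-cell phenotype labels are Binomial(n_cells,
  contractile_fraction). Default screen simulations use 400 cells/well,
  treated wells at fraction 0.6 against controls at 0.2.
* **Cell shapes are ellipses.** Contractile cells draw their axis ratio
  from Uniform(7, 10) and synthetic cells from Uniform(1.2, 2.0). The
  contractile range is dictated by geometry: an ideal ellipse reaches
  `CSI < 0.4` only above axis ratio ~5.8, so ratios of 7–10 (true CSI
  ~0.24–0.33) keep planted labels unambiguous on both the E and CSI
  criteria, and the synthetic lower bound 1.2 keeps `E > 1` with margin.
  Real contractile VSMCs are spindle-shaped with rougher perimeters and
  reach low CSI at more modest axis ratios; passing recovery tests on
  elliptical cells therefore demonstrates correctness of the measurement
  chain, not that real cells are ellipses.
* **Sizes and rendering**: minor semi-axes Uniform(5, 8) px, matching VSMC
  widths at 10x magnification (~0.65 um/px) and keeping single-cell moment
  estimates in a regime where digitization error is small. Cells are
  placed by rejection sampling of non-overlapping bounding circles (cap
  10000 attempts/well) padded by 4 px so blur tails never fuse neighboring
  bodies. Rendering is anti-aliased (4x4 subpixel coverage), followed by a
  Gaussian blur of sigma 1 px and additive Gaussian read noise (sd 0.02);
  Poisson shot noise and texture are deliberately absent.
* **Counts**: negative binomial with gene-wise means from a log2-uniform
  abundance range (1, 10), library sizes log-uniform in (0.5e6, 2e6),
  dispersion 0.1, 4 replicates per serum condition; planted effects
  multiply low-serum means by `2^(+-1.5)` on a 10 % subset.
* **Network fixtures**: the target table realizes the planted k-sharing
  exactly; planted hub cliques are fully connected in the PPI table; the
  remaining PPI edges form a sparse partial matching among non-clique
  genes, so every non-planted node has MCC <= 1 and planted structure is
  exactly recoverable by construction. Drug rows are emitted verbatim.

What passing tests on this generator does **not** show: robustness to
uneven illumination, overlapping or textured cells, segmentation of
non-elliptical morphologies, or count matrices with outlier libraries.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` run morphometry on 200 rendered
cells (8 mixed wells of 20 plus 40 circles), 50 seeded screen repetitions
of a 3-replicate plate at 400 cells/well, 21 negative-binomial simulations
of 2000 miRNAs (one type-I run, twenty FDR-null runs) plus one power run,
and 200 random graphs of at most 10 nodes against a brute-force clique
oracle — a few tens of seconds in total. All generators restore the
caller's RNG state and derive per-well/per-stage child seeds from one root
seed, so identical seeds give byte-identical artifacts.

## Known limitations

* The classifier inherits the published thresholds; no threshold
  re-optimization or machine-learning calibration is provided.
* CSI depends on the perimeter estimator; estimates other than the
  Crofton-style one shift CSI systematically and would require re-deriving
  the class margins.
* MCC enumeration is exponential in the worst case; dense graphs must be
  reduced to subgraphs before scoring (the budget guard enforces this).
* The moderated-t stage assumes approximately normal logCPM within groups;
  very low counts with large dispersion depart from this, which is visible
  as mild type-I inflation in the simulations' tails.
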