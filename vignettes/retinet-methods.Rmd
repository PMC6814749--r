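---
title: "Multiresolution archetypal cell networks: models and methods"
author: "retinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiresolution archetypal cell networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`retinet` implements a network-based workflow for annotating single-cell
RNA-seq atlases of complex tissues, developed around the human retina:
quality control and depth normalization, mutual nearest-neighbor (MNN)
batch correction, a multiresolution archetypal decomposition whose
footprints define a square-root Jensen-Shannon (JS) metric over cells, an
adaptive k\*-nearest-neighbor cell network, diffusion-based marker
annotation with permutation testing and doublet filtering,
discriminating-power marker discovery, macroglial subtype analysis with
regional enrichment, and a competitive gene-set regression linking
cell-type expression specificity to gene-level GWAS statistics. A
negative-binomial simulator generates datasets with the statistical
structure every stage assumes, so the whole pipeline is exercisable and
testable at desk scale.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and the design decisions taken where the
methodology was genuinely open. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

# Preprocessing

**QC filtering** retains cells detecting at least `min_genes_per_cell`
(default 300) genes and genes detected in at least `min_cells_per_gene`
(default 10) cells. Because removing genes can invalidate the cell rule
and vice versa, `qc_filter()` alternates the two rules to a fixed point,
which guarantees both postconditions hold simultaneously on the result
and makes the filter idempotent. A single pass can leave violations; the
fixed point is the only order-independent reading of the two thresholds.

**Depth normalization** scales every cell to the median library size and
applies `log1p`. The per-cell factors are stored, making the transform
exactly invertible; within-cell rank order of genes is preserved.
"Normalization based on count depth" admits several conventions; median
scaling was chosen because it keeps values on the raw count scale and has
no tunable target.

**Reduction** is an exact rank-`d` truncated SVD (default `d = 50`) of
the gene-centered matrix, computed through the smaller Gram matrix with a
deterministic sign convention, so results are reproducible to machine
precision.

# MNN batch correction

Batches are merged sequentially, largest first (`order = "by_size"`; the
merge order is not dictated by the method, so it is exposed). Coordinates
are cosine-normalized internally; mutual k-NN pairs (default
`k = 20`) between the reference and the incoming batch define per-pair
correction vectors, and each incoming cell is shifted by a
Gaussian-kernel-weighted average of those vectors. The bandwidth defaults
to the mean distance to the k-th within-batch neighbor, adapting to the
local scale. Correction is performed in the `d = 50` reduced space: the
downstream network is built there, and the reduced space is where the
correction is consumed. A batch with no mutual pairs is appended
uncorrected with a warning.

# Archetypal decomposition and the cell network

At depth $k$, the decomposition approximately minimizes
$\lVert S - S C H \rVert_F$ over column-stochastic $C$ (cells $\times$
$k$; archetypes as convex combinations of cells) and $H$ ($k$ $\times$
cells; per-cell archetype footprints), where $S$ holds the reduced cell
profiles in columns. Both subproblems are convex and each column is
solved *exactly* as a simplex-constrained least-squares problem with an
active-set method (C++ core, warm-started across sweeps). Initialization
uses a successive-projection (spread-out) heuristic; `restarts = 3`
independent starts are kept (the first deterministic, later ones from a
random seed column), ties broken by the lowest restart index.
Convergence is declared when the relative residual improvement falls
below `1e-7` or after `max_iter = 50` sweeps; a dead archetype (zero
footprint) is relocated to the worst-reconstructed cell.

The ladder runs depths `k_min = 2` to `k_max` (default 30; the pipeline
demo uses 15, which the test suite exercises). Besides the independent
restarts, each depth is additionally seeded with the previous depth's
solution augmented by one archetype placed on the worst-reconstructed
cell. Because the optimizer never increases the objective from its
initialization, this makes the recorded reconstruction error provably
non-increasing in $k$ — independent restarts alone cannot guarantee
that.

Per-cell footprints from all depths are concatenated and renormalized
into a probability vector (all depths weighted equally; no depth is
privileged a priori). Pairwise cell distance is
$\sqrt{\mathrm{JSD}(p, q)}$ with the divergence in bits, a true metric
bounded by 1, so $1 - d$ is a valid edge weight. Neighborhoods are chosen
per cell by the k\* rule: with distances sorted ascending, neighbor
$j{+}1$ is admitted while
$d_{j+1} \le \beta_j = \frac{1}{j}\bigl(\sum_{i\le j} d_i +
\sqrt{j\lambda + (\sum d_i)^2 - j \sum d_i^2}\bigr)$, with
$\lambda = 1$ and a cap of $2\lceil\sqrt{n}\rceil$ neighbors. With
distances bounded by 1 and $\lambda = 1$ the rule truncates only at
pronounced gaps, so the cap is the binding constraint on homogeneous
data; $\lambda$ is exposed for sparser graphs. Directed neighborhoods are
symmetrized by union. The 2-D layout (`net_layout()`) is a force-directed
embedding of the weighted graph, cosmetic only: no analysis consumes the
coordinates.

# Annotation, permutation testing, and doublet filtering

Each marker gene's normalized expression is imputed over the network by a
restart random walk, $s = (1-\alpha)(I - \alpha P)^{-1} x$ with $P$ the
column-stochastic transition matrix; total mass is conserved and
isolated nodes keep their own value. The restart complement defaults to
$\alpha = 0.85$, the common random-walk-with-restart convention. For
matrices of genes the resolvent is applied by a sparse direct solve,
which is mathematically identical to the fixed-point iteration at its
tolerance.

Two standardization choices, made after diagnosing the scoring on
synthetic data, are deliberately documented:

1. **Degree debiasing.** On irregular graphs the restart walk
   concentrates mass on high-degree cells for *every* gene alike (the
   diffused unit vector spans roughly 0.6-2.0 on the default synthetic
   network). Imputed values are divided by the diffused unit vector
   before scoring, removing this shared bias.
2. **Raw-sd standardization.** Z-scaling each diffused gene by the
   diffused profile's own standard deviation lets sparsely expressed
   noise genes explode (their diffused spread is near zero, so local
   bumps become extreme z-values). Imputed values are therefore
   standardized by the gene's *raw* expression standard deviation across
   cells; constant genes score zero.

A type's score per cell is the unweighted mean of its markers' z-values.
Significance comes from a permutation test: null scores from random gene
sets of matched size, drawn from detection-frequency-matched bins (10
quantile bins; matching prevents trivial rejections driven by sparsity),
with the plus-one empirical estimator
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{\text{perm}})$,
$n_{\text{perm}} = 1000$, and per-cell Benjamini-Hochberg adjustment
across types at 0.05. Cells significant for no type are filtered as
`unassigned_none`; for two or more types as `unassigned_multi` (doublet
suspects); exactly one significant type assigns that label. A final
coherence filter flags cells whose network neighbors are not enriched for
the same label (one-sided hypergeometric against the label's global
frequency, BH at 0.05; degree-zero cells are flagged by convention, and a
neighborhood consisting entirely of the same label is always coherent).

**Doublet sensitivity.** On the default simulation (5% doublets formed by
summing two random singlets), the two-rule filter recovers only a
minority of doublets. The test suite computes the number honestly rather
than asserting success: a quarter of summed pairs mix their components at
worse than 30/70 because library sizes are log-normal, the weaker
component's diffused signal at the doublet is about half the singlet
level, and one in eight uniform pairs is same-type and undetectable in
principle. Multi-significance doublet filtering should therefore be
treated as a high-precision, low-recall filter; dedicated doublet
callers are out of scope here.

# Marker discovery

Signature profiles average the member cells' reduced profiles into a
metagene per type, back-transform to gene space with the left-singular
vectors, and center each gene across types; the centered value is the
gene's discriminating power for that type, and the per-gene mean across
types (the baseline) is retained. Centering follows the back-transform:
the power is defined relative to the gene's typical signature, and the
order is exposed through the stored uncentered matrix for anyone wanting
the alternative.

Differential tests are one-sided Wilcoxon rank-sum (type vs rest) per
gene per type: exact null distribution when the smaller group has at most
8 members, the total at most 25, and no ties; otherwise a normal
approximation with continuity and tie correction. Selection requires
BH-adjusted $p < 0.001$ (adjustment jointly across all gene-type pairs —
the more conservative, symmetric scope), AUC $> 0.5$, and positive log
fold change (difference of log1p-normalized means). A gene passing in
exactly one type is an *exclusive* marker; the top 10 per type are
ordered by descending power with lexicographic tie-breaks.

Cross-platform consistency is the partial Pearson correlation between the
two platforms' signature columns over shared genes, controlling for
*both* platforms' baselines simultaneously (the symmetric choice),
computed via regression residuals; the best match per type is the argmax.

# Macroglial subtypes

The parent class is extracted from the annotation; cells whose
contamination-marker association (rod markers by default, scored with the
same diffusion-permutation machinery on the induced subnetwork) is
significant are removed — a cell with zero contamination counts is never
removed. The subset is renormalized, reduced, re-corrected with MNN, and
decomposed; each cell is assigned its dominant archetype at resolution
`k = 3` (the retina use case), or `k` chosen by maximal mean pairwise
label agreement across 5 restarts with `"auto"`. Clusters are renamed by
decreasing size.

Regional enrichment tests each subtype's per-cell association scores
(archetype footprints) between macula and periphery with one-sided
Wilcoxon tests in both directions; a two-proportion test on frequencies
is reported alongside, and per-gene regional expression tests are
available. The rank test on per-cell scores is primary because a rank
test needs per-cell observations; what exactly constitutes the ranked
unit in regional comparisons is ambiguous in common practice, so both
views are reported.

# GWAS gene-set association

Per-gene cell-type specificity is the one-sided Wilcoxon test of the
locus gene within each type, BH-adjusted across tested pairs, clipped
below at `1e-300`, scored as $-\log_{10}(p_{\text{adj}})$, and flagged at
the stringent `1e-10` threshold. Normalized (not imputed) expression
feeds the test by default; a flag exposes the alternative. Cell-type gene
sets take genes at FDR < 0.01 that are detected (raw count > 0) in at
least 25% of the type's cells.

The competitive gene-set analysis regresses gene-level Z-scores on an
intercept, set membership, and covariates (gene size by default), with a
one-sided t-test for a positive membership coefficient. SNP-to-gene
aggregation with LD is out of scope: gene-level statistics are an input.
With no covariates the coefficient reduces exactly to the difference of
member and non-member mean Z, which the tests verify to 1e-10. The
negative-control panel runs the regression per (trait, type) and marks
significance at $p < 0.05$.

# The synthetic data generator

`sim_config()` defaults define the study conditions used throughout the
tests: 2,000 genes; 8 retinal cell types (rods, cones, retinal ganglion,
bipolar, amacrine, horizontal, macroglia, microglia) with 500 cells each;
8 exclusive markers per type at 8-fold elevation, the curated panel genes
first so annotation targets planted signal; negative-binomial counts with
size 2 (variance $\mu + \mu^2/2$, a single-cell-like overdispersion);
log-normal baseline means ($\mu = -1.5$, $\sigma = 1$ on the log scale);
library-size factors with CV 0.35; two batches with per-gene log-normal
multiplicative offsets (sd 0.15) — the structure MNN corrects; 5%
doublets as element-wise sums of two uniformly paired singlets (the worst
case for neighborhood coherence); optionally two platforms sharing the
types with an extra per-gene offset (sd 0.25).

Macroglia carry three planted subtypes with the field's signature genes
(FOS/GFAP/SPARCL1/EGR1; COL4A3/VEGFA/HTRA1/SLC2A1; FTL/FTH1/DBI) at
8-fold, plus 12 unnamed program genes each at 4-fold — real glial
subtypes differ by co-regulated expression programs, not by three genes,
and a generator without the programs produces subtypes no unsupervised
method could separate. Region labels are macula/periphery with subtype
biases 30/70 (FOS-like, periphery-enriched), 70/30 (COL4A3-like,
macula-enriched), and 50/50 (FTL-like).

The generator deliberately omits gene-gene correlation beyond the
type/subtype programs, ambient RNA, and UMI-level structure. Passing
tests therefore demonstrate that the algorithms recover the structure
they model — planted markers, batch shifts, subtype programs, regional
biases, enriched gene sets — not that they are robust to every artifact
of real droplet data.

# Numerical choices and problem sizes

All randomness flows from explicit integer seeds; fixed seeds fix every
output array exactly, and `run_pipeline()` writes an MD5 manifest that is
bit-identical across reruns. The simplex solver uses an active-set
tolerance of `1e-10` with a ridge of machine-epsilon scale on the normal
equations; ladder feasibility holds to `1e-6` by test. Diffusion solves
to `1e-8`. The test suite and the acceptance script run the full default
scale (2,000 x 4,000 cells, ladder to depth 15, 1,000 permutations, 500
regression replicates) in a few minutes on one CPU; the package-default
`k_max = 30` is used unchanged for larger analyses.

# Known limitations

Doublet recall of the two-rule filter is limited (see above). The k\*
rule with JS distances in [0, 1] and $\lambda = 1$ saturates at the
neighbor cap on homogeneous data. MNN correction estimates batch vectors
from mutual-pair differences and partially under-corrects constant
shifts when pairs mix biological neighbors (the duplicated-cells
construction in the tests isolates the exact-pair regime). The
permutation null is frequency-matched but not expression-program-matched;
marker panels sharing programs with non-panel genes lose a little power.
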