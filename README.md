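# retinet

Multiresolution archetypal cell networks for single-cell transcriptomic
atlases, developed around the human retina and its disease genetics.

## The problem

Annotating a single-cell RNA-seq atlas of a complex tissue requires more
than one clustering resolution: cell identity is better described by a
spectrum of *archetypes* — extreme transcriptional states expressed as
convex combinations of cells — collected across increasing decomposition
depths. `retinet` implements that workflow end to end for analysts
working with sparse 10x-style count matrices:

- **QC and normalization** — iterated gene/cell detection filters to a
  fixed point; median-depth scaling with `log1p`, exactly invertible.
- **Batch correction** — mutual nearest-neighbor (MNN) correction in the
  reduced space.
- **Archetypal ladder and cell network** — for each depth *k*, minimize
  ‖S − S·C·H‖_F over column-stochastic C (archetypes as convex mixtures
  of cells) and H (per-cell archetype footprints), solved by exact
  simplex-constrained least squares from spread-out initializations.
  Concatenated footprints define a √Jensen–Shannon metric (base 2, so
  distances lie in [0, 1]) and an adaptive k\*-nearest-neighbor graph.
- **Annotation** — curated marker panels imputed by a restart random
  walk, aggregated into per-cell type scores, tested against
  frequency-matched permutation nulls, with doublet and
  network-coherence filters.
- **Marker discovery** — discriminating-power signatures (metagene
  back-transform through the left-singular vectors), one-sided Wilcoxon
  selection (adjusted p < 0.001, AUC > 0.5, positive log fold change),
  exclusivity flags, top-10 ranking, and cross-platform partial-Pearson
  alignment.
- **Macroglial subtypes** — contamination cleaning, sub-network
  decomposition into FOS-, COL4A3-, and FTL-like subtypes, subtype
  markers, and macula/periphery enrichment tests.
- **GWAS cell-type association** — per-gene specificity scores for a
  locus gene list (−log10 adjusted p, clipped at 1e-300, significant at
  1e-10) and a MAGMA-style competitive gene-set regression of gene-level
  Z-scores on set membership plus covariates, with negative-control
  traits.
- **Synthetic data** — a negative-binomial generator planting exclusive
  markers, batch effects, doublets, two platforms, three macroglial
  subtypes with regional biases, and enriched GWAS gene sets, so every
  stage is testable without external data.

## A worked example

```r
library(retinet)

# simulate the default retina-like dataset: 2,000 genes x 4,000 cells,
# 8 cell types, 5% doublets, 2 batches
ds <- generate_counts(sim_config(seed = 7))
ds
#> synthetic_dataset: 2000 genes x 4000 cells, 8 types, 200 doublets

qc <- qc_filter(ds$counts)          # 2000 x 3882 after filtering
nm <- depth_normalize(qc)
rp <- reduce_profile(nm, d = 50)
rp$scores <- mnn_correct(rp$scores, qc$cell_meta$batch)

ladder <- build_ladder(rp, k_min = 2, k_max = 15, seed = 1)
round(ladder_errors(ladder), 1)
#>      2      3      4      5      6      7      8      9     10     11     12     13     14     15
#> 3505.2 3364.0 3244.7 3136.6 3040.1 2954.4 2883.0 2847.8 2815.4 2780.2 2750.9 2724.5 2703.4 2681.4

net <- build_kstar_nn(cell_profiles(ladder))
ann <- annotate_cells(net, nm, n_perm = 1000, seed = 2)
table(ann$label)[c("rods", "unassigned_multi")]
#>             rods unassigned_multi
#>              442              117
```

The reconstruction errors decrease monotonically with depth (the ladder
warm-starts each depth from the previous solution, so this is
guaranteed, not luck). Against the simulation's planted truth, the
labels reach an adjusted Rand index of about 0.97 on retained singlets
with about 3% of singlets lost to the filters; `wilcoxon_markers()`
recovers 100% of the planted exclusive markers with no false exclusives,
and the macroglial sub-analysis separates the three planted subtypes at
ARI ≈ 0.92 with the correct macula/periphery biases. These numbers are
recomputed, not quoted: see below.

The demo pipeline (every stage, small scale, ~10 s) runs with:

```r
run_pipeline(demo_pipeline_config(seed = 1, out_dir = "demo_out"))
```

or from a shell via the bundled wrapper:

```sh
Rscript inst/cli/retinet.R run-all --seed 1 --out demo_out
```

## Package layout

- `R/` — one file per stage: `synth.R`, `io_qc.R`, `mnn.R`, `archnet.R`,
  `annotate.R`, `markers.R`, `subtypes.R`, `gwas.R`, `pipeline.R`.
- `src/action_core.cpp` — the simplex-constrained least-squares solver,
  archetypal decomposition, and √JS / k\*-NN kernels.
- `vignettes/retinet-methods.Rmd` — models, parameters, numerical
  choices, and design decisions.
- `tests/testthat/` — unit, property, and end-to-end acceptance tests.
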