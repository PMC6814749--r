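Package: retinet
Title: Multiresolution Archetypal Cell Networks for Single-Cell Retina Atlases
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An archetypal-analysis based workflow for single-cell RNA-seq
    atlases of the human retina: quality control and depth normalization of
    sparse count matrices, mutual nearest-neighbor batch correction, a
    multiresolution archetypal decomposition with a square-root
    Jensen-Shannon cell metric and an adaptive k*-nearest-neighbor cell
    network, diffusion-based marker annotation with permutation testing and
    doublet filtering, discriminating-power marker discovery with one-sided
    Wilcoxon selection, macroglial subtype analysis with regional
    enrichment, and competitive gene-set regression linking cell-type
    expression specificity to gene-level GWAS association statistics.
    Includes a negative-binomial synthetic data generator emulating the
    statistical structure every downstream stage assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports: Matrix, igraph, methods, stats, utils, tools, Rcpp, yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), mclust, jsonlite, withr
Config/testthat/edition: 3
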