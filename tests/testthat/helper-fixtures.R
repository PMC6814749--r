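# memoized heavyweight fixtures shared across test files; each is built at
# most once per test run, at the default study scale
.fx <- new.env(parent = emptyenv())

# full default-scale run: 2,000 genes x 4,000 cells, 8 types, 5% doublets,
# 2 batches; ladder 2..15, k*-NN network, annotation with 1,000 perms
demo_fit <- function() {
  if (!is.null(.fx$fit)) return(.fx$fit)
  ds <- generate_counts(sim_config(seed = 7))
  qc <- qc_filter(ds$counts)
  nm <- depth_normalize(qc)
  rp <- reduce_profile(nm, 50)
  rp$scores <- mnn_correct(rp$scores, qc$cell_meta$batch)
  ladder <- build_ladder(rp, 2, 15, restarts = 3, seed = 1)
  net <- build_kstar_nn(cell_profiles(ladder))
  ann <- suppressWarnings(annotate_cells(net, nm, n_perm = 1000, seed = 2))
  keep <- match(qc$cell_ids, ds$counts$cell_ids)
  .fx$fit <- list(
    ds = ds, qc = qc, nm = nm, rp = rp, ladder = ladder, net = net,
    ann = ann, truth = ds$true_type[keep], is_doublet = ds$is_doublet[keep],
    true_subtype = ds$true_subtype[keep])
  .fx$fit
}

# small structured dataset for unit tests: 3 types, no doublets, 1 batch
tiny_dataset <- function() {
  if (!is.null(.fx$tiny)) return(.fx$tiny)
  types <- data.frame(name = c("rods", "bipolar", "macroglia"),
                      n_cells = 120L, n_markers = 4L, marker_fold = 8,
                      stringsAsFactors = FALSE)
  cfg <- sim_config(n_genes = 300, cell_types = types, n_batches = 1,
                    doublet_rate = 0, subtype_spec = NULL, seed = 101)
  ds <- generate_counts(cfg)
  qc <- qc_filter(ds$counts, min_genes_per_cell = 20, min_cells_per_gene = 3)
  nm <- depth_normalize(qc)
  rp <- reduce_profile(nm, 20)
  ladder <- build_ladder(rp, 2, 5, restarts = 2, seed = 1)
  net <- build_kstar_nn(cell_profiles(ladder))
  keep <- match(qc$cell_ids, ds$counts$cell_ids)
  .fx$tiny <- list(ds = ds, qc = qc, nm = nm, rp = rp, net = net,
                   truth = ds$true_type[keep])
  .fx$tiny
}

# hand-built cell network from an edge list (1-based indices)
make_net <- function(n, from, to, weight = rep(1, length(from))) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = weight),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  structure(list(graph = g, cell_ids = as.character(seq_len(n)),
                 k_star = igraph::degree(g), layout = NULL),
            class = "cell_network")
}

# minimal normalized_matrix from a dense matrix
make_nm <- function(X, genes = rownames(X), cells = colnames(X)) {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(X)))
  if (is.null(cells)) cells <- paste0("c", seq_len(ncol(X)))
  v <- methods::as(Matrix::Matrix(X, sparse = TRUE), "CsparseMatrix")
  dimnames(v) <- list(genes, cells)
  structure(list(values = v, depth_factors = rep(1, ncol(X)),
                 gene_ids = genes, cell_ids = cells, cell_meta = NULL),
            class = "normalized_matrix")
}

filter_codes <- c("unassigned_none", "unassigned_multi",
                  "incoherent_neighborhood")
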