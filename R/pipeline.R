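#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown keys are
#' rejected; every threshold is range-checked.
#'
#' @param input Directory with a Matrix-Market triplet to read, or `NULL`
#'   to simulate data from `sim`.
#' @param sim A [sim_config()] used when `input` is `NULL`.
#' @param out_dir Output directory.
#' @param seed Master seed; stage seeds are derived from it.
#' @param min_genes_per_cell,min_cells_per_gene QC thresholds.
#' @param d Reduction dimension.
#' @param mnn_k,mnn_order MNN settings (`mnn_k = 0` disables correction).
#' @param k_min,k_max,restarts Archetypal ladder depths and restarts.
#' @param max_k_nn,lambda k*-NN settings (`NULL` max_k = adaptive cap).
#' @param alpha Diffusion restart-complement.
#' @param n_perm Permutation count for annotation.
#' @param p_thresh,auc_thresh,lfc_thresh Marker selection thresholds.
#' @param run_subtypes,subtype_parent,subtype_k,contamination_markers
#'   Subtype stage settings.
#' @param run_gwas,gwas_genes,gwas_stats GWAS stage settings:
#'   a locus gene list and a per-trait list of gene-statistics tables
#'   (both default to synthetic constructions when simulating).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, sim = sim_config(),
                            out_dir = tempfile("retinet_"), seed = 1L,
                            min_genes_per_cell = 300,
                            min_cells_per_gene = 10,
                            d = 50, mnn_k = 20, mnn_order = "by_size",
                            k_min = 2, k_max = 15, restarts = 3,
                            max_k_nn = NULL, lambda = 1,
                            alpha = 0.85, n_perm = 1000,
                            p_thresh = 1e-3, auc_thresh = 0.5,
                            lfc_thresh = 0,
                            run_subtypes = TRUE,
                            subtype_parent = "macroglia", subtype_k = 3,
                            contamination_markers = retina_markers()$rods,
                            run_gwas = TRUE,
                            gwas_genes = NULL, gwas_stats = NULL) {
  cfg <- as.list(environment())
  stopifnot(alpha >= 0, alpha < 1, d >= 2, k_min >= 2, k_max >= k_min,
            n_perm >= 100, p_thresh > 0, p_thresh <= 1,
            auc_thresh >= 0, auc_thresh < 1,
            min_genes_per_cell >= 0, min_cells_per_gene >= 0)
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Flat keys mirror the arguments of [pipeline_config()]; the nested
#' `sim:` block mirrors [sim_config()]. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(y$sim)) {
    skn <- names(formals(sim_config))
    sbad <- setdiff(names(y$sim), skn)
    if (length(sbad))
      stop("unknown sim keys: ", paste(sbad, collapse = ", "))
    y$sim <- do.call(sim_config, y$sim)
  }
  do.call(pipeline_config, y)
}

#' Demo pipeline configuration
#'
#' A down-scaled configuration exercising every stage in about a minute:
#' 800 genes, four cell types of 250 cells each (including macroglia with
#' the three planted subtypes), ladder depths 2..8, 500 permutations.
#'
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return A [pipeline_config()].
#' @export
demo_pipeline_config <- function(seed = 1L, out_dir = tempfile("retinet_demo_")) {
  types <- data.frame(
    name = c("rods", "bipolar", "macroglia", "microglia"),
    n_cells = 250L, n_markers = 8L, marker_fold = 8,
    stringsAsFactors = FALSE)
  pipeline_config(
    sim = sim_config(n_genes = 800, cell_types = types, seed = seed),
    out_dir = out_dir, seed = seed,
    min_genes_per_cell = 100, min_cells_per_gene = 5,
    d = 30, k_max = 8, n_perm = 500)
}

.stage_msg <- function(...) {
  message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> QC -> normalize -> reduce -> MNN ->
#' archetypal ladder -> k*-NN network -> annotation -> markers ->
#' subtypes (optional) -> GWAS (optional), persisting every intermediate
#' artifact under `out_dir` and writing a `manifest.tsv` of files and MD5
#' checksums. Identical config and seed give identical checksums.
#'
#' @param config A [pipeline_config()] (or a YAML path).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest data.frame.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$input) && !dir.exists(config$input))
    stop("input directory does not exist: ", config$input)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  seed <- as.integer(config$seed)

  # --- data ---
  truth <- NULL
  if (is.null(config$input)) {
    .stage_msg("stage simulate")
    sim <- config$sim
    sim$seed <- seed
    truth <- generate_counts(sim)
    counts <- truth$counts
    write_mtx_triplet(counts, file.path(out, "counts"))
    files <- c(files, list.files(file.path(out, "counts"),
                                 full.names = TRUE))
    tdf <- data.frame(barcode = counts$cell_ids,
                      true_type = truth$true_type,
                      is_doublet = truth$is_doublet,
                      true_subtype = truth$true_subtype,
                      stringsAsFactors = FALSE)
    files <- c(files, .write_tsv(tdf, file.path(out, "truth.tsv")))
  } else {
    .stage_msg("stage read")
    counts <- read_mtx_triplet(config$input)
  }

  # --- io_qc ---
  .stage_msg("stage qc (min_genes_per_cell=", config$min_genes_per_cell,
             ", min_cells_per_gene=", config$min_cells_per_gene, ")")
  qc <- qc_filter(counts, config$min_genes_per_cell,
                  config$min_cells_per_gene)
  if (ncol(qc$values) == 0) stop("stage qc: empty matrix")
  nm <- depth_normalize(qc)

  # --- reduce + mnn ---
  .stage_msg("stage reduce (d=", config$d, ")")
  rp <- reduce_profile(nm, d = min(config$d, min(dim(nm$values)) - 1))
  batch <- if (!is.null(qc$cell_meta) && "batch" %in% names(qc$cell_meta))
    qc$cell_meta$batch else NULL
  if (!is.null(batch) && length(unique(batch)) > 1 && config$mnn_k > 0) {
    .stage_msg("stage mnn (k=", config$mnn_k, ", order=",
               paste(config$mnn_order, collapse = ","), ")")
    rp$scores <- mnn_correct(rp$scores, batch, k = config$mnn_k,
                             order = config$mnn_order)
  }
  coords <- data.frame(barcode = qc$cell_ids, rp$scores)
  files <- c(files, .write_tsv(coords, file.path(out, "coords.tsv")))

  # --- archnet ---
  .stage_msg("stage ladder (k=", config$k_min, "..", config$k_max,
             ", restarts=", config$restarts, ")")
  ladder <- build_ladder(rp, config$k_min, config$k_max,
                         restarts = config$restarts, seed = seed)
  files <- c(files, .write_tsv(
    data.frame(k = ladder$depths, rss = unname(ladder_errors(ladder))),
    file.path(out, "ladder_errors.tsv")))
  .stage_msg("stage network (lambda=", config$lambda, ")")
  prof <- cell_profiles(ladder)
  net <- build_kstar_nn(prof, max_k = config$max_k_nn,
                        lambda = config$lambda)
  el <- igraph::as_data_frame(net$graph, "edges")
  el$from <- net$cell_ids[as.integer(el$from)]
  el$to <- net$cell_ids[as.integer(el$to)]
  files <- c(files, .write_tsv(el, file.path(out, "network_edges.tsv")))

  # --- annotate ---
  .stage_msg("stage annotate (alpha=", config$alpha,
             ", n_perm=", config$n_perm, ")")
  ann <- annotate_cells(net, nm, alpha = config$alpha,
                        n_perm = config$n_perm, seed = seed + 1L)
  adf <- data.frame(
    barcode = qc$cell_ids, label = ann$label,
    best_score = apply(ann$score, 1, max),
    p_best = apply(ann$adj_p, 1, min), stringsAsFactors = FALSE)
  files <- c(files, .write_tsv(adf, file.path(out, "annotation.tsv")))

  # --- markers ---
  .stage_msg("stage markers (p<", config$p_thresh, ", auc>",
             config$auc_thresh, ", lfc>", config$lfc_thresh, ")")
  sig <- signature_profiles(rp, ann$label)
  res <- wilcoxon_markers(nm, ann$label, config$p_thresh,
                          config$auc_thresh, config$lfc_thresh)
  top <- rank_top(sig, res)
  files <- c(files, .write_tsv(res, file.path(out, "marker_tests.tsv")))
  topdf <- do.call(rbind, lapply(names(top), function(t)
    if (nrow(top[[t]])) cbind(type = t, top[[t]]) else NULL))
  files <- c(files, .write_tsv(topdf, file.path(out, "top_markers.tsv")))

  # --- subtypes ---
  subres <- NULL
  if (isTRUE(config$run_subtypes) &&
      sum(ann$label == config$subtype_parent) >= 50) {
    .stage_msg("stage subtypes (parent=", config$subtype_parent,
               ", k=", config$subtype_k, ")")
    sub <- extract_and_clean(qc, ann$label, net, config$subtype_parent,
                             config$contamination_markers,
                             n_perm = config$n_perm, seed = seed + 2L)
    sc <- subcluster(sub, k = config$subtype_k,
                     batch = if (is.null(sub$cell_meta)) NULL else
                       sub$cell_meta$batch,
                     restarts = config$restarts, seed = seed + 3L)
    smk <- subtype_markers(sub, sc$labels, p_thresh = config$p_thresh)
    region <- if (!is.null(sub$cell_meta)) {
      sub$cell_meta[names(sc$labels), "region"]
    } else NULL
    enr <- if (!is.null(region) && length(unique(region)) == 2)
      region_enrichment(sc$labels, region, sc$H) else NULL
    sdf <- data.frame(barcode = names(sc$labels), subtype = sc$labels,
                      stringsAsFactors = FALSE)
    files <- c(files, .write_tsv(sdf, file.path(out, "subtypes.tsv")))
    if (!is.null(enr))
      files <- c(files, .write_tsv(enr$table,
                                   file.path(out, "region_enrichment.tsv")))
    subres <- list(subset = sub, clusters = sc, markers = smk,
                   enrichment = enr)
  }

  # --- gwas ---
  gwres <- NULL
  if (isTRUE(config$run_gwas)) {
    .stage_msg("stage gwas")
    genes <- config$gwas_genes
    stats_list <- config$gwas_stats
    if (is.null(stats_list) && !is.null(truth)) {
      # synthetic trait: planted enrichment on the macroglial set, plus a
      # null negative-control trait
      planted <- truth$true_markers[["macroglia"]]
      if (is.null(planted)) planted <- truth$true_markers[[1]]
      stats_list <- list(
        trait_planted = generate_gwas_stats(
          nm$gene_ids, intersect(planted, nm$gene_ids), effect = 0.5,
          seed = seed + 4L),
        trait_null = generate_gwas_stats(
          nm$gene_ids, intersect(planted, nm$gene_ids), effect = 0,
          seed = seed + 5L))
    }
    if (is.null(genes) && !is.null(truth))
      genes <- unique(unlist(truth$true_markers))
    if (!is.null(stats_list) && !is.null(genes)) {
      spec <- specificity_scores(nm, ann$label, genes)
      sets <- build_gene_sets(nm, qc, ann$label)
      panel <- negative_control_panel(stats_list, sets)
      files <- c(files, .write_tsv(spec, file.path(out, "specificity.tsv")))
      pdf_ <- data.frame(trait = rownames(panel$neglog10p),
                         panel$neglog10p, check.names = FALSE)
      files <- c(files, .write_tsv(pdf_, file.path(out,
                                                   "gwas_association.tsv")))
      gwres <- list(specificity = spec, sets = sets, panel = panel)
    }
  }

  manifest <- data.frame(
    file = sub(paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                                normalizePath(out)), "/?"), "",
               normalizePath(files)),
    md5 = unname(tools::md5sum(files)), stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  .write_tsv(manifest, file.path(out, "manifest.tsv"))
  .stage_msg("done: ", nrow(manifest), " artifacts in ", out)
  invisible(list(counts = counts, qc = qc, nm = nm, rp = rp,
                 ladder = ladder, network = net, annotation = ann,
                 signatures = sig, markers = res, top_markers = top,
                 subtypes = subres, gwas = gwres, truth = truth,
                 manifest = manifest, out_dir = out))
}
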