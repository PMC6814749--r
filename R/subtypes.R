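#' Extract a cell class and remove contamination-marker doublets
#'
#' Retains cells annotated with the parent label and removes those whose
#' contamination-marker association score (the diffusion-scoring and
#' permutation machinery of the annotation stage, run on the induced
#' subnetwork) is significant — in the retina use case, macroglial cells
#' still carrying rod-specific markers.
#'
#' @param counts A [count_matrix()] covering all annotated cells.
#' @param labels Per-cell labels aligned with `counts`.
#' @param net The full [build_kstar_nn()] cell network (its induced
#'   subgraph provides the diffusion context); `NULL` scores raw
#'   normalized expression without diffusion.
#' @param parent Parent label to extract (e.g. `"macroglia"`).
#' @param contamination_markers Character vector of contamination marker
#'   genes (e.g. rod markers); empty means pure extraction.
#' @param sig_level Removal threshold on the adjusted permutation p.
#' @param n_perm,seed Permutation settings.
#' @param min_parent Minimum parent cells required (default 50).
#' @return A [count_matrix()] subset, with attributes `removed`
#'   (barcodes) and `n_removed`.
#' @export
extract_and_clean <- function(counts, labels, net = NULL, parent,
                              contamination_markers = retina_markers()$rods,
                              sig_level = 0.05, n_perm = 1000, seed = 1L,
                              min_parent = 50) {
  stopifnot(inherits(counts, "count_matrix"),
            length(labels) == ncol(counts$values))
  idx <- which(labels == parent)
  if (length(idx) == 0) stop("no cells carry the parent label: ", parent)
  if (length(idx) < min_parent)
    stop("fewer than ", min_parent, " parent cells")
  sub <- subset_counts(counts, cells = idx)
  if (length(contamination_markers) == 0) {
    attr(sub, "removed") <- character(0)
    attr(sub, "n_removed") <- 0L
    return(sub)
  }
  # never remove a cell with zero contamination-marker counts
  mk <- intersect(contamination_markers, sub$gene_ids)
  has_any <- if (length(mk))
    Matrix::colSums(sub$values[mk, , drop = FALSE]) > 0
  else rep(FALSE, ncol(sub$values))
  nm <- depth_normalize(qc_nonzero(sub))
  subnet <- .induced_network(net, counts$cell_ids[idx], nm$cell_ids)
  pt <- permutation_test(subnet, nm,
                         markers = list(contamination = contamination_markers),
                         n_perm = n_perm, seed = seed)
  signif <- pt$adj_p[, 1] < sig_level
  drop_bc <- nm$cell_ids[signif]
  drop_bc <- drop_bc[has_any[match(drop_bc, sub$cell_ids)]]
  keep <- setdiff(sub$cell_ids, drop_bc)
  if (length(keep) == 0) stop("no cells left after contamination cleaning")
  out <- subset_counts(sub, cells = match(keep, sub$cell_ids))
  attr(out, "removed") <- drop_bc
  attr(out, "n_removed") <- length(drop_bc)
  message(length(drop_bc), " contaminated cells removed")
  out
}

# drop all-zero cells (qc guard before normalization of a subset)
qc_nonzero <- function(m) {
  keep <- Matrix::colSums(m$values) > 0
  subset_counts(m, cells = which(keep))
}

# induced subnetwork on a barcode subset; builds a fresh k*-NN network
# from raw profiles when no parent network is supplied
.induced_network <- function(net, subset_ids, final_ids) {
  if (is.null(net)) return(NULL)
  keep <- match(final_ids, net$cell_ids)
  g <- igraph::induced_subgraph(net$graph, keep)
  structure(list(graph = g, cell_ids = final_ids,
                 k_star = igraph::degree(g), layout = NULL),
            class = "cell_network")
}

#' Subcluster a cell subset via a sub-network archetypal decomposition
#'
#' Re-runs the normalization, reduction, MNN correction and archetypal
#' decomposition on the subset and assigns each cell to its dominant
#' archetype at resolution `k`. With `k = "auto"` the resolution in
#' `k_range` maximizing mean pairwise label agreement (adjusted Rand
#' index) across restarts is chosen. Clusters are relabeled by
#' decreasing size.
#'
#' @param subset A [count_matrix()] subset (>= 50 cells; smaller inputs
#'   are allowed for toy examples but a warning is emitted).
#' @param k Number of subtypes, or `"auto"`.
#' @param k_range Candidate resolutions for `"auto"`.
#' @param d Reduction dimension (capped by the subset size).
#' @param batch Optional per-cell batch labels for MNN re-correction.
#' @param restarts,seed Decomposition settings.
#' @return list with `labels` (subtype_1, ... by size), `H` (archetype
#'   footprints, k x cells), `network`, `reduced`, `k`.
#' @export
subcluster <- function(subset, k = 3, k_range = 2:6, d = 30,
                       batch = NULL, restarts = 3, seed = 1L) {
  stopifnot(inherits(subset, "count_matrix"))
  n <- ncol(subset$values)
  if (n < 50) warning("subclustering fewer than 50 cells")
  nm <- depth_normalize(qc_nonzero(subset))
  d <- min(d, nrow(nm$values) - 1, ncol(nm$values) - 1)
  rp <- reduce_profile(nm, d = d)
  if (!is.null(batch)) {
    b <- batch[match(nm$cell_ids, subset$cell_ids)]
    if (length(unique(b)) > 1 && min(table(b)) > 20)
      rp$scores <- mnn_correct(rp$scores, b)
  }
  S <- t(rp$scores)
  if (identical(k, "auto")) {
    ag <- vapply(k_range, function(kk) {
      labs <- lapply(seq_len(5), function(r)
        .dominant_archetype(action_decompose(
          S, kk, restarts = 1, seed = seed + 97L * r)$H))
      pairs <- utils::combn(5, 2)
      mean(apply(pairs, 2, function(pp)
        .rand_index_adj(labs[[pp[1]]], labs[[pp[2]]])))
    }, numeric(1))
    k <- k_range[which.max(ag)]
  }
  if (k == 1) {
    labels <- stats::setNames(rep("subtype_1", n), subset$cell_ids)
    return(list(labels = labels, H = matrix(1, 1, n), network = NULL,
                reduced = rp, k = 1L))
  }
  fit <- action_decompose(S, k, restarts = restarts, seed = seed)
  raw <- .dominant_archetype(fit$H)
  # relabel by decreasing cluster size (ties by first occurrence)
  sizes <- sort(table(raw), decreasing = TRUE)
  map <- stats::setNames(paste0("subtype_", seq_along(sizes)), names(sizes))
  labels <- stats::setNames(map[as.character(raw)], nm$cell_ids)
  H <- fit$H[as.integer(names(sizes)), , drop = FALSE]
  rownames(H) <- map
  colnames(H) <- nm$cell_ids
  net <- tryCatch(
    build_kstar_nn(cell_profiles(structure(
      list(fits = list(fit), depths = k, cell_ids = nm$cell_ids),
      class = "archetype_ladder"))),
    error = function(e) NULL)
  list(labels = labels, H = H, network = net, reduced = rp, k = k)
}

.dominant_archetype <- function(H) apply(H, 2, which.max)

# adjusted Rand index (used internally for the "auto" stability rule)
.rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(v) sum(choose(v, 2))
  sij <- sum(choose(tab, 2))
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  exp_idx <- si * sj / choose(n, 2)
  max_idx <- (si + sj) / 2
  if (max_idx == exp_idx) return(1)
  (sij - exp_idx) / (max_idx - exp_idx)
}

#' Subtype markers
#'
#' Delegates to [wilcoxon_markers()] on the subset.
#'
#' @param subset A [count_matrix()] subset.
#' @param labels Subtype labels from [subcluster()].
#' @param ... Passed to [wilcoxon_markers()].
#' @return A `marker_test` data frame.
#' @export
subtype_markers <- function(subset, labels, ...) {
  nm <- depth_normalize(qc_nonzero(subset))
  wilcoxon_markers(nm, labels[match(nm$cell_ids, names(labels))], ...)
}

#' Regional enrichment of subtypes
#'
#' Primary test: per subtype, a one-sided Wilcoxon rank-sum on the
#' per-cell subtype-association scores (archetype footprints) between
#' macula and periphery, in each direction. Companion: a two-proportion
#' test on subtype frequencies. Optionally, per-gene regional expression
#' tests (one-sided Wilcoxon on normalized expression, macula >
#' periphery).
#'
#' @param labels Per-cell subtype labels.
#' @param region Per-cell region labels in {macula, periphery}.
#' @param scores Subtypes x cells association-score matrix (`H` from
#'   [subcluster()]); `NULL` falls back to 0/1 membership scores.
#' @param nm Optional `normalized_matrix` for `test_genes`.
#' @param test_genes Genes to test for macula-vs-periphery expression.
#' @return Object of class `region_enrichment`: data.frame per subtype
#'   (freq_macula, freq_periphery, p_macula, p_periphery, direction,
#'   p_prop), plus optional `gene_tests`.
#' @export
region_enrichment <- function(labels, region, scores = NULL,
                              nm = NULL, test_genes = NULL) {
  stopifnot(length(labels) == length(region))
  region <- as.character(region)
  if (!all(region %in% c("macula", "periphery")))
    stop("region labels must be macula/periphery")
  if (length(unique(region)) < 2)
    stop("both regions must be represented")
  subtypes <- sort(unique(labels))
  if (is.null(scores)) {
    scores <- t(vapply(subtypes, function(s) as.numeric(labels == s),
                       numeric(length(labels))))
    rownames(scores) <- subtypes
  }
  in_mac <- region == "macula"
  rows <- lapply(subtypes, function(s) {
    fm <- mean(labels[in_mac] == s)
    fp <- mean(labels[!in_mac] == s)
    sc <- scores[s, ]
    if (length(subtypes) == 1) {
      return(data.frame(subtype = s, freq_macula = fm, freq_periphery = fp,
                        p_macula = NA_real_, p_periphery = NA_real_,
                        direction = "none", p_prop = NA_real_,
                        stringsAsFactors = FALSE))
    }
    pm <- stats::wilcox.test(sc[in_mac], sc[!in_mac],
                             alternative = "greater", exact = FALSE)$p.value
    pp <- stats::wilcox.test(sc[!in_mac], sc[in_mac],
                             alternative = "greater", exact = FALSE)$p.value
    np <- suppressWarnings(stats::prop.test(
      c(sum(labels[in_mac] == s), sum(labels[!in_mac] == s)),
      c(sum(in_mac), sum(!in_mac)))$p.value)
    data.frame(subtype = s, freq_macula = fm, freq_periphery = fp,
               p_macula = pm, p_periphery = pp,
               direction = if (pm < pp) "macula" else "periphery",
               p_prop = np, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  gene_tests <- NULL
  if (!is.null(nm) && length(test_genes)) {
    g <- intersect(test_genes, nm$gene_ids)
    gene_tests <- do.call(rbind, lapply(g, function(gg) {
      v <- as.numeric(nm$values[gg, ])
      data.frame(
        gene = gg,
        p_macula_gt = stats::wilcox.test(
          v[in_mac], v[!in_mac], alternative = "greater",
          exact = FALSE)$p.value,
        stringsAsFactors = FALSE)
    }))
  }
  structure(list(table = out, gene_tests = gene_tests),
            class = "region_enrichment")
}

#' @export
print.region_enrichment <- function(x, ...) {
  print(x$table)
  if (!is.null(x$gene_tests)) print(x$gene_tests)
  invisible(x)
}
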