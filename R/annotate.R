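# column-stochastic transition matrix of the weighted graph; isolated
# nodes transition to themselves
.transition_matrix <- function(net) {
  g <- net$graph
  n <- igraph::vcount(g)
  A <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = TRUE)
  A <- methods::as(A, "CsparseMatrix")
  deg <- Matrix::colSums(A)
  iso <- which(deg == 0)
  if (length(iso)) {
    A <- A + Matrix::sparseMatrix(i = iso, j = iso, x = 1, dims = c(n, n))
    deg[iso] <- 1
  }
  A %*% Matrix::Diagonal(x = 1 / deg)
}

#' Network diffusion with restart
#'
#' Computes `s = (1 - alpha) (I - alpha P)^{-1} x` where `P` is the
#' column-stochastic transition matrix of the weighted cell network
#' (random walk with restart). Total mass is conserved:
#' `sum(s) = sum(x)`. Isolated nodes keep their own value.
#'
#' @param net A [build_kstar_nn()] network.
#' @param x Per-cell nonnegative vector (or cells x m matrix, diffused
#'   column-wise).
#' @param alpha Restart-complement in [0, 1); `alpha = 0` returns `x`.
#' @param tol Convergence tolerance of the iterative solve.
#' @return Diffused vector/matrix of the same shape.
#' @export
diffuse <- function(net, x, alpha = 0.85, tol = 1e-8) {
  stopifnot(inherits(net, "cell_network"), alpha >= 0, alpha < 1)
  vec_in <- is.null(dim(x))
  X <- if (vec_in) matrix(x, ncol = 1) else as.matrix(x)
  if (nrow(X) != length(net$cell_ids))
    stop("x is not aligned with the network nodes")
  if (alpha == 0) return(if (vec_in) as.numeric(X) else X)
  P <- .transition_matrix(net)
  S <- X
  X0 <- (1 - alpha) * X
  # fixed-point iteration; contraction factor alpha
  max_it <- ceiling(log(tol) / log(alpha)) + 5
  for (it in seq_len(max_it)) {
    S_new <- as.matrix(alpha * (P %*% S)) + X0
    if (max(abs(S_new - S)) < tol * max(1, max(abs(X)))) { S <- S_new; break }
    S <- S_new
  }
  if (vec_in) as.numeric(S) else S
}

# diffuse every gene of a normalized matrix at once (direct sparse solve;
# mathematically identical to the iterative form, exact to solver precision)
.diffuse_all_genes <- function(net, nm, alpha = 0.85) {
  n <- length(net$cell_ids)
  X <- t(as.matrix(nm$values))             # cells x genes
  if (alpha == 0) return(X)
  P <- .transition_matrix(net)
  A <- Matrix::Diagonal(n) - alpha * P
  S <- as.matrix(Matrix::solve(A, (1 - alpha) * X))
  dimnames(S) <- dimnames(X)
  S
}

# standardize columns across cells; `scale_by` supplies the per-column
# scale (defaults to the column sd); zero-variance columns become all-zero
.zscale_cols <- function(M, scale_by = NULL) {
  mu <- colMeans(M)
  sd <- if (is.null(scale_by))
    sqrt(pmax(colMeans(M^2) - mu^2, 0)) else scale_by
  Z <- sweep(M, 2, mu)
  keep <- sd > 1e-12
  Z[, keep] <- sweep(Z[, keep, drop = FALSE], 2, sd[keep], "/")
  Z[, !keep] <- 0
  Z
}

# shared scoring machinery: diffused, degree-debiased and z-scaled
# expression of every gene, detection-rate bins for frequency-matched null
# draws, matched marker sets. The diffused values are divided by the
# diffused unit vector: on irregular graphs the restart walk concentrates
# mass on high-degree cells for every gene alike, and the ratio removes
# that shared bias before z-scaling.
.score_machinery <- function(net, nm, markers, alpha = 0.85, n_bins = 10) {
  S <- .diffuse_all_genes(net, nm, alpha)
  if (alpha > 0) {
    n <- length(net$cell_ids)
    P <- .transition_matrix(net)
    bias <- as.numeric(Matrix::solve(
      Matrix::Diagonal(n) - alpha * P, (1 - alpha) * rep(1, n)))
    S <- S / bias
  }
  # standardize by the raw expression sd: the diffused profile of a
  # sparsely expressed noise gene has near-zero spread, and dividing by it
  # would turn local noise bumps into extreme z-values
  rmu <- Matrix::rowMeans(nm$values)
  raw_sd <- sqrt(pmax(Matrix::rowMeans(nm$values^2) - rmu^2, 0))
  raw_sd[raw_sd <= 1e-8 * (1 + abs(rmu))] <- 0  # constant genes
  Z <- .zscale_cols(S, scale_by = raw_sd)
  genes <- nm$gene_ids
  matched <- lapply(markers, function(g) {
    i <- match(g, genes)
    i[!is.na(i)]
  })
  missing <- lapply(seq_along(markers), function(t)
    setdiff(markers[[t]], genes))
  names(missing) <- names(markers)
  empty <- vapply(matched, length, integer(1)) == 0
  if (any(empty)) {
    warning("cell types with no matched markers excluded: ",
            paste(names(markers)[empty], collapse = ", "))
    matched <- matched[!empty]
  }
  if (length(matched) == 0) stop("no marker matched any gene")
  det <- Matrix::rowMeans(nm$values > 0)
  br <- unique(stats::quantile(det, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(det, breaks = br, include.lowest = TRUE, labels = FALSE)
  bin_members <- split(seq_along(genes), bin)
  list(Z = Z, matched = matched, missing = missing, bin = bin,
       bin_members = bin_members, cell_ids = nm$cell_ids)
}

#' Marker-based cell-type association scores
#'
#' Each marker gene's depth-normalized expression is imputed over the
#' cell network by diffusion, z-scaled across cells, and the z-values of a
#' type's markers averaged into a per-cell association score.
#'
#' @param net A [build_kstar_nn()] network.
#' @param nm A [depth_normalize()] result aligned with the network.
#' @param markers Named list, cell type -> gene symbols (case-sensitive);
#'   default the curated retina panel [retina_markers()].
#' @param alpha Diffusion restart-complement.
#' @return Cells x types score matrix.
#' @export
score_cell_types <- function(net, nm, markers = retina_markers(),
                             alpha = 0.85) {
  mach <- .score_machinery(net, nm, markers, alpha)
  .scores_from_machinery(mach)
}

.scores_from_machinery <- function(mach) {
  sc <- vapply(mach$matched,
               function(i) rowMeans(mach$Z[, i, drop = FALSE]),
               numeric(nrow(mach$Z)))
  rownames(sc) <- mach$cell_ids
  sc
}

#' Permutation test of association scores
#'
#' Null scores are built from random gene sets of matched size, drawn from
#' detection-frequency-matched bins (genes binned by detection rate).
#' Empirical p-values use the plus-one estimator
#' `p = (1 + #(null >= obs)) / (1 + n_perm)` and are Benjamini-Hochberg
#' adjusted per cell across types.
#'
#' @inheritParams score_cell_types
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return list with `score` (cells x types), `perm_p` (raw empirical p),
#'   `adj_p` (BH per cell across types).
#' @export
permutation_test <- function(net, nm, markers = retina_markers(),
                             alpha = 0.85, n_perm = 1000, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  mach <- .score_machinery(net, nm, markers, alpha)
  set.seed(seed)
  obs <- .scores_from_machinery(mach)
  n_cells <- nrow(obs)
  types <- colnames(obs)
  ge <- matrix(0, n_cells, length(types), dimnames = dimnames(obs))
  for (t in seq_along(types)) {
    idx <- mach$matched[[t]]
    m <- length(idx)
    pools <- mach$bin_members[as.character(mach$bin[idx])]
    for (j in seq_along(pools))
      if (length(pools[[j]]) < 2) pools[[j]] <- seq_along(mach$bin)
    draw <- vapply(pools, function(p)
      p[sample.int(length(p), n_perm, replace = TRUE)],
      integer(n_perm))                      # n_perm x m
    draw <- matrix(draw, nrow = n_perm)
    # averaging operator: genes x n_perm sparse, 1/m per drawn gene
    Ag <- Matrix::sparseMatrix(
      i = as.integer(t(draw)),
      j = rep(seq_len(n_perm), each = m),
      x = 1 / m, dims = c(ncol(mach$Z), n_perm))
    nullsc <- mach$Z %*% Ag                 # cells x n_perm
    ge[, t] <- Matrix::rowSums(nullsc >= obs[, t])
  }
  perm_p <- (1 + ge) / (1 + n_perm)
  adj_p <- if (ncol(perm_p) == 1) perm_p else {
    a <- t(apply(perm_p, 1, stats::p.adjust, method = "BH"))
    dimnames(a) <- dimnames(perm_p)
    a
  }
  list(score = obs, perm_p = perm_p, adj_p = adj_p)
}

#' Assign cell labels from scores and permutation p-values
#'
#' A cell significant (adjusted p below `sig_level`) for exactly one type
#' gets that label; zero significant types yields `unassigned_none`, two
#' or more yields `unassigned_multi` (doublet suspects). When exactly one
#' type is significant the label is the argmax-score significant type.
#'
#' @param scores Cells x types score matrix.
#' @param adj_p Matching matrix of BH-adjusted permutation p-values.
#' @param sig_level Significance threshold (default 0.05).
#' @return Character vector of labels/filter codes.
#' @export
assign_labels <- function(scores, adj_p, sig_level = 0.05) {
  stopifnot(all(dim(scores) == dim(adj_p)))
  sig <- adj_p < sig_level
  n_sig <- rowSums(sig)
  lab <- rep("unassigned_none", nrow(scores))
  lab[n_sig >= 2] <- "unassigned_multi"
  one <- which(n_sig == 1)
  if (length(one)) {
    masked <- scores[one, , drop = FALSE]
    masked[!sig[one, , drop = FALSE]] <- -Inf
    lab[one] <- colnames(scores)[max.col(masked, ties.method = "first")]
  }
  names(lab) <- rownames(scores)
  lab
}

#' Neighborhood-coherence filter
#'
#' For each labeled cell, a one-sided hypergeometric test asks whether its
#' network neighbors are enriched for the same label relative to the
#' label's global frequency; cells whose BH-adjusted p-value is not below
#' `alpha_test` are flagged `incoherent_neighborhood`. Degree-zero nodes
#' are flagged by convention.
#'
#' @param net A [build_kstar_nn()] network.
#' @param labels Per-cell labels (filter codes are passed through).
#' @param alpha_test Significance level (default 0.05).
#' @return Labels with incoherent cells recoded.
#' @export
coherence_filter <- function(net, labels, alpha_test = 0.05) {
  stopifnot(length(labels) == length(net$cell_ids))
  g <- net$graph
  nbr <- igraph::adjacent_vertices(g, igraph::V(g))
  is_type <- !labels %in%
    c("unassigned_none", "unassigned_multi", "incoherent_neighborhood")
  tab <- table(labels[is_type])
  n_lab <- sum(is_type)
  pv <- rep(NA_real_, length(labels))
  for (i in which(is_type)) {
    nb <- as.integer(nbr[[i]])
    nb <- nb[is_type[nb]]
    k <- length(nb)
    if (k == 0) { pv[i] <- 1; next }
    same <- sum(labels[nb] == labels[i])
    if (same == k) { pv[i] <- 0; next }  # saturated: maximally coherent
    K <- tab[[labels[i]]]
    # P(X >= same) drawing k from n_lab with K successes
    pv[i] <- stats::phyper(same - 1, K, n_lab - K, k, lower.tail = FALSE)
  }
  adj <- pv
  adj[is_type] <- stats::p.adjust(pv[is_type], method = "BH")
  out <- labels
  out[is_type & !(adj < alpha_test)] <- "incoherent_neighborhood"
  deg0 <- igraph::degree(g) == 0
  out[is_type & deg0] <- "incoherent_neighborhood"
  names(out) <- net$cell_ids
  out
}

#' Full marker-based annotation
#'
#' Runs scoring, permutation testing, label assignment, and the
#' neighborhood-coherence filter in one pass.
#'
#' @inheritParams permutation_test
#' @param sig_level Assignment significance threshold.
#' @param coherence Apply the coherence filter (default TRUE).
#' @return Object of class `cell_annotation` with `score`, `perm_p`,
#'   `adj_p`, `label` (post-filter), `label_raw` (pre-coherence).
#' @export
annotate_cells <- function(net, nm, markers = retina_markers(),
                           alpha = 0.85, n_perm = 1000, seed = 1L,
                           sig_level = 0.05, coherence = TRUE) {
  pt <- permutation_test(net, nm, markers, alpha, n_perm, seed)
  lab_raw <- assign_labels(pt$score, pt$adj_p, sig_level)
  lab <- if (coherence) coherence_filter(net, lab_raw) else lab_raw
  structure(list(score = pt$score, perm_p = pt$perm_p, adj_p = pt$adj_p,
                 label = lab, label_raw = lab_raw),
            class = "cell_annotation")
}

#' @export
print.cell_annotation <- function(x, ...) {
  cat("cell_annotation:\n")
  print(table(x$label))
  invisible(x)
}

#' @export
summary.cell_annotation <- function(object, ...) {
  tab <- table(object$label)
  filt <- sum(tab[names(tab) %in% c("unassigned_none", "unassigned_multi",
                                    "incoherent_neighborhood")])
  cat(sprintf("%d cells, %d assigned, %d filtered\n",
              length(object$label), length(object$label) - filt, filt))
  print(tab)
  invisible(tab)
}
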