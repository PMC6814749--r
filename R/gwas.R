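#' Cell-type specificity scores for a locus gene list
#'
#' For each locus gene present in the matrix, a one-sided Wilcoxon
#' rank-sum test of expression within each cell type versus the rest
#' (delegated to the marker machinery); p-values are BH adjusted across
#' all tested (gene, type) pairs, clipped below at 1e-300, and scored as
#' `-log10(adjusted p)` with a stringent significance threshold of 1e-10.
#'
#' @param nm A [depth_normalize()] result.
#' @param labels Per-cell labels; filter codes ignored.
#' @param genes Locus gene list (character).
#' @param p_clip Lower clip for p-values (default 1e-300).
#' @param sig_thresh Significance threshold (default 1e-10).
#' @return data.frame: gene, type, p, adj_p, score (in [0, 300]),
#'   significant; attribute `skipped` lists genes absent from the matrix.
#' @export
specificity_scores <- function(nm, labels, genes,
                               p_clip = 1e-300, sig_thresh = 1e-10) {
  present <- intersect(genes, nm$gene_ids)
  skipped <- setdiff(genes, nm$gene_ids)
  if (length(present) == 0) stop("no locus gene found in the matrix")
  sub <- nm
  sub$values <- nm$values[match(present, nm$gene_ids), , drop = FALSE]
  sub$gene_ids <- present
  res <- wilcoxon_markers(sub, labels, p_thresh = 1)  # reuse the test path
  res$adj_p <- stats::p.adjust(res$p, method = "BH")
  res$adj_p <- pmax(res$adj_p, p_clip)
  out <- data.frame(gene = res$gene, type = res$type, p = res$p,
                    adj_p = res$adj_p, score = -log10(res$adj_p),
                    significant = res$adj_p < sig_thresh,
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Cell-type preferential gene sets
#'
#' Per type: genes with one-sided Wilcoxon FDR below `fdr` (type versus
#' rest, BH across all gene-type pairs) that are detected (raw count > 0)
#' in at least `min_detect` of the type's cells.
#'
#' @param nm A [depth_normalize()] result.
#' @param counts The matching raw [count_matrix()] (detection fractions
#'   are recomputed from raw counts).
#' @param labels Per-cell labels.
#' @param fdr FDR threshold (default 0.01).
#' @param min_detect Minimum detection fraction (default 0.25).
#' @return Named list of gene vectors per type; empty sets are reported
#'   via a warning and dropped.
#' @export
build_gene_sets <- function(nm, counts, labels, fdr = 0.01,
                            min_detect = 0.25) {
  stopifnot(inherits(counts, "count_matrix"))
  res <- wilcoxon_markers(nm, labels, p_thresh = fdr, auc_thresh = 0,
                          lfc_thresh = -Inf)
  keep <- !labels %in% c("unassigned_none", "unassigned_multi",
                         "incoherent_neighborhood") & !is.na(labels)
  types <- sort(unique(res$type))
  idx <- match(nm$gene_ids, counts$gene_ids)
  sets <- lapply(types, function(t) {
    g <- res$gene[res$type == t & res$adj_p < fdr]
    if (length(g) == 0) return(character(0))
    cells <- which(keep & labels == t)
    det <- Matrix::rowMeans(
      counts$values[idx[match(g, nm$gene_ids)], cells, drop = FALSE] > 0)
    g[det >= min_detect]
  })
  names(sets) <- types
  empty <- vapply(sets, length, integer(1)) == 0
  if (any(empty)) {
    warning("empty gene sets dropped: ",
            paste(types[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  sets
}

#' Competitive gene-set regression
#'
#' Ordinary least squares of gene-level association Z-scores on an
#' intercept, a gene-set membership indicator, and covariates, with a
#' one-sided t-test for a positive membership coefficient (the
#' competitive gene-set analysis of the MAGMA family, taking gene-level
#' statistics as input).
#'
#' @param stats data.frame with columns `gene`, `z`, and any covariates.
#' @param set Character vector of member genes (nonempty strict subset of
#'   `stats$gene`).
#' @param covariates Covariate column names (default `"gene_size"` when
#'   present).
#' @return One-row data.frame: beta, se, t, p (one-sided), neglog10p, n,
#'   n_members, covariates.
#' @export
geneset_regression <- function(stats, set,
                               covariates = intersect("gene_size",
                                                      names(stats))) {
  stopifnot(is.data.frame(stats), all(c("gene", "z") %in% names(stats)))
  if (nrow(stats) < 50) stop("need at least 50 genes")
  member <- as.numeric(stats$gene %in% set)
  if (sum(member) == 0) stop("gene set does not overlap the statistics")
  if (all(member == 1))
    stop("gene set equals the whole universe: membership is collinear")
  M <- cbind(intercept = 1, member = member)
  for (cv in covariates) M <- cbind(M, stats[[cv]])
  colnames(M) <- c("intercept", "member", covariates)
  q <- qr(M)
  if (q$rank < ncol(M))
    stop("membership is collinear with the covariates")
  fit <- stats::lm.fit(M, stats$z)
  df <- nrow(M) - ncol(M)
  s2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(qr.R(q))
  se <- sqrt(s2 * XtXinv[2, 2])
  beta <- fit$coefficients["member"]
  tval <- beta / se
  p <- stats::pt(tval, df, lower.tail = FALSE)
  data.frame(beta = unname(beta), se = se, t = tval, p = p,
             neglog10p = -log10(max(p, 1e-300)),
             n = nrow(M), n_members = sum(member),
             covariates = paste(covariates, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Cell-type association panel across traits
#'
#' Runs [geneset_regression()] for every (trait, cell-type gene set)
#' combination — e.g. the disease of interest plus negative-control
#' traits — and assembles the -log10 p matrix with significance marks at
#' p < 0.05.
#'
#' @param stats_list Named list of per-trait gene-statistics tables.
#' @param sets Named list of per-type gene sets ([build_gene_sets()]).
#' @param ... Passed to [geneset_regression()].
#' @return list with `neglog10p` and `significant` (traits x types
#'   matrices) and `detail` (long data.frame).
#' @export
negative_control_panel <- function(stats_list, sets, ...) {
  if (length(stats_list) < 2)
    stop("supply at least 2 trait statistics tables")
  traits <- names(stats_list)
  types <- names(sets)
  nl <- matrix(NA_real_, length(traits), length(types),
               dimnames = list(traits, types))
  sg <- matrix(NA, length(traits), length(types),
               dimnames = list(traits, types))
  rows <- list()
  for (tr in traits) {
    st <- stats_list[[tr]]
    for (ty in types) {
      res <- tryCatch(geneset_regression(st, sets[[ty]], ...),
                      error = function(e) NULL)
      if (is.null(res)) next
      nl[tr, ty] <- res$neglog10p
      sg[tr, ty] <- res$p < 0.05
      rows[[paste(tr, ty)]] <- cbind(trait = tr, type = ty, res)
    }
  }
  list(neglog10p = nl, significant = sg,
       detail = if (length(rows)) do.call(rbind, rows) else NULL)
}
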