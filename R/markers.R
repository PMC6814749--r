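#' Cell-type signature profiles (discriminating power)
#'
#' For each cell type, the member cells' reduced scores are averaged into
#' a metagene vector, back-transformed to gene space with the
#' left-singular vectors (`basis %*% metagene`), and the resulting gene x
#' type matrix is centered per gene across types so entries measure the
#' influence of each gene in distinguishing one type from the rest.
#'
#' @param rp A [reduce_profile()] result.
#' @param labels Per-cell labels; filter codes
#'   (`unassigned_*`, `incoherent_neighborhood`) are ignored.
#' @param min_cells Types with fewer member cells are excluded with a
#'   warning (default 3).
#' @return Object of class `signature_profile`: `power` (genes x types,
#'   centered), `baseline` (per-gene mean across types, uncentered),
#'   `raw` (uncentered back-transform), `gene_ids`.
#' @export
signature_profiles <- function(rp, labels, min_cells = 3) {
  stopifnot(inherits(rp, "reduced_profile"))
  stopifnot(length(labels) == nrow(rp$scores))
  keep <- !labels %in% c("unassigned_none", "unassigned_multi",
                         "incoherent_neighborhood") & !is.na(labels)
  types <- sort(unique(labels[keep]))
  sizes <- table(labels[keep])
  small <- types[sizes[types] < min_cells]
  if (length(small)) {
    warning("types with fewer than ", min_cells, " cells excluded: ",
            paste(small, collapse = ", "))
    types <- setdiff(types, small)
  }
  if (length(types) < 2) stop("need at least 2 labeled types")
  meta <- vapply(types, function(t)
    colMeans(rp$scores[keep & labels == t, , drop = FALSE]),
    numeric(ncol(rp$scores)))                 # d x types
  raw <- rp$basis %*% meta                    # genes x types
  rownames(raw) <- rp$gene_ids
  baseline <- rowMeans(raw)
  power <- raw - baseline
  rownames(power) <- rp$gene_ids
  structure(list(power = power, baseline = baseline, raw = raw,
                 gene_ids = rp$gene_ids, types = types),
            class = "signature_profile")
}

#' @export
print.signature_profile <- function(x, ...) {
  cat(sprintf("signature_profile: %d genes x %d types\n",
              nrow(x$power), ncol(x$power)))
  invisible(x)
}

# tie term sum(t^3 - t) per gene, over values across all cells
.tie_terms <- function(X) {
  apply(X, 1, function(v) {
    t <- rle(sort(v))$lengths
    sum(t^3 - t)
  })
}

# one-sided (greater) Wilcoxon rank-sum of group-1 values vs group-2,
# exact via the null U distribution when sizes are small and there are no
# ties, otherwise normal approximation with continuity and tie correction
.wilcox_greater <- function(x, y, exact_max_group = 8, exact_max_total = 25) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  auc <- U / (n1 * n2)
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (!has_ties && min(n1, n2) <= exact_max_group &&
      n1 + n2 <= exact_max_total) {
    p <- stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
  } else {
    N <- n1 + n2
    t <- rle(sort(c(x, y)))$lengths
    tie <- sum(t^3 - t)
    sig2 <- n1 * n2 / 12 * ((N + 1) - tie / (N * (N - 1)))
    if (sig2 <= 0) return(list(U = U, auc = auc, p = 1))
    z <- (U - n1 * n2 / 2 - 0.5) / sqrt(sig2)
    p <- stats::pnorm(z, lower.tail = FALSE)
  }
  list(U = U, auc = auc, p = p)
}

#' One-sided Wilcoxon marker selection
#'
#' For every (gene, type) pair, tests type-member expression greater than
#' the rest (one-sided rank-sum; exact null distribution for small
#' tie-free groups, normal approximation with continuity and tie
#' correction otherwise), with AUC = U / (n1 n2) and log fold change =
#' mean(in) - mean(out) on the log1p-normalized values. P-values are BH
#' adjusted jointly across all (gene, type) tests. A gene passes for a
#' type iff adjusted p < `p_thresh`, AUC > `auc_thresh` and lfc >
#' `lfc_thresh`; the exclusivity flag marks genes passing for exactly one
#' type.
#'
#' @param nm A [depth_normalize()] result (or genes x cells matrix).
#' @param labels Per-cell labels; filter codes ignored.
#' @param p_thresh,auc_thresh,lfc_thresh Selection criteria.
#' @param min_cells Minimum member cells per tested type.
#' @return data.frame of class `marker_test`: gene, type, U, auc, lfc, p,
#'   adj_p, passes, exclusive.
#' @export
wilcoxon_markers <- function(nm, labels, p_thresh = 1e-3,
                             auc_thresh = 0.5, lfc_thresh = 0,
                             min_cells = 3) {
  X <- if (inherits(nm, "normalized_matrix")) as.matrix(nm$values)
       else as.matrix(nm)
  stopifnot(ncol(X) == length(labels))
  keep <- !labels %in% c("unassigned_none", "unassigned_multi",
                         "incoherent_neighborhood") & !is.na(labels)
  X <- X[, keep, drop = FALSE]
  labels <- labels[keep]
  types <- sort(unique(labels))
  types <- types[table(labels)[types] >= min_cells]
  if (length(types) < 2) stop("need at least 2 types with enough cells")
  genes <- rownames(X)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(X)))
  N <- ncol(X)
  G <- nrow(X)

  # ranks, tie terms and constant-gene flags are shared across the splits
  R <- t(apply(X, 1, rank))
  tie <- .tie_terms(X)
  const <- apply(X, 1, function(v) length(unique(v)) == 1)
  small_exact <- N <= 25
  res <- vector("list", length(types))
  for (ti in seq_along(types)) {
    inb <- labels == types[ti]
    n1 <- sum(inb); n2 <- N - n1
    rsum <- rowSums(R[, inb, drop = FALSE])
    U <- rsum - n1 * (n1 + 1) / 2
    auc <- U / (n1 * n2)
    lfc <- rowMeans(X[, inb, drop = FALSE]) -
      rowMeans(X[, !inb, drop = FALSE])
    if (small_exact && min(n1, n2) <= 8) {
      p <- vapply(seq_len(G), function(g) {
        if (const[g]) return(1)
        .wilcox_greater(X[g, inb], X[g, !inb])$p
      }, numeric(1))
    } else {
      sig2 <- n1 * n2 / 12 * ((N + 1) - tie / (N * (N - 1)))
      z <- (U - n1 * n2 / 2 - 0.5) / sqrt(pmax(sig2, 1e-300))
      p <- stats::pnorm(z, lower.tail = FALSE)
      p[sig2 <= 0 | const] <- 1
    }
    res[[ti]] <- data.frame(gene = genes, type = types[ti], U = U,
                            auc = auc, lfc = lfc, p = p,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  out$passes <- out$adj_p < p_thresh & out$auc > auc_thresh &
    out$lfc > lfc_thresh
  n_pass <- tapply(out$passes, out$gene, sum)
  out$exclusive <- out$passes & n_pass[out$gene] == 1
  rownames(out) <- NULL
  class(out) <- c("marker_test", "data.frame")
  out
}

#' Top-ranked exclusive markers per type
#'
#' Among exclusive passing genes of each type, ranks by descending
#' discriminating power (signature value), breaking ties lexicographically
#' by symbol, and returns the top `n`.
#'
#' @param sig A [signature_profiles()] result.
#' @param res A [wilcoxon_markers()] result.
#' @param n Genes per type (default 10).
#' @return Named list of data.frames (gene, power, rank) per type; types
#'   with fewer than `n` available return all, with attribute
#'   `n_available`.
#' @export
rank_top <- function(sig, res, n = 10) {
  stopifnot(inherits(sig, "signature_profile"), inherits(res, "marker_test"))
  types <- intersect(colnames(sig$power), unique(res$type))
  out <- lapply(types, function(t) {
    g <- res$gene[res$type == t & res$exclusive]
    g <- intersect(g, rownames(sig$power))
    pw <- sig$power[g, t]
    ord <- order(-pw, g)
    g <- g[ord]; pw <- pw[ord]
    take <- seq_len(min(n, length(g)))
    df <- data.frame(gene = g[take], power = pw[take], rank = take,
                     stringsAsFactors = FALSE)
    attr(df, "n_available") <- length(g)
    df
  })
  names(out) <- types
  out
}

# partial correlation of x and y given control columns Z, via residuals
.pcor_resid <- function(x, y, Z) {
  M <- cbind(1, Z)
  qx <- stats::lm.fit(M, x)$residuals
  qy <- stats::lm.fit(M, y)$residuals
  if (stats::sd(qx) < 1e-12 || stats::sd(qy) < 1e-12) return(NA_real_)
  stats::cor(qx, qy)
}

#' Cross-platform alignment of signature profiles
#'
#' Computes, for every type pair, the partial Pearson correlation of the
#' two platforms' signature vectors over the shared genes, controlling
#' simultaneously for both platforms' per-gene baseline discriminating
#' power; the best match per row is the argmax.
#'
#' @param sig_a,sig_b [signature_profiles()] of the two platforms.
#' @param min_shared Minimum shared genes (default 50).
#' @return list with `pcor` (types_a x types_b), `best_match` (named
#'   character vector, per type of platform A).
#' @export
cross_platform_alignment <- function(sig_a, sig_b, min_shared = 50) {
  g <- intersect(rownames(sig_a$power), rownames(sig_b$power))
  if (length(g) < min_shared)
    stop("fewer than ", min_shared, " shared genes")
  A <- sig_a$power[g, , drop = FALSE]
  B <- sig_b$power[g, , drop = FALSE]
  Z <- cbind(sig_a$baseline[g], sig_b$baseline[g])
  pc <- matrix(NA_real_, ncol(A), ncol(B),
               dimnames = list(colnames(A), colnames(B)))
  for (i in seq_len(ncol(A)))
    for (j in seq_len(ncol(B)))
      pc[i, j] <- .pcor_resid(A[, i], B[, j], Z)
  best <- colnames(B)[apply(pc, 1, function(r)
    if (all(is.na(r))) NA_integer_ else which.max(r))]
  names(best) <- colnames(A)
  list(pcor = pc, best_match = best)
}
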