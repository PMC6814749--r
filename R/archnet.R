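#' Reduced expression profile via truncated SVD
#'
#' Computes a rank-`d` truncated SVD of the gene-centered (per-gene mean
#' across cells removed) normalized matrix. `basis %*% t(scores)`
#' approximates the centered input; `basis` columns are orthonormal
#' left-singular vectors.
#'
#' @param nm A `normalized_matrix` (or a plain genes x cells matrix).
#' @param d Target dimension (default 50).
#' @return Object of class `reduced_profile`: `scores` (cells x d =
#'   `diag(sv) %*% t(V)` transposed), `basis` (genes x d), `sv`
#'   (singular values), `center` (per-gene means), `gene_ids`, `cell_ids`.
#' @export
reduce_profile <- function(nm, d = 50) {
  X <- if (inherits(nm, "normalized_matrix")) nm$values else nm
  gene_ids <- if (inherits(nm, "normalized_matrix")) nm$gene_ids
              else rownames(X)
  cell_ids <- if (inherits(nm, "normalized_matrix")) nm$cell_ids
              else colnames(X)
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite values in input")
  if (d > min(dim(X))) stop("d exceeds matrix rank bound")
  ctr <- rowMeans(X)
  Xc <- X - ctr
  # exact truncated SVD through the smaller Gram matrix
  if (nrow(Xc) <= ncol(Xc)) {
    G <- tcrossprod(Xc)                    # genes x genes
    eg <- eigen(G, symmetric = TRUE)
    sv <- sqrt(pmax(eg$values[seq_len(d)], 0))
    U <- eg$vectors[, seq_len(d), drop = FALSE]
    Vt <- crossprod(U, Xc)                 # d x cells = sv * t(V)
  } else {
    G <- crossprod(Xc)                     # cells x cells
    eg <- eigen(G, symmetric = TRUE)
    sv <- sqrt(pmax(eg$values[seq_len(d)], 0))
    V <- eg$vectors[, seq_len(d), drop = FALSE]
    U <- Xc %*% V
    pos <- sv > 1e-12
    U[, pos] <- sweep(U[, pos, drop = FALSE], 2, sv[pos], "/")
    Vt <- sv * t(V)
  }
  # deterministic sign convention: largest-|.| basis entry positive
  for (j in seq_len(d)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) { U[, j] <- -U[, j]; Vt[j, ] <- -Vt[j, ] }
  }
  structure(list(scores = t(Vt), basis = U, sv = sv, center = ctr,
                 gene_ids = gene_ids, cell_ids = cell_ids),
            class = "reduced_profile")
}

#' @export
print.reduced_profile <- function(x, ...) {
  cat(sprintf("reduced_profile: %d cells x %d dims (%d genes)\n",
              nrow(x$scores), ncol(x$scores), nrow(x$basis)))
  invisible(x)
}

#' Archetypal decomposition at a single depth
#'
#' Approximately minimizes `||S - S C H||_F` over column-stochastic
#' nonnegative `C` (cells x k, candidate-cell weights defining archetypes)
#' and `H` (k x cells, archetype footprint per cell), where `S` is the
#' cells-in-columns reduced score matrix. The alternating convex
#' subproblems are solved exactly (each column a simplex-constrained
#' least-squares problem) from a spread-out successive-projection
#' initialization; the best of `restarts` runs is kept, ties broken by
#' lowest restart index.
#'
#' @param rp A [reduce_profile()] result, or a d x cells score matrix.
#' @param k Number of archetypes (>= 2, or 1 for the trivial depth).
#' @param restarts Independent restarts (first is deterministic; later
#'   ones use a random spread-out seed column).
#' @param seed Integer seed.
#' @param max_iter,tol Alternation sweeps cap and relative convergence
#'   tolerance.
#' @param warm Optional list(C, H) used as an additional candidate
#'   initialization (used by [build_ladder()] to enforce monotone
#'   reconstruction error).
#' @return list with `C`, `H`, `rss`, `converged`.
#' @export
action_decompose <- function(rp, k, restarts = 3, seed = 1L,
                             max_iter = 50, tol = 1e-7, warm = NULL) {
  S <- if (inherits(rp, "reduced_profile")) t(rp$scores) else as.matrix(rp)
  n <- ncol(S)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k exceeds the number of cells")
  set.seed(seed)
  empty <- matrix(0, 0, 0)
  best <- NULL
  for (r in seq_len(restarts)) {
    start <- if (r == 1) -1L else sample.int(n, 1) - 1L
    init <- cpp_spa(S, k, start)
    fit <- cpp_archetypal(S, k, init, empty, empty, max_iter, tol)
    if (is.null(best) || fit$rss < best$rss - 1e-12) best <- fit
  }
  if (!is.null(warm)) {
    Hw <- warm$H
    Cw <- warm$C
    stopifnot(nrow(Hw) == k, ncol(Hw) == n, nrow(Cw) == n, ncol(Cw) == k)
    fit <- cpp_archetypal(S, k, cpp_spa(S, k, -1L), Cw, Hw, max_iter, tol)
    if (fit$rss < best$rss - 1e-12) best <- fit
  }
  list(C = best$C, H = best$H, rss = best$rss,
       converged = isTRUE(best$converged))
}

#' Multiresolution archetypal ladder
#'
#' Runs [action_decompose()] for every depth `k_min..k_max`. In addition
#' to independent restarts, each depth is seeded with the previous depth's
#' solution augmented by one extra archetype (placed on the
#' worst-reconstructed cell), which makes the recorded reconstruction
#' error non-increasing in k.
#'
#' @inheritParams action_decompose
#' @param k_min,k_max Depth range (k_min >= 2).
#' @return Object of class `archetype_ladder`: per-depth list with `C`,
#'   `H`, `rss`, plus `depths` and `cell_ids`.
#' @export
build_ladder <- function(rp, k_min = 2, k_max = 30, restarts = 3,
                         seed = 1L, max_iter = 50, tol = 1e-7) {
  stopifnot(k_min >= 2, k_max >= k_min)
  S <- if (inherits(rp, "reduced_profile")) t(rp$scores) else as.matrix(rp)
  cell_ids <- if (inherits(rp, "reduced_profile")) rp$cell_ids else colnames(S)
  n <- ncol(S)
  depths <- seq.int(k_min, k_max)
  fits <- vector("list", length(depths))
  prev <- NULL
  for (i in seq_along(depths)) {
    k <- depths[i]
    warm <- NULL
    if (!is.null(prev)) {
      # previous solution plus one archetype on the worst-fit cell
      W <- S %*% prev$C
      res <- colSums((S - W %*% prev$H)^2)
      iw <- which.max(res)
      Cw <- cbind(prev$C, 0)
      Cw[iw, k] <- 1
      Hw <- rbind(prev$H, 0)
      warm <- list(C = Cw, H = Hw)
    }
    fits[[i]] <- action_decompose(S, k, restarts = restarts,
                                  seed = seed + k, max_iter = max_iter,
                                  tol = tol, warm = warm)
    prev <- fits[[i]]
  }
  structure(list(fits = fits, depths = depths, cell_ids = cell_ids),
            class = "archetype_ladder")
}

#' @export
print.archetype_ladder <- function(x, ...) {
  cat(sprintf("archetype_ladder: depths %d..%d over %d cells\n",
              min(x$depths), max(x$depths), ncol(x$fits[[1]]$H)))
  cat("reconstruction error by depth:\n")
  print(round(stats::setNames(vapply(x$fits, `[[`, numeric(1), "rss"),
                              x$depths), 4))
  invisible(x)
}

#' Reconstruction errors across the ladder
#' @param ladder An [build_ladder()] result.
#' @return Named numeric vector of Frobenius residual sums of squares.
#' @export
ladder_errors <- function(ladder) {
  stats::setNames(vapply(ladder$fits, `[[`, numeric(1), "rss"),
                  ladder$depths)
}

#' Multiresolution cell profiles
#'
#' Concatenates each cell's archetype footprints across all depths of the
#' ladder and renormalizes to a probability vector, defining the metric
#' space for the sqrt-Jensen-Shannon distance.
#'
#' @param ladder An [build_ladder()] result.
#' @return Cells x total-archetypes matrix; rows sum to 1.
#' @export
cell_profiles <- function(ladder) {
  stopifnot(inherits(ladder, "archetype_ladder"), length(ladder$fits) > 0)
  H <- do.call(rbind, lapply(ladder$fits, `[[`, "H"))
  P <- t(H)
  rs <- rowSums(P)
  if (any(rs <= 0)) stop("all-zero footprint encountered")
  P <- P / rs
  rownames(P) <- ladder$cell_ids
  P
}

#' Square-root Jensen-Shannon distance
#'
#' `sqrt(JSD(p, q))` with the divergence in bits (log base 2) and the
#' convention 0*log(0) = 0; a true metric with values in [0, 1].
#'
#' @param p,q Probability vectors of equal length (each sums to 1).
#' @return Scalar distance.
#' @export
js_distance <- function(p, q) {
  if (length(p) != length(q)) stop("length mismatch")
  if (any(p < 0) || any(q < 0)) stop("negative entries")
  h <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  jsd <- h((p + q) / 2) - 0.5 * (h(p) + h(q))
  sqrt(max(jsd, 0))
}

#' Pairwise sqrt-JS distance matrix
#' @param P Rows = probability vectors.
#' @return Symmetric distance matrix.
#' @export
js_distance_matrix <- function(P) {
  P <- as.matrix(P)
  D <- cpp_jsd_matrix(P)
  dimnames(D) <- list(rownames(P), rownames(P))
  D
}

#' Adaptive k*-nearest-neighbor cell network
#'
#' For each cell, neighbors are sorted by sqrt-JS distance and included
#' while the next distance stays below the adaptive threshold
#' `beta_j = (1/j) (sum_{i<=j} d_i + sqrt(j*lambda + (sum d_i)^2 -
#' j * sum d_i^2))`; the directed neighborhoods are symmetrized by union
#' and edges weighted `1 - d`.
#'
#' @param profiles Cells x archetypes probability matrix
#'   ([cell_profiles()]).
#' @param max_k Per-node neighbor cap; default `2 * ceiling(sqrt(n))`.
#' @param lambda Regularization of the k* rule (default 1).
#' @return Object of class `cell_network`: an `igraph` graph in `$graph`
#'   with `cell_ids`, plus the per-node adaptive neighbor counts.
#' @export
build_kstar_nn <- function(profiles, max_k = NULL, lambda = 1) {
  P <- as.matrix(profiles)
  n <- nrow(P)
  if (n < 2) stop("need at least 2 cells")
  if (is.null(max_k)) max_k <- 2 * ceiling(sqrt(n))
  if (max_k < 1) stop("max_k must be >= 1")
  ed <- cpp_kstar_edges(P, as.integer(max_k), lambda)
  df <- data.frame(from = ed$from, to = ed$to, dist = ed$dist)
  k_star <- tabulate(df$from, nbins = n)
  # union symmetrization on unordered pairs
  a <- pmin(df$from, df$to)
  b <- pmax(df$from, df$to)
  key <- paste(a, b)
  keep <- !duplicated(key)
  w <- 1 - df$dist[keep]
  w[w <= 0] <- 1e-12
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[keep], to = b[keep], weight = w),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  ids <- rownames(P)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  structure(list(graph = g, cell_ids = ids, k_star = k_star,
                 layout = NULL), class = "cell_network")
}

#' @export
print.cell_network <- function(x, ...) {
  cat(sprintf(
    "cell_network: %d cells, %d edges, median adaptive k = %g\n",
    length(x$cell_ids), igraph::ecount(x$graph),
    stats::median(x$k_star)))
  invisible(x)
}

#' Force-directed 2-D layout of a cell network
#'
#' Cosmetic embedding of the network (Fruchterman-Reingold on the weighted
#' graph); coordinates carry no analytic meaning.
#'
#' @param net A [build_kstar_nn()] network.
#' @param seed Integer seed for reproducible coordinates.
#' @return The network with `$layout` set (cells x 2).
#' @export
net_layout <- function(net, seed = 1L) {
  stopifnot(inherits(net, "cell_network"))
  if (igraph::vcount(net$graph) == 0) {
    net$layout <- matrix(numeric(0), 0, 2)
    return(net)
  }
  set.seed(seed)
  xy <- igraph::layout_with_fr(net$graph,
                               weights = igraph::E(net$graph)$weight)
  rownames(xy) <- net$cell_ids
  net$layout <- xy
  net
}

#' @export
plot.cell_network <- function(x, labels = NULL, ...) {
  if (is.null(x$layout)) x <- net_layout(x)
  col <- if (is.null(labels)) "grey40"
         else as.integer(factor(labels)) + 1L
  plot(x$layout, col = col, pch = 16, cex = 0.4,
       xlab = "layout-1", ylab = "layout-2", ...)
  invisible(x)
}
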