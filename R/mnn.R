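#' Mutual nearest-neighbor batch correction
#'
#' Merges batches sequentially. Coordinates are cosine-normalized
#' internally (optional), mutual k-NN pairs between the current reference
#' and the incoming batch define per-pair correction vectors
#' (reference minus incoming), and each incoming cell is shifted by the
#' Gaussian-kernel-weighted average of those vectors. The merged result
#' becomes the new reference. The reference batch itself is never moved.
#'
#' @param coords Cells x d numeric matrix (reduced or gene space, d >= 2).
#' @param batch Per-cell batch labels.
#' @param k Number of neighbors for mutual-pair detection.
#' @param sigma Gaussian smoothing bandwidth; `NULL` uses the mean
#'   distance to the k-th within-batch neighbor of the incoming batch
#'   (scale-adaptive).
#' @param order `"by_size"` (descending batch size, largest = reference)
#'   or an explicit character vector of batch levels.
#' @param cosine Cosine-normalize rows before correcting (default TRUE).
#' @return Corrected coords, same rows/order as the input.
#' @export
mnn_correct <- function(coords, batch, k = 20, sigma = NULL,
                        order = "by_size", cosine = TRUE) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(batch), ncol(coords) >= 2)
  batch <- as.character(batch)
  sizes <- sort(table(batch), decreasing = TRUE)
  if (identical(order, "by_size")) {
    ord <- names(sizes)
  } else {
    stopifnot(setequal(order, names(sizes)))
    ord <- as.character(order)
  }
  if (min(sizes) < k)
    stop("every batch must have at least k cells")
  if (length(ord) == 1) return(coords)  # nothing to correct
  X <- coords
  if (cosine) {
    nr <- sqrt(rowSums(X^2))
    nr[nr == 0] <- 1
    X <- X / nr
  }

  out <- X
  ref_idx <- which(batch == ord[1])
  for (b in ord[-1]) {
    inc_idx <- which(batch == b)
    ref <- out[ref_idx, , drop = FALSE]
    inc <- out[inc_idx, , drop = FALSE]
    pairs <- .mutual_pairs(ref, inc, k)
    if (nrow(pairs) == 0) {
      warning("no mutual pairs for batch ", b, "; appended uncorrected")
      ref_idx <- c(ref_idx, inc_idx)
      next
    }
    vecs <- ref[pairs[, 1], , drop = FALSE] - inc[pairs[, 2], , drop = FALSE]
    anchors <- inc[pairs[, 2], , drop = FALSE]
    sg <- if (is.null(sigma)) .mean_kth_dist(inc, k) else sigma
    if (!is.finite(sg) || sg <= 0) sg <- 1
    d2 <- .cross_dist2(inc, anchors)
    w <- exp(-d2 / (2 * sg^2))
    ws <- rowSums(w)
    shift <- (w %*% vecs) / ifelse(ws > 0, ws, 1)
    flat <- ws <= 1e-12
    if (any(flat))
      shift[flat, ] <- matrix(colMeans(vecs), sum(flat), ncol(vecs),
                              byrow = TRUE)
    out[inc_idx, ] <- inc + shift
    ref_idx <- c(ref_idx, inc_idx)
  }
  out
}

# squared euclidean cross-distance matrix (rows of A vs rows of B)
.cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# mutual k-NN pairs between reference (rows of ref) and incoming
.mutual_pairs <- function(ref, inc, k) {
  d2 <- .cross_dist2(ref, inc) # nref x ninc
  k1 <- min(k, ncol(d2))
  k2 <- min(k, nrow(d2))
  nn_of_ref <- apply(d2, 1, function(r) order(r)[seq_len(k1)])
  nn_of_inc <- apply(d2, 2, function(c) order(c)[seq_len(k2)])
  nn_of_ref <- matrix(nn_of_ref, nrow = k1)
  nn_of_inc <- matrix(nn_of_inc, nrow = k2)
  res <- vector("list", ncol(d2))
  for (i in seq_len(ncol(d2))) {
    cand <- nn_of_inc[, i]                       # ref cells near inc i
    hit <- cand[vapply(cand, function(r) i %in% nn_of_ref[, r], logical(1))]
    if (length(hit))
      res[[i]] <- cbind(ref = hit, inc = rep.int(i, length(hit)))
  }
  m <- do.call(rbind, res)
  if (is.null(m)) matrix(integer(0), 0, 2) else m
}

.mean_kth_dist <- function(X, k) {
  d2 <- .cross_dist2(X, X)
  diag(d2) <- Inf
  kk <- min(k, nrow(X) - 1)
  mean(sqrt(apply(d2, 1, function(r) sort(r)[kk])))
}
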