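#' Sparse gene x cell count matrix container
#'
#' @param values Sparse nonnegative integer matrix, rows = genes, columns =
#'   cells.
#' @param gene_ids Unique gene symbols (duplicates must be aggregated
#'   before construction; [read_mtx_triplet()] sums them on read).
#' @param cell_ids Unique cell barcodes.
#' @param cell_meta Per-cell data frame (sample, platform, region, batch);
#'   may be `NULL`.
#' @return Object of class `count_matrix`.
#' @export
count_matrix <- function(values, gene_ids, cell_ids, cell_meta = NULL) {
  # force a general (non-symmetric, non-triangular) sparse representation:
  # square inputs can otherwise round-trip through Matrix-Market as
  # symmetric and mirror their dimnames
  values <- methods::as(methods::as(values, "generalMatrix"),
                        "CsparseMatrix")
  if (nrow(values) != length(gene_ids) || ncol(values) != length(cell_ids))
    stop("dimension mismatch between matrix and id lists")
  if (anyDuplicated(gene_ids)) stop("duplicate gene symbols")
  if (anyDuplicated(cell_ids)) stop("duplicate barcodes")
  if (length(values@x) && min(values@x) < 0) stop("negative counts")
  if (!is.null(cell_meta)) {
    stopifnot(is.data.frame(cell_meta), nrow(cell_meta) == length(cell_ids))
    rownames(cell_meta) <- cell_ids
  }
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_meta = cell_meta), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells (%.2f%% nonzero)\n",
              nrow(x$values), ncol(x$values),
              100 * length(x$values@x) / prod(dim(x$values))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

# subset helper preserving ids/meta
subset_counts <- function(m, genes = NULL, cells = NULL) {
  gi <- if (is.null(genes)) seq_len(nrow(m$values)) else genes
  ci <- if (is.null(cells)) seq_len(ncol(m$values)) else cells
  count_matrix(m$values[gi, ci, drop = FALSE],
               m$gene_ids[gi], m$cell_ids[ci],
               if (is.null(m$cell_meta)) NULL else
                 m$cell_meta[ci, , drop = FALSE])
}

#' Read a Matrix-Market triplet directory (10x style)
#'
#' Expects `matrix.mtx` with 1-based indices plus `genes.tsv` and
#' `barcodes.tsv` sidecars, and optionally `cell_metadata.tsv` (tab
#' delimited with header, one row per barcode). Duplicate gene symbols are
#' summed on read.
#'
#' @param dir Directory containing the files, or a named list of explicit
#'   paths (`mtx`, `genes`, `barcodes`, `meta`).
#' @return A [count_matrix()].
#' @export
read_mtx_triplet <- function(dir) {
  p <- if (is.list(dir)) dir else list(
    mtx = file.path(dir, "matrix.mtx"),
    genes = file.path(dir, "genes.tsv"),
    barcodes = file.path(dir, "barcodes.tsv"),
    meta = file.path(dir, "cell_metadata.tsv"))
  for (f in c(p$mtx, p$genes, p$barcodes))
    if (!file.exists(f)) stop("missing file: ", f)
  m <- methods::as(Matrix::readMM(p$mtx), "CsparseMatrix")
  genes <- readLines(p$genes)
  genes <- genes[nzchar(genes)]
  genes <- vapply(strsplit(genes, "\t"), `[`, character(1), 1L)
  barcodes <- readLines(p$barcodes)
  barcodes <- barcodes[nzchar(barcodes)]
  if (nrow(m) != length(genes))
    stop(sprintf("matrix has %d rows but genes.tsv has %d entries",
                 nrow(m), length(genes)))
  if (ncol(m) != length(barcodes))
    stop(sprintf("matrix has %d columns but barcodes.tsv has %d entries",
                 ncol(m), length(barcodes)))
  if (anyDuplicated(barcodes)) stop("duplicate barcodes")
  if (anyDuplicated(genes)) {
    f <- factor(genes, levels = unique(genes))
    agg <- Matrix::fac2sparse(f) %*% m
    m <- methods::as(agg, "CsparseMatrix")
    genes <- levels(f)
  }
  meta <- NULL
  if (!is.null(p$meta) && file.exists(p$meta)) {
    meta <- utils::read.delim(p$meta, stringsAsFactors = FALSE)
    if (nrow(meta) != length(barcodes))
      stop("cell_metadata.tsv row count does not match barcodes")
  }
  count_matrix(m, genes, barcodes, meta)
}

#' Write a count matrix as a Matrix-Market triplet directory
#'
#' @param m A [count_matrix()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_mtx_triplet <- function(m, dir) {
  stopifnot(inherits(m, "count_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  v <- methods::as(m$values, "generalMatrix")
  dimnames(v) <- NULL
  Matrix::writeMM(v, file.path(dir, "matrix.mtx"))
  writeLines(m$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(m$cell_ids, file.path(dir, "barcodes.tsv"))
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  if (!is.null(m$cell_meta)) {
    mp <- file.path(dir, "cell_metadata.tsv")
    utils::write.table(m$cell_meta, mp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, mp)
  }
  invisible(paths)
}

#' Quality-control filtering of cells and genes
#'
#' Retains cells detecting at least `min_genes_per_cell` genes and genes
#' detected in at least `min_cells_per_gene` cells. The two rules are
#' alternated until a fixed point so both hold simultaneously on the
#' result; the order of surviving rows and columns is preserved.
#'
#' @param m A [count_matrix()].
#' @param min_genes_per_cell Minimum detected genes per retained cell.
#' @param min_cells_per_gene Minimum detecting cells per retained gene.
#' @return A filtered [count_matrix()]; empty (with a warning) when
#'   nothing survives.
#' @export
qc_filter <- function(m, min_genes_per_cell = 300, min_cells_per_gene = 10) {
  stopifnot(inherits(m, "count_matrix"))
  keep_g <- rep(TRUE, nrow(m$values))
  keep_c <- rep(TRUE, ncol(m$values))
  bin <- m$values
  bin@x <- rep(1, length(bin@x))
  repeat {
    det_per_gene <- as.numeric(bin[, keep_c, drop = FALSE] %*%
                                 rep(1, sum(keep_c)))
    new_g <- keep_g & (det_per_gene >= min_cells_per_gene)
    det_per_cell <- as.numeric(rep(1, sum(new_g)) %*%
                                 bin[new_g, , drop = FALSE])
    new_c <- keep_c & (det_per_cell >= min_genes_per_cell)
    if (identical(new_g, keep_g) && identical(new_c, keep_c)) break
    keep_g <- new_g
    keep_c <- new_c
    if (!any(keep_g) || !any(keep_c)) {
      keep_g[] <- FALSE
      keep_c[] <- FALSE
      break
    }
  }
  if (!any(keep_g) || !any(keep_c))
    warning("qc_filter removed everything; returning an empty matrix")
  subset_counts(m, which(keep_g), which(keep_c))
}

#' Depth normalization
#'
#' Scales every cell to a common target depth and applies log1p:
#' `depth_factor_i = target / total_i`, output value =
#' `log1p(count * depth_factor)`. The stored factors make the transform
#' reversible.
#'
#' @param m A [count_matrix()].
#' @param target `"median"` (median library size) or a positive scalar.
#' @return Object of class `normalized_matrix` with fields `values`
#'   (sparse), `depth_factors`, `gene_ids`, `cell_ids`, `cell_meta`.
#' @export
depth_normalize <- function(m, target = "median") {
  stopifnot(inherits(m, "count_matrix"))
  totals <- Matrix::colSums(m$values)
  if (any(totals == 0))
    stop("zero-depth cell(s): ",
         paste(utils::head(m$cell_ids[totals == 0], 5), collapse = ", "))
  tgt <- if (identical(target, "median")) stats::median(totals)
         else as.numeric(target)
  factors <- tgt / totals
  v <- m$values %*% Matrix::Diagonal(x = factors)
  v <- methods::as(v, "CsparseMatrix")
  v@x <- log1p(v@x)
  dimnames(v) <- dimnames(m$values)
  structure(list(values = v, depth_factors = factors,
                 gene_ids = m$gene_ids, cell_ids = m$cell_ids,
                 cell_meta = m$cell_meta),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d cells (log1p, depth-scaled)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
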