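#' Build an expression dataset from spliced and unspliced count matrices
#'
#' The central container of the package: paired spliced (mature mRNA) and
#' unspliced (nascent pre-mRNA) UMI count matrices over the same cells and
#' genes, plus optional ground-truth annotations carried by the simulator.
#'
#' @param S_raw,U_raw cells x genes non-negative integer matrices of spliced
#'   and unspliced UMI counts.
#' @param cell_ids,gene_ids unique character vectors matching the matrix
#'   dimensions.
#' @param true_phase optional per-cell phase in cycles on \code{[0, 1)}
#'   (simulations only).
#' @param true_labels optional per-cell subpopulation tags.
#' @return an object of class \code{ExpressionDataset} with slots
#'   \code{S_raw}, \code{U_raw}, \code{S_smooth}, \code{U_smooth} (NULL until
#'   \code{\link{knn_smooth}} is run), \code{total_counts} (per-cell spliced +
#'   unspliced UMIs), and the id vectors.
#' @export
ExpressionDataset <- function(S_raw, U_raw, cell_ids, gene_ids,
                              true_phase = NULL, true_labels = NULL) {
  S_raw <- as.matrix(S_raw)
  U_raw <- as.matrix(U_raw)
  if (!identical(dim(S_raw), dim(U_raw))) {
    stop(sprintf("dimension mismatch: spliced is %d x %d but unspliced is %d x %d",
                 nrow(S_raw), ncol(S_raw), nrow(U_raw), ncol(U_raw)))
  }
  if (nrow(S_raw) != length(cell_ids)) {
    stop(sprintf("matrix has %d rows but %d cell ids were given",
                 nrow(S_raw), length(cell_ids)))
  }
  if (ncol(S_raw) != length(gene_ids)) {
    stop(sprintf("matrix has %d columns but %d gene ids were given",
                 ncol(S_raw), length(gene_ids)))
  }
  if (anyDuplicated(cell_ids)) stop("cell ids are not unique")
  if (anyDuplicated(gene_ids)) stop("gene ids are not unique")
  check_counts <- function(M, what) {
    if (any(!is.finite(M))) stop(sprintf("non-finite entries in %s counts", what))
    if (any(M < 0)) stop(sprintf("negative entries in %s counts", what))
    if (any(M != round(M))) stop(sprintf("non-integer entries in %s counts", what))
  }
  check_counts(S_raw, "spliced")
  check_counts(U_raw, "unspliced")
  total <- rowSums(S_raw) + rowSums(U_raw)
  if (any(total == 0)) {
    stop("cells with zero total counts: ",
         paste(utils::head(cell_ids[total == 0], 5L), collapse = ", "))
  }
  if (!is.null(true_phase)) {
    stopifnot(length(true_phase) == nrow(S_raw), all(true_phase >= 0 & true_phase < 1))
  }
  if (!is.null(true_labels)) stopifnot(length(true_labels) == nrow(S_raw))
  dimnames(S_raw) <- dimnames(U_raw) <- list(cell_ids, gene_ids)
  structure(list(
    cell_ids = as.character(cell_ids),
    gene_ids = as.character(gene_ids),
    S_raw = S_raw, U_raw = U_raw,
    S_smooth = NULL, U_smooth = NULL,
    total_counts = total,
    true_phase = true_phase, true_labels = true_labels,
    knn_graph = NULL
  ), class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d cells x %d genes\n",
              length(x$cell_ids), length(x$gene_ids)))
  cat(sprintf("  smoothed layers: %s\n",
              if (is.null(x$S_smooth)) "absent" else "present"))
  if (!is.null(x$true_phase)) cat("  ground-truth phases present\n")
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) c(length(x$cell_ids), length(x$gene_ids))

#' Load spliced/unspliced layers from Matrix Market files
#'
#' Reads two cells x genes count matrices (MatrixMarket \code{.mtx}) sharing
#' one barcode list and one gene list, and assembles an
#' \code{\link{ExpressionDataset}}. Matrices stored genes x cells are
#' transposed automatically when that matches the id lists unambiguously.
#'
#' @param spliced_path,unspliced_path paths to \code{.mtx} count matrices.
#' @param cells_path path to a plain-text file with one cell barcode per line.
#' @param genes_path path to a plain-text file with one gene symbol per line
#'   (first whitespace-separated token is used).
#' @return an \code{ExpressionDataset} with raw layers populated and
#'   \code{total_counts} computed; smoothed layers unset.
#' @seealso \code{\link{write_counts}} for the inverse operation.
#' @export
load_counts <- function(spliced_path, unspliced_path, cells_path, genes_path) {
  for (p in c(spliced_path, unspliced_path, cells_path, genes_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  cells <- read.table(cells_path, header = FALSE,
                      stringsAsFactors = FALSE)[[1L]]
  genes <- read.table(genes_path, header = FALSE,
                      stringsAsFactors = FALSE)[[1L]]
  read_layer <- function(path, what) {
    M <- as.matrix(Matrix::readMM(path))
    if (nrow(M) == length(genes) && ncol(M) == length(cells) &&
        nrow(M) != length(cells)) {
      M <- t(M)
    }
    if (nrow(M) != length(cells) || ncol(M) != length(genes)) {
      stop(sprintf(
        "%s matrix is %d x %d but %d cells and %d genes were listed",
        what, nrow(M), ncol(M), length(cells), length(genes)))
    }
    M
  }
  S <- read_layer(spliced_path, "spliced")
  U <- read_layer(unspliced_path, "unspliced")
  ExpressionDataset(S, U, cells, genes)
}

#' Write the raw layers of a dataset as Matrix Market files
#'
#' Writes \code{spliced.mtx}, \code{unspliced.mtx}, \code{barcodes.tsv} and
#' \code{genes.tsv} into \code{dir}; \code{\link{load_counts}} on these files
#' reproduces the raw layers exactly.
#'
#' @param ds an \code{ExpressionDataset}.
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_counts <- function(ds, dir) {
  stopifnot(is(ds, "ExpressionDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(ds$S_raw, sparse = TRUE),
                  file.path(dir, "spliced.mtx"))
  Matrix::writeMM(Matrix::Matrix(ds$U_raw, sparse = TRUE),
                  file.path(dir, "unspliced.mtx"))
  writeLines(ds$cell_ids, file.path(dir, "barcodes.tsv"))
  writeLines(ds$gene_ids, file.path(dir, "genes.tsv"))
  invisible(dir)
}

#' Smooth counts over a cell-cell kNN graph (first-order moments)
#'
#' Replaces each cell's raw spliced and unspliced counts by the arithmetic
#' mean over its \code{n_neighbors} nearest cells (the cell itself included).
#' Neighbors are found by Euclidean distance in the space of the first
#' \code{n_pcs} principal components of log1p total-count-normalized spliced
#' counts. This is the denoising step applied before any per-gene fitting:
#' single-cell UMI counts are too sparse for the circular spliced-unspliced
#' patterns to be visible per cell.
#'
#' @param ds an \code{ExpressionDataset}.
#' @param n_neighbors neighborhood size, self included (default 30).
#' @param n_pcs number of principal components for the distance space
#'   (default 30, capped at the matrix rank).
#' @return the dataset with \code{S_smooth}, \code{U_smooth} filled in and
#'   the neighbor index matrix recorded in \code{knn_graph}.
#' @export
knn_smooth <- function(ds, n_neighbors = 30L, n_pcs = 30L) {
  stopifnot(is(ds, "ExpressionDataset"))
  n_cells <- length(ds$cell_ids)
  n_genes <- length(ds$gene_ids)
  if (n_neighbors < 1L) stop("n_neighbors must be >= 1")
  if (n_neighbors > n_cells) {
    stop(sprintf("n_neighbors (%d) exceeds the number of cells (%d)",
                 n_neighbors, n_cells))
  }
  n_pcs <- min(n_pcs, n_cells - 1L, n_genes)
  if (n_pcs < 1L) stop("n_pcs must be >= 1")
  s_tot <- rowSums(ds$S_raw)
  if (any(s_tot == 0)) {
    stop("cells with zero spliced counts cannot be normalized: ",
         paste(utils::head(ds$cell_ids[s_tot == 0], 5L), collapse = ", "))
  }
  if (n_neighbors == 1L) {
    ds$S_smooth <- ds$S_raw
    ds$U_smooth <- ds$U_raw
    ds$knn_graph <- matrix(seq_len(n_cells), ncol = 1L)
    return(ds)
  }
  norm <- log1p(ds$S_raw / s_tot * stats::median(s_tot))
  pcs <- stats::prcomp(norm, center = TRUE, scale. = FALSE,
                       rank. = n_pcs)$x
  nn_idx <- knn_indices(pcs, n_neighbors)
  W <- Matrix::sparseMatrix(
    i = rep(seq_len(n_cells), each = n_neighbors),
    j = as.vector(t(nn_idx)),
    x = 1 / n_neighbors,
    dims = c(n_cells, n_cells))
  ds$S_smooth <- as.matrix(W %*% ds$S_raw)
  ds$U_smooth <- as.matrix(W %*% ds$U_raw)
  dimnames(ds$S_smooth) <- dimnames(ds$U_smooth) <- dimnames(ds$S_raw)
  ds$knn_graph <- nn_idx
  ds
}

# exact k nearest neighbors (self included) by squared Euclidean distance;
# ties broken by row index so results are deterministic
knn_indices <- function(X, k) {
  n <- nrow(X)
  sq <- rowSums(X^2)
  G <- tcrossprod(X)
  D2 <- outer(sq, sq, "+") - 2 * G
  idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    o <- order(D2[i, ], seq_len(n))
    idx[i, ] <- o[seq_len(k)]
  }
  idx
}

#' Restrict a dataset to a list of genes
#'
#' Keeps the intersection of \code{gene_list} with the dataset's genes, in
#' the dataset's original order. Names absent from the dataset are dropped
#' with a warning; an empty intersection is an error.
#'
#' @param ds an \code{ExpressionDataset}.
#' @param gene_list character vector of gene symbols.
#' @return the restricted dataset (all layers subset consistently).
#' @export
subset_genes <- function(ds, gene_list) {
  stopifnot(is(ds, "ExpressionDataset"), length(gene_list) >= 1L)
  keep <- ds$gene_ids %in% gene_list
  if (!any(keep)) stop("none of the requested genes are present in the dataset")
  n_missing <- sum(!(gene_list %in% ds$gene_ids))
  if (n_missing > 0L) {
    warning(sprintf("%d requested gene(s) absent from the dataset", n_missing))
  }
  ds$gene_ids <- ds$gene_ids[keep]
  for (layer in c("S_raw", "U_raw", "S_smooth", "U_smooth")) {
    if (!is.null(ds[[layer]])) ds[[layer]] <- ds[[layer]][, keep, drop = FALSE]
  }
  ds$total_counts <- rowSums(ds$S_raw) + rowSums(ds$U_raw)
  ds
}
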