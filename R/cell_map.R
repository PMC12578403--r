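#' Construct a cell map
#'
#' A cell map is one spatial-transcriptomics sample: per-cell centroid
#' coordinates (micrometres) plus a sparse nonnegative-integer cell-by-gene
#' count matrix over a named gene panel. This is the container every
#' downstream stage (QC, categorization, proximity statistics) consumes.
#'
#' @param cell_ids Character vector of unique cell identifiers.
#' @param x,y Numeric centroid coordinates in micrometres; finite.
#' @param genes Character vector of unique gene symbols.
#' @param counts Cells-by-genes matrix of nonnegative integers; any matrix
#'   coercible to `Matrix::dgCMatrix`.
#' @return An object of class `cell_map`: a list with elements `cell_ids`,
#'   `x`, `y`, `genes` and `counts` (a `dgCMatrix`, rows = cells).
#' @examples
#' cm <- cell_map(c("a", "b"), x = c(0, 10), y = c(0, 0),
#'                genes = c("ARG1", "IL6"),
#'                counts = matrix(c(1, 0, 0, 2), nrow = 2))
#' cm
#' @export
cell_map <- function(cell_ids, x, y, genes, counts) {
  cell_ids <- as.character(cell_ids)
  genes <- as.character(genes)
  x <- as.numeric(x)
  y <- as.numeric(y)
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  n <- length(cell_ids)
  if (length(x) != n || length(y) != n)
    prox_error("bad_coords", "x and y must have one entry per cell id")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    prox_error("bad_coords", "cell coordinates must be finite")
  if (anyDuplicated(cell_ids))
    prox_error("duplicate_ids", "duplicate cell ids in cell map")
  if (anyDuplicated(genes))
    prox_error("duplicate_genes", "duplicate gene symbols in cell map")
  if (nrow(counts) != n || ncol(counts) != length(genes))
    prox_error("shape_mismatch", sprintf(
      "counts is %d x %d but there are %d cells and %d genes",
      nrow(counts), ncol(counts), n, length(genes)))
  if (length(counts@x) && any(counts@x < 0))
    prox_error("negative_counts", "counts contain negative entries")
  if (length(counts@x) && any(counts@x != round(counts@x)))
    prox_error("noninteger_counts", "counts contain non-integer entries")
  dimnames(counts) <- list(cell_ids, genes)
  structure(
    list(cell_ids = cell_ids, x = x, y = y, genes = genes, counts = counts),
    class = "cell_map")
}

#' @export
print.cell_map <- function(x, ...) {
  cat(sprintf("cell_map: %d cells x %d genes\n",
              length(x$cell_ids), length(x$genes)))
  cat(sprintf("  x range: [%.6g, %.6g] um; y range: [%.6g, %.6g] um\n",
              min(x$x), max(x$x), min(x$y), max(x$y)))
  cat(sprintf("  total counts: %g; median counts/cell: %g\n",
              sum(x$counts), stats::median(Matrix::rowSums(x$counts))))
  invisible(x)
}

#' @export
dim.cell_map <- function(x) c(length(x$cell_ids), length(x$genes))

# Coordinates as an n x 2 matrix (internal convenience).
coords_matrix <- function(map) cbind(x = map$x, y = map$y)

# Subset a cell_map to cell indices `i` (and optionally gene indices `j`),
# preserving order as given.
subset_cell_map <- function(map, i, j = seq_along(map$genes)) {
  cell_map(map$cell_ids[i], map$x[i], map$y[i], map$genes[j],
           map$counts[i, j, drop = FALSE])
}
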