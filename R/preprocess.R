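#' QC-filter a cell map
#'
#' Applies the standard two-step quality filter in a single pass: first,
#' cells with total transcript counts below `min_counts_per_cell` are
#' removed; then genes detected (nonzero) in fewer than `min_cells_per_gene`
#' of the *surviving* cells are removed. The pass is not iterated to a fixed
#' point, so a cell whose total drops below threshold after gene removal is
#' kept — matching the usual min-counts/min-cells convention.
#'
#' @param map A [cell_map].
#' @param min_counts_per_cell Keep cells with total counts >= this (default
#'   10).
#' @param min_cells_per_gene Keep genes with nonzero counts in >= this many
#'   surviving cells (default 5).
#' @return The filtered [cell_map], with an attribute `qc_report` giving
#'   cell/gene tallies before and after.
#' @examples
#' cm <- cell_map(letters[1:3], x = 1:3, y = 1:3, genes = c("g1", "g2"),
#'                counts = matrix(c(10, 4, 20, 5, 0, 0), nrow = 3))
#' qc_filter(cm, 10, 1)
#' @export
qc_filter <- function(map, min_counts_per_cell = 10, min_cells_per_gene = 5) {
  stopifnot(inherits(map, "cell_map"))
  if (min_counts_per_cell < 0 || min_cells_per_gene < 0)
    prox_error("bad_qc_params", "QC thresholds must be nonnegative")
  totals <- Matrix::rowSums(map$counts)
  keep_cells <- which(totals >= min_counts_per_cell)
  if (length(keep_cells) == 0)
    prox_error("empty_after_qc", "empty sample after QC: all cells removed")
  detected <- Matrix::colSums(map$counts[keep_cells, , drop = FALSE] > 0)
  keep_genes <- which(detected >= min_cells_per_gene)
  if (length(keep_genes) == 0)
    prox_error("empty_after_qc", "empty sample after QC: all genes removed")
  out <- subset_cell_map(map, keep_cells, keep_genes)
  attr(out, "qc_report") <- list(
    cells_before = length(map$cell_ids), cells_after = length(keep_cells),
    genes_before = length(map$genes), genes_after = length(keep_genes),
    min_counts_per_cell = min_counts_per_cell,
    min_cells_per_gene = min_cells_per_gene)
  out
}

#' Depth-normalize and log-transform counts
#'
#' Scales each cell's counts to a common total of `target` (default
#' 1e4) and applies the natural-log transform `x -> log(1 + x)`. The raw
#' counts are retained unchanged on the returned map; categorization always
#' uses raw counts, and the transform preserves the zero/nonzero pattern
#' positivity depends on.
#'
#' @param map A QC-filtered [cell_map]; every cell must have positive total
#'   counts.
#' @param target Per-cell total after scaling (default `1e4`).
#' @return The input [cell_map] with an added element `lognorm`, a sparse
#'   cells-by-genes matrix of log-normalized expression.
#' @export
normalize_log <- function(map, target = 1e4) {
  stopifnot(inherits(map, "cell_map"))
  totals <- Matrix::rowSums(map$counts)
  if (any(totals == 0))
    prox_error("zero_total_cell",
               "cannot normalize: some cells have zero total counts")
  scaled <- Matrix::Diagonal(x = target / totals) %*% map$counts
  scaled <- as(scaled, "CsparseMatrix")
  scaled@x <- log1p(scaled@x)
  dimnames(scaled) <- dimnames(map$counts)
  map$lognorm <- scaled
  map
}

#' Marker rule for proximity-analysis categories
#'
#' Defines which genes mark the reference cells, the paracrine signal and
#' the fibroblast lineage, and the positivity threshold. Positivity of a
#' marker means raw counts strictly greater than `min_count` (default 0,
#' i.e. any nonzero count).
#'
#' @param reference_marker Gene marking the reference category (default
#'   `"ARG1"`).
#' @param signal_marker Gene splitting fibroblasts into signal-positive and
#'   -negative (default `"IL6"`).
#' @param fibroblast_markers Genes any one of which marks a fibroblast
#'   (default `c("COL1A1", "CTHRC1")`).
#' @param min_count Positivity threshold on raw counts; a marker is positive
#'   when its count exceeds this (default 0).
#' @return A `category_rule` list.
#' @export
category_rule <- function(reference_marker = "ARG1",
                          signal_marker = "IL6",
                          fibroblast_markers = c("COL1A1", "CTHRC1"),
                          min_count = 0) {
  stopifnot(length(reference_marker) == 1, length(signal_marker) == 1,
            length(fibroblast_markers) >= 1, min_count >= 0)
  structure(list(reference_marker = reference_marker,
                 signal_marker = signal_marker,
                 fibroblast_markers = fibroblast_markers,
                 min_count = min_count),
            class = "category_rule")
}

#' Assign each cell to a proximity-analysis category
#'
#' Mutually exclusive labels from raw-count marker positivity, with
#' reference positivity taking precedence:
#' \itemize{
#'   \item `reference`: reference marker positive (ARG1+), regardless of
#'     other markers;
#'   \item `il6pos_fib`: reference-negative, signal marker positive, and at
#'     least one fibroblast marker positive;
#'   \item `il6neg_fib`: reference-negative, signal marker negative, and at
#'     least one fibroblast marker positive;
#'   \item `other`: everything else.
#' }
#'
#' @param map A [cell_map] (typically after [qc_filter()]).
#' @param rule A [category_rule()].
#' @return A factor over [CATEGORY_LEVELS], named by cell id.
#' @export
assign_categories <- function(map, rule = category_rule()) {
  stopifnot(inherits(map, "cell_map"), inherits(rule, "category_rule"))
  needed <- c(rule$reference_marker, rule$signal_marker,
              rule$fibroblast_markers)
  missing <- setdiff(needed, map$genes)
  if (length(missing))
    prox_error("missing_marker",
               paste0("marker gene(s) absent from panel: ",
                      paste(missing, collapse = ", ")))
  pos <- function(g) as.vector(map$counts[, g] > rule$min_count)
  ref <- pos(rule$reference_marker)
  sig <- pos(rule$signal_marker)
  fib <- Reduce(`|`, lapply(rule$fibroblast_markers, pos))
  lab <- ifelse(ref, "reference",
                ifelse(sig & fib, "il6pos_fib",
                       ifelse(fib, "il6neg_fib", "other")))
  f <- factor(lab, levels = CATEGORY_LEVELS)
  names(f) <- map$cell_ids
  f
}
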