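# All delimited output is tab-separated UTF-8 with '.' decimals; numbers are
# serialized with 17 significant digits so doubles round-trip exactly.
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
}

read_lines_strict <- function(path) {
  if (!file.exists(path))
    prox_error("missing_file", sprintf("file not found: %s", path))
  readLines(path, warn = FALSE)
}

# Sidecar lists (10x convention): one gene/cell per line; gene files may have
# extra tab-separated columns (id, symbol, type) -- the symbol column is used
# if present, else the first column.
read_sidecar <- function(path, kind) {
  lines <- read_lines_strict(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  idx <- if (kind == "genes" && all(ncol >= 2)) 2L else 1L
  vapply(fields, `[[`, character(1), idx)
}

#' Read a cell map from disk
#'
#' Reads a sample's counts plus centroid coordinates into a validated
#' [cell_map]. Counts may be MatrixMarket coordinate format (`.mtx`, with
#' gene and cell sidecar lists, the 10x/Xenium convention) or a dense
#' tab-delimited table whose first column is the cell id and whose remaining
#' columns are genes. Coordinates are a tab-delimited table with columns
#' `cell_id`, `x`, `y`, taken to be micrometres already. Cell order is
#' harmonized to the coordinate file's order.
#'
#' @param counts_path Path to `.mtx` or dense TSV counts.
#' @param coords_path Path to the coordinates TSV.
#' @param genes_path,cells_path Sidecar lists (required for `.mtx` input).
#' @param genes_as_rows For `.mtx` input: `TRUE` (default, 10x convention)
#'   if the matrix is genes x cells, `FALSE` if cells x genes. Never guessed
#'   from shape.
#' @return A validated [cell_map].
#' @export
read_cell_map <- function(counts_path, coords_path,
                          genes_path = NULL, cells_path = NULL,
                          genes_as_rows = TRUE) {
  if (grepl("\\.mtx$", counts_path)) {
    if (is.null(genes_path) || is.null(cells_path))
      prox_error("missing_sidecar",
                 "MTX input requires genes_path and cells_path sidecars")
    hdr <- read_lines_strict(counts_path)[1]
    if (!grepl("^%%MatrixMarket[ \t]+matrix[ \t]+coordinate", hdr))
      prox_error("malformed_mtx",
                 sprintf("not a MatrixMarket coordinate file: %s", counts_path))
    m <- Matrix::readMM(counts_path)
    genes <- read_sidecar(genes_path, "genes")
    cells <- read_sidecar(cells_path, "cells")
    if (genes_as_rows) m <- Matrix::t(m)
    if (nrow(m) != length(cells) || ncol(m) != length(genes))
      prox_error("sidecar_mismatch", sprintf(
        "matrix is %d x %d (cells x genes) but sidecars list %d cells, %d genes",
        nrow(m), ncol(m), length(cells), length(genes)))
  } else {
    tab <- read.delim(counts_path, check.names = FALSE,
                      stringsAsFactors = FALSE)
    cells <- as.character(tab[[1]])
    genes <- colnames(tab)[-1]
    m <- as.matrix(tab[, -1, drop = FALSE])
  }

  co <- read.delim(coords_path, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "x", "y") %in% colnames(co)))
    prox_error("malformed_coords",
               "coordinates file must have columns cell_id, x, y")
  co$cell_id <- as.character(co$cell_id)
  if (anyDuplicated(cells) || anyDuplicated(co$cell_id))
    prox_error("duplicate_ids", "duplicate cell ids")
  if (!setequal(cells, co$cell_id))
    prox_error("unmatched_cells",
               "unmatched cells between counts and coordinates")
  ord <- match(co$cell_id, cells)
  m <- m[ord, , drop = FALSE]
  cell_map(co$cell_id, co$x, co$y, genes, m)
}

#' Write a cell map to disk
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate), `genes.tsv`, `cells.tsv`
#' and `coords.tsv` into `dir`, in the formats [read_cell_map()] reads; the
#' write/read round trip is the identity on the cell map.
#'
#' @param map A [cell_map].
#' @param dir Output directory (created if absent).
#' @param genes_as_rows Write the matrix genes x cells (default, 10x
#'   convention) or cells x genes.
#' @return `dir`, invisibly.
#' @export
write_cell_map <- function(map, dir, genes_as_rows = TRUE) {
  stopifnot(inherits(map, "cell_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- if (genes_as_rows) Matrix::t(map$counts) else map$counts
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(map$genes, file.path(dir, "genes.tsv"))
  writeLines(map$cell_ids, file.path(dir, "cells.tsv"))
  co <- data.frame(cell_id = map$cell_ids,
                   x = fmt_num(map$x), y = fmt_num(map$y))
  write.table(co, file.path(dir, "coords.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write proximity-analysis results
#'
#' One tab-delimited row per (sample, category, radius) with the ratio, its
#' numerator and denominator, the number of reference centers and the
#' subsampling interval bounds (NA when no interval was computed), followed
#' by an optional `#paired_t` footer line with the cross-sample test. All
#' numbers carry full double precision.
#'
#' @param results A data frame with columns `sample`, `category`, `radius`,
#'   `numerator`, `denominator`, `ratio`, `n_centers`, `ci_low`, `ci_high`
#'   (zero rows allowed), e.g. the `$results` of [run_cohort_analysis()].
#' @param path Output file path.
#' @param paired Optional `paired_t_result` footer.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, paired = NULL) {
  cols <- c("sample", "category", "radius", "numerator", "denominator",
            "ratio", "n_centers", "ci_low", "ci_high")
  if (!all(cols %in% colnames(results)))
    prox_error("malformed_results",
               paste0("results must have columns: ", paste(cols, collapse = ", ")))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(results)) {
    num <- c("radius", "numerator", "denominator", "ratio",
             "ci_low", "ci_high")
    out <- results[, cols, drop = FALSE]
    for (cc in num) out[[cc]] <- fmt_num(as.numeric(out[[cc]]))
    out$n_centers <- as.character(as.integer(out$n_centers))
    writeLines(do.call(paste, c(as.list(out), sep = "\t")), con)
  }
  if (!is.null(paired)) {
    stopifnot(inherits(paired, "paired_t_result"))
    writeLines(sprintf("#paired_t\t%s\t%d\t%s",
                       fmt_num(paired$statistic), paired$df,
                       fmt_num(paired$p_value)), con)
  }
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path File written by [write_results()].
#' @return A list with `results` (data frame, possibly zero rows) and
#'   `paired` (`NULL`, or a list with `statistic`, `df`, `p_value`).
#' @export
read_results <- function(path) {
  lines <- read_lines_strict(path)
  footer <- grep("^#paired_t\t", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#")]
  df <- read.delim(text = paste(body, collapse = "\n"),
                   stringsAsFactors = FALSE,
                   colClasses = c(sample = "character",
                                  category = "character",
                                  radius = "numeric", numerator = "numeric",
                                  denominator = "numeric", ratio = "numeric",
                                  n_centers = "integer",
                                  ci_low = "numeric", ci_high = "numeric"))
  paired <- NULL
  if (length(footer)) {
    f <- strsplit(footer[1], "\t", fixed = TRUE)[[1]]
    paired <- list(statistic = as.numeric(f[2]), df = as.integer(f[3]),
                   p_value = as.numeric(f[4]))
  }
  list(results = df, paired = paired)
}

#' Write a category assignment as TSV
#'
#' @param categories Factor from [assign_categories()], named by cell id.
#' @param path Output path; columns `cell_id`, `label`.
#' @return `path`, invisibly.
#' @export
write_categories <- function(categories, path) {
  write.table(data.frame(cell_id = names(categories),
                         label = as.character(categories)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Structured key-value config text: "key<TAB>value" lines, vectors
# comma-joined, nested names flattened with '.'.
write_config <- function(config, path) {
  flat <- unlist(config)
  writeLines(paste(names(flat), vapply(flat, as.character, character(1)),
                   sep = "\t"), path)
  invisible(path)
}
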