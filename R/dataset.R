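#' Construct an expression dataset
#'
#' Bundles a genes x cells expression matrix (sparse or dense) with gene and
#' cell identifiers and the cell-to-sample assignment. The matrix may hold raw
#' counts (`values_are_counts = TRUE`) or already-normalized expression.
#'
#' @param values Genes x cells matrix; a base matrix or any `Matrix` sparse
#'   matrix (stored internally as `dgCMatrix`).
#' @param gene_ids Character vector of unique gene identifiers (defaults to
#'   rownames, or `gene_1 ...` when absent).
#' @param cell_ids Character vector of unique cell identifiers (defaults to
#'   colnames, or `cell_1 ...` when absent).
#' @param sample_of_cell Either an integer vector of sample indices, or a
#'   character/factor vector of sample labels, one per cell. `NULL` assigns
#'   every cell to a single sample.
#' @param sample_ids Optional character vector naming the samples; required
#'   length `max(sample_of_cell)` when `sample_of_cell` is integer.
#' @param values_are_counts Logical; `TRUE` for raw counts (checked
#'   non-negative), `FALSE` for pre-normalized expression used verbatim.
#' @return An object of class `expression_dataset`.
#' @seealso [normalize_dataset()], [generate_dataset()], [read_10x_triplet()]
#' @export
expression_dataset <- function(values,
                               gene_ids = rownames(values),
                               cell_ids = colnames(values),
                               sample_of_cell = NULL,
                               sample_ids = NULL,
                               values_are_counts = TRUE) {
  if (is(values, "Matrix")) {
    values <- as(as(values, "CsparseMatrix"), "generalMatrix")
  } else if (!is.matrix(values)) {
    stop("'values' must be a matrix or a Matrix sparse matrix")
  }
  n_genes <- nrow(values)
  n_cells <- ncol(values)
  gene_ids <- as.character(gene_ids %||% paste0("gene_", seq_len(n_genes)))
  cell_ids <- as.character(cell_ids %||% paste0("cell_", seq_len(n_cells)))
  if (length(gene_ids) != n_genes) {
    stop("length of 'gene_ids' does not match the number of matrix rows")
  }
  if (length(cell_ids) != n_cells) {
    stop("length of 'cell_ids' does not match the number of matrix columns")
  }
  if (anyDuplicated(gene_ids)) stop("'gene_ids' must be unique")
  if (anyDuplicated(cell_ids)) stop("'cell_ids' must be unique")

  if (is.null(sample_of_cell)) {
    sample_of_cell <- rep.int(1L, n_cells)
    sample_ids <- sample_ids %||% "sample_1"
  }
  if (is.character(sample_of_cell) || is.factor(sample_of_cell)) {
    labels <- as.character(sample_of_cell)
    sample_ids <- sample_ids %||% unique(labels)
    sample_of_cell <- match(labels, sample_ids)
    if (anyNA(sample_of_cell)) stop("sample labels not covered by 'sample_ids'")
  }
  sample_of_cell <- as.integer(sample_of_cell)
  if (length(sample_of_cell) != n_cells) {
    stop("'sample_of_cell' must assign every cell to exactly one sample")
  }
  n_samples <- max(sample_of_cell)
  sample_ids <- as.character(sample_ids %||% paste0("sample_", seq_len(n_samples)))
  if (length(sample_ids) != n_samples) {
    stop("'sample_ids' must name every sample index")
  }
  if (any(sample_of_cell < 1L)) stop("sample indices must be >= 1")
  if (any(tabulate(sample_of_cell, n_samples) == 0L)) {
    stop("every sample must contain at least one cell")
  }
  if (values_are_counts) {
    neg <- if (is(values, "Matrix")) any(values@x < 0) else any(values < 0)
    if (isTRUE(neg)) stop("count data must have no negative entries")
  }

  structure(
    list(
      values = values,
      gene_ids = gene_ids,
      cell_ids = cell_ids,
      sample_of_cell = sample_of_cell,
      sample_ids = sample_ids,
      n_samples = n_samples,
      values_are_counts = isTRUE(values_are_counts)
    ),
    class = "expression_dataset"
  )
}

#' @method print expression_dataset
#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "expression_dataset: %d genes x %d cells, %d sample(s), %s\n",
    length(x$gene_ids), length(x$cell_ids), x$n_samples,
    if (x$values_are_counts) "raw counts" else "normalized expression"
  ))
  invisible(x)
}

# Column indices of the cells belonging to each sample, in dataset order.
cells_of_sample <- function(data) {
  split(seq_along(data$sample_of_cell), data$sample_of_cell)
}

#' Library-size normalize a count dataset
#'
#' Transforms raw counts as `log(1 + scale_factor * x / colsum)`, the standard
#' log1p depth normalization for single-cell RNA-seq. Pre-normalized datasets
#' are returned unchanged. Zero entries stay zero, so sparsity is preserved.
#'
#' @param data An [expression_dataset()].
#' @param scale_factor Pseudo-depth each cell is scaled to before `log1p`.
#' @return An `expression_dataset` flagged as normalized.
#' @export
normalize_dataset <- function(data, scale_factor = 1e4) {
  stopifnot(inherits(data, "expression_dataset"))
  if (!data$values_are_counts) {
    return(data)
  }
  values <- data$values
  n_cells <- ncol(values)
  cs <- numeric(n_cells)
  for (idx in cells_of_sample(data)) {
    cs[idx] <- colSums(dense_block(values, idx, what = "normalize_block"))
  }
  cs[cs == 0] <- 1 # empty cells stay all-zero
  if (is(values, "Matrix")) {
    per_entry <- rep.int(cs, diff(values@p))
    values@x <- log1p(scale_factor * values@x / per_entry)
  } else {
    denom <- matrix(cs, nrow(values), n_cells, byrow = TRUE)
    values <- log1p(scale_factor * values / denom)
  }
  data$values <- values
  data$values_are_counts <- FALSE
  data
}
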