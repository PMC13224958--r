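## Readers and writers for 10x-style MatrixMarket triplet directories.

read_lines_clean <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  sub("\r$", "", readLines(con, warn = FALSE))
}

open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else path
}

#' Read a 10x-style MatrixMarket triplet
#'
#' Loads a sparse expression matrix from a MatrixMarket coordinate file plus
#' features and barcodes text files (optionally gzipped), without ever
#' densifying. Orientation is normalized to genes x cells: if the matrix
#' header dimensions match barcodes-first layout, the matrix is transposed.
#' Duplicate gene ids are disambiguated by suffixing. Matrices containing
#' non-integer values are flagged as normalized input rather than counts.
#'
#' @param matrix_path Path to the `.mtx` (or `.mtx.gz`) file.
#' @param features_path Path to the features/genes file (first tab column is
#'   the gene id).
#' @param barcodes_path Path to the barcodes file (one cell id per line).
#' @param sample_of_cell,sample_ids Optional cell-to-sample assignment,
#'   as in [expression_dataset()]; by default all cells form one sample.
#' @return An [expression_dataset()].
#' @export
read_10x_triplet <- function(matrix_path, features_path, barcodes_path,
                             sample_of_cell = NULL, sample_ids = NULL) {
  feat_lines <- read_lines_clean(features_path)
  feat_lines <- feat_lines[nzchar(feat_lines)]
  gene_ids <- vapply(strsplit(feat_lines, "\t", fixed = TRUE), `[[`, "", 1L)
  barcodes <- read_lines_clean(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]

  con <- open_maybe_gz(matrix_path)
  m <- Matrix::readMM(con)
  m <- as(as(m, "CsparseMatrix"), "generalMatrix")

  n_feat <- length(gene_ids)
  n_bc <- length(barcodes)
  if (nrow(m) == n_feat && ncol(m) == n_bc) {
    # genes x cells, as expected
  } else if (nrow(m) == n_bc && ncol(m) == n_feat && n_feat != n_bc) {
    m <- Matrix::t(m)
    m <- as(as(m, "CsparseMatrix"), "generalMatrix")
  } else {
    stop(sprintf(
      "matrix dimensions %d x %d do not match %d features and %d barcodes",
      nrow(m), ncol(m), n_feat, n_bc))
  }
  if (length(m@x) == 0L) {
    warning("matrix has zero stored entries; returning an all-zero dataset")
  }
  if (anyDuplicated(gene_ids)) {
    gene_ids <- make.unique(gene_ids, sep = "_")
  }
  is_counts <- length(m@x) == 0L ||
    (all(m@x >= 0) && all(m@x == trunc(m@x)))
  expression_dataset(m, gene_ids = gene_ids, cell_ids = barcodes,
                     sample_of_cell = sample_of_cell, sample_ids = sample_ids,
                     values_are_counts = is_counts)
}

#' Write a dataset as a 10x-style triplet directory
#'
#' Writes `matrix.mtx`, `features.tsv` and `barcodes.tsv` under `dir`, plus
#' `samples.tsv` mapping each cell to its sample (and usable by
#' [read_sample_table()]). Values round-trip exactly through
#' [read_10x_triplet()].
#'
#' @param data An [expression_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(data, dir) {
  stopifnot(inherits(data, "expression_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    matrix = file.path(dir, "matrix.mtx"),
    features = file.path(dir, "features.tsv"),
    barcodes = file.path(dir, "barcodes.tsv"),
    samples = file.path(dir, "samples.tsv")
  )
  m <- data$values
  if (!is(m, "Matrix")) m <- Matrix(m, sparse = TRUE)
  m <- as(as(m, "CsparseMatrix"), "generalMatrix")
  # coordinate lines are written at 17 significant digits so that values
  # survive the round trip bitwise (writeMM prints too few digits)
  trip <- Matrix::summary(m)
  writeLines(
    c("%%MatrixMarket matrix coordinate real general",
      paste(nrow(m), ncol(m), nrow(trip)),
      sprintf("%d %d %.17g", trip$i, trip$j, trip$x)),
    paths$matrix
  )
  writeLines(paste(data$gene_ids, data$gene_ids, sep = "\t"), paths$features)
  writeLines(data$cell_ids, paths$barcodes)
  writeLines(
    c("cell_id\tsample_id",
      paste(data$cell_ids, data$sample_ids[data$sample_of_cell], sep = "\t")),
    paths$samples
  )
  invisible(paths)
}
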