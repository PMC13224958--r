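## Sample/covariate tables and GMT gene-set files.

#' Read a cell-to-sample table with optional sample covariates
#'
#' Reads a TSV with header columns `cell_id` and `sample_id`; any remaining
#' columns are sample-level covariates and must be constant within each
#' sample. Numeric columns are used as-is; categorical columns are one-hot
#' expanded with the reference (first) level dropped. Rows may appear in any
#' order: the returned map is keyed by cell id and aligned to `cell_ids`,
#' and samples are numbered by first appearance along the dataset cell
#' order.
#'
#' @param path Path to the TSV file (LF or CRLF line endings).
#' @param cell_ids Character vector of dataset cell ids to align to.
#' @return A list with `sample_of_cell` (integer per cell), `sample_ids`,
#'   and `design` (a [sample_design()], or `NULL` when the table has no
#'   covariate columns).
#' @export
read_sample_table <- function(path, cell_ids) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("cell_id", "sample_id")
  if (!all(need %in% names(tab))) {
    stop("sample table must contain columns 'cell_id' and 'sample_id'")
  }
  row_of <- match(cell_ids, tab$cell_id)
  if (anyNA(row_of)) {
    missing <- cell_ids[is.na(row_of)]
    stop(sprintf("cell id(s) missing from sample table: %s%s",
                 paste(head(missing, 10), collapse = ", "),
                 if (length(missing) > 10) sprintf(" (and %d more)",
                                                   length(missing) - 10) else ""))
  }
  labels <- as.character(tab$sample_id)[row_of]
  sample_ids <- unique(labels) # first appearance in dataset cell order
  sample_of_cell <- match(labels, sample_ids)

  cov_cols <- setdiff(names(tab), need)
  design <- NULL
  if (length(cov_cols)) {
    S <- length(sample_ids)
    per_sample <- vector("list", length(cov_cols))
    names(per_sample) <- cov_cols
    for (cc in cov_cols) {
      vals <- tab[[cc]][row_of]
      by_sample <- split(vals, sample_of_cell)
      if (any(vapply(by_sample, function(v) length(unique(v)) > 1L, TRUE))) {
        stop(sprintf("covariate '%s' varies within a sample", cc))
      }
      per_sample[[cc]] <- vapply(seq_len(S),
                                 function(i) by_sample[[as.character(i)]][1],
                                 tab[[cc]][1])
    }
    blocks <- list()
    for (cc in cov_cols) {
      v <- per_sample[[cc]]
      if (is.numeric(v)) {
        blocks[[cc]] <- matrix(as.numeric(v), ncol = 1,
                               dimnames = list(NULL, cc))
      } else {
        f <- factor(v)
        if (nlevels(f) < 2L) {
          stop(sprintf("categorical covariate '%s' has a single level", cc))
        }
        mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(mm) <- paste0(cc, "_", levels(f)[-1])
        blocks[[cc]] <- mm
      }
    }
    X <- do.call(cbind, blocks)
    rownames(X) <- sample_ids
    design <- sample_design(X, covariate_names = colnames(X))
  }
  list(sample_of_cell = sample_of_cell, sample_ids = sample_ids,
       design = design)
}

#' Read gene sets / regulons from a GMT file
#'
#' Standard GMT lines are `name<TAB>description<TAB>gene1<TAB>gene2...`;
#' entries of the form `gene,weight` are supported for signed regulons
#' (e.g. `TP53,-1`). Member genes absent from `gene_ids` are dropped (a
#' per-set count is reported via `message`); sets empty after intersection
#' are dropped with a warning.
#'
#' @param path Path to the GMT file.
#' @param gene_ids Character vector of dataset gene ids to align the prior
#'   to.
#' @return A [gene_program_prior()] whose matrix rows follow `gene_ids`.
#' @export
read_gene_sets_gmt <- function(path, gene_ids) {
  lines <- read_lines_clean(path)
  lines <- lines[nzchar(lines)]
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  keep_names <- character(0)
  col <- 0L
  for (ln in seq_along(lines)) {
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("malformed GMT line %d: expected at least 3 tab-separated fields", ln))
    }
    set_name <- fields[1]
    entries <- fields[-(1:2)]
    entries <- entries[nzchar(entries)]
    has_weight <- grepl(",", entries, fixed = TRUE)
    genes <- ifelse(has_weight,
                    vapply(strsplit(entries, ",", fixed = TRUE), `[[`, "", 1L),
                    entries)
    weights <- rep(1, length(entries))
    if (any(has_weight)) {
      w <- suppressWarnings(as.numeric(
        vapply(strsplit(entries[has_weight], ",", fixed = TRUE), `[[`, "", 2L)))
      if (anyNA(w)) {
        stop(sprintf("malformed gene,weight entry in GMT line %d", ln))
      }
      weights[has_weight] <- w
    }
    idx <- match(genes, gene_ids)
    dropped <- sum(is.na(idx))
    if (dropped > 0) {
      message(sprintf("gene set '%s': dropped %d gene(s) absent from the dataset",
                      set_name, dropped))
    }
    keep <- !is.na(idx)
    if (!any(keep)) {
      warning(sprintf("gene set '%s' has no genes in the dataset; dropped", set_name))
      next
    }
    col <- col + 1L
    keep_names <- c(keep_names, set_name)
    ii <- c(ii, idx[keep])
    jj <- c(jj, rep.int(col, sum(keep)))
    xx <- c(xx, weights[keep])
  }
  if (col == 0L) stop("no usable gene sets in GMT file")
  A <- sparseMatrix(i = ii, j = jj, x = xx,
                    dims = c(length(gene_ids), col))
  gene_program_prior(A, program_names = keep_names, gene_ids = gene_ids)
}
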