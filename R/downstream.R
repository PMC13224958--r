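## Downstream products of a fitted model: integrated embedding,
## clustering-free differential-expression vector fields, and gene-program
## (regulon) activity projection.

#' Differential-expression vector field
#'
#' The per-cell, per-gene expression shift induced by a unit change of a
#' sample-level covariate, evaluated continuously at each cell's latent
#' state without any clustering: `shifts[, n] = D_t b_n`, where `D_t` is the
#' genes x K slice of the covariate map for the requested covariate.
#'
#' Gene scores aggregate each gene's shift as its root-mean-square across
#' the queried cells; cell magnitudes are the L2 norm of each cell's shift.
#'
#' @param model A fitted `scwarp_model` or `scwarp_fit` with a covariate map
#'   (fitted with a design).
#' @param covariate Covariate name (or index) among the design's covariates.
#' @param cells Cells to evaluate (indices or ids); `NULL` for all cells.
#' @return An object of class `vector_field_result`: list with `shifts`
#'   (genes x cells), `covariate`, `gene_scores` (genes), `cell_magnitudes`
#'   (cells).
#' @export
de_vector_field <- function(model, covariate, cells = NULL) {
  model <- as_scwarp_model(model)
  if (is.null(model$D)) {
    stop("model was fitted without a sample design; no covariate map available")
  }
  if (is.character(covariate)) {
    t_idx <- match(covariate, model$covariate_names)
    if (is.na(t_idx)) {
      stop(sprintf("covariate '%s' not in design; available: %s",
                   covariate, paste(model$covariate_names, collapse = ", ")))
    }
  } else {
    t_idx <- as.integer(covariate)
    if (is.na(t_idx) || t_idx < 1L || t_idx > ncol(model$D)) {
      stop(sprintf("covariate index out of range; available: %s",
                   paste(model$covariate_names, collapse = ", ")))
    }
  }
  cells <- resolve_cells(model, cells)
  G <- nrow(model$Z); K <- ncol(model$Z)
  Dt <- matrix(model$D[, t_idx], G, K)
  shifts <- Dt %*% model$B[, cells, drop = FALSE]
  dimnames(shifts) <- list(model$gene_ids, model$cell_ids[cells])
  gene_scores <- sqrt(rowMeans(shifts^2))
  names(gene_scores) <- model$gene_ids
  cell_magnitudes <- sqrt(colSums(shifts^2))
  names(cell_magnitudes) <- model$cell_ids[cells]
  structure(
    list(shifts = shifts,
         covariate = model$covariate_names[t_idx],
         gene_scores = gene_scores,
         cell_magnitudes = cell_magnitudes),
    class = "vector_field_result"
  )
}

#' @method print vector_field_result
#' @export
print.vector_field_result <- function(x, ...) {
  cat(sprintf(
    "DE vector field for covariate '%s': %d genes x %d cells\n",
    x$covariate, nrow(x$shifts), ncol(x$shifts)
  ))
  top <- head(sort(x$gene_scores, decreasing = TRUE), 5)
  cat("top genes by RMS shift:",
      paste(sprintf("%s (%.3g)", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Gene-program (regulon) activities per cell
#'
#' Projects each cell onto the gene programs of the prior used at fit time:
#' `activity[p, n] = (W b_n)_p`. The program weights `W` are kept consistent
#' with the orthonormalization gauge at every iteration, so `A W b_n`
#' reproduces the model's reference reconstruction `Z b_n`.
#'
#' @param model A fitted `scwarp_model` or `scwarp_fit` carrying program
#'   weights (fitted with a [gene_program_prior()]).
#' @param cells Cells to evaluate (indices or ids); `NULL` for all cells.
#' @return Programs x cells numeric matrix of activities.
#' @export
program_activities <- function(model, cells = NULL) {
  model <- as_scwarp_model(model)
  if (is.null(model$W)) {
    stop("model was fitted without a gene-program prior; refit with 'prior' to project activities")
  }
  cells <- resolve_cells(model, cells)
  out <- model$W %*% model$B[, cells, drop = FALSE]
  dimnames(out) <- list(model$program_names, model$cell_ids[cells])
  out
}

#' Integrated cell embedding
#'
#' The cells x K coordinates of all cells in the shared latent space
#' (transpose of `B`), suitable as input to neighborhood-graph or UMAP
#' tooling. Columns are mean-centered by the model's gauge convention.
#'
#' @param model A fitted `scwarp_model` or `scwarp_fit`.
#' @return Cells x K matrix with cell ids as rownames and `factor_1 ...`
#'   column names.
#' @export
integrated_embedding <- function(model) {
  model <- as_scwarp_model(model)
  out <- t(model$B)
  dimnames(out) <- list(model$cell_ids,
                        paste0("factor_", seq_len(ncol(out))))
  out
}
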