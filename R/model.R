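## Model container and the reconstruction / objective equations.
##
## A fitted model holds:
##   Z      genes x K   shared orthonormal reference axes
##   delta  list of genes x K per-sample axis distortions (Delta Z_i)
##   B      K x cells   cell embeddings (rows mean-centered across cells)
##   o      genes       gene offsets
##   s      cells       cell offsets (log-space size factors)
##   D      (genes*K) x covariates   covariate map (optional)
##   W      programs x K program weights (optional, with Z = A W)
##   A      genes x programs gene-program prior (optional)
## Expected expression of cell n in sample i is
##   o + s_n * 1 + (Z + Delta Z_i) b_n.

new_scwarp_model <- function(Z, delta, B, o, s, D = NULL, W = NULL, A = NULL,
                             gene_ids, cell_ids, sample_ids, sample_of_cell,
                             covariate_names = NULL, program_names = NULL) {
  structure(
    list(Z = Z, delta = delta, B = B, o = o, s = s, D = D, W = W, A = A,
         gene_ids = gene_ids, cell_ids = cell_ids, sample_ids = sample_ids,
         sample_of_cell = as.integer(sample_of_cell),
         covariate_names = covariate_names, program_names = program_names),
    class = "scwarp_model"
  )
}

#' @method print scwarp_model
#' @export
print.scwarp_model <- function(x, ...) {
  cat(sprintf(
    "scwarp_model: %d genes, %d cells, %d sample(s), K = %d%s%s\n",
    nrow(x$Z), ncol(x$B), length(x$delta), ncol(x$Z),
    if (!is.null(x$D)) sprintf(", %d covariate(s)", ncol(x$D)) else "",
    if (!is.null(x$W)) sprintf(", %d program(s)", nrow(x$W)) else ""
  ))
  invisible(x)
}

# Accept either a model or the fit object returned by scwarp().
as_scwarp_model <- function(x) {
  if (inherits(x, "scwarp_fit")) return(x$model)
  if (inherits(x, "scwarp_model")) return(x)
  stop("expected an 'scwarp_model' or 'scwarp_fit' object")
}

check_model_dims <- function(model) {
  G <- nrow(model$Z); K <- ncol(model$Z); N <- ncol(model$B)
  if (nrow(model$B) != K) {
    stop(sprintf("dimension mismatch in parameter 'B': %d rows, expected K = %d",
                 nrow(model$B), K), call. = FALSE)
  }
  if (length(model$o) != G) {
    stop(sprintf("dimension mismatch in parameter 'o': length %d, expected %d genes",
                 length(model$o), G), call. = FALSE)
  }
  if (length(model$s) != N) {
    stop(sprintf("dimension mismatch in parameter 's': length %d, expected %d cells",
                 length(model$s), N), call. = FALSE)
  }
  for (i in seq_along(model$delta)) {
    d <- model$delta[[i]]
    if (nrow(d) != G || ncol(d) != K) {
      stop(sprintf(
        "dimension mismatch in parameter 'delta[[%d]]': %d x %d, expected %d x %d",
        i, nrow(d), ncol(d), G, K), call. = FALSE)
    }
  }
  invisible(TRUE)
}

# The genes x K distortion predicted by the covariate map at covariate
# vector x_i; zero when no map is present.
covariate_distortion <- function(model, x_i) {
  G <- nrow(model$Z); K <- ncol(model$Z)
  if (is.null(model$D)) return(matrix(0, G, K))
  matrix(model$D %*% as.numeric(x_i), G, K)
}

#' Reconstruct the expected expression of one cell
#'
#' Returns the model's expected expression vector for a single cell:
#' `o + s_n * 1 + (Z + DeltaZ_i) b_n`, where `i` is the cell's sample.
#'
#' @param model A fitted `scwarp_model` (or `scwarp_fit`).
#' @param cell Cell index (1-based) or cell id.
#' @return Numeric vector of length genes, named by gene id.
#' @export
reconstruct_cell <- function(model, cell) {
  model <- as_scwarp_model(model)
  check_model_dims(model)
  if (is.character(cell)) cell <- match(cell, model$cell_ids)
  cell <- as.integer(cell)
  if (length(cell) != 1L || is.na(cell) || cell < 1L || cell > ncol(model$B)) {
    stop("invalid cell index")
  }
  i <- model$sample_of_cell[cell]
  out <- model$o + model$s[cell] +
    drop((model$Z + model$delta[[i]]) %*% model$B[, cell])
  names(out) <- model$gene_ids
  out
}

#' Evaluate the penalized least-squares objective
#'
#' The objective is the squared reconstruction error summed over cells plus
#' ridge penalties: `lambda_b` on cell embeddings, `lambda_delta` on each
#' sample's distortion around its covariate prediction, `lambda_d` on the
#' covariate map and `lambda_w` on program weights. Penalty terms with zero
#' weight contribute exactly zero.
#'
#' @param model A `scwarp_model`.
#' @param data The [expression_dataset()] the model is fitted to (normalized
#'   expression).
#' @param hp A [scwarp_hyperparams()] object supplying the penalty weights.
#' @param design Optional [sample_design()] paired with the model's covariate
#'   map.
#' @param sample_order Optional permutation of sample indices; processing
#'   order never changes the result and is exposed for invariance testing.
#' @return Scalar objective value.
#' @export
compute_loss <- function(model, data, hp, design = NULL, sample_order = NULL) {
  model <- as_scwarp_model(model)
  check_model_dims(model)
  for (nm in c("Z", "B", "o", "s", "D", "W")) check_finite(model[[nm]], nm)
  check_finite(model$delta, "delta")
  if (data$values_are_counts) {
    stop("compute_loss expects normalized expression; run normalize_dataset() first")
  }
  idx_of <- cells_of_sample(data)
  parts <- sample_apply(data$n_samples, function(i) {
    idx <- idx_of[[i]]
    Y <- dense_block(data$values, idx)
    R <- Y - model$o -
      rep(model$s[idx], each = nrow(Y)) -
      (model$Z + model$delta[[i]]) %*% model$B[, idx, drop = FALSE]
    fit <- sum(R * R)
    dev <- 0
    if (hp$lambda_delta > 0) {
      Dx <- if (is.null(design)) {
        matrix(0, nrow(model$Z), ncol(model$Z))
      } else {
        covariate_distortion(model, design$X[i, ])
      }
      E <- model$delta[[i]] - Dx
      dev <- sum(E * E)
    }
    c(fit = fit, dev = dev)
  }, n_workers = hp$n_workers, order = sample_order)
  fit_term <- 0
  dev_term <- 0
  for (i in seq_len(data$n_samples)) {
    fit_term <- fit_term + parts[[i]][["fit"]]
    dev_term <- dev_term + parts[[i]][["dev"]]
  }
  loss <- fit_term
  if (hp$lambda_b > 0) loss <- loss + hp$lambda_b * sum(model$B^2)
  if (hp$lambda_delta > 0) loss <- loss + hp$lambda_delta * dev_term
  if (hp$lambda_d > 0 && !is.null(model$D)) loss <- loss + hp$lambda_d * sum(model$D^2)
  if (hp$lambda_w > 0 && !is.null(model$W)) loss <- loss + hp$lambda_w * sum(model$W^2)
  loss
}

#' Batch-corrected expression
#'
#' The shared-space reconstruction `Z B` of the selected cells: expression
#' with sample-specific distortions and cell size factors removed. With
#' `include_offsets = TRUE` the gene offsets `o` are added back columnwise;
#' the distortion and cell-offset terms are never included.
#'
#' @param model A fitted `scwarp_model` or `scwarp_fit`.
#' @param cells Cell indices or ids; `NULL` selects all cells. An empty
#'   selection yields an empty matrix.
#' @param include_offsets Logical; add gene offsets to every column.
#' @return Genes x cells numeric matrix.
#' @export
batch_corrected_expression <- function(model, cells = NULL, include_offsets = FALSE) {
  model <- as_scwarp_model(model)
  cells <- resolve_cells(model, cells)
  out <- model$Z %*% model$B[, cells, drop = FALSE]
  if (include_offsets && length(cells)) out <- out + model$o
  dimnames(out) <- list(model$gene_ids, model$cell_ids[cells])
  out
}

#' Sample-specific expression distortion
#'
#' The component `DeltaZ_i B` of expression attributable to sample `i`'s
#' warping of the reference axes, for cells belonging to that sample.
#'
#' @param model A fitted `scwarp_model` or `scwarp_fit`.
#' @param sample Sample index or sample id.
#' @param cells Cells to evaluate (indices or ids); `NULL` selects all cells
#'   of the sample. Cells from other samples raise an error naming the cell.
#' @return Genes x cells numeric matrix.
#' @export
sample_distortion <- function(model, sample, cells = NULL) {
  model <- as_scwarp_model(model)
  if (is.character(sample)) sample <- match(sample, model$sample_ids)
  sample <- as.integer(sample)
  if (is.na(sample) || sample < 1L || sample > length(model$delta)) {
    stop("invalid sample index")
  }
  if (is.null(cells)) {
    cells <- which(model$sample_of_cell == sample)
  } else {
    cells <- resolve_cells(model, cells)
    bad <- cells[model$sample_of_cell[cells] != sample]
    if (length(bad)) {
      stop(sprintf("cell '%s' does not belong to sample '%s'",
                   model$cell_ids[bad[1]], model$sample_ids[sample]))
    }
  }
  out <- model$delta[[sample]] %*% model$B[, cells, drop = FALSE]
  dimnames(out) <- list(model$gene_ids, model$cell_ids[cells])
  out
}

resolve_cells <- function(model, cells) {
  if (is.null(cells)) return(seq_len(ncol(model$B)))
  if (is.character(cells)) {
    idx <- match(cells, model$cell_ids)
    if (anyNA(idx)) {
      stop(sprintf("unknown cell id(s): %s",
                   paste(head(cells[is.na(idx)], 5), collapse = ", ")))
    }
    return(idx)
  }
  cells <- as.integer(cells)
  if (length(cells) && (anyNA(cells) || any(cells < 1L | cells > ncol(model$B)))) {
    stop("cell indices out of range")
  }
  cells
}
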