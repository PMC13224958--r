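## Model setup and latent-variable initialization.
##
## setup_model() allocates every parameter block at its final size (the
## workspace contract: shapes never change after setup). initialize_latents()
## fills offsets from data means and (Z, B) from a seeded randomized
## truncated SVD of the doubly centered matrix, computed blockwise per sample
## so the full gene x cell matrix is never densified.

#' Allocate an unfitted model
#'
#' Allocates all parameter blocks at their final sizes: `Z` and the
#' per-sample distortions at genes x K (distortions zero), `B` at K x cells,
#' offsets at their lengths, and — when a design or gene-program prior is
#' supplied — the covariate map `D` and program weights `W` (zero).
#'
#' @param data An [expression_dataset()].
#' @param hp A [scwarp_hyperparams()].
#' @param design Optional [sample_design()].
#' @param prior Optional [gene_program_prior()]; its gene dimension must
#'   match the dataset.
#' @return An unfitted `scwarp_model` with all blocks allocated.
#' @export
setup_model <- function(data, hp, design = NULL, prior = NULL) {
  stopifnot(inherits(data, "expression_dataset"),
            inherits(hp, "scwarp_hyperparams"))
  G <- length(data$gene_ids)
  N <- length(data$cell_ids)
  K <- hp$k
  if (K > min(G, N)) {
    stop(sprintf("k = %d exceeds min(genes, cells) = %d", K, min(G, N)))
  }
  small <- tabulate(data$sample_of_cell, data$n_samples) < K
  if (any(small)) {
    warning(sprintf("sample(s) with fewer than k = %d cells: %s", K,
                    paste(data$sample_ids[small], collapse = ", ")))
  }
  if (!is.null(design)) {
    stopifnot(inherits(design, "sample_design"))
    if (nrow(design$X) != data$n_samples) {
      stop("design row count does not match the number of samples")
    }
  }
  A <- NULL; W <- NULL; program_names <- NULL
  if (!is.null(prior)) {
    stopifnot(inherits(prior, "gene_program_prior"))
    if (nrow(prior$A) != G) {
      stop("gene-program prior gene dimension does not match the dataset")
    }
    A <- prior$A
    W <- matrix(0, ncol(A), K)
    program_names <- prior$program_names
  }
  new_scwarp_model(
    Z = matrix(0, G, K),
    delta = rep(list(matrix(0, G, K)), data$n_samples),
    B = matrix(0, K, N),
    o = numeric(G),
    s = numeric(N),
    D = if (!is.null(design)) matrix(0, G * K, ncol(design$X)) else NULL,
    W = W, A = A,
    gene_ids = data$gene_ids, cell_ids = data$cell_ids,
    sample_ids = data$sample_ids, sample_of_cell = data$sample_of_cell,
    covariate_names = if (!is.null(design)) design$covariate_names else NULL,
    program_names = program_names
  )
}

# Blockwise products with the implicitly doubly-centered matrix
# Yc = Y - o 1' - 1 s'. Never materializes Yc itself.
centered_mult <- function(data, o, s, V, idx_of) {
  acc <- matrix(0, length(o), ncol(V))
  for (i in seq_along(idx_of)) {
    idx <- idx_of[[i]]
    acc <- acc + dense_block(data$values, idx) %*% V[idx, , drop = FALSE]
  }
  acc - outer(o, colSums(V)) - outer(rep(1, length(o)), drop(crossprod(s, V)))
}

centered_crossprod <- function(data, o, s, Q, idx_of) {
  out <- matrix(0, length(s), ncol(Q))
  for (i in seq_along(idx_of)) {
    idx <- idx_of[[i]]
    out[idx, ] <- crossprod(dense_block(data$values, idx), Q)
  }
  out - outer(rep(1, length(s)), drop(crossprod(o, Q))) - outer(s, colSums(Q))
}

# Seeded randomized truncated SVD of the doubly centered matrix, with
# power iterations for spectral-gap robustness.
randomized_svd_centered <- function(data, o, s, k, seed,
                                    n_power = 4L, oversample = 10L) {
  idx_of <- cells_of_sample(data)
  N <- length(s)
  p <- min(k + oversample, N)
  Omega <- with_seed(seed, matrix(rnorm(N * p), N, p))
  Q <- qr.Q(qr(centered_mult(data, o, s, Omega, idx_of)))
  for (t in seq_len(n_power)) {
    Q2 <- qr.Q(qr(centered_crossprod(data, o, s, Q, idx_of)))
    Q <- qr.Q(qr(centered_mult(data, o, s, Q2, idx_of)))
  }
  C <- t(centered_crossprod(data, o, s, Q, idx_of)) # p x N
  sv <- svd(C, nu = min(k, p), nv = min(k, p))
  list(
    Z = Q %*% sv$u[, seq_len(k), drop = FALSE],
    B = sv$d[seq_len(k)] * t(sv$v[, seq_len(k), drop = FALSE])
  )
}

# Sign convention: each reference axis's largest-magnitude entry is made
# positive (ties resolved to the lowest gene index by which.max), removing
# the factorization's sign indeterminacy so runs are bitwise reproducible.
fix_signs <- function(Z, B) {
  for (j in seq_len(ncol(Z))) {
    i_star <- which.max(abs(Z[, j]))
    if (Z[i_star, j] < 0) {
      Z[, j] <- -Z[, j]
      B[j, ] <- -B[j, ]
    }
  }
  list(Z = Z, B = B)
}

#' Initialize latent variables
#'
#' Fills an allocated model: gene offsets are per-gene means of the
#' normalized data, cell offsets per-cell means of the gene-centered data,
#' and `(Z, B)` come from a seeded randomized rank-K SVD of the doubly
#' centered matrix. After initialization `Z` is orthonormal with the sign
#' convention applied and rows of `B` are mean-centered, the means being
#' absorbed into the gene offsets.
#'
#' @param model Output of [setup_model()].
#' @param data The [expression_dataset()] (normalized expression).
#' @param hp A [scwarp_hyperparams()]; `hp$seed` drives the randomized SVD.
#' @return The initialized `scwarp_model`.
#' @export
initialize_latents <- function(model, data, hp) {
  stopifnot(inherits(model, "scwarp_model"))
  if (data$values_are_counts) {
    stop("initialize_latents expects normalized expression; run normalize_dataset() first")
  }
  G <- nrow(model$Z); N <- ncol(model$B); K <- ncol(model$Z)
  idx_of <- cells_of_sample(data)

  o <- numeric(G)
  for (idx in idx_of) o <- o + rowSums(dense_block(data$values, idx))
  o <- o / N
  s <- numeric(N)
  for (idx in idx_of) s[idx] <- colMeans(dense_block(data$values, idx) - o)

  # degenerate all-zero (after centering) input
  total_sq <- 0
  for (idx in idx_of) {
    Yb <- dense_block(data$values, idx)
    Rb <- Yb - o - rep(s[idx], each = G)
    total_sq <- total_sq + sum(Rb * Rb)
  }
  if (total_sq < 1e-24 * max(1, G * N)) {
    warning("doubly centered matrix is numerically zero; using canonical axes")
    Z <- diag(1, G, K)
    B <- matrix(0, K, N)
  } else {
    dec <- randomized_svd_centered(data, o, s, K, hp$seed)
    Z <- dec$Z
    B <- dec$B
  }
  sb <- fix_signs(Z, B)
  Z <- sb$Z; B <- sb$B
  # noise-variance estimate from the rank-K residual: penalty weights are
  # specified in units of this variance (Gaussian-prior MAP reading), so the
  # default ridges stay mild at any data scale
  sigma_sq <- max(0, (total_sq - sum(B^2)) / (G * N))
  model$sigma_sq <- sigma_sq
  # exact ridge minimizer over B given orthonormal Z
  B <- B / (1 + hp$lambda_b * sigma_sq)
  b_bar <- rowMeans(B)
  o <- o + drop(Z %*% b_bar)
  B <- B - b_bar

  model$o <- o
  model$s <- s
  model$Z <- Z
  model$B <- B

  if (!is.null(model$A)) {
    AtA <- as.matrix(crossprod(model$A))
    W <- solve_gram(AtA + diag(hp$lambda_w * sigma_sq, ncol(AtA)),
                    as.matrix(crossprod(model$A, model$Z)),
                    context = "program-weight system")
    model$W <- W
    model$Z <- as.matrix(model$A %*% W)
    model <- orthogonalize_reference(model)
  }
  model
}
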