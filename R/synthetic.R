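## Synthetic multi-sample datasets with known ground truth, exhibiting
## exactly the structure the model assumes: shared orthonormal axes, a
## cluster + trajectory latent geometry (so the cell-state continuum is
## present and clustering-free DE is meaningfully testable), covariate-linked
## per-sample axis distortions with planted DE genes, offsets, and Gaussian
## measurement noise. Everything is reproducible from a single seed.

## Identifiable-gauge reference axes: the model's per-cell scalar offset
## absorbs any component of the axes along the all-ones gene vector, so the
## planted axes are drawn orthogonal to it (columns centered before QR);
## otherwise the truth could not be recovered even from noiseless data.
random_orthonormal <- function(n, k) {
  M <- matrix(rnorm(n * k), n, k)
  M <- sweep(M, 2, colMeans(M))
  qr.Q(qr(M))
}

#' Generate a synthetic multi-sample dataset with ground truth
#'
#' Latent cell states are drawn from a mixture of 3 clusters plus a 1-D
#' trajectory component, then gauge-fixed (orthonormal `Z_true`, row-centered
#' `B_true`) so the truth lives in the model's identifiable gauge. Each
#' sample's axis distortion is `DeltaZ_i = D_true(x_i) + distortion_scale * E_i`
#' with `E_i` Gaussian at the same per-entry scale as the reference axes, and
#' `D_true` supported on `n_de_genes` planted genes with magnitude
#' `covariate_effect` for a binary `disease` covariate split evenly across
#' samples. Observed expression is
#' `Y = o 1' + 1 s' + (Z + DeltaZ_i) B + noise` with i.i.d. Gaussian noise.
#'
#' @param genes,k,n_samples,cells_per_sample Problem dimensions (all >= 1).
#' @param noise_sd Standard deviation of the Gaussian measurement noise.
#' @param distortion_scale Scale of the random (covariate-independent) part
#'   of each sample's distortion, relative to the reference-axis entry scale.
#' @param covariate_effect Magnitude of the covariate-driven distortion on
#'   the planted DE genes.
#' @param n_de_genes Number of planted condition-responsive genes.
#' @param seed Integer seed; identical seeds give bitwise-identical output.
#' @param prior `NULL`, an integer number of signed gene programs to plant
#'   (the reference axes are then built as `A W_true`), or a
#'   [gene_program_prior()] to use as-is.
#' @return A list with `dataset` (an [expression_dataset()], normalized
#'   expression stored sparsely), `design` (a [sample_design()] with an
#'   intercept and the binary `disease` covariate), and `truth` (class
#'   `scwarp_truth`:
#'   `Z_true`, `delta_true`, `B_true`, `o_true`, `s_true`, `D_true`, `X`,
#'   `planted_de_genes`, and when a prior is used `program_matrix`,
#'   `W_true`, `activities_true`).
#' @export
generate_dataset <- function(genes = 200, k = 5, n_samples = 4,
                             cells_per_sample = 500, noise_sd = 0.1,
                             distortion_scale = 0.3, covariate_effect = 1.0,
                             n_de_genes = 20, seed = 7, prior = NULL) {
  stopifnot(genes >= 1, k >= 1, n_samples >= 1, cells_per_sample >= 1,
            noise_sd >= 0, distortion_scale >= 0, covariate_effect >= 0)
  if (n_de_genes > genes) {
    stop("n_de_genes must not exceed the number of genes")
  }
  G <- as.integer(genes); K <- as.integer(k)
  S <- as.integer(n_samples); C <- as.integer(cells_per_sample)
  N <- S * C

  with_seed(seed, {
    ## gene-program prior (optional) and reference axes
    A <- NULL; program_names <- NULL; W_true <- NULL
    if (!is.null(prior)) {
      if (inherits(prior, "gene_program_prior")) {
        A <- prior$A
        program_names <- prior$program_names
        if (nrow(A) != G) stop("prior gene dimension does not match 'genes'")
      } else {
        P <- as.integer(prior)
        stopifnot(P >= 1, P <= G)
        # disjoint blocks of member genes with random signs
        block <- split(seq_len(G), rep_len(seq_len(P), G))
        ii <- unlist(block)
        jj <- rep(seq_len(P), vapply(block, length, 1L))
        xx <- sample(c(-1, 1), G, replace = TRUE)
        A <- sparseMatrix(i = ii, j = jj, x = xx, dims = c(G, P))
        program_names <- paste0("program_", seq_len(P))
      }
      P <- ncol(A)
      W0 <- matrix(rnorm(P * K), P, K)
      Z0 <- as.matrix(A %*% W0)
      qrz <- qr(Z0)
      Rm <- qr.R(qrz)
      d <- sign(diag(Rm)); d[d == 0] <- 1
      Z_true <- sweep(qr.Q(qrz), 2, d, `*`)
      W_true <- t(backsolve(d * Rm, t(W0), transpose = TRUE)) # W0 R^-1
    } else {
      Z_true <- random_orthonormal(G, K)
    }

    ## latent cell states: 3 clusters + 1-D trajectory
    centers <- matrix(rnorm(3 * K, sd = 2), K, 3)
    traj_dir <- rnorm(K); traj_dir <- traj_dir / sqrt(sum(traj_dir^2))
    cluster <- sample.int(3, N, replace = TRUE)
    tpos <- runif(N, 0, 2)
    ## The latent states are whitened to covariance 4 I after centering.
    ## Cluster + trajectory geometry survives (whitening is linear), but
    ## every reference axis then carries the same variance: with 3 cluster
    ## centers the raw between-cluster spread is only rank 2, and at unlucky
    ## seeds the smallest eigenvalue of the raw latent covariance would sink
    ## to the level of the distortion components, making that axis
    ## unrecoverable by any method. Axes are defined only up to rotation, so
    ## stating the truth in the whitened basis loses no generality.
    B_true <- centers[, cluster] +
      outer(traj_dir, tpos) +
      matrix(rnorm(K * N, sd = 1), K, N)
    B_true <- B_true - rowMeans(B_true) # model gauge: centered embeddings
    cov_b <- tcrossprod(B_true) / N
    eg <- eigen(cov_b, symmetric = TRUE)
    white <- eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
    B_true <- 2 * (white %*% B_true)

    ## offsets
    o_true <- rnorm(G, sd = 1)
    s_true <- rnorm(N, sd = 0.2)

    ## covariates: intercept plus binary disease split evenly across samples.
    ## The intercept lets the fitted covariate map separate any distortion
    ## shared by all samples from the disease-differential part. A
    ## single-sample dataset has no between-sample contrast: intercept only.
    x_disease <- if (S > 1) as.numeric(seq_len(S) > S / 2) else numeric(1)
    X <- if (S > 1) cbind(intercept = 1, disease = x_disease)
         else cbind(intercept = 1)

    ## disease slice of the covariate map, supported on planted genes; entry
    ## scale covariate_effect/sqrt(G) makes effect 1.0 mean "distortion
    ## comparable to a typical reference-axis loading" on planted genes —
    ## strong per-gene DE while the shared axes stay dominant
    planted <- sort(sample.int(G, n_de_genes))
    D_slice <- matrix(0, G, K)
    if (covariate_effect > 0 && n_de_genes > 0) {
      D_slice[planted, ] <- matrix(rnorm(n_de_genes * K,
                                         sd = covariate_effect / sqrt(G)),
                                   n_de_genes, K)
      # truth lives in the model's identifiable gauge: distortions carry no
      # reference-axis component
      D_slice <- D_slice - Z_true %*% crossprod(Z_true, D_slice)
    }
    D_true <- if (S > 1) cbind(intercept = 0, disease = as.vector(D_slice))
              else matrix(0, G * K, 1, dimnames = list(NULL, "intercept"))

    ## Per-sample distortions in the fully identifiable gauge: orthogonal to
    ## the reference axes AND averaging to zero across samples (otherwise the
    ## mean distortion would be part of the shared reference, not of the
    ## distortions). The disease effect is therefore symmetric: +D/2 in
    ## affected samples, -D/2 in the rest; the disease *contrast* is D.
    E_list <- lapply(seq_len(S), function(i) {
      E <- matrix(rnorm(G * K, sd = 1 / sqrt(G)), G, K)
      E - Z_true %*% crossprod(Z_true, E)
    })
    E_bar <- Reduce(`+`, E_list) / S
    x_centered <- x_disease - mean(x_disease)
    delta_true <- lapply(seq_len(S), function(i) {
      x_centered[i] * D_slice + distortion_scale * (E_list[[i]] - E_bar)
    })

    ## observed expression
    sample_of_cell <- rep(seq_len(S), each = C)
    Y <- matrix(0, G, N)
    for (i in seq_len(S)) {
      idx <- which(sample_of_cell == i)
      Y[, idx] <- (Z_true + delta_true[[i]]) %*% B_true[, idx, drop = FALSE]
    }
    Y <- Y + o_true + rep(s_true, each = G)
    if (noise_sd > 0) {
      Y <- Y + matrix(rnorm(G * N, sd = noise_sd), G, N)
    } else {
      Y[abs(Y) < 1e-8] <- 0
    }
    values <- as(as(Matrix(Y, sparse = TRUE), "CsparseMatrix"), "generalMatrix")

    dataset <- expression_dataset(
      values,
      gene_ids = paste0("gene_", seq_len(G)),
      cell_ids = paste0("cell_", seq_len(N)),
      sample_of_cell = sample_of_cell,
      sample_ids = paste0("sample_", seq_len(S)),
      values_are_counts = FALSE
    )
    design <- sample_design(X, covariate_names = colnames(X),
                            intercept_included = TRUE)
    truth <- structure(
      list(Z_true = Z_true, delta_true = delta_true, B_true = B_true,
           o_true = o_true, s_true = s_true, D_true = D_true, X = X,
           planted_de_genes = planted,
           program_matrix = A, W_true = W_true,
           activities_true = if (!is.null(W_true)) W_true %*% B_true else NULL,
           cluster = cluster, trajectory_position = tpos,
           noise_sd = noise_sd, seed = seed),
      class = "scwarp_truth"
    )
    list(dataset = dataset, design = design, truth = truth)
  })
}

#' Generate an integer-count variant of the synthetic dataset
#'
#' Passes the Gaussian latent means through `exp`, scales each cell to an
#' expected depth of `mean_depth`, and samples Poisson counts, so the raw
#' count normalization path (`log1p` of depth-scaled counts) is exercised
#' end-to-end.
#'
#' @inheritParams generate_dataset
#' @param mean_depth Expected total counts per cell (> 0).
#' @return As [generate_dataset()], but `dataset` holds raw integer counts
#'   (`values_are_counts = TRUE`).
#' @export
generate_counts <- function(genes = 200, k = 5, n_samples = 4,
                            cells_per_sample = 500, noise_sd = 0.1,
                            distortion_scale = 0.3, covariate_effect = 1.0,
                            n_de_genes = 20, seed = 7, prior = NULL,
                            mean_depth = 5000) {
  if (!is.numeric(mean_depth) || mean_depth <= 0) {
    stop("'mean_depth' must be > 0")
  }
  sim <- generate_dataset(genes, k, n_samples, cells_per_sample, noise_sd,
                          distortion_scale, covariate_effect, n_de_genes,
                          seed, prior)
  G <- length(sim$dataset$gene_ids)
  idx_of <- cells_of_sample(sim$dataset)
  with_seed(seed + 1L, {
    counts_cols <- vector("list", length(sim$dataset$cell_ids))
    for (idx in idx_of) {
      mu <- dense_block(sim$dataset$values, idx)
      lam <- exp(mu)
      if (any(!is.finite(lam))) {
        stop("latent means overflow exp(); use smaller effect sizes")
      }
      for (jj in seq_along(idx)) {
        p <- lam[, jj] / sum(lam[, jj])
        counts_cols[[idx[jj]]] <- rpois(G, mean_depth * p)
      }
    }
    counts <- do.call(cbind, counts_cols)
    sim$dataset <- expression_dataset(
      as(as(Matrix(counts, sparse = TRUE), "CsparseMatrix"), "generalMatrix"),
      gene_ids = sim$dataset$gene_ids,
      cell_ids = sim$dataset$cell_ids,
      sample_of_cell = sim$dataset$sample_of_cell,
      sample_ids = sim$dataset$sample_ids,
      values_are_counts = TRUE
    )
  })
  sim
}
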