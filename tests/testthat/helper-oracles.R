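# Independent dense oracles and small fixture builders used across tests.
# Oracles are written with explicit loops / base linear algebra so they stay
# independent of the implementation paths they check.

# Mann-Whitney AUROC of `score` for the index set `positives`.
auroc <- function(score, positives) {
  r <- rank(score)
  np <- length(positives)
  nn <- length(score) - np
  (sum(r[positives]) - np * (np + 1) / 2) / (np * nn)
}

# A random dense model + dataset pair with consistent dimensions, built
# directly (not via the fitting path). Values are exact reconstructions plus
# optional noise, so loss values are controllable.
random_instance <- function(genes = 12, k = 3, n_samples = 2,
                            cells_per_sample = 8, noise_sd = 0.3,
                            with_design = FALSE, seed = 1) {
  set.seed(seed)
  G <- genes; K <- k; S <- n_samples; N <- S * cells_per_sample
  Z <- qr.Q(qr(matrix(rnorm(G * K), G, K)))
  delta <- lapply(seq_len(S), function(i) matrix(rnorm(G * K, sd = 0.2), G, K))
  B <- matrix(rnorm(K * N), K, N)
  B <- B - rowMeans(B)
  o <- rnorm(G)
  s <- rnorm(N, sd = 0.3)
  soc <- rep(seq_len(S), each = cells_per_sample)
  Y <- matrix(0, G, N)
  for (i in seq_len(S)) {
    idx <- which(soc == i)
    Y[, idx] <- (Z + delta[[i]]) %*% B[, idx, drop = FALSE]
  }
  Y <- Y + o + rep(s, each = G)
  if (noise_sd > 0) Y <- Y + matrix(rnorm(G * N, sd = noise_sd), G, N)
  data <- expression_dataset(Y, sample_of_cell = soc, values_are_counts = FALSE)
  design <- NULL
  D <- NULL
  if (with_design) {
    X <- cbind(intercept = 1, x = rnorm(S))
    design <- sample_design(X, intercept_included = TRUE)
    D <- matrix(rnorm(G * K * 2, sd = 0.1), G * K, 2)
  }
  model <- scwarp:::new_scwarp_model(
    Z = Z, delta = delta, B = B, o = o, s = s, D = D,
    gene_ids = data$gene_ids, cell_ids = data$cell_ids,
    sample_ids = data$sample_ids, sample_of_cell = soc,
    covariate_names = if (with_design) colnames(design$X)
  )
  list(model = model, data = data, design = design, Y = Y)
}

# Loop-based objective oracle: cell-by-cell, gene-by-gene.
oracle_loss <- function(model, data, hp, design = NULL) {
  Y <- as.matrix(data$values)
  G <- nrow(Y); N <- ncol(Y)
  total <- 0
  for (n in seq_len(N)) {
    i <- data$sample_of_cell[n]
    mu <- model$o + model$s[n] + (model$Z + model$delta[[i]]) %*% model$B[, n]
    for (g in seq_len(G)) total <- total + (Y[g, n] - mu[g])^2
  }
  total <- total + hp$lambda_b * sum(model$B^2)
  for (i in seq_len(data$n_samples)) {
    Dx <- if (is.null(design)) 0 * model$delta[[i]] else {
      matrix(model$D %*% design$X[i, ], nrow(model$Z), ncol(model$Z))
    }
    total <- total + hp$lambda_delta * sum((model$delta[[i]] - Dx)^2)
  }
  if (!is.null(model$D)) total <- total + hp$lambda_d * sum(model$D^2)
  if (!is.null(model$W)) total <- total + hp$lambda_w * sum(model$W^2)
  total
}

# Cell-by-cell normal-equations oracle for the embedding update.
oracle_embeddings <- function(model, data, hp) {
  Y <- as.matrix(data$values)
  K <- ncol(model$Z)
  B <- matrix(0, K, ncol(Y))
  for (n in seq_len(ncol(Y))) {
    i <- data$sample_of_cell[n]
    M <- model$Z + model$delta[[i]]
    rhs <- t(M) %*% (Y[, n] - model$o - model$s[n])
    B[, n] <- solve(t(M) %*% M + hp$lambda_b * diag(K), rhs)
  }
  B
}

# Per-sample ridge oracle for the distortion update, including the
# Z-orthogonality gauge projection.
oracle_distortions <- function(model, data, hp, design = NULL) {
  Y <- as.matrix(data$values)
  G <- nrow(Y); K <- ncol(model$Z)
  lapply(seq_len(data$n_samples), function(i) {
    idx <- which(data$sample_of_cell == i)
    Dx <- if (is.null(design)) matrix(0, G, K) else {
      matrix(model$D %*% design$X[i, ], G, K)
    }
    Bi <- model$B[, idx, drop = FALSE]
    R <- Y[, idx, drop = FALSE] - model$o - rep(model$s[idx], each = G) -
      model$Z %*% Bi
    sol <- (R %*% t(Bi) + hp$lambda_delta * Dx) %*%
      solve(Bi %*% t(Bi) + hp$lambda_delta * diag(K))
    sol - model$Z %*% (t(model$Z) %*% sol)
  })
}

# Vectorized ridge-regression oracle for the covariate map.
oracle_covariate_map <- function(model, design, hp) {
  S <- nrow(design$X); P <- ncol(design$X)
  V <- t(vapply(seq_len(S), function(i) as.vector(model$delta[[i]]),
                numeric(length(model$delta[[1]]))))
  ridge <- hp$lambda_d / hp$lambda_delta
  t(solve(t(design$X) %*% design$X + ridge * diag(P), t(design$X) %*% V))
}

# Dense Procrustes oracle for the (prior-free) reference update: loop-built
# cross-moment, then the polar factor via SVD.
oracle_reference <- function(model, data) {
  Y <- as.matrix(data$values)
  G <- nrow(Y); K <- ncol(model$Z)
  Cyb <- matrix(0, G, K)
  for (n in seq_len(ncol(Y))) {
    i <- data$sample_of_cell[n]
    r <- Y[, n] - model$o - model$s[n] - model$delta[[i]] %*% model$B[, n]
    Cyb <- Cyb + r %*% t(model$B[, n])
  }
  sv <- svd(Cyb)
  sv$u %*% t(sv$v)
}

# Sequential-means oracle for the offset update (o given s, then s, then
# absorb embedding row means).
oracle_offsets <- function(model, data) {
  Y <- as.matrix(data$values)
  G <- nrow(Y); N <- ncol(Y)
  Fmat <- matrix(0, G, N)
  for (n in seq_len(N)) {
    i <- data$sample_of_cell[n]
    Fmat[, n] <- (model$Z + model$delta[[i]]) %*% model$B[, n]
  }
  o <- rowMeans(Y - rep(model$s, each = G) - Fmat)
  s <- colMeans(Y - o - Fmat)
  b_bar <- rowMeans(model$B)
  list(o = o + as.vector(model$Z %*% b_bar), s = s, B = model$B - b_bar)
}

expect_monotone_loss <- function(report, tol_factor = 1e-9) {
  tr <- report$loss_trajectory
  expect_true(all(diff(tr) <= tol_factor * abs(tr[1])))
}
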