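test_that("embedding update reduces to residual projection for trivial axes", {
  # M = I, lambda_b = 0: b_n = y_n - o - s_n
  K <- 4
  Y <- matrix(rnorm(K * 6), K, 6)
  data <- expression_dataset(Y, values_are_counts = FALSE)
  m <- scwarp:::new_scwarp_model(
    Z = diag(K), delta = list(matrix(0, K, K)),
    B = matrix(0, K, 6), o = rnorm(K), s = rnorm(6),
    gene_ids = data$gene_ids, cell_ids = data$cell_ids,
    sample_ids = "s1", sample_of_cell = rep(1L, 6)
  )
  hp <- scwarp_hyperparams(K, lambda_b = 0)
  m2 <- update_cell_embeddings(m, data, hp)
  want <- Y - m$o - rep(m$s, each = K)
  expect_lt(max(abs(m2$B - want)), 1e-12)
})

test_that("embedding update is the left inverse for orthonormal axes", {
  inst <- random_instance(genes = 10, k = 3, noise_sd = 0.2, seed = 12)
  m <- inst$model
  for (i in seq_along(m$delta)) m$delta[[i]][] <- 0 # M = Z orthonormal
  hp <- scwarp_hyperparams(3, lambda_b = 0)
  m2 <- update_cell_embeddings(m, inst$data, hp)
  Y <- inst$Y
  resid <- Y - m$o - rep(m$s, each = nrow(Y))
  expect_lt(max(abs(m2$B - crossprod(m$Z, resid))), 1e-10)
})

test_that("block updates match independent dense oracles on random instances", {
  for (seed in 1:6) {
    inst <- random_instance(genes = 12, k = 3, n_samples = 2,
                            cells_per_sample = 9, with_design = TRUE,
                            seed = seed)
    hp <- scwarp_hyperparams(3, lambda_b = 0.6, lambda_delta = 1.2,
                             lambda_d = 0.8)
    m <- inst$model

    mb <- update_cell_embeddings(m, inst$data, hp)
    expect_lt(max(abs(mb$B - oracle_embeddings(m, inst$data, hp))), 1e-10)

    md <- update_sample_distortions(m, inst$data, hp, design = inst$design)
    want <- oracle_distortions(m, inst$data, hp, design = inst$design)
    for (i in seq_along(want)) {
      expect_lt(max(abs(md$delta[[i]] - want[[i]])), 1e-10)
    }

    mc <- update_covariate_map(m, inst$design, hp)
    expect_lt(max(abs(mc$D - oracle_covariate_map(m, inst$design, hp))), 1e-10)

    mz <- update_reference(m, inst$data, hp)
    expect_lt(max(abs(mz$Z - oracle_reference(m, inst$data))), 1e-10)

    mo <- update_offsets(m, inst$data, hp)
    wo <- oracle_offsets(m, inst$data)
    expect_lt(max(abs(mo$o - wo$o)), 1e-10)
    expect_lt(max(abs(mo$s - wo$s)), 1e-10)
    expect_lt(max(abs(mo$B - wo$B)), 1e-10)
  }
})

test_that("distortions approach the gauge-projected prior mean as lambda_delta grows", {
  inst <- random_instance(genes = 10, k = 2, with_design = TRUE, seed = 13)
  hp <- scwarp_hyperparams(2, lambda_delta = 1e12)
  m2 <- update_sample_distortions(inst$model, inst$data, hp,
                                  design = inst$design)
  Z <- inst$model$Z
  for (i in seq_along(m2$delta)) {
    Dx <- matrix(inst$model$D %*% inst$design$X[i, ], nrow(Z), ncol(Z))
    Dx_perp <- Dx - Z %*% crossprod(Z, Dx)
    expect_lt(max(abs(m2$delta[[i]] - Dx_perp)), 1e-4)
  }
})

test_that("distortions are recovered from noiseless single-factor data", {
  set.seed(14)
  G <- 30; N <- 40
  Z <- qr.Q(qr(matrix(rnorm(G), G, 1)))
  delta_true <- matrix(rnorm(G, sd = 0.2), G, 1)
  delta_true <- delta_true - Z %*% crossprod(Z, delta_true) # gauge
  B <- matrix(rnorm(N, sd = 2), 1, N); B <- B - rowMeans(B)
  Y <- (Z + delta_true) %*% B
  data <- expression_dataset(Y, values_are_counts = FALSE)
  m <- scwarp:::new_scwarp_model(
    Z = Z, delta = list(matrix(0, G, 1)), B = B,
    o = numeric(G), s = numeric(N),
    gene_ids = data$gene_ids, cell_ids = data$cell_ids,
    sample_ids = "s1", sample_of_cell = rep(1L, N)
  )
  hp <- scwarp_hyperparams(1, lambda_delta = 1e-9)
  m2 <- update_sample_distortions(m, data, hp)
  expect_lt(max(abs(m2$delta[[1]] - as.vector(delta_true))), 1e-4)
})

test_that("covariate map solves exact linear relationships", {
  inst <- random_instance(genes = 8, k = 2, n_samples = 4,
                          cells_per_sample = 5, with_design = TRUE, seed = 15)
  m <- inst$model
  hp <- scwarp_hyperparams(2, lambda_delta = 1, lambda_d = 0)

  # all distortions equal, intercept-only design: D(intercept) is that value
  common <- matrix(rnorm(8 * 2), 8, 2)
  m1 <- m
  for (i in 1:4) m1$delta[[i]] <- common
  des1 <- sample_design(matrix(1, 4, 1), covariate_names = "intercept",
                        intercept_included = TRUE)
  m1$D <- matrix(0, 16, 1)
  got <- update_covariate_map(m1, des1, hp)
  expect_lt(max(abs(matrix(got$D[, 1], 8, 2) - common)), 1e-10)

  # delta_i = x_i * Q recovers Q exactly at lambda_d = 0
  Q <- matrix(rnorm(8 * 2), 8, 2)
  x <- rnorm(4)
  m2 <- m
  for (i in 1:4) m2$delta[[i]] <- x[i] * Q
  des2 <- sample_design(matrix(x, 4, 1), covariate_names = "x")
  m2$D <- matrix(0, 16, 1)
  got2 <- update_covariate_map(m2, des2, hp)
  expect_lt(max(abs(matrix(got2$D[, 1], 8, 2) - Q)), 1e-10)
})

test_that("covariate map requires a ridge when under-determined", {
  inst <- random_instance(genes = 6, k = 2, n_samples = 2,
                          cells_per_sample = 4, with_design = TRUE, seed = 16)
  X <- cbind(1, rnorm(2), rnorm(2)) # 3 covariates, 2 samples
  des <- sample_design(X, covariate_names = c("a", "b", "c"),
                       intercept_included = TRUE)
  m <- inst$model
  m$D <- matrix(0, 12, 3)
  hp <- scwarp_hyperparams(2, lambda_delta = 1, lambda_d = 0)
  expect_error(update_covariate_map(m, des, hp), "ridge")
})

test_that("reference update recovers the SVD subspace on noiseless rank-K data", {
  sim <- generate_dataset(genes = 40, k = 3, n_samples = 1,
                          cells_per_sample = 60, noise_sd = 0,
                          distortion_scale = 0, covariate_effect = 0, seed = 17)
  hp <- scwarp_hyperparams(3, lambda_b = 0, lambda_delta = 0, seed = 17)
  m <- initialize_latents(setup_model(sim$dataset, hp), sim$dataset, hp)
  # rotate Z away, then a single reference update must re-align the subspace
  set.seed(17)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  m$Z <- m$Z %*% R
  m$B <- t(R) %*% m$B
  m2 <- update_reference(m, sim$dataset, hp)
  Y <- as.matrix(sim$dataset$values)
  Yc <- Y - m$o - rep(m$s, each = 40)
  sv <- svd(Yc, nu = 3)
  expect_lt(max(principal_angles(m2$Z, sv$u)), 1e-6)
})

test_that("reference update with an identity prior ridge-shrinks the solve", {
  inst <- random_instance(genes = 10, k = 2, seed = 18)
  m <- inst$model
  m$A <- Matrix::Diagonal(10)
  m$W <- matrix(0, 10, 2)
  m$program_names <- paste0("p", 1:10)
  hp <- scwarp_hyperparams(2, lambda_w = 0.5)

  # unconstrained normal-equations solve computed independently
  Y <- inst$Y
  Cyb <- matrix(0, 10, 2); Cbb <- matrix(0, 2, 2)
  for (n in seq_len(ncol(Y))) {
    i <- m$sample_of_cell[n]
    r <- Y[, n] - m$o - m$s[n] - m$delta[[i]] %*% m$B[, n]
    Cyb <- Cyb + r %*% t(m$B[, n])
    Cbb <- Cbb + m$B[, n] %*% t(m$B[, n])
  }
  Zstar <- t(solve(Cbb, t(Cyb)))
  m2 <- update_reference(m, inst$data, hp)
  expect_lt(max(abs(m2$W - Zstar / 1.5)), 1e-10) # (I + 0.5 I)^-1 Z*
  expect_lt(max(abs(m2$Z - m2$W)), 1e-12)        # Z = A W with A = I
})

test_that("orthogonalization is an exact gauge transformation", {
  inst <- random_instance(genes = 10, k = 3, seed = 19)
  m <- inst$model

  # already orthonormal: Q = Z, B unchanged
  m1 <- orthogonalize_reference(m)
  expect_lt(max(abs(m1$Z - m$Z)), 1e-12)
  expect_lt(max(abs(m1$B - m$B)), 1e-12)

  # scaling Z by 2 moves the scale into B
  m2 <- m
  m2$Z <- 2 * m$Z
  m2 <- orthogonalize_reference(m2)
  expect_lt(max(abs(m2$Z - m$Z)), 1e-12)
  expect_lt(max(abs(m2$B - 2 * m$B)), 1e-12)

  # random Z: QR identity and orthonormality, reconstruction invariant
  m3 <- m
  set.seed(19)
  m3$Z <- matrix(rnorm(30), 10, 3)
  rec <- m3$Z %*% m3$B
  m3o <- orthogonalize_reference(m3)
  expect_lt(max(abs(crossprod(m3o$Z) - diag(3))), 1e-12)
  expect_lt(max(abs(m3o$Z %*% m3o$B - rec)), 1e-10)

  # rank-deficient axes are rejected with the collapsed factor named
  m4 <- m
  m4$Z[, 3] <- m4$Z[, 1]
  expect_error(orthogonalize_reference(m4), "rank-deficient")
})

test_that("offset update zeroes the per-gene mean residual", {
  inst <- random_instance(genes = 9, k = 2, seed = 20)
  m <- inst$model

  # no factor part, no cell offsets: gene offsets are row means
  m0 <- m
  m0$B[] <- 0; m0$s[] <- 0
  m0 <- update_offsets(m0, inst$data)
  expect_lt(max(abs(m0$o - rowMeans(inst$Y))), 1e-12)

  m2 <- update_offsets(m, inst$data)
  Y <- inst$Y
  Fmat <- matrix(0, nrow(Y), ncol(Y))
  for (n in seq_len(ncol(Y))) {
    i <- m2$sample_of_cell[n]
    Fmat[, n] <- (m2$Z + m2$delta[[i]]) %*% m2$B[, n]
  }
  resid <- Y - m2$o - rep(m2$s, each = nrow(Y)) - Fmat
  expect_lt(max(abs(colMeans(resid))), 1e-10)
  expect_lt(max(abs(rowMeans(m2$B))), 1e-12)
})

test_that("fitting converges with a non-increasing loss trajectory", {
  sim <- generate_dataset(genes = 60, k = 3, n_samples = 3,
                          cells_per_sample = 50, seed = 22)
  fit <- scwarp(sim$dataset, k = 3, design = sim$design, seed = 22)
  expect_true(fit$report$converged)
  expect_monotone_loss(fit$report)
  expect_lt(max(abs(crossprod(fit$model$Z) - diag(3))), 1e-8)
  expect_lt(max(abs(rowMeans(fit$model$B))), 1e-8)
})

test_that("tol = Inf stops after exactly one iteration", {
  sim <- generate_dataset(genes = 30, k = 2, n_samples = 2,
                          cells_per_sample = 20, seed = 23)
  fit <- scwarp(sim$dataset, k = 2, tol = Inf, seed = 23)
  expect_identical(fit$report$n_iter, 1L)
  expect_true(fit$report$converged)
})

test_that("noiseless data is fit to numerical zero", {
  sim <- generate_dataset(genes = 50, k = 3, n_samples = 2,
                          cells_per_sample = 40, noise_sd = 0,
                          distortion_scale = 0, covariate_effect = 0, seed = 24)
  fit <- scwarp(sim$dataset, k = 3, lambda_b = 1e-9, lambda_delta = 1e-9,
                lambda_d = 1e-9, seed = 24)
  tr <- fit$report$loss_trajectory
  expect_lt(tr[length(tr)], 1e-6 * tr[1])
})

test_that("results are invariant to worker count and sample processing order", {
  sim <- generate_dataset(genes = 50, k = 3, n_samples = 4,
                          cells_per_sample = 30, seed = 25)
  f1 <- scwarp(sim$dataset, k = 3, design = sim$design, seed = 25, n_workers = 1)
  f4 <- scwarp(sim$dataset, k = 3, design = sim$design, seed = 25, n_workers = 4)
  fp <- scwarp(sim$dataset, k = 3, design = sim$design, seed = 25,
               sample_order = c(3, 1, 4, 2))
  for (other in list(f4, fp)) {
    expect_lt(max(abs(f1$model$Z - other$model$Z)), 1e-10)
    expect_lt(max(abs(f1$model$B - other$model$B)), 1e-10)
    expect_lt(max(abs(f1$model$o - other$model$o)), 1e-10)
    for (i in 1:4) {
      expect_lt(max(abs(f1$model$delta[[i]] - other$model$delta[[i]])), 1e-10)
    }
  }
})

test_that("sparse and densified inputs give identical fits", {
  sim <- generate_dataset(genes = 40, k = 3, n_samples = 3,
                          cells_per_sample = 25, seed = 26)
  dense <- expression_dataset(as.matrix(sim$dataset$values),
                              gene_ids = sim$dataset$gene_ids,
                              cell_ids = sim$dataset$cell_ids,
                              sample_of_cell = sim$dataset$sample_of_cell,
                              sample_ids = sim$dataset$sample_ids,
                              values_are_counts = FALSE)
  fs <- scwarp(sim$dataset, k = 3, design = sim$design, seed = 26)
  fd <- scwarp(dense, k = 3, design = sim$design, seed = 26)
  expect_lt(max(abs(fs$model$Z - fd$model$Z)), 1e-10)
  expect_lt(max(abs(fs$model$B - fd$model$B)), 1e-10)
  expect_lt(max(abs(fs$model$s - fd$model$s)), 1e-10)
})

test_that("no update allocates a dense genes x all-cells array after setup", {
  sim <- generate_dataset(genes = 40, k = 3, n_samples = 4,
                          cells_per_sample = 20, seed = 27)
  old <- options(scwarp.track_alloc = TRUE)
  on.exit(options(old))
  scwarp:::reset_alloc_log()
  fit <- scwarp(sim$dataset, k = 3, design = sim$design, seed = 27)
  log <- scwarp:::alloc_log()
  expect_gt(length(log), 10)
  ncols <- vapply(log, function(e) e$ncol, 1L)
  expect_true(all(ncols <= 20L)) # per-sample scratch only
})
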