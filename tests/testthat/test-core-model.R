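test_that("reconstruct_cell handles degenerate parameter settings exactly", {
  inst <- random_instance(genes = 8, k = 3, seed = 2)
  m <- inst$model

  # zero embedding and zero cell offset: expectation is the gene offset
  m0 <- m
  m0$B[, 1] <- 0
  m0$s[1] <- 0
  expect_equal(unname(reconstruct_cell(m0, 1)), m0$o)

  # identity axes, everything else off: expectation is the embedding itself
  K <- ncol(m$Z)
  mi <- scwarp:::new_scwarp_model(
    Z = diag(K), delta = list(matrix(0, K, K)),
    B = matrix(rnorm(K * 2), K, 2), o = numeric(K), s = numeric(2),
    gene_ids = paste0("g", 1:K), cell_ids = paste0("c", 1:2),
    sample_ids = "s1", sample_of_cell = c(1L, 1L)
  )
  expect_equal(unname(reconstruct_cell(mi, 2)), unname(mi$B[, 2]))
})

test_that("reconstruct_cell matches an independent dense oracle", {
  inst <- random_instance(genes = 8, k = 3, seed = 3)
  m <- inst$model
  for (n in c(1, 5, ncol(m$B))) {
    i <- m$sample_of_cell[n]
    mu <- as.vector(m$o + m$s[n] + (m$Z + m$delta[[i]]) %*% m$B[, n])
    expect_lt(max(abs(reconstruct_cell(m, n) - mu)), 1e-12)
  }
})

test_that("reconstruct_cell reports the offending parameter on dimension mismatch", {
  inst <- random_instance(seed = 4)
  m <- inst$model
  m$o <- m$o[-1]
  expect_error(reconstruct_cell(m, 1), "'o'")
  m <- inst$model
  m$delta[[2]] <- m$delta[[2]][, -1, drop = FALSE]
  expect_error(reconstruct_cell(m, 1), "delta")
})

test_that("compute_loss is exact in closed-form corner cases", {
  inst <- random_instance(genes = 10, k = 2, noise_sd = 0, seed = 5)
  hp0 <- scwarp_hyperparams(2, lambda_b = 0, lambda_delta = 0, lambda_d = 0)

  # perfect reconstruction with all penalties zero
  expect_lt(compute_loss(inst$model, inst$data, hp0), 1e-18 * sum(inst$Y^2))

  # all parameters zero: loss is the sum of squared data
  zero <- inst$model
  zero$Z[] <- 0; zero$B[] <- 0; zero$o[] <- 0; zero$s[] <- 0
  for (i in seq_along(zero$delta)) zero$delta[[i]][] <- 0
  expect_equal(compute_loss(zero, inst$data, hp0), sum(inst$Y^2))
})

test_that("compute_loss matches a fully dense loop oracle", {
  for (seed in 1:5) {
    inst <- random_instance(genes = 9, k = 2, cells_per_sample = 6,
                            with_design = (seed %% 2 == 0), seed = seed)
    hp <- scwarp_hyperparams(2, lambda_b = 0.7, lambda_delta = 1.3,
                             lambda_d = 0.4)
    got <- compute_loss(inst$model, inst$data, hp, design = inst$design)
    want <- oracle_loss(inst$model, inst$data, hp, design = inst$design)
    expect_lt(abs(got - want) / abs(want), 1e-10)
  }
})

test_that("compute_loss rejects non-finite parameters by name", {
  inst <- random_instance(seed = 6)
  hp <- scwarp_hyperparams(3)
  bad <- inst$model
  bad$Z[2, 1] <- NaN
  expect_error(compute_loss(bad, inst$data, hp), "'Z'")
  bad <- inst$model
  bad$s[3] <- Inf
  expect_error(compute_loss(bad, inst$data, hp), "'s'")
})

test_that("compute_loss is invariant to gene and cell reordering", {
  inst <- random_instance(genes = 10, k = 3, cells_per_sample = 7, seed = 7)
  hp <- scwarp_hyperparams(3, lambda_b = 0.5, lambda_delta = 0.8)
  base <- compute_loss(inst$model, inst$data, hp)

  set.seed(11)
  pg <- sample(nrow(inst$Y))
  pc <- sample(ncol(inst$Y))
  m2 <- inst$model
  m2$Z <- m2$Z[pg, , drop = FALSE]
  m2$delta <- lapply(m2$delta, function(d) d[pg, , drop = FALSE])
  m2$o <- m2$o[pg]
  m2$B <- m2$B[, pc, drop = FALSE]
  m2$s <- m2$s[pc]
  m2$sample_of_cell <- m2$sample_of_cell[pc]
  m2$gene_ids <- m2$gene_ids[pg]
  m2$cell_ids <- m2$cell_ids[pc]
  data2 <- expression_dataset(inst$Y[pg, pc],
                              gene_ids = m2$gene_ids, cell_ids = m2$cell_ids,
                              sample_of_cell = m2$sample_of_cell,
                              sample_ids = inst$data$sample_ids,
                              values_are_counts = FALSE)
  expect_lt(abs(compute_loss(m2, data2, hp) - base) / abs(base), 1e-10)
})

test_that("batch-corrected expression excludes sample and cell terms", {
  inst <- random_instance(genes = 8, k = 2, seed = 8)
  m <- inst$model

  m$B[, 3] <- 0
  expect_equal(unname(batch_corrected_expression(m, 3)),
               matrix(0, nrow(m$Z), 1))

  # equal embeddings in different samples give identical corrected columns
  n1 <- 1L
  n2 <- which(m$sample_of_cell != m$sample_of_cell[n1])[1]
  m$B[, n2] <- m$B[, n1]
  corr <- batch_corrected_expression(m, c(n1, n2))
  expect_identical(unname(corr[, 1]), unname(corr[, 2]))

  # empty cell set: empty matrix, not an error
  empty <- batch_corrected_expression(m, integer(0))
  expect_identical(dim(empty), c(nrow(m$Z), 0L))

  with_o <- batch_corrected_expression(m, 5, include_offsets = TRUE)
  without <- batch_corrected_expression(m, 5)
  expect_equal(unname(with_o - without), matrix(m$o, ncol = 1))
})

test_that("sample_distortion matches closed forms and rejects foreign cells", {
  inst <- random_instance(genes = 8, k = 3, seed = 9)
  m <- inst$model

  m0 <- m
  m0$delta[[1]][] <- 0
  cells1 <- which(m$sample_of_cell == 1)
  expect_equal(unname(sample_distortion(m0, 1, cells1)),
               matrix(0, nrow(m$Z), length(cells1)))

  # rank-1 case: K = 1, distortion column u, embedding beta -> beta * u
  u <- rnorm(6)
  m1 <- scwarp:::new_scwarp_model(
    Z = matrix(rnorm(6), 6, 1), delta = list(matrix(u, 6, 1)),
    B = matrix(2.5, 1, 1), o = numeric(6), s = numeric(1),
    gene_ids = paste0("g", 1:6), cell_ids = "c1",
    sample_ids = "s1", sample_of_cell = 1L
  )
  expect_equal(unname(sample_distortion(m1, 1, 1)), matrix(2.5 * u, ncol = 1))

  # dense oracle
  got <- sample_distortion(m, 2)
  cells2 <- which(m$sample_of_cell == 2)
  want <- m$delta[[2]] %*% m$B[, cells2, drop = FALSE]
  expect_lt(max(abs(got - want)), 1e-12)

  foreign <- which(m$sample_of_cell == 1)[1]
  expect_error(sample_distortion(m, 2, foreign), m$cell_ids[foreign],
               fixed = TRUE)
})

test_that("reconstruction decomposes into corrected expression plus distortion", {
  inst <- random_instance(genes = 10, k = 3, seed = 10)
  m <- inst$model
  for (n in c(2, 9, 14)) {
    i <- m$sample_of_cell[n]
    lhs <- reconstruct_cell(m, n)
    rhs <- batch_corrected_expression(m, n, include_offsets = TRUE) +
      m$s[n] + sample_distortion(m, i, n)
    expect_lt(max(abs(lhs - rhs)), 1e-10)
  }
})

test_that("with no distortions and no penalties the optimum is the truncated SVD", {
  sim <- generate_dataset(genes = 50, k = 4, n_samples = 1,
                          cells_per_sample = 120, noise_sd = 0.2,
                          distortion_scale = 0, covariate_effect = 0, seed = 21)
  fit <- scwarp(sim$dataset, k = 4, lambda_b = 1e-9, lambda_delta = 1e-9,
                lambda_d = 1e-9, fit_distortions = FALSE,
                tol = 1e-12, max_iter = 200, seed = 21)
  m <- fit$model
  Y <- as.matrix(sim$dataset$values)
  Yc <- Y - m$o - rep(m$s, each = nrow(Y))
  sv <- svd(Yc)
  svd_rec <- sv$u[, 1:4] %*% (sv$d[1:4] * t(sv$v[, 1:4]))
  fit_rec <- m$Z %*% m$B
  expect_lt(norm(fit_rec - svd_rec, "F") / norm(svd_rec, "F"), 1e-6)
})
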