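## Block-coordinate descent. Every block update is the exact minimizer of the
## penalized least-squares objective over that block. Per-sample blocks
## (embeddings, distortions) are mutually independent and may run on forked
## workers; global blocks (covariate map, reference axes, offsets) reduce
## per-sample partial sums in ascending sample index regardless of worker
## count or processing order, so results are worker- and order-invariant.

#' Update cell embeddings
#'
#' For each sample `i` with warped axes `M_i = Z + DeltaZ_i` and each of its
#' cells, solves the ridge system
#' `b_n = (M_i' M_i + lambda_b I)^-1 M_i' (y_n - o - s_n 1)`.
#' The Gram matrix is formed once per sample.
#'
#' @inheritParams compute_loss
#' @return The model with `B` updated.
#' @export
update_cell_embeddings <- function(model, data, hp, sample_order = NULL) {
  model <- as_scwarp_model(model)
  idx_of <- cells_of_sample(data)
  K <- ncol(model$Z)
  parts <- sample_apply(data$n_samples, function(i) {
    idx <- idx_of[[i]]
    M <- model$Z + model$delta[[i]]
    Gm <- crossprod(M) + diag(hp$lambda_b, K)
    Y <- dense_block(data$values, idx)
    Rhs <- crossprod(M, Y - model$o - rep(model$s[idx], each = nrow(Y)))
    solve_gram(Gm, Rhs, context = "embedding system")
  }, n_workers = hp$n_workers, order = sample_order)
  for (i in seq_len(data$n_samples)) {
    model$B[, idx_of[[i]]] <- parts[[i]]
  }
  model
}

#' Update sample-specific axis distortions
#'
#' For each sample, with residuals `R_i = Y_i - o 1' - 1 s_i' - Z B_i`,
#' solves the ridge system
#' `DeltaZ_i = (R_i B_i' + lambda_delta D(x_i)) (B_i B_i' + lambda_delta I)^-1`,
#' shrinking each distortion toward its covariate prediction (toward zero
#' when no design is present), then projects onto the model's
#' distortion-identifiability gauge `Z' DeltaZ_i = 0`: distortions carry only
#' expression structure orthogonal to the reference axes. Without this gauge
#' the decomposition `Z b_n` versus `DeltaZ_i b_n` is degenerate — a shared
#' multiple of `Z` can migrate into every distortion while the embeddings
#' rescale — and batch-corrected values would not be identifiable. Because
#' the ridge Gram acts on the right of the solution, the projection yields
#' the exact minimizer of the penalized objective over the constraint set.
#' A sample with zero cells receives its (projected) prior mean.
#'
#' @inheritParams compute_loss
#' @return The model with `delta` updated.
#' @export
update_sample_distortions <- function(model, data, hp, design = NULL,
                                      sample_order = NULL) {
  model <- as_scwarp_model(model)
  idx_of <- cells_of_sample(data)
  K <- ncol(model$Z)
  Z <- model$Z
  parts <- sample_apply(data$n_samples, function(i) {
    idx <- idx_of[[i]]
    Dx <- if (is.null(design)) {
      matrix(0, nrow(Z), K)
    } else {
      covariate_distortion(model, design$X[i, ])
    }
    if (length(idx) == 0L) return(Dx - Z %*% crossprod(Z, Dx))
    Bi <- model$B[, idx, drop = FALSE]
    Y <- dense_block(data$values, idx)
    R <- Y - model$o - rep(model$s[idx], each = nrow(Y)) - Z %*% Bi
    Gm <- tcrossprod(Bi) + diag(hp$lambda_delta, K)
    sol <- t(solve_gram(Gm, t(R %*% t(Bi) + hp$lambda_delta * Dx),
                        context = "distortion system"))
    sol - Z %*% crossprod(Z, sol)
  }, n_workers = hp$n_workers, order = sample_order)
  model$delta <- parts
  model
}

#' Update the covariate map
#'
#' Solves, in one ridge regression across samples, for the map `D` that best
#' predicts the vectorized distortions from the sample covariates:
#' `argmin_D sum_i ||DeltaZ_i - D(x_i)||_F^2 + (lambda_d / lambda_delta) ||D||_F^2`.
#' This is a global, synchronized step.
#'
#' @inheritParams compute_loss
#' @return The model with `D` updated.
#' @export
update_covariate_map <- function(model, design, hp) {
  model <- as_scwarp_model(model)
  if (is.null(design)) stop("update_covariate_map requires a sample design")
  S <- nrow(design$X)
  P <- ncol(design$X)
  if (hp$lambda_delta == 0) {
    model$D <- matrix(0, nrow(model$D), ncol(model$D))
    return(model)
  }
  ridge <- hp$lambda_d / hp$lambda_delta
  if (S < P && ridge == 0) {
    stop("fewer samples than covariates with lambda_d = 0; use a ridge (lambda_d > 0)")
  }
  V <- do.call(rbind, lapply(seq_len(S), function(i) as.vector(model$delta[[i]])))
  Gm <- crossprod(design$X) + diag(ridge, P)
  coef <- solve_gram(Gm, crossprod(design$X, V), context = "covariate-map system")
  D <- t(coef) # (genes*K) x covariates
  dimnames(D) <- NULL
  model$D <- D
  model
}

#' Update the shared reference axes
#'
#' Updates `Z` from the global cross-moment
#' `C_yb = sum_n (y_n - o - s_n 1 - DeltaZ_i b_n) b_n'`, accumulating
#' per-sample partial sums in ascending sample index.
#'
#' Without a gene-program prior the update is the exact minimizer of the
#' objective over `Z` subject to the model's orthonormality gauge with `B`
#' held fixed — the orthogonal-Procrustes solution, i.e. the polar factor
#' `U V'` of the SVD `C_yb = U S V'`. Because the constrained subproblem is
#' solved exactly and no gauge transfer touches `B`, the objective can never
#' increase at this step, at any penalty weight.
#'
#' With a prior the axes are constrained to program space: the unconstrained
#' least-squares solve `Z* = C_yb (C_bb + eps I)^-1` (with
#' `C_bb = sum_n b_n b_n'`) is projected onto the prior,
#' `W = (A'A + lambda_w I)^-1 A' Z*`, `Z* <- A W`; callers then restore the
#' orthonormal gauge with [orthogonalize_reference()]. A near-singular
#' `C_bb` receives an epsilon-ridge of `1e-10 * trace` with a warning.
#'
#' @inheritParams compute_loss
#' @return The model with `Z` (and `W`, when present) updated.
#' @export
update_reference <- function(model, data, hp, sample_order = NULL) {
  model <- as_scwarp_model(model)
  idx_of <- cells_of_sample(data)
  K <- ncol(model$Z)
  parts <- sample_apply(data$n_samples, function(i) {
    idx <- idx_of[[i]]
    Bi <- model$B[, idx, drop = FALSE]
    Y <- dense_block(data$values, idx)
    R <- Y - model$o - rep(model$s[idx], each = nrow(Y)) - model$delta[[i]] %*% Bi
    list(Cyb = R %*% t(Bi), Cbb = tcrossprod(Bi))
  }, n_workers = hp$n_workers, order = sample_order)
  Cyb <- matrix(0, nrow(model$Z), K)
  Cbb <- matrix(0, K, K)
  for (i in seq_len(data$n_samples)) {
    Cyb <- Cyb + parts[[i]]$Cyb
    Cbb <- Cbb + parts[[i]]$Cbb
  }
  if (is.null(model$A)) {
    sv <- svd(Cyb, nu = K, nv = K)
    if (sv$d[K] <= sv$d[1] * 1e-12) {
      warning("cross-moment C_yb is near rank-deficient; reference axes under-determined")
    }
    model$Z <- sv$u %*% t(sv$v)
    return(model)
  }
  if (rcond(Cbb) < 1e-12) {
    warning("rank-deficient embedding Gram matrix; applying epsilon-ridge")
    Cbb <- Cbb + diag(1e-10 * sum(diag(Cbb)), K)
  }
  Zstar <- t(solve(Cbb, t(Cyb)))
  AtA <- as.matrix(crossprod(model$A))
  W <- solve_gram(AtA + diag(hp$lambda_w, ncol(AtA)),
                  as.matrix(crossprod(model$A, Zstar)),
                  context = "program-weight system")
  model$W <- W
  model$Z <- as.matrix(model$A %*% W)
  model
}

#' Re-orthonormalize the reference axes
#'
#' Thin QR factorization `Z = Q R` with the diagonal of `R` forced
#' non-negative; sets `Z <- Q` and `B <- R B`, leaving the reconstruction
#' `Z B` (and every distortion) unchanged. When program weights are present
#' they are carried along (`W <- W R^-1`) so `Z = A W` still holds.
#'
#' @param model A `scwarp_model` whose `Z` has full column rank.
#' @return The model in the orthonormal gauge.
#' @export
orthogonalize_reference <- function(model) {
  model <- as_scwarp_model(model)
  K <- ncol(model$Z)
  qrz <- qr(model$Z)
  Rm <- qr.R(qrz)
  small <- abs(diag(Rm)) <= max(abs(diag(Rm))) * 1e-12
  if (any(small)) {
    stop(sprintf("reference axes are rank-deficient: factor %d collapsed",
                 which(small)[1]))
  }
  Q <- qr.Q(qrz)
  d <- sign(diag(Rm))
  Q <- sweep(Q, 2, d, `*`)
  Rm <- d * Rm
  model$Z <- Q
  model$B <- Rm %*% model$B
  if (!is.null(model$W)) {
    # W <- W R^-1, i.e. solve t(R) t(W_new) = t(W)
    model$W <- t(backsolve(Rm, t(model$W), transpose = TRUE))
  }
  model
}

#' Update gene and cell offsets
#'
#' Sets the gene offsets to the per-gene mean residual (given current cell
#' offsets and factor reconstruction), then the cell offsets to the per-cell
#' mean residual, then absorbs the row means of `B` into the gene offsets
#' (`o <- o + Z b_bar`, `b_n <- b_n - b_bar`), maintaining the mean-centered
#' embedding convention.
#'
#' @inheritParams compute_loss
#' @return The model with `o`, `s` updated and `B` re-centered.
#' @export
update_offsets <- function(model, data, hp = NULL, sample_order = NULL) {
  model <- as_scwarp_model(model)
  idx_of <- cells_of_sample(data)
  G <- nrow(model$Z)
  N <- ncol(model$B)
  n_workers <- if (is.null(hp)) 1L else hp$n_workers

  parts <- sample_apply(data$n_samples, function(i) {
    idx <- idx_of[[i]]
    Y <- dense_block(data$values, idx)
    Fi <- (model$Z + model$delta[[i]]) %*% model$B[, idx, drop = FALSE]
    rowSums(Y - rep(model$s[idx], each = G) - Fi)
  }, n_workers = n_workers, order = sample_order)
  o <- numeric(G)
  for (i in seq_len(data$n_samples)) o <- o + parts[[i]]
  o <- o / N
  model$o <- o

  parts <- sample_apply(data$n_samples, function(i) {
    idx <- idx_of[[i]]
    Y <- dense_block(data$values, idx)
    Fi <- (model$Z + model$delta[[i]]) %*% model$B[, idx, drop = FALSE]
    colMeans(Y - o - Fi)
  }, n_workers = n_workers, order = sample_order)
  for (i in seq_len(data$n_samples)) model$s[idx_of[[i]]] <- parts[[i]]

  b_bar <- rowMeans(model$B)
  model$o <- model$o + drop(model$Z %*% b_bar)
  model$B <- model$B - b_bar
  model
}

#' Fit the model by block-coordinate descent
#'
#' Runs setup and initialization, then iterates the block updates
#' (embeddings, distortions, covariate map, reference axes + QR
#' re-orthogonalization, offsets) until the relative loss change drops below
#' `tol` or `max_iter` is reached. Raw counts are library-size normalized
#' (`log1p` of depth-scaled counts) before fitting; pre-normalized input is
#' used verbatim.
#'
#' @param data An [expression_dataset()].
#' @param k Number of latent factors.
#' @param design Optional [sample_design()] enabling covariate-linked
#'   distortions and DE vector fields.
#' @param prior Optional [gene_program_prior()] constraining the reference
#'   axes to gene-program combinations (enables [program_activities()]).
#' @param fit_distortions Logical; `FALSE` keeps all distortions fixed at
#'   zero (single-manifold fit).
#' @param sample_order Optional permutation of sample indices used for
#'   processing; never changes results (exposed for invariance testing).
#' @param verbose Logical; log per-iteration loss to the message stream.
#' @inheritParams scwarp_hyperparams
#' @return An object of class `scwarp_fit`: a list with elements `model`
#'   (the fitted [scwarp_model]) and `report` (loss trajectory, convergence
#'   flag, iteration count, hyperparameters, wall-clock seconds).
#' @export
#' @examples
#' sim <- generate_dataset(genes = 60, k = 3, n_samples = 2,
#'                         cells_per_sample = 80, seed = 1)
#' fit <- scwarp(sim$dataset, k = 3, design = sim$design, seed = 1)
#' fit$report$converged
scwarp <- function(data, k, design = NULL, prior = NULL,
                   lambda_b = 1, lambda_delta = 1, lambda_d = 1, lambda_w = 1,
                   max_iter = 100L, tol = 1e-6, seed = 1L, n_workers = 1L,
                   fit_distortions = TRUE, sample_order = NULL,
                   verbose = FALSE) {
  hp <- scwarp_hyperparams(k, lambda_b, lambda_delta, lambda_d, lambda_w,
                           max_iter, tol, seed, n_workers)
  t0 <- proc.time()[["elapsed"]]
  data <- normalize_dataset(data)
  model <- setup_model(data, hp, design = design, prior = prior)
  # loss of the allocated zero model (= sum of squared data): the baseline
  # every later iteration is measured against
  loss_setup <- compute_loss(model, data, hp, design = design,
                             sample_order = sample_order)
  model <- initialize_latents(model, data, hp)

  # Penalty weights are specified in units of the noise variance (Gaussian
  # priors in a MAP objective); convert once, against the initialization's
  # variance estimate, and optimize the resulting fixed quadratic objective.
  hp_eff <- hp
  for (nm in c("lambda_b", "lambda_delta", "lambda_d", "lambda_w")) {
    hp_eff[[nm]] <- hp[[nm]] * model$sigma_sq
  }

  loss_prev <- compute_loss(model, data, hp_eff, design = design,
                            sample_order = sample_order)
  trajectory <- c(loss_setup, loss_prev)
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(hp$max_iter)) {
    model <- update_cell_embeddings(model, data, hp_eff, sample_order = sample_order)
    if (fit_distortions) {
      model <- update_sample_distortions(model, data, hp_eff, design = design,
                                         sample_order = sample_order)
      if (!is.null(design)) model <- update_covariate_map(model, design, hp_eff)
    }
    model <- update_reference(model, data, hp_eff, sample_order = sample_order)
    model <- orthogonalize_reference(model)
    model <- update_offsets(model, data, hp_eff, sample_order = sample_order)
    loss <- compute_loss(model, data, hp_eff, design = design,
                         sample_order = sample_order)
    n_iter <- it
    trajectory <- c(trajectory, loss)
    if (!is.finite(loss)) {
      bad <- "objective"
      for (nm in c("B", "delta", "D", "Z", "W", "o", "s")) {
        ok <- tryCatch({ check_finite(model[[nm]], nm); TRUE },
                       error = function(e) FALSE)
        if (!ok) { bad <- nm; break }
      }
      stop(sprintf("non-finite loss at iteration %d (first offending block: %s)",
                   it, bad))
    }
    rel <- abs(loss - loss_prev) / abs(loss_prev)
    if (verbose) {
      message(sprintf("iter %3d  loss %.8e  rel-change %.3e", it, loss, rel))
    }
    loss_prev <- loss
    if (rel < hp$tol) {
      converged <- TRUE
      break
    }
  }
  report <- structure(
    list(loss_trajectory = trajectory, converged = converged, n_iter = n_iter,
         hyperparams = hp, hyperparams_effective = hp_eff,
         noise_variance = model$sigma_sq,
         wall_seconds = proc.time()[["elapsed"]] - t0),
    class = "scwarp_fit_report"
  )
  structure(list(model = model, report = report), class = "scwarp_fit")
}

#' @method print scwarp_fit
#' @export
print.scwarp_fit <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "scwarp fit: %s after %d iteration(s), final loss %.6g (%.2fs)\n",
    if (r$converged) "converged" else "max_iter reached",
    r$n_iter, r$loss_trajectory[length(r$loss_trajectory)], r$wall_seconds
  ))
  print(x$model)
  invisible(x)
}

#' @method print scwarp_fit_report
#' @export
print.scwarp_fit_report <- function(x, ...) {
  cat(sprintf("scwarp fit report: %d iteration(s), converged = %s\n",
              x$n_iter, x$converged))
  cat("loss trajectory: ",
      paste(signif(x$loss_trajectory, 6), collapse = " "), "\n")
  invisible(x)
}
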