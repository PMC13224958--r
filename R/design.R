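#' Construct a sample-level design
#'
#' Holds the samples x covariates matrix used to model sample-specific axis
#' distortions as functions of sample-level variables (e.g. disease status).
#'
#' @param X Numeric samples x covariates matrix (vectors are treated as a
#'   single covariate).
#' @param covariate_names Character vector naming the covariates (defaults to
#'   column names).
#' @param intercept_included Logical; set when `X` carries an intercept
#'   column. Constant columns are rejected unless this flag is set.
#' @return An object of class `sample_design`.
#' @export
sample_design <- function(X, covariate_names = colnames(X),
                          intercept_included = FALSE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("design matrix must not contain missing values")
  covariate_names <- as.character(
    covariate_names %||% paste0("covariate_", seq_len(ncol(X)))
  )
  if (length(covariate_names) != ncol(X)) {
    stop("'covariate_names' must name every design column")
  }
  constant <- apply(X, 2, function(col) diff(range(col)) == 0)
  if (any(constant) && !intercept_included) {
    stop(sprintf(
      "constant design column(s) %s; set intercept_included = TRUE if intended",
      paste(covariate_names[constant], collapse = ", ")
    ))
  }
  if (sum(constant) > 1) {
    stop("at most one constant (intercept) column is allowed")
  }
  colnames(X) <- covariate_names
  structure(
    list(X = X, covariate_names = covariate_names,
         intercept_included = isTRUE(intercept_included)),
    class = "sample_design"
  )
}

#' Construct a gene-program prior
#'
#' A genes x programs (optionally signed) membership matrix `A` expressing
#' the reference axes as combinations of known gene programs — pathways or
#' transcription-factor regulons. Entries may be signs in `{-1, 0, +1}` or
#' real weights.
#'
#' @param A Genes x programs matrix, sparse or dense.
#' @param program_names Character vector of program names (defaults to column
#'   names).
#' @param gene_ids Optional gene identifiers to attach as rownames.
#' @return An object of class `gene_program_prior`.
#' @export
gene_program_prior <- function(A, program_names = colnames(A), gene_ids = rownames(A)) {
  A <- as(as(Matrix(A, sparse = TRUE), "CsparseMatrix"), "generalMatrix")
  program_names <- as.character(
    program_names %||% paste0("program_", seq_len(ncol(A)))
  )
  if (length(program_names) != ncol(A)) {
    stop("'program_names' must name every program column")
  }
  nz <- diff(A@p)
  if (any(nz == 0L)) {
    stop(sprintf("program(s) with no member genes: %s",
                 paste(program_names[nz == 0L], collapse = ", ")))
  }
  if (!is.null(gene_ids)) rownames(A) <- gene_ids
  colnames(A) <- program_names
  structure(
    list(A = A, program_names = program_names),
    class = "gene_program_prior"
  )
}

#' Hyperparameters for model fitting
#'
#' The ridge weights are the precisions of Gaussian priors in the model's
#' MAP objective. [scwarp()] therefore interprets them in units of the
#' noise variance: the effective penalty entering the quadratic objective is
#' `lambda * sigma0^2`, with `sigma0^2` estimated once from the
#' initialization residual. The block-update functions and [compute_loss()]
#' use whatever weights their `hp` argument carries, verbatim.
#'
#' @param k Number of latent factors (reference axes).
#' @param lambda_b Ridge weight on cell embeddings (>= 0).
#' @param lambda_delta Ridge weight pulling each sample's distortion toward
#'   its covariate prediction (or toward zero with no design) (>= 0).
#' @param lambda_d Ridge weight on the covariate map (>= 0).
#' @param lambda_w Ridge weight on program weights, used when a gene-program
#'   prior is supplied (>= 0).
#' @param max_iter Maximum number of block-coordinate-descent iterations.
#' @param tol Convergence threshold on the relative loss change.
#' @param seed Integer seed driving the randomized initialization.
#' @param n_workers Number of forked workers for per-sample updates; affects
#'   wall time only, never results.
#' @return An object of class `scwarp_hyperparams`.
#' @export
scwarp_hyperparams <- function(k, lambda_b = 1, lambda_delta = 1, lambda_d = 1,
                               lambda_w = 1, max_iter = 100L, tol = 1e-6,
                               seed = 1L, n_workers = 1L) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L) stop("'k' must be an integer >= 1")
  for (nm in c("lambda_b", "lambda_delta", "lambda_d", "lambda_w")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop(sprintf("'%s' must be a single non-negative number", nm))
    }
  }
  if (!is.numeric(tol) || tol <= 0) stop("'tol' must be > 0")
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L) stop("'max_iter' must be >= 1")
  structure(
    list(k = k, lambda_b = lambda_b, lambda_delta = lambda_delta,
         lambda_d = lambda_d, lambda_w = lambda_w, max_iter = max_iter,
         tol = as.numeric(tol), seed = as.integer(seed),
         n_workers = as.integer(n_workers)),
    class = "scwarp_hyperparams"
  )
}
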