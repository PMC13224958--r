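`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` with the global RNG seeded at `seed`, restoring the caller's
# RNG state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## ---- allocation tracking hooks ---------------------------------------------
## Dense scratch blocks are routed through dense_block() / note_alloc() so that
## tests can assert the memory contract: after setup, no operation materializes
## a dense genes x total-cells array (per-sample residual blocks are permitted).
.alloc_env <- new.env(parent = emptyenv())
.alloc_env$log <- list()

reset_alloc_log <- function() {
  .alloc_env$log <- list()
  invisible(NULL)
}

alloc_log <- function() .alloc_env$log

note_alloc <- function(nrow, ncol, what) {
  if (isTRUE(getOption("scwarp.track_alloc", FALSE))) {
    .alloc_env$log[[length(.alloc_env$log) + 1L]] <-
      list(nrow = as.integer(nrow), ncol = as.integer(ncol), what = what)
  }
  invisible(NULL)
}

# Extract columns `cols` of a (possibly sparse) genes x cells matrix as a plain
# dense matrix. This is the only route by which expression values enter dense
# arithmetic; it guarantees identical floating-point behaviour for sparse and
# dense inputs and is the unit the allocation tracker records.
dense_block <- function(values, cols, what = "sample_block") {
  out <- as.matrix(values[, cols, drop = FALSE])
  dimnames(out) <- NULL
  note_alloc(nrow(out), ncol(out), what)
  out
}

## ---- small numerics --------------------------------------------------------

#' Principal angles between two subspaces
#'
#' Computes the principal angles (in radians) between the column spans of two
#' matrices, the standard rotation-invariant measure of subspace recovery.
#' Columns are orthonormalized internally, so the inputs need not be
#' orthonormal.
#'
#' @param u,v Matrices with the same number of rows.
#' @return Numeric vector of principal angles in radians, non-decreasing.
#' @export
#' @examples
#' q <- qr.Q(qr(matrix(rnorm(40), 10, 4)))
#' max(principal_angles(q, q)) < 1e-10
principal_angles <- function(u, v) {
  if (nrow(u) != nrow(v)) {
    stop("principal_angles: 'u' and 'v' must have the same number of rows")
  }
  qu <- qr.Q(qr(as.matrix(u)))
  qv <- qr.Q(qr(as.matrix(v)))
  d <- svd(crossprod(qu, qv), nu = 0, nv = 0)$d
  acos(pmin(1, pmax(-1, rev(sort(d)))))
}

# Ridge/pseudo-inverse linear solve used by block updates. Solves (G) X = B.
# When G is numerically singular and no ridge is active, falls back to the
# Moore-Penrose pseudo-inverse with a warning.
solve_gram <- function(G, B, context = "linear system") {
  out <- tryCatch(solve(G, B), error = function(e) NULL)
  if (is.null(out)) {
    warning(sprintf("singular %s; using pseudo-inverse fallback", context))
    s <- svd(G)
    pos <- s$d > max(s$d[1], 0) * 1e-12
    d_inv <- ifelse(pos, 1 / s$d, 0)
    out <- s$v %*% ((d_inv) * crossprod(s$u, B))
  }
  out
}

check_finite <- function(x, name) {
  if (is.null(x)) return(invisible(TRUE))
  flatten <- function(m) if (is(m, "Matrix")) m@x else as.numeric(m)
  v <- if (is.list(x)) unlist(lapply(x, flatten)) else flatten(x)
  if (!all(is.finite(v))) {
    stop(sprintf("non-finite entries in parameter '%s'", name), call. = FALSE)
  }
  invisible(TRUE)
}

# Map per-sample computations, optionally on forked workers. Results are
# always returned indexed by sample (ascending), so any subsequent reduction
# is independent of both the worker count and the processing order.
sample_apply <- function(n_samples, fun, n_workers = 1L, order = NULL) {
  ord <- order %||% seq_len(n_samples)
  if (length(ord) != n_samples || !setequal(ord, seq_len(n_samples))) {
    stop("'sample_order' must be a permutation of the sample indices")
  }
  raw <- if (n_workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(ord, fun, mc.cores = n_workers, mc.preschedule = TRUE)
  } else {
    lapply(ord, fun)
  }
  out <- vector("list", n_samples)
  out[ord] <- raw
  out
}
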