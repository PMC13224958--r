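## Model archive: a directory with one text array file per parameter block
## plus a JSON sidecar describing shapes, ids and the fit report. Array
## values are written as C99 hexadecimal floating-point literals, which
## round-trip IEEE doubles bitwise through strtod.

ARCHIVE_FORMAT_VERSION <- "1.0"

write_array <- function(x, path) {
  writeLines(sprintf("%a", as.numeric(x)), path)
}

read_array <- function(path, n_expected, what) {
  if (!file.exists(path)) {
    stop(sprintf("model archive is missing block file '%s'", basename(path)))
  }
  v <- as.numeric(read_lines_clean(path))
  if (length(v) != n_expected || anyNA(v)) {
    stop(sprintf(
      "model archive block '%s' is truncated or corrupt: %d values, expected %d",
      what, length(v), n_expected))
  }
  v
}

#' Write a fitted model archive
#'
#' Serializes every model block, the hyperparameters and the fit report to a
#' directory: one plain-text array file per block (column-major, hex-float
#' literals, bitwise exact) and a `meta.json` sidecar recording shapes,
#' identifiers and provenance. `read_model(write_model(fit))` reproduces the
#' model bitwise.
#'
#' @param fit A `scwarp_fit` (or bare `scwarp_model`).
#' @param path Directory to create/overwrite.
#' @return Invisibly, `path`.
#' @export
write_model <- function(fit, path) {
  model <- as_scwarp_model(fit)
  report <- if (inherits(fit, "scwarp_fit")) fit$report else NULL
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  G <- nrow(model$Z); K <- ncol(model$Z)
  S <- length(model$delta); N <- ncol(model$B)

  blocks <- list(Z = c(G, K), B = c(K, N), o = c(G, 1), s = c(N, 1))
  write_array(model$Z, file.path(path, "Z.txt"))
  write_array(model$B, file.path(path, "B.txt"))
  write_array(model$o, file.path(path, "o.txt"))
  write_array(model$s, file.path(path, "s.txt"))
  for (i in seq_len(S)) {
    nm <- sprintf("delta_%d", i)
    blocks[[nm]] <- c(G, K)
    write_array(model$delta[[i]], file.path(path, paste0(nm, ".txt")))
  }
  if (!is.null(model$D)) {
    blocks$D <- dim(model$D)
    write_array(model$D, file.path(path, "D.txt"))
  }
  if (!is.null(model$W)) {
    blocks$W <- dim(model$W)
    write_array(model$W, file.path(path, "W.txt"))
  }
  if (!is.null(model$A)) {
    A <- as(as(model$A, "CsparseMatrix"), "generalMatrix")
    blocks$A <- c(nrow(A), ncol(A))
    # sparse triplet: i, j as integers, x as hex floats
    trip <- Matrix::summary(A)
    writeLines(
      c(paste(nrow(A), ncol(A), nrow(trip)),
        sprintf("%d %d %a", trip$i, trip$j, trip$x)),
      file.path(path, "A.txt")
    )
  }
  meta <- list(
    format_version = ARCHIVE_FORMAT_VERSION,
    dims = list(genes = G, k = K, cells = N, samples = S),
    blocks = lapply(blocks, as.integer),
    dtype = "float64",
    gene_ids = model$gene_ids,
    cell_ids = model$cell_ids,
    sample_ids = model$sample_ids,
    sample_of_cell = model$sample_of_cell,
    covariate_names = model$covariate_names,
    program_names = model$program_names,
    sigma_sq = sprintf("%a", model$sigma_sq %||% 0)
  )
  if (!is.null(report)) {
    meta$report <- list(
      loss_trajectory = sprintf("%a", report$loss_trajectory),
      converged = report$converged,
      n_iter = report$n_iter,
      wall_seconds = report$wall_seconds,
      hyperparams = unclass(report$hyperparams)
    )
  }
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a model archive
#'
#' Restores a model (and fit report, when present) written by
#' [write_model()], bitwise.
#'
#' @param path Archive directory.
#' @return A `scwarp_fit` (with `report = NULL` when the archive was written
#'   from a bare model).
#' @export
read_model <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) {
    stop(sprintf("'%s' is not a model archive (missing meta.json)", path))
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$format_version, ARCHIVE_FORMAT_VERSION)) {
    stop(sprintf("model archive format version '%s' is not supported (reader version '%s')",
                 meta$format_version, ARCHIVE_FORMAT_VERSION))
  }
  G <- meta$dims$genes; K <- meta$dims$k
  N <- meta$dims$cells; S <- meta$dims$samples

  get_block <- function(nm) {
    d <- meta$blocks[[nm]]
    matrix(read_array(file.path(path, paste0(nm, ".txt")), prod(d), nm),
           d[1], d[2])
  }
  Z <- get_block("Z")
  B <- get_block("B")
  o <- drop(get_block("o"))
  s <- drop(get_block("s"))
  delta <- lapply(seq_len(S), function(i) get_block(sprintf("delta_%d", i)))
  D <- if ("D" %in% names(meta$blocks)) get_block("D") else NULL
  W <- if ("W" %in% names(meta$blocks)) get_block("W") else NULL
  A <- NULL
  if ("A" %in% names(meta$blocks)) {
    lines <- read_lines_clean(file.path(path, "A.txt"))
    hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
    trip <- strsplit(lines[-1], " ", fixed = TRUE)
    if (length(trip) != hdr[3]) {
      stop(sprintf("model archive block 'A' is truncated: %d entries, expected %d",
                   length(trip), hdr[3]))
    }
    A <- sparseMatrix(
      i = as.integer(vapply(trip, `[[`, "", 1L)),
      j = as.integer(vapply(trip, `[[`, "", 2L)),
      x = as.numeric(vapply(trip, `[[`, "", 3L)),
      dims = hdr[1:2]
    )
    rownames(A) <- meta$gene_ids
    colnames(A) <- meta$program_names
  }
  model <- new_scwarp_model(
    Z = Z, delta = delta, B = B, o = o, s = s, D = D, W = W, A = A,
    gene_ids = meta$gene_ids, cell_ids = meta$cell_ids,
    sample_ids = meta$sample_ids, sample_of_cell = meta$sample_of_cell,
    covariate_names = meta$covariate_names,
    program_names = meta$program_names
  )
  if (!is.null(meta$sigma_sq)) model$sigma_sq <- as.numeric(meta$sigma_sq)
  report <- NULL
  if (!is.null(meta$report)) {
    hp <- meta$report$hyperparams
    report <- structure(
      list(
        loss_trajectory = as.numeric(meta$report$loss_trajectory),
        converged = meta$report$converged,
        n_iter = meta$report$n_iter,
        hyperparams = scwarp_hyperparams(
          hp$k, hp$lambda_b, hp$lambda_delta, hp$lambda_d, hp$lambda_w,
          hp$max_iter, hp$tol, hp$seed, hp$n_workers),
        wall_seconds = meta$report$wall_seconds
      ),
      class = "scwarp_fit_report"
    )
  }
  structure(list(model = model, report = report), class = "scwarp_fit")
}
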