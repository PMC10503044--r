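#' Construct an omics tensor
#'
#' Bundles a 3-mode numeric array with identifier lists for each mode and an
#' optional sample design. The canonical layout is feature x replicate x
#' condition for single-omics data, or sample x sample x layer for Gram
#' tensors.
#'
#' @param values Numeric 3-mode array; all entries must be finite.
#' @param feature_ids Character vector of mode-1 identifiers (defaults to
#'   `f1..fN`).
#' @param mode2_ids Character vector of mode-2 identifiers (replicates or
#'   samples).
#' @param mode3_ids Character vector of mode-3 identifiers (conditions,
#'   tissues or omics layers).
#' @param design Optional [sample_design()] describing modes 2 and 3.
#' @return An object of class `omics_tensor`: a list with elements `values`,
#'   `feature_ids`, `mode2_ids`, `mode3_ids` and `design`.
#' @examples
#' x <- omics_tensor(array(rnorm(24), c(4, 3, 2)))
#' dim(x$values)
#' @export
omics_tensor <- function(values, feature_ids = NULL, mode2_ids = NULL,
                         mode3_ids = NULL, design = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-mode array")
  if (!all(is.finite(values)))
    stop("tensor contains non-finite values")
  d <- dim(values)
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(d[1]))
  if (is.null(mode2_ids))  mode2_ids  <- paste0("m2_", seq_len(d[2]))
  if (is.null(mode3_ids))  mode3_ids  <- paste0("m3_", seq_len(d[3]))
  if (length(feature_ids) != d[1] || length(mode2_ids) != d[2] ||
      length(mode3_ids) != d[3])
    stop("identifier lengths must match tensor dimensions")
  if (!is.null(design)) {
    stopifnot(inherits(design, "sample_design"))
    if (length(design$replicate_labels) != d[2] ||
        length(design$condition_levels) != d[3])
      stop("design does not match tensor mode-2/mode-3 dimensions")
  }
  dimnames(values) <- list(feature_ids, mode2_ids, mode3_ids)
  structure(
    list(values = values, feature_ids = as.character(feature_ids),
         mode2_ids = as.character(mode2_ids),
         mode3_ids = as.character(mode3_ids), design = design),
    class = "omics_tensor"
  )
}

#' @export
print.omics_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("omics_tensor: %d features x %d x %d\n", d[1], d[2], d[3]))
  invisible(x)
}

as_tensor_array <- function(x) {
  if (inherits(x, "omics_tensor")) x$values
  else if (is.array(x) && length(dim(x)) == 3L) x
  else stop("expected an omics_tensor or a 3-mode array")
}

#' Mode-n unfolding (matricization) of a 3-mode tensor
#'
#' Rearranges the tensor into a matrix whose rows are indexed by the chosen
#' mode. Column ordering convention, fixed package-wide: the remaining modes
#' vary with the lower-numbered remaining mode fastest, so
#' [fold_tensor()] is the exact inverse.
#'
#' @param tensor An `omics_tensor` or 3-mode array.
#' @param mode Integer 1, 2 or 3.
#' @return A matrix of shape `dim[mode]` x `prod(dim[-mode])`.
#' @seealso [fold_tensor()]
#' @export
unfold_tensor <- function(tensor, mode) {
  x <- as_tensor_array(tensor)
  if (!(length(mode) == 1L && mode %in% 1:3))
    stop("`mode` must be 1, 2 or 3")
  d <- dim(x)
  perm <- switch(mode, c(1L, 2L, 3L), c(2L, 1L, 3L), c(3L, 1L, 2L))
  xp <- aperm(x, perm)
  dim(xp) <- c(d[mode], prod(d[-mode]))
  xp
}

#' Fold a mode-n unfolding back into a 3-mode tensor
#'
#' Exact inverse of [unfold_tensor()] under the package's column-ordering
#' convention.
#'
#' @param mat Matrix produced by (or shaped like) a mode-`mode` unfolding.
#' @param mode Integer 1, 2 or 3.
#' @param dims Integer vector of length 3: the target tensor dimensions.
#' @return A 3-mode array of dimension `dims`.
#' @export
fold_tensor <- function(mat, mode, dims) {
  if (!(length(mode) == 1L && mode %in% 1:3))
    stop("`mode` must be 1, 2 or 3")
  dims <- as.integer(dims)
  if (length(dims) != 3L || nrow(mat) != dims[mode] ||
      ncol(mat) != prod(dims[-mode]))
    stop("matrix shape inconsistent with `dims` and `mode`")
  perm <- switch(mode, c(1L, 2L, 3L), c(2L, 1L, 3L), c(3L, 1L, 2L))
  arr <- array(mat, dims[perm])
  aperm(arr, order(perm))
}

# Mode-m product of a 3-mode array with a matrix (rows index the new mode).
ttm <- function(x, mat, mode) {
  d <- dim(x)
  d[mode] <- nrow(mat)
  fold_tensor(mat %*% unfold_tensor(x, mode), mode, d)
}

# Leading left singular vectors and singular values of A, with a Gram-matrix
# shortcut (eigen of the smaller crossproduct) when rows greatly outnumber
# columns. Falls back to svd() when the spectrum is degenerate near zero.
mode_svd <- function(A, rank) {
  m <- nrow(A)
  n <- ncol(A)
  if (m > 4L * n) {
    eg <- eigen(crossprod(A), symmetric = TRUE)
    dvals <- sqrt(pmax(eg$values, 0))
    tol <- max(dvals, 0) * 1e-8
    if (max(dvals) > 0 && all(dvals[seq_len(rank)] > tol)) {
      U <- A %*% eg$vectors[, seq_len(rank), drop = FALSE]
      U <- sweep(U, 2L, dvals[seq_len(rank)], "/")
      return(list(u = U, d = dvals[seq_len(rank)]))
    }
  }
  sv <- svd(A, nu = rank, nv = 0)
  list(u = sv$u, d = sv$d[seq_len(rank)])
}

# Flip each column so its largest-magnitude entry is positive (ties: first).
canonicalize_signs <- function(U) {
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  U
}

#' Higher-order singular value decomposition (Tucker via per-mode SVD)
#'
#' Computes the HOSVD of a 3-mode tensor: the mode-m factor matrix holds the
#' leading left singular vectors of the mode-m unfolding, ordered by
#' decreasing singular value, and the core tensor is the input contracted
#' with the transposed factors on every mode. Factor columns are
#' sign-canonicalized so that each column's largest-magnitude entry is
#' positive. Economy ranks `min(dim_m, prod(other dims))` are used by
#' default; when the feature mode is much longer than the product of the
#' other modes its factor is obtained through the Gram-matrix trick
#' (eigen-decomposition of the smaller-side crossproduct).
#'
#' @param tensor An `omics_tensor` or 3-mode array with finite entries.
#' @param ranks Optional integer vector `(R1, R2, R3)`; each must not exceed
#'   the economy bound for its mode.
#' @return An object of class `tucker_model`: list with `core` (R1 x R2 x R3
#'   array), `factors` (list of 3 matrices with orthonormal columns),
#'   `ranks`, `dims`, and `mode_sv` (per-mode singular values).
#' @examples
#' x <- array(rnorm(60), c(5, 4, 3))
#' fit <- hosvd(x)
#' max(abs(reconstruct(fit) - x)) < 1e-10
#' @export
hosvd <- function(tensor, ranks = NULL) {
  x <- as_tensor_array(tensor)
  if (!all(is.finite(x))) stop("tensor contains non-finite values")
  d <- dim(x)
  econ <- vapply(1:3, function(m) min(d[m], prod(d[-m])), numeric(1))
  if (is.null(ranks)) ranks <- econ
  ranks <- as.integer(ranks)
  if (length(ranks) != 3L || any(ranks < 1L))
    stop("`ranks` must be three positive integers")
  if (any(ranks > econ))
    stop(sprintf("rank (%s) exceeds economy bound (%s)",
                 paste(ranks, collapse = ","), paste(econ, collapse = ",")))
  factors <- vector("list", 3L)
  mode_sv <- vector("list", 3L)
  for (m in 1:3) {
    sv <- mode_svd(unfold_tensor(x, m), ranks[m])
    factors[[m]] <- canonicalize_signs(sv$u)
    mode_sv[[m]] <- sv$d
  }
  core <- x
  for (m in 1:3) core <- ttm(core, t(factors[[m]]), m)
  structure(
    list(core = core, factors = factors, ranks = ranks, dims = d,
         mode_sv = mode_sv),
    class = "tucker_model"
  )
}

#' @export
print.tucker_model <- function(x, ...) {
  cat(sprintf("tucker_model: dims (%s), ranks (%s)\n",
              paste(x$dims, collapse = " x "),
              paste(x$ranks, collapse = ", ")))
  invisible(x)
}

#' Reconstruct a tensor from its Tucker model
#'
#' Evaluates the Tucker sum: the core contracted with the factor matrix on
#' every mode. At full economy ranks this reproduces the decomposed tensor
#' to numerical precision; at truncated ranks it is the corresponding
#' low-multilinear-rank approximation.
#'
#' @param model A `tucker_model` from [hosvd()].
#' @return A 3-mode array of the model's original dimensions.
#' @export
reconstruct <- function(model) {
  stopifnot(inherits(model, "tucker_model"))
  rk <- dim(model$core)
  for (m in 1:3) {
    if (ncol(model$factors[[m]]) != rk[m])
      stop(sprintf("mode-%d factor has %d columns but core dimension is %d",
                   m, ncol(model$factors[[m]]), rk[m]))
  }
  x <- model$core
  for (m in 1:3) x <- ttm(x, model$factors[[m]], m)
  x
}

#' Save / load a Tucker model as a plain-text directory
#'
#' Writes the core tensor (one TSV per mode-3 slice), the three factor
#' matrices (TSV) and a JSON metadata file into `dir`. `load_tucker()`
#' restores the model.
#'
#' @param model A `tucker_model`.
#' @param dir Directory to create/write into.
#' @return `save_tucker()` returns `dir` invisibly; `load_tucker()` returns
#'   a `tucker_model`.
#' @export
save_tucker <- function(model, dir) {
  stopifnot(inherits(model, "tucker_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_len(dim(model$core)[3]))
    utils::write.table(model$core[, , k],
                       file.path(dir, sprintf("core_slice%03d.tsv", k)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  for (m in 1:3)
    utils::write.table(model$factors[[m]],
                       file.path(dir, sprintf("factor%d.tsv", m)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  meta <- list(ranks = model$ranks, dims = model$dims,
               mode_sv = model$mode_sv)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), digits = NA)
  invisible(dir)
}

#' @rdname save_tucker
#' @export
load_tucker <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  ranks <- as.integer(meta$ranks)
  core <- array(0, ranks)
  for (k in seq_len(ranks[3]))
    core[, , k] <- as.matrix(utils::read.table(
      file.path(dir, sprintf("core_slice%03d.tsv", k)), sep = "\t"))
  factors <- lapply(1:3, function(m)
    as.matrix(utils::read.table(file.path(dir, sprintf("factor%d.tsv", m)),
                                sep = "\t")))
  factors <- lapply(factors, function(f) {
    dimnames(f) <- NULL
    f
  })
  dimnames(core) <- NULL
  structure(
    list(core = core, factors = factors, ranks = ranks,
         dims = as.integer(meta$dims), mode_sv = meta$mode_sv),
    class = "tucker_model"
  )
}
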