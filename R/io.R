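#' Read a feature x sample matrix
#'
#' TSV/CSV files must have a header row of sample identifiers and feature
#' identifiers in the first column. MatrixMarket (`.mtx`) files are read
#' through the Matrix package with sidecar identifier files
#' `<path>.rows` and `<path>.cols` (one id per line). Duplicate
#' identifiers and non-numeric cells are rejected with the offending
#' coordinates; row order is preserved.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"tsv"`, `"csv"` or `"mtx"`.
#' @return Numeric matrix with feature ids as rownames and sample ids as
#'   colnames.
#' @export
read_matrix <- function(path, format = c("auto", "tsv", "csv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, tsv = "tsv", txt = "tsv", csv = "csv",
                     mtx = "mtx",
                     stop("cannot infer format from extension '.", ext,
                          "'; pass `format` explicitly"))
  }
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    rows <- readLines(paste0(path, ".rows"))
    cols <- readLines(paste0(path, ".cols"))
    if (length(rows) != nrow(m) || length(cols) != ncol(m))
      stop("sidecar id files do not match matrix dimensions")
    if (anyDuplicated(rows)) stop("duplicate feature ids in ", path, ".rows")
    if (anyDuplicated(cols)) stop("duplicate sample ids in ", path, ".cols")
    dimnames(m) <- list(rows, cols)
    return(m)
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2L) stop("matrix file needs an id column plus data columns")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate feature ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(colnames(df)[-1]))
    stop("duplicate sample ids in header")
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        stop(sprintf("non-numeric cell at row %d ('%s'), column '%s': '%s'",
                     bad[1], ids[bad[1]], colnames(vals)[j], col[bad[1]]))
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a matrix in a format [read_matrix()] can read back
#'
#' @param mat Numeric matrix with dimnames.
#' @param path Output file.
#' @param format `"auto"`, `"tsv"`, `"csv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path, format = c("auto", "tsv", "csv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", csv = "csv", mtx = "mtx", "tsv")
  if (is.null(rownames(mat))) rownames(mat) <- paste0("f", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(mat, sparse = TRUE), path)
    writeLines(rownames(mat), paste0(path, ".rows"))
    writeLines(colnames(mat), paste0(path, ".cols"))
    return(invisible(path))
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-design sheet
#'
#' A TSV/CSV with columns `sample_id`, `replicate`, `condition`; condition
#' ordering is taken from order of first appearance (list conditions in
#' their ordinal order).
#'
#' @param path Input file.
#' @return A data.frame with those three character columns.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  need <- c("sample_id", "replicate", "condition")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("design sheet is missing column(s): ", paste(miss, collapse = ", "))
  df[need] <- lapply(df[need], as.character)
  df
}

#' Assemble a 3-mode tensor from a matrix and a sample design
#'
#' Rearranges the columns of a feature x sample matrix into a feature x
#' replicate x condition array. The design must be balanced: every
#' (replicate, condition) pair occurs exactly once among the columns; gaps
#' or duplicates are reported explicitly (no imputation). Column order in
#' the matrix is irrelevant — samples are matched by id.
#'
#' @param mat Numeric matrix from [read_matrix()].
#' @param design Data.frame from [read_design()] (columns `sample_id`,
#'   `replicate`, `condition`), or a [sample_design()] plus matching column
#'   names.
#' @return An [omics_tensor()] carrying the implied [sample_design()].
#' @export
assemble_tensor <- function(mat, design) {
  stopifnot(is.matrix(mat))
  if (!is.data.frame(design))
    stop("`design` must be a data.frame with sample_id/replicate/condition")
  need <- c("sample_id", "replicate", "condition")
  if (!all(need %in% colnames(design)))
    stop("design needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample_id in design")
  missing_cols <- setdiff(design$sample_id, colnames(mat))
  if (length(missing_cols))
    stop("design samples absent from matrix: ",
         paste(missing_cols, collapse = ", "))
  reps <- unique(design$replicate)
  conds <- unique(design$condition)
  key <- paste(design$replicate, design$condition, sep = "\r")
  full <- as.vector(outer(reps, conds, paste, sep = "\r"))
  dup <- key[duplicated(key)]
  if (length(dup)) {
    pair <- strsplit(dup[1], "\r", fixed = TRUE)[[1]]
    stop(sprintf("duplicated (replicate, condition) cell: (%s, %s)",
                 pair[1], pair[2]))
  }
  gaps <- setdiff(full, key)
  if (length(gaps)) {
    pairs <- vapply(strsplit(gaps, "\r", fixed = TRUE),
                    function(p) sprintf("(%s, %s)", p[1], p[2]), character(1))
    stop("design is not a complete replicate x condition grid; missing: ",
         paste(pairs, collapse = ", "))
  }
  N <- nrow(mat)
  x <- array(NA_real_, c(N, length(reps), length(conds)))
  for (r in seq_along(reps)) {
    for (k in seq_along(conds)) {
      sid <- design$sample_id[design$replicate == reps[r] &
                                design$condition == conds[k]]
      x[, r, k] <- mat[, sid]
    }
  }
  dsn <- sample_design(reps, conds)
  omics_tensor(x,
               feature_ids = rownames(mat) %||% paste0("f", seq_len(N)),
               mode2_ids = reps, mode3_ids = conds, design = dsn)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a JSON run manifest
#'
#' Records everything needed to reproduce a run: the configuration echo,
#' chosen components, per-layer null SDs, package version and seed.
#'
#' @param manifest Named list.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  manifest$package_version <-
    as.character(utils::packageVersion("tensorfe"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
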