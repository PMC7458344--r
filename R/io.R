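#' Read a gene expression matrix from delimited text
#'
#' Reads a TPM (or log-scale) expression table with one header row and one
#' identifier column, and returns it in the canonical genes-in-rows
#' orientation as an [expression_matrix()].
#'
#' The field separator is taken from the file extension (`.csv` is
#' comma-separated, anything else tab-separated). Identifiers are treated
#' case-sensitively; duplicates are a hard error because downstream joins key
#' on them.
#'
#' @param path Path to a tab- or comma-separated text file.
#' @param orientation `"genes_in_rows"` (default) if rows are genes, or
#'   `"samples_in_rows"` if the file stores one sample per row; the latter is
#'   transposed on read.
#' @param transform Transform tag for the stored values: `"tpm"` (default),
#'   `"log2p1"` or `"normalized_log"`.
#' @return An `expression_matrix`: a numeric matrix, genes in rows, with a
#'   `transform` attribute.
#' @seealso [write_expression()], [log_transform()]
#' @export
read_expression <- function(path,
                            orientation = c("genes_in_rows", "samples_in_rows"),
                            transform = c("tpm", "log2p1", "normalized_log")) {
  orientation <- match.arg(orientation)
  transform <- match.arg(transform)
  raw <- read_delim_table(path)
  ids <- raw[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate identifiers in ", path, ": ", paste(dup, collapse = ", "))
  }
  mat <- parse_numeric_block(raw, path)
  rownames(mat) <- ids
  if (orientation == "samples_in_rows") mat <- t(mat)
  expression_matrix(mat, transform = transform)
}

#' Construct an expression matrix
#'
#' Wraps a numeric genes-in-rows matrix with a transform tag so that
#' log-transformation can refuse to run twice.
#'
#' @param mat Numeric matrix with unique row (gene) and column (sample) names.
#' @param transform One of `"tpm"`, `"log2p1"`, `"normalized_log"`.
#' @return The matrix with class `expression_matrix` and attribute
#'   `transform`.
#' @export
expression_matrix <- function(mat, transform = c("tpm", "log2p1", "normalized_log")) {
  transform <- match.arg(transform)
  if (!is.matrix(mat) || !is.numeric(mat)) stop("expression values must form a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("expression matrix needs gene row names and sample column names")
  }
  if (anyDuplicated(rownames(mat))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(mat))) stop("duplicate sample identifiers")
  if (transform == "tpm" && any(mat < 0, na.rm = TRUE)) {
    stop("TPM values must be non-negative")
  }
  structure(mat, transform = transform, class = c("expression_matrix", "matrix", "array"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s)\n",
              nrow(x), ncol(x), attr(x, "transform")))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 6L)), drop = FALSE], 5L))
  invisible(x)
}

#' Log-transform a TPM expression matrix
#'
#' Applies `log2(x + 1)` to a raw TPM matrix. A matrix already on log scale
#' is refused rather than silently transformed twice.
#'
#' @param expr An [expression_matrix()] with transform tag `"tpm"`.
#' @return An `expression_matrix` tagged `"log2p1"`.
#' @export
log_transform <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (!identical(attr(expr, "transform"), "tpm")) {
    stop("input is already on log scale (transform = ",
         attr(expr, "transform"), "); refusing to transform twice")
  }
  expression_matrix(log2(unclass(expr) + 1), transform = "log2p1")
}

#' Write an expression matrix to tab-separated text
#'
#' Values are written at full precision so read/write round-trips are exact.
#'
#' @param expr An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  write_matrix_tsv(unclass(expr), path, id_col = "gene")
}

#' Read a per-patient immunohistology table
#'
#' Expects a CSV (or TSV) with columns `patient`, `cd3`, `cd8`, `cd68`
#' (marker-positive cell densities per mm^2), `time` (survival, months) and
#' `event` (1/0 or TRUE/FALSE death indicator); `pathology` is optional.
#' Empty or `NA` density fields are read as missing, never coerced to zero.
#'
#' @param path Path to the table.
#' @return A data frame of class `ihc_table`, one row per patient.
#' @export
read_ihc <- function(path) {
  raw <- read_delim_table(path)
  names(raw) <- tolower(names(raw))
  need <- c("patient", "cd3", "cd8", "cd68", "time", "event")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop("IHC table ", path, " lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(patient = as.character(raw$patient), stringsAsFactors = FALSE)
  if (anyDuplicated(out$patient)) stop("duplicate patient identifiers in ", path)
  for (col in c("cd3", "cd8", "cd68", "time")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- !is.na(raw[[col]]) & raw[[col]] != "" & is.na(v)
    if (any(bad)) {
      stop("non-numeric ", col, " value at row ", which(bad)[1L], " of ", path)
    }
    if (any(v < 0, na.rm = TRUE)) {
      stop("negative ", col, " value at row ", which(v < 0)[1L], " of ", path)
    }
    out[[col]] <- v
  }
  ev <- raw$event
  ok <- ev %in% c("0", "1", 0, 1, TRUE, FALSE, "TRUE", "FALSE")
  if (!all(ok)) {
    stop("event value not codable as boolean at row ", which(!ok)[1L],
         " of ", path, " (got '", ev[!ok][1L], "')")
  }
  out$event <- as.logical(as.numeric(ev %in% c("1", 1, TRUE, "TRUE")))
  if (any(is.na(out$time))) stop("missing survival time in ", path)
  out$pathology <- if ("pathology" %in% names(raw)) as.character(raw$pathology) else NA_character_
  class(out) <- c("ihc_table", "data.frame")
  out
}

#' Write an IHC table to CSV
#' @param ihc An `ihc_table` (see [read_ihc()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ihc <- function(ihc, path) {
  df <- as.data.frame(ihc)
  df$event <- as.integer(df$event)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA", eol = "\n")
  invisible(path)
}

#' Read a deconvolution score table
#'
#' Reads a cell type x sample score matrix as produced by bulk deconvolution
#' tools. The orientation is auto-detected when `samples` is given (whichever
#' axis matches the supplied sample identifiers becomes columns); otherwise
#' rows are assumed to be cell types. Trailing diagnostic columns that
#' deconvolution tools commonly append (p-value, correlation, RMSE and
#' friends) are dropped by a name allowlist, with a message.
#'
#' @param path Path to a tab- or comma-separated score table.
#' @param method Free-text method tag (e.g. `"cibersort-like"`).
#' @param semantics Score semantics: `"fraction"` (must lie in \[0,1\]),
#'   `"enrichment"` or `"arbitrary"`.
#' @param samples Optional character vector of sample identifiers used to
#'   auto-detect orientation.
#' @return A `deconvolution_result`: numeric matrix, cell types in rows, with
#'   `method` and `semantics` attributes.
#' @export
read_deconvolution <- function(path, method,
                               semantics = c("fraction", "enrichment", "arbitrary"),
                               samples = NULL) {
  semantics <- match.arg(semantics)
  raw <- read_delim_table(path)
  ids <- raw[[1L]]
  diagnostic <- c("P-value", "Correlation", "RMSE", "Pearson Correlation",
                  "Absolute score", "Absolute score (sig.score)", "RMSE (Pearson)")
  drop_col <- names(raw)[-1L] %in% diagnostic
  if (any(drop_col)) {
    message("dropping diagnostic columns: ",
            paste(names(raw)[-1L][drop_col], collapse = ", "))
    raw <- raw[, c(TRUE, !drop_col), drop = FALSE]
  }
  drop_row <- ids %in% diagnostic
  if (any(drop_row)) {
    message("dropping diagnostic rows: ", paste(ids[drop_row], collapse = ", "))
    raw <- raw[!drop_row, , drop = FALSE]
    ids <- ids[!drop_row]
  }
  mat <- parse_numeric_block(raw, path)
  rownames(mat) <- ids
  if (!is.null(samples)) {
    row_hits <- sum(rownames(mat) %in% samples)
    col_hits <- sum(colnames(mat) %in% samples)
    if (row_hits > col_hits) mat <- t(mat)
  }
  deconvolution_result(mat, method = method, semantics = semantics)
}

#' Construct a deconvolution result
#'
#' @param mat Numeric matrix, cell types in rows, samples in columns.
#' @param method Free-text method tag.
#' @param semantics One of `"fraction"`, `"enrichment"`, `"arbitrary"`.
#' @return A `deconvolution_result` object.
#' @export
deconvolution_result <- function(mat, method,
                                 semantics = c("fraction", "enrichment", "arbitrary")) {
  semantics <- match.arg(semantics)
  if (!is.matrix(mat) || !is.numeric(mat)) stop("scores must form a numeric matrix")
  if (is.null(rownames(mat))) stop("cell-type row names required")
  if (anyDuplicated(rownames(mat))) stop("duplicate cell-type names")
  if (semantics == "fraction") {
    bad <- which(mat < 0 | mat > 1, arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stop(sprintf("fraction semantics violated at [%s, %s]: value %g",
                   rownames(mat)[bad[1L, 1L]],
                   colnames(mat)[bad[1L, 2L]],
                   mat[bad[1L, , drop = FALSE]]))
    }
  }
  structure(mat, method = method, semantics = semantics,
            class = c("deconvolution_result", "matrix", "array"))
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat(sprintf("deconvolution_result (%s, %s): %d cell types x %d samples\n",
              attr(x, "method"), attr(x, "semantics"), nrow(x), ncol(x)))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 6L)), drop = FALSE], 5L))
  invisible(x)
}

#' Write a deconvolution result to tab-separated text
#' @param decon A `deconvolution_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deconvolution <- function(decon, path) {
  write_matrix_tsv(unclass(decon), path, id_col = "cell_type")
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene1<TAB>...`.
#' Descriptions are discarded and genes de-duplicated within a set.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (a gene-set collection).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nms <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nms)) {
    stop("duplicate gene-set name in ", path, ": ", nms[duplicated(nms)][1L])
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- nms
  empty <- lengths(sets) == 0L
  if (any(empty)) stop("empty gene set in ", path, ": ", nms[empty][1L])
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

## shared low-level helpers ----------------------------------------------

read_delim_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (ncol(df) < 2L) stop("no data columns found in ", path)
  df
}

# columns 2..n of a read_delim_table() result as a numeric matrix; non-numeric
# cells are a hard error with coordinates (1-based data rows)
parse_numeric_block <- function(raw, path) {
  block <- raw[, -1L, drop = FALSE]
  mat <- matrix(NA_real_, nrow(block), ncol(block),
                dimnames = list(NULL, names(block)))
  for (j in seq_len(ncol(block))) {
    v <- block[[j]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & v != "NA" & is.na(num))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric value '%s' at row %d, column '%s' of %s",
                   v[bad[1L]], bad[1L], names(block)[j], path))
    }
    mat[, j] <- num
  }
  mat
}

write_matrix_tsv <- function(mat, path, id_col) {
  con <- file(path, open = "wb")  # binary: force LF endings everywhere
  on.exit(close(con))
  header <- paste(c(id_col, colnames(mat)), collapse = "\t")
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i],
            formatC(mat[i, ], format = "g", digits = 17)), collapse = "\t")
  }, "")
  writeLines(c(header, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
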