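# Reading and writing delimited expression matrices and the packaged
# worked-example fixture.

#' Read a delimited gene-expression matrix
#'
#' Expects a rectangular table with a header row of condition identifiers
#' and gene identifiers in the first column. Lines starting with `#` are
#' treated as comments. Rows containing missing or non-numeric cells are
#' dropped with a logged count (the similarity measures require complete
#' profiles); duplicate gene identifiers and ragged rows are errors, the
#' latter naming the offending line.
#'
#' @param path Path to the file.
#' @param delimiter Field separator, tab by default (use `","` for CSV).
#' @return A numeric genes x conditions matrix with gene identifiers as
#'   rownames and condition identifiers as colnames.
#' @export
read_expression_matrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 2L)
    stop(sprintf("parse error in %s: need a header row and at least one gene row", path),
         call. = FALSE)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  header <- fields[[1L]]
  body <- fields[-1L]
  m <- length(body[[1L]]) - 1L
  if (m < 2L)
    stop(sprintf("parse error in %s: need at least 2 condition columns", path),
         call. = FALSE)
  ragged <- which(lengths(body) != m + 1L)
  if (length(ragged))
    stop(sprintf("parse error at line %d of %s: expected %d fields, found %d",
                 lineno[ragged[1L] + 1L], path, m + 1L,
                 lengths(body)[ragged[1L]]), call. = FALSE)
  condition_ids <- if (length(header) == m + 1L) header[-1L] else header
  if (length(condition_ids) != m)
    stop(sprintf("parse error in %s: header has %d fields for %d data columns",
                 path, length(header), m + 1L), call. = FALSE)
  ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate gene identifier '%s' in %s",
                 ids[anyDuplicated(ids)], path), call. = FALSE)
  vals <- suppressWarnings(
    t(vapply(body, function(r) as.numeric(r[-1L]), numeric(m)))
  )
  ok <- apply(is.finite(vals), 1L, all)
  if (any(!ok))
    message(sprintf("read_expression_matrix: dropped %d gene row(s) with missing or non-numeric values",
                    sum(!ok)))
  vals <- vals[ok, , drop = FALSE]
  if (nrow(vals) < 2L)
    stop(sprintf("parse error in %s: fewer than 2 usable gene rows", path),
         call. = FALSE)
  dimnames(vals) <- list(ids[ok], condition_ids)
  vals
}

#' Write a gene-expression matrix to a delimited text file
#'
#' Numbers are written with `%.17g` so that a write-then-read round trip
#' reproduces the matrix exactly.
#'
#' @param mat Numeric matrix with gene identifiers as rownames.
#' @param path Output path.
#' @param delimiter Field separator (tab by default).
#' @param header_comment Optional comment line (written prefixed with `#`).
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(mat, path, delimiter = "\t",
                                    header_comment = NULL) {
  mat <- check_expression_matrix(mat)
  if (is.null(colnames(mat))) colnames(mat) <- paste0("c", seq_len(ncol(mat)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  writeLines(paste(c("gene_id", colnames(mat)), collapse = delimiter), con)
  body <- vapply(seq_len(nrow(mat)), function(i)
    paste(c(rownames(mat)[i], sprintf("%.17g", mat[i, ])), collapse = delimiter),
    character(1))
  writeLines(body, con)
  invisible(path)
}

#' The packaged worked-example pattern family
#'
#' Nine expression patterns over nine conditions: a reference pattern `a`,
#' its purely shifted copy `b1` (= a + 6), the shifted anti-correlated
#' pattern `b8` (= 17 - a), and the six uniformly interpolated intermediate
#' patterns `b2`..`b7` between `b1` and `b8` (printed to 4 decimal places).
#' This family illustrates how NMRS decays from 1 to 0 across the
#' interpolation while Pearson stays at |1| throughout.
#'
#' @return A 9 x 9 numeric matrix (genes `a`, `b1`..`b8`).
#' @export
pattern_family <- function() {
  path <- system.file("extdata", "pattern_family.tsv", package = "modminer",
                      mustWork = TRUE)
  read_expression_matrix(path)
}
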