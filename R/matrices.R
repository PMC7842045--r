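## Matrix containers and TSV / GEO series-matrix I/O.
##
## Methylation matrices are probe x sample numeric matrices of beta-values in
## [0, 1] (NA allowed); expression matrices are gene x sample numeric matrices
## on a log scale (log2(FPKM + 1) or similar), no missing values. Both are
## carried as base matrices with dimnames, the standard container for array
## data in this field.

# Tokens accepted as missing in methylation input (XENA and GEO exports).
NA_TOKENS <- c("NA", "NaN", "null", "")

validate_methylation_matrix <- function(beta) {
  stopifnot(is.matrix(beta), is.numeric(beta))
  if ((nrow(beta) > 0L && is.null(rownames(beta))) ||
      (ncol(beta) > 0L && is.null(colnames(beta))))
    stop("methylation matrix needs probe rownames and sample colnames")
  if (anyDuplicated(rownames(beta))) stop("duplicate probe IDs")
  if (anyDuplicated(colnames(beta))) stop("duplicate sample IDs")
  v <- beta[!is.na(beta)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    stop("beta-values outside [0, 1]")
  invisible(beta)
}

validate_expression_matrix <- function(expr) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if ((nrow(expr) > 0L && is.null(rownames(expr))) ||
      (ncol(expr) > 0L && is.null(colnames(expr))))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(expr))) stop("duplicate gene IDs")
  if (anyDuplicated(colnames(expr))) stop("duplicate sample IDs")
  if (any(!is.finite(expr)))
    stop("expression matrix contains missing or non-finite values")
  invisible(expr)
}

#' Read a methylation or expression matrix from TSV
#'
#' Reads a tab-separated table with row identifiers (Illumina cg probe IDs or
#' gene symbols) in the first column and sample IDs in the header. For
#' methylation input the GEO series-matrix dialect is also accepted: leading
#' `!`-prefixed annotation lines with the beta-value table enclosed between
#' `!series_matrix_table_begin` and `!series_matrix_table_end` markers.
#'
#' Missing-value tokens (`NA`, `NaN`, `null`, empty cell) become `NA` in a
#' methylation matrix and raise an error in an expression matrix, which must
#' be complete after loading. Beta-values outside `[0, 1]`, duplicated row or
#' column IDs, and non-numeric cells outside the token set are errors.
#'
#' @param path Path to the TSV (or series-matrix) file.
#' @param kind `"methylation"` or `"expression"`.
#' @return A numeric matrix, rows = probes or genes, columns = samples, in
#'   file order.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("id\ts1\ts2", "cg01\t0.1\t0.9", "cg02\tNA\t0.5"), tf)
#' read_matrix(tf, "methylation")
#' @export
read_matrix <- function(path, kind = c("methylation", "expression")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) && startsWith(first, "!")) {
    lines <- readLines(path)
    begin <- grep("table_begin", lines, ignore.case = TRUE)
    end <- grep("table_end", lines, ignore.case = TRUE)
    if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L)
      stop("malformed series-matrix file: table markers not found in ", path)
    dt <- data.table::fread(
      text = lines[(begin + 1L):(end - 1L)], sep = "\t", header = TRUE,
      colClasses = "character", na.strings = NULL, quote = "\""
    )
  } else {
    dt <- data.table::fread(
      path, sep = "\t", header = TRUE,
      colClasses = "character", na.strings = NULL, quote = "\""
    )
  }
  if (ncol(dt) < 1L) stop("empty table in ", path)
  row_ids <- gsub('^"|"$', "", dt[[1L]])
  sample_ids <- gsub('^"|"$', "", colnames(dt)[-1L])
  if (anyDuplicated(row_ids)) stop("duplicate row IDs in ", path)
  if (anyDuplicated(sample_ids)) stop("duplicate sample (column) IDs in ", path)

  raw <- as.matrix(dt[, -1L, with = FALSE])
  is_tok <- array(raw %in% NA_TOKENS, dim = dim(raw))
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- is.na(vals) & !is_tok
  if (any(bad)) {
    stop("non-numeric cell(s) outside the NA token set, e.g. ",
         dQuote(raw[which(bad)[1L]]), " in ", path)
  }
  vals[is_tok] <- NA_real_
  dimnames(vals) <- list(row_ids, sample_ids)

  if (kind == "methylation") {
    validate_methylation_matrix(vals)
  } else {
    if (anyNA(vals)) stop("expression matrix contains missing values: ", path)
    validate_expression_matrix(vals)
  }
  vals
}

# Serialize a numeric matrix as TSV with 17 significant digits so values
# round-trip bit-stably through decimal text.
write_matrix_tsv <- function(mat, path, id_col) {
  ch <- matrix(sprintf("%.17g", mat), nrow = nrow(mat), ncol = ncol(mat))
  ch[is.na(mat)] <- "NA"
  df <- data.frame(rownames(mat) %||% character(), ch,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(mat))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Write an expression matrix to TSV
#'
#' Genes as rows, samples as columns; values serialized with 17 significant
#' digits so `read_matrix()` reproduces them exactly.
#'
#' @param expr Gene x sample numeric matrix.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  write_matrix_tsv(expr, path, id_col = "gene_id")
}

#' Write a methylation beta-value matrix to TSV
#'
#' Probes as rows, samples as columns; missing beta-values written as `NA`.
#'
#' @param beta Probe x sample numeric matrix of beta-values.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_methylation_matrix <- function(beta, path) {
  validate_methylation_matrix(beta)
  write_matrix_tsv(beta, path, id_col = "probe_id")
}
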