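#' Read a delimited feature table
#'
#' Reads a CSV/TSV file with a header row into a numeric matrix. The
#' delimiter is sniffed from the header line (tab, comma, or semicolon)
#' unless given. A leading non-numeric ID column becomes row names. Omics
#' tables stored features-as-rows load with `transpose = TRUE`. Duplicate
#' feature names, ragged rows, and non-numeric cells are errors naming the
#' offender.
#'
#' @param path file path.
#' @param sep field delimiter, or `NULL` to sniff.
#' @param transpose set `TRUE` when the file stores features as rows.
#' @return numeric matrix, samples as rows.
#' @export
read_feature_table <- function(path, sep = NULL, transpose = FALSE) {
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) ","
           else if (grepl(";", header)) ";" else
             stop("could not sniff delimiter in ", path, call. = FALSE)
  }
  nf <- utils::count.fields(path, sep = sep)
  if (length(unique(nf[-1L])) > 1L) {
    bad <- which(nf[-1L] != nf[2L])[1L] + 1L
    stop(sprintf("ragged row: line %d has %d fields, expected %d",
                 bad, nf[bad], nf[2L]), call. = FALSE)
  }
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE, fill = FALSE)
  rn <- NULL
  if (ncol(df) > 1L && !is.numeric(df[[1L]]) &&
      !any(duplicated(df[[1L]]))) {
    rn <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  bad <- names(df)[!vapply(df, is.numeric, TRUE)]
  if (length(bad)) {
    stop("non-numeric values in column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dup <- names(df)[duplicated(names(df))]
  if (length(dup)) {
    stop("duplicate feature names: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(df)
  if (!is.null(rn)) rownames(X) <- rn
  if (transpose) X <- t(X)
  X
}

#' Write a feature table or result table
#'
#' Writes a matrix or data frame as delimited text with a header row;
#' matrices with row names gain a leading ID column so that
#' [read_feature_table()] round-trips them.
#'
#' @param x matrix or data frame.
#' @param path output path.
#' @param sep delimiter (default tab).
#' @export
write_feature_table <- function(x, path, sep = "\t") {
  if (is.matrix(x) && !is.null(rownames(x))) {
    df <- data.frame(id = rownames(x), x, check.names = FALSE)
  } else {
    df <- as.data.frame(x)
  }
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
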