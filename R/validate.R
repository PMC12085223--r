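#' Validate a feature matrix
#'
#' Checks an `n x p` numeric predictor matrix: finite entries, at least 10
#' samples, unique feature names. Column names are assigned (`X1..Xp`) when
#' absent so that every downstream result can refer to features by name.
#'
#' @param X numeric matrix or data frame, samples as rows.
#' @param min_n minimum number of samples required.
#' @return the validated numeric matrix with unique column names.
#' @export
validate_features <- function(X, min_n = 10L) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("'X' must be a numeric matrix (samples x features)", call. = FALSE)
  }
  if (anyNA(X) || any(!is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1L, ]
    stop(sprintf("'X' contains missing or non-finite values (first at row %d, column %d)",
                 bad[1L], bad[2L]), call. = FALSE)
  }
  if (nrow(X) < min_n) stop(sprintf("need at least %d samples, got %d", min_n, nrow(X)), call. = FALSE)
  if (ncol(X) < 1L) stop("'X' must have at least one feature", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  dup <- colnames(X)[duplicated(colnames(X))]
  if (length(dup)) {
    stop("duplicate feature names: ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  X
}

#' Classify an outcome vector as continuous or binary
#'
#' @param y numeric outcome vector.
#' @return `"binary"` when all values are in \{0, 1\} with both classes
#'   present, otherwise `"continuous"`.
#' @export
outcome_kind <- function(y) {
  u <- unique(y)
  if (all(u %in% c(0, 1)) && length(u) == 2L) "binary" else "continuous"
}

validate_outcome <- function(y, n, kind = NULL) {
  if (!is.numeric(y)) stop("'y' must be numeric", call. = FALSE)
  if (anyNA(y) || any(!is.finite(y))) stop("'y' contains missing or non-finite values", call. = FALSE)
  if (length(y) != n) {
    stop(sprintf("outcome length (%d) does not match number of samples (%d)", length(y), n),
         call. = FALSE)
  }
  kind <- kind %||% outcome_kind(y)
  kind <- match.arg(kind, c("continuous", "binary"))
  if (kind == "binary") {
    if (!all(y %in% c(0, 1))) stop("binary outcome must be coded 0/1", call. = FALSE)
    if (length(unique(y)) < 2L) stop("binary outcome must contain both classes", call. = FALSE)
  }
  kind
}

`%||%` <- function(a, b) if (is.null(a)) b else a
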