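#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Column-wise Euclidean norms of a matrix.
col_norms <- function(M) sqrt(colSums(M^2))

## Scale every column of M to unit Euclidean norm (zero columns left as-is).
normalize_columns <- function(M) {
  nrm <- col_norms(M)
  nrm[nrm == 0] <- 1
  sweep(M, 2, nrm, "/")
}

## Check that `x` is a single positive integer-valued number.
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop(sprintf("`%s` must be a single integer >= %d (got %s)",
                 name, min, paste(format(x), collapse = ", ")), call. = FALSE)
  }
  as.integer(x)
}

check_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop(sprintf("`%s` contains non-finite entries", name), call. = FALSE)
  }
  x
}

## Labels are integer class ids 0..C-1 (the convention used throughout).
check_labels <- function(labels, n_classes = NULL, name = "labels") {
  if (any(!is.finite(labels)) || any(labels != round(labels))) {
    stop(sprintf("`%s` must be integer class ids", name), call. = FALSE)
  }
  labels <- as.integer(labels)
  if (!is.null(n_classes) && (any(labels < 0L) || any(labels >= n_classes))) {
    stop(sprintf("`%s` must lie in 0..%d", name, n_classes - 1L), call. = FALSE)
  }
  labels
}

## One-hot label matrix P (C x N), p[c+1, i] = 1 iff sample i has class c.
one_hot <- function(labels, n_classes) {
  labels <- check_labels(labels, n_classes)
  P <- matrix(0, n_classes, length(labels))
  P[cbind(labels + 1L, seq_along(labels))] <- 1
  P
}
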