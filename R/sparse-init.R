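#' Orthogonal matching pursuit
#'
#' Greedy sparse coding of a single vector on a unit-column dictionary: at each
#' step the atom with maximal absolute correlation with the current residual is
#' selected (ties broken toward the lowest atom index) and the coefficients are
#' re-solved by least squares on the selected support. Selection stops after
#' `T` atoms or when the residual norm drops to `tol`.
#'
#' @param D `d x K` dictionary whose columns have unit Euclidean norm
#'   (checked to `1e-8`).
#' @param x Length-`d` vector to encode.
#' @param T_max Sparsity budget, `1 <= T_max <= min(d, K)`.
#' @param tol Residual-norm stopping threshold (`>= 0`).
#'
#' @return A list of class `"sparse_code"` with `indices` (strictly increasing
#'   atom indices in `1..K`), `values` (their coefficients), and `length` (`K`).
#' @export
#' @examples
#' D <- diag(4)
#' omp(D, c(1, 0, 2, 0), T_max = 2)
omp <- function(D, x, T_max, tol = 0) {
  D <- check_matrix(D, "D")
  nrm <- col_norms(D)
  bad <- which(abs(nrm - 1) > 1e-8)
  if (length(bad) > 0L) {
    stop(sprintf("dictionary column %d does not have unit norm (norm = %.6g)",
                 bad[1], nrm[bad[1]]), call. = FALSE)
  }
  d <- nrow(D); K <- ncol(D)
  if (length(x) != d) stop("`x` length must match nrow(D)", call. = FALSE)
  T_max <- check_count(T_max, "T_max")
  if (T_max > min(d, K)) {
    stop(sprintf("`T_max` must be <= min(d, K) = %d", min(d, K)), call. = FALSE)
  }

  residual <- x
  support <- integer(0)
  coef <- numeric(0)
  while (length(support) < T_max && sqrt(sum(residual^2)) > tol) {
    corr <- abs(crossprod(D, residual))
    corr[support] <- -Inf
    if (max(corr) < 1e-12) break  # residual orthogonal to all remaining atoms
    sel <- which.max(corr)  # which.max returns the first (lowest index) maximum
    support <- c(support, sel)
    Ds <- D[, support, drop = FALSE]
    ## minimum-norm least squares; robust to (near-)duplicate atoms
    qrd <- qr(Ds)
    coef <- if (qrd$rank == ncol(Ds)) qr.coef(qrd, x) else MASS::ginv(Ds) %*% x
    residual <- x - Ds %*% coef
  }
  ord <- order(support)
  structure(list(indices = support[ord], values = as.numeric(coef)[ord],
                 length = K),
            class = "sparse_code")
}

## Dense K x N code matrix from column-wise OMP.
omp_encode <- function(D, X, T_max, tol = 0) {
  A <- matrix(0, ncol(D), ncol(X))
  for (i in seq_len(ncol(X))) {
    sc <- omp(D, X[, i], T_max = T_max, tol = tol)
    A[sc$indices, i] <- sc$values
  }
  A
}

#' K-SVD dictionary learning
#'
#' Alternates OMP sparse coding with sequential atom updates: for each atom,
#' the residual restricted to the samples using it is formed and its rank-1
#' SVD gives the new atom (leading left singular vector) and coefficients
#' (singular value times right singular vector). Atoms unused by any sample
#' are replaced by the worst-reconstructed sample, renormalized. The coding
#' step is monotone by construction: a column's new OMP code is kept only if
#' it reconstructs that column at least as well as its previous code, so the
#' Frobenius reconstruction error never increases at a coding step.
#'
#' @param X `d x N` data matrix (columns are samples); must not be all zero.
#' @param K Number of atoms. A warning is issued if `K > N`.
#' @param T_max OMP sparsity budget per column.
#' @param n_iter Number of alternating iterations (`>= 1`).
#' @param seed Integer seed for the random initial dictionary.
#'
#' @return List with `D` (`d x K`, unit columns), `A` (`K x N` codes), and
#'   `err_trace` (Frobenius reconstruction error after each iteration's
#'   coding step). Atom signs are fixed so each atom's largest-magnitude
#'   coefficient is positive.
#' @export
ksvd_fit <- function(X, K, T_max, n_iter = 30L, seed = 1L) {
  X <- check_matrix(X, "X")
  if (all(X == 0)) stop("`X` must not be all zero", call. = FALSE)
  K <- check_count(K, "K")
  n_iter <- check_count(n_iter, "n_iter")
  N <- ncol(X)
  if (K > N) warning("K > N: more atoms than samples", call. = FALSE)
  T_max <- min(check_count(T_max, "T_max"), nrow(X), K)  # budget cannot exceed dict size
  seed <- check_count(seed, "seed", min = 0L)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  d <- nrow(X)
  ## init: random unit atoms. Initializing from data columns is the common
  ## alternative but collapses when samples concentrate in a cone (e.g.
  ## nonnegative sparse codes); random directions recover reliably.
  D <- normalize_columns(matrix(stats::rnorm(d * K), d, K))

  A <- matrix(0, K, N)
  err_trace <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    ## monotone coding step
    A_new <- omp_encode(D, X, T_max = T_max)
    old_res <- colSums((X - D %*% A)^2)
    new_res <- colSums((X - D %*% A_new)^2)
    keep_old <- old_res < new_res
    if (any(keep_old)) A_new[, keep_old] <- A[, keep_old]
    A <- A_new
    err_trace[it] <- sqrt(sum((X - D %*% A)^2))

    ## sequential atom updates
    R_full <- X - D %*% A
    for (k in seq_len(K)) {
      users <- which(A[k, ] != 0)
      if (length(users) == 0L) {
        ## replace by the worst-reconstructed sample
        res_norms <- colSums(R_full^2)
        worst <- which.max(res_norms)
        cand <- X[, worst]
        if (sum(cand^2) == 0) next
        D[, k] <- cand / sqrt(sum(cand^2))
        next
      }
      E <- R_full[, users, drop = FALSE] + D[, k] %*% A[k, users, drop = FALSE]
      sv <- svd(E, nu = 1, nv = 1)
      atom <- sv$u[, 1]
      coefs <- sv$d[1] * sv$v[, 1]
      ## sign convention: largest-|coefficient| positive
      if (coefs[which.max(abs(coefs))] < 0) {
        atom <- -atom
        coefs <- -coefs
      }
      R_full[, users] <- R_full[, users, drop = FALSE] +
        D[, k] %*% A[k, users, drop = FALSE] - atom %*% t(coefs)
      D[, k] <- atom
      A[k, users] <- coefs
    }
  }
  list(D = D, A = A, err_trace = err_trace)
}

#' Layer-wise initialization of a deep dictionary model
#'
#' Builds the initial dictionaries and codes for the multi-layer model:
#' a K-SVD dictionary is learned per class and the subclass dictionaries are
#' concatenated into `D_1` (recording each atom's source class); `A_1` is the
#' OMP code of `X` on `D_1`; each subsequent layer factorizes the previous
#' layer's code matrix with K-SVD. Last-layer atom labels are assigned by the
#' contiguous class-block partition of `K_M` (every layer size must be
#' divisible by the number of classes).
#'
#' @param X `d x N` feature matrix (columns are samples).
#' @param labels Integer class ids `0..C-1`; every class must be present.
#' @param layer_sizes Integer vector `K_1 .. K_M`, each divisible by `C`.
#' @param atoms_per_class Atoms per class in the first layer; defaults to
#'   `layer_sizes[1] / C` and must equal it.
#' @param T_max OMP sparsity budget.
#' @param n_iter K-SVD iterations per layer.
#' @param seed Integer seed.
#'
#' @return List with `dictionaries` (list `D_1..D_M`), `codes` (list
#'   `A_1..A_M`), and `atom_labels` (list of per-layer atom class ids,
#'   `atoms-per-class` entries of each class at every layer).
#' @export
init_deep_model <- function(X, labels, layer_sizes, atoms_per_class = NULL,
                            T_max = 5L, n_iter = 15L, seed = 1L) {
  X <- check_matrix(X, "X")
  labels <- check_labels(labels)
  classes <- sort(unique(labels))
  C <- length(classes)
  if (!identical(classes, 0:(C - 1L))) {
    stop("`labels` must contain every class in 0..C-1", call. = FALSE)
  }
  M <- length(layer_sizes)
  layer_sizes <- vapply(seq_len(M), function(i)
    check_count(layer_sizes[i], sprintf("layer_sizes[%d]", i)), integer(1))
  if (any(layer_sizes %% C != 0L)) {
    stop("every layer size must be divisible by the number of classes", call. = FALSE)
  }
  apc <- layer_sizes[1L] %/% C
  if (is.null(atoms_per_class)) atoms_per_class <- apc
  if (atoms_per_class != apc) {
    stop(sprintf("`atoms_per_class` (%d) must equal layer_sizes[1]/C = %d",
                 atoms_per_class, apc), call. = FALSE)
  }
  seed <- check_count(seed, "seed", min = 0L)

  ## per-class K-SVD for the first layer
  D1_parts <- vector("list", C)
  for (c0 in 0:(C - 1L)) {
    cols <- which(labels == c0)
    if (length(cols) < apc) {
      stop(sprintf("class %d has %d samples, fewer than its subclass dictionary size %d",
                   c0, length(cols), apc), call. = FALSE)
    }
    fit <- ksvd_fit(X[, cols, drop = FALSE], K = apc, T_max = T_max,
                    n_iter = n_iter, seed = seed + c0)
    D1_parts[[c0 + 1L]] <- fit$D
  }
  dictionaries <- vector("list", M)
  codes <- vector("list", M)
  atom_labels <- vector("list", M)
  dictionaries[[1L]] <- do.call(cbind, D1_parts)
  atom_labels[[1L]] <- rep(0:(C - 1L), each = apc)
  codes[[1L]] <- omp_encode(dictionaries[[1L]], X,
                            T_max = min(T_max, nrow(X), layer_sizes[1L]))

  if (M > 1L) {
    for (m in 2:M) {
      fit <- ksvd_fit(codes[[m - 1L]], K = layer_sizes[m], T_max = T_max,
                      n_iter = n_iter, seed = seed + C + m)
      dictionaries[[m]] <- fit$D
      codes[[m]] <- fit$A
      atom_labels[[m]] <- rep(0:(C - 1L), each = layer_sizes[m] %/% C)
    }
  }
  list(dictionaries = dictionaries, codes = codes, atom_labels = atom_labels)
}
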