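#' Supervised k-nearest-neighbor graph over last-layer dictionary atoms
#'
#' For each atom (column of `D_M`), its `k` nearest atoms of the *same class*
#' by Euclidean distance receive weight `exp(-dist^2 / sigma)` (Gaussian
#' kernel; set `squared = FALSE` for `exp(-dist / sigma)`). Atoms of different
#' classes are never connected, embedding the supervised information in the
#' graph. The directed k-NN weights are symmetrized by elementwise maximum and
#' the combinatorial Laplacian `L = diag(rowSums(W)) - W` is formed.
#'
#' @param D_M Matrix whose `K_M` columns are the last-layer atoms.
#' @param atom_labels Integer class ids (`0..C-1`), one per atom.
#' @param k Neighbors per atom; must be smaller than the smallest class's
#'   atom count.
#' @param sigma Kernel width (`> 0`).
#' @param squared Use squared Euclidean distance in the exponent (default).
#'
#' @return Object of class `"atom_graph"`: list with `W` (symmetric
#'   nonnegative, zero diagonal), `L` (positive semidefinite, zero row sums),
#'   `k`, `sigma`, and `atom_labels`. Duplicate atoms are allowed (distance 0
#'   gives weight 1). Neighbor ties are broken toward the lowest atom index.
#' @export
atom_knn_graph <- function(D_M, atom_labels, k = 5L, sigma = 1, squared = TRUE) {
  D_M <- check_matrix(D_M, "D_M")
  K <- ncol(D_M)
  atom_labels <- check_labels(atom_labels, name = "atom_labels")
  if (length(atom_labels) != K) {
    stop("`atom_labels` must have one entry per atom", call. = FALSE)
  }
  k <- check_count(k, "k")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("`sigma` must be a single real > 0", call. = FALSE)
  }
  min_block <- min(table(atom_labels))
  if (k >= min_block) {
    stop(sprintf("`k` (%d) must be smaller than the smallest class atom block (%d)",
                 k, min_block), call. = FALSE)
  }

  G <- crossprod(D_M)
  nn <- diag(G)
  D2 <- outer(nn, nn, "+") - 2 * G
  D2[D2 < 0] <- 0  # numerical guard

  W <- matrix(0, K, K)
  for (j in seq_len(K)) {
    same <- which(atom_labels == atom_labels[j])
    same <- same[same != j]
    d2 <- D2[same, j]
    ## k nearest, ties toward the lowest atom index (stable order)
    ord <- same[order(d2, same)][seq_len(k)]
    dist_term <- if (squared) D2[ord, j] else sqrt(D2[ord, j])
    W[ord, j] <- exp(-dist_term / sigma)
  }
  W <- pmax(W, t(W))
  diag(W) <- 0
  L <- diag(rowSums(W), K) - W
  structure(list(W = W, L = L, k = k, sigma = sigma, atom_labels = atom_labels,
                 squared = squared),
            class = "atom_graph")
}

#' Graph-Laplacian locality penalty
#'
#' Computes `Tr(A^T L A)`, which for a symmetric weight matrix equals
#' `1/2 * sum_ij w_ij || row_i(A) - row_j(A) ||^2`: rows of the last-layer
#' code matrix belonging to similar same-class atoms are pulled together.
#'
#' @param L `K x K` graph Laplacian (e.g. from [atom_knn_graph()]).
#' @param A_M `K x N` last-layer code matrix.
#' @return A single nonnegative number.
#' @export
laplacian_penalty <- function(L, A_M) {
  L <- check_matrix(L, "L")
  A_M <- check_matrix(A_M, "A_M")
  if (nrow(L) != ncol(L) || nrow(A_M) != nrow(L)) {
    stop(sprintf("dimension mismatch: L is %dx%d, A_M has %d rows",
                 nrow(L), ncol(L), nrow(A_M)), call. = FALSE)
  }
  sum(A_M * (L %*% A_M))
}
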