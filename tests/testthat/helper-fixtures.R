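# Shared fixtures and oracles for the test suite.

random_unit_dict <- function(d, K, seed) {
  set.seed(seed)
  D <- matrix(rnorm(d * K), d, K)
  sweep(D, 2, sqrt(colSums(D^2)), "/")
}

# A small random model instance whose ReLU pre-activations are bounded away
# from 0 (|z| >= margin), so the objective is smooth in a finite-difference
# neighborhood. Codes are drawn around 1 so positive activations dominate.
smooth_instance <- function(M = 2, d = 6, sizes = c(8, 6, 5)[seq_len(M)],
                            N = 10, C = 2, seed = 1, margin = 2e-3,
                            lambda1 = 0.3, lambda2 = 0.2, lambda3 = 0.7) {
  set.seed(seed)
  for (attempt in 1:200) {
    dims_in <- c(d, sizes[-M])
    dicts <- lapply(seq_len(M), function(m) {
      D <- matrix(rnorm(dims_in[m] * sizes[m]), dims_in[m], sizes[m])
      sweep(D, 2, sqrt(colSums(D^2)), "/")
    })
    A <- matrix(rnorm(sizes[M] * N, mean = 1, sd = 0.5), sizes[M], N)
    ok <- TRUE
    if (M > 1) {
      cur <- A
      for (m in M:2) {
        Z <- dicts[[m]] %*% cur
        if (min(abs(Z)) < margin) { ok <- FALSE; break }
        cur <- pmax(Z, 0)
      }
    }
    if (ok) break
  }
  stopifnot(ok)
  K_M <- sizes[M]
  atom_labels <- rep(0:(C - 1), length.out = K_M)
  atom_labels <- sort(atom_labels)
  graph <- atom_knn_graph(dicts[[M]], atom_labels,
                          k = min(2L, min(table(atom_labels)) - 1L), sigma = 1)
  S <- matrix(rnorm(K_M * C), K_M, C)
  H <- matrix(rnorm(C * N), C, N)
  theta <- matrix(rnorm(K_M * C, sd = 0.1), K_M, C)
  labels <- rep(0:(C - 1), length.out = N)
  P <- matrix(0, C, N); P[cbind(labels + 1, seq_len(N))] <- 1
  X <- matrix(rnorm(d * N), d, N)
  model <- new_cdllc_model(dicts, A, S, H, theta, atom_labels,
                           hyper = list(lambda1 = lambda1, lambda2 = lambda2,
                                        lambda3 = lambda3),
                           graph = graph)
  list(model = model, X = X, P = P, labels = labels)
}

# Central finite difference of f at x (scalar-valued f, matrix x).
num_grad_matrix <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    xp <- x; xp[i, j] <- x[i, j] + eps
    xm <- x; xm[i, j] <- x[i, j] - eps
    g[i, j] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Greedy one-to-one atom matching by maximal |correlation|; returns the
# fraction of true atoms matched above the threshold.
match_atom_fraction <- function(D_true, D_learned, threshold = 0.99) {
  K <- ncol(D_true)
  Cm <- abs(crossprod(D_true, D_learned))
  matched <- 0L
  for (i in seq_len(K)) {
    mx <- which(Cm == max(Cm), arr.ind = TRUE)[1, ]
    if (Cm[mx[1], mx[2]] > threshold) matched <- matched + 1L
    Cm[mx[1], ] <- -1
    Cm[, mx[2]] <- -1
  }
  matched / K
}

rel_frob_err <- function(X, Xhat) sqrt(sum((X - Xhat)^2)) / sqrt(sum(X^2))

# The study-condition training fixture used across trainer/inference tests.
training_fixture <- function(seed = 11, n_per_class = 50, noise = 0.05) {
  make_deep_sparse_dataset(d = 20, layer_sizes = c(24, 12), n_classes = 3,
                           n_per_class = n_per_class, sparsity = 3,
                           noise_sigma = noise, seed = seed)
}
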