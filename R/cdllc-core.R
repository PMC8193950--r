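## Activation functions and their derivatives. The ReLU derivative at exactly
## 0 is defined as 0 (deterministic subgradient choice).
activation_funs <- function(name) {
  switch(name,
    relu = list(
      fn = function(z) pmax(z, 0),
      grad = function(z) (z > 0) * 1
    ),
    sigmoid = list(
      fn = function(z) 1 / (1 + exp(-z)),
      grad = function(z) { s <- 1 / (1 + exp(-z)); s * (1 - s) }
    ),
    tanh = list(
      fn = function(z) tanh(z),
      grad = function(z) 1 - tanh(z)^2
    ),
    stop(sprintf("unknown activation '%s' (use relu, sigmoid or tanh)", name),
         call. = FALSE)
  )
}

#' Construct a deep dictionary model object
#'
#' Bundles the free parameters of the model — dictionaries `D_1..D_M`,
#' last-layer codes `A_M`, low-rank factors `S` (`K_M x C`) and `H` (`C x N`),
#' softmax classifier weights `theta` (`K_M x C`) — with the atom labels, the
#' atom graph, the activation name, and the hyperparameters. Intermediate
#' codes `A_1..A_{M-1}` are not parameters: they are activations recomputed by
#' [forward_reconstruct()].
#'
#' @param dictionaries List of matrices `D_1` (`d x K_1`) .. `D_M`
#'   (`K_{M-1} x K_M`); every column must have squared norm at most
#'   `1 + 1e-8`.
#' @param A_M `K_M x N` last-layer code matrix.
#' @param S,H Low-rank factors with `A_M ~ S H`.
#' @param theta `K_M x C` classifier weight matrix (column per class).
#' @param atom_labels Last-layer atom class ids (`0..C-1`).
#' @param activation One of `"relu"` (default), `"sigmoid"`, `"tanh"`.
#' @param hyper Named list of hyperparameters (`lambda1`, `lambda2`,
#'   `lambda3`, `sigma`, `k`, `T_max`, ...).
#' @param graph An `"atom_graph"` for the current `D_M`, or `NULL`.
#' @param center,scale Optional per-feature standardization parameters
#'   learned on training data.
#'
#' @return Object of class `"cdllc"`.
#' @export
new_cdllc_model <- function(dictionaries, A_M, S, H, theta, atom_labels,
                            activation = "relu", hyper = list(), graph = NULL,
                            center = NULL, scale = NULL) {
  stopifnot(is.list(dictionaries), length(dictionaries) >= 1L)
  M <- length(dictionaries)
  for (m in seq_len(M)) {
    Dm <- check_matrix(dictionaries[[m]], sprintf("D_%d", m))
    if (any(colSums(Dm^2) > 1 + 1e-8)) {
      stop(sprintf("layer %d has a column with squared norm > 1", m), call. = FALSE)
    }
    if (m > 1L && nrow(Dm) != ncol(dictionaries[[m - 1L]])) {
      stop(sprintf("shape mismatch between layers %d and %d", m - 1L, m),
           call. = FALSE)
    }
  }
  K_M <- ncol(dictionaries[[M]])
  if (nrow(A_M) != K_M) stop("`A_M` must have K_M rows", call. = FALSE)
  C <- ncol(S)
  stopifnot(nrow(S) == K_M, nrow(H) == C, nrow(theta) == K_M, ncol(theta) == C,
            length(atom_labels) == K_M)
  activation_funs(activation)  # validates the name
  structure(list(dictionaries = dictionaries, A_M = A_M, S = S, H = H,
                 theta = theta, atom_labels = check_labels(atom_labels),
                 activation = activation, hyper = hyper, graph = graph,
                 center = center, scale = scale, n_classes = C),
            class = "cdllc")
}

#' @export
print.cdllc <- function(x, ...) {
  dims <- vapply(x$dictionaries, function(D) sprintf("%dx%d", nrow(D), ncol(D)),
                 character(1))
  cat(sprintf("Deep dictionary model: %d layer(s) [%s], %d classes, activation '%s'\n",
              length(x$dictionaries), paste(dims, collapse = " -> "),
              x$n_classes, x$activation))
  invisible(x)
}

#' Forward reconstruction through the dictionary chain
#'
#' Given last-layer codes `A`, computes the activations
#' `A_m = phi(D_{m+1} A_{m+1})` top-down for `m = M-1 .. 1` and the
#' reconstruction `D_1 A_1`. A single-layer model applies no nonlinearity.
#'
#' @param model A `"cdllc"` model (or plain list with `dictionaries` and
#'   `activation`).
#' @param A `K_M x n` code matrix.
#' @return List with `reconstruction` (`d x n`), `activations` (list
#'   `A_1..A_M`, where `A_M` is the input), and `preacts` (list of
#'   pre-activations `Z_m = D_m A_m` for `m = 2..M`, used by the trainer).
#' @export
forward_reconstruct <- function(model, A) {
  dicts <- model$dictionaries
  M <- length(dicts)
  A <- check_matrix(A, "A")
  if (nrow(A) != ncol(dicts[[M]])) {
    stop(sprintf("layer %d shape mismatch: A has %d rows, D_%d has %d columns",
                 M, nrow(A), M, ncol(dicts[[M]])), call. = FALSE)
  }
  act <- activation_funs(model$activation)
  activations <- vector("list", M)
  preacts <- vector("list", M)  # preacts[[m]] = D_m %*% A_m for m >= 2
  activations[[M]] <- A
  if (M > 1L) {
    for (m in M:2) {
      Z <- dicts[[m]] %*% activations[[m]]
      preacts[[m]] <- Z
      activations[[m - 1L]] <- act$fn(Z)
    }
  }
  list(reconstruction = dicts[[1L]] %*% activations[[1L]],
       activations = activations, preacts = preacts)
}

#' Softmax class probabilities
#'
#' Columnwise softmax of the linear scores `theta^T A`, computed with
#' max-subtraction for overflow safety.
#'
#' @param theta `K x C` classifier weights.
#' @param A `K x n` code matrix.
#' @return `C x n` matrix of probabilities; every column sums to 1.
#' @export
softmax_probs <- function(theta, A) {
  logits <- crossprod(theta, A)            # C x n
  logits <- sweep(logits, 2, apply(logits, 2, max), "-")
  E <- exp(logits)
  sweep(E, 2, colSums(E), "/")
}

#' Full training objective
#'
#' Evaluates the joint objective
#' `J = ||X - D_1 phi(... phi(D_M A_M))||_F^2 + lambda1 ||A_M - S H||_F^2 +
#' lambda2 Tr(A_M^T L A_M) + lambda3/N * cross-entropy(theta^T A_M, P)`
#' and returns the total together with its four parts.
#'
#' @param model A `"cdllc"` model with a current atom graph (`model$graph`),
#'   unless `lambda2 = 0`.
#' @param X `d x N` data matrix.
#' @param P `C x N` one-hot label matrix.
#' @return List with `total`, `J1` (reconstruction), `rank_term`
#'   (`lambda1`-weighted low-rank deviation), `J2` (`lambda2`-weighted
#'   Laplacian penalty), `J3` (`lambda3`-weighted mean cross-entropy).
#' @export
objective <- function(model, X, P) {
  X <- check_matrix(X, "X")
  N <- ncol(X)
  if (ncol(model$A_M) != N || ncol(P) != N) {
    stop("X, A_M and P must have the same number of columns", call. = FALSE)
  }
  h <- model$hyper
  lambda1 <- h$lambda1 %||% 0
  lambda2 <- h$lambda2 %||% 0
  lambda3 <- h$lambda3 %||% 0

  fwd <- forward_reconstruct(model, model$A_M)
  J1 <- sum((X - fwd$reconstruction)^2)
  rank_term <- lambda1 * sum((model$A_M - model$S %*% model$H)^2)
  J2 <- if (lambda2 > 0) {
    lambda2 * laplacian_penalty(model$graph$L, model$A_M)
  } else 0
  probs <- softmax_probs(model$theta, model$A_M)
  ## cross-entropy with the 0*log0 guard on the one-hot mask
  J3 <- -(lambda3 / N) * sum(P * log(pmax(probs, .Machine$double.xmin)))

  parts <- c(J1 = J1, rank_term = rank_term, J2 = J2, J3 = J3)
  bad <- which(!is.finite(parts))
  if (length(bad) > 0L) {
    stop(sprintf("objective part %s is non-finite", names(parts)[bad[1]]),
         call. = FALSE)
  }
  list(total = sum(parts), J1 = J1, rank_term = rank_term, J2 = J2, J3 = J3)
}
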