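#' Backpropagated objective gradients with respect to the layer codes
#'
#' Computes `dJ/dA_m` for every layer by the chain rule:
#' `dJ/dA_1 = 2 D_1^T (D_1 A_1 - X)` and, for `m >= 2`,
#' `dJ/dA_m = D_m^T [ dJ/dA_{m-1} * phi'(D_m A_m) ]` (elementwise product).
#' The last-layer delta additionally receives the gradients of the low-rank,
#' Laplacian, and softmax terms:
#' `+ 2 lambda1 (A_M - S H) + 2 lambda2 L A_M +
#'  (lambda3/N) theta (softmax(theta^T A_M) - P)`.
#'
#' @param model A `"cdllc"` model.
#' @param X `d x N` data matrix.
#' @param P `C x N` one-hot label matrix.
#' @param fwd Output of [forward_reconstruct()] on the current `model$A_M`.
#' @return List of matrices `dJ/dA_1 .. dJ/dA_M`.
#' @export
backprop_deltas <- function(model, X, P, fwd) {
  dicts <- model$dictionaries
  M <- length(dicts)
  acts <- fwd$activations
  if (ncol(acts[[M]]) != ncol(X) || nrow(fwd$reconstruction) != nrow(X)) {
    stop("activations do not match X (stale forward pass?)", call. = FALSE)
  }
  act <- activation_funs(model$activation)
  N <- ncol(X)
  h <- model$hyper
  lambda1 <- h$lambda1 %||% 0
  lambda2 <- h$lambda2 %||% 0
  lambda3 <- h$lambda3 %||% 0

  deltas <- vector("list", M)
  deltas[[1L]] <- 2 * crossprod(dicts[[1L]], fwd$reconstruction - X)
  if (M > 1L) {
    for (m in 2:M) {
      deltas[[m]] <- crossprod(dicts[[m]],
                               deltas[[m - 1L]] * act$grad(fwd$preacts[[m]]))
    }
  }
  extra <- 0
  if (lambda1 > 0) extra <- extra + 2 * lambda1 * (model$A_M - model$S %*% model$H)
  if (lambda2 > 0) extra <- extra + 2 * lambda2 * (model$graph$L %*% model$A_M)
  if (lambda3 > 0) {
    probs <- softmax_probs(model$theta, model$A_M)
    extra <- extra + (lambda3 / N) * (model$theta %*% (probs - P))
  }
  deltas[[M]] <- deltas[[M]] + extra
  deltas
}

#' Objective gradients with respect to the dictionaries
#'
#' `dJ/dD_1 = 2 (D_1 A_1 - X) A_1^T` and, for `m >= 2`,
#' `dJ/dD_m = [ dJ/dA_{m-1} * phi'(D_m A_m) ] A_m^T`. The atom graph is held
#' constant with respect to `D_M` within an outer iteration.
#'
#' @inheritParams backprop_deltas
#' @param deltas Output of [backprop_deltas()].
#' @return List of gradient matrices, one per dictionary.
#' @export
grad_dictionaries <- function(model, X, fwd, deltas) {
  dicts <- model$dictionaries
  M <- length(dicts)
  act <- activation_funs(model$activation)
  grads <- vector("list", M)
  grads[[1L]] <- 2 * (fwd$reconstruction - X) %*% t(fwd$activations[[1L]])
  if (M > 1L) {
    for (m in 2:M) {
      grads[[m]] <- (deltas[[m - 1L]] * act$grad(fwd$preacts[[m]])) %*%
        t(fwd$activations[[m]])
    }
  }
  grads
}

#' Closed-form update of the low-rank factor S
#'
#' `S = A_M H^T (H H^T)^+` — the least-squares minimizer of
#' `||A_M - S H||_F^2`, satisfying the stationarity condition
#' `A_M H^T - S H H^T = 0`.
#'
#' @param A_M `K_M x N` code matrix.
#' @param H `C x N` factor.
#' @return `K_M x C` matrix.
#' @export
update_S <- function(A_M, H) {
  A_M <- check_matrix(A_M, "A_M"); H <- check_matrix(H, "H")
  if (ncol(A_M) != ncol(H)) stop("A_M and H must have equal column counts", call. = FALSE)
  A_M %*% t(H) %*% MASS::ginv(H %*% t(H))
}

#' Closed-form update of the low-rank factor H
#'
#' `H = (S^T S)^+ S^T A_M` — the least-squares minimizer of
#' `||A_M - S H||_F^2` in `H`, satisfying `S^T S H - S^T A_M = 0`.
#'
#' @param A_M `K_M x N` code matrix.
#' @param S `K_M x C` factor.
#' @return `C x N` matrix.
#' @export
update_H <- function(A_M, S) {
  A_M <- check_matrix(A_M, "A_M"); S <- check_matrix(S, "S")
  if (nrow(A_M) != nrow(S)) stop("A_M and S must have equal row counts", call. = FALSE)
  MASS::ginv(crossprod(S)) %*% crossprod(S, A_M)
}

#' Gradient of the softmax cross-entropy term in the classifier weights
#'
#' `dJ3/dtheta = (lambda3/N) A_M (softmax(theta^T A_M) - P)^T`, the exact
#' gradient of the mean cross-entropy term of the objective.
#'
#' @param theta `K_M x C` classifier weights.
#' @param A_M `K_M x N` code matrix.
#' @param P `C x N` one-hot label matrix.
#' @param lambda3 Weight of the classification term.
#' @return `K_M x C` gradient matrix.
#' @export
grad_theta <- function(theta, A_M, P, lambda3) {
  probs <- softmax_probs(theta, A_M)
  (lambda3 / ncol(A_M)) * A_M %*% t(probs - P)
}

#' Project dictionary columns onto the unit Euclidean ball
#'
#' Columns with norm greater than 1 are rescaled to norm exactly 1; columns
#' already inside the ball are untouched. Idempotent.
#'
#' @param D Numeric matrix.
#' @return Matrix of the same shape with all column norms `<= 1`.
#' @export
project_unit_columns <- function(D) {
  D <- check_matrix(D, "D")
  nrm <- col_norms(D)
  over <- nrm > 1
  if (any(over)) D[, over] <- sweep(D[, over, drop = FALSE], 2, nrm[over], "/")
  D
}

#' Training configuration
#'
#' Fixed per-block step sizes for the full-batch gradient updates, iteration
#' and convergence controls. Defaults are tuned for standardized inputs of a
#' few dozen features and a few hundred samples.
#'
#' @param rate_dict Step size for every dictionary update.
#' @param rate_code Initial step size for the last-layer code update; the
#'   actual step is chosen by Armijo backtracking (halving) so the code update
#'   never increases the objective.
#' @param code_steps Code gradient steps per outer iteration.
#' @param rate_theta Step size for the classifier update.
#' @param theta_steps Classifier gradient steps per outer iteration.
#' @param max_outer_iter Maximum outer iterations.
#' @param tol Relative objective-change convergence threshold.
#' @param tol_patience Consecutive small-change iterations required to stop.
#' @param init_iter K-SVD iterations used during initialization.
#' @param verbose Emit one log line per outer iteration to stderr.
#' @param trace_file Optional CSV path receiving the per-iteration trace.
#' @return List of class `"cdllc_control"`.
#' @export
cdllc_control <- function(rate_dict = 2e-4, rate_code = 0.2, code_steps = 2L,
                          rate_theta = 2, theta_steps = 5L,
                          max_outer_iter = 200L, tol = 1e-5,
                          tol_patience = 3L, init_iter = 15L, verbose = FALSE,
                          trace_file = NULL) {
  stopifnot(rate_dict > 0, rate_code > 0, rate_theta > 0)
  max_outer_iter <- check_count(max_outer_iter, "max_outer_iter")
  code_steps <- check_count(code_steps, "code_steps")
  theta_steps <- check_count(theta_steps, "theta_steps")
  tol_patience <- check_count(tol_patience, "tol_patience")
  if (tol < 0) stop("`tol` must be >= 0", call. = FALSE)
  structure(list(rate_dict = rate_dict, rate_code = rate_code,
                 code_steps = code_steps,
                 rate_theta = rate_theta, theta_steps = theta_steps,
                 max_outer_iter = max_outer_iter, tol = tol,
                 tol_patience = tol_patience, init_iter = init_iter,
                 verbose = isTRUE(verbose), trace_file = trace_file),
            class = "cdllc_control")
}

#' Fit a deep dictionary classification model
#'
#' Trains the joint model by alternating minimization. Initialization runs
#' per-class K-SVD for the first layer, OMP coding, and layer-wise K-SVD for
#' the deeper layers; `H` starts from the one-hot labels, `S` from its
#' closed-form update, `theta` from zero, and the supervised atom k-NN graph
#' is built from the initial last-layer dictionary. Each outer iteration then
#' performs: forward pass, backpropagated deltas, a projected gradient step on
#' every dictionary, a gradient step on the last-layer codes, closed-form `S`
#' and `H` updates, classifier gradient step(s), a rebuild of the atom graph
#' from the new last-layer dictionary, and an objective evaluation. Training
#' stops at `max_outer_iter` or when the relative objective change stays below
#' `tol` for `tol_patience` consecutive iterations. Fully deterministic given
#' `seed`.
#'
#' @param X `d x N` feature matrix (columns are samples).
#' @param labels Integer class ids `0..C-1`.
#' @param layer_sizes Dictionary sizes `K_1 .. K_M`, each divisible by the
#'   number of classes.
#' @param lambda1,lambda2,lambda3 Weights of the low-rank, Laplacian, and
#'   classification terms.
#' @param sigma Atom-graph kernel width.
#' @param k Atom-graph neighbor count (must be below the per-class last-layer
#'   atom block size).
#' @param T_max OMP sparsity budget used in initialization.
#' @param activation `"relu"` (default), `"sigmoid"`, or `"tanh"`.
#' @param standardize Center and scale features using training statistics
#'   (stored in the model and reused at prediction time).
#' @param control A [cdllc_control()] list.
#' @param seed Integer seed for the initialization.
#'
#' @return List with `model` (a `"cdllc"` object) and `trace` (data frame of
#'   per-iteration objective parts and gradient norms, with attributes
#'   `converged` and `reason`).
#' @export
#' @examples
#' ds <- make_deep_sparse_dataset(20, c(12, 6), n_classes = 3, n_per_class = 8,
#'                                sparsity = 2, noise_sigma = 0.05, seed = 3)
#' fit <- cdllc_fit(ds$X, ds$labels, layer_sizes = c(12, 6), k = 1,
#'                  control = cdllc_control(max_outer_iter = 5))
#' fit$trace$J_total
cdllc_fit <- function(X, labels, layer_sizes, lambda1 = 1, lambda2 = 0.1,
                      lambda3 = 1, sigma = 1, k = 3L, T_max = 5L,
                      activation = "relu", standardize = TRUE,
                      control = cdllc_control(), seed = 1L) {
  X <- check_matrix(X, "X")
  labels <- check_labels(labels)
  C <- length(unique(labels))
  N <- ncol(X)
  if (length(labels) != N) stop("one label per column of X is required", call. = FALSE)
  stopifnot(inherits(control, "cdllc_control"))

  center <- scale <- NULL
  if (standardize) {
    center <- rowMeans(X)
    scale <- apply(X, 1, stats::sd)
    scale[scale == 0] <- 1
    X <- (X - center) / scale
  }

  init <- init_deep_model(X, labels, layer_sizes, T_max = T_max,
                          n_iter = control$init_iter, seed = seed)
  M <- length(layer_sizes)
  dicts <- lapply(init$dictionaries, project_unit_columns)
  A_M <- init$codes[[M]]
  atom_labels <- init$atom_labels[[M]]
  P <- one_hot(labels, C)
  H <- P
  S <- update_S(A_M, H)
  theta <- matrix(0, nrow(A_M), C)
  hyper <- list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                sigma = sigma, k = k, T_max = T_max, seed = seed)
  graph <- atom_knn_graph(dicts[[M]], atom_labels, k = k, sigma = sigma)

  model <- new_cdllc_model(dicts, A_M, S, H, theta, atom_labels,
                           activation = activation, hyper = hyper,
                           graph = graph, center = center, scale = scale)
  model$labels <- labels

  trace <- data.frame(iter = integer(0), J_total = numeric(0), J1 = numeric(0),
                      rank_term = numeric(0), J2 = numeric(0), J3 = numeric(0),
                      dict_grad_norm = numeric(0), code_grad_norm = numeric(0),
                      theta_grad_norm = numeric(0))
  obj_prev <- objective(model, X, P)$total
  initial_objective <- obj_prev
  small_changes <- 0L
  converged <- FALSE
  reason <- "max_outer_iter reached"

  for (it in seq_len(control$max_outer_iter)) {
    fwd <- forward_reconstruct(model, model$A_M)
    deltas <- backprop_deltas(model, X, P, fwd)
    dgrads <- grad_dictionaries(model, X, fwd, deltas)

    for (m in seq_len(M)) {
      model$dictionaries[[m]] <- project_unit_columns(
        model$dictionaries[[m]] - control$rate_dict * dgrads[[m]])
    }
    ## code update(s): Armijo backtracking on the objective with the
    ## dictionaries, S, H, theta and graph held fixed
    f_cur <- objective(model, X, P)$total
    g_code <- deltas[[M]]
    for (cs in seq_len(control$code_steps)) {
      if (cs > 1L) {
        fwd_c <- forward_reconstruct(model, model$A_M)
        g_code <- backprop_deltas(model, X, P, fwd_c)[[length(deltas)]]
      }
      gn2 <- sum(g_code^2)
      if (gn2 == 0) break
      step <- control$rate_code
      moved <- FALSE
      for (bt in 1:30) {
        cand <- model
        cand$A_M <- model$A_M - step * g_code
        f_new <- objective(cand, X, P)$total
        if (f_new <= f_cur - 1e-4 * step * gn2) {
          model$A_M <- cand$A_M
          f_cur <- f_new
          moved <- TRUE
          break
        }
        step <- step / 2
      }
      if (!moved) break
    }
    model$S <- update_S(model$A_M, model$H)
    model$H <- update_H(model$A_M, model$S)
    tg_norm <- 0
    for (s in seq_len(control$theta_steps)) {
      tg <- grad_theta(model$theta, model$A_M, P, lambda3)
      tg_norm <- sqrt(sum(tg^2))
      model$theta <- model$theta - control$rate_theta * tg
    }
    model$graph <- atom_knn_graph(model$dictionaries[[M]], atom_labels,
                                  k = k, sigma = sigma)

    obj <- tryCatch(objective(model, X, P), error = function(e) e)
    if (inherits(obj, "error")) {
      cond <- structure(
        class = c("cdllc_divergence", "error", "condition"),
        list(message = sprintf("objective diverged at iteration %d: %s",
                               it, conditionMessage(obj)),
             call = NULL, trace = trace))
      stop(cond)
    }
    trace[nrow(trace) + 1L, ] <- list(
      it, obj$total, obj$J1, obj$rank_term, obj$J2, obj$J3,
      sqrt(sum(vapply(dgrads, function(g) sum(g^2), numeric(1)))),
      sqrt(sum(deltas[[M]]^2)), tg_norm)
    if (control$verbose) {
      message(sprintf(
        "iter %4d  J=%.6g  J1=%.6g rank=%.6g J2=%.6g J3=%.6g  |gD|=%.3g |gA|=%.3g |gT|=%.3g",
        it, obj$total, obj$J1, obj$rank_term, obj$J2, obj$J3,
        trace$dict_grad_norm[it], trace$code_grad_norm[it], trace$theta_grad_norm[it]))
    }

    rel_change <- abs(obj$total - obj_prev) / max(abs(obj_prev), .Machine$double.eps)
    small_changes <- if (rel_change < control$tol) small_changes + 1L else 0L
    obj_prev <- obj$total
    if (small_changes >= control$tol_patience) {
      converged <- TRUE
      reason <- sprintf("relative change < %g for %d iterations",
                        control$tol, control$tol_patience)
      break
    }
  }

  attr(trace, "converged") <- converged
  attr(trace, "reason") <- reason
  attr(trace, "initial_objective") <- initial_objective
  if (!is.null(control$trace_file)) {
    utils::write.csv(trace, control$trace_file, row.names = FALSE)
  }
  list(model = model, trace = trace)
}
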