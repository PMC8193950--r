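#' Encode a test sample against a trained model
#'
#' Minimizes the per-sample encoding objective
#' `||x - D_1 phi(... phi(D_M a))||^2 + lambda1 || (I - S (S^T S)^+ S^T) a ||^2`
#' by gradient descent with Armijo backtracking line search. The second term
#' is the joint minimization over the unknown per-sample factor `h` of
#' `lambda1 ||a - S h||^2`; eliminating `h` leaves the residual of the
#' orthogonal projection onto the column space of `S`.
#'
#' @param model A trained `"cdllc"` model.
#' @param x Length-`d` feature vector, already on the training scale (callers
#'   such as [predict.cdllc()] apply the stored standardization first).
#' @param n_iter Maximum gradient iterations.
#' @param rate Initial step size for the backtracking search.
#' @param warm_start Start from the OMP code of `x` on the composite linear
#'   dictionary `D_1 D_2 ... D_M` (default). With `FALSE` the iteration starts
#'   at `a = 0`, which for a ReLU chain with more than one layer is a
#'   stationary point and will not move.
#'
#' @return List with `a` (the code), `value` (final objective), `grad_norm`,
#'   and `iterations` (iterations actually taken). The objective is
#'   nonincreasing across iterations by construction.
#' @export
encode_test <- function(model, x, n_iter = 100L, rate = 0.5, warm_start = TRUE) {
  dicts <- model$dictionaries
  M <- length(dicts)
  d <- nrow(dicts[[1L]])
  if (length(x) != d) stop("`x` length must match the model input dimension", call. = FALSE)
  K_M <- ncol(dicts[[M]])
  lambda1 <- model$hyper$lambda1 %||% 0
  act <- activation_funs(model$activation)

  ## projection-residual penalty matrix Q = I - S (S^T S)^+ S^T
  Q <- if (lambda1 > 0) {
    S <- model$S
    diag(K_M) - S %*% MASS::ginv(crossprod(S)) %*% t(S)
  } else NULL

  fval <- function(a) {
    fwd <- forward_reconstruct(model, matrix(a, ncol = 1))
    v <- sum((x - fwd$reconstruction)^2)
    if (lambda1 > 0) v <- v + lambda1 * sum((Q %*% a)^2)
    v
  }
  fgrad <- function(a) {
    fwd <- forward_reconstruct(model, matrix(a, ncol = 1))
    g <- 2 * crossprod(dicts[[1L]], fwd$reconstruction - x)
    if (M > 1L) {
      for (m in 2:M) g <- crossprod(dicts[[m]], g * act$grad(fwd$preacts[[m]]))
    }
    g <- as.numeric(g)
    if (lambda1 > 0) g <- g + 2 * lambda1 * as.numeric(Q %*% a)
    g
  }

  a <- if (warm_start) {
    Deff <- Reduce(`%*%`, dicts)
    nrm <- col_norms(Deff)
    nrm[nrm == 0] <- 1
    sc <- omp(sweep(Deff, 2, nrm, "/"), x,
              T_max = min(model$hyper$T_max %||% 5L, d, K_M))
    a0 <- numeric(K_M)
    a0[sc$indices] <- sc$values / nrm[sc$indices]
    a0
  } else {
    numeric(K_M)
  }

  f <- fval(a)
  iters <- 0L
  for (it in seq_len(n_iter)) {
    g <- fgrad(a)
    gn2 <- sum(g^2)
    if (gn2 == 0) break
    step <- rate
    ok <- FALSE
    for (bt in 1:40) {
      a_new <- a - step * g
      f_new <- fval(a_new)
      if (!is.finite(f_new)) {
        cond <- structure(class = c("cdllc_divergence", "error", "condition"),
                          list(message = sprintf("non-finite encoding objective at iteration %d", it),
                               call = NULL))
        stop(cond)
      }
      if (f_new <= f - 1e-4 * step * gn2) { ok <- TRUE; break }
      step <- step / 2
    }
    if (!ok) break  # no admissible step: at (numerical) stationarity
    a <- a_new
    f <- f_new
    iters <- it
  }
  list(a = a, value = f, grad_norm = sqrt(sum(fgrad(a)^2)), iterations = iters)
}

#' Classify new samples with a trained model
#'
#' Each column of `newdata` is standardized with the training transform,
#' encoded with [encode_test()], and classified by the trained softmax head.
#' Probability ties are broken toward the lowest class index.
#'
#' @param object A trained `"cdllc"` model.
#' @param newdata `d x n` matrix of samples in columns (a single vector is
#'   treated as one sample).
#' @param n_iter,rate,warm_start Passed to [encode_test()].
#' @param ... Ignored.
#'
#' @return Object of class `"cdllc_prediction"`: list with `label` (integer
#'   vector in `0..C-1`), `prob` (`C x n`, columns sum to 1), `codes`
#'   (`K_M x n`), and `objective` (length-`n` encoding objective values).
#' @export
predict.cdllc <- function(object, newdata, n_iter = 100L, rate = 0.5,
                          warm_start = TRUE, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, ncol = 1)
  newdata <- check_matrix(newdata, "newdata")
  if (!is.null(object$center)) {
    newdata <- (newdata - object$center) / object$scale
  }
  n <- ncol(newdata)
  K_M <- ncol(object$dictionaries[[length(object$dictionaries)]])
  codes <- matrix(0, K_M, n)
  objv <- numeric(n)
  for (i in seq_len(n)) {
    enc <- encode_test(object, newdata[, i], n_iter = n_iter, rate = rate,
                       warm_start = warm_start)
    codes[, i] <- enc$a
    objv[i] <- enc$value
  }
  prob <- softmax_probs(object$theta, codes)
  label <- apply(prob, 2, which.max) - 1L  # which.max: lowest index on ties
  structure(list(label = as.integer(label), prob = prob, codes = codes,
                 objective = objv),
            class = "cdllc_prediction")
}

#' @export
print.cdllc_prediction <- function(x, ...) {
  cat(sprintf("Predictions for %d sample(s); class counts:\n", length(x$label)))
  print(table(x$label))
  invisible(x)
}
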