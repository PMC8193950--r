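test_that("backpropagated deltas match finite differences of the objective", {
  for (M in 1:3) {
    inst <- smooth_instance(M = M, seed = 20 + M)
    m <- inst$model; X <- inst$X; P <- inst$P
    fwd <- forward_reconstruct(m, m$A_M)
    deltas <- backprop_deltas(m, X, P, fwd)
    f_A <- function(A) { mm <- m; mm$A_M <- A; objective(mm, X, P)$total }
    num <- num_grad_matrix(f_A, m$A_M)
    expect_lt(max(abs(num - deltas[[M]])) / max(abs(num)), 1e-4)
  }
})

test_that("dictionary gradients match finite differences at every layer", {
  for (M in 1:3) {
    inst <- smooth_instance(M = M, seed = 30 + M)
    m <- inst$model; X <- inst$X; P <- inst$P
    fwd <- forward_reconstruct(m, m$A_M)
    deltas <- backprop_deltas(m, X, P, fwd)
    grads <- grad_dictionaries(m, X, fwd, deltas)
    for (layer in seq_len(M)) {
      f_D <- function(D) {
        mm <- m; mm$dictionaries[[layer]] <- D
        objective(mm, X, P)$total
      }
      num <- num_grad_matrix(f_D, m$dictionaries[[layer]])
      expect_lt(max(abs(num - grads[[layer]])) / max(abs(num)), 1e-4)
    }
  }
})

test_that("gradients vanish at the stated degenerate optima", {
  ## perfect single-layer reconstruction with no regularizers
  D1 <- random_unit_dict(6, 4, seed = 2)
  A <- matrix(rnorm(4 * 8), 4, 8)
  X <- D1 %*% A
  model <- new_cdllc_model(list(D1), A, S = matrix(0, 4, 2),
                           H = matrix(0, 2, 8), theta = matrix(0, 4, 2),
                           atom_labels = rep(0:1, each = 2),
                           hyper = list(lambda1 = 0, lambda2 = 0, lambda3 = 0))
  P <- matrix(0.0, 2, 8); P[1, ] <- 1
  fwd <- forward_reconstruct(model, A)
  deltas <- backprop_deltas(model, X, P, fwd)
  expect_equal(max(abs(deltas[[1]])), 0, tolerance = 1e-12)
  grads <- grad_dictionaries(model, X, fwd, deltas)
  expect_equal(max(abs(grads[[1]])), 0, tolerance = 1e-12)

  ## zero codes: dictionary gradient is zero regardless of X
  model$A_M <- A * 0
  fwd0 <- forward_reconstruct(model, model$A_M)
  deltas0 <- backprop_deltas(model, X, P, fwd0)
  grads0 <- grad_dictionaries(model, X, fwd0, deltas0)
  expect_equal(grads0[[1]], 2 * (fwd0$reconstruction - X) %*% t(model$A_M * 0))
  expect_true(all(grads0[[1]] == 0))
})

test_that("an empty graph contributes nothing to the last-layer delta", {
  inst <- smooth_instance(M = 2, seed = 40, lambda1 = 0, lambda3 = 0, lambda2 = 0.7)
  m <- inst$model
  m$graph$L <- m$graph$L * 0
  fwd <- forward_reconstruct(m, m$A_M)
  d_with <- backprop_deltas(m, inst$X, inst$P, fwd)[[2]]
  m0 <- m; m0$hyper$lambda2 <- 0
  d_without <- backprop_deltas(m0, inst$X, inst$P, fwd)[[2]]
  expect_equal(d_with, d_without, tolerance = 1e-14)
})

test_that("closed-form S and H updates satisfy their stationarity conditions", {
  set.seed(50)
  for (rep in 1:100) {
    K <- sample(4:10, 1); N <- sample(8:30, 1); C <- sample(2:4, 1)
    A <- matrix(rnorm(K * N), K, N)
    H <- matrix(rnorm(C * N), C, N)
    S <- update_S(A, H)
    expect_lt(norm(A %*% t(H) - S %*% H %*% t(H), "F"),
              1e-8 * max(norm(A %*% t(H), "F"), 1e-12))
    S2 <- matrix(rnorm(K * C), K, C)
    H2 <- update_H(A, S2)
    expect_lt(norm(crossprod(S2) %*% H2 - crossprod(S2, A), "F"),
              1e-8 * max(norm(crossprod(S2, A), "F"), 1e-12))
  }
})

test_that("S and H updates equal an independent least-squares solve", {
  set.seed(51)
  A <- matrix(rnorm(6 * 20), 6, 20)
  H <- matrix(rnorm(3 * 20), 3, 20)
  ## oracle: solve min_S ||A - S H||_F row by row via qr on t(H)
  S_oracle <- t(qr.solve(t(H), t(A)))
  expect_equal(update_S(A, H), S_oracle, tolerance = 1e-10)
  S <- matrix(rnorm(6 * 3), 6, 3)
  H_oracle <- qr.solve(S, A)
  expect_equal(update_H(A, S), H_oracle, tolerance = 1e-10)

  ## orthonormal special cases
  Hq <- qr.Q(qr(matrix(rnorm(20 * 3), 20, 3)))  # t(Hq) has orthonormal rows
  expect_equal(update_S(A, t(Hq)), A %*% Hq, tolerance = 1e-12)
  Sq <- qr.Q(qr(matrix(rnorm(6 * 3), 6, 3)))
  expect_equal(update_H(A, Sq), crossprod(Sq, A), tolerance = 1e-12)
})

test_that("S/H updates never increase the factorization residual", {
  set.seed(52)
  for (rep in 1:20) {
    A <- matrix(rnorm(8 * 15), 8, 15)
    S <- matrix(rnorm(8 * 3), 8, 3)
    H <- matrix(rnorm(3 * 15), 3, 15)
    before <- sum((A - S %*% H)^2)
    S <- update_S(A, H)
    mid <- sum((A - S %*% H)^2)
    H <- update_H(A, S)
    after <- sum((A - S %*% H)^2)
    expect_lte(mid, before + 1e-9)
    expect_lte(after, mid + 1e-9)
  }
})

test_that("classifier gradient matches finite differences and closed forms", {
  set.seed(53)
  K <- 6; C <- 3; N <- 12
  A <- matrix(rnorm(K * N), K, N)
  theta <- matrix(rnorm(K * C, sd = 0.3), K, C)
  labels <- rep(0:(C - 1), length.out = N)
  P <- matrix(0, C, N); P[cbind(labels + 1, 1:N)] <- 1
  lambda3 <- 0.8
  g <- grad_theta(theta, A, P, lambda3)
  J3 <- function(th) {
    pr <- softmax_probs(th, A)
    -(lambda3 / N) * sum(P * log(pr))
  }
  num <- num_grad_matrix(J3, theta)
  expect_lt(max(abs(num - g)) / max(abs(num)), 1e-6)

  ## theta = 0, two balanced classes: uniform softmax closed form
  C2 <- 2; P2 <- matrix(0, C2, N); P2[cbind(rep(1:2, 6), 1:N)] <- 1
  g0 <- grad_theta(matrix(0, K, C2), A, P2, lambda3)
  expect_equal(g0, (lambda3 / N) * A %*% t(0.5 - P2), tolerance = 1e-12)

  ## softmax output equal to P: zero gradient (perfect classification limit)
  expect_equal(grad_theta(matrix(0, K, C2), A * 0, P2 * 0 + 0.5, lambda3),
               matrix(0, K, C2), tolerance = 1e-12)
})

test_that("unit-ball projection rescales only over-norm columns, idempotently", {
  D <- cbind(c(0.3, 0.4), c(0, 2), c(1, 0))
  Dp <- project_unit_columns(D)
  expect_equal(Dp[, 1], c(0.3, 0.4))          # interior point untouched
  expect_equal(Dp[, 2], c(0, 1))              # boundary projection, direction kept
  expect_equal(Dp[, 3], c(1, 0))
  expect_equal(project_unit_columns(Dp), Dp)  # idempotent
})

test_that("training is bit-reproducible and structurally sound", {
  ds <- training_fixture(seed = 13, n_per_class = 15)
  ctrl <- cdllc_control(max_outer_iter = 8)
  f1 <- cdllc_fit(ds$X, ds$labels, c(24, 12), k = 3, control = ctrl, seed = 13)
  f2 <- cdllc_fit(ds$X, ds$labels, c(24, 12), k = 3, control = ctrl, seed = 13)
  expect_identical(f1$model$dictionaries, f2$model$dictionaries)
  expect_identical(f1$model$A_M, f2$model$A_M)
  expect_identical(f1$model$theta, f2$model$theta)
  expect_identical(f1$trace, f2$trace)

  ## constraint maintenance after every iteration's projection
  for (Dm in f1$model$dictionaries) {
    expect_true(all(colSums(Dm^2) <= 1 + 1e-8))
  }
  ## trace bookkeeping
  expect_equal(nrow(f1$trace), 8L)
  expect_true(all(is.finite(f1$trace$J_total)))
  expect_equal(f1$trace$J_total,
               with(f1$trace, J1 + rank_term + J2 + J3), tolerance = 1e-12)
})

test_that("one iteration with a tiny dictionary rate does not increase the objective", {
  ## the code step backtracks and S/H are exact minimizers, so with a small
  ## enough dictionary step a full iteration descends (fixed graph within it)
  for (seed in 1:5) {
    ds <- training_fixture(seed = seed, n_per_class = 10)
    ctrl <- cdllc_control(max_outer_iter = 1, rate_dict = 1e-7, rate_theta = 1e-7,
                          theta_steps = 1)
    fit <- cdllc_fit(ds$X, ds$labels, c(24, 12), k = 3, lambda2 = 0,
                     control = ctrl, seed = seed)
    expect_lte(fit$trace$J_total[1],
               attr(fit$trace, "initial_objective") + 1e-9)
  }
})

test_that("the objective trace is attributed with a convergence reason", {
  ds <- training_fixture(seed = 3, n_per_class = 10)
  fit <- cdllc_fit(ds$X, ds$labels, c(24, 12), k = 3,
                   control = cdllc_control(max_outer_iter = 300, tol = 1e-2),
                   seed = 3)
  expect_true(attr(fit$trace, "converged"))
  expect_match(attr(fit$trace, "reason"), "relative change")
  expect_lt(nrow(fit$trace), 300)
})
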