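test_that("confusion matrices count and normalize correctly", {
  cm <- confusion(c(0, 0, 1, 1), c(0, 1, 1, 1), n_classes = 2)
  expect_equal(cm$counts, matrix(c(1L, 0L, 1L, 2L), 2, 2))
  expect_equal(cm$row_normalized, matrix(c(0.5, 0, 0.5, 1), 2, 2))

  y <- c(2, 0, 1, 1, 2, 0)
  cmp <- confusion(y, y, n_classes = 3)
  expect_equal(cmp$counts, diag(as.integer(table(y))))
  expect_equal(cmp$row_normalized, diag(3))
  expect_error(confusion(c(0, 3), c(0, 1), n_classes = 2), "0..1")
})

test_that("metrics reproduce hand-computed values", {
  ## binary example worked out by hand
  cm <- list(counts = matrix(c(8, 1, 2, 9), 2, 2))
  class(cm) <- "cdllc_confusion"
  m <- classification_metrics(cm)
  expect_equal(m$accuracy, 17 / 20)
  expect_equal(m$per_class$recall[1], 0.8)
  expect_equal(m$per_class$precision[1], 8 / 9)
  expect_equal(m$per_class$f1[1], 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9))

  ## macro recall of a row-normalized diagonal (0.9686, 0.9127, 0.9309):
  ## the mean of the per-class rates, 0.93740...
  counts <- round(rbind(c(0.9686, 0.0100, 0.0214),
                        c(0.0621, 0.9127, 0.0252),
                        c(0.0583, 0.0108, 0.9309)) * 10000)
  m3 <- classification_metrics(structure(list(counts = counts),
                                         class = "cdllc_confusion"))
  expect_equal(m3$recall, (0.9686 + 0.9127 + 0.9309) / 3, tolerance = 1e-12)
  expect_equal(m3$balance, m3$recall)

  ## perfect classifier: everything is 1
  mp <- classification_metrics(structure(list(counts = diag(5L) * 7L),
                                         class = "cdllc_confusion"))
  expect_equal(unlist(mp[c("accuracy", "recall", "precision", "f1", "balance")]),
               c(accuracy = 1, recall = 1, precision = 1, f1 = 1, balance = 1))
})

test_that("per-class F1 is the harmonic mean identity and micro-accuracy decomposes", {
  set.seed(60)
  for (rep in 1:20) {
    C <- sample(2:4, 1); n <- 60
    y <- sample(0:(C - 1), n, replace = TRUE)
    p <- ifelse(runif(n) < 0.7, y, sample(0:(C - 1), n, replace = TRUE))
    cm <- confusion(y, p, C)
    m <- classification_metrics(cm)
    pc <- m$per_class
    ok <- pc$precision + pc$recall > 0
    expect_equal(pc$f1[ok],
                 2 * pc$precision[ok] * pc$recall[ok] / (pc$precision + pc$recall)[ok])
    ## micro accuracy = prevalence-weighted mean of per-class recalls
    prev <- pc$support / sum(pc$support)
    expect_equal(m$accuracy, sum(prev * pc$recall), tolerance = 1e-12)
  }
})

test_that("stratified k-fold partitions are valid, balanced and seeded", {
  labels <- rep(0:2, times = c(40, 35, 25))
  folds <- stratified_kfold(labels, k = 5, seed = 9)
  test_all <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_equal(test_all, seq_along(labels))          # disjoint cover
  for (f in folds) {
    expect_equal(sort(c(f$train, f$test)), seq_along(labels))
    tab <- table(factor(labels[f$test], levels = 0:2))
    expect_true(all(abs(tab - c(8, 7, 5)) <= 1))     # proportions within 1
  }
  expect_identical(stratified_kfold(labels, k = 5, seed = 9), folds)
  expect_false(identical(stratified_kfold(labels, k = 5, seed = 10), folds))

  labels100 <- rep(0:1, each = 50)
  f100 <- stratified_kfold(labels100, k = 5, seed = 1)
  expect_true(all(vapply(f100, function(f) length(f$test), integer(1)) == 20L))
  expect_error(stratified_kfold(c(0, 0, 0, 1), k = 3, seed = 1), "class 1")
})

test_that("the inner 70/30 split has exact stratified sizes", {
  ## an 80-sample training fold splits into exactly 56 train / 24 validation
  labels <- rep(0:2, times = c(30, 28, 22))
  sp <- stratified_split(labels, train_frac = 0.7, seed = 4)
  expect_length(sp$train, 56L)
  expect_length(sp$val, 24L)
  expect_equal(sort(c(sp$train, sp$val)), seq_along(labels))
  ## stratification: per-class validation counts apportioned within 1 sample
  tab <- table(factor(labels[sp$val], levels = 0:2))
  expect_true(all(abs(tab - 0.3 * c(30, 28, 22)) <= 1))
})

test_that("the lambda grid enumerates the documented combinations", {
  g5 <- c(0.001, 0.01, 0.1, 1, 10)
  tied <- lambda_grid(g5, mode = "tied")
  expect_equal(nrow(tied), 75L)                      # 25 per slice, 3 slices
  expect_equal(as.vector(table(tied$slice)), rep(25L, 3))
  expect_true(all(tied$lambda1 %in% g5 & tied$lambda2 %in% g5 & tied$lambda3 %in% g5))
  expect_true(all(tied$lambda1[tied$slice == "l1=l2"] ==
                  tied$lambda2[tied$slice == "l1=l2"]))
  expect_equal(sort(unique(tied$lambda3)), g5)
  full <- lambda_grid(g5, mode = "full")
  expect_equal(nrow(full), 125L)
})

test_that("grid search returns the single point of a degenerate grid", {
  ds <- make_deep_sparse_dataset(12, c(12, 6), 3, 20, 2, 0.05, seed = 2)
  gs <- grid_search_lambdas(ds$X, ds$labels, c(12, 6), grid = 0.1, mode = "tied",
                            k = 1, control = cdllc_control(max_outer_iter = 5),
                            seed = 2)
  expect_equal(unname(gs$best), c(0.1, 0.1, 0.1))
  expect_equal(nrow(gs$table), 1L)
})

test_that("grid search is reproducible and breaks ties lexicographically", {
  ds <- make_deep_sparse_dataset(12, c(12, 6), 3, 20, 2, 0.05, seed = 2)
  ctrl <- cdllc_control(max_outer_iter = 5)
  g1 <- grid_search_lambdas(ds$X, ds$labels, c(12, 6), grid = c(0.01, 1),
                            mode = "tied", k = 1, control = ctrl, seed = 2)
  g2 <- grid_search_lambdas(ds$X, ds$labels, c(12, 6), grid = c(0.01, 1),
                            mode = "tied", k = 1, control = ctrl, seed = 2)
  expect_identical(g1$table, g2$table)
  expect_false(any(g1$table$failed))
  ## tie-break: the winner is lexicographically minimal among the best rows
  best_acc <- max(g1$table$val_accuracy)
  cand <- g1$table[g1$table$val_accuracy == best_acc, ]
  cand <- cand[order(cand$lambda1, cand$lambda2, cand$lambda3), ]
  expect_equal(unname(g1$best),
               unname(unlist(cand[1, c("lambda1", "lambda2", "lambda3")])))
})

test_that("cross-validation aggregates per-fold metrics for both splits", {
  ds <- make_deep_sparse_dataset(12, c(12, 6), 3, 15, 2, 0.05, seed = 31)
  cv <- cross_validate(ds$X, ds$labels, c(12, 6), folds = 3, repeats = 2,
                       k = 1, control = cdllc_control(max_outer_iter = 10),
                       seed = 31)
  expect_equal(nrow(cv$per_fold), 2 * 3 * 2)         # repeats x folds x splits
  expect_setequal(unique(cv$per_fold$split), c("training", "test"))
  expect_true(all(cv$per_fold$accuracy >= 0 & cv$per_fold$accuracy <= 1))
  expect_equal(nrow(cv$summary), 10L)
  ## every sample appears in exactly one test fold per repeat
  for (r in 1:2) {
    folds <- stratified_kfold(ds$labels, k = 3, seed = 31 + 1000 * r)
    expect_equal(sort(unlist(lapply(folds, `[[`, "test"))), seq_along(ds$labels))
  }
})
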