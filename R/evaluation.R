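#' Confusion matrix
#'
#' @param y_true,y_pred Integer class ids in `0..C-1`.
#' @param n_classes Number of classes `C`.
#' @return Object of class `"cdllc_confusion"`: list with `counts` (`C x C`
#'   integer matrix, rows = true class, columns = predicted class) and
#'   `row_normalized` (rows divided by their sums; rows with zero support are
#'   all zero and listed in the `empty_rows` attribute).
#' @export
confusion <- function(y_true, y_pred, n_classes) {
  n_classes <- check_count(n_classes, "n_classes")
  y_true <- check_labels(y_true, n_classes, "y_true")
  y_pred <- check_labels(y_pred, n_classes, "y_pred")
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  }
  counts <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(y_true)) {
    counts[y_true[i] + 1L, y_pred[i] + 1L] <- counts[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  }
  rs <- rowSums(counts)
  rn <- counts / ifelse(rs == 0, 1, rs)
  structure(list(counts = counts, row_normalized = rn),
            class = "cdllc_confusion", empty_rows = which(rs == 0))
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, macro-averaged recall, precision and F1, and the balance metric
#' (balanced accuracy, i.e. macro recall — used as a surrogate for the
#' "balance loss" reported in the brain-tumor classification literature, which
#' is cited there without a formula). Per-class precision and recall use the
#' convention 0 for empty denominators; per-class F1 is
#' `2 P_c R_c / (P_c + R_c)` (0 when `P_c + R_c = 0`) and the macro F1 is the
#' unweighted mean of the per-class values.
#'
#' @param cm A `"cdllc_confusion"` object or a plain counts matrix.
#' @return List with `accuracy`, `recall`, `precision`, `f1`, `balance`
#'   (all in `[0, 1]`) and `per_class` (data frame of per-class values).
#' @export
classification_metrics <- function(cm) {
  counts <- if (inherits(cm, "cdllc_confusion")) cm$counts else check_matrix(cm, "cm")
  if (nrow(counts) != ncol(counts)) stop("confusion matrix must be square", call. = FALSE)
  total <- sum(counts)
  if (total == 0) stop("confusion matrix is empty", call. = FALSE)
  C <- nrow(counts)
  tp <- diag(counts)
  rs <- rowSums(counts)  # support per true class
  cs <- colSums(counts)  # predictions per class
  recall <- ifelse(rs > 0, tp / rs, 0)
  precision <- ifelse(cs > 0, tp / cs, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  list(accuracy = sum(tp) / total,
       recall = mean(recall),
       precision = mean(precision),
       f1 = mean(f1),
       balance = mean(recall),
       per_class = data.frame(class = 0:(C - 1L), recall = recall,
                              precision = precision, f1 = f1, support = rs))
}

#' Stratified k-fold partition
#'
#' Splits sample indices into `k` test folds preserving per-class proportions
#' within one sample; deterministic given `seed`.
#'
#' @param labels Integer class ids.
#' @param k Number of folds (`>= 2`); every class must have at least `k`
#'   members.
#' @param seed Integer seed.
#' @return List of `k` lists, each with `train` and `test` index vectors
#'   (1-based). Test folds are pairwise disjoint and cover all samples.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  labels <- check_labels(labels)
  k <- check_count(k, "k", min = 2L)
  seed <- check_count(seed, "seed", min = 0L)
  tab <- table(labels)
  small <- names(tab)[tab < k]
  if (length(small) > 0L) {
    stop(sprintf("class %s has fewer than k = %d samples", small[1], k), call. = FALSE)
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  n <- length(labels)
  fold_of <- integer(n)
  for (cls in sort(unique(labels))) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    fold_of[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f) {
    list(train = which(fold_of != f), test = which(fold_of == f))
  })
}

#' Stratified train/validation split
#'
#' Splits indices into a training and a validation part with per-class
#' stratification. The validation size is exactly `round((1 - train_frac) * n)`
#' in total, apportioned to classes by largest remainder (so an 80-sample set
#' with `train_frac = 0.7` yields exactly 56 training and 24 validation
#' samples).
#'
#' @param labels Integer class ids.
#' @param train_frac Fraction assigned to training (default 0.7).
#' @param seed Integer seed.
#' @return List with `train` and `val` index vectors.
#' @export
stratified_split <- function(labels, train_frac = 0.7, seed = 1L) {
  labels <- check_labels(labels)
  stopifnot(train_frac > 0, train_frac < 1)
  seed <- check_count(seed, "seed", min = 0L)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  n <- length(labels)
  classes <- sort(unique(labels))
  n_c <- vapply(classes, function(cls) sum(labels == cls), integer(1))
  target_val <- round((1 - train_frac) * n)
  ideal <- (1 - train_frac) * n_c
  base <- floor(ideal)
  rem <- target_val - sum(base)
  if (rem > 0) {
    ord <- order(ideal - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  } else if (rem < 0) {
    ord <- order(ideal - base)
    take <- ord[base[ord] > 0][seq_len(-rem)]
    base[take] <- base[take] - 1L
  }
  val <- integer(0)
  for (ci in seq_along(classes)) {
    idx <- which(labels == classes[ci])
    idx <- idx[sample.int(length(idx))]
    val <- c(val, idx[seq_len(base[ci])])
  }
  val <- sort(val)
  list(train = setdiff(seq_len(n), val), val = val)
}

#' Enumerate a lambda grid
#'
#' `mode = "full"` crosses the grid over all three regularization weights;
#' `mode = "tied"` enumerates the three tied slices used for parameter
#' analysis (`lambda1 = lambda2`, `lambda2 = lambda3`, `lambda1 = lambda3`),
#' each slice crossing the grid over the tied pair and the free parameter
#' (`length(grid)^2` combinations per slice).
#'
#' @param grid Numeric vector of candidate values (default
#'   `c(0.001, 0.01, 0.1, 1, 10)`).
#' @param mode `"tied"` or `"full"`.
#' @return Data frame with columns `lambda1`, `lambda2`, `lambda3`, `slice`.
#' @export
lambda_grid <- function(grid = c(0.001, 0.01, 0.1, 1, 10),
                        mode = c("tied", "full")) {
  mode <- match.arg(mode)
  stopifnot(length(grid) >= 1L, all(grid > 0))
  if (mode == "full") {
    g <- expand.grid(lambda1 = grid, lambda2 = grid, lambda3 = grid,
                     KEEP.OUT.ATTRS = FALSE)
    g$slice <- "full"
    return(g)
  }
  tied <- expand.grid(a = grid, b = grid, KEEP.OUT.ATTRS = FALSE)
  rbind(
    data.frame(lambda1 = tied$a, lambda2 = tied$a, lambda3 = tied$b, slice = "l1=l2"),
    data.frame(lambda1 = tied$b, lambda2 = tied$a, lambda3 = tied$a, slice = "l2=l3"),
    data.frame(lambda1 = tied$a, lambda2 = tied$b, lambda3 = tied$a, slice = "l1=l3")
  )
}

#' Grid search over the regularization weights
#'
#' Splits the data 70/30 (stratified), trains one model per grid point on the
#' 70% part, scores validation accuracy, and returns the winning
#' `(lambda1, lambda2, lambda3)` with the full validation table. Ties are
#' broken toward smaller `(lambda1, lambda2, lambda3)` lexicographically.
#' Grid points whose training fails are marked failed (`NA` accuracy) rather
#' than aborting the search.
#'
#' @param X `d x N` feature matrix; `labels` integer class ids.
#' @param labels Integer class ids `0..C-1`.
#' @param layer_sizes Passed to [cdllc_fit()].
#' @param grid Candidate values for each lambda.
#' @param mode `"tied"` or `"full"` (see [lambda_grid()]).
#' @param train_frac Inner training fraction (default 0.7).
#' @param seed Integer seed (split and training).
#' @param ... Further arguments to [cdllc_fit()] (e.g. `k`, `sigma`,
#'   `control`).
#' @return List with `best` (named vector `lambda1..3`), `table` (data frame
#'   with a `val_accuracy` and a `failed` column), and `seed`.
#' @export
grid_search_lambdas <- function(X, labels, layer_sizes,
                                grid = c(0.001, 0.01, 0.1, 1, 10),
                                mode = c("tied", "full"), train_frac = 0.7,
                                seed = 1L, ...) {
  mode <- match.arg(mode)
  pts <- unique(lambda_grid(grid, mode)[, c("lambda1", "lambda2", "lambda3")])
  split <- stratified_split(labels, train_frac = train_frac, seed = seed)
  Xtr <- X[, split$train, drop = FALSE]; ltr <- labels[split$train]
  Xva <- X[, split$val, drop = FALSE]; lva <- labels[split$val]

  pts$val_accuracy <- NA_real_
  pts$failed <- FALSE
  for (i in seq_len(nrow(pts))) {
    res <- tryCatch({
      fit <- cdllc_fit(Xtr, ltr, layer_sizes,
                       lambda1 = pts$lambda1[i], lambda2 = pts$lambda2[i],
                       lambda3 = pts$lambda3[i], seed = seed, ...)
      pred <- predict(fit$model, Xva)
      mean(pred$label == lva)
    }, error = function(e) NA_real_)
    pts$val_accuracy[i] <- res
    pts$failed[i] <- is.na(res)
  }
  ok <- which(!pts$failed)
  if (length(ok) == 0L) stop("every grid point failed to train", call. = FALSE)
  best_acc <- max(pts$val_accuracy[ok])
  cand <- pts[ok, ][pts$val_accuracy[ok] == best_acc, , drop = FALSE]
  cand <- cand[order(cand$lambda1, cand$lambda2, cand$lambda3), , drop = FALSE]
  best <- c(lambda1 = cand$lambda1[1], lambda2 = cand$lambda2[1],
            lambda3 = cand$lambda3[1])
  list(best = best, table = pts, seed = seed)
}

#' Cross-validated evaluation
#'
#' Runs `repeats` rounds of stratified `folds`-fold cross-validation. Per
#' fold, the regularization weights are selected by [grid_search_lambdas()] on
#' an inner 70/30 split of the training fold (skipped when the grid has a
#' single point), a final model is trained on the whole training fold, and the
#' five metrics of [classification_metrics()] are recorded for both the
#' training and the test split of the fold.
#'
#' @param X `d x N` feature matrix; `labels` integer class ids.
#' @param labels Integer class ids `0..C-1`.
#' @param layer_sizes Passed to [cdllc_fit()].
#' @param folds,repeats Cross-validation shape (defaults 5 folds, 2 repeats).
#' @param grid Lambda candidates; a single value fixes
#'   `lambda1 = lambda2 = lambda3` without an inner search. `NULL` uses the
#'   [cdllc_fit()] defaults without a search.
#' @param mode Grid mode for the inner search.
#' @param seed Integer seed.
#' @param ... Further arguments to [cdllc_fit()].
#' @return Object of class `"cdllc_cv"`: list with `per_fold` (data frame:
#'   repeat, fold, split, the five metrics, selected lambdas) and `summary`
#'   (mean and sd of each metric by split).
#' @export
cross_validate <- function(X, labels, layer_sizes, folds = 5L, repeats = 2L,
                           grid = NULL, mode = c("tied", "full"), seed = 1L, ...) {
  mode <- match.arg(mode)
  labels <- check_labels(labels)
  folds <- check_count(folds, "folds", min = 2L)
  repeats <- check_count(repeats, "repeats")
  seed <- check_count(seed, "seed", min = 0L)
  C <- length(unique(labels))

  rows <- list()
  for (r in seq_len(repeats)) {
    fold_list <- stratified_kfold(labels, k = folds, seed = seed + 1000L * r)
    for (f in seq_len(folds)) {
      tr <- fold_list[[f]]$train; te <- fold_list[[f]]$test
      fold_seed <- seed + 1000L * r + f
      if (!is.null(grid) && length(grid) > 1L) {
        gs <- grid_search_lambdas(X[, tr, drop = FALSE], labels[tr], layer_sizes,
                                  grid = grid, mode = mode, seed = fold_seed, ...)
        lam <- gs$best
      } else {
        lam <- NULL
      }
      fit_args <- list(X = X[, tr, drop = FALSE], labels = labels[tr],
                       layer_sizes = layer_sizes, seed = fold_seed, ...)
      if (!is.null(lam)) {
        fit_args$lambda1 <- lam[["lambda1"]]
        fit_args$lambda2 <- lam[["lambda2"]]
        fit_args$lambda3 <- lam[["lambda3"]]
      } else if (!is.null(grid)) {
        fit_args$lambda1 <- fit_args$lambda2 <- fit_args$lambda3 <- grid[1]
        lam <- c(lambda1 = grid[1], lambda2 = grid[1], lambda3 = grid[1])
      }
      fit <- do.call(cdllc_fit, fit_args)
      for (split in c("training", "test")) {
        idx <- if (split == "training") tr else te
        pred <- predict(fit$model, X[, idx, drop = FALSE])
        m <- classification_metrics(confusion(labels[idx], pred$label, C))
        rows[[length(rows) + 1L]] <- data.frame(
          rep = r, fold = f, split = split, accuracy = m$accuracy,
          recall = m$recall, precision = m$precision, f1 = m$f1,
          balance = m$balance,
          lambda1 = if (is.null(lam)) NA_real_ else lam[["lambda1"]],
          lambda2 = if (is.null(lam)) NA_real_ else lam[["lambda2"]],
          lambda3 = if (is.null(lam)) NA_real_ else lam[["lambda3"]])
      }
    }
  }
  per_fold <- do.call(rbind, rows)
  metrics <- c("accuracy", "recall", "precision", "f1", "balance")
  summary <- do.call(rbind, lapply(c("training", "test"), function(s) {
    sub <- per_fold[per_fold$split == s, metrics, drop = FALSE]
    data.frame(split = s, metric = metrics,
               mean = vapply(sub, mean, numeric(1)),
               sd = vapply(sub, stats::sd, numeric(1)), row.names = NULL)
  }))
  structure(list(per_fold = per_fold, summary = summary, folds = folds,
                 repeats = repeats, seed = seed),
            class = "cdllc_cv")
}

#' @export
print.cdllc_cv <- function(x, ...) {
  cat(sprintf("Cross-validation: %d folds x %d repeats\n", x$folds, x$repeats))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
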