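#' Generate a synthetic dataset from a known multi-layer dictionary chain
#'
#' Draws a random chain of unit-column dictionaries `D_1 .. D_M`, class-block
#' structured sparse nonnegative last-layer codes `A_M`, and produces
#' `X = D_1 phi(D_2 phi(... phi(D_M A_M)))` plus i.i.d. Gaussian noise, where
#' `phi` is the ReLU nonlinearity (no nonlinearity is applied for a
#' single-layer chain). The last-layer atoms are partitioned into `n_classes`
#' contiguous equal blocks and each sample's nonzeros are drawn only from its
#' own class block, so classes occupy disjoint subspaces of the code space and
#' the dataset is a well-posed recovery and classification target.
#'
#' @param d Feature dimension (rows of `X`).
#' @param layer_sizes Integer vector `K_1 .. K_M` of dictionary sizes per
#'   layer; each must be at least `n_classes` and the last must be divisible
#'   by `n_classes`.
#' @param n_classes Number of classes `C` (labels are `0..C-1`).
#' @param n_per_class Samples generated per class.
#' @param sparsity Number of nonzeros per column of the last-layer code; must
#'   not exceed the per-class atom block size `K_M / C`.
#' @param noise_sigma Standard deviation of the additive Gaussian noise
#'   (`>= 0`).
#' @param seed Integer seed; the same seed reproduces `X` bit-identically.
#' @param dictionaries Optional list of generating dictionaries from a
#'   previous call (`$true_dictionaries`). When supplied, only the codes and
#'   noise are redrawn, so a new seed produces fresh samples from the *same*
#'   generating model — the natural way to draw a held-out test set.
#'
#' @return An object of class `"cdllc_synth"`: a list with elements `X`
#'   (`d x N` matrix, `N = n_classes * n_per_class`), `labels` (length-`N`
#'   integer vector in `0..C-1`), `true_dictionaries` (list of `M` unit-column
#'   matrices), `true_codes` (`K_M x N` nonnegative sparse matrix),
#'   `noise_sigma`, and `seed`.
#'
#' @details Dictionary entries are standard normal with columns scaled to unit
#'   norm (so they satisfy the unit-ball feasibility constraint of the model).
#'   Code coefficients are uniform on `[0.5, 1.5]` — positive and bounded away
#'   from zero — so that signal survives the ReLU chain.
#'
#' @seealso [make_toy_tumor_images()], [cdllc_fit()]
#' @export
#' @examples
#' ds <- make_deep_sparse_dataset(d = 20, layer_sizes = c(24, 12), n_classes = 3,
#'                                n_per_class = 10, sparsity = 3, noise_sigma = 0,
#'                                seed = 1)
#' dim(ds$X)
#' table(ds$labels)
make_deep_sparse_dataset <- function(d, layer_sizes, n_classes, n_per_class,
                                     sparsity, noise_sigma = 0, seed = 1L,
                                     dictionaries = NULL) {
  d <- check_count(d, "d")
  n_classes <- check_count(n_classes, "n_classes")
  n_per_class <- check_count(n_per_class, "n_per_class")
  sparsity <- check_count(sparsity, "sparsity")
  if (length(layer_sizes) < 1L) stop("`layer_sizes` must have at least one entry", call. = FALSE)
  layer_sizes <- vapply(seq_along(layer_sizes), function(i) {
    check_count(layer_sizes[i], sprintf("layer_sizes[%d]", i))
  }, integer(1))
  if (any(layer_sizes < n_classes)) {
    stop("every entry of `layer_sizes` must be >= `n_classes`", call. = FALSE)
  }
  M <- length(layer_sizes)
  K_M <- layer_sizes[M]
  if (K_M %% n_classes != 0L) {
    stop("the last entry of `layer_sizes` must be divisible by `n_classes`", call. = FALSE)
  }
  block <- K_M %/% n_classes
  if (sparsity > block) {
    stop(sprintf("`sparsity` (%d) exceeds the per-class atom block size (%d)",
                 sparsity, block), call. = FALSE)
  }
  if (!is.numeric(noise_sigma) || length(noise_sigma) != 1L || noise_sigma < 0) {
    stop("`noise_sigma` must be a single real >= 0", call. = FALSE)
  }
  seed <- check_count(seed, "seed", min = 0L)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  dims_in <- c(d, layer_sizes[-M])
  if (is.null(dictionaries)) {
    dicts <- lapply(seq_len(M), function(m) {
      normalize_columns(matrix(stats::rnorm(dims_in[m] * layer_sizes[m]),
                               dims_in[m], layer_sizes[m]))
    })
  } else {
    stopifnot(is.list(dictionaries), length(dictionaries) == M)
    for (m in seq_len(M)) {
      if (nrow(dictionaries[[m]]) != dims_in[m] ||
          ncol(dictionaries[[m]]) != layer_sizes[m]) {
        stop(sprintf("supplied dictionary %d has the wrong shape", m), call. = FALSE)
      }
    }
    dicts <- dictionaries
  }

  N <- n_classes * n_per_class
  labels <- rep(0:(n_classes - 1L), each = n_per_class)
  A <- matrix(0, K_M, N)
  for (i in seq_len(N)) {
    blk <- labels[i] * block
    idx <- blk + sample.int(block, sparsity)
    A[idx, i] <- stats::runif(sparsity, 0.5, 1.5)
  }

  X0 <- deep_forward_compose(dicts, A)
  X <- X0 + if (noise_sigma > 0) {
    matrix(stats::rnorm(d * N, sd = noise_sigma), d, N)
  } else 0

  structure(list(X = X, labels = labels, true_dictionaries = dicts,
                 true_codes = A, noise_sigma = noise_sigma, seed = seed),
            class = "cdllc_synth")
}

## Noiseless forward composition D_1 phi(D_2 phi(... phi(D_M A))) with ReLU;
## a single layer applies no nonlinearity.
deep_forward_compose <- function(dicts, A) {
  M <- length(dicts)
  cur <- A
  if (M > 1L) {
    for (m in M:2) cur <- pmax(dicts[[m]] %*% cur, 0)
  }
  dicts[[1L]] %*% cur
}

#' Generate toy labeled grayscale images with class-specific texture
#'
#' Produces small synthetic grayscale "tumor slice" images in `[0, 1]` whose
#' classes differ in blob count, blob radius, and background texture variance,
#' so that the ten first- and second-order texture features computed by
#' [texture_features()] separate the classes. This stands in for real MR data
#' in tests and examples; it makes no attempt at MR physics.
#'
#' @param n_per_class Images per class.
#' @param image_size Side length in pixels (`>= 16`).
#' @param n_classes Number of classes, between 2 and 5.
#' @param seed Integer seed; identical seeds give pixel-identical images.
#'
#' @return A list with `images` (list of `image_size x image_size` matrices
#'   with values in `[0, 1]`) and `labels` (integer vector in `0..C-1`).
#' @export
#' @examples
#' toy <- make_toy_tumor_images(n_per_class = 4, image_size = 32, n_classes = 3,
#'                              seed = 1)
#' length(toy$images)
make_toy_tumor_images <- function(n_per_class, image_size = 64L, n_classes = 3L,
                                  seed = 1L) {
  n_per_class <- check_count(n_per_class, "n_per_class")
  image_size <- check_count(image_size, "image_size", min = 16L)
  n_classes <- check_count(n_classes, "n_classes", min = 2L)
  if (n_classes > 5L) stop("`n_classes` must be in 2..5", call. = FALSE)
  seed <- check_count(seed, "seed", min = 0L)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  ## Per-class pattern parameters: blob count, blob radius (fraction of the
  ## image side), background texture standard deviation.
  n_blobs <- c(2L, 6L, 12L, 20L, 30L)[seq_len(n_classes)]
  radius_frac <- c(0.16, 0.09, 0.06, 0.045, 0.035)[seq_len(n_classes)]
  bg_sd <- c(0.02, 0.07, 0.12, 0.17, 0.22)[seq_len(n_classes)]

  rows <- matrix(seq_len(image_size), image_size, image_size)
  cols <- t(rows)

  labels <- rep(0:(n_classes - 1L), each = n_per_class)
  images <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    c0 <- labels[i] + 1L
    img <- 0.25 + matrix(stats::rnorm(image_size^2, sd = bg_sd[c0]),
                         image_size, image_size)
    r0 <- radius_frac[c0] * image_size
    for (b in seq_len(n_blobs[c0])) {
      cy <- stats::runif(1, 0.15, 0.85) * image_size
      cx <- stats::runif(1, 0.15, 0.85) * image_size
      r <- r0 * stats::runif(1, 0.8, 1.2)
      amp <- stats::runif(1, 0.45, 0.65)
      img <- img + amp * exp(-((rows - cy)^2 + (cols - cx)^2) / (2 * r^2))
    }
    images[[i]] <- pmin(pmax(img, 0), 1)
  }
  list(images = images, labels = labels)
}
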