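#' Gray-level co-occurrence matrix (GLCM)
#'
#' Quantizes an image to `levels` equal-width gray bins over its min-max range
#' and accumulates symmetric co-occurrence counts over the given pixel offsets
#' (each offset is counted together with its opposite), normalized to a joint
#' probability matrix.
#'
#' @param image Numeric matrix of pixel intensities (finite values).
#' @param levels Number of gray levels (`>= 2`).
#' @param offsets List of integer pairs `c(dr, dc)`; defaults to the four
#'   standard Haralick directions at distance 1:
#'   `(0,1), (1,0), (1,1), (1,-1)`.
#'
#' @return A `levels x levels` matrix with nonnegative entries summing to 1.
#'   A constant image (zero intensity range) quantizes entirely to bin 1, so
#'   its GLCM has a single unit entry at `[1, 1]`.
#' @export
#' @examples
#' img <- matrix(c(0, 1, 0, 1), 2, 2)
#' glcm(img, levels = 2, offsets = list(c(0, 1)))
glcm <- function(image, levels = 8L,
                 offsets = list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
  image <- check_matrix(image, "image")
  levels <- check_count(levels, "levels", min = 2L)
  if (length(offsets) == 0L) stop("`offsets` must be nonempty", call. = FALSE)

  rng <- range(image)
  if (rng[2] > rng[1]) {
    q <- floor((image - rng[1]) / (rng[2] - rng[1]) * levels)
    q[q >= levels] <- levels - 1L
  } else {
    q <- matrix(0L, nrow(image), ncol(image))
  }
  q <- q + 1L  # bins 1..levels

  nr <- nrow(q); nc <- ncol(q)
  P <- matrix(0, levels, levels)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    if (length(r1) == 0L || length(c1) == 0L) next
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dr, c1 + dc, drop = FALSE]
    ## symmetric: count (a, b) and (b, a)
    tab <- table(factor(a, levels = 1:levels), factor(b, levels = 1:levels))
    P <- P + tab + t(tab)
  }
  s <- sum(P)
  if (s == 0) stop("image too small for the given offsets", call. = FALSE)
  P / s
}

#' First- and second-order statistical texture features of a grayscale image
#'
#' Computes the ten texture features commonly used for MR image
#' classification: first-order intensity statistics (mean, variance, standard
#' deviation, skewness, kurtosis) from the raw pixel values, and second-order
#' Haralick statistics (contrast, energy, entropy, correlation, homogeneity)
#' from the symmetric [glcm()].
#'
#' @param image Numeric matrix of pixel intensities; must be nonempty.
#' @param levels Gray levels for the co-occurrence matrix.
#' @param offsets Offsets passed to [glcm()].
#'
#' @return Named numeric vector with elements `mean`, `variance`,
#'   `standard_deviation`, `skewness`, `kurtosis`, `contrast`, `energy`,
#'   `entropy`, `correlation`, `homogeneity`.
#'
#' @details Variance is the population variance; skewness and excess kurtosis
#'   are the Fisher moment ratios, defined as 0 for a constant image. Entropy
#'   uses the natural logarithm with `0 * log 0 = 0`. GLCM correlation is
#'   defined as 0 when either marginal standard deviation is 0.
#' @export
texture_features <- function(image, levels = 8L,
                             offsets = list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
  image <- check_matrix(image, "image")
  if (length(image) == 0L) stop("`image` must be nonempty", call. = FALSE)
  x <- as.vector(image)
  n <- length(x)
  mu <- mean(x)
  v <- mean((x - mu)^2)
  sdev <- sqrt(v)
  if (sdev > 0) {
    skew <- mean((x - mu)^3) / sdev^3
    kurt <- mean((x - mu)^4) / sdev^4 - 3
  } else {
    skew <- 0
    kurt <- 0
  }

  P <- glcm(image, levels = levels, offsets = offsets)
  i <- row(P); j <- col(P)
  contrast <- sum(P * (i - j)^2)
  energy <- sum(P^2)
  pos <- P > 0
  entropy <- -sum(P[pos] * log(P[pos]))
  homogeneity <- sum(P / (1 + abs(i - j)))
  pi_m <- rowSums(P); pj_m <- colSums(P)
  mu_i <- sum(seq_along(pi_m) * pi_m)
  mu_j <- sum(seq_along(pj_m) * pj_m)
  sd_i <- sqrt(sum((seq_along(pi_m) - mu_i)^2 * pi_m))
  sd_j <- sqrt(sum((seq_along(pj_m) - mu_j)^2 * pj_m))
  correlation <- if (sd_i > 0 && sd_j > 0) {
    sum((i - mu_i) * (j - mu_j) * P) / (sd_i * sd_j)
  } else 0

  c(mean = mu, variance = v, standard_deviation = sdev, skewness = skew,
    kurtosis = kurt, contrast = contrast, energy = energy, entropy = entropy,
    correlation = correlation, homogeneity = homogeneity)
}

#' Texture feature matrix for a list of images
#'
#' Applies [texture_features()] to each image and assembles the column-per-
#' sample feature matrix used by the rest of the package.
#'
#' @param images List of numeric matrices.
#' @inheritParams texture_features
#' @return A `10 x N` matrix; rows are named after the features.
#' @export
texture_feature_matrix <- function(images, levels = 8L,
                                   offsets = list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
  stopifnot(is.list(images), length(images) > 0L)
  vapply(images, texture_features, numeric(10), levels = levels, offsets = offsets)
}
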