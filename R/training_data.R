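# Separable labeled feature generators for filter training and
# benchmarking.  Classes are Gaussian in feature space with mean blocks
# 3 standard deviations apart, so a correctly implemented learner must
# find a clean decision boundary; shuffled-label controls on the same
# draws should fall to chance.

#' Simulate separable split-read feature vectors
#'
#' Draws `n` vectors over the 22 inter-signature features, split evenly
#' across the six classes; each class elevates its own block of three
#' features by `sep` standard deviations.
#'
#' @param n Total vectors (default 10000).
#' @param sep Class-mean separation in sd units (default 3).
#' @param seed Integer seed.
#' @return List with `features` (n x 22 named matrix) and `labels`.
#' @export
simulate_rf_training_set <- function(n = 10000, sep = 3, seed = 1) {
  set.seed(seed)
  classes <- RF_CLASSES
  labels <- sample(rep(classes, length.out = n))
  x <- matrix(stats::rnorm(n * 22), n, 22,
              dimnames = list(NULL, INTER_FEATURES))
  for (k in seq_along(classes)) {
    block <- ((k - 1L) * 3L + 1L):((k - 1L) * 3L + 3L)
    x[labels == classes[k], block] <- x[labels == classes[k], block] + sep
  }
  list(features = x, labels = labels)
}

#' Simulate separable cluster feature matrices
#'
#' Draws `n` clusters with depths uniform on `[depth_range]`; member
#' rows are Gaussian around a class-specific mean (blocks of five
#' features elevated by `sep` sd).  Matrices are normalized with global
#' bounds and zero-filled to 100 x 25.
#'
#' @param n Total matrices (default 5000).
#' @param sep Class-mean separation in sd units (default 3).
#' @param depth_range Cluster depth range (default `c(3, 60)`).
#' @param seed Integer seed.
#' @return List with `matrices` (list of 100 x 25), `labels`, `bounds`.
#' @export
simulate_cnn_training_set <- function(n = 5000, sep = 3,
                                      depth_range = c(3, 60), seed = 1) {
  set.seed(seed)
  classes <- CNN_CLASSES
  labels <- sample(rep(classes, length.out = n))
  depths <- sample(depth_range[1]:depth_range[2], n, replace = TRUE)
  raw <- vector("list", n)
  for (i in seq_len(n)) {
    k <- match(labels[i], classes)
    mu <- numeric(25)
    mu[((k - 1L) * 5L + 1L):((k - 1L) * 5L + 5L)] <- sep
    raw[[i]] <- matrix(stats::rnorm(depths[i] * 25), depths[i], 25,
                       dimnames = list(NULL, INTRA_FEATURES)) +
      matrix(mu, depths[i], 25, byrow = TRUE)
  }
  bounds <- feature_bounds(do.call(rbind, raw))
  matrices <- lapply(raw, function(m) {
    build_cluster_matrix(m, seq_len(nrow(m)), 1, bounds)
  })
  list(matrices = matrices, labels = labels, bounds = bounds)
}
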