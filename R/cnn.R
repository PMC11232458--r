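# Convolutional false-positive filter for intra-alignment signature
# clusters, applied after clustering.
#
# A cluster is encoded as a fixed (100, 25) matrix: one row per member
# signature (ordered by start, zero-filled beyond the cluster depth),
# one column per intra feature, min-max normalized with bounds frozen at
# training time.  The network is implemented directly with matrix
# algebra (im2col convolutions, max pooling with argmax routing, Adam).
# The first two convolution kernels span the full current width
# (3 x 25 on the input, 3 x 8 on the 8 feature maps it produces, giving
# 16 maps); the third is a width-1 kernel (3 x 1) sliding down each of
# the 16 columns with 2 filters.  Rows are halved by max pooling after
# every convolution; three fully connected layers (320 -> 256 -> 64 ->
# 3) with batch standardization and dropout produce the softmax over
# {DEL, INS, false}.

CNN_CLASSES <- c("DEL", "INS", "false")
CNN_ROWS <- 100L
CNN_COLS <- 25L

#' Build the fixed-size feature matrix for one cluster
#'
#' Rows are member signatures ordered by start coordinate; clusters
#' larger than 100 keep the 100 members whose starts are nearest the
#' consensus breakpoint; smaller clusters are zero-filled.  Features are
#' min-max normalized with `bounds` and clipped to `[0, 1]`.
#'
#' @param features Numeric matrix (members x 25 intra features).
#' @param starts Member start coordinates (orders the rows).
#' @param consensus Consensus start of the cluster (for truncation).
#' @param bounds Normalization bounds from [feature_bounds()].
#' @return A 100 x 25 matrix with attribute `depth` (original member
#'   count, capped at 100).
#' @export
build_cluster_matrix <- function(features, starts, consensus, bounds) {
  stopifnot(nrow(features) >= 1L, ncol(features) == CNN_COLS,
            length(starts) == nrow(features))
  if (nrow(features) > CNN_ROWS) {
    dev <- abs(starts - consensus)
    keep <- order(dev, seq_along(starts))[seq_len(CNN_ROWS)]
    keep <- sort(keep)
    features <- features[keep, , drop = FALSE]
    starts <- starts[keep]
  }
  features <- features[order(starts), , drop = FALSE]
  xn <- normalize_features(features, bounds)
  depth <- nrow(xn)
  out <- matrix(0, CNN_ROWS, CNN_COLS,
                dimnames = list(NULL, colnames(features)))
  out[seq_len(depth), ] <- xn
  attr(out, "depth") <- depth
  out
}

#' Augment a low-depth cluster by row truncation
#'
#' For clusters of depth 1-20, each member is used as a starting row and
#' a window size smaller than the cluster depth is drawn uniformly; the
#' window wraps within the member list.  Depth-1 clusters yield the
#' single untruncated matrix.
#'
#' @param features Raw member feature matrix (depth x 25, start-ordered).
#' @param starts Member start coordinates.
#' @param consensus Consensus start.
#' @param bounds Normalization bounds.
#' @param rng_seed Seed making the window draws reproducible.
#' @return List of 100 x 25 matrices (one per starting member).
#' @export
augment_low_depth <- function(features, starts, consensus, bounds,
                              rng_seed = 1) {
  depth <- nrow(features)
  if (depth < 1L || depth > 20L) {
    stop("augmentation applies to cluster depths in [1, 20]")
  }
  if (depth == 1L) {
    return(list(build_cluster_matrix(features, starts, consensus, bounds)))
  }
  set.seed(rng_seed)
  lapply(seq_len(depth), function(i) {
    w <- sample.int(depth - 1L, 1)
    rows <- ((i - 1L + seq_len(w) - 1L) %% depth) + 1L
    build_cluster_matrix(features[rows, , drop = FALSE], starts[rows],
                         consensus, bounds)
  })
}

# --- network ---------------------------------------------------------------

# im2col for kernels spanning the full width: input B x R x W ->
# (B*(R-2)) x (3*W), patches over rows with kernel height 3
im2col3 <- function(x) {
  d <- dim(x)
  B <- d[1]; R <- d[2]; W <- d[3]
  out <- array(0, c(B, R - 2L, 3L * W))
  for (k in 0:2) {
    out[, , (k * W + 1L):((k + 1L) * W)] <- x[, (1L + k):(R - 2L + k), ,
                                              drop = FALSE]
  }
  dim(out) <- c(B * (R - 2L), 3L * W)
  out
}

# scatter gradient of im2col back to input shape B x R x W
col2im3 <- function(g, B, R, W) {
  dim(g) <- c(B, R - 2L, 3L * W)
  out <- array(0, c(B, R, W))
  for (k in 0:2) {
    out[, (1L + k):(R - 2L + k), ] <-
      out[, (1L + k):(R - 2L + k), , drop = FALSE] +
      g[, , (k * W + 1L):((k + 1L) * W), drop = FALSE]
  }
  out
}

# max pool over row pairs; returns pooled array and argmax mask
pool2 <- function(x) {
  d <- dim(x)
  R2 <- d[2] %/% 2L
  a <- x[, 2L * seq_len(R2) - 1L, , drop = FALSE]
  b <- x[, 2L * seq_len(R2), , drop = FALSE]
  list(out = pmax(a, b), take_a = a >= b, R = d[2])
}

unpool2 <- function(g, p, B, W) {
  R2 <- dim(g)[2]
  out <- array(0, c(B, p$R, W))
  ga <- g; ga[!p$take_a] <- 0
  gb <- g; gb[p$take_a] <- 0
  out[, 2L * seq_len(R2) - 1L, ] <- ga
  out[, 2L * seq_len(R2), ] <- gb
  out
}

cnn_init <- function(seed, n_classes = 3L) {
  set.seed(seed)
  he <- function(nin, nout) {
    matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
  }
  # small positive biases keep early ReLUs alive under He init
  b0 <- function(n) rep(0.01, n)
  list(
    W1 = he(75, 8),  b1 = b0(8),          # conv 3x25: width 25 -> 8 maps
    W2 = he(24, 16), b2 = b0(16),         # conv 3x8:  width  8 -> 16 maps
    W3 = he(3, 2),   b3 = b0(2),          # conv 3x1 per column, 2 filters
    W4 = he(320, 256), b4 = b0(256),      # FC head 320 -> 256 -> 64 -> 3
    W5 = he(256, 64),  b5 = b0(64),
    W6 = he(64, n_classes), b6 = numeric(n_classes),
    bn_mean = numeric(320), bn_sd = rep(1, 320)
  )
}

cnn_forward <- function(par, X, train = FALSE, drop_mask = NULL) {
  B <- dim(X)[1]
  A1 <- im2col3(X)                               # (B*98) x 75
  Z1 <- sweep(A1 %*% par$W1, 2, par$b1, "+")
  H1 <- pmax(Z1, 0)
  H1a <- H1; dim(H1a) <- c(B, 98L, 8L)
  P1 <- pool2(H1a)                               # B x 49 x 8
  A2 <- im2col3(P1$out)                          # (B*47) x 24
  Z2 <- sweep(A2 %*% par$W2, 2, par$b2, "+")
  H2 <- pmax(Z2, 0)
  H2a <- H2; dim(H2a) <- c(B, 47L, 16L)
  P2 <- pool2(H2a)                               # B x 23 x 16
  T1 <- P2$out
  Z3 <- array(0, c(B, 21L, 32L))                 # 2 filters x 16 columns
  for (f in 1:2) {
    Z3[, , (f - 1L) * 16L + 1:16] <-
      par$W3[1, f] * T1[, 1:21, , drop = FALSE] +
      par$W3[2, f] * T1[, 2:22, , drop = FALSE] +
      par$W3[3, f] * T1[, 3:23, , drop = FALSE] + par$b3[f]
  }
  H3a <- pmax(Z3, 0)
  P3 <- pool2(H3a)                               # B x 10 x 32
  Fl <- P3$out; dim(Fl) <- c(B, 320L)
  if (train) {
    mu <- colMeans(Fl)
    sdv <- sqrt(colMeans(sweep(Fl, 2, mu, "-")^2) + 1e-5)
    Fn <- sweep(sweep(Fl, 2, mu, "-"), 2, sdv, "/")
  } else {
    mu <- par$bn_mean; sdv <- par$bn_sd
    Fn <- sweep(sweep(Fl, 2, mu, "-"), 2, sdv, "/")
  }
  D1 <- if (train) drop_mask$d1 else 1
  Z4 <- sweep(Fn %*% par$W4, 2, par$b4, "+")
  H4 <- pmax(Z4, 0) * D1
  D2 <- if (train) drop_mask$d2 else 1
  Z5 <- sweep(H4 %*% par$W5, 2, par$b5, "+")
  H5 <- pmax(Z5, 0) * D2
  Z6 <- sweep(H5 %*% par$W6, 2, par$b6, "+")
  Zs <- Z6 - apply(Z6, 1, max)
  P <- exp(Zs) / rowSums(exp(Zs))
  list(A1 = A1, Z1 = Z1, P1 = P1, A2 = A2, Z2 = Z2, P2 = P2,
       T1 = T1, Z3 = Z3, P3 = P3, Fl = Fl, Fn = Fn, mu = mu, sdv = sdv,
       Z4 = Z4, H4 = H4, Z5 = Z5, H5 = H5, P = P, B = B,
       D1 = D1, D2 = D2)
}

cnn_backward <- function(par, fw, y_onehot, sample_w = NULL,
                         bn_batch = TRUE) {
  B <- fw$B
  dZ6 <- (fw$P - y_onehot) / B                    # B x 3
  if (!is.null(sample_w)) dZ6 <- dZ6 * sample_w
  g <- list()
  g$W6 <- t(fw$H5) %*% dZ6; g$b6 <- colSums(dZ6)
  dH5 <- dZ6 %*% t(par$W6) * fw$D2
  dZ5 <- dH5 * (fw$Z5 > 0)
  g$W5 <- t(fw$H4) %*% dZ5; g$b5 <- colSums(dZ5)
  dH4 <- dZ5 %*% t(par$W5) * fw$D1
  dZ4 <- dH4 * (fw$Z4 > 0)
  g$W4 <- t(fw$Fn) %*% dZ4; g$b4 <- colSums(dZ4)
  dFn <- dZ4 %*% t(par$W4)
  if (bn_batch) {
    # exact gradient through batch standardization (mu, sd from batch)
    m1 <- colMeans(dFn)
    m2 <- colMeans(dFn * fw$Fn)
    dFl <- sweep(sweep(dFn, 2, m1, "-") - sweep(fw$Fn, 2, m2, "*"),
                 2, fw$sdv, "/")
  } else {
    dFl <- sweep(dFn, 2, fw$sdv, "/")   # inference stats are constants
  }
  dim(dFl) <- c(B, 10L, 32L)
  dP3 <- unpool2(dFl, fw$P3, B, 32L)              # B x 21 x 32
  dZ3 <- dP3 * (fw$Z3 > 0)
  g$W3 <- matrix(0, 3, 2); g$b3 <- numeric(2)
  dT1 <- array(0, c(B, 23L, 16L))
  for (f in 1:2) {
    dZf <- dZ3[, , (f - 1L) * 16L + 1:16, drop = FALSE]
    g$b3[f] <- sum(dZf)
    for (k in 1:3) {
      g$W3[k, f] <- sum(dZf * fw$T1[, k:(20L + k), , drop = FALSE])
      dT1[, k:(20L + k), ] <- dT1[, k:(20L + k), , drop = FALSE] +
        par$W3[k, f] * dZf
    }
  }
  dH2a <- unpool2(dT1, fw$P2, B, 16L)             # B x 47 x 16
  dH2 <- dH2a; dim(dH2) <- c(B * 47L, 16L)
  dZ2 <- dH2 * (fw$Z2 > 0)
  g$W2 <- t(fw$A2) %*% dZ2; g$b2 <- colSums(dZ2)
  dA2 <- dZ2 %*% t(par$W2)
  dP1in <- col2im3(dA2, B, 49L, 8L)
  dH1a <- unpool2(dP1in, fw$P1, B, 8L)            # B x 98 x 8
  dH1 <- dH1a; dim(dH1) <- c(B * 98L, 8L)
  dZ1 <- dH1 * (fw$Z1 > 0)
  g$W1 <- t(fw$A1) %*% dZ1; g$b1 <- colSums(dZ1)
  g
}

#' Train the cluster-filter CNN
#'
#' Three convolutions (kernels 3x25, 3x8, 3x1) each followed by max
#' pooling, then three fully connected layers (320 -> 256 -> 64 -> 3)
#' with batch standardization and dropout 0.5, softmax over
#' `{DEL, INS, false}`.  Optimized with Adam on cross-entropy, batch
#' size 256, 15 epochs, learning rate 1e-3 decayed x0.1 every 5 epochs.
#'
#' @param matrices List of 100 x 25 matrices from
#'   [build_cluster_matrix()] (already normalized).
#' @param labels Character labels over `DEL, INS, false`.
#' @param seed Integer seed (weight init, shuffling, dropout).
#' @param epochs,batch_size,lr Training protocol parameters.
#' @param holdout_frac Held-out fraction for the reported accuracy
#'   (default 0.2).
#' @return The `cnn` half of a filter bundle: `par` (weights),
#'   `classes`, `accuracy` (held-out), `final_loss`, `features`
#'   (schema), `bounds` must be attached by the caller that normalized.
#' @export
train_cnn <- function(matrices, labels, seed = 1, epochs = 15,
                      batch_size = 256, lr = 1e-3, holdout_frac = 0.2) {
  stopifnot(length(matrices) == length(labels))
  classes <- CNN_CLASSES
  if (length(unique(labels)) < 2L) {
    stop("CNN training needs at least two classes")
  }
  y_all <- match(labels, classes)
  if (anyNA(y_all)) stop("labels must be DEL, INS or false")
  set.seed(seed)
  n <- length(matrices)
  X <- array(0, c(n, CNN_ROWS, CNN_COLS))
  for (i in seq_len(n)) X[i, , ] <- matrices[[i]]
  hold <- sample.int(n, max(1L, round(n * holdout_frac)))
  tr <- setdiff(seq_len(n), hold)
  # inverse-frequency class weights: cluster corpora are dominated by
  # low-depth false clusters, which would otherwise swamp the loss
  cls_n <- table(factor(labels[tr], levels = classes))
  cls_w <- length(tr) / (sum(cls_n > 0) * pmax(1, as.numeric(cls_n)))
  names(cls_w) <- classes
  par <- cnn_init(seed, length(classes))
  adam <- lapply(par[1:12], function(w) list(m = w * 0, v = w * 0))
  t_step <- 0
  final_loss <- NA_real_
  decay_every <- max(1L, floor(epochs / 3))
  for (ep in seq_len(epochs)) {
    # fixed-step decay: x0.1 at each third of training (every 5 epochs
    # under the default 15)
    lr_ep <- lr * 0.1^((ep - 1) %/% decay_every)
    ord <- sample(tr)
    ep_loss <- 0; nb <- 0
    for (b0 in seq(1, length(ord), by = batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1L, length(ord))]
      if (length(idx) < 2L) next
      Xb <- X[idx, , , drop = FALSE]
      yb <- y_all[idx]
      Y <- matrix(0, length(idx), length(classes))
      Y[cbind(seq_along(idx), yb)] <- 1
      dm <- list(
        d1 = matrix(stats::rbinom(length(idx) * 256, 1, 0.5) * 2,
                    length(idx), 256),
        d2 = matrix(stats::rbinom(length(idx) * 64, 1, 0.5) * 2,
                    length(idx), 64))
      fw <- cnn_forward(par, Xb, train = TRUE, drop_mask = dm)
      wb <- cls_w[yb]
      loss <- -mean(wb * log(pmax(fw$P[cbind(seq_along(idx), yb)], 1e-12)))
      ep_loss <- ep_loss + loss; nb <- nb + 1
      # running batch-norm statistics for inference
      par$bn_mean <- 0.9 * par$bn_mean + 0.1 * fw$mu
      par$bn_sd <- 0.9 * par$bn_sd + 0.1 * fw$sdv
      g <- cnn_backward(par, fw, Y, sample_w = wb)
      t_step <- t_step + 1
      for (nmw in names(adam)) {
        adam[[nmw]]$m <- 0.9 * adam[[nmw]]$m + 0.1 * g[[nmw]]
        adam[[nmw]]$v <- 0.999 * adam[[nmw]]$v + 0.001 * g[[nmw]]^2
        mhat <- adam[[nmw]]$m / (1 - 0.9^t_step)
        vhat <- adam[[nmw]]$v / (1 - 0.999^t_step)
        par[[nmw]] <- par[[nmw]] - lr_ep * mhat / (sqrt(vhat) + 1e-8)
      }
    }
    final_loss <- ep_loss / max(1, nb)
  }
  pred <- cnn_predict_classes(par, X[hold, , , drop = FALSE], classes)
  acc <- mean(pred == classes[y_all[hold]])
  list(par = par, classes = classes, accuracy = acc,
       final_loss = final_loss, features = INTRA_FEATURES)
}

cnn_predict_classes <- function(par, X, classes, chunk = 512L) {
  n <- dim(X)[1]
  if (n == 0L) return(character(0))
  out <- character(n)
  for (b0 in seq(1, n, by = chunk)) {
    idx <- b0:min(b0 + chunk - 1L, n)
    fw <- cnn_forward(par, X[idx, , , drop = FALSE], train = FALSE)
    out[idx] <- classes[max.col(fw$P, ties.method = "first")]
  }
  out
}

#' Filter clustered intra-alignment calls with a trained CNN
#'
#' Only clusters of nominal type DEL or INS that contain intra-alignment
#' members are scored (the network's classes are DEL/INS/false); all
#' other clusters pass through.  A `false` prediction removes the
#' cluster.  A conflicting DEL/INS prediction does not relabel: the
#' nominal type of an intra cluster is fixed by its CIGAR operations
#' (a deletion gap cannot be an insertion), so the network's vote is
#' used only to separate real events from clustering noise.
#'
#' @param clusters Cluster list from [cluster_signatures()].
#' @param intra Intra-signature frame (source of member features).
#' @param pool The pooled signature frame the clusters index into.
#' @param cnn The `cnn` half of a filter bundle (with `bounds`).
#' @return Filtered cluster list.
#' @export
cnn_filter <- function(clusters, intra, pool, cnn) {
  if (!identical(cnn$features, INTRA_FEATURES)) {
    stop("bundle schema does not match the extractor feature schema")
  }
  scored <- which(vapply(clusters, function(cl) {
    cl$type %in% c("DEL", "INS") &&
      any(pool$source[cl$members] == "intra")
  }, TRUE))
  if (!length(scored)) return(clusters)
  X <- array(0, c(length(scored), CNN_ROWS, CNN_COLS))
  for (j in seq_along(scored)) {
    cl <- clusters[[scored[j]]]
    rows <- pool$src_row[cl$members][pool$source[cl$members] == "intra"]
    feats <- as.matrix(intra[rows, INTRA_FEATURES, drop = FALSE])
    X[j, , ] <- build_cluster_matrix(feats, intra$start[rows], cl$start,
                                     cnn$bounds)
  }
  pred <- cnn_predict_classes(cnn$par, X, cnn$classes)
  out <- list()
  for (i in seq_along(clusters)) {
    j <- match(i, scored)
    if (is.na(j)) { out[[length(out) + 1L]] <- clusters[[i]]; next }
    if (pred[j] == "false") next
    out[[length(out) + 1L]] <- clusters[[i]]
  }
  out
}
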