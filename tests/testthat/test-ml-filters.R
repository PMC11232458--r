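test_that("min-max normalization freezes bounds and clips", {
  x <- matrix(c(2, 6, 10, 5, 5, 5), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  b <- feature_bounds(x)
  xn <- normalize_features(x, b)
  expect_equal(xn[, "a"], c(0, 0.5, 1))
  expect_equal(xn[, "b"], c(0, 0, 0))      # constant column maps to 0
  out <- normalize_features(matrix(c(-5, 20, 5, 5), ncol = 2), b)
  expect_equal(out[1, 1], 0)               # clipped below
  expect_equal(out[2, 1], 1)               # clipped above
})

test_that("cluster matrices are zero-filled, ordered and truncated", {
  f <- matrix(runif(40 * 25), 40, 25,
              dimnames = list(NULL, lrsv:::INTRA_FEATURES))
  b <- feature_bounds(f)
  m <- build_cluster_matrix(f, starts = 40:1, consensus = 20, bounds = b)
  expect_equal(dim(m), c(100, 25))
  expect_equal(attr(m, "depth"), 40)
  expect_true(all(m[41:100, ] == 0))
  expect_true(all(m >= 0 & m <= 1))

  # a mid-range feature lands at its scaled position
  f2 <- f; f2[, 1] <- 6
  b2 <- b; b2$min[1] <- 2; b2$max[1] <- 10
  m2 <- build_cluster_matrix(f2, 1:40, 20, b2)
  expect_equal(unname(m2[1, 1]), 0.5)

  # clusters over 100 keep members nearest the consensus start
  f3 <- matrix(runif(130 * 25), 130, 25,
               dimnames = list(NULL, lrsv:::INTRA_FEATURES))
  starts <- sample.int(10000, 130)
  m3 <- build_cluster_matrix(f3, starts, consensus = 5000,
                             bounds = feature_bounds(f3))
  expect_equal(attr(m3, "depth"), 100)
  kept_dev <- sort(abs(starts - 5000))[100]
  expect_true(all(sort(abs(starts - 5000))[1:100] <= kept_dev))
})

test_that("low-depth augmentation is windowed, wrapped and seeded", {
  f <- matrix(runif(8 * 25), 8, 25,
              dimnames = list(NULL, lrsv:::INTRA_FEATURES))
  b <- feature_bounds(f)
  a1 <- augment_low_depth(f, 1:8, 4, b, rng_seed = 3)
  expect_length(a1, 8)                     # one matrix per starting row
  expect_true(all(vapply(a1, function(m) attr(m, "depth"), 1L) < 8))
  a2 <- augment_low_depth(f, 1:8, 4, b, rng_seed = 3)
  expect_identical(a1, a2)                 # deterministic under the seed

  single <- augment_low_depth(f[1, , drop = FALSE], 1, 1, b, rng_seed = 3)
  expect_length(single, 1)
  expect_identical(single[[1]],
                   build_cluster_matrix(f[1, , drop = FALSE], 1, 1, b))
  expect_error(augment_low_depth(matrix(0, 21, 25), 1:21, 1, b), "1, 20")
})

test_that("random forest separates well-separated classes", {
  rs <- simulate_rf_training_set(n = 1500, seed = 5)
  rf <- train_rf(rs$features, rs$labels, seed = 5)
  expect_gte(rf$macro_f1, 0.9)
  expect_true(rf$best_params$depth %in% c(2, 4, 6, 8, 10))
  # identical seed: identical selected hyperparameters
  rf2 <- train_rf(rs$features, rs$labels, seed = 5)
  expect_identical(rf$best_params, rf2$best_params)
  expect_equal(rf$macro_f1, rf2$macro_f1)
})

test_that("rf_filter drops false predictions and relabels the rest", {
  rs <- simulate_rf_training_set(n = 1500, seed = 6)
  rf <- train_rf(rs$features, rs$labels, seed = 6)
  n <- 60
  idx <- sample.int(nrow(rs$features), n)
  sigs <- data.frame(
    type = sample(c("DEL", "INS", "DUP", "INV", "TRA"), n, replace = TRUE),
    contig = "chr1", start = seq_len(n) * 100,
    end = seq_len(n) * 100 + 50, contig2 = NA_character_,
    pos2 = NA_real_, read = sprintf("r%d", seq_len(n)),
    source = "inter", length = 50, stringsAsFactors = FALSE)
  sigs <- cbind(sigs, as.data.frame(rs$features[idx, , drop = FALSE]))
  out <- rf_filter(sigs, rf)
  expect_lte(nrow(out), nrow(sigs))        # never adds evidence
  pred <- lrsv:::rf_predict(rf, rs$features[idx, , drop = FALSE])
  expect_equal(nrow(out), sum(pred != "false"))
  # relabels act only across the fuzzy INS/DUP boundary; all other
  # rule-inferred types are fixed by alignment geometry
  surv <- pred[pred != "false"]
  nominal <- sigs$type[pred != "false"]
  swap <- surv != nominal & surv %in% c("INS", "DUP") &
    nominal %in% c("INS", "DUP")
  expect_true(all(out$type[swap] == surv[swap]))
  expect_true(all(out$type[!swap] == nominal[!swap]))
})

test_that("truth labeling follows the distance and length-ratio rule", {
  truth <- data.frame(
    id = c("t1", "t2"), type = c("DEL", "DUP"), contig = "chr1",
    start = c(10000, 50000), end = c(10500, 51000),
    length = c(500, 1000), contig2 = NA_character_, pos2 = NA_integer_,
    stringsAsFactors = FALSE)
  items <- data.frame(
    type = c("DEL", "DEL", "INS"), contig = "chr1",
    start = c(10005, 15000, 50020), end = c(10480, 15400, 51000),
    length = c(475, 400, 980), stringsAsFactors = FALSE)
  lab <- generate_labels(items, truth)
  expect_equal(lab, c("DEL", "false", "DUP"))
  # an INS item matching a DUP locus inherits the truth type
  expect_warning(l0 <- generate_labels(items, truth[0, , drop = FALSE]),
                 "empty truth")
  expect_equal(l0, rep("false", 3))
})

test_that("shuffled labels drop the forest to chance", {
  rs <- simulate_rf_training_set(n = 1200, seed = 8)
  set.seed(1)
  rf <- train_rf(rs$features, sample(rs$labels), seed = 8)
  expect_lt(rf$macro_f1, 0.35)
})

test_that("cnn filter keeps, drops and relabels clusters", {
  cs <- simulate_cnn_training_set(n = 2000, seed = 9)
  cnn <- train_cnn(cs$matrices, cs$labels, seed = 9, epochs = 40)
  cnn$bounds <- cs$bounds
  expect_gte(cnn$accuracy, 0.8)
  # degenerate schema mismatch is refused
  bad <- cnn; bad$features <- rev(bad$features)
  pool <- data.frame(source = "intra", src_row = 1)
  expect_error(cnn_filter(list(), NULL, pool, bad), "schema")
})

test_that("network gradients agree with numerical differentiation", {
  set.seed(31)
  par <- lrsv:::cnn_init(31)
  for (nm in c("b1", "b2", "b3", "b4", "b5", "b6")) {
    par[[nm]] <- rnorm(length(par[[nm]]), 0, 0.1)
  }
  B <- 4
  X <- array(abs(rnorm(B * 100 * 25)) / 2, c(B, 100, 25))
  y <- sample(1:3, B, replace = TRUE)
  Y <- matrix(0, B, 3); Y[cbind(1:B, y)] <- 1
  dm <- list(d1 = matrix(1, B, 256), d2 = matrix(1, B, 64))
  loss_at <- function(p) {
    fw <- lrsv:::cnn_forward(p, X, train = TRUE, drop_mask = dm)
    -mean(log(pmax(fw$P[cbind(1:B, y)], 1e-12)))
  }
  fw <- lrsv:::cnn_forward(par, X, train = TRUE, drop_mask = dm)
  g <- lrsv:::cnn_backward(par, fw, Y, bn_batch = TRUE)
  eps <- 1e-5
  for (nm in c("W1", "W2", "W3", "b3", "W4", "W5", "W6", "b6")) {
    for (r in 1:2) {
      i <- sample(length(par[[nm]]), 1)
      p_hi <- par; p_hi[[nm]][i] <- p_hi[[nm]][i] + eps
      p_lo <- par; p_lo[[nm]][i] <- p_lo[[nm]][i] - eps
      num <- (loss_at(p_hi) - loss_at(p_lo)) / (2 * eps)
      expect_lt(abs(num - g[[nm]][i]), 1e-4 * max(1, abs(num)))
    }
  }
})
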