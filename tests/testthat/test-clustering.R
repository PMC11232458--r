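test_that("global depth is the mean local depth per type", {
  expect_equal(global_depth(c(2, 4, 6))$GD, 4)
  expect_equal(global_depth(7)$GD, 7)
  expect_equal(global_depth(c(1, 1, 1, 9))$GD, 3)
  expect_equal(global_depth(c(2, 4, 6))$N, 3)
  expect_error(global_depth(integer(0)), "no partitions")
})

test_that("adaptive lambda combines depth deviation and global depth", {
  expect_equal(adaptive_lambda(20, 20), 20)
  expect_equal(adaptive_lambda(10, 5), 10.5)
  expect_equal(adaptive_lambda(0.5, 0.5), 1)  # clamped to the >= 1 floor
  expect_error(adaptive_lambda(0, 1), "positive")
})

test_that("similarity score follows the locus/span distance formula", {
  expect_equal(signature_similarity(100, 200, 100, 200, 5), 0)
  expect_equal(signature_similarity(100, 200, 110, 210, 10), 0.01)
  expect_equal(signature_similarity(100, 200, 100, 150, 1), 0.75)
  # symmetry
  expect_equal(signature_similarity(10, 50, 30, 200, 2),
               signature_similarity(30, 200, 10, 50, 2))
  # degenerate spans (translocation breakends): pos_dis / lambda
  expect_equal(signature_similarity(500, 500, 530, 530, 10), 3)
})

test_that("similarity is non-increasing in lambda", {
  set.seed(42)
  for (i in 1:50) {
    s1 <- sample.int(1e5, 1); e1 <- s1 + sample.int(500, 1)
    s2 <- sample.int(1e5, 1); e2 <- s2 + sample.int(500, 1)
    l1 <- runif(1, 1, 50); l2 <- l1 + runif(1, 0, 50)
    expect_gte(signature_similarity(s1, e1, s2, e2, l1),
               signature_similarity(s1, e1, s2, e2, l2))
  }
})

test_that("spatial distance separates span and point conventions", {
  expect_equal(spatial_distance("DEL", 0, 1000, 1500), 500)
  expect_equal(spatial_distance("DUP", 100, 900, 950), 50)
  expect_equal(spatial_distance("INS", 200, 200, 200), 0)
  expect_equal(spatial_distance("INS", 200, 200, 450), 250)
  # overlapping span signatures are distance zero, so repeated
  # observations of one long event share a partition
  expect_equal(spatial_distance("DEL", 1000, 4000, 1000), 0)
})

test_that("partitioning sweeps by the 1000 bp gap rule", {
  sig <- function(s, e) {
    data.frame(type = "DEL", contig = "chr1", start = s, end = e,
               contig2 = NA_character_, pos2 = NA_real_,
               read = paste0("r", s), source = "intra", length = e - s,
               stringsAsFactors = FALSE)
  }
  # gaps between consecutive signatures: 500, 900, 1200
  sigs <- rbind(sig(0, 100), sig(600, 700), sig(1600, 1700),
                sig(2900, 3000))
  ids <- partition_signatures(sigs, partition_gap = 1000)
  expect_equal(ids, c(1L, 1L, 1L, 2L))
  # single signature
  expect_equal(partition_signatures(sig(5, 50)), 1L)
  # all gaps > 1000: five singleton partitions
  far <- do.call(rbind, lapply(seq(0, by = 2000, length.out = 5),
                               function(s) sig(s, s + 100)))
  expect_equal(partition_signatures(far), 1:5)
  # unsorted input is rejected
  expect_error(partition_signatures(rbind(sig(500, 600), sig(0, 100))),
               "sorted")
})

test_that("two signatures merge below the threshold and split above", {
  sigs <- random_signature_frame(2)
  sigs$start <- c(100, 110); sigs$end <- c(200, 210)
  sigs$length <- c(100, 100)
  cl <- cluster_partition(sigs, GD = 10, threshold = 0.3)  # S = 0.01
  expect_length(cl, 1)
  expect_equal(cl[[1]]$support, 2)
  sigs$start <- c(100, 100); sigs$end <- c(200, 150)
  sigs$length <- c(100, 50)
  cl <- cluster_partition(sigs, GD = 1, threshold = 0.3)   # S = 0.75
  expect_length(cl, 2)
})

test_that("consensus coordinates are lower medians", {
  sigs <- random_signature_frame(3)
  sigs$start <- c(100, 102, 104); sigs$end <- c(200, 202, 204)
  sigs$length <- rep(100, 3)
  cl <- cluster_partition(sigs, GD = 3)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$start, 102)
  expect_equal(cl[[1]]$end, 202)
  sigs4 <- random_signature_frame(4)
  sigs4$start <- c(100, 102, 104, 106); sigs4$end <- sigs4$start + 100
  sigs4$length <- rep(100, 4)
  cl <- cluster_partition(sigs4, GD = 4)
  expect_equal(cl[[1]]$start, 102)  # lower median of an even count
})

test_that("cluster_partition matches a brute-force agglomerative oracle", {
  set.seed(1234)
  n_cases <- 200
  for (case in seq_len(n_cases)) {
    n <- sample(2:12, 1)
    sigs <- random_signature_frame(n)
    GD <- runif(1, 1, 30)
    lambda <- adaptive_lambda(GD, n)
    S <- lrsv:::similarity_matrix(sigs, lambda)
    expected <- canonical_partition(brute_force_cluster(S, 0.3))
    got <- cluster_partition(sigs, GD, threshold = 0.3)
    got <- canonical_partition(lapply(got, `[[`, "members"))
    expect_identical(got, expected)
  }
})

test_that("clusters cover every signature exactly once", {
  set.seed(77)
  for (case in 1:20) {
    sigs <- random_signature_frame(sample(5:40, 1))
    cl <- cluster_signatures(sigs)
    total <- sum(vapply(cl, function(x) length(x$members), 1L))
    expect_equal(total, nrow(sigs))
    reads <- unlist(lapply(cl, `[[`, "reads"))
    expect_setequal(reads, sigs$read)
  }
})

test_that("clustering is invariant to input order", {
  set.seed(99)
  sigs <- random_signature_frame(30)
  key <- function(cls) {
    s <- vapply(cls, function(x) {
      paste(x$type, x$contig, x$start, x$end, x$support)
    }, "")
    sort(s)
  }
  base <- cluster_signatures(sigs)
  for (i in 1:5) {
    perm <- sigs[sample.int(nrow(sigs)), , drop = FALSE]
    expect_identical(key(cluster_signatures(perm)), key(base))
  }
})
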