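test_that("base distribution counts bases and homopolymer runs", {
  expect_equal(unname(base_distribution("AAAAA")),
               c(1, 0, 0, 0, 1))
  b <- base_distribution("ACGTACGT")
  expect_equal(unname(b), c(0.25, 0.25, 0.25, 0.25, 0))
  # runs of 5, 5, 4: 10 of 14 positions inside runs >= 5
  expect_equal(base_distribution("AAAAACCCCCGGGG")[["rep_freq"]], 10 / 14)
  # N counts toward the denominator only
  bn <- base_distribution("AAAAANNNNN")
  expect_equal(bn[["freq_a"]], 0.5)
  expect_equal(bn[["rep_freq"]], 0.5)
  expect_equal(unname(base_distribution("")), rep(0, 5))
  # window argument restricts the view (0-based half-open)
  expect_equal(base_distribution("AAAATTTT", window = c(4, 8))[["freq_t"]], 1)
})

test_that("CIGAR deletion and insertion gaps become signatures", {
  rec <- make_record("100M50D100M", ref_start = 1000)
  s <- extract_intra_signatures(rec, min_size = 30)
  expect_equal(nrow(s), 1)
  expect_equal(s$type, "DEL")
  expect_equal(s$start, 1100)
  expect_equal(s$end, 1150)

  rec <- make_record("100M20I100M")
  expect_equal(nrow(extract_intra_signatures(rec, min_size = 30)), 0)

  rec <- make_record("50S100M40I60M200D100M", ref_start = 0)
  s <- extract_intra_signatures(rec, min_size = 30)
  expect_equal(s$type, c("INS", "DEL"))
  expect_equal(s$start, c(100, 160))
  expect_equal(s$end, c(140, 360))
  expect_equal(s$length, c(40, 200))
})

test_that("intra feature vectors have the full 25-entry schema", {
  rec <- make_record("50S100M40I60M200D100M", nm = 12L)
  s <- extract_intra_signatures(rec, min_size = 30)
  expect_true(all(lrsv:::INTRA_FEATURES %in% colnames(s)))
  feats <- as.matrix(s[, lrsv:::INTRA_FEATURES])
  expect_equal(ncol(feats), 25)
  expect_false(anyNA(feats))
  expect_equal(s$clip_left[1], 50)
  expect_equal(s$n_large_gaps[1], 2)
  expect_equal(s$gap_type_code, c(1, 0))
  freqs <- feats[, c("freq_a", "freq_c", "freq_g", "freq_t",
                     "rep_freq_read", "rep_freq_window")]
  expect_true(all(freqs >= 0 & freqs <= 1))
})

test_that("a missing read sequence zeroes base features without error", {
  rec <- make_record("100M60D100M")
  rec$read_sequence <- NA_character_
  s <- extract_intra_signatures(rec, min_size = 30)
  expect_equal(nrow(s), 1)
  expect_equal(s$freq_a + s$freq_c + s$freq_g + s$freq_t, 0)
})

test_that("nearby same-type gaps merge into one signature", {
  # two 40 bp deletions separated by 100 bp of match: one merged DEL
  rec <- make_record("100M40D100M40D100M")
  s <- extract_intra_signatures(rec, min_size = 30, merge_gap = 150)
  expect_equal(nrow(s), 1)
  expect_equal(s$start, 100)
  expect_equal(s$end, 280)
  # far apart: two signatures
  rec2 <- make_record("100M40D300M40D100M")
  s2 <- extract_intra_signatures(rec2, min_size = 30, merge_gap = 150)
  expect_equal(nrow(s2), 2)
})

test_that("split-read pairs follow the lenient inter rules", {
  # read gap 50 < ref gap 2000: deletion of 1950 at the junction
  pri <- make_record("1000M1000S", ref_start = 10000)
  sup <- make_record("1050H950M", ref_start = 13000, primary = FALSE)
  s <- extract_inter_signatures(list(pri, sup), min_size = 30)
  expect_equal(s$type, "DEL")
  expect_equal(s$start, 11000)
  expect_equal(s$end, 12950)
  expect_equal(s$length, 1950)

  # read gap 500 > ref gap 0: insertion
  pri <- make_record("1000M1500S", ref_start = 10000)
  sup <- make_record("1500H1000M", ref_start = 11000, primary = FALSE)
  s <- extract_inter_signatures(list(pri, sup))
  expect_equal(s$type, "INS")
  expect_equal(s$length, 500)

  # reference backtrack: duplication
  pri <- make_record("1000M1000S", ref_start = 10000)
  sup <- make_record("1000H1000M", ref_start = 10600, primary = FALSE)
  s <- extract_inter_signatures(list(pri, sup))
  expect_equal(s$type, "DUP")
  expect_equal(s$start, 10600)
  expect_equal(s$end, 11000)

  # opposite strands on one contig: inversion
  pri <- make_record("1000M1000S", ref_start = 10000)
  sup <- make_record("1000H1000M", ref_start = 11000, primary = FALSE,
                     strand = "-")
  s <- extract_inter_signatures(list(pri, sup))
  expect_equal(s$type, "INV")

  # different contigs: translocation with mate coordinates
  pri <- make_record("1000M1000S", ref_start = 10000, contig = "chr1")
  sup <- make_record("1000H1000M", ref_start = 5000, contig = "chr5",
                     primary = FALSE)
  s <- extract_inter_signatures(list(pri, sup))
  expect_equal(s$type, "TRA")
  expect_equal(s$contig, "chr1")
  expect_equal(s$contig2, "chr5")
  expect_equal(s$start, 11000)
  expect_equal(s$pos2, 5000)

  # single segment: no inter evidence
  expect_equal(nrow(extract_inter_signatures(list(pri))), 0)
})

test_that("inter feature vectors have the full 22-entry schema", {
  pri <- make_record("1000M1000S", ref_start = 10000)
  sup <- make_record("1050H950M", ref_start = 13000, primary = FALSE)
  s <- extract_inter_signatures(list(pri, sup))
  expect_true(all(lrsv:::INTER_FEATURES %in% colnames(s)))
  feats <- as.matrix(s[, lrsv:::INTER_FEATURES])
  expect_equal(ncol(feats), 22)
  expect_false(anyNA(feats))
  expect_true(all(s$same_contig %in% c(0, 1)))
  expect_true(all(s$same_strand %in% c(0, 1)))
  expect_equal(s$read_gap, 50)
  expect_equal(s$ref_gap, 2000)
})

test_that("signature extraction is invariant to record order", {
  sim <- small_sim()
  recs <- stream_alignments(sim$bam_path)
  sigs <- extract_signatures(recs)
  set.seed(5)
  perm <- recs[sample.int(length(recs))]
  sigs_p <- extract_signatures(perm)
  key <- function(df) {
    k <- paste(df$type, df$contig, df$start, df$end, df$read)
    sort(k)
  }
  expect_identical(key(sigs_p$intra), key(sigs$intra))
  expect_identical(key(sigs_p$inter), key(sigs$inter))
})
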