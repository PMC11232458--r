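test_that("CIGAR parsing round-trips operations and lengths", {
  cig <- parse_cigar("50S100M40I60M200D100M")
  expect_equal(cig$op, c("S", "M", "I", "M", "D", "M"))
  expect_equal(cig$len, c(50L, 100L, 40L, 60L, 200L, 100L))
  expect_length(parse_cigar("*")$op, 0)
  expect_error(parse_cigar("12Q"), "malformed")
})

test_that("secondary and unmapped records are excluded from streams", {
  dir <- file.path(tempdir(), "lrsv_sam_fixture")
  dir.create(dir, showWarnings = FALSE)
  seq1 <- paste(rep("ACGT", 50), collapse = "")
  sam <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:10000",
    paste("r1", 0, "chr1", 101, 60, "200M", "*", 0, 0, seq1, "*",
          "NM:i:3", sep = "\t"),
    paste("r2", 0, "chr1", 301, 60, "200M", "*", 0, 0, seq1, "*",
          sep = "\t"),
    paste("r2", 256, "chr1", 501, 60, "200M", "*", 0, 0, seq1, "*",
          sep = "\t"),   # secondary: excluded
    paste("r3", 4, "*", 0, 0, "*", "*", 0, 0, seq1, "*",
          sep = "\t"),   # unmapped: excluded
    paste("r4", 2048, "chr1", 701, 60, "100H100M", "*", 0, 0,
          substr(seq1, 101, 200), "*", "SA:Z:chr1,101,+,100M100S,60,0;",
          sep = "\t"),   # supplementary: retained
    paste("r5", 0, "chr1", 901, 10, "200M", "*", 0, 0, seq1, "*",
          sep = "\t")    # below the MAPQ floor: dropped
  )
  sam_path <- file.path(dir, "mini.sam")
  writeLines(sam, sam_path)
  bam0 <- Rsamtools::asBam(sam_path, file.path(dir, "mini.unsorted"),
                           overwrite = TRUE, indexDestination = FALSE)
  bam <- Rsamtools::sortBam(bam0, file.path(dir, "mini"))
  Rsamtools::indexBam(bam)
  recs <- stream_alignments(bam, mapq_floor = 20)
  expect_equal(length(recs), 3)
  expect_setequal(vapply(recs, `[[`, "", "read_name"), c("r1", "r2", "r4"))
  r4 <- recs[[which(vapply(recs, `[[`, "", "read_name") == "r4")]]
  expect_true(r4$is_supplementary)
  expect_equal(r4$read_length, 200)
  expect_equal(length(r4$sa_entries), 1)
  expect_equal(r4$sa_entries[[1]]$pos, 100)  # 0-based internally
  r1 <- recs[[which(vapply(recs, `[[`, "", "read_name") == "r1")]]
  expect_equal(r1$ref_start, 100)
  expect_equal(r1$ref_end, 300)
  expect_equal(r1$edit_distance, 3)

  # region queries use 0-based half-open overlap semantics
  hit <- stream_alignments(bam, region = list(contig = "chr1",
                                              start = 0, end = 150))
  expect_equal(vapply(hit, `[[`, "", "read_name"), "r1")

  # a missing index is an error
  bad <- file.path(dir, "noindex.bam")
  file.copy(bam, bad)
  expect_error(stream_alignments(bad), "index")
})

test_that("streaming the synthetic fixture matches its manifest", {
  sim <- small_sim()
  recs <- stream_alignments(sim$bam_path, mapq_floor = 0)
  counts <- table(vapply(recs, `[[`, "", "read_name"))
  expect_equal(sum(sim$manifest$n_records), length(recs))
  m <- sim$manifest$n_records[match(names(counts), sim$manifest$read)]
  expect_equal(as.integer(counts), m)
  # full-file stream equals the union of per-contig streams
  per_contig <- unlist(lapply(names(sim$contigs), function(ctg) {
    rs <- stream_alignments(sim$bam_path,
                            region = list(contig = ctg, start = 0,
                                          end = sim$contigs[[ctg]]),
                            mapq_floor = 0)
    vapply(rs, function(r) paste(r$read_name, r$contig, r$ref_start), "")
  }))
  whole <- vapply(recs, function(r) paste(r$read_name, r$contig, r$ref_start), "")
  expect_setequal(unique(per_contig), whole)
})

test_that("VCF output follows the SV conventions and round-trips", {
  contigs <- c(chr1 = 100000L, chr2 = 50000L)
  del <- list(type = "DEL", contig = "chr1", start = 101, end = 301,
              length = 200L, support = 12L, genotype = "0/1",
              gt_quality = 30L, ref_support = 10L, alt_support = 12L,
              filter = "PASS")
  path <- file.path(tempdir(), "one.vcf")
  write_vcf(list(del), contigs, path)
  lines <- readLines(path)
  rec <- strsplit(lines[!startsWith(lines, "#")], "\t")[[1]]
  expect_equal(rec[2], "101")
  expect_match(rec[8], "SVTYPE=DEL;SVLEN=-200;END=301")
  expect_equal(rec[9], "GT:DP:AD")
  expect_equal(rec[10], "0/1:22:10,12")

  # empty call set: header-only file
  write_vcf(list(), contigs, path)
  expect_false(any(!startsWith(readLines(path), "#")))

  # 50 random calls round-trip bit-exactly
  set.seed(8)
  calls <- lapply(1:50, function(i) {
    type <- sample(c("DEL", "INS", "DUP", "INV", "TRA"), 1)
    ctg <- sample(names(contigs), 1)
    start <- sample.int(40000, 1)
    len <- if (type == "TRA") 0L else sample(50:5000, 1)
    list(type = type, contig = ctg, start = start,
         end = if (type %in% c("DEL", "DUP", "INV")) start + len
               else if (type == "INS") start + len else start,
         length = len,
         contig2 = if (type == "TRA") "chr2" else NA_character_,
         pos2 = if (type == "TRA") sample.int(40000, 1) else NA_real_,
         support = sample(2:40, 1),
         genotype = sample(c("0/0", "0/1", "1/1"), 1),
         gt_quality = sample(0:99, 1),
         ref_support = sample(0:30, 1), alt_support = sample(2:40, 1),
         filter = sample(c("PASS", "low_support"), 1))
  })
  ord <- order(match(vapply(calls, `[[`, "", "contig"), names(contigs)),
               vapply(calls, `[[`, 1, "start"))
  calls <- calls[ord]
  write_vcf(calls, contigs, path)
  back <- read_vcf(path)
  expect_equal(back$contigs, contigs)
  expect_length(back$calls, 50)
  for (field in c("type", "contig", "start", "end", "length", "support",
                  "genotype", "ref_support", "alt_support", "filter")) {
    expect_equal(lapply(back$calls, `[[`, field),
                 lapply(calls, `[[`, field),
                 info = field)
  }
  tra_in <- Filter(function(x) x$type == "TRA", calls)
  tra_out <- Filter(function(x) x$type == "TRA", back$calls)
  expect_equal(lapply(tra_out, `[[`, "pos2"), lapply(tra_in, `[[`, "pos2"))

  # unsorted calls and unknown contigs are rejected
  expect_error(write_vcf(rev(calls), contigs, path), "sorted")
  badcall <- del; badcall$contig <- "chrX"
  expect_error(write_vcf(list(badcall), contigs, path), "absent")
})

test_that("emitted VCF is accepted by an independent parser", {
  sim <- small_sim()
  out <- file.path(tempdir(), "valid.vcf")
  run_call(sim$bam_path, sim$ref_path, out, mode = "sensitive",
           min_support = "auto")
  res <- system2("bcftools", c("view", out), stdout = TRUE, stderr = TRUE)
  expect_null(attr(res, "status"))
  expect_true(any(grepl("^##fileformat=VCFv4.2", res)))
})
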