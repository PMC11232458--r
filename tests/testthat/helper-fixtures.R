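# Shared fixtures, built once per test run and cached in an environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small noisy sample shared by pipeline-level tests
small_sim <- function() {
  cached("small_sim", function() {
    # sizes 100-2000 bp: inside the range split alignment can represent
    # at this read length (the full 50-5000 bp condition is exercised
    # by the large-scale recovery experiment)
    spec <- simulation_spec(
      ref_length = 2e5,
      n_sv = c(DEL = 4, INS = 4, DUP = 3, INV = 3, TRA = 2),
      sv_size_range = c(100, 2000),
      depth = 20, read_length = 3500, noise_rate = 0.1, seed = 7)
    dir <- file.path(tempdir(), "lrsv_small_sim")
    sim <- simulate_sample(spec, dir)
    sim$spec <- spec
    sim
  })
}

# noise-free sample for extraction oracles
clean_sim <- function() {
  cached("clean_sim", function() {
    spec <- simulation_spec(
      ref_length = 2e5,
      n_sv = c(DEL = 4, INS = 4, DUP = 3, INV = 3, TRA = 2),
      sv_size_range = c(100, 2000),
      depth = 15, read_length = 3500, noise_rate = 0, hom_frac = 1,
      platform = "CCS", seed = 21)
    dir <- file.path(tempdir(), "lrsv_clean_sim")
    sim <- simulate_sample(spec, dir)
    sim$spec <- spec
    sim
  })
}

# a hand-built alignment record
make_record <- function(cigar, ref_start = 0L, contig = "chr1",
                        read_name = "r1", mapq = 60L, strand = "+",
                        primary = TRUE, seq = NULL, nm = 0L) {
  cig <- parse_cigar(cigar)
  qlen <- sum(cig$len[cig$op %in% c("M", "I", "S", "H", "=", "X")])
  if (is.null(seq)) {
    seq <- paste(rep(c("A", "C", "G", "T"),
                     length.out = qlen -
                       sum(cig$len[cig$op == "H"])), collapse = "")
  }
  list(read_name = read_name, contig = contig, ref_start = ref_start,
       ref_end = ref_start + sum(cig$len[cig$op %in% c("M", "D", "N", "=", "X")]),
       mapq = mapq, strand = strand, is_primary = primary,
       is_supplementary = !primary, cigar = cig, edit_distance = nm,
       sa_entries = list(), read_sequence = seq, read_length = qlen)
}

# brute-force average-linkage agglomeration: merge the closest pair of
# clusters while the average pairwise similarity is below the threshold
brute_force_cluster <- function(S, threshold = 0.3) {
  n <- nrow(S)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1L) break
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- mean(S[clusters[[i]], clusters[[j]]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    if (best_d >= threshold) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  lapply(clusters, sort)
}

canonical_partition <- function(groups) {
  groups <- lapply(groups, sort)
  groups[order(vapply(groups, min, 1))]
}

random_signature_frame <- function(n, type = "DEL", contig = "chr1") {
  start <- sort(sample.int(2000, n, replace = TRUE))
  span <- sample(30:500, n, replace = TRUE)
  data.frame(type = type, contig = contig, start = start,
             end = start + span,   # insertions also span their length

             contig2 = NA_character_, pos2 = NA_real_,
             read = sprintf("r%03d", seq_len(n)), source = "intra",
             length = span, stringsAsFactors = FALSE)
}

# the full-scale recovery experiment (1 Mb, 100 SVs, 30x, noise 0.1),
# with filter bundles trained on an independent simulated sample
acceptance_run <- function() {
  cached("acceptance_run", function() {
    train_spec <- simulation_spec(
      ref_length = 1e6,
      n_sv = c(DEL = 30, INS = 30, DUP = 15, INV = 15, TRA = 10),
      depth = 30, read_length = 3500, noise_rate = 0.15, seed = 101)
    train_sim <- simulate_sample(train_spec,
                                 file.path(tempdir(), "lrsv_acc_train"))
    bundle <- train_filter_bundle(train_sim$bam_path, train_sim$svs,
                                  seed = 101)
    spec <- simulation_spec(
      ref_length = 1e6,
      n_sv = c(DEL = 20, INS = 20, DUP = 20, INV = 20, TRA = 20),
      depth = 30, read_length = 3500, noise_rate = 0.1, seed = 42)
    sim <- simulate_sample(spec, file.path(tempdir(), "lrsv_acc_test"))
    dir <- file.path(tempdir(), "lrsv_acc_out")
    dir.create(dir, showWarnings = FALSE)
    sens <- run_call(sim$bam_path, sim$ref_path,
                     file.path(dir, "sensitive.vcf"), mode = "sensitive",
                     min_support = "auto", genotype = FALSE)
    gen <- run_call(sim$bam_path, sim$ref_path,
                    file.path(dir, "general.vcf"), mode = "general",
                    bundle = bundle, min_support = "auto",
                    genotype = FALSE)
    ev_s <- evaluate_calls(sens, sim$svs)
    ev_g <- evaluate_calls(gen, sim$svs)
    list(bundle = bundle, sim = sim,
         sensitive = ev_s, general = ev_g,
         sens_calls = sens, gen_calls = gen,
         bp_median = stats::median(unlist(ev_s$breakpoint_errors)))
  })
}
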