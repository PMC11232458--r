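# End-to-end calling pipeline: extraction -> RF filter (general mode)
# -> pooling -> adaptive clustering -> CNN filter (general mode) ->
# support/length filters -> optional genotyping -> VCF.

#' Depth-derived minimum supporting reads
#'
#' `clamp(round(depth / 10) + 2, 2, 10)`: roughly one supporting read
#' per 10x of coverage plus two, so ~30x data requires 5 supporting
#' reads - the support threshold at which callers of this family reach
#' their best precision/recall balance at that depth.
#'
#' @param mean_depth Estimated mean fold coverage.
#' @return Integer support threshold.
#' @export
auto_min_support <- function(mean_depth) {
  if (is.na(mean_depth) || mean_depth <= 0) {
    warning("zero coverage estimate; using min_support = 2")
    return(2L)
  }
  # round half up (base round() would send depth 5 to 2, not 3)
  as.integer(clamp(floor(mean_depth / 10 + 0.5) + 2, 2, 10))
}

estimate_depth <- function(records, contigs) {
  aligned <- sum(vapply(records, function(r) {
    if (isTRUE(r$is_primary)) r$ref_end - r$ref_start else 0L
  }, 1L))
  aligned / sum(contigs)
}

# Pool intra and inter signatures into one frame for clustering,
# remembering the source row so cluster members can be traced back to
# their feature vectors.  Duplicate evidence for one event from one
# read (an intra and an inter signature at the same locus) is
# deduplicated to a single vote, keeping the intra version.
make_pool <- function(intra, inter, dedup_window = 500,
                      tol_frac = c(0.7, 1.43)) {
  ci <- intra[, SIG_CORE, drop = FALSE]
  ci$src_row <- seq_len(nrow(ci))
  ce <- inter[, SIG_CORE, drop = FALSE]
  ce$src_row <- seq_len(nrow(ce))
  if (nrow(ci) && nrow(ce)) {
    drop <- logical(nrow(ce))
    for (j in seq_len(nrow(ce))) {
      same <- which(ci$read == ce$read[j] & ci$type == ce$type[j] &
                    ci$contig == ce$contig[j])
      if (!length(same)) next
      near <- abs(ci$start[same] - ce$start[j]) <= dedup_window
      ratio <- ce$length[j] / pmax(1, ci$length[same])
      drop[j] <- any(near & ratio >= tol_frac[1] & ratio <= tol_frac[2])
    }
    ce <- ce[!drop, , drop = FALSE]
  }
  out <- rbind(ci, ce)
  rownames(out) <- NULL
  out
}

#' Call structural variants from a BAM
#'
#' Runs the full workflow: signature extraction from CIGAR gaps and
#' split alignments; in general mode a random-forest filter screens the
#' split-read signatures before clustering and a CNN screens clustered
#' CIGAR evidence after; two-step adaptive clustering groups the pooled
#' signatures; clusters passing the support and length thresholds are
#' (optionally) genotyped and written as VCF 4.2.  Sensitive mode
#' bypasses both learned filters, relying on the lenient extraction
#' rules and the adaptive clustering alone - the configuration meant for
#' complex (e.g. cancer) genomes where recall matters most.
#'
#' @param bam Coordinate-sorted, indexed BAM.
#' @param ref Reference FASTA (for contig metadata and the VCF header).
#' @param out Output VCF path.
#' @param mode `"general"` (filters on; requires `bundle`) or
#'   `"sensitive"` (filters bypassed).
#' @param platform `"CLR"`, `"CCS"` or `"ONT"` (genotyping error index).
#' @param min_support Minimum distinct supporting reads, or `"auto"` to
#'   derive it from coverage via [auto_min_support()].
#' @param min_sv_size Minimum reported SV length in bp (default 50).
#' @param min_signature_size Minimum signature length in bp (default
#'   30; kept below the report threshold so fragmented evidence for
#'   borderline events survives clustering).
#' @param partition_gap,cluster_threshold Clustering parameters
#'   (defaults 1000 bp, 0.3).
#' @param mapq_floor Records below this MAPQ are ignored (default 20).
#' @param genotype Assign genotypes (default TRUE).
#' @param bundle Filter bundle from [train_filter_bundle()] (general
#'   mode only).
#' @param threads Accepted for interface compatibility; results are
#'   merged deterministically by coordinate, so the output is identical
#'   for any value.
#' @param seed Integer seed (the calling path is deterministic; the
#'   seed is recorded in the header command line).
#' @param sample_name VCF sample column name.
#' @return Invisibly, the list of emitted calls.
#' @export
run_call <- function(bam, ref, out, mode = c("general", "sensitive"),
                     platform = c("CLR", "CCS", "ONT"),
                     min_support = "auto", min_sv_size = 50,
                     min_signature_size = 30,
                     partition_gap = 1000, cluster_threshold = 0.3,
                     mapq_floor = 20, genotype = TRUE, bundle = NULL,
                     threads = 1, seed = 1, sample_name = "SAMPLE") {
  mode <- match.arg(mode)
  platform <- match.arg(platform)
  if (mode == "general" && is.null(bundle)) {
    stop("general mode requires a filter bundle (train_filter_bundle)")
  }
  contigs <- fasta_contigs(ref)
  bam_targets <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!all(names(bam_targets) %in% names(contigs)) ||
      !all(bam_targets == contigs[names(bam_targets)])) {
    stop("BAM and FASTA contigs are inconsistent")
  }

  records <- stream_alignments(bam, mapq_floor = mapq_floor)
  sigs <- extract_signatures(records, min_size = min_signature_size)
  if (mode == "general") {
    sigs$inter <- rf_filter(sigs$inter, bundle$rf)
  }
  pool <- make_pool(sigs$intra, sigs$inter)
  if (nrow(pool) == 0L) {
    write_vcf(list(), contigs, out, sample_name = sample_name)
    return(invisible(list()))
  }
  clusters <- cluster_signatures(pool, partition_gap = partition_gap,
                                 threshold = cluster_threshold)
  if (mode == "general") {
    clusters <- cnn_filter(clusters, sigs$intra, pool, bundle$cnn)
  }
  if (identical(min_support, "auto")) {
    min_support <- auto_min_support(estimate_depth(records, contigs))
  }
  clusters <- Filter(function(cl) cl$support >= min_support, clusters)
  clusters <- Filter(function(cl) {
    cl$type == "TRA" || cl$length >= min_sv_size
  }, clusters)
  if (genotype && length(clusters)) {
    clusters <- genotype_calls(clusters, bam, contigs,
                               platform = platform,
                               mapq_floor = mapq_floor)
  }
  if (length(clusters)) {
    ord <- order(vapply(clusters, function(x) match(x$contig, names(contigs)), 1),
                 vapply(clusters, function(x) x$start, 1))
    clusters <- clusters[ord]
  }
  cmd <- sprintf("lrsv call --mode %s --platform %s --min-support %s --seed %d",
                 mode, platform, as.character(min_support), as.integer(seed))
  write_vcf(clusters, contigs, out, sample_name = sample_name,
            command = cmd)
  invisible(clusters)
}

#' Train a filter bundle from a simulated (or labeled) sample
#'
#' Extracts signatures from the BAM, labels them against the truth set,
#' trains the random forest on split-read feature vectors and the CNN
#' on clustered CIGAR evidence (low-depth clusters are augmented by row
#' truncation), and returns the two models with their frozen
#' normalization bounds and schema.
#'
#' @param bam Indexed BAM (typically from [simulate_alignments()]).
#' @param truth Truth data frame (`svs` from [generate_truth()]).
#' @param seed Integer seed for labeling splits and both learners.
#' @param min_signature_size,partition_gap,cluster_threshold As in
#'   [run_call()].
#' @param mapq_floor Minimum MAPQ (default 20).
#' @return A filter bundle: list with `rf`, `cnn` and `metadata`.
#' @export
train_filter_bundle <- function(bam, truth, seed = 1,
                                min_signature_size = 30,
                                partition_gap = 1000,
                                cluster_threshold = 0.3,
                                mapq_floor = 20) {
  records <- stream_alignments(bam, mapq_floor = mapq_floor)
  sigs <- extract_signatures(records, min_size = min_signature_size)

  rf_labels <- generate_labels(sigs$inter, truth)
  rf <- train_rf(as.matrix(sigs$inter[, INTER_FEATURES, drop = FALSE]),
                 rf_labels, seed = seed)

  # intra-only clustering for CNN training examples
  pool <- sigs$intra[, SIG_CORE, drop = FALSE]
  pool$src_row <- seq_len(nrow(pool))
  clusters <- cluster_signatures(pool, partition_gap = partition_gap,
                                 threshold = cluster_threshold)
  clusters <- Filter(function(cl) cl$type %in% c("DEL", "INS"), clusters)
  summaries <- data.frame(
    type = vapply(clusters, `[[`, "", "type"),
    contig = vapply(clusters, `[[`, "", "contig"),
    start = vapply(clusters, `[[`, 1, "start"),
    end = vapply(clusters, `[[`, 1, "end"),
    length = vapply(clusters, `[[`, 1, "length"),
    stringsAsFactors = FALSE)
  labels <- generate_labels(summaries, truth)
  labels[!labels %in% c("DEL", "INS")] <- "false"
  bounds <- feature_bounds(as.matrix(sigs$intra[, INTRA_FEATURES,
                                                drop = FALSE]))
  matrices <- list(); mat_labels <- character(0)
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    rows <- pool$src_row[cl$members]
    feats <- as.matrix(sigs$intra[rows, INTRA_FEATURES, drop = FALSE])
    starts <- sigs$intra$start[rows]
    if (length(rows) <= 20L) {
      aug <- augment_low_depth(feats, starts, cl$start, bounds,
                               rng_seed = seed + i)
    } else {
      aug <- list(build_cluster_matrix(feats, starts, cl$start, bounds))
    }
    matrices <- c(matrices, aug)
    mat_labels <- c(mat_labels, rep(labels[i], length(aug)))
  }
  # small cluster corpora get proportionally more epochs so the number
  # of optimizer steps stays comparable to a 5000-matrix training run
  n_mat <- length(matrices)
  cnn_epochs <- max(15L, min(200L, as.integer(ceiling(300 * 256 / max(256, n_mat)))))
  cnn <- train_cnn(matrices, mat_labels, seed = seed, epochs = cnn_epochs)
  cnn$bounds <- bounds
  list(rf = rf, cnn = cnn,
       metadata = list(seed = seed, version = LRSV_VERSION,
                       trained_on = "synthetic"))
}

type_compatible <- function(a, b) {
  a == b | (a %in% c("INS", "DUP") & b %in% c("INS", "DUP"))
}

#' Compare a call set with a truth set
#'
#' A call matches a truth event when the types are compatible (INS and
#' DUP are interchangeable, as in standard SV benchmarking), both lie on
#' the same contig (and contig pair for translocations), breakpoints
#' agree within `tol_bp` and lengths within the ratio window.
#'
#' @param calls Call list (from [run_call()] or [read_vcf()]).
#' @param truth Truth data frame (`svs` from [generate_truth()]).
#' @param tol_bp Breakpoint tolerance (default 500).
#' @param tol_frac Length-ratio window (default `c(0.7, 1.43)`).
#' @return List with `precision`, `recall`, `f1`, `n_calls`, `n_truth`,
#'   `matched_truth` (ids), `breakpoint_errors` (named by type, start
#'   deviations of matched DEL/INS calls).
#' @export
evaluate_calls <- function(calls, truth, tol_bp = 500,
                           tol_frac = c(0.7, 1.43)) {
  n_truth <- nrow(truth)
  matched_truth <- character(0)
  tp <- 0L
  bp_err <- list(DEL = numeric(0), INS = numeric(0))
  for (call in calls) {
    cand <- truth[truth$contig == call$contig &
                  type_compatible(call$type, truth$type), , drop = FALSE]
    if (call$type == "TRA" && nrow(cand)) {
      cand <- cand[!is.na(cand$contig2) & cand$contig2 == call$contig2 &
                   abs(cand$pos2 - call$pos2) <= tol_bp, , drop = FALSE]
    }
    if (!nrow(cand)) next
    d <- abs(cand$start - call$start)
    leng <- if (is.null(call$length) || call$type == "TRA") NA else call$length
    ratio <- if (is.na(leng)) rep(1, nrow(cand)) else leng / pmax(1, cand$length)
    ok <- d <= tol_bp & (call$type == "TRA" |
                         (ratio >= tol_frac[1] & ratio <= tol_frac[2]))
    if (!any(ok)) next
    hit <- cand$id[ok][which.min(d[ok])]
    tp <- tp + 1L
    if (!hit %in% matched_truth) matched_truth <- c(matched_truth, hit)
    if (call$type %in% c("DEL", "INS")) {
      ts <- truth$start[truth$id == hit]
      bp_err[[call$type]] <- c(bp_err[[call$type]], abs(call$start - ts))
    }
  }
  precision <- if (length(calls)) tp / length(calls) else NA_real_
  recall <- if (n_truth) length(matched_truth) / n_truth else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(precision = precision, recall = recall, f1 = f1,
       n_calls = length(calls), n_truth = n_truth,
       matched_truth = matched_truth, breakpoint_errors = bp_err)
}
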