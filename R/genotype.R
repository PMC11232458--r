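# Maximum-likelihood genotyping over allele-support counts.
#
# Each candidate call is genotyped under three hypotheses on the
# alternate-allele fraction: e (homozygous reference, alt reads are
# errors), 1/2 (heterozygous) and 1 - e (homozygous alternate).  The
# error index e is platform- and event-specific: insertion-like events
# are harder to support on noisy long reads, so they carry a larger e.

#' Platform-specific genotyping error indices
#'
#' @param platform `"CLR"`, `"ONT"` or `"CCS"`.
#' @param sv_type SV type; `INS` and `DUP` use the insertion index, all
#'   other types the generic one.
#' @return The error probability `e` (0 < e < 0.5).
#' @export
genotype_error_index <- function(platform = c("CLR", "ONT", "CCS"),
                                 sv_type = "DEL") {
  platform <- match.arg(platform)
  insertion_like <- sv_type %in% c("INS", "DUP")
  if (platform == "CCS") {
    if (insertion_like) 0.1 else 0.05
  } else {
    if (insertion_like) 0.2 else 0.1
  }
}

#' Genotype likelihoods from allele support
#'
#' With `n = ref_count + alt_count` and `k = alt_count`, the three
#' log-likelihoods are `Binom(k; n, e)`, `Binom(k; n, 1/2)` and
#' `Binom(k; n, 1 - e)` for genotypes 0/0, 0/1 and 1/1.  The genotype is
#' the argmax and its quality the Phred-scaled likelihood ratio of the
#' best to the second-best hypothesis.
#'
#' @param ref_count,alt_count Non-negative read counts.
#' @param e Error index from [genotype_error_index()].
#' @return List with `genotype` (`"0/0"`, `"0/1"`, `"1/1"` or `"./."`),
#'   `gt_quality` (integer Phred), and `loglik` (named numeric length 3).
#' @export
genotype_likelihoods <- function(ref_count, alt_count, e) {
  if (ref_count < 0 || alt_count < 0) stop("negative allele counts")
  if (e <= 0 || e >= 0.5) stop("error index must lie in (0, 0.5)")
  n <- ref_count + alt_count
  k <- alt_count
  if (n == 0) {
    return(list(genotype = "./.", gt_quality = 0L,
                loglik = c(`0/0` = NA_real_, `0/1` = NA_real_, `1/1` = NA_real_)))
  }
  ll <- c(
    `0/0` = stats::dbinom(k, n, e, log = TRUE),
    `0/1` = stats::dbinom(k, n, 0.5, log = TRUE),
    `1/1` = stats::dbinom(k, n, 1 - e, log = TRUE)
  )
  ord <- order(ll, decreasing = TRUE)
  q <- round(10 * (ll[ord[1]] - ll[ord[2]]) / log(10))
  list(genotype = names(ll)[ord[1]], gt_quality = as.integer(q), loglik = ll)
}

#' Count reference and alternate allele support for a call
#'
#' The alternate count is the cluster support (distinct reads carrying
#' the signature).  The reference count is the mean read depth over the
#' two flanking windows (default 500 bp each side of the breakpoints,
#' clipped to the contig), minus the alternate reads, floored at zero.
#'
#' @param call A cluster/call list with `contig`, `start`, `end`,
#'   `support` and `reads`.
#' @param bam_path Indexed BAM file.
#' @param contig_lengths Named integer vector of contig lengths.
#' @param flank Flank window size in bp (default 500).
#' @param mapq_floor Minimum MAPQ for counted reads (default 20).
#' @return List with `ref_count`, `alt_count`.
#' @export
count_allele_support <- function(call, bam_path, contig_lengths,
                                 flank = 500, mapq_floor = 20) {
  clen <- contig_lengths[[call$contig]]
  # an insertion occupies a point on the reference: both flanks abut it
  ref_end <- if (identical(call$type, "INS")) call$start else call$end
  windows <- list(
    c(max(0, call$start - flank), max(1, call$start)),
    c(min(clen - 1, ref_end), min(clen, ref_end + flank))
  )
  depths <- vapply(windows, function(w) {
    if (w[2] <= w[1]) return(NA_real_)
    param <- Rsamtools::ScanBamParam(
      which = GenomicRanges::GRanges(call$contig,
                                     IRanges::IRanges(w[1] + 1, w[2])),
      what = c("qname", "pos", "mapq", "cigar"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE)
    )
    res <- Rsamtools::scanBam(bam_path, param = param)[[1]]
    keep <- !is.na(res$mapq) & res$mapq >= mapq_floor &
      !(res$qname %in% call$reads)
    if (!any(keep)) return(0)
    # mean per-base depth of non-alt reads over the window
    starts <- res$pos[keep] - 1L
    ends <- starts + vapply(res$cigar[keep],
                            function(cg) cigar_ref_span(parse_cigar(cg)), 1)
    cov <- pmin(ends, w[2]) - pmax(starts, w[1])
    sum(pmax(cov, 0)) / (w[2] - w[1])
  }, 1)
  ref <- mean(depths, na.rm = TRUE)
  if (is.nan(ref)) ref <- 0
  list(ref_count = max(0L, as.integer(round(ref))),
       alt_count = as.integer(call$support))
}

#' Genotype a list of calls against a BAM
#'
#' @param calls List of call objects (clusters with support and reads).
#' @param bam_path Indexed BAM.
#' @param contig_lengths Named contig length vector.
#' @param platform Sequencing platform for the error index.
#' @param flank,mapq_floor See [count_allele_support()].
#' @return `calls` with `genotype`, `gt_quality`, `ref_support`,
#'   `alt_support` filled in.
#' @export
genotype_calls <- function(calls, bam_path, contig_lengths,
                           platform = "CLR", flank = 500, mapq_floor = 20) {
  lapply(calls, function(call) {
    sup <- count_allele_support(call, bam_path, contig_lengths,
                                flank = flank, mapq_floor = mapq_floor)
    e <- genotype_error_index(platform, call$type)
    gl <- genotype_likelihoods(sup$ref_count, sup$alt_count, e)
    call$genotype <- gl$genotype
    call$gt_quality <- gl$gt_quality
    call$ref_support <- sup$ref_count
    call$alt_support <- sup$alt_count
    call
  })
}
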