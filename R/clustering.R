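# Two-step adaptive clustering of SV signatures.
#
# Signatures of one SV type are first swept into coarse coordinate
# partitions (spatial distance > partition_gap opens a new partition),
# then each partition is refined by average-linkage hierarchical
# clustering under a similarity score whose locus-distance term is scaled
# by an adaptive factor lambda derived from the partition's local
# signature depth (LD) and the genome-wide per-type global depth (GD).

#' Spatial distance between two signatures of the same type
#'
#' For deletions, duplications and inversions the distance between an
#' earlier signature `i` and a later signature `j` is `s_j - e_i` (start
#' of the next event to the end of the previous one), floored at zero:
#' signatures whose intervals overlap are at distance 0, so repeated
#' observations of one long event always share a partition.  For
#' insertions and translocations, which are anchored at a point, the
#' distance is `|s_j - s_i|`.
#'
#' @param type SV type, one of `"DEL","INS","DUP","INV","TRA"`.
#' @param s_i,e_i Start/end (0-based) of the earlier signature.
#' @param s_j Start of the later signature.
#' @return Distance in bp (non-negative numeric).
#' @export
spatial_distance <- function(type, s_i, e_i, s_j) {
  type <- match.arg(type, SV_TYPES)
  if (type %in% c("DEL", "DUP", "INV")) max(0, s_j - e_i) else abs(s_j - s_i)
}

#' Partition sorted signatures by coordinate proximity
#'
#' Greedy left-to-right sweep over signatures of one SV type sorted by
#' (contig, start): a new partition opens when the contig (for
#' translocations, the ordered contig pair) changes or the spatial
#' distance to the previous signature exceeds `partition_gap`.
#'
#' @param sigs A signature data frame (see [extract_intra_signatures()])
#'   containing a single `type`; must be sorted by contig then start.
#' @param partition_gap Maximum spatial distance (bp) between adjacent
#'   members of one partition. Default 1000.
#' @return Integer vector of partition ids (1-based, contiguous), one per
#'   row of `sigs`.
#' @export
partition_signatures <- function(sigs, partition_gap = 1000) {
  n <- nrow(sigs)
  if (n == 0L) return(integer(0))
  type <- sigs$type[1]
  if (!all(sigs$type == type)) stop("partition_signatures: mixed SV types")
  key <- if (type == "TRA") paste(sigs$contig, sigs$contig2) else sigs$contig
  if (n > 1L) {
    same <- key[-1L] == key[-n]
    if (any(same & diff(sigs$start) < 0)) {
      stop("partition_signatures: signatures not sorted by (contig, start)")
    }
  }
  ids <- integer(n)
  ids[1L] <- 1L
  if (n > 1L) {
    for (i in 2L:n) {
      new_part <- key[i] != key[i - 1L] ||
        spatial_distance(type, sigs$start[i - 1L], sigs$end[i - 1L],
                         sigs$start[i]) > partition_gap
      ids[i] <- if (new_part) ids[i - 1L] + 1L else ids[i - 1L]
    }
  }
  ids
}

#' Global signature depth per SV type
#'
#' The global depth GD of one SV type is the arithmetic mean of the
#' local depths (member counts, LD) of that type's partitions. It
#' summarizes the average SV-signal strength across the whole sample and
#' anchors the adaptive similarity scale.
#'
#' @param local_depths Integer vector of partition sizes (LD) for one type.
#' @return A list with `GD` (mean LD) and `N` (partition count).
#' @export
global_depth <- function(local_depths) {
  if (length(local_depths) == 0L) stop("global_depth: no partitions")
  if (any(local_depths < 1)) stop("global_depth: LD must be >= 1")
  list(GD = mean(local_depths), N = length(local_depths))
}

#' Adaptive similarity scale lambda
#'
#' `lambda = |GD - LD| / max(GD, LD) + GD`, clamped below at 1: the
#' normalized deviation of the partition's local depth from the global
#' depth plus the global depth itself. Deep data (large GD) downweights
#' the locus-distance term of the similarity score so scattered
#' signatures of one event still merge; the deviation term loosens
#' clustering in partitions that are unusually shallow or deep relative
#' to the sample.
#'
#' @param GD Global depth (> 0).
#' @param LD Local depth of the partition (> 0).
#' @return The scale lambda (>= 1).
#' @export
adaptive_lambda <- function(GD, LD) {
  if (GD <= 0 || LD <= 0) stop("adaptive_lambda: depths must be positive")
  max(1, abs(GD - LD) / max(GD, LD) + GD)
}

#' Similarity score between two signatures
#'
#' `pos_dis` is the absolute difference of interval midpoints, `span_dis`
#' the absolute difference of spans, and
#' `S = (pos_dis / lambda + span_dis) / max(span_i, span_j)`.
#' Smaller is more similar; pairs with `S` below the clustering threshold
#' merge. When both spans are zero (translocation breakends, point
#' evidence) the denominator is replaced by 1 and `span_dis` is 0, so
#' `S = pos_dis / lambda`.
#'
#' @param s_i,e_i,s_j,e_j Signature coordinates (0-based, `e >= s`).
#' @param lambda Scale from [adaptive_lambda()].
#' @return Non-negative similarity score (symmetric in i and j).
#' @export
signature_similarity <- function(s_i, e_i, s_j, e_j, lambda) {
  pos_dis <- abs((s_i + e_i) / 2 - (s_j + e_j) / 2)
  span_i <- e_i - s_i
  span_j <- e_j - s_j
  if (span_i < 0 || span_j < 0) stop("signature_similarity: negative span")
  if (span_i == 0 && span_j == 0) return(pos_dis / lambda)
  span_dis <- abs(span_i - span_j)
  (pos_dis / lambda + span_dis) / max(span_i, span_j)
}

# Full symmetric similarity matrix for the rows of a signature frame.
similarity_matrix <- function(sigs, lambda) {
  n <- nrow(sigs)
  mid <- (sigs$start + sigs$end) / 2
  span <- sigs$end - sigs$start
  pos_dis <- abs(outer(mid, mid, "-"))
  span_dis <- abs(outer(span, span, "-"))
  denom <- outer(span, span, pmax)
  degenerate <- denom == 0
  denom[degenerate] <- 1
  span_dis[degenerate] <- 0
  S <- (pos_dis / lambda + span_dis) / denom
  diag(S) <- 0
  S
}

#' Cluster one partition by adaptive hierarchical clustering
#'
#' Builds the pairwise similarity matrix under
#' `lambda = adaptive_lambda(GD, LD)` and merges signatures by
#' average-linkage agglomeration while the linkage distance is below
#' `threshold` (default 0.3). Each cluster's consensus breakpoints are
#' the (lower) medians of the member coordinates; support is the number
#' of distinct read names.
#'
#' @param sigs Signature data frame: the members of one partition
#'   (single type and contig/contig pair).
#' @param GD Global depth for this SV type.
#' @param threshold Similarity cut; linkage distances strictly below it
#'   merge. Default 0.3.
#' @return A list of clusters; each is a list with `type`, `contig`,
#'   `start`, `end`, `length`, `support`, `reads`, `members` (row
#'   indices into `sigs`), and for translocations `contig2`, `pos2`.
#' @export
cluster_partition <- function(sigs, GD, threshold = 0.3) {
  n <- nrow(sigs)
  if (n == 0L) return(list())
  lambda <- adaptive_lambda(GD, n)
  if (n == 1L) {
    assign <- 1L
  } else {
    S <- similarity_matrix(sigs, lambda)
    hc <- stats::hclust(stats::as.dist(S), method = "average")
    # merge while linkage distance < threshold (ties at the threshold do
    # not merge)
    assign <- stats::cutree(hc, h = threshold * (1 - 1e-9))
  }
  lapply(unname(split(seq_len(n), assign)), function(idx) {
    m <- sigs[idx, , drop = FALSE]
    # .row carries the caller's global row ids through partitioning
    global <- if (".row" %in% names(sigs)) sigs$.row[idx] else idx
    cl <- list(
      type = m$type[1],
      contig = m$contig[1],
      start = lower_median(m$start),
      end = lower_median(m$end),
      length = lower_median(m$length),
      support = length(unique(m$read)),
      reads = unique(m$read),
      members = global
    )
    if (cl$type == "TRA") {
      cl$contig2 <- m$contig2[1]
      cl$pos2 <- lower_median(m$pos2)
      cl$end <- cl$start
      cl$length <- 0L
    }
    if (cl$type == "INS") cl$end <- cl$start + cl$length
    cl
  })
}

#' Cluster a full signature pool
#'
#' Runs the two clustering steps for every SV type in `sigs`: sort,
#' partition with [partition_signatures()], compute per-type global
#' depth, then refine each partition with [cluster_partition()].
#'
#' @param sigs Signature data frame with all types pooled.
#' @param partition_gap Partition sweep gap in bp (default 1000).
#' @param threshold Similarity cut (default 0.3).
#' @return A list of clusters (see [cluster_partition()]), ordered by
#'   type, contig and start.
#' @export
cluster_signatures <- function(sigs, partition_gap = 1000, threshold = 0.3) {
  out <- list()
  sigs$.row <- seq_len(nrow(sigs))
  for (type in SV_TYPES) {
    st <- sigs[sigs$type == type, , drop = FALSE]
    if (nrow(st) == 0L) next
    key <- if (type == "TRA") paste(st$contig, st$contig2) else st$contig
    st <- st[order(key, st$start), , drop = FALSE]
    parts <- partition_signatures(st, partition_gap)
    gd <- global_depth(tabulate(parts))$GD
    for (p in split(seq_len(nrow(st)), parts)) {
      out <- c(out, cluster_partition(st[p, , drop = FALSE], gd, threshold))
    }
  }
  if (length(out) > 1L) {
    ord <- order(
      vapply(out, function(x) match(x$type, SV_TYPES), 1),
      vapply(out, function(x) x$contig, ""),
      vapply(out, function(x) x$start, 1)
    )
    out <- out[ord]
  }
  out
}
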