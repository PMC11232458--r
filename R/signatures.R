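# SV signature extraction.
#
# A signature is the atomic piece of single-read SV evidence, the
# quadruple (type, contig, start, end) plus provenance.  Intra-alignment
# signatures come from I/D gaps inside one CIGAR; inter-alignment
# signatures come from the geometry of a read's split (primary +
# supplementary) alignments under deliberately lenient rules - the
# random-forest filter, not the extraction rules, is responsible for
# rejecting noise.

INTRA_FEATURES <- c(
  # global alignment
  "mapq", "clip_left", "clip_right", "n_ins_ops", "n_del_ops",
  "edit_distance", "read_length", "aligned_frac", "n_suppl",
  # CIGAR-local
  "gap_read_offset", "gap_ref_offset", "gap_len", "gap_type_code",
  "dist_nearest_gap", "n_large_gaps",
  # base distribution (whole read, then signature-local window)
  "freq_a", "freq_c", "freq_g", "freq_t",
  "wfreq_a", "wfreq_c", "wfreq_g", "wfreq_t",
  "rep_freq_read", "rep_freq_window"
)

INTER_FEATURES <- c(
  # global alignment
  "pri_mapq", "sup_mapq", "pri_aln_len", "sup_aln_len",
  "pri_clip_left", "pri_clip_right", "pri_edit_distance",
  "sup_edit_distance",
  # split alignment
  "same_contig", "same_strand", "read_gap", "ref_gap", "gap_diff",
  "read_overlap", "ref_overlap", "n_sa", "type_code",
  # base distribution (primary read sequence)
  "freq_a", "freq_c", "freq_g", "freq_t", "rep_freq"
)

SIG_CORE <- c("type", "contig", "start", "end", "contig2", "pos2",
              "read", "source", "length")

sig_frame <- function(rows, feature_names) {
  cols <- c(SIG_CORE, feature_names)
  if (length(rows) == 0L) {
    df <- stats::setNames(
      c(list(character(0), character(0), numeric(0), numeric(0),
             character(0), numeric(0), character(0), character(0),
             numeric(0)),
        rep(list(numeric(0)), length(feature_names))),
      cols
    )
    return(as.data.frame(df, stringsAsFactors = FALSE))
  }
  out <- lapply(cols, function(cn) {
    v <- lapply(rows, function(r) r[[cn]] %||% NA)
    if (cn %in% c("type", "contig", "contig2", "read", "source")) {
      as.character(unlist(v))
    } else {
      as.numeric(unlist(v))
    }
  })
  stats::setNames(as.data.frame(out, stringsAsFactors = FALSE), cols)
}

#' Base-composition and homopolymer statistics of a sequence
#'
#' Returns the frequency of A, C, G and T plus the repeated-base
#' frequency: the fraction of positions lying inside any homopolymer run
#' of length >= 5.  `N` bases count toward the denominator only.
#'
#' @param seq A single DNA string over `A,C,G,T,N` (case-insensitive).
#' @param window Optional `c(start, end)` 0-based half-open sub-interval.
#' @return Named numeric vector `freq_a, freq_c, freq_g, freq_t, rep_freq`.
#' @examples
#' base_distribution("AAAAACCCCCGGGG")
#' @export
base_distribution <- function(seq, window = NULL) {
  zero <- c(freq_a = 0, freq_c = 0, freq_g = 0, freq_t = 0, rep_freq = 0)
  if (is.null(seq) || is.na(seq) || !nzchar(seq)) return(zero)
  if (!is.null(window)) {
    lo <- max(0L, as.integer(window[1]))
    hi <- min(nchar(seq), as.integer(window[2]))
    if (hi <= lo) return(zero)
    seq <- substr(seq, lo + 1L, hi)
  }
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(chars)
  runs <- rle(chars)
  rep_pos <- sum(runs$lengths[runs$lengths >= 5 & runs$values != "N"])
  c(freq_a = sum(chars == "A") / n,
    freq_c = sum(chars == "C") / n,
    freq_g = sum(chars == "G") / n,
    freq_t = sum(chars == "T") / n,
    rep_freq = rep_pos / n)
}

# Walk a CIGAR and list every I/D gap with read/reference offsets.
# Returned offsets are in full read space (hard clips counted) and in
# reference space from rec$ref_start.
cigar_gaps <- function(cig, ref_start) {
  qpos <- 0L
  rpos <- ref_start
  gaps <- list()
  for (i in seq_along(cig$op)) {
    op <- cig$op[i]; len <- cig$len[i]
    if (op == "I" && len > 0L) {
      gaps[[length(gaps) + 1L]] <-
        list(type = "INS", qpos = qpos, rpos = rpos, len = len)
    } else if (op %in% c("D", "N") && len > 0L) {
      gaps[[length(gaps) + 1L]] <-
        list(type = "DEL", qpos = qpos, rpos = rpos, len = len)
    }
    if (op %in% c("M", "I", "S", "H", "=", "X")) qpos <- qpos + len
    if (op %in% c("M", "D", "N", "=", "X")) rpos <- rpos + len
  }
  gaps
}

# Merge same-type gaps separated by < merge_gap bp of reference between
# them; fragmented evidence for one event then clusters as one
# signature. Gaps below noise_floor bp are never merge seeds.
merge_gaps <- function(gaps, merge_gap = 150, noise_floor = 10) {
  gaps <- Filter(function(g) g$len >= noise_floor, gaps)
  if (length(gaps) <= 1L) return(gaps)
  out <- list(gaps[[1L]])
  for (g in gaps[-1L]) {
    last <- out[[length(out)]]
    gap_between <- g$rpos - (last$rpos + if (last$type == "DEL") last$len else 0L)
    if (g$type == last$type && gap_between >= 0 && gap_between < merge_gap) {
      last$len <- last$len + g$len
      if (last$type == "DEL") {
        # span the merged interval, absorbing the matched spacer
        last$len <- g$rpos + g$len - last$rpos
      }
      out[[length(out)]] <- last
    } else {
      out[[length(out) + 1L]] <- g
    }
  }
  out
}

#' Extract intra-alignment signatures from one alignment record
#'
#' Scans the record's CIGAR: every deletion gap of length >= `min_size`
#' yields a DEL signature over its reference interval, every insertion
#' gap an INS signature anchored at its reference position with
#' `end = start + length`.  Nearby same-type gaps (< `merge_gap` bp of
#' reference apart) are merged first, so fragmented evidence for one
#' event produces one signature.  Each signature carries the 25-entry
#' intra feature vector (global alignment, CIGAR-local and
#' base-distribution groups).
#'
#' @param rec An alignment record (list) as produced by
#'   [stream_alignments()].
#' @param min_size Minimum signature length in bp (default 30).
#' @param merge_gap Merge window for fragmented gaps (default 150).
#' @return A signature data frame (possibly 0 rows) with feature columns.
#' @export
extract_intra_signatures <- function(rec, min_size = 30, merge_gap = 150) {
  cig <- rec$cigar
  gaps <- cigar_gaps(cig, rec$ref_start)
  all_large <- Filter(function(g) g$len >= min_size, gaps)
  merged <- merge_gaps(gaps, merge_gap = merge_gap)
  keep <- Filter(function(g) g$len >= min_size, merged)
  if (length(keep) == 0L) return(sig_frame(list(), INTRA_FEATURES))

  read_len <- rec$read_length
  aligned <- sum(cig$len[cig$op %in% c("M", "=", "X")])
  seq_ok <- !is.null(rec$read_sequence) && !is.na(rec$read_sequence) &&
    nzchar(rec$read_sequence)
  base_read <- if (seq_ok) base_distribution(rec$read_sequence) else
    c(freq_a = 0, freq_c = 0, freq_g = 0, freq_t = 0, rep_freq = 0)
  # soft-clip offset: read_sequence excludes hard clips
  hard_left <- if (length(cig$op) && cig$op[1] == "H") cig$len[1] else 0L

  rows <- lapply(keep, function(g) {
    others <- Filter(function(h) h$rpos != g$rpos || h$type != g$type, all_large)
    dist_near <- if (length(others) == 0L) -1 else
      min(vapply(others, function(h) abs(h$rpos - g$rpos), 1))
    win <- c(g$qpos - 100L - hard_left,
             g$qpos + (if (g$type == "INS") g$len else 0L) + 100L - hard_left)
    base_win <- if (seq_ok) base_distribution(rec$read_sequence, win) else
      c(freq_a = 0, freq_c = 0, freq_g = 0, freq_t = 0, rep_freq = 0)
    list(
      type = g$type, contig = rec$contig,
      start = g$rpos,
      end = g$rpos + g$len,   # for INS the span encodes the length
      contig2 = NA_character_, pos2 = NA_real_,
      read = rec$read_name, source = "intra", length = g$len,
      mapq = rec$mapq,
      clip_left = cigar_left_clip(cig),
      clip_right = cigar_right_clip(cig),
      n_ins_ops = sum(cig$op == "I"),
      n_del_ops = sum(cig$op == "D"),
      edit_distance = rec$edit_distance %||% 0,
      read_length = read_len,
      aligned_frac = if (read_len > 0) aligned / read_len else 0,
      n_suppl = length(rec$sa_entries %||% list()),
      gap_read_offset = g$qpos / max(1, read_len),
      gap_ref_offset = g$rpos - rec$ref_start,
      gap_len = g$len,
      gap_type_code = if (g$type == "DEL") 0 else 1,
      dist_nearest_gap = dist_near,
      n_large_gaps = length(all_large),
      freq_a = base_read[["freq_a"]], freq_c = base_read[["freq_c"]],
      freq_g = base_read[["freq_g"]], freq_t = base_read[["freq_t"]],
      wfreq_a = base_win[["freq_a"]], wfreq_c = base_win[["freq_c"]],
      wfreq_g = base_win[["freq_g"]], wfreq_t = base_win[["freq_t"]],
      rep_freq_read = base_read[["rep_freq"]],
      rep_freq_window = base_win[["rep_freq"]]
    )
  })
  sig_frame(rows, INTRA_FEATURES)
}

# One aligned segment of a read in read-forward coordinates.
segment_of <- function(rec) {
  qi <- cigar_query_interval(rec$cigar, rec$strand)
  list(contig = rec$contig, ref_start = rec$ref_start, ref_end = rec$ref_end,
       strand = rec$strand, q_start = qi[1], q_end = qi[2],
       mapq = rec$mapq, nm = rec$edit_distance %||% 0,
       is_primary = isTRUE(rec$is_primary),
       aln_len = rec$ref_end - rec$ref_start)
}

#' Extract inter-alignment signatures from all records of one read
#'
#' Orders the read's aligned segments by query offset (hard clips
#' converted to read space) and applies one lenient rule per adjacent
#' pair: different contigs give a translocation; opposite strands an
#' inversion (the inverted segment's reference interval); a reference
#' backtrack of at least `min_size` on the same strand a duplication;
#' otherwise the difference between the reference-space and read-space
#' gaps gives a deletion (reference gap longer) or an insertion (read
#' gap longer).  No other heuristics are applied: separating true from
#' spurious splits is the random-forest filter's job.  Each signature
#' carries the 22-entry inter feature vector.
#'
#' @param records All alignment records of one read (one primary,
#'   any number of supplementary).
#' @param min_size Minimum signature length in bp (default 30).
#' @return A signature data frame (possibly 0 rows) with feature columns.
#' @export
extract_inter_signatures <- function(records, min_size = 30) {
  if (length(records) < 2L) return(sig_frame(list(), INTER_FEATURES))
  qn <- unique(vapply(records, function(r) r$read_name, ""))
  if (length(qn) != 1L) stop("extract_inter_signatures: mixed read names")
  segs <- lapply(records, segment_of)
  ord <- order(vapply(segs, function(s) s$q_start, 1),
               vapply(segs, function(s) s$ref_start, 1))
  segs <- segs[ord]
  pri <- segs[[which(vapply(segs, function(s) s$is_primary, TRUE))[1]]]
  pri_rec <- records[[which(vapply(records, function(r) isTRUE(r$is_primary), TRUE))[1]]]
  base <- base_distribution(pri_rec$read_sequence %||% NA_character_)
  n_sa <- length(segs) - 1L

  rows <- list()
  for (k in seq_len(length(segs) - 1L)) {
    a <- segs[[k]]; b <- segs[[k + 1L]]
    read_gap <- b$q_start - a$q_end
    same_contig <- a$contig == b$contig
    same_strand <- a$strand == b$strand
    sig <- NULL
    if (!same_contig) {
      s <- if (a$strand == "+") a$ref_end else a$ref_start
      p2 <- if (b$strand == "+") b$ref_start else b$ref_end
      # canonical orientation so both derivative-chromosome views of one
      # junction cluster together
      if (a$contig > b$contig) {
        sig <- list(type = "TRA", contig = b$contig, start = p2, end = p2,
                    contig2 = a$contig, pos2 = s, length = 0)
      } else {
        sig <- list(type = "TRA", contig = a$contig, start = s, end = s,
                    contig2 = b$contig, pos2 = p2, length = 0)
      }
      ref_gap <- 0
    } else if (!same_strand) {
      # inverted-junction boundaries: a forward->reverse transition joins
      # the two segment ends, a reverse->forward transition the two
      # starts; either way the pair brackets the inverted interval
      if (a$strand == "+") {
        s_sig <- a$ref_end; e_sig <- b$ref_end
      } else {
        s_sig <- a$ref_start; e_sig <- b$ref_start
      }
      if (s_sig > e_sig) { tmp <- s_sig; s_sig <- e_sig; e_sig <- tmp }
      sig <- list(type = "INV", contig = a$contig, start = s_sig,
                  end = e_sig, contig2 = NA_character_,
                  pos2 = NA_real_, length = e_sig - s_sig)
      ref_gap <- 0
    } else {
      ref_gap <- if (a$strand == "+") b$ref_start - a$ref_end
                 else a$ref_start - b$ref_end
      if (-ref_gap >= min_size) {
        # reference backtrack: segment pair duplicated in the reference
        if (a$strand == "+") {
          sig <- list(type = "DUP", contig = a$contig, start = b$ref_start,
                      end = a$ref_end)
        } else {
          sig <- list(type = "DUP", contig = a$contig, start = a$ref_start,
                      end = b$ref_end)
        }
        sig$contig2 <- NA_character_; sig$pos2 <- NA_real_
        sig$length <- sig$end - sig$start
      } else {
        diff <- ref_gap - read_gap
        if (diff >= min_size) {
          s <- if (a$strand == "+") a$ref_end else b$ref_end
          sig <- list(type = "DEL", contig = a$contig, start = s,
                      end = s + diff, contig2 = NA_character_,
                      pos2 = NA_real_, length = diff)
        } else if (-diff >= min_size) {
          s <- if (a$strand == "+") min(a$ref_end, b$ref_start)
               else min(b$ref_end, a$ref_start)
          sig <- list(type = "INS", contig = a$contig, start = s,
                      end = s - diff, contig2 = NA_character_,
                      pos2 = NA_real_, length = -diff)
        }
      }
    }
    if (is.null(sig)) next
    if (sig$type != "TRA" && sig$length < min_size) next
    sup <- if (!a$is_primary) a else b
    rows[[length(rows) + 1L]] <- c(sig, list(
      read = qn, source = "inter",
      pri_mapq = pri$mapq, sup_mapq = sup$mapq,
      pri_aln_len = pri$aln_len, sup_aln_len = sup$aln_len,
      pri_clip_left = cigar_left_clip(pri_rec$cigar),
      pri_clip_right = cigar_right_clip(pri_rec$cigar),
      pri_edit_distance = pri$nm, sup_edit_distance = sup$nm,
      same_contig = as.numeric(same_contig),
      same_strand = as.numeric(same_strand),
      read_gap = read_gap, ref_gap = ref_gap,
      gap_diff = ref_gap - read_gap,
      read_overlap = max(0, -read_gap), ref_overlap = max(0, -ref_gap),
      n_sa = n_sa,
      type_code = match(sig$type, SV_TYPES) - 1,
      freq_a = base[["freq_a"]], freq_c = base[["freq_c"]],
      freq_g = base[["freq_g"]], freq_t = base[["freq_t"]],
      rep_freq = base[["rep_freq"]]
    ))
  }
  sig_frame(rows, INTER_FEATURES)
}

#' Extract all signatures from a stream of alignment records
#'
#' Applies [extract_intra_signatures()] to every record and
#' [extract_inter_signatures()] to each read's record group.
#'
#' @param records List of alignment records (one contig or whole file).
#' @param min_size Minimum signature length (default 30).
#' @param merge_gap Intra-gap merge window (default 150).
#' @return List with `intra` and `inter` signature data frames.
#' @export
extract_signatures <- function(records, min_size = 30, merge_gap = 150) {
  intra <- lapply(records, extract_intra_signatures,
                  min_size = min_size, merge_gap = merge_gap)
  intra <- do.call(rbind, c(list(sig_frame(list(), INTRA_FEATURES)), intra))
  by_read <- split(records, vapply(records, function(r) r$read_name, ""))
  inter <- lapply(by_read, function(rs) {
    if (length(rs) < 2L || !any(vapply(rs, function(r) isTRUE(r$is_primary), TRUE))) {
      return(sig_frame(list(), INTER_FEATURES))
    }
    extract_inter_signatures(rs, min_size = min_size)
  })
  inter <- do.call(rbind, c(list(sig_frame(list(), INTER_FEATURES)), inter))
  rownames(intra) <- NULL
  rownames(inter) <- NULL
  list(intra = intra, inter = inter)
}
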