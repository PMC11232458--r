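# Deterministic synthetic-data generator.
#
# Builds a random reference (with planted homopolymer runs so
# repeat-content features are exercised), implants non-overlapping SVs
# of all five types as a diploid donor, and synthesizes alignment
# records directly - every read is sampled from a donor haplotype and
# its CIGAR/split structure derived analytically from the donor-to-
# reference block map, with platform-style small-indel noise and, at a
# configurable rate, spurious gaps and split fragments of the kind the
# learned filters are meant to reject.  No aligner is involved, so the
# ground truth per read is exact and everything is reproducible from a
# seed.

#' Simulation specification
#'
#' @param ref_length Total reference length in bp, split over two
#'   contigs (default 1e6).
#' @param n_sv Named count of implanted SVs per type (default 20 each).
#' @param sv_size_range Length range for implanted events (default
#'   50-5000 bp).
#' @param depth Target fold coverage (default 30).
#' @param read_length Mean read length in bp (default 3500, near the
#'   longest mean read length for which 100 spaced events plus their
#'   translocation mate breakpoints fit in a 1 Mb reference under the
#'   two-read-length spacing rule).
#' @param noise_rate Fraction of reads receiving a spurious 30-80 bp
#'   gap; half that rate additionally receive a spurious low-quality
#'   split fragment (default 0.1).
#' @param hom_frac Fraction of homozygous events (default 0.5).
#' @param platform Noise profile, `"CLR"`, `"ONT"` or `"CCS"`; controls
#'   the small-indel error rate injected into CIGARs.
#' @param seed Integer seed; every downstream draw derives from it.
#' @return A validated spec (list, class `lrsv_simspec`).
#' @export
simulation_spec <- function(ref_length = 1e6,
                            n_sv = c(DEL = 20, INS = 20, DUP = 20,
                                     INV = 20, TRA = 20),
                            sv_size_range = c(50, 5000),
                            depth = 30,
                            read_length = 3500,
                            noise_rate = 0.1,
                            hom_frac = 0.5,
                            platform = c("CLR", "ONT", "CCS"),
                            seed = 1) {
  platform <- match.arg(platform)
  stopifnot(ref_length >= 1e4, all(n_sv >= 0), depth >= 0,
            read_length >= 500, noise_rate >= 0, noise_rate <= 1,
            hom_frac >= 0, hom_frac <= 1,
            sv_size_range[1] >= 30, sv_size_range[2] >= sv_size_range[1])
  full <- c(DEL = 0, INS = 0, DUP = 0, INV = 0, TRA = 0)
  full[names(n_sv)] <- n_sv
  structure(list(ref_length = ref_length, n_sv = full,
                 sv_size_range = sv_size_range, depth = depth,
                 read_length = read_length, noise_rate = noise_rate,
                 hom_frac = hom_frac, platform = platform,
                 seed = as.integer(seed)),
            class = "lrsv_simspec")
}

random_reference <- function(len) {
  bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  # plant homopolymer runs (>= 5) roughly every 500 bp
  n_runs <- max(1L, len %/% 500L)
  pos <- sort(sample.int(len - 20L, n_runs))
  for (p in pos) {
    rl <- sample(5:15, 1)
    bases[p:(p + rl - 1L)] <- sample(c("A", "C", "G", "T"), 1)
  }
  paste(bases, collapse = "")
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# place n footprints of given sizes in [0, len) with >= spacing bp
# between them and from the contig ends; returns start positions
place_events <- function(sizes, len, spacing) {
  n <- length(sizes)
  if (n == 0L) return(integer(0))
  need <- sum(sizes) + (n + 1) * spacing
  if (need > len) {
    stop("infeasible placement: ", n, " events of total footprint ",
         sum(sizes), " bp do not fit in ", len,
         " bp with ", spacing, " bp spacing")
  }
  slack <- len - need
  cuts <- sort(stats::runif(n, 0, slack))
  starts <- numeric(n)
  cursor <- 0
  prev_cut <- 0
  for (i in seq_len(n)) {
    cursor <- cursor + spacing + (cuts[i] - prev_cut)
    starts[i] <- floor(cursor)
    cursor <- cursor + sizes[i]
    prev_cut <- cuts[i]
  }
  as.integer(starts)
}

#' Generate a reference and an implanted truth set
#'
#' Writes `ref.fa` (+ index) and `truth.vcf` under `dir` and returns the
#' truth in memory.  Events are placed non-overlapping with at least two
#' read lengths between footprints; translocation junctions pair a
#' breakpoint on the first contig with one on the second (paired in
#' coordinate order, so the two derivative chromosomes are consistent).
#'
#' @param spec A [simulation_spec()].
#' @param dir Output directory (created if needed).
#' @return List with `ref_path`, `truth_path`, `reference` (named
#'   character vector of contig sequences), `contigs` (named lengths)
#'   and `svs` (data frame: id, type, contig, start, end, length,
#'   genotype, contig2, pos2, ins_seq).
#' @export
generate_truth <- function(spec, dir) {
  stopifnot(inherits(spec, "lrsv_simspec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  len1 <- as.integer(round(spec$ref_length * 0.5))
  len2 <- as.integer(spec$ref_length - len1)
  contigs <- c(chr1 = len1, chr2 = len2)
  reference <- c(chr1 = random_reference(len1),
                 chr2 = random_reference(len2))

  n <- spec$n_sv
  draw_size <- function(k) {
    as.integer(round(exp(stats::runif(
      k, log(spec$sv_size_range[1]), log(spec$sv_size_range[2])))))
  }
  ev <- data.frame(
    type = rep(names(n), n), stringsAsFactors = FALSE)
  if (nrow(ev) == 0L) {
    ev <- data.frame(type = character(0), length = integer(0),
                     footprint = integer(0), contig = character(0),
                     start = integer(0), end = integer(0),
                     contig2 = character(0), pos2 = integer(0),
                     genotype = character(0), ins_seq = character(0),
                     id = character(0), stringsAsFactors = FALSE)
    ref_path <- file.path(dir, "ref.fa")
    writeLines(unlist(lapply(names(reference), function(nm) {
      c(paste0(">", nm),
        substring(reference[[nm]],
                  seq(1, nchar(reference[[nm]]), 70),
                  pmin(seq(1, nchar(reference[[nm]]), 70) + 69,
                       nchar(reference[[nm]]))))
    })), ref_path)
    Rsamtools::indexFa(ref_path)
    truth_path <- file.path(dir, "truth.vcf")
    write_vcf(list(), contigs, truth_path, sample_name = "TRUTH",
              command = "lrsv simulate")
    return(list(ref_path = ref_path, truth_path = truth_path,
                reference = reference, contigs = contigs, svs = ev))
  }
  ev$length <- draw_size(nrow(ev))
  ev$length[ev$type == "TRA"] <- 0L
  ev$footprint <- ifelse(ev$type %in% c("DEL", "DUP", "INV"),
                         ev$length, 1L)
  # TRA p-side goes on chr1 (mates on chr2); other events are split
  # across the contigs in balanced counts so placement stays feasible
  ev$contig <- "chr1"
  non_tra <- which(ev$type != "TRA")
  ev$contig[non_tra] <- sample(rep(names(contigs),
                                   length.out = length(non_tra)))
  spacing <- 2L * spec$read_length
  starts <- integer(nrow(ev))
  tra <- which(ev$type == "TRA")
  q_pos <- integer(0)
  for (ctg in names(contigs)) {
    idx <- which(ev$contig == ctg)
    # TRA mate breakpoints occupy point slots on chr2, placed jointly
    # with chr2's own events so every slot respects the spacing rule
    extra <- if (ctg == "chr2") length(tra) else 0L
    n_all <- length(idx) + extra
    if (n_all == 0L) next
    sizes_all <- c(ev$footprint[idx], rep(1L, extra))
    ord <- sample.int(n_all)   # shuffle type order along the contig
    pos <- place_events(sizes_all[ord], contigs[[ctg]], spacing)
    placed <- integer(n_all)
    placed[ord] <- pos
    if (length(idx)) starts[idx] <- placed[seq_along(idx)]
    if (extra) q_pos <- placed[length(idx) + seq_len(extra)]
  }
  ev$start <- starts
  ev$end <- ev$start + ifelse(ev$type %in% c("DEL", "DUP", "INV"),
                              ev$length, 0L)
  ev$contig2 <- NA_character_
  ev$pos2 <- NA_integer_
  if (length(tra)) {
    # pair p and q in coordinate order for consistent derivatives
    ord_p <- order(ev$start[tra])
    ev$contig2[tra[ord_p]] <- "chr2"
    ev$pos2[tra[ord_p]] <- sort(q_pos)
  }
  ev$genotype <- ifelse(stats::runif(nrow(ev)) < spec$hom_frac,
                        "1/1", "0/1")
  ev$ins_seq <- NA_character_
  ins <- which(ev$type == "INS")
  for (i in ins) ev$ins_seq[i] <- random_seq(ev$length[i])
  ev <- ev[order(match(ev$contig, names(contigs)), ev$start), ,
           drop = FALSE]
  ev$id <- sprintf("truth_%03d", seq_len(nrow(ev)))
  rownames(ev) <- NULL

  ref_path <- file.path(dir, "ref.fa")
  writeLines(unlist(lapply(names(reference), function(nm) {
    c(paste0(">", nm),
      substring(reference[[nm]],
                seq(1, nchar(reference[[nm]]), 70),
                pmin(seq(1, nchar(reference[[nm]]), 70) + 69,
                     nchar(reference[[nm]]))))
  })), ref_path)
  Rsamtools::indexFa(ref_path)

  truth_path <- file.path(dir, "truth.vcf")
  truth_calls <- lapply(seq_len(nrow(ev)), function(i) {
    r <- ev[i, ]
    list(type = r$type, contig = r$contig, start = r$start, end = r$end,
         length = r$length, contig2 = r$contig2, pos2 = r$pos2,
         support = NA_integer_, genotype = r$genotype, filter = "PASS")
  })
  write_vcf(truth_calls, contigs, truth_path, sample_name = "TRUTH",
            command = "lrsv simulate")

  list(ref_path = ref_path, truth_path = truth_path,
       reference = reference, contigs = contigs, svs = ev)
}

# --- donor block model -----------------------------------------------------
# A block: list(contig, ref_start, len, strand, kind = "ref"|"ins",
#               seq (ins only), sv (truth id or NA))

contig_blocks <- function(contig, events, from, to) {
  blocks <- list()
  cursor <- from
  push <- function(b) blocks[[length(blocks) + 1L]] <<- b
  evs <- events[events$contig == contig & events$start >= from &
                events$end <= to & events$start < to &
                events$type != "TRA", , drop = FALSE]
  if (nrow(evs)) evs <- evs[order(evs$start), , drop = FALSE]
  for (i in seq_len(nrow(evs))) {
    e <- evs[i, ]
    if (e$start > cursor) {
      push(list(contig = contig, ref_start = cursor,
                len = e$start - cursor, strand = "+", kind = "ref",
                sv = NA_character_))
    }
    if (e$type == "DEL") {
      # zero-length marker so the per-read manifest can attribute
      # deletion carriers; skipped during read assembly
      push(list(contig = contig, ref_start = e$start, len = 0L,
                strand = "+", kind = "ref", sv = e$id))
      cursor <- e$end
    } else if (e$type == "INS") {
      push(list(contig = contig, ref_start = e$start, len = e$length,
                strand = "+", kind = "ins", seq = e$ins_seq, sv = e$id))
      cursor <- e$start
    } else if (e$type == "DUP") {
      push(list(contig = contig, ref_start = e$start, len = e$length,
                strand = "+", kind = "ref", sv = NA_character_))
      push(list(contig = contig, ref_start = e$start, len = e$length,
                strand = "+", kind = "ref", sv = e$id))
      cursor <- e$end
    } else if (e$type == "INV") {
      push(list(contig = contig, ref_start = e$start, len = e$length,
                strand = "-", kind = "ref", sv = e$id))
      cursor <- e$end
    }
  }
  if (to > cursor) {
    push(list(contig = contig, ref_start = cursor, len = to - cursor,
              strand = "+", kind = "ref", sv = NA_character_))
  }
  blocks
}

# Donor contigs of one haplotype: per-contig block lists, restructured
# across the two reference contigs when the haplotype carries
# translocations (derivative chromosomes from paired junctions).
donor_contigs <- function(events, contigs) {
  tra <- events[events$type == "TRA", , drop = FALSE]
  if (nrow(tra) == 0L) {
    return(lapply(names(contigs), function(ctg) {
      contig_blocks(ctg, events, 0L, contigs[[ctg]])
    }))
  }
  tra <- tra[order(tra$start), , drop = FALSE]
  p <- c(tra$start, contigs[["chr1"]])
  q <- c(tra$pos2, contigs[["chr2"]])
  derA <- list(); derB <- list()
  # derA: chr1[0,p1) chr2[q1,q2) chr1[p2,p3) ...
  cur <- "chr1"; i <- 1L; lo <- 0L
  repeat {
    if (cur == "chr1") {
      derA <- c(derA, contig_blocks("chr1", events, lo, p[i]))
      if (i > nrow(tra)) break
      lo <- q[i]; cur <- "chr2"; i <- i + 1L
    } else {
      derA <- c(derA, contig_blocks("chr2", events, lo, q[i]))
      if (i > nrow(tra)) break
      lo <- p[i]; cur <- "chr1"; i <- i + 1L
    }
  }
  cur <- "chr2"; i <- 1L; lo <- 0L
  repeat {
    if (cur == "chr2") {
      derB <- c(derB, contig_blocks("chr2", events, lo, q[i]))
      if (i > nrow(tra)) break
      lo <- p[i]; cur <- "chr1"; i <- i + 1L
    } else {
      derB <- c(derB, contig_blocks("chr1", events, lo, p[i]))
      if (i > nrow(tra)) break
      lo <- q[i]; cur <- "chr2"; i <- i + 1L
    }
  }
  list(derA, derB)
}

# --- read synthesis --------------------------------------------------------

PLATFORM_NOISE <- list(
  CLR = list(indel_rate = 0.002, mismatch_rate = 0.05),
  ONT = list(indel_rate = 0.002, mismatch_rate = 0.05),
  CCS = list(indel_rate = 2e-04, mismatch_rate = 0.005)
)

SPLIT_MAX <- 1000L   # gaps larger than this are represented as splits
SEG_MIN <- 100L      # aligned segments shorter than this are dropped

# slice the donor pieces overlapped by donor interval [t0, t0 + L)
read_pieces <- function(blocks, cum, t0, L) {
  t1 <- t0 + L
  out <- list()
  for (i in seq_along(blocks)) {
    b0 <- cum[i]; b1 <- cum[i + 1L]
    if (b1 <= t0) next
    if (b0 >= t1) break
    d0 <- max(t0, b0) - b0
    d1 <- min(t1, b1) - b0
    b <- blocks[[i]]
    p <- list(kind = b$kind, contig = b$contig, strand = b$strand,
              len = d1 - d0, sv = b$sv)
    if (b$kind == "ins") {
      p$seq_from <- d0 + 1L
      p$seq_to <- d1
      p$seq <- substr(b$seq, d0 + 1L, d1)
    } else if (b$strand == "+") {
      p$ref_start <- b$ref_start + d0
      p$ref_end <- b$ref_start + d1
    } else {
      p$ref_start <- b$ref_start + b$len - d1
      p$ref_end <- b$ref_start + b$len - d0
    }
    out[[length(out) + 1L]] <- p
  }
  out
}

# emit a noisy match run: small sequencing indels inside an M stretch
noisy_match <- function(m, refslice, indel_rate) {
  k <- stats::rpois(1, m * indel_rate)
  if (k == 0L || m < 40L) {
    return(list(ops = list(c("M", m)), seq = refslice, nm = 0L))
  }
  pos <- sort(sample.int(m - 20L, min(k, max(1L, m %/% 50L))))
  pos <- pos[c(TRUE, diff(pos) > 15L)]   # keep noise events apart
  ops <- list(); chunks <- character(0); nm <- 0L
  cur <- 0L   # consumed ref bases of this run
  for (p in pos) {
    if (p <= cur) next
    size <- sample(1:8, 1)
    ops[[length(ops) + 1L]] <- c("M", p - cur)
    chunks <- c(chunks, substr(refslice, cur + 1L, p))
    if (stats::runif(1) < 0.5) {          # insertion of junk bases
      ops[[length(ops) + 1L]] <- c("I", size)
      chunks <- c(chunks, random_seq(size))
      cur <- p
    } else {                              # deletion: skip ref bases
      size <- min(size, m - p - 1L)
      if (size < 1L) { cur <- p; ops[[length(ops)]] <- NULL; chunks <- chunks[-length(chunks)]; next }
      ops[[length(ops) + 1L]] <- c("D", size)
      cur <- p + size
    }
    nm <- nm + size
  }
  if (m > cur) {
    ops[[length(ops) + 1L]] <- c("M", m - cur)
    chunks <- c(chunks, substr(refslice, cur + 1L, m))
  }
  list(ops = ops, seq = paste(chunks, collapse = ""), nm = nm)
}

new_segment <- function(contig, strand, a, b, q0, q1, ops, seq, nm) {
  list(contig = contig, strand = strand, ref_start = a, ref_end = b,
       q_start = q0, q_end = q1, ops = ops, seq = seq, nm = nm,
       mapq = 60L)
}

# assemble aligned segments + full read sequence from donor pieces
assemble_read <- function(pieces, reference, indel_rate) {
  segments <- list(); seg <- NULL
  q <- 0L; pending_ins <- 0L; pending_seq <- ""
  seq_chunks <- character(0)
  close_seg <- function() {
    if (!is.null(seg)) segments[[length(segments) + 1L]] <<- seg
    seg <<- NULL
  }
  for (p in pieces) {
    if (p$len == 0L) next   # zero-length manifest markers
    if (p$kind == "ins") {
      seq_chunks <- c(seq_chunks, p$seq)
      if (p$len > SPLIT_MAX || is.null(seg)) {
        close_seg()
        pending_ins <- 0L; pending_seq <- ""
      } else {
        pending_ins <- pending_ins + p$len
        pending_seq <- paste0(pending_seq, p$seq)
      }
      q <- q + p$len
      next
    }
    refslice <- substr(reference[[p$contig]], p$ref_start + 1L, p$ref_end)
    if (p$strand == "-") refslice <- revcomp(refslice)
    nm <- noisy_match(p$len, refslice, indel_rate)
    seq_chunks <- c(seq_chunks, nm$seq)
    q0 <- q; q <- q + p$len +
      sum(vapply(nm$ops, function(o) {
        if (o[1] == "I") as.integer(o[2]) else if (o[1] == "D") -as.integer(o[2]) else 0L
      }, 1L))
    # q advanced by read bases: M + I of the noisy run
    cont <- FALSE
    if (!is.null(seg) && seg$contig == p$contig && seg$strand == p$strand) {
      gap <- if (p$strand == "+") p$ref_start - seg$ref_end
             else seg$ref_start - p$ref_end
      if (gap >= 0L && gap <= SPLIT_MAX) cont <- TRUE
    }
    if (cont) {
      if (pending_ins > 0L) seg$ops[[length(seg$ops) + 1L]] <- c("I", pending_ins)
      if (gap > 0L) seg$ops[[length(seg$ops) + 1L]] <- c("D", gap)
      seg$ops <- c(seg$ops, nm$ops)
      seg$seq <- paste0(seg$seq, pending_seq, nm$seq)
      seg$nm <- seg$nm + nm$nm
      if (p$strand == "+") seg$ref_end <- p$ref_end else seg$ref_start <- p$ref_start
      seg$q_end <- q
    } else {
      close_seg()
      seg <- new_segment(p$contig, p$strand, p$ref_start, p$ref_end,
                         q0, q, nm$ops, nm$seq, nm$nm)
    }
    pending_ins <- 0L; pending_seq <- ""
  }
  close_seg()
  list(segments = segments, seq = paste(seq_chunks, collapse = ""),
       read_len = q)
}

# spurious 30-80 bp gap inside the longest segment's largest M run
inject_spurious_gap <- function(segments) {
  if (!length(segments)) return(list(segments = segments, hit = FALSE))
  si <- which.max(vapply(segments, function(s) s$q_end - s$q_start, 1L))
  seg <- segments[[si]]
  mlens <- vapply(seg$ops, function(o) {
    if (o[1] == "M") as.integer(o[2]) else 0L
  }, 1L)
  oi <- which.max(mlens)
  m <- mlens[oi]
  if (m < 300L) return(list(segments = segments, hit = FALSE))
  g <- sample(30:80, 1)
  x <- sample.int(m - g - 100L, 1) + 50L
  if (stats::runif(1) < 0.5) {
    # spurious deletion: ref span grows, read unchanged
    repl <- list(c("M", x), c("D", g), c("M", m - x))
    seg$ref_end <- seg$ref_end + g
  } else {
    # spurious insertion: g read bases flagged as inserted
    repl <- list(c("M", x), c("I", g), c("M", m - x - g))
    seg$ref_end <- seg$ref_end - g
  }
  seg$ops <- append(seg$ops[-oi], repl, after = oi - 1L)
  seg$nm <- seg$nm + g
  segments[[si]] <- seg
  list(segments = segments, hit = TRUE)
}

# spurious low-quality split fragment: clip the primary's tail and remap
# it to a random location
inject_spurious_split <- function(segments, contigs, read_len) {
  if (!length(segments)) return(list(segments = segments, hit = FALSE))
  si <- which.max(vapply(segments, function(s) s$q_end - s$q_start, 1L))
  seg <- segments[[si]]
  last <- seg$ops[[length(seg$ops)]]
  chunk <- sample(300:800, 1)
  if (last[1] != "M" || as.integer(last[2]) < chunk + 300L) {
    return(list(segments = segments, hit = FALSE))
  }
  keep <- as.integer(last[2]) - chunk
  seg$ops[[length(seg$ops)]] <- c("M", keep)
  if (seg$strand == "+") seg$ref_end <- seg$ref_end - chunk
  else seg$ref_start <- seg$ref_start + chunk
  tail_seq <- substr(seg$seq, nchar(seg$seq) - chunk + 1L, nchar(seg$seq))
  seg$seq <- substr(seg$seq, 1L, nchar(seg$seq) - chunk)
  q0 <- seg$q_end - chunk
  seg$q_end <- q0
  ctg <- sample(names(contigs), 1)
  pos <- sample.int(contigs[[ctg]] - chunk - 1L, 1)
  fake <- new_segment(ctg, sample(c("+", "-"), 1), pos, pos + chunk,
                      q0, q0 + chunk, list(c("M", chunk)), tail_seq,
                      as.integer(round(chunk * 0.15)))
  fake$mapq <- sample(20:40, 1)
  segments[[si]] <- seg
  list(segments = c(segments, list(fake)), hit = TRUE)
}

ops_to_cigar <- function(ops) {
  paste(vapply(ops, function(o) paste0(o[2], o[1]), ""), collapse = "")
}

# SAM line(s) for one read's segments
sam_records <- function(qname, segments, seq, read_len, mismatch_rate) {
  keep <- vapply(segments, function(s) {
    sum(vapply(s$ops, function(o) if (o[1] == "M") as.integer(o[2]) else 0L,
               1L)) >= SEG_MIN
  }, TRUE)
  segments <- segments[keep]
  if (!length(segments)) return(character(0))
  alen <- vapply(segments, function(s) s$ref_end - s$ref_start, 1L)
  pri <- which.max(alen)
  nm_tot <- vapply(segments, function(s) {
    s$nm + as.integer(round((s$ref_end - s$ref_start) * mismatch_rate))
  }, 1L)

  seg_cigar <- function(s, hard) {
    left <- s$q_start
    right <- read_len - s$q_end
    ops <- s$ops
    if (s$strand == "-") { ops <- rev(ops); tmp <- left; left <- right; right <- tmp }
    clip <- if (hard) "H" else "S"
    paste0(if (left > 0L) paste0(left, clip) else "",
           ops_to_cigar(ops),
           if (right > 0L) paste0(right, clip) else "")
  }
  sa_of <- function(i) {
    others <- setdiff(seq_along(segments), i)
    if (!length(others)) return(NULL)
    paste0(vapply(others, function(j) {
      s <- segments[[j]]
      sprintf("%s,%d,%s,%s,%d,%d;", s$contig, s$ref_start + 1L, s$strand,
              seg_cigar(s, hard = j != pri), s$mapq, nm_tot[j])
    }, ""), collapse = "")
  }
  vapply(seq_along(segments), function(i) {
    s <- segments[[i]]
    is_pri <- i == pri
    flag <- 0L
    if (s$strand == "-") flag <- flag + 16L
    if (!is_pri) flag <- flag + 2048L
    if (is_pri) {
      sq <- seq
      if (s$strand == "-") sq <- revcomp(sq)
    } else {
      sq <- s$seq
      if (s$strand == "-") sq <- revcomp(sq)
    }
    sa <- sa_of(i)
    paste(c(qname, flag, s$contig, s$ref_start + 1L, s$mapq,
            seg_cigar(s, hard = !is_pri), "*", 0L, 0L, sq, "*",
            paste0("NM:i:", nm_tot[i]),
            if (!is.null(sa)) paste0("SA:Z:", sa)),
          collapse = "\t")
  }, "")
}

#' Simulate alignments for a truth set
#'
#' Samples reads from the diploid donor implied by the truth set and
#' writes a coordinate-sorted, indexed BAM plus a per-read manifest
#' (`manifest.tsv`: read name, haplotype, donor span, SV ids covered,
#' noise flags).  Reads crossing an implanted event carry the
#' corresponding CIGAR gap or split structure; platform noise adds
#' small indels everywhere and, at `noise_rate`, spurious gaps/splits.
#'
#' @param truth Output of [generate_truth()].
#' @param spec The same [simulation_spec()].
#' @param dir Output directory.
#' @return List with `bam_path`, `manifest` (data frame) and
#'   `manifest_path`.
#' @export
simulate_alignments <- function(truth, spec, dir) {
  stopifnot(inherits(spec, "lrsv_simspec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed + 1L)
  ev <- truth$svs
  het <- ev$genotype == "0/1"
  het_hap <- ifelse(stats::runif(nrow(ev)) < 0.5, 1L, 2L)
  hap_events <- list(
    ev[!het | het_hap == 1L, , drop = FALSE],
    ev[!het | het_hap == 2L, , drop = FALSE]
  )
  noise <- PLATFORM_NOISE[[spec$platform]]
  rl <- spec$read_length
  sam <- character(0)
  manifest <- list()
  ridx <- 0L
  for (hap in 1:2) {
    donors <- donor_contigs(hap_events[[hap]], truth$contigs)
    for (di in seq_along(donors)) {
      blocks <- donors[[di]]
      lens <- vapply(blocks, function(b) b$len, 1L)
      cum <- c(0L, cumsum(lens))
      dlen <- cum[length(cum)]
      n_reads <- as.integer(round(spec$depth / 2 * (dlen + rl) / rl))
      if (n_reads == 0L) next
      t0s <- as.integer(floor(stats::runif(n_reads, -rl, dlen)))
      lread <- pmax(500L, as.integer(round(stats::rnorm(n_reads, rl, 0.1 * rl))))
      for (k in seq_len(n_reads)) {
        t0 <- max(0L, t0s[k])
        t1 <- min(dlen, t0s[k] + lread[k])
        if (t1 - t0 < 500L) next
        pieces <- read_pieces(blocks, cum, t0, t1 - t0)
        if (!length(pieces)) next
        asm <- assemble_read(pieces, truth$reference, noise$indel_rate)
        if (!length(asm$segments)) next
        ridx <- ridx + 1L
        qname <- sprintf("read_%06d", ridx)
        gap_hit <- FALSE; split_hit <- FALSE
        if (stats::runif(1) < spec$noise_rate) {
          r <- inject_spurious_gap(asm$segments)
          asm$segments <- r$segments; gap_hit <- r$hit
        }
        if (stats::runif(1) < spec$noise_rate / 2) {
          r <- inject_spurious_split(asm$segments, truth$contigs,
                                     asm$read_len)
          asm$segments <- r$segments; split_hit <- r$hit
        }
        recs <- sam_records(qname, asm$segments, asm$seq, asm$read_len,
                            noise$mismatch_rate)
        if (!length(recs)) { ridx <- ridx - 1L; next }
        sam <- c(sam, recs)
        svs <- unique(stats::na.omit(
          vapply(pieces, function(p) p$sv %||% NA_character_, "")))
        manifest[[length(manifest) + 1L]] <- list(
          read = qname, hap = hap, donor = di, donor_start = t0,
          length = t1 - t0, svs = paste(svs, collapse = ","),
          spurious_gap = gap_hit, spurious_split = split_hit,
          n_records = length(recs))
      }
    }
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(truth$contigs),
                   truth$contigs))
  sam_path <- file.path(dir, "reads.sam")
  writeLines(c(hdr, sam), sam_path)
  bam_tmp <- Rsamtools::asBam(sam_path,
                              destination = file.path(dir, "reads.unsorted"),
                              overwrite = TRUE, indexDestination = FALSE)
  bam_path <- Rsamtools::sortBam(bam_tmp, file.path(dir, "reads"))
  Rsamtools::indexBam(bam_path)
  unlink(c(sam_path, bam_tmp))
  manifest <- data.frame(
    read = vapply(manifest, `[[`, "", "read"),
    hap = vapply(manifest, `[[`, 1L, "hap"),
    donor = vapply(manifest, `[[`, 1L, "donor"),
    donor_start = vapply(manifest, `[[`, 1L, "donor_start"),
    length = vapply(manifest, function(m) as.integer(m$length), 1L),
    svs = vapply(manifest, `[[`, "", "svs"),
    spurious_gap = vapply(manifest, `[[`, TRUE, "spurious_gap"),
    spurious_split = vapply(manifest, `[[`, TRUE, "spurious_split"),
    n_records = vapply(manifest, function(m) as.integer(m$n_records), 1L),
    stringsAsFactors = FALSE)
  manifest_path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  list(bam_path = bam_path, manifest = manifest,
       manifest_path = manifest_path)
}

#' Simulate a complete sample (truth + alignments)
#'
#' @param spec A [simulation_spec()].
#' @param dir Output directory.
#' @return Combined list from [generate_truth()] and
#'   [simulate_alignments()].
#' @export
simulate_sample <- function(spec, dir) {
  truth <- generate_truth(spec, dir)
  aln <- simulate_alignments(truth, spec, dir)
  c(truth, aln)
}
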