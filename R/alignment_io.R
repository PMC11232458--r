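# Alignment input and VCF output.
#
# Internal coordinates are 0-based half-open everywhere; the single
# conversion to VCF's 1-based convention happens inside write_vcf()
# (POS is the anchor base before the event, END the last affected base,
# which numerically equal the 0-based start and exclusive end).

LRSV_VERSION <- "0.1.0"

parse_sa_tag <- function(sa) {
  if (is.null(sa) || is.na(sa) || !nzchar(sa)) return(list())
  entries <- strsplit(sa, ";", fixed = TRUE)[[1]]
  lapply(entries[nzchar(entries)], function(e) {
    f <- strsplit(e, ",", fixed = TRUE)[[1]]
    list(contig = f[1], pos = as.integer(f[2]) - 1L, strand = f[3],
         cigar = f[4], mapq = as.integer(f[5]))
  })
}

#' Stream alignment records from a BAM file
#'
#' Reads primary and supplementary alignments (secondary and unmapped
#' records are excluded, as are records below `mapq_floor`) and exposes
#' them as plain R lists with parsed CIGARs, NM/SA tags and 0-based
#' half-open reference coordinates.
#'
#' @param path Coordinate-sorted, indexed BAM file.
#' @param region Optional `list(contig =, start =, end =)` with 0-based
#'   half-open coordinates; only overlapping records are returned.
#' @param mapq_floor Records below this MAPQ are dropped (default 20).
#' @return List of alignment-record lists, in coordinate order, each with
#'   `read_name`, `contig`, `ref_start`, `ref_end`, `mapq`, `strand`,
#'   `is_primary`, `is_supplementary`, `cigar` (parsed), `edit_distance`,
#'   `sa_entries`, `read_sequence`, `read_length`.
#' @export
stream_alignments <- function(path, region = NULL, mapq_floor = 20) {
  if (!file.exists(path)) stop("BAM not found: ", path)
  bai <- paste0(path, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", path))) {
    stop("BAM index (.bai) not found for ", path)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE)
  what <- c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar", "seq")
  if (is.null(region)) {
    param <- Rsamtools::ScanBamParam(what = what, tag = c("NM", "SA"),
                                     flag = flag)
  } else {
    gr <- GenomicRanges::GRanges(
      region$contig, IRanges::IRanges(region$start + 1L, region$end))
    param <- Rsamtools::ScanBamParam(what = what, tag = c("NM", "SA"),
                                     flag = flag, which = gr)
  }
  res <- Rsamtools::scanBam(path, param = param)
  res <- if (length(res) == 1L) res[[1]] else {
    # concatenate multi-range results
    out <- res[[1]]
    for (r in res[-1]) {
      for (nm in names(out)) {
        if (nm == "tag") {
          out$tag$NM <- c(out$tag$NM, r$tag$NM)
          out$tag$SA <- c(out$tag$SA, r$tag$SA)
        } else out[[nm]] <- c(out[[nm]], r[[nm]])
      }
    }
    out
  }
  n <- length(res$qname)
  if (n == 0L) return(list())
  seqs <- as.character(res$seq)
  records <- vector("list", n)
  kept <- 0L
  for (i in seq_len(n)) {
    if (is.na(res$mapq[i]) || res$mapq[i] < mapq_floor) next
    cig <- parse_cigar(res$cigar[i])
    start0 <- res$pos[i] - 1L
    suppl <- bitwAnd(res$flag[i], 2048L) > 0L
    sq <- seqs[i]
    if (!nzchar(sq) || sq == "*") sq <- NA_character_
    records[[kept + 1L]] <- list(
      read_name = res$qname[i],
      contig = as.character(res$rname[i]),
      ref_start = start0,
      ref_end = start0 + cigar_ref_span(cig),
      mapq = as.integer(res$mapq[i]),
      strand = as.character(res$strand[i]),
      is_primary = !suppl,
      is_supplementary = suppl,
      cigar = cig,
      edit_distance = if (is.null(res$tag$NM)) NA_integer_ else res$tag$NM[i],
      sa_entries = parse_sa_tag(if (is.null(res$tag$SA)) NA else res$tag$SA[i]),
      read_sequence = sq,
      read_length = cigar_query_len(cig, include_hard = TRUE)
    )
    kept <- kept + 1L
  }
  records[seq_len(kept)]
}

#' Read contig names and lengths from a FASTA index
#'
#' @param fasta_path FASTA file; a `.fai` index is created if absent.
#' @return Named integer vector of contig lengths in FASTA order.
#' @export
fasta_contigs <- function(fasta_path) {
  fai <- paste0(fasta_path, ".fai")
  if (!file.exists(fai)) Rsamtools::indexFa(fasta_path)
  idx <- utils::read.table(fai, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(as.integer(idx[[2]]), as.character(idx[[1]]))
}

format_info <- function(call) {
  if (call$type == "TRA") return(NULL)
  svlen <- if (call$type == "DEL") -call$length else call$length
  # VCF convention: an insertion's END equals its POS
  endp <- if (call$type == "INS") call$start else call$end
  sprintf("SVTYPE=%s;SVLEN=%d;END=%d;SUPPORT=%d",
          call$type, as.integer(svlen), as.integer(endp),
          as.integer(call$support))
}

format_sample <- function(call) {
  gt <- call$genotype %||% "./."
  ref <- call$ref_support %||% NA_integer_
  alt <- call$alt_support %||% as.integer(call$support)
  dp <- if (is.na(ref)) "." else as.character(ref + alt)
  ad <- if (is.na(ref)) paste0(".,", alt) else paste0(ref, ",", alt)
  paste(gt, dp, ad, sep = ":")
}

#' Write structural-variant calls to VCF 4.2
#'
#' DEL/INS/DUP/INV calls are written as symbolic-ALT records with
#' `SVTYPE`, `SVLEN`, `END` and `SUPPORT` in INFO and `GT:DP:AD` in the
#' sample column; translocations become paired breakend (BND) records.
#' Internal 0-based half-open coordinates are converted here and only
#' here: `POS` is the anchor base before the event and `END` the last
#' affected reference base.
#'
#' @param calls List of call objects sorted by contig then start.
#' @param contigs Named integer vector of contig lengths (header order).
#' @param path Output path.
#' @param sample_name Sample column name (default `"SAMPLE"`).
#' @param command Command line recorded in the header (optional).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, contigs, path, sample_name = "SAMPLE",
                      command = NULL) {
  for (call in calls) {
    if (!call$contig %in% names(contigs)) {
      stop("call contig absent from header: ", call$contig)
    }
  }
  if (length(calls) > 1L) {
    key_c <- vapply(calls, function(x) match(x$contig, names(contigs)), 1)
    key_s <- vapply(calls, function(x) x$start, 1)
    o <- order(key_c, key_s)
    if (!identical(o, seq_along(calls))) {
      stop("calls must be sorted by contig then position")
    }
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=lrsv-%s", LRSV_VERSION),
    if (!is.null(command)) sprintf("##commandline=%s", command),
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=INS,Description=\"Insertion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length (negative for deletions)\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Distinct supporting reads\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend id\">",
    "##FILTER=<ID=low_support,Description=\"Support below the minimum read threshold\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype (translocation genotypes are low-confidence)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Ref + alt supporting reads\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Ref and alt read counts\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  body <- character(0)
  idx <- 0L
  for (call in calls) {
    idx <- idx + 1L
    filt <- call$filter %||% "PASS"
    qual <- call$gt_quality %||% "."
    smp <- format_sample(call)
    if (call$type == "TRA") {
      id1 <- sprintf("lrsv.BND.%d.1", idx)
      id2 <- sprintf("lrsv.BND.%d.2", idx)
      pos1 <- max(1L, as.integer(call$start))
      pos2 <- max(1L, as.integer(call$pos2))
      info1 <- sprintf("SVTYPE=BND;MATEID=%s;SUPPORT=%d", id2,
                       as.integer(call$support))
      info2 <- sprintf("SVTYPE=BND;MATEID=%s;SUPPORT=%d", id1,
                       as.integer(call$support))
      alt1 <- sprintf("N[%s:%d[", call$contig2, pos2)
      alt2 <- sprintf("N]%s:%d]", call$contig, pos1)
      body <- c(body,
        paste(call$contig, pos1, id1, "N", alt1, qual, filt, info1,
              "GT:DP:AD", smp, sep = "\t"),
        paste(call$contig2, pos2, id2, "N", alt2, qual, filt, info2,
              "GT:DP:AD", smp, sep = "\t"))
    } else {
      pos <- max(1L, as.integer(call$start))
      body <- c(body,
        paste(call$contig, pos, sprintf("lrsv.%s.%d", call$type, idx), "N",
              sprintf("<%s>", call$type), qual, filt, format_info(call),
              "GT:DP:AD", smp, sep = "\t"))
    }
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Parse a VCF of structural-variant calls
#'
#' Reads the subset of VCF 4.2 that [write_vcf()] emits (symbolic SV
#' ALTs plus paired breakends) back into call objects; also understands
#' the truth VCFs written by the simulator.  Paired BND records are
#' folded into one translocation call.
#'
#' @param path VCF file.
#' @return List with `calls` (list of call objects, 0-based half-open
#'   coordinates) and `contigs` (named lengths from the header).
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "##")]
  contig_lines <- hdr[startsWith(hdr, "##contig=")]
  contigs <- integer(0)
  if (length(contig_lines)) {
    ids <- sub(".*ID=([^,>]+).*", "\\1", contig_lines)
    lens <- as.integer(sub(".*length=([0-9]+).*", "\\1", contig_lines))
    contigs <- stats::setNames(lens, ids)
  }
  rec_lines <- lines[!startsWith(lines, "#")]
  calls <- list()
  seen_bnd <- character(0)
  for (ln in rec_lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    info <- f[8]
    get_info <- function(key) {
      m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
      if (!length(m)) return(NA_character_)
      sub(paste0(".*", key, "="), "", m)
    }
    svtype <- get_info("SVTYPE")
    support <- suppressWarnings(as.integer(get_info("SUPPORT")))
    gt <- NA_character_; ref_sup <- NA_integer_; alt_sup <- NA_integer_
    if (length(f) >= 10) {
      fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
      vals <- strsplit(f[10], ":", fixed = TRUE)[[1]]
      gt <- vals[match("GT", fmt)]
      ad <- vals[match("AD", fmt)]
      if (!is.na(ad)) {
        adv <- strsplit(ad, ",", fixed = TRUE)[[1]]
        ref_sup <- suppressWarnings(as.integer(adv[1]))
        alt_sup <- suppressWarnings(as.integer(adv[2]))
      }
    }
    if (identical(svtype, "BND")) {
      mate <- get_info("MATEID")
      if (f[3] %in% seen_bnd) next   # second record of a seen pair
      seen_bnd <- c(seen_bnd, mate)
      alt <- f[5]
      m <- regmatches(alt, regexpr("[][]([^:]+):([0-9]+)[][]", alt))
      mate_contig <- sub("^[][]([^:]+):.*$", "\\1", m)
      mate_pos <- as.integer(sub("^[][][^:]+:([0-9]+)[][]$", "\\1", m))
      calls[[length(calls) + 1L]] <- list(
        type = "TRA", contig = f[1], start = as.integer(f[2]),
        end = as.integer(f[2]), length = 0L,
        contig2 = mate_contig, pos2 = mate_pos,
        support = support, filter = f[7], genotype = gt,
        gt_quality = suppressWarnings(as.integer(f[6])),
        ref_support = ref_sup, alt_support = alt_sup)
    } else {
      svlen <- suppressWarnings(as.integer(get_info("SVLEN")))
      endp <- suppressWarnings(as.integer(get_info("END")))
      start <- as.integer(f[2])
      endv <- if (identical(svtype, "INS")) start + abs(svlen)
              else if (!is.na(endp)) endp else start
      calls[[length(calls) + 1L]] <- list(
        type = svtype, contig = f[1], start = start,
        end = endv,
        length = abs(svlen),
        contig2 = NA_character_, pos2 = NA_real_,
        support = support, filter = f[7], genotype = gt,
        gt_quality = suppressWarnings(as.integer(f[6])),
        ref_support = ref_sup, alt_support = alt_sup)
    }
  }
  list(calls = calls, contigs = contigs)
}
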