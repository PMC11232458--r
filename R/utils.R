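#' @keywords internal
"_PACKAGE"

SV_TYPES <- c("DEL", "INS", "DUP", "INV", "TRA")

#' Parse a CIGAR string into operation/length vectors
#'
#' @param cigar A single CIGAR string, e.g. `"50S100M40I60M"`.
#' @return A list with `op` (character vector of single-letter operations)
#'   and `len` (integer vector of operation lengths). `"*"` or an empty
#'   string yields zero-length vectors.
#' @examples
#' parse_cigar("100M50D100M")
#' @export
parse_cigar <- function(cigar) {
  if (length(cigar) != 1L || is.na(cigar) || cigar == "*" || !nzchar(cigar)) {
    return(list(op = character(0), len = integer(0)))
  }
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar, perl = TRUE)[[1]]
  if (m[1] == -1L) stop("malformed CIGAR: ", cigar)
  parts <- regmatches(cigar, gregexpr("(\\d+)([MIDNSHP=X])", cigar, perl = TRUE))[[1]]
  if (sum(nchar(parts)) != nchar(cigar)) stop("malformed CIGAR: ", cigar)
  list(
    op  = substr(parts, nchar(parts), nchar(parts)),
    len = as.integer(substr(parts, 1L, nchar(parts) - 1L))
  )
}

cigar_ref_span <- function(cig) {
  sum(cig$len[cig$op %in% c("M", "D", "N", "=", "X")])
}

cigar_query_len <- function(cig, include_hard = TRUE) {
  ops <- c("M", "I", "S", "=", "X")
  if (include_hard) ops <- c(ops, "H")
  sum(cig$len[cig$op %in% ops])
}

cigar_left_clip <- function(cig, include_hard = TRUE) {
  n <- length(cig$op)
  if (n == 0L) return(0L)
  tot <- 0L
  for (i in seq_len(n)) {
    if (cig$op[i] == "H" && include_hard) tot <- tot + cig$len[i]
    else if (cig$op[i] == "S") tot <- tot + cig$len[i]
    else if (cig$op[i] != "H") break
  }
  tot
}

cigar_right_clip <- function(cig, include_hard = TRUE) {
  n <- length(cig$op)
  if (n == 0L) return(0L)
  tot <- 0L
  for (i in rev(seq_len(n))) {
    if (cig$op[i] == "H" && include_hard) tot <- tot + cig$len[i]
    else if (cig$op[i] == "S") tot <- tot + cig$len[i]
    else if (cig$op[i] != "H") break
  }
  tot
}

# Query interval [start, end) of the aligned part of the read, in full
# read-space coordinates (hard clips counted), on the forward strand of
# the read as it was sequenced.
cigar_query_interval <- function(cig, strand) {
  ql <- cigar_query_len(cig, include_hard = TRUE)
  lc <- cigar_left_clip(cig, include_hard = TRUE)
  rc <- cigar_right_clip(cig, include_hard = TRUE)
  if (strand == "+") c(lc, ql - rc) else c(rc, ql - lc)
}

phred <- function(p) -10 * log10(p)

# lower median: for even n take the smaller of the two central values
lower_median <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
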