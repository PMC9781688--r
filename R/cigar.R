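# CIGAR arithmetic. Ops: M/=/X align query to reference; D/N consume reference
# only (N = spliced-out intron); I/S consume query only; H/P consume neither.

.CIGAR_REF <- c("M", "D", "N", "=", "X")
.CIGAR_QUERY <- c("M", "I", "S", "=", "X")

#' Parse one CIGAR string into its operations
#'
#' @param cigar A CIGAR string such as `"5M100N5M"`, or `"*"`.
#' @return A tibble with columns `op` (character) and `len` (integer); zero
#'   rows for `"*"`.
#' @export
cigar_ops <- function(cigar) {
  stopifnot(is.character(cigar), length(cigar) == 1)
  if (cigar == "*" || !nzchar(cigar)) {
    return(tibble::tibble(op = character(), len = integer()))
  }
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (paste(toks, collapse = "") != cigar) {
    stop("unparsable CIGAR string: ", cigar, call. = FALSE)
  }
  len <- as.integer(sub("[MIDNSHP=X]$", "", toks))
  if (any(len <= 0)) stop("CIGAR operation with non-positive length: ", cigar, call. = FALSE)
  tibble::tibble(op = substring(toks, nchar(toks)), len = len)
}

#' Reference span consumed by CIGAR strings
#'
#' @param cigar Character vector of CIGAR strings.
#' @return Integer vector: number of reference bases each alignment consumes
#'   (M/=/X/D/N); 0 for `"*"`.
#' @export
cigar_reference_length <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- cigar_ops(cg)
    sum(ops$len[ops$op %in% .CIGAR_REF])
  }, integer(1), USE.NAMES = FALSE)
}

#' Query length implied by CIGAR strings
#'
#' @param cigar Character vector of CIGAR strings.
#' @return Integer vector: number of query bases (M/I/S/=/X); 0 for `"*"`.
#' @export
cigar_query_length <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- cigar_ops(cg)
    sum(ops$len[ops$op %in% .CIGAR_QUERY])
  }, integer(1), USE.NAMES = FALSE)
}

# Reference intervals where the read places aligned bases (M/=/X), as a
# two-column matrix (start, end), 1-based inclusive. D intervals included only
# when count_deletions is TRUE; N never adds aligned bases.
.aligned_blocks <- function(pos, cigar, count_deletions = FALSE) {
  ops <- cigar_ops(cigar)
  keep_ops <- c("M", "=", "X", if (count_deletions) "D")
  cur <- pos
  starts <- integer(0)
  ends <- integer(0)
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]
    len <- ops$len[i]
    if (op %in% keep_ops) {
      starts <- c(starts, cur)
      ends <- c(ends, cur + len - 1L)
    }
    if (op %in% .CIGAR_REF) cur <- cur + len
  }
  cbind(start = starts, end = ends)
}

# Introns implied by N ops: an N of length L with reference cursor at q (last
# aligned/consumed base) spans skipped bases q+1 .. q+L.
.cigar_introns <- function(pos, cigar) {
  ops <- cigar_ops(cigar)
  cur <- pos
  starts <- integer(0)
  ends <- integer(0)
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]
    len <- ops$len[i]
    if (op == "N") {
      starts <- c(starts, cur)
      ends <- c(ends, cur + len - 1L)
    }
    if (op %in% .CIGAR_REF) cur <- cur + len
  }
  cbind(start = starts, end = ends)
}
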