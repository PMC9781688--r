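#' Read SAM alignment records into a tibble
#'
#' Parses SAM-dialect text: header lines beginning `@` are skipped and the 11
#' mandatory tab-separated columns of each alignment line are kept (optional
#' tags are ignored). Flag bits are decoded into the booleans downstream
#' filters need. `*` sentinels are honoured: an unmapped record or `*` CIGAR
#' yields `is_mapped = FALSE` and an empty CIGAR.
#'
#' @param x Path to a SAM file, or a character vector of SAM lines.
#' @return A tibble with one row per alignment line and columns `qname`,
#'   `flag`, `chrom`, `pos`, `mapq`, `cigar`, `rnext`, `pnext`, `tlen`, `seq`,
#'   `qual`, plus decoded `is_paired`, `is_mapped`, `is_primary`,
#'   `mate_chrom`, `mate_pos`.
#' @export
read_sam <- function(x) {
  if (length(x) == 0) return(.empty_alignments())
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readr::read_lines(x)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  line_no <- seq_along(lines)
  body <- !startsWith(lines, "@") & nzchar(lines)
  lines <- lines[body]
  line_no <- line_no[body]
  if (length(lines) == 0) return(.empty_alignments())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11)) {
    bad <- line_no[which(nf < 11)[1]]
    stop("malformed SAM record at line ", bad, ": fewer than 11 mandatory columns",
         call. = FALSE)
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)

  flag <- suppressWarnings(as.integer(col(2)))
  pos <- suppressWarnings(as.integer(col(4)))
  if (anyNA(flag) || anyNA(pos)) {
    bad <- line_no[which(is.na(flag) | is.na(pos))[1]]
    stop("malformed SAM record at line ", bad, ": non-numeric FLAG or POS", call. = FALSE)
  }
  cigar <- col(6)
  for (i in seq_along(cigar)) {
    ok <- cigar[i] == "*" || tryCatch({cigar_ops(cigar[i]); TRUE}, error = function(e) FALSE)
    if (!ok) stop("malformed SAM record at line ", line_no[i],
                  ": unparsable CIGAR '", cigar[i], "'", call. = FALSE)
  }

  chrom <- col(3)
  rnext <- col(7)
  pnext <- suppressWarnings(as.integer(col(8)))
  is_mapped <- bitwAnd(flag, 4L) == 0L & chrom != "*" & cigar != "*"
  cigar[!is_mapped] <- ""

  tibble::tibble(
    qname = col(1),
    flag = flag,
    chrom = chrom,
    pos = pos,
    mapq = suppressWarnings(as.integer(col(5))),
    cigar = cigar,
    rnext = rnext,
    pnext = pnext,
    tlen = suppressWarnings(as.integer(col(9))),
    seq = col(10),
    qual = col(11),
    is_paired = bitwAnd(flag, 1L) != 0L,
    is_mapped = is_mapped,
    is_primary = bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L,
    mate_chrom = dplyr::case_when(
      rnext == "=" ~ chrom,
      rnext == "*" ~ NA_character_,
      .default = rnext
    ),
    mate_pos = dplyr::if_else(pnext > 0L, pnext, NA_integer_)
  )
}

.empty_alignments <- function() {
  tibble::tibble(
    qname = character(), flag = integer(), chrom = character(), pos = integer(),
    mapq = integer(), cigar = character(), rnext = character(), pnext = integer(),
    tlen = integer(), seq = character(), qual = character(),
    is_paired = logical(), is_mapped = logical(), is_primary = logical(),
    mate_chrom = character(), mate_pos = integer()
  )
}

#' Serialize alignment records back to SAM text
#'
#' Writes the 11 mandatory columns; content read by [read_sam()] round-trips.
#'
#' @param records Alignment tibble from [read_sam()] or [simulate_dataset()].
#' @param path Output path; when `NULL`, the lines are returned invisibly
#'   instead of written.
#' @param header Optional character vector of `@`-prefixed header lines.
#' @return Invisibly, the SAM lines.
#' @export
write_sam <- function(records, path = NULL, header = NULL) {
  cg <- records$cigar
  cg[!nzchar(cg)] <- "*"
  body <- paste(records$qname, records$flag, records$chrom, records$pos,
                records$mapq, cg, records$rnext, records$pnext,
                records$tlen, records$seq, records$qual, sep = "\t")
  lines <- c(header, body)
  if (!is.null(path)) readr::write_lines(lines, path)
  invisible(lines)
}

# Mean Phred base quality per record; NA where QUAL is "*".
.mean_base_quality <- function(qual) {
  vapply(qual, function(q) {
    if (q == "*" || !nzchar(q)) return(NA_real_)
    mean(utf8ToInt(q) - 33L)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Filter alignments on base-call quality
#'
#' Keeps mapped, primary records whose mean Phred base quality is at least
#' `min_q` (the Q20 convention: "above Q20" is read as mean base quality >= 20,
#' inclusive, matching common read-trimming practice). Records without stored
#' base qualities (`QUAL == "*"`) fall back to mapping quality `mapq >= min_q`.
#' Secondary and supplementary alignments are dropped here so that depth never
#' double-counts a read.
#'
#' @param records Alignment tibble from [read_sam()].
#' @param min_q Phred threshold, default 20.
#' @return The filtered tibble, a subset of the input rows.
#' @export
filter_quality <- function(records, min_q = 20) {
  if (min_q < 0) stop("`min_q` must be non-negative", call. = FALSE)
  mq <- .mean_base_quality(records$qual)
  q_ok <- dplyr::if_else(is.na(mq), records$mapq >= min_q, mq >= min_q)
  dplyr::filter(records, .data$is_mapped, .data$is_primary, q_ok)
}

#' Filter alignments to a genomic window, read-pair aware
#'
#' Implements the targeted-window filter: a paired record is kept when its own
#' reference span overlaps the window, or when its mate's start position falls
#' inside it; both mates of a kept pair are retained. This either-mate policy
#' maximizes sensitivity for sparse signal from a weakly expressed locus —
#' reads whose mate anchors in the window are rescued. Single-end records are
#' kept on own-span overlap only. Set `require_both = TRUE` for the stricter
#' policy where both mates must themselves overlap the window.
#'
#' @param records Alignment tibble from [read_sam()].
#' @param region Target [genomic_region()].
#' @param require_both Require both mates of a pair to overlap the window.
#' @return The filtered tibble.
#' @export
filter_region_pairs <- function(records, region, require_both = FALSE) {
  stopifnot(inherits(region, "genomic_region"))
  if (nrow(records) == 0) return(records)
  if (!any(records$chrom == region$chrom)) {
    rlang::inform(paste0("no records on ", region$chrom, "; returning empty set"))
    return(records[0, ])
  }
  ref_len <- cigar_reference_length(records$cigar)
  self_ok <- records$is_mapped &
    records$chrom == region$chrom &
    records$pos <= region$end - 1L &
    records$pos + ref_len - 1L >= region$start
  if (require_both) {
    paired <- records$is_paired
    both_ok_names <- names(which(tapply(self_ok[paired], records$qname[paired], all)))
    keep <- (self_ok & !paired) | (paired & records$qname %in% both_ok_names & self_ok)
    return(records[keep, ])
  }
  mate_ok <- records$is_paired &
    !is.na(records$mate_chrom) & records$mate_chrom == region$chrom &
    !is.na(records$mate_pos) & region_contains(region, records$mate_pos)
  keep <- self_ok | mate_ok
  kept_pairs <- unique(records$qname[keep & records$is_paired])
  keep <- keep | (records$is_paired & records$qname %in% kept_pairs)
  records[keep, ]
}

#' Read a dataset manifest
#'
#' A manifest is a tab-separated table with columns `dataset_id`, `path`, and
#' `group_label` (e.g. "epithelial", "basal", "fibroblast"), one row per
#' alignment file. An optional `accession` column may carry the originating
#' archive accession as metadata.
#'
#' @param path Path to the manifest TSV.
#' @return A tibble; errors if `dataset_id` values are not unique.
#' @export
read_manifest <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("dataset_id", "path", "group_label")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(m$dataset_id)) {
    stop("duplicate dataset_id in manifest: ",
         paste(unique(m$dataset_id[duplicated(m$dataset_id)]), collapse = ", "),
         call. = FALSE)
  }
  m
}
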