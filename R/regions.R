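#' Define a genomic region
#'
#' Regions use a 1-based, end-exclusive span convention: a region covers
#' positions `start` to `end - 1` and its length is `end - start`. This is the
#' only reading under which the coordinates of the AC061979.1 transcript
#' (chr11:1,218,530-1,220,242) yield its annotated 1712 nt length; a 1-based
#' fully inclusive reading would give 1713.
#'
#' @param chrom Chromosome name, non-empty string.
#' @param start 1-based first covered position.
#' @param end Position one past the last covered position (`end > start`).
#' @return An object of class `genomic_region`.
#' @examples
#' genomic_region("chr11", 1218530, 1220242)
#' @export
genomic_region <- function(chrom, start, end) {
  stopifnot(is.character(chrom), length(chrom) == 1, nzchar(chrom))
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(start) || start < 1) stop("`start` must be a position >= 1", call. = FALSE)
  if (is.na(end) || end <= start) stop("`end` must be greater than `start` (end-exclusive span)", call. = FALSE)
  structure(list(chrom = chrom, start = start, end = end), class = "genomic_region")
}

#' @export
print.genomic_region <- function(x, ...) {
  cat(sprintf("<genomic_region> %s:%d-%d (%d bp)\n", x$chrom, x$start, x$end, span_length(x)))
  invisible(x)
}

#' Parse a region string of the form "chrom:start-end"
#'
#' @param x A string such as `"chr11:1202000-1220500"`. Commas in numbers are
#'   allowed and stripped.
#' @return A [genomic_region()].
#' @export
parse_region <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  x <- gsub(",", "", x, fixed = TRUE)
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) != 4) stop("cannot parse region string: ", x, call. = FALSE)
  genomic_region(m[2], as.integer(m[3]), as.integer(m[4]))
}

#' Length of a region in nucleotides
#'
#' @param region A [genomic_region()].
#' @return Integer span, `end - start`.
#' @examples
#' span_length(genomic_region("chr11", 1218530, 1220242)) # 1712
#' @export
span_length <- function(region) {
  stopifnot(inherits(region, "genomic_region"))
  region$end - region$start
}

#' Covered positions of a region
#'
#' @param region A [genomic_region()].
#' @return Integer vector `start:(end - 1)`.
#' @export
region_positions <- function(region) {
  stopifnot(inherits(region, "genomic_region"))
  seq.int(region$start, region$end - 1L)
}

#' Does a position fall inside a region?
#'
#' @param region A [genomic_region()].
#' @param pos 1-based position(s).
#' @return Logical vector.
#' @export
region_contains <- function(region, pos) {
  stopifnot(inherits(region, "genomic_region"))
  pos >= region$start & pos < region$end
}

#' Annotate a target locus
#'
#' Bundles the geometry of a targeted transcript: its span, a SNP of interest,
#' and the wider analysis window used for read filtering. Invariants are
#' enforced: the SNP must lie inside the transcript and the transcript inside
#' the window.
#'
#' @param transcript [genomic_region()] of the transcript.
#' @param snp_pos 1-based SNP position, inside the transcript.
#' @param snp_alleles Length-2 character vector `(ref, alt)`.
#' @param analysis_window [genomic_region()] containing the transcript.
#' @param exon2_note Free-text provenance on the SNP/exon relationship.
#' @return An object of class `locus_annotation`.
#' @export
locus_annotation <- function(transcript, snp_pos, snp_alleles = c("G", "T"),
                             analysis_window, exon2_note = "") {
  stopifnot(inherits(transcript, "genomic_region"), inherits(analysis_window, "genomic_region"))
  snp_pos <- as.integer(snp_pos)
  if (transcript$chrom != analysis_window$chrom)
    stop("transcript and analysis window are on different chromosomes", call. = FALSE)
  if (!region_contains(transcript, snp_pos))
    stop("snp_pos ", snp_pos, " lies outside the transcript", call. = FALSE)
  if (transcript$start < analysis_window$start || transcript$end > analysis_window$end)
    stop("transcript does not lie within the analysis window", call. = FALSE)
  structure(
    list(transcript = transcript, snp_pos = snp_pos,
         snp_alleles = snp_alleles, analysis_window = analysis_window,
         exon2_note = exon2_note),
    class = "locus_annotation"
  )
}

#' The MUC5B promoter pancRNA locus
#'
#' Geometry of the AC061979.1 lncRNA in the MUC5B promoter on GRCh38:
#' transcript chr11:1,218,530-1,220,242 (1712 nt), the IPF-associated G/T SNP
#' rs35705950 at chr11:1,219,991 (the second nucleotide of the putative
#' exon 2), and the chr11:1,202,000-1,220,500 window used when filtering
#' alignments.
#'
#' @return A [locus_annotation()].
#' @export
muc5b_pancrna_locus <- function() {
  locus_annotation(
    transcript = genomic_region("chr11", 1218530L, 1220242L),
    snp_pos = 1219991L,
    snp_alleles = c("G", "T"),
    analysis_window = genomic_region("chr11", 1202000L, 1220500L),
    exon2_note = "rs35705950 falls at the second nucleotide of putative exon 2"
  )
}
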