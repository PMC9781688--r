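#' Load a gapped (aligned) FASTA alignment
#'
#' Reads an aligned FASTA file — equal-length rows over `{A,C,G,T,N,-}` as
#' produced by global aligners — into a `gapped_alignment` object.
#'
#' @param x Path to an aligned FASTA file, or a named character vector of
#'   equal-length gapped sequences.
#' @param reference Index or name of the coordinate-bearing row (the row whose
#'   ungapped coordinates conserved segments are reported in). Default 1.
#' @return An object of class `gapped_alignment` with fields `names`, `rows`,
#'   `reference`.
#' @export
gapped_alignment <- function(x, reference = 1) {
  if (length(x) == 1 && !grepl("[\n>]", x) && file.exists(x)) {
    ss <- Biostrings::readBStringSet(x)
    rows <- toupper(as.character(ss))
    names(rows) <- names(ss)
  } else {
    rows <- toupper(x)
    if (is.null(names(rows))) names(rows) <- paste0("seq", seq_along(rows))
  }
  if (length(rows) < 1) stop("alignment has no sequences", call. = FALSE)
  w <- nchar(rows)
  if (length(unique(w)) != 1) {
    stop("ragged alignment: rows have different lengths (",
         paste(w, collapse = ", "), ")", call. = FALSE)
  }
  if (is.character(reference)) reference <- match(reference, names(rows))
  if (is.na(reference) || reference < 1 || reference > length(rows)) {
    stop("reference row not found in alignment", call. = FALSE)
  }
  if (!grepl("[ACGTN]", rows[[reference]])) {
    stop("reference row has no non-gap characters", call. = FALSE)
  }
  structure(list(names = names(rows), rows = unname(rows), reference = reference),
            class = "gapped_alignment")
}

#' @export
print.gapped_alignment <- function(x, ...) {
  cat(sprintf("<gapped_alignment> %d rows x %d columns; reference: %s\n",
              length(x$rows), nchar(x$rows[1]), x$names[x$reference]))
  invisible(x)
}

#' Sliding-window percent identity between two alignment rows
#'
#' For every window of `window` alignment columns (step 1 column), identity is
#' the fraction of columns where the two rows carry identical, unambiguous
#' nucleotides; any column holding a gap or `N` in either row counts as a
#' mismatch (the conservative convention of VISTA-style conservation plots).
#' The per-window start is also mapped to ungapped coordinates of the
#' alignment's reference row.
#'
#' @param aln A [gapped_alignment()].
#' @param rows Length-2 vector of row indices or names to compare. Default the
#'   first two rows.
#' @param window Window width in alignment columns, default 50.
#' @return A tibble `col_start` (1-based alignment column of the window),
#'   `ref_start` (ungapped reference coordinate of the first reference base at
#'   or after `col_start`), `identity` in `[0, 1]`. When the alignment is
#'   shorter than `window` a single truncated window is returned, flagged by
#'   the attribute `truncated = TRUE` and a warning.
#' @export
window_identity <- function(aln, rows = c(1, 2), window = 50) {
  stopifnot(inherits(aln, "gapped_alignment"), window >= 1)
  if (is.character(rows)) rows <- match(rows, aln$names)
  stopifnot(length(rows) == 2, !anyNA(rows))
  a <- strsplit(aln$rows[rows[1]], "", fixed = TRUE)[[1]]
  b <- strsplit(aln$rows[rows[2]], "", fixed = TRUE)[[1]]
  L <- length(a)
  match_col <- a == b & a %in% c("A", "C", "G", "T")

  ref <- strsplit(aln$rows[aln$reference], "", fixed = TRUE)[[1]]
  ref_cum <- cumsum(ref != "-")
  # ungapped ref coordinate of the first ref base at or after each column
  nxt <- ref_cum + (ref == "-")
  nxt <- pmin(nxt, max(ref_cum))

  truncated <- L < window
  if (truncated) {
    warning("alignment (", L, " columns) shorter than window (", window,
            "); returning one truncated window", call. = FALSE)
    out <- tibble::tibble(col_start = 1L, ref_start = nxt[1],
                          identity = mean(match_col))
  } else {
    cs <- c(0, cumsum(match_col))
    starts <- seq_len(L - window + 1L)
    out <- tibble::tibble(
      col_start = starts,
      ref_start = nxt[starts],
      identity = (cs[starts + window] - cs[starts]) / window
    )
  }
  attr(out, "window") <- as.integer(window)
  attr(out, "truncated") <- truncated
  attr(out, "ref_map") <- ref_cum
  out
}

#' Call conserved segments from windowed identities
#'
#' Windows at or above `threshold` (inclusive: a 35/50 window passes the
#' 70%/50 bp criterion, a 34/50 window does not) are merged when they overlap
#' in alignment columns; merged spans are reported in ungapped coordinates of
#' the reference row together with the mean identity of their member windows.
#'
#' @param identities Output of [window_identity()].
#' @param threshold Identity fraction in `(0, 1]`, default 0.70.
#' @param window Window width used (taken from `identities` when available).
#' @return A tibble `start`, `end` (1-based ungapped reference coordinates),
#'   `mean_identity`, `n_windows`.
#' @export
call_conserved <- function(identities, threshold = 0.70, window = NULL) {
  if (threshold <= 0 || threshold > 1) {
    stop("`threshold` must lie in (0, 1]", call. = FALSE)
  }
  window <- window %||% attr(identities, "window") %||% 50L
  ref_map <- attr(identities, "ref_map")
  hit <- identities$identity >= threshold
  empty <- tibble::tibble(start = integer(), end = integer(),
                          mean_identity = numeric(), n_windows = integer())
  if (!any(hit)) return(empty)

  idx <- which(hit)
  # merge windows whose column spans [col_start, col_start + window - 1] overlap
  brk <- c(TRUE, diff(identities$col_start[idx]) >= window)
  grp <- cumsum(brk)
  purrr::map(split(idx, grp), function(ii) {
    col_s <- identities$col_start[ii[1]]
    col_e <- identities$col_start[ii[length(ii)]] + window - 1L
    if (!is.null(ref_map)) {
      col_e <- min(col_e, length(ref_map))
      start <- identities$ref_start[ii[1]]
      end <- ref_map[col_e]
    } else {
      start <- col_s
      end <- col_e
    }
    tibble::tibble(start = start, end = end,
                   mean_identity = mean(identities$identity[ii]),
                   n_windows = length(ii))
  }) |> dplyr::bind_rows()
}

#' Default SMAD-binding-element motif set
#'
#' The two SMAD binding elements with literature-stated sequences: the
#' canonical SBE `CAGAC`, and the 5GC SBE `GGC(GC)(CG)` expanded to its two
#' concrete forms `GGCGC` and `GGCCG`. Other motifs of interest (for example
#' a FOXA2 site) can be supplied by the user as additional IUPAC patterns.
#'
#' @return A tibble with columns `name`, `pattern`.
#' @export
sbe_motifs <- function() {
  tibble::tibble(
    name = c("SBE", "5GC_SBE", "5GC_SBE"),
    pattern = c("CAGAC", "GGCGC", "GGCCG")
  )
}

#' Scan a sequence for IUPAC nucleotide motifs
#'
#' Exact IUPAC-degenerate matching on the forward strand and, optionally, the
#' reverse complement; minus-strand hits are reported in plus-strand
#' coordinates with the plus-strand text at the hit.
#'
#' @param seq A nucleotide string (IUPAC alphabet).
#' @param motifs Tibble with columns `name`, `pattern` (IUPAC). Default
#'   [sbe_motifs()]. A degenerate motif may span several rows with the same
#'   name (an alternation).
#' @param both_strands Also scan the reverse complement. Default `TRUE`.
#' @return A tibble `motif_name`, `pattern`, `start` (1-based, plus strand),
#'   `strand` (`"+"`/`"-"`), `matched_text`, sorted by `start`.
#' @export
scan_motifs <- function(seq, motifs = sbe_motifs(), both_strands = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1)
  subject <- Biostrings::DNAString(toupper(seq))
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  hits <- purrr::pmap(motifs, function(name, pattern, ...) {
    pat_chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
    if (!all(pat_chars %in% iupac)) {
      stop("invalid IUPAC character in pattern '", pattern, "'", call. = FALSE)
    }
    pat <- Biostrings::DNAString(toupper(pattern))
    fwd <- Biostrings::matchPattern(pat, subject, fixed = FALSE)
    out <- tibble::tibble(
      motif_name = name, pattern = toupper(pattern),
      start = BiocGenerics::start(fwd), strand = "+",
      matched_text = as.character(fwd)
    )
    if (both_strands) {
      rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat),
                                      subject, fixed = FALSE)
      out <- dplyr::bind_rows(out, tibble::tibble(
        motif_name = name, pattern = toupper(pattern),
        start = BiocGenerics::start(rev), strand = "-",
        matched_text = as.character(rev)
      ))
    }
    out
  })
  dplyr::bind_rows(hits) |> dplyr::arrange(.data$start, .data$strand)
}
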