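#' Per-base depth of coverage over a region
#'
#' CIGAR-aware pileup: position `p` gains +1 for every record whose CIGAR
#' places an aligned base (`M`, `=`, `X`) at `p`. Deletions (`D`) and spliced
#' introns (`N`) consume reference without adding depth (set
#' `count_deletions = TRUE` to count deleted positions as covered);
#' insertions and clips add nothing. Records on other chromosomes are ignored
#' and coverage outside the region is truncated. Overlapping mates of a pair
#' double-count by default — raw depth is collapsed without mate-aware
#' deduplication — and `dedup_mates = TRUE` counts each read-pair name at most
#' once per position.
#'
#' @param records Alignment tibble from [read_sam()].
#' @param region Target [genomic_region()].
#' @param count_deletions Count `D` positions as covered. Default `FALSE`.
#' @param dedup_mates Collapse overlapping mates of the same pair. Default `FALSE`.
#' @param dataset_id Optional label attached as a column.
#' @return A tibble with columns `chrom`, `pos` (1-based, ascending over the
#'   whole region), `depth` (and `dataset_id` when given); depth is stored as
#'   double so composite sums over many datasets cannot overflow.
#' @export
compute_depth <- function(records, region, count_deletions = FALSE,
                          dedup_mates = FALSE, dataset_id = NULL) {
  stopifnot(inherits(region, "genomic_region"))
  n <- span_length(region)
  records <- records[records$is_mapped & records$chrom == region$chrom, , drop = FALSE]

  blocks <- vector("list", nrow(records))
  skipped <- 0L
  for (i in seq_len(nrow(records))) {
    b <- .aligned_blocks(records$pos[i], records$cigar[i], count_deletions)
    if (nrow(b) == 0) {
      skipped <- skipped + 1L
      next
    }
    blocks[[i]] <- b
  }
  if (skipped > 0) {
    warning(skipped, " record(s) with zero reference-consuming span skipped",
            call. = FALSE)
  }

  if (dedup_mates && nrow(records) > 0) {
    keep <- !vapply(blocks, is.null, logical(1))
    blocks <- lapply(split(blocks[keep], records$qname[keep]), function(bs) {
      .union_intervals(do.call(rbind, bs))
    })
  }

  # difference-array accumulation over the clipped region
  delta <- numeric(n + 1L)
  for (b in blocks) {
    if (is.null(b) || nrow(b) == 0) next
    s <- pmax(b[, 1], region$start) - region$start + 1L
    e <- pmin(b[, 2], region$end - 1L) - region$start + 1L
    ok <- s <= e
    for (j in which(ok)) {
      delta[s[j]] <- delta[s[j]] + 1
      delta[e[j] + 1L] <- delta[e[j] + 1L] - 1
    }
  }
  depth <- cumsum(delta[seq_len(n)])

  out <- tibble::tibble(chrom = region$chrom, pos = region_positions(region),
                        depth = depth)
  if (!is.null(dataset_id)) out$dataset_id <- dataset_id
  out
}

# Merge overlapping/adjacent 1-based inclusive intervals.
.union_intervals <- function(b) {
  if (is.null(b) || nrow(b) <= 1) return(b)
  o <- order(b[, 1])
  s <- b[o, 1]; e <- b[o, 2]
  ms <- s[1]; me <- e[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me + 1L) {
      me <- max(me, e[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- s[i]; me <- e[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

#' Extract splice junctions from CIGAR N operations
#'
#' Every `N` operation of length `L` whose reference cursor stands at `q`
#' (the last reference base consumed before the skip) yields the intron
#' `(q + 1, q + L)` in 1-based coordinates of the first and last skipped
#' bases. Identical junctions across reads are merged with summed read
#' support.
#'
#' @param records Alignment tibble from [read_sam()].
#' @return A tibble `chrom`, `intron_start`, `intron_end`, `support`, sorted
#'   by `(chrom, intron_start)`.
#' @export
extract_junctions <- function(records) {
  records <- records[records$is_mapped, , drop = FALSE]
  rows <- purrr::map(seq_len(nrow(records)), function(i) {
    j <- .cigar_introns(records$pos[i], records$cigar[i])
    if (nrow(j) == 0) return(NULL)
    tibble::tibble(chrom = records$chrom[i], intron_start = unname(j[, 1]),
                   intron_end = unname(j[, 2]))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(chrom = character(), intron_start = integer(),
                          intron_end = integer(), support = integer()))
  }
  out |>
    dplyr::count(.data$chrom, .data$intron_start, .data$intron_end, name = "support") |>
    dplyr::arrange(.data$chrom, .data$intron_start)
}

#' Write per-position depth as tab-separated text
#'
#' The primary per-position output: one line `chrom<TAB>pos<TAB>depth` per
#' position of the region, 1-based, ascending, byte-for-byte deterministic.
#'
#' @param cov Coverage tibble from [compute_depth()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_depth_txt <- function(cov, path) {
  lines <- paste(cov$chrom, cov$pos, format(cov$depth, scientific = FALSE, trim = TRUE),
                 sep = "\t")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read per-position depth text written by [write_depth_txt()]
#'
#' @param path Path to a depth TXT file.
#' @return A tibble `chrom`, `pos`, `depth`.
#' @export
read_depth_txt <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "pos", "depth"),
                  col_types = "cid", progress = FALSE)
}

#' Write a depth track as bedGraph
#'
#' Adjacent equal-depth positions are run-length merged; intervals are 0-based
#' half-open as bedGraph requires.
#'
#' @param cov Tibble with `chrom`, `pos`, and a depth column.
#' @param path Output path.
#' @param value Name of the depth column. Default `"depth"`.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(cov, path, value = "depth") {
  v <- cov[[value]]
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  lines <- paste(cov$chrom[starts], cov$pos[starts] - 1L, cov$pos[ends],
                 format(r$values, scientific = FALSE, trim = TRUE), sep = "\t")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write splice junctions as BED
#'
#' Introns as 0-based half-open intervals, score = read support.
#'
#' @param junctions Tibble from [extract_junctions()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_junctions_bed <- function(junctions, path) {
  lines <- paste(junctions$chrom, junctions$intron_start - 1L, junctions$intron_end,
                 sprintf("junction_%d", seq_len(nrow(junctions))),
                 junctions$support, ".", sep = "\t")
  readr::write_lines(lines, path)
  invisible(path)
}
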