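#' Collapse per-dataset coverage into a composite signal
#'
#' The signal-integration step: depth vectors from many independent datasets
#' over the same region are summed position-wise into one composite track.
#' Transcripts whose per-dataset coverage sits at background level can become
#' unambiguous in the composite — the mechanism that reveals technically
#' occluded, weakly expressed transcripts. The default is an unnormalized sum
#' of raw depths; `normalize = TRUE` scales each dataset to depth per million
#' summed in-window bases first, for heterogeneous library sizes.
#'
#' @param cov Either a long tibble with columns `chrom`, `pos`, `depth`,
#'   `dataset_id` (rows from several datasets), or a list of per-dataset
#'   coverage tibbles from [compute_depth()].
#' @param normalize Per-dataset per-million scaling before summing.
#' @return A tibble `chrom`, `pos`, `total_depth`, `n_nonzero` (datasets with
#'   depth > 0 at each position), with attributes `dataset_ids` and
#'   `n_datasets`.
#' @export
collapse_coverage <- function(cov, normalize = FALSE) {
  if (is.data.frame(cov)) {
    if (!"dataset_id" %in% names(cov)) cov$dataset_id <- "dataset_1"
    cov <- split(cov[c("chrom", "pos", "depth")], cov$dataset_id)
  } else {
    nm <- purrr::imap_chr(cov, function(v, i) {
      if ("dataset_id" %in% names(v)) as.character(v$dataset_id[1]) else paste0("dataset_", i)
    })
    names(cov) <- nm
  }
  if (length(cov) == 0) stop("no coverage vectors to collapse", call. = FALSE)

  ref <- cov[[1]]
  same <- vapply(cov, function(v) {
    nrow(v) == nrow(ref) && v$chrom[1] == ref$chrom[1] && identical(v$pos, ref$pos)
  }, logical(1))
  if (!all(same)) {
    stop("coverage regions do not match for dataset(s): ",
         paste(names(cov)[!same], collapse = ", "), call. = FALSE)
  }

  depths <- lapply(cov, function(v) {
    d <- as.numeric(v$depth)
    if (normalize) {
      tot <- sum(d)
      if (tot > 0) d <- d / tot * 1e6
    }
    d
  })
  total <- Reduce(`+`, depths)
  nonzero <- Reduce(`+`, lapply(depths, function(d) as.integer(d > 0)))

  out <- tibble::tibble(chrom = ref$chrom[1], pos = ref$pos,
                        total_depth = total, n_nonzero = nonzero)
  attr(out, "dataset_ids") <- names(cov)
  attr(out, "n_datasets") <- length(cov)
  out
}

#' Call expressed segments from a depth track
#'
#' Scans for maximal runs of positions at or above `min_depth`; runs separated
#' by sub-threshold gaps of at most `max_gap` positions are bridged, and
#' bridged runs shorter than `min_len` are discarded. This is an explicit,
#' parameterized stand-in for calling expression "by eye" on a coverage plot:
#' the thresholds are operational choices, not biological constants, and all
#' are exposed.
#'
#' @param sig Tibble with `chrom`, `pos` and a depth column (`total_depth`
#'   from [collapse_coverage()], falling back to `depth`).
#' @param min_depth Minimum depth for a position to count. Default 2.
#' @param min_len Minimum bridged run length in bp. Default 50.
#' @param max_gap Maximum sub-threshold gap to bridge, in bp. Default 10.
#' @return A tibble of non-overlapping segments sorted by start: `chrom`,
#'   `start`, `end` (1-based inclusive), `length`, `max_depth`, `mean_depth`,
#'   `breadth` (fraction of segment positions at or above `min_depth`).
#' @export
call_segments <- function(sig, min_depth = 2, min_len = 50, max_gap = 10) {
  stopifnot(min_depth >= 1, min_len >= 1, max_gap >= 0)
  depth <- if ("total_depth" %in% names(sig)) sig$total_depth else sig$depth
  pos <- sig$pos
  above <- depth >= min_depth

  empty <- tibble::tibble(chrom = character(), start = integer(), end = integer(),
                          length = integer(), max_depth = numeric(),
                          mean_depth = numeric(), breadth = numeric())
  if (!any(above)) return(empty)

  r <- rle(above)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  on_s <- run_start[r$values]
  on_e <- run_end[r$values]

  # bridge gaps <= max_gap between consecutive above-threshold runs
  seg_s <- on_s[1]; seg_e <- on_e[1]
  starts <- integer(0); ends <- integer(0)
  for (i in seq_along(on_s)[-1]) {
    if (on_s[i] - seg_e - 1L <= max_gap) {
      seg_e <- on_e[i]
    } else {
      starts <- c(starts, seg_s); ends <- c(ends, seg_e)
      seg_s <- on_s[i]; seg_e <- on_e[i]
    }
  }
  starts <- c(starts, seg_s); ends <- c(ends, seg_e)

  len <- ends - starts + 1L
  keep <- len >= min_len
  if (!any(keep)) return(empty)
  starts <- starts[keep]; ends <- ends[keep]

  purrr::map2(starts, ends, function(s, e) {
    d <- depth[s:e]
    tibble::tibble(chrom = sig$chrom[1], start = pos[s], end = pos[e],
                   length = e - s + 1L, max_depth = max(d), mean_depth = mean(d),
                   breadth = mean(d >= min_depth))
  }) |> dplyr::bind_rows()
}

#' Write expressed segments as BED
#'
#' @param segments Tibble from [call_segments()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_segments_bed <- function(segments, path) {
  lines <- paste(segments$chrom, segments$start - 1L, segments$end,
                 sprintf("segment_%d", seq_len(nrow(segments))),
                 format(round(segments$mean_depth, 2), scientific = FALSE, trim = TRUE),
                 ".", sep = "\t")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Compare composite signals between two sample groups
#'
#' Position-wise contrast of two composite tracks over the same region (for
#' example differentiated epithelium versus undifferentiated basal cells).
#' Depths are also reported normalized to depth per million summed in-window
#' depth, so groups with different total sequencing effort are comparable;
#' the `difference` column is `norm_a - norm_b`.
#'
#' @param a,b Composite tibbles from [collapse_coverage()] (or single-dataset
#'   coverage from [compute_depth()]) over identical regions.
#' @param labels Length-2 character vector naming the groups.
#' @return A tibble `chrom`, `pos`, `depth_<a>`, `depth_<b>`, `norm_<a>`,
#'   `norm_<b>`, `difference`.
#' @export
compare_groups <- function(a, b, labels = c("a", "b")) {
  da <- if ("total_depth" %in% names(a)) a$total_depth else a$depth
  db <- if ("total_depth" %in% names(b)) b$total_depth else b$depth
  if (a$chrom[1] != b$chrom[1] || nrow(a) != nrow(b) || !identical(a$pos, b$pos)) {
    stop("signals cover different regions; cannot compare", call. = FALSE)
  }
  norm <- function(d) if (sum(d) > 0) d / sum(d) * 1e6 else d
  na <- norm(da); nb <- norm(db)
  out <- tibble::tibble(chrom = a$chrom[1], pos = a$pos,
                        depth_a = da, depth_b = db,
                        norm_a = na, norm_b = nb,
                        difference = na - nb)
  names(out)[3:6] <- c(paste0("depth_", labels), paste0("norm_", labels))
  out
}
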