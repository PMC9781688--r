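# Independent brute-force oracles. These deliberately use different
# algorithms from the package internals (position sets and boolean
# gap-filling rather than difference arrays and rle), so agreement is a
# genuine cross-check.

# Per-(record, position) depth count: for every record, enumerate the exact
# set of reference positions carrying an aligned base, then count membership
# per region position.
oracle_depth <- function(records, region) {
  pos_sets <- lapply(seq_len(nrow(records)), function(i) {
    if (!records$is_mapped[i] || records$chrom[i] != region$chrom) return(integer(0))
    ops <- cigar_ops(records$cigar[i])
    cur <- records$pos[i]
    covered <- integer(0)
    for (k in seq_len(nrow(ops))) {
      op <- ops$op[k]; len <- ops$len[k]
      if (op %in% c("M", "=", "X")) covered <- c(covered, seq.int(cur, cur + len - 1L))
      if (op %in% c("M", "=", "X", "D", "N")) cur <- cur + len
    }
    covered
  })
  vapply(region_positions(region), function(p) {
    sum(vapply(pos_sets, function(s) p %in% s, logical(1)))
  }, numeric(1))
}

# Segment calling by boolean gap-filling: bridge FALSE runs of length
# <= max_gap that are flanked by TRUE on both sides, then take maximal TRUE
# runs of length >= min_len.
oracle_segments <- function(depth, pos, min_depth, min_len, max_gap) {
  above <- depth >= min_depth
  n <- length(above)
  filled <- above
  i <- 1L
  while (i <= n) {
    if (!above[i]) {
      j <- i
      while (j < n && !above[j + 1L]) j <- j + 1L
      if (i > 1L && j < n && (j - i + 1L) <= max_gap) filled[i:j] <- TRUE
      i <- j + 1L
    } else i <- i + 1L
  }
  segs <- list()
  i <- 1L
  while (i <= n) {
    if (filled[i]) {
      j <- i
      while (j < n && filled[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_len) segs[[length(segs) + 1L]] <- c(pos[i], pos[j])
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(segs) == 0) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  m <- do.call(rbind, segs)
  tibble::tibble(start = m[, 1], end = m[, 2])
}

# Column-by-column window identity with explicit loops.
oracle_window_identity <- function(row_a, row_b, window) {
  a <- strsplit(row_a, "")[[1]]
  b <- strsplit(row_b, "")[[1]]
  n <- length(a)
  starts <- seq_len(max(n - window + 1L, 1L))
  vapply(starts, function(s) {
    e <- min(s + window - 1L, n)
    hits <- 0L
    for (k in s:e) {
      if (a[k] %in% c("A", "C", "G", "T") && a[k] == b[k]) hits <- hits + 1L
    }
    hits / window
  }, numeric(1))
}

# Random alignment records rendered as SAM text, with mixed M/I/D/N/S CIGARs
# and consistent SEQ/QUAL lengths.
random_sam_lines <- function(n_reads, chrom = "chrT", max_pos = 60,
                             mean_q = 35) {
  make_read <- function(i) {
    ops <- character(0); lens <- integer(0)
    add <- function(op, len) { ops <<- c(ops, op); lens <<- c(lens, len) }
    if (runif(1) < 0.3) add("S", sample(1:5, 1))
    add("M", sample(3:12, 1))
    if (runif(1) < 0.6) {
      add(sample(c("I", "D", "N"), 1), sample(1:15, 1))
      add("M", sample(3:12, 1))
    }
    if (runif(1) < 0.2) add("S", sample(1:5, 1))
    cigar <- paste0(lens, ops, collapse = "")
    qlen <- sum(lens[ops %in% c("M", "I", "S")])
    seq <- paste(sample(c("A", "C", "G", "T"), qlen, replace = TRUE), collapse = "")
    qual <- paste(intToUtf8(pmin(pmax(round(rnorm(qlen, mean_q, 4)), 2), 41) + 33,
                            multiple = TRUE), collapse = "")
    paste(sprintf("r%03d", i), 0L, chrom, sample(seq_len(max_pos), 1), 60L,
          cigar, "*", 0L, 0L, seq, qual, sep = "\t")
  }
  vapply(seq_len(n_reads), make_read, character(1))
}

reverse_complement <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", vapply(x, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}
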