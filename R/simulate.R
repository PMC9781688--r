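# Evaluate code under a fixed RNG seed without disturbing the caller's stream.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Define a synthetic locus for read simulation
#'
#' A synthetic genome carrying one short, weakly expressed, optionally spliced
#' transcript. The default geometry mirrors the MUC5B promoter pancRNA study
#' system scaled into a 20 kb sequence: a 1712 nt transcript placed at the
#' same offset the real transcript has inside its 18.5 kb analysis window
#' (start 16,531), an intron at transcript offsets 1001-1460, and the SNP at
#' offset 1462 — the second nucleotide of exon 2, as for rs35705950.
#'
#' @param genome_length Length of the synthetic genome. Default 20000.
#' @param chrom Name of the synthetic chromosome. Default `"chrS"`.
#' @param transcript_start 1-based genomic start of the transcript.
#' @param transcript_length Transcript length in nt. Default 1712.
#' @param intron Length-2 vector: 1-based first and last intronic position in
#'   transcript-relative coordinates, strictly inside the transcript; `NULL`
#'   for an intronless transcript.
#' @param snp_offset 1-based transcript-relative SNP position.
#' @param polyadenylated Is the transcript polyadenylated? Non-polyA
#'   transcripts are thinned by the capture probability during library
#'   simulation. Default `FALSE`.
#' @param genome_seq Optional explicit genome sequence; generated uniformly
#'   at random from `seed` when `NULL`.
#' @param seed Seed for genome sequence generation. Default 1.
#' @return An object of class `simulated_locus`.
#' @export
simulated_locus <- function(genome_length = 20000, chrom = "chrS",
                            transcript_start = 16531, transcript_length = 1712,
                            intron = c(1001, 1460), snp_offset = 1462,
                            polyadenylated = FALSE, genome_seq = NULL, seed = 1) {
  genome_length <- as.integer(genome_length)
  transcript_start <- as.integer(transcript_start)
  transcript_length <- as.integer(transcript_length)
  stopifnot(transcript_start >= 1,
            transcript_start + transcript_length - 1 <= genome_length)
  if (!is.null(intron)) {
    intron <- as.integer(intron)
    stopifnot(length(intron) == 2, intron[1] > 1, intron[2] >= intron[1],
              intron[2] < transcript_length)
  }
  snp_offset <- as.integer(snp_offset)
  stopifnot(snp_offset >= 1, snp_offset <= transcript_length)
  if (is.null(genome_seq)) {
    genome_seq <- .with_seed(seed, paste(
      sample(c("A", "C", "G", "T"), genome_length, replace = TRUE), collapse = ""))
  }
  stopifnot(nchar(genome_seq) == genome_length)
  structure(
    list(genome_seq = genome_seq, genome_length = genome_length, chrom = chrom,
         transcript_start = transcript_start, transcript_length = transcript_length,
         intron = intron, snp_offset = snp_offset, polyadenylated = polyadenylated),
    class = "simulated_locus"
  )
}

#' @export
print.simulated_locus <- function(x, ...) {
  cat(sprintf("<simulated_locus> %s (%d bp); transcript %d-%d (%d nt)%s; SNP offset %d\n",
              x$chrom, x$genome_length, x$transcript_start,
              x$transcript_start + x$transcript_length - 1L, x$transcript_length,
              if (is.null(x$intron)) "" else
                sprintf("; intron offsets %d-%d", x$intron[1], x$intron[2]),
              x$snp_offset))
  invisible(x)
}

#' Genomic region spanned by a simulated locus' genome
#' @param locus A [simulated_locus()].
#' @return A [genomic_region()] covering the whole synthetic genome.
#' @export
genome_region <- function(locus) {
  genomic_region(locus$chrom, 1L, locus$genome_length + 1L)
}

#' Genomic region spanned by the simulated transcript
#' @param locus A [simulated_locus()].
#' @return A [genomic_region()] (end-exclusive).
#' @export
transcript_region <- function(locus) {
  genomic_region(locus$chrom, locus$transcript_start,
                 locus$transcript_start + locus$transcript_length)
}

# Intron in genomic coordinates (1-based inclusive), or NULL.
.genomic_intron <- function(locus) {
  if (is.null(locus$intron)) return(NULL)
  locus$transcript_start + locus$intron - 1L
}

#' Define a per-dataset simulation profile
#'
#' Emulates one independent sequencing dataset contributing near-zero reads
#' from the target transcript. Defaults put a single dataset in the
#' "sporadic reads" regime: with `transcript_fragments = 20` and
#' `capture_prob = 0.1` a non-polyadenylated transcript yields on average two
#' surviving 100 nt reads per dataset — too sparse for a segment call on its
#' own — plus a thin uniform background over the genome.
#'
#' @param dataset_id Dataset label.
#' @param n_background_reads Background reads drawn uniformly over the genome.
#' @param transcript_fragments Poisson mean of fragments originating from the
#'   transcript before library-prep thinning.
#' @param capture_prob Probability that a fragment from a non-polyadenylated
#'   transcript survives polyA-selective library preparation, in `[0, 1]`.
#' @param read_len Read length in nt.
#' @param paired Emit abutting mate pairs instead of single-end reads.
#' @param spliced_fraction Fraction of transcript fragments drawn from the
#'   spliced (mature) form, producing junction-spanning M-N-M reads.
#' @param error_rate Per-base substitution rate applied to read sequences.
#'   Default 0 (error-free; base-calling noise is orthogonal to the
#'   aggregation mechanism).
#' @param seed RNG seed for this dataset.
#' @return An object of class `dataset_profile`.
#' @export
dataset_profile <- function(dataset_id = "sim1", n_background_reads = 10,
                            transcript_fragments = 20, capture_prob = 0.1,
                            read_len = 100, paired = FALSE,
                            spliced_fraction = 0, error_rate = 0, seed = 1) {
  stopifnot(n_background_reads >= 0, transcript_fragments >= 0,
            capture_prob >= 0, capture_prob <= 1,
            spliced_fraction >= 0, spliced_fraction <= 1,
            error_rate >= 0, error_rate <= 1, read_len >= 1)
  structure(
    list(dataset_id = dataset_id,
         n_background_reads = as.integer(n_background_reads),
         transcript_fragments = transcript_fragments,
         capture_prob = capture_prob, read_len = as.integer(read_len),
         paired = paired, spliced_fraction = spliced_fraction,
         error_rate = error_rate, seed = as.integer(seed)),
    class = "dataset_profile"
  )
}

.subseq <- function(seq, start, len) substr(seq, start, start + len - 1L)

.apply_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Simulate one dataset of aligned reads over a synthetic locus
#'
#' Draws `K ~ Poisson(transcript_fragments)` fragments from the transcript,
#' thins them by `capture_prob` when the transcript is not polyadenylated,
#' assigns a fraction `spliced_fraction` of the survivors to the spliced form
#' (reads spanning the exon-exon junction carry an `M-N-M` CIGAR whose `N`
#' equals the intron length), and adds uniform background reads over the
#' genome. Output is byte-identical for a fixed profile seed.
#'
#' @param locus A [simulated_locus()].
#' @param prof A [dataset_profile()].
#' @return An alignment tibble in the schema of [read_sam()], with a
#'   `dataset_id` attribute.
#' @export
simulate_dataset <- function(locus, prof) {
  stopifnot(inherits(locus, "simulated_locus"), inherits(prof, "dataset_profile"))
  rl <- prof$read_len
  e1_len <- if (is.null(locus$intron)) locus$transcript_length else locus$intron[1] - 1L
  e2_len <- if (is.null(locus$intron)) 0L else locus$transcript_length - locus$intron[2]
  if (rl > e1_len || (!is.null(locus$intron) && rl > e2_len)) {
    stop("read_len (", rl, ") exceeds an exon length (",
         e1_len, if (!is.null(locus$intron)) paste0("/", e2_len), ")", call. = FALSE)
  }
  if (rl > locus$genome_length) stop("read_len exceeds genome length", call. = FALSE)

  .with_seed(prof$seed, {
    k <- stats::rpois(1, prof$transcript_fragments)
    kept <- if (locus$polyadenylated) k else stats::rbinom(1, k, prof$capture_prob)
    n_spliced <- if (is.null(locus$intron)) 0L else stats::rbinom(1, kept, prof$spliced_fraction)
    n_unspliced <- kept - n_spliced

    rows <- list()

    if (n_unspliced > 0) {
      starts <- locus$transcript_start +
        sample.int(locus$transcript_length - rl + 1L, n_unspliced, replace = TRUE) - 1L
      rows$unspliced <- tibble::tibble(
        qname = sprintf("%s_tx%04d", prof$dataset_id, seq_len(n_unspliced)),
        pos = starts, cigar = paste0(rl, "M"),
        seq = vapply(starts, function(s) .subseq(locus$genome_seq, s, rl),
                     character(1))
      )
    }

    if (n_spliced > 0) {
      intron_len <- locus$intron[2] - locus$intron[1] + 1L
      # mature-transcript starts that make the read span the junction
      s_lo <- max(1L, e1_len - rl + 2L)
      s_mature <- s_lo + sample.int(e1_len - s_lo + 1L, n_spliced, replace = TRUE) - 1L
      left_m <- e1_len - s_mature + 1L
      right_m <- rl - left_m
      g_pos <- locus$transcript_start + s_mature - 1L
      exon2_g <- locus$transcript_start + locus$intron[2]  # first genomic base of exon 2
      rows$spliced <- tibble::tibble(
        qname = sprintf("%s_sp%04d", prof$dataset_id, seq_len(n_spliced)),
        pos = g_pos,
        cigar = sprintf("%dM%dN%dM", left_m, intron_len, right_m),
        seq = vapply(seq_len(n_spliced), function(i) {
          paste0(.subseq(locus$genome_seq, g_pos[i], left_m[i]),
                 .subseq(locus$genome_seq, exon2_g, right_m[i]))
        }, character(1))
      )
    }

    if (prof$n_background_reads > 0) {
      starts <- sample.int(locus$genome_length - rl + 1L,
                           prof$n_background_reads, replace = TRUE)
      rows$background <- tibble::tibble(
        qname = sprintf("%s_bg%04d", prof$dataset_id, seq_len(prof$n_background_reads)),
        pos = starts, cigar = paste0(rl, "M"),
        seq = vapply(starts, function(s) .subseq(locus$genome_seq, s, rl),
                     character(1))
      )
    }

    reads <- dplyr::bind_rows(rows)
    if (nrow(reads) > 0 && prof$error_rate > 0) {
      reads$seq <- vapply(reads$seq, .apply_errors, character(1),
                          rate = prof$error_rate, USE.NAMES = FALSE)
    }

    if (nrow(reads) == 0) {
      out <- .empty_alignments()
    } else if (!prof$paired) {
      out <- tibble::tibble(
        qname = reads$qname, flag = 0L, chrom = locus$chrom, pos = reads$pos,
        mapq = 60L, cigar = reads$cigar, rnext = "*", pnext = 0L, tlen = 0L,
        seq = reads$seq, qual = strrep("I", rl),
        is_paired = FALSE, is_mapped = TRUE, is_primary = TRUE,
        mate_chrom = NA_character_, mate_pos = NA_integer_
      )
    } else {
      # abutting mate: an all-M read starting just after mate 1's reference end
      ref_end <- reads$pos + cigar_reference_length(reads$cigar) - 1L
      mate_pos <- pmin(ref_end + 1L, locus$genome_length - rl + 1L)
      m1 <- tibble::tibble(
        qname = reads$qname, flag = 99L, chrom = locus$chrom, pos = reads$pos,
        mapq = 60L, cigar = reads$cigar, rnext = "=", pnext = mate_pos,
        tlen = mate_pos + rl - reads$pos,
        seq = reads$seq, qual = strrep("I", rl),
        is_paired = TRUE, is_mapped = TRUE, is_primary = TRUE,
        mate_chrom = locus$chrom, mate_pos = mate_pos
      )
      m2 <- tibble::tibble(
        qname = reads$qname, flag = 147L, chrom = locus$chrom, pos = mate_pos,
        mapq = 60L, cigar = paste0(rl, "M"), rnext = "=", pnext = reads$pos,
        tlen = -(mate_pos + rl - reads$pos),
        seq = vapply(mate_pos, function(s) .subseq(locus$genome_seq, s, rl),
                     character(1)),
        qual = strrep("I", rl),
        is_paired = TRUE, is_mapped = TRUE, is_primary = TRUE,
        mate_chrom = locus$chrom, mate_pos = reads$pos
      )
      out <- dplyr::bind_rows(m1, m2) |> dplyr::arrange(.data$pos)
    }
    attr(out, "dataset_id") <- prof$dataset_id
    out
  })
}

#' SAM header lines for a simulated dataset
#'
#' Includes the `@SQ` line for the synthetic genome and `@CO` audit lines
#' recording the dataset id and seed.
#'
#' @param locus A [simulated_locus()].
#' @param prof A [dataset_profile()].
#' @return Character vector of header lines.
#' @export
simulated_sam_header <- function(locus, prof) {
  c("@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", locus$chrom, locus$genome_length),
    sprintf("@CO\tdataset_id=%s\tseed=%d", prof$dataset_id, prof$seed))
}

#' Write the synthetic genome as FASTA
#'
#' @param locus A [simulated_locus()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genome_fasta <- function(locus, path) {
  ss <- Biostrings::DNAStringSet(locus$genome_seq)
  names(ss) <- locus$chrom
  Biostrings::writeXStringSet(ss, path, width = 70)
  invisible(path)
}

#' Detection power of composite coverage versus dataset count
#'
#' Quantifies the central signal-integration property: for each `n` in
#' `n_grid`, simulates `n` independent datasets, collapses their depth over
#' the whole synthetic genome, calls expressed segments, and scores a
#' detection when a segment overlaps the embedded transcript. Repeated
#' `reps` times per `n`; everything is driven by `seed`.
#'
#' @param locus A [simulated_locus()].
#' @param prof Template [dataset_profile()]; per-dataset ids and seeds are
#'   derived from it and from `seed`.
#' @param n_grid Dataset counts to evaluate, e.g. `c(1, 2, 5, 10, 20)`.
#' @param reps Replicates per grid point. Default 50.
#' @param min_depth,min_len,max_gap Segment-caller parameters
#'   (see [call_segments()]).
#' @param seed Master seed; per-dataset seeds are split from it and recorded.
#' @return A tibble `n_datasets`, `detections`, `reps`,
#'   `detection_probability`.
#' @export
power_experiment <- function(locus, prof = dataset_profile(),
                             n_grid = c(1, 2, 5, 10, 20), reps = 50,
                             min_depth = 2, min_len = 50, max_gap = 10,
                             seed = 1) {
  if (length(n_grid) == 0) stop("`n_grid` must be non-empty", call. = FALSE)
  stopifnot(reps >= 1)
  region <- genome_region(locus)
  tx <- transcript_region(locus)
  total <- sum(n_grid) * reps
  seeds <- if (total > 0) .with_seed(seed, sample.int(.Machine$integer.max - 1L, total)) else integer(0)
  cursor <- 0L

  purrr::map(n_grid, function(n) {
    hits <- 0L
    for (r in seq_len(reps)) {
      if (n == 0) next
      covs <- vector("list", n)
      for (i in seq_len(n)) {
        cursor <<- cursor + 1L
        p <- prof
        p$dataset_id <- sprintf("d%02d", i)
        p$seed <- seeds[cursor]
        recs <- simulate_dataset(locus, p)
        covs[[i]] <- compute_depth(recs, region, dataset_id = p$dataset_id)
      }
      sig <- collapse_coverage(covs)
      segs <- call_segments(sig, min_depth = min_depth, min_len = min_len,
                            max_gap = max_gap)
      detected <- nrow(segs) > 0 &&
        any(segs$end >= tx$start & segs$start <= tx$end - 1L)
      hits <- hits + detected
    }
    tibble::tibble(n_datasets = n, detections = hits, reps = as.integer(reps),
                   detection_probability = hits / reps)
  }) |> dplyr::bind_rows()
}

#' Can the pipeline recover the embedded splice junction?
#'
#' Simulates one dataset and checks whether [extract_junctions()] reports the
#' locus' intron at its exact genomic coordinates — the positive control for
#' concluding that absence of junction evidence in real data is not a
#' pipeline blind spot.
#'
#' @param locus A [simulated_locus()] with an intron.
#' @param prof A [dataset_profile()] with `spliced_fraction > 0` to exercise
#'   recovery (0 is allowed and must recover nothing).
#' @return A list: `recovered` (logical), `junctions` (tibble),
#'   `expected_intron` (length-2 vector of genomic start/end).
#' @export
junction_recovery_check <- function(locus, prof) {
  stopifnot(!is.null(locus$intron))
  recs <- simulate_dataset(locus, prof)
  j <- extract_junctions(recs)
  expected <- .genomic_intron(locus)
  recovered <- nrow(j) > 0 &&
    any(j$intron_start == expected[1] & j$intron_end == expected[2])
  list(recovered = recovered, junctions = j, expected_intron = expected)
}
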