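test_that("locus geometry mirrors the targeted transcript", {
  loc <- simulated_locus()
  expect_equal(loc$transcript_length, 1712L)
  expect_equal(span_length(transcript_region(loc)), 1712L)
  expect_equal(loc$snp_offset, loc$intron[2] + 2L)  # second base of exon 2
  expect_equal(nchar(loc$genome_seq), loc$genome_length)
  expect_error(simulated_locus(intron = c(2, 100)), NA)  # valid small intron
  expect_error(simulated_locus(intron = c(100, 1712)))   # must end inside
})

test_that("fragment counts honour the capture model", {
  loc <- simulated_locus(seed = 11)
  none <- simulate_dataset(loc, dataset_profile(transcript_fragments = 0,
                                                n_background_reads = 5, seed = 12))
  expect_true(all(grepl("_bg", none$qname)))

  uncaptured <- simulate_dataset(loc, dataset_profile(
    transcript_fragments = 50, capture_prob = 0, n_background_reads = 3, seed = 13))
  expect_true(all(grepl("_bg", uncaptured$qname)))

  polya <- simulated_locus(seed = 11, polyadenylated = TRUE)
  full <- simulate_dataset(polya, dataset_profile(
    transcript_fragments = 50, capture_prob = 0, n_background_reads = 0, seed = 13))
  expect_gt(nrow(full), 20)  # polyA transcripts are not thinned
})

test_that("the same seed reproduces byte-identical SAM output", {
  loc <- simulated_locus(seed = 14)
  prof <- dataset_profile(transcript_fragments = 40, spliced_fraction = 0.3, seed = 15)
  a <- write_sam(simulate_dataset(loc, prof), header = simulated_sam_header(loc, prof))
  b <- write_sam(simulate_dataset(loc, prof), header = simulated_sam_header(loc, prof))
  expect_identical(a, b)
  prof2 <- dataset_profile(transcript_fragments = 40, spliced_fraction = 0.3, seed = 16)
  c <- write_sam(simulate_dataset(loc, prof2))
  expect_false(identical(a[-(1:3)], c))
})

test_that("simulated reads round-trip losslessly through the SAM parser", {
  loc <- simulated_locus(seed = 17)
  prof <- dataset_profile(transcript_fragments = 30, spliced_fraction = 0.4,
                          n_background_reads = 8, seed = 18)
  recs <- simulate_dataset(loc, prof)
  reparsed <- read_sam(write_sam(recs))
  expect_equal(as.data.frame(reparsed), as.data.frame(recs), ignore_attr = TRUE)
})

test_that("read length longer than an exon is rejected", {
  loc <- simulated_locus()  # exon 2 is 252 nt
  expect_error(simulate_dataset(loc, dataset_profile(read_len = 300)),
               "exceeds an exon length")
})

test_that("read sequences come from the genome at the mapped position", {
  loc <- simulated_locus(seed = 19)
  recs <- simulate_dataset(loc, dataset_profile(transcript_fragments = 20,
                                                n_background_reads = 5, seed = 20))
  unspliced <- recs[!grepl("N", recs$cigar), ]
  for (i in seq_len(nrow(unspliced))) {
    expect_equal(unspliced$seq[i],
                 substr(loc$genome_seq, unspliced$pos[i], unspliced$pos[i] + 99L))
  }
})

test_that("spliced reads recover the embedded intron exactly", {
  loc <- simulated_locus(seed = 21)
  chk <- junction_recovery_check(loc, dataset_profile(
    transcript_fragments = 500, spliced_fraction = 0.5, seed = 22))
  expect_true(chk$recovered)
  expect_equal(chk$expected_intron,
               loc$transcript_start + loc$intron - 1L)
  # every junction from transcript reads has the intron's length
  intron_len <- loc$intron[2] - loc$intron[1] + 1L
  expect_true(all(chk$junctions$intron_end - chk$junctions$intron_start + 1L ==
                    intron_len))

  unspliced <- junction_recovery_check(loc, dataset_profile(
    transcript_fragments = 500, spliced_fraction = 0, seed = 23))
  expect_false(unspliced$recovered)
  expect_equal(nrow(unspliced$junctions), 0L)
})

test_that("paired mode emits both mates with reciprocal coordinates", {
  loc <- simulated_locus(seed = 24)
  recs <- simulate_dataset(loc, dataset_profile(
    transcript_fragments = 20, n_background_reads = 5, paired = TRUE, seed = 25))
  expect_true(all(recs$is_paired))
  expect_equal(sum(bitwAnd(recs$flag, 64L) > 0), sum(bitwAnd(recs$flag, 128L) > 0))
  by_name <- split(recs$pos, recs$qname)
  expect_true(all(lengths(by_name) == 2))
})

test_that("composite depth converges to the expected per-dataset signal", {
  loc <- simulated_locus(seed = 26)
  prof <- dataset_profile(transcript_fragments = 20, capture_prob = 0.1,
                          n_background_reads = 0)
  n <- 50
  tx <- transcript_region(loc)
  covs <- lapply(seq_len(n), function(i) {
    p <- prof; p$seed <- 2600 + i; p$dataset_id <- paste0("d", i)
    compute_depth(simulate_dataset(loc, p), tx, dataset_id = p$dataset_id)
  })
  sig <- collapse_coverage(covs)
  # expected mean depth per dataset over the transcript:
  # fragments * capture * read_len / transcript_length
  expected <- n * prof$transcript_fragments * prof$capture_prob *
    prof$read_len / loc$transcript_length
  observed <- mean(sig$total_depth)
  expect_lt(abs(observed - expected) / expected, 0.25)
})

test_that("detection power rises with both fragments and dataset count", {
  loc <- simulated_locus(seed = 27)
  pw <- power_experiment(loc, dataset_profile(), n_grid = c(0, 2, 8), reps = 12,
                         seed = 28)
  expect_equal(pw$detection_probability[1], 0)  # no data, no detection
  expect_lte(pw$detection_probability[2] - 0.3, pw$detection_probability[3])

  rich <- power_experiment(loc, dataset_profile(transcript_fragments = 1000,
                                                capture_prob = 0.5),
                           n_grid = 1, reps = 8, seed = 29)
  expect_equal(rich$detection_probability, 1)  # saturation at high expression
  expect_error(power_experiment(loc, dataset_profile(), n_grid = integer(0)),
               "non-empty")
})
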