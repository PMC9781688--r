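sam_line <- function(qname = "r1", flag = 0, chrom = "chr11", pos = 1219991,
                     mapq = 60, cigar = "10M", rnext = "*", pnext = 0,
                     tlen = 0, seq = "ACGTACGTAC", qual = "IIIIIIIIII") {
  paste(qname, flag, chrom, pos, mapq, cigar, rnext, pnext, tlen, seq, qual,
        sep = "\t")
}

test_that("read_sam maps mandatory fields and skips headers", {
  rec <- read_sam(c("@HD\tVN:1.6", sam_line()))
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$pos, 1219991L)
  expect_equal(rec$cigar, "10M")
  expect_true(rec$is_mapped)
  expect_false(rec$is_paired)
  expect_equal(nrow(read_sam(character(0))), 0L)
})

test_that("unmapped flag and '*' CIGAR yield an unmapped record", {
  rec <- read_sam(sam_line(flag = 4, cigar = "*"))
  expect_false(rec$is_mapped)
  expect_equal(rec$cigar, "")
})

test_that("malformed SAM lines are rejected with their line number", {
  expect_error(read_sam(c("@HD\tVN:1.6", "r1\t0\tchr1\t10")),
               "line 2.*11 mandatory")
  expect_error(read_sam(c(sam_line(), sam_line(qname = "r2", cigar = "10Q"))),
               "line 2.*CIGAR")
})

test_that("mate fields resolve '=' and '*' sentinels", {
  rec <- read_sam(c(
    sam_line(flag = 99, rnext = "=", pnext = 500),
    sam_line(qname = "r2", flag = 147, rnext = "chr5", pnext = 900),
    sam_line(qname = "r3")
  ))
  expect_equal(rec$mate_chrom, c("chr11", "chr5", NA))
  expect_equal(rec$mate_pos, c(500L, 900L, NA))
})

test_that("quality filter keeps by mean base quality with mapq fallback", {
  hi <- sam_line(qname = "hi", qual = strrep("?", 10))           # Q30
  lo <- sam_line(qname = "lo", qual = strrep("+", 10))           # Q10
  noq <- sam_line(qname = "noq", qual = "*", mapq = 25)
  noq_lo <- sam_line(qname = "noq_lo", qual = "*", mapq = 5)
  sec <- sam_line(qname = "sec", flag = 256, qual = strrep("?", 10))
  kept <- filter_quality(read_sam(c(hi, lo, noq, noq_lo, sec)), min_q = 20)
  expect_setequal(kept$qname, c("hi", "noq"))
  expect_error(filter_quality(read_sam(hi), min_q = -1), "non-negative")
})

test_that("quality filter agrees with per-read arithmetic on random reads", {
  set.seed(101)
  lines <- random_sam_lines(100, mean_q = 20)
  rec <- read_sam(lines)
  kept <- filter_quality(rec, min_q = 20)
  expected <- vapply(rec$qual, function(q) mean(utf8ToInt(q) - 33) >= 20,
                     logical(1), USE.NAMES = FALSE)
  expect_setequal(kept$qname, rec$qname[expected])
})

test_that("quality filter is monotone in the threshold", {
  set.seed(102)
  rec <- read_sam(random_sam_lines(60, mean_q = 25))
  prev <- rec
  for (q in c(10, 20, 30, 40)) {
    cur <- filter_quality(rec, min_q = q)
    expect_true(all(cur$qname %in% prev$qname))
    prev <- cur
  }
})

test_that("region pair filter keeps pairs when either mate is in-window", {
  win <- genomic_region("chr11", 1202000, 1220500)
  a <- sam_line(qname = "p", flag = 99, pos = 1219991, rnext = "=", pnext = 2219991)
  b <- sam_line(qname = "p", flag = 147, pos = 2219991, rnext = "=", pnext = 1219991)
  kept <- filter_region_pairs(read_sam(c(a, b)), win)
  expect_equal(nrow(kept), 2L)  # either-mate policy retains both mates

  far <- read_sam(c(
    sam_line(qname = "q", flag = 99, chrom = "chr2", pos = 100, rnext = "=", pnext = 300),
    sam_line(qname = "q", flag = 147, chrom = "chr2", pos = 300, rnext = "=", pnext = 100)
  ))
  expect_message(out <- filter_region_pairs(far, win), "no records")
  expect_equal(nrow(out), 0L)

  single <- read_sam(sam_line(pos = 1219991))
  expect_equal(nrow(filter_region_pairs(single, win)), 1L)
})

test_that("require_both tightens the pair policy", {
  win <- genomic_region("chr11", 1202000, 1220500)
  rec <- read_sam(c(
    sam_line(qname = "p", flag = 99, pos = 1219991, rnext = "=", pnext = 2219991),
    sam_line(qname = "p", flag = 147, pos = 2219991, rnext = "=", pnext = 1219991),
    sam_line(qname = "q", flag = 99, pos = 1210000, rnext = "=", pnext = 1210200),
    sam_line(qname = "q", flag = 147, pos = 1210200, rnext = "=", pnext = 1210000)
  ))
  loose <- filter_region_pairs(rec, win)
  strict <- filter_region_pairs(rec, win, require_both = TRUE)
  expect_setequal(loose$qname, c("p", "p", "q", "q"))
  expect_setequal(strict$qname, c("q", "q"))
})

test_that("region filter output is a subset and idempotent", {
  set.seed(103)
  win <- genomic_region("chrT", 20, 50)
  rec <- read_sam(random_sam_lines(80))
  once <- filter_region_pairs(rec, win)
  twice <- filter_region_pairs(once, win)
  expect_true(all(once$qname %in% rec$qname))
  expect_identical(once, twice)
})

test_that("a record spanning into the window from outside is kept", {
  win <- genomic_region("chrT", 100, 200)
  rec <- read_sam(sam_line(chrom = "chrT", pos = 95, cigar = "10M"))
  expect_equal(nrow(filter_region_pairs(rec, win)), 1L)
  outside <- read_sam(sam_line(chrom = "chrT", pos = 85, cigar = "10M"))
  expect_equal(nrow(filter_region_pairs(outside, win)), 0L)
})

test_that("SAM records round-trip through write_sam", {
  set.seed(104)
  lines <- random_sam_lines(20)
  rec <- read_sam(lines)
  out <- write_sam(rec)
  expect_identical(out, lines)
  expect_identical(read_sam(out), rec)
})

test_that("manifest reading validates columns and unique ids", {
  p <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(dataset_id = c("a", "b"), path = c("x", "y"),
                                  group_label = c("epithelial", "basal")), p)
  m <- read_manifest(p)
  expect_equal(m$dataset_id, c("a", "b"))

  readr::write_tsv(tibble::tibble(dataset_id = c("a", "a"), path = c("x", "y"),
                                  group_label = c("g", "g")), p)
  expect_error(read_manifest(p), "duplicate dataset_id")
})
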