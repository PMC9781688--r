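test_that("identical rows give identity 1 in every window", {
  rows <- c(human = strrep("ACGTG", 12), mouse = strrep("ACGTG", 12))  # 60 cols
  aln <- gapped_alignment(rows)
  wi <- window_identity(aln, window = 50)
  expect_equal(nrow(wi), 11L)
  expect_true(all(wi$identity == 1))
  seg <- call_conserved(wi)
  expect_equal(nrow(seg), 1L)
  expect_equal(c(seg$start, seg$end), c(1L, 60L))
  expect_equal(seg$mean_identity, 1)
})

test_that("a 35/50 window meets the 70% criterion and 34/50 does not", {
  base <- strsplit(strrep("ACGTGACGTG", 5), "")[[1]]
  mutate_at <- function(n) {
    other <- base
    other[seq_len(n)] <- ifelse(base[seq_len(n)] == "A", "C", "A")
    paste(other, collapse = "")
  }
  ref <- paste(base, collapse = "")

  aln35 <- gapped_alignment(c(a = ref, b = mutate_at(15)))  # 35 matches
  wi35 <- window_identity(aln35, window = 50)
  expect_equal(wi35$identity, 0.70)
  expect_equal(nrow(call_conserved(wi35, threshold = 0.70)), 1L)

  aln34 <- gapped_alignment(c(a = ref, b = mutate_at(16)))  # 34 matches
  wi34 <- window_identity(aln34, window = 50)
  expect_equal(wi34$identity, 0.68)
  expect_equal(nrow(call_conserved(wi34, threshold = 0.70)), 0L)
})

test_that("gaps and N count as mismatches", {
  aln <- gapped_alignment(c(a = "ACGTACGT", b = "AC-TNCGT"))
  wi <- suppressWarnings(window_identity(aln, window = 8))
  expect_equal(wi$identity, 6 / 8)
})

test_that("window identities match the brute-force column counter", {
  set.seed(401)
  alphabet <- c("A", "C", "G", "T", "N", "-")
  for (i in 1:10) {
    n <- sample(60:120, 1)
    a <- paste(sample(alphabet, n, replace = TRUE, prob = c(rep(0.22, 4), 0.04, 0.08)),
               collapse = "")
    b <- paste(sample(alphabet, n, replace = TRUE, prob = c(rep(0.22, 4), 0.04, 0.08)),
               collapse = "")
    a <- sub("^-+", "A", a)  # keep a non-gap reference character
    aln <- gapped_alignment(c(ref = a, other = b))
    w <- sample(c(10, 25, 50), 1)
    wi <- window_identity(aln, window = w)
    expect_equal(wi$identity, oracle_window_identity(a, b, w))
    expect_true(all(wi$identity >= 0 & wi$identity <= 1))
  }
})

test_that("alignments shorter than the window yield one flagged window", {
  aln <- gapped_alignment(c(a = "ACGTACGTAC", b = "ACGTACGTAC"))
  expect_warning(wi <- window_identity(aln, window = 50), "truncated")
  expect_equal(nrow(wi), 1L)
  expect_true(attr(wi, "truncated"))
})

test_that("reverse-complementing both rows reverses the identity profile", {
  set.seed(402)
  a <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
  b <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
  wi <- window_identity(gapped_alignment(c(x = a, y = b)), window = 20)
  wi_rc <- window_identity(
    gapped_alignment(c(x = reverse_complement(a), y = reverse_complement(b))),
    window = 20)
  expect_equal(wi_rc$identity, rev(wi$identity))
})

test_that("conserved positions shrink as the threshold rises", {
  set.seed(403)
  a <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  noisy <- strsplit(a, "")[[1]]
  flip <- sample(300, 70)
  noisy[flip] <- ifelse(noisy[flip] == "A", "G", "A")
  aln <- gapped_alignment(c(ref = a, other = paste(noisy, collapse = "")))
  wi <- window_identity(aln, window = 50)
  covered <- function(th) {
    segs <- call_conserved(wi, threshold = th)
    if (nrow(segs) == 0) 0L else sum(segs$end - segs$start + 1L)
  }
  cov_by_th <- vapply(c(0.5, 0.6, 0.7, 0.8, 0.9), covered, integer(1))
  expect_true(all(diff(cov_by_th) <= 0))
  expect_error(call_conserved(wi, threshold = 1.2), "0, 1")
})

test_that("conserved segments are reported in ungapped reference coordinates", {
  # 10 matching columns, then a 5-column gap in the reference, then 10 matching
  ref <- paste0(strrep("ACGTA", 2), "-----", strrep("ACGTA", 2))
  oth <- paste0(strrep("ACGTA", 2), "CCCCC", strrep("ACGTA", 2))
  aln <- gapped_alignment(c(ref = ref, oth = oth))
  wi <- window_identity(aln, window = 10)
  segs <- call_conserved(wi, threshold = 0.99, window = 10)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$start, c(1L, 11L))
  expect_equal(segs$end, c(10L, 20L))
})

test_that("IUPAC motif scan finds stated SBE hits on both strands", {
  hits <- scan_motifs("AACAGACTT", tibble::tibble(name = "SBE", pattern = "CAGAC"))
  expect_equal(hits$start, 3L)
  expect_equal(hits$strand, "+")

  hits5gc <- scan_motifs("TTGGCGCAA", sbe_motifs())
  hit <- hits5gc[hits5gc$motif_name == "5GC_SBE" & hits5gc$strand == "+", ]
  expect_equal(hit$start, 3L)
  expect_equal(hit$matched_text, "GGCGC")

  rc <- scan_motifs("AAGTCTGAA", tibble::tibble(name = "SBE", pattern = "CAGAC"))
  expect_equal(rc$strand, "-")
  expect_equal(rc$start, 3L)
  expect_equal(rc$matched_text, "GTCTG")

  expect_error(scan_motifs("ACGT", tibble::tibble(name = "bad", pattern = "CAG!C")),
               "IUPAC")
})

test_that("degenerate IUPAC codes match their expansions", {
  hits <- scan_motifs("AACAGACTT", tibble::tibble(name = "sbe_iupac", pattern = "CASAC"),
                      both_strands = FALSE)
  expect_equal(hits$start, 3L)
  expect_equal(hits$matched_text, "CAGAC")
})

test_that("a sequence plus its reverse complement has symmetric hit counts", {
  set.seed(404)
  s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  both <- paste0(s, reverse_complement(s))
  hits <- scan_motifs(both, sbe_motifs(), both_strands = TRUE)
  expect_equal(sum(hits$strand == "+"), sum(hits$strand == "-"))
})
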