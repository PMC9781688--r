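---
title: "Methods: composite coverage mining for weakly expressed transcripts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite coverage mining for weakly expressed transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covmine)
```

## The detection model

covmine targets a specific failure mode of RNA-seq: a short, weakly
expressed, non-polyadenylated transcript whose reads survive polyA-selective
library preparation only sporadically. In any single dataset the locus shows
a couple of alignments — indistinguishable from noise. The package's central
operation treats many independent datasets as repeated noisy measurements of
the same underlying signal and sums their per-base depth:

\[ D(p) = \sum_{i=1}^{n} d_i(p) \]

where \(d_i(p)\) counts aligned read bases (CIGAR `M`/`=`/`X`) that dataset
\(i\) places at position \(p\). Real transcription accumulates coherently at
the same positions across datasets while background is diffuse, so the
composite mean depth at the locus grows linearly in \(n\) and eventually
crosses any calling threshold. The assumptions are: all datasets are aligned
to the same reference; the transcript's position is fixed across datasets
(true for a genomic locus, the unit of analysis here); and datasets are
independent, so heterogeneity of sources works for us — there is no shared
batch structure to masquerade as signal. Note what the model does *not*
assume: comparable library sizes. The default collapse is an unnormalized
raw sum, because the quantity of interest is cumulative evidence of
transcription, not a per-dataset expression estimate; `normalize = TRUE`
(per-dataset depth per million summed in-window bases) is available when
heterogeneous sequencing effort must not let one deep dataset dominate.

Background accumulates too, at its own (lower) density. Consequently the
fixed segment-calling threshold is meaningful at a given \(n\); as more
datasets are collapsed, both signal and noise rise, and the separation
criterion is the *density contrast*, not the absolute depth. This is visible
in the worked example in the README: the transcript segments stand out by
max depth, while chance overlaps of background reads produce shallow calls.

## Coordinates and span arithmetic

All user-facing coordinates are 1-based. Regions are end-exclusive: a
region `chrom:start-end` covers positions `start` to `end − 1` and spans
`end − start` nucleotides. This convention is forced by the anchoring locus
itself: the transcript at chr11:1,218,530–1,220,242 has an annotated length
of 1712 nt, which equals `end − start`; a fully inclusive reading would give
1713. Internal arrays are 0-based offsets from `start`; per-position TXT
output is 1-based again.

## Filtering parameters

* `min_q = 20` (Phred). "Q20" is interpreted as **mean base quality ≥ 20,
  inclusive**, the convention of common read-trimming tools. Whether a
  quality cut of this kind refers to base or mapping quality is genuinely
  ambiguous in pipeline descriptions; we chose base quality as the stricter,
  per-read reading and fall back to MAPQ ≥ `min_q` when base qualities are
  absent (`QUAL == "*"`). Secondary and supplementary alignments are dropped
  here so no read contributes depth twice.
* Window pair policy: a paired record is kept when **either** its own
  reference span overlaps the window or its mate starts inside it, and both
  mates of a kept pair are retained. For a sparse signal, sensitivity is the
  priority — a read whose mate anchors in the window is exactly the kind of
  evidence worth rescuing. The stricter both-mates policy is exposed as
  `require_both = TRUE`.

## Depth, junctions, and their conventions

Depth follows CIGAR reference consumption: `M`/`=`/`X` add depth, `D` and
`N` consume reference without adding it, `I`/`S`/`H` add nothing. Two
defaults deserve explanation because depth tools differ silently on them:

* **Deletions do not add depth** (`count_deletions = FALSE`). A deleted base
  is not observed in the read; counting it inflates apparent coverage.
* **Overlapping mates double-count** (`dedup_mates = FALSE`). The raw
  collapse is a sum over aligned bases; mate-aware deduplication is a
  different (fragment-level) quantity and is available behind a flag.

Both choices are declared conventions, not inferences — they are the common
defaults of depth utilities, and the flags make the alternatives testable.
Depth is stored as doubles so composite sums across hundreds of datasets
cannot overflow integer range.

A junction is emitted for every `N` operation: with the reference cursor at
`q` before an `N` of length `L`, the intron is `(q+1, q+L)` — first and last
skipped bases, 1-based. Identical junctions are merged with summed support.

Segment calling scans for maximal runs of positions with depth
≥ `min_depth`, bridging sub-threshold gaps of up to `max_gap` positions, and
keeps bridged runs of at least `min_len` bp. Defaults `min_depth = 2`,
`min_len = 50`, `max_gap = 10` are operational stand-ins for judging a
coverage plot by eye: depth 2 excludes singleton reads, 50 bp matches a
typical read's scale of evidence, and a 10 bp bridge tolerates ragged run
edges. There is no biological constant behind them; the defaults are fixed,
documented, and exposed, and the caller's monotonicity (raising any
threshold never increases called territory) is property-tested.

## Conservation and motif scanning

Window identity is computed per alignment-column window (width 50, step 1):
identity = identical unambiguous nucleotide pairs / window width. Gaps and
`N` count as mismatches — the conservative convention of VISTA-style plots,
which avoids rewarding alignments for shared absence. The 70% threshold is
**inclusive**: 35/50 passes, 34/50 does not, and the boundary is pinned by
tests. Windows above threshold that overlap in alignment columns are merged
and reported in ungapped coordinates of the reference row (conservation
figures are anchored on the reference transcript). When the alignment is
shorter than one window, a single truncated window is returned and flagged
rather than silently rescaled.

Motif scanning does exact IUPAC matching on both strands (minus-strand hits
reported in plus coordinates). The bundled set contains only the two SMAD
binding elements whose sequences are literature-stated: canonical `CAGAC`
and the 5GC variant `GGC(GC)(CG)`, expanded to the explicit alternation
{`GGCGC`, `GGCCG`} rather than encoded as `GGCSS` (which would wrongly also
match `GGCGG` and `GGCCC`). No FOXA2 pattern is bundled: its published
binding-site sequence is not reproduced in the sources this package draws
its defaults from, and shipping a guessed motif would be worse than
accepting a user-supplied one.

## qPCR quantification

`delta_ct()` computes ΔCt = mean(Ct target) − mean(Ct reference) per sample,
with replicate spread propagated as \(\sqrt{sd_t^2 + sd_r^2}\). The "±"
reported alongside ΔCt values is declared to be a **standard deviation**
across replicates and labelled as such in output; ± without a definition is
ambiguous, and sd is the conservative reading (sem would be smaller).
Undetected reactions — explicit `ND` or Ct at/beyond the 40-cycle protocol
limit — are propagated as flags, never imputed with a pseudo-Ct: a single
undetected replicate makes the group's ΔCt undefined. Fold differences use
the comparative form \(2^{-\Delta\Delta Ct}\). Amplification efficiency
comes from the standard-curve slope of `Ct ~ log10(input)` via least
squares: \((10^{-1/m} - 1) \times 100\), so the ideal slope −3.3219 gives
100%.

## What the simulator emulates — and what it does not

`simulated_locus()` defaults reconstruct the study geometry at full scale
inside a 20 kb uniform-random genome: a 1712 nt transcript starting at
16,531 (the same offset the real transcript has inside its 18.5 kb analysis
window), an intron at transcript offsets 1001–1460 chosen so that the SNP
offset 1462 is the second nucleotide of exon 2 (matching
1,219,991 − 1,218,530 + 1 = 1462; the real exon boundaries are otherwise
unspecified, so exon 1 was set to 1 kb), and a non-polyadenylated transcript.

`dataset_profile()` defaults define the weak-expression regime:
`transcript_fragments = 20` (Poisson mean) thinned by `capture_prob = 0.1`
— about two surviving 100 nt transcript reads per dataset — plus 10
uniform background reads over the 20 kb genome. These were chosen
analytically to reproduce the qualitative situation the method addresses: a
couple of sporadic in-window reads per dataset, where two reads must overlap
by ≥ 50 bp before the default caller can fire, so a single dataset rarely
supports a call, while the composite of tens of datasets saturates. Reads
are error-free by default (`error_rate` flag available): base-calling noise
affects the upstream aligner, not the aggregation mechanism under test here.

The simulator deliberately does **not** model realistic fragmentation,
GC/positional bias, alignment ambiguity, polyA-selection chemistry, or
single-cell sparsity. Passing tests therefore demonstrate the correctness of
the counting, collapsing and calling machinery and the in-principle power of
aggregation — they do not certify detection power on real archives, where
background structure and alignment artifacts are less forgiving.

Seeding: every stochastic function takes an explicit seed;
`power_experiment()` splits one master seed into per-dataset seeds, and the
SAM writer records dataset id and seed in `@CO` header lines for audit.
Fixed seeds give byte-identical SAM output.

## Problem sizes used by the test suite

The power experiment runs 50 replicates at each of n ∈ {1, 2, 5, 10, 20}
datasets (1,900 simulated datasets, ~30 s); depth correctness is checked on
200 randomized alignment instances against a brute-force per-(read,
position) oracle; junction recovery uses 500 transcript fragments at 50%
spliced fraction, enough to make junction reads essentially certain. These
sizes give stable Monte-Carlo behaviour at fixed seeds while keeping the
suite fast.

## Known limitations

* Input is SAM text (or anything a caller converts to it); BAM random
  access and CRAM are out of scope by design — targeted windows keep files
  small after `samtools view`-style extraction upstream.
* The segment caller is a threshold rule, not a statistical test; no
  FDR-controlled differential calling between groups is attempted, and
  `compare_groups()` is descriptive.
* Conservation operates on externally produced alignments; the package does
  not implement global alignment itself.
* Background in the composite grows with the number of datasets; users
  collapsing very many datasets should raise `min_depth` (or normalize) and
  judge segments by depth contrast, as discussed above.
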