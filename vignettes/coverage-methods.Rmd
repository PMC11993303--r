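---
title: "Coverage statistics from read alignments: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage statistics from read alignments: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covstats)
```

## The model

The depth of a reference base is the number of filtered alignment
segments overlapping it. `covstats` computes it with a delta array: for a
contig of length $L$, an integer array $\delta$ of $L+1$ slots receives
$+1$ at the start and $-1$ at the (half-open) end of every covered
segment, and the depth at base $p$ is $\sum_{q \le p}\delta_q$. The extra
slot lets segments ending at the contig end close without special
casing. The array is exact — every statistic below is computed on true
per-base depth, not an approximation — and is built and reduced one
contig at a time, so memory is bounded by a single contig.

A read's covered segments come from its CIGAR: M/`=`/X consume reference
and query; D consumes reference only and **does count as covered** (a
deleted base is spanned by the mapped segment); N (reference skip) splits
the footprint into separate segments; S/H/I/P consume no reference.
Treating D as covered is a choice — the convention for genomic
alignments, where D models a short deletion rather than an intron.

All coordinates are 0-based half-open internally; SAM's 1-based `POS` is
converted at parse time. Input must be coordinate-sorted: the package
validates (grouped references, non-decreasing positions, no reference
revisited) and refuses unsorted input rather than sorting, since sorting
is the aligner/samtools pipeline's job.

## Which reads count

Secondary (0x100) records never contribute; supplementary (0x800)
records are excluded by default. Both would double-count one sequenced
read. "Total reads" — the denominator of relative abundance — is the
number of *primary* records, mapped or not; when a BAM was stripped of
unmapped reads, `total_read_count` lets the caller supply the true
library size.

Filters (all comparisons inclusive, `>=`):

* **percent identity** $= 1 - \mathrm{NM}/\text{aligned length}$, with
  aligned length $=$ M/`=`/X $+$ I bases. Insertions therefore count as
  potential errors. The gap-inclusive per-alignment identity is the
  conventional reading; a column-only identity would differ slightly for
  gapped alignments, and no parity with any particular aligner's
  definition is asserted.
* **aligned length** in bp, and **aligned fraction** of the read length
  (soft clips count toward read length, hard clips do not — hard-clipped
  bases are absent from the stored record).
* **pair mode**: `independent` judges each record alone; `together`
  keeps a pair only if both mates pass. Mates are matched by query name
  and first/second-in-pair flag across the file; a mate that never
  appears (unmapped, or absent) leaves an orphan that is judged alone and
  counted in a warning. No mapping-quality or duplicate filter is applied
  by default — the behaviour for those flags is unspecified upstream, so
  they are left to the caller.

## The statistics and their parameters

* `end_exclusion` (default **75 bp** per contig end, units bp): depth
  statistics ignore contig ends, where assembly artefacts and edge
  effects depress depth. Contigs with `length <= 2 * end_exclusion` have
  an empty effective region and report 0 for depth statistics; their
  count-based statistics still use the full length.
* `trim_lower`/`trim_upper` (default **0.05** each, fractions
  *per tail*): the trimmed mean sorts the effective region's depths and
  discards `floor(trim * n)` bases at each end. Per-tail is the reading
  consistent with the MetaBAT lineage of the statistic; `floor` makes
  trim = 0 an exact identity with the mean.
* variance uses the **n − 1** (sample) denominator, the convention of the
  binning ecosystem that consumes these numbers.
* `rpkm`/`tpm` denominators use reads *passing filters* in the sample,
  consistent with every other statistic being post-filter. TPM sums to
  $10^6$ whenever any reads align.
* the MetaBAT-adjusted pair (depth, variance) recomputes depth under that
  tool's own default 97% identity pre-filter, independent of user
  filters. Bit-exact parity with the original `jgi_summarize` tool's
  tie-breaking cannot be asserted; the variant implemented here is the
  documented one.
* `count` counts each primary alignment once on the contig where it is
  placed; reads are never fractionally split.

## Genome mode

A genome's statistics pool **all bases of all its contigs together**
(after per-contig end exclusion): the genome mean is the
effective-length-weighted contig mean, identical to the mean over pooled
bases, and the trimmed mean, variance and covered fraction are computed
on the pooled depth multiset. Weighting by *effective* length (rather
than raw length) keeps mean, trimmed mean and variance mutually
consistent on the same base population; the alternative raw-length
weighting would make the mean inconsistent with the pooled variance.
Pooling is implemented with per-contig depth histograms (depth value →
base count), which add across contigs and reproduce sort-based
statistics exactly.

* `min_covered_fraction` (default **0.10** in genome mode, 0 in contig
  mode, fraction of effective genome length): a genome with fewer covered
  bases than the gate is deemed absent — off-target alignments to
  conserved regions would otherwise produce spurious low-level
  detections. The comparison is inclusive, the denominator is the
  effective genome length (consistency with every other depth metric),
  and the reads of gated-out genomes are moved to the unmapped mass so
  the abundance budget still sums to exactly 100%. Whether contig-mode
  output should be gated at all is not specified upstream; the gate
  defaults to 0 there and is exposed as a parameter.

Relative abundance apportions the aligned fraction of the library by
mean-coverage share:

$$\mathrm{RA}_i = \frac{\bar d_i}{\sum_j \bar d_j}
  \cdot \frac{\text{aligned reads}}{\text{total reads}} \cdot 100\%$$

It assumes (i) genomes missing from the reference set have the same
average genome size as those present, and (ii) reference genomes are
roughly complete and uncontaminated. Both are caveats, not corrections —
nothing in the computation adjusts for genome-size differences.

## The synthetic-data generator

`simulate_fixture()` is first-class, tested code: it emits a FASTA of
random contigs, a coordinate-sorted SAM, and a truth record with *exact*
per-base depths computed by direct pileup while the reads are generated —
an accounting that never touches the delta-array engine. Its defaults are
the stated world of the test suite, chosen once:

* read length **150 bp** (typical short-read data), per-genome target
  depth **5×**, per-contig read count $\sim$ Poisson(depth · L / read
  length), uniform start positions, per-read NM $\sim$
  Binomial(read length, **0.01**);
* `fraction_unmapped` **0.2** — a metagenome against an incomplete
  reference routinely leaves a fifth or more of reads unaligned, and it
  matches the 800/1000 aligned fraction of the worked abundance example.

What it does **not** emulate: realistic fragment-size and error models,
position-dependent quality, chimeras, or reference bias. A green test
therefore establishes the *arithmetic* of the pipeline — depth
construction, filtering semantics, aggregation, normalisation — not
robustness to messy real alignments. The complementary
`random_alignments()` fuzzer exercises the parts where implementations
actually break: CIGARs with soft clips, insertions, deletions and skips
at and across contig boundaries, checked against a brute-force pileup
oracle (`pileup_oracle()`) that uses a plain increment loop and no delta
arrays.

## Numerical and degenerate-input choices

* Depth, deltas, histograms and covered-base counts are integer
  arithmetic throughout; only final ratios are floating point, so
  permutation invariance and determinism are exact and TSV output is
  byte-identical across runs.
* Empty effective regions, zero-read contigs and genomes with zero
  effective length report 0 rather than NaN; an entirely empty library in
  genome mode reports every genome at 0% and unmapped at 100% (the
  low-level `relative_abundance()` treats `total_reads = 0` as an error,
  since the formula is undefined there).
* A negative running depth — impossible for well-formed input — aborts
  with an internal-consistency error rather than clamping.
* Floats print with six fixed decimals; `length`, `count` and
  `covered_bases` print as integers.
* Sample names are BAM file stems; collisions get `.1`, `.2` suffixes.

## Limitations

CRAM input, BAM index construction, windowed depth export, aligner
invocation and genome dereplication are out of scope: the package
consumes pre-aligned, pre-sorted BAM/SAM only. Name-sorted input is
rejected, not buffered. Exact output parity with other coverage tools
(column naming, MetaBAT tie-breaking) is documented as this package's own
convention rather than asserted.
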