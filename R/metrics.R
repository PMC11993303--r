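## Per-reference coverage metrics.
##
## Depth-based statistics (mean, trimmed mean, variance, covered
## fraction/bases) are computed over the effective region of each contig:
## the first and last `end_exclusion` bases (default 75, the MetaBAT
## convention) are ignored to avoid edge artifacts. Count-based statistics
## (count, reads per base, RPKM, TPM) use the full reference length.
##
## Internally, a region's depths are summarised as a histogram (depth value
## -> number of bases); histograms of several contigs add, so genome-mode
## pooling reuses the same reductions exactly.

#' Effective region of a contig after end exclusion
#'
#' @param length contig length in bp.
#' @param end_exclusion bases excluded at each end (default 75).
#' @return half-open 0-based interval `c(start, end)`; empty (`end <=
#'   start`) when `length <= 2 * end_exclusion`.
#' @examples
#' effective_region(1000, 75)  # (75, 925): 850 positions
#' effective_region(150, 75)   # empty
#' @export
effective_region <- function(length, end_exclusion = 75L) {
  stopifnot(length > 0L, end_exclusion >= 0L)
  if (length > 2L * end_exclusion) {
    c(end_exclusion, length - end_exclusion)
  } else {
    c(0L, 0L)
  }
}

## depths over the effective region of a full-contig depth vector
.effective_depths <- function(depths, end_exclusion) {
  r <- effective_region(length(depths), end_exclusion)
  if (r[2L] <= r[1L]) return(integer())
  depths[(r[1L] + 1L):r[2L]]
}

#' Depth histogram of a region
#'
#' Summarises a per-base depth vector as counts per depth value:
#' `h[v + 1]` is the number of bases at depth `v`. Histograms of disjoint
#' regions add, which is how genome mode pools contigs.
#'
#' @param depths integer vector of per-base depths.
#' @return integer histogram vector (length `max(depths) + 1`; empty for
#'   an empty region).
#' @export
depth_histogram <- function(depths) {
  if (length(depths) == 0L) return(integer())
  tabulate(depths + 1L, nbins = max(depths) + 1L)
}

add_histograms <- function(a, b) {
  n <- max(length(a), length(b))
  length(a) <- n
  length(b) <- n
  a[is.na(a)] <- 0L
  b[is.na(b)] <- 0L
  a + b
}

hist_n <- function(h) sum(h)
hist_sum <- function(h) {
  if (length(h) == 0L) return(0)
  sum(as.numeric(seq_along(h) - 1L) * h)
}

hist_mean <- function(h) {
  n <- hist_n(h)
  if (n == 0L) 0 else hist_sum(h) / n
}

## sample variance (n - 1 denominator), 0 when fewer than 2 positions
hist_variance <- function(h) {
  n <- hist_n(h)
  if (n < 2L) return(0)
  m <- hist_mean(h)
  v <- seq_along(h) - 1L
  sum(h * (v - m)^2) / (n - 1)
}

## discard floor(trim_lower * n) lowest and floor(trim_upper * n) highest
## depths, mean of the remainder; equivalent to sort-and-slice on the
## underlying multiset
hist_trimmed_mean <- function(h, trim_lower = 0.05, trim_upper = 0.05) {
  stopifnot(trim_lower >= 0, trim_upper >= 0, trim_lower + trim_upper < 1)
  n <- hist_n(h)
  if (n == 0L) return(0)
  lo <- floor(trim_lower * n)
  hi <- floor(trim_upper * n)
  keep <- h
  drop <- lo
  for (i in seq_along(keep)) {
    if (drop <= 0L) break
    d <- min(drop, keep[i])
    keep[i] <- keep[i] - d
    drop <- drop - d
  }
  drop <- hi
  for (i in rev(seq_along(keep))) {
    if (drop <= 0L) break
    d <- min(drop, keep[i])
    keep[i] <- keep[i] - d
    drop <- drop - d
  }
  if (sum(keep) == 0L) return(0)
  hist_mean(keep)
}

hist_covered <- function(h) {
  if (length(h) == 0L) return(0L)
  sum(h[-1L])
}

#' Mean coverage over the effective region
#'
#' @param depths integer per-base depth vector for a full contig.
#' @param end_exclusion bases excluded at each end (default 75).
#' @return mean depth over the effective region; 0 when it is empty.
#' @export
mean_coverage <- function(depths, end_exclusion = 75L) {
  hist_mean(depth_histogram(.effective_depths(depths, end_exclusion)))
}

#' Trimmed mean coverage
#'
#' Per-base depths of the effective region are sorted; the lowest
#' `floor(trim_lower * n)` and highest `floor(trim_upper * n)` are
#' discarded (default 5% per tail) and the remainder averaged.
#'
#' @inheritParams mean_coverage
#' @param trim_lower,trim_upper per-tail trim fractions, `trim_lower +
#'   trim_upper < 1`.
#' @return trimmed mean depth; 0 on an empty region.
#' @export
trimmed_mean <- function(depths, end_exclusion = 75L,
                         trim_lower = 0.05, trim_upper = 0.05) {
  hist_trimmed_mean(depth_histogram(.effective_depths(depths, end_exclusion)),
                    trim_lower, trim_upper)
}

#' Coverage variance
#'
#' Sample variance (denominator n - 1) of per-base depths over the
#' effective region; 0 when the region has fewer than 2 positions.
#'
#' @inheritParams mean_coverage
#' @return variance of depth.
#' @export
coverage_variance <- function(depths, end_exclusion = 75L) {
  hist_variance(depth_histogram(.effective_depths(depths, end_exclusion)))
}

#' Covered bases and covered fraction
#'
#' @inheritParams mean_coverage
#' @return list with `covered_bases` (positions of the effective region at
#'   depth >= 1) and `covered_fraction` (their fraction of the effective
#'   length; 0 on an empty region).
#' @export
covered_stats <- function(depths, end_exclusion = 75L) {
  e <- .effective_depths(depths, end_exclusion)
  cb <- hist_covered(depth_histogram(e))
  list(covered_bases = cb,
       covered_fraction = if (length(e)) cb / length(e) else 0)
}

#' Reads per base
#'
#' @param count number of reads aligned to the reference.
#' @param length full reference length in bp (no end exclusion).
#' @return `count / length`.
#' @export
reads_per_base <- function(count, length) {
  stopifnot(all(length > 0))
  count / length
}

#' RPKM: reads per kilobase of reference per million reads aligned
#'
#' @param count reads aligned to the reference.
#' @param length full reference length in bp.
#' @param total_mapped reads aligned in the sample (after filtering).
#' @return `count * 1e9 / (length * total_mapped)`; 0 when `total_mapped`
#'   is 0.
#' @export
rpkm <- function(count, length, total_mapped) {
  stopifnot(all(length > 0))
  if (total_mapped == 0) return(rep(0, base::length(count)))
  count * 1e9 / (length * total_mapped)
}

#' TPM: length-normalised read rates scaled to sum to one million
#'
#' @param counts per-reference read counts.
#' @param lengths per-reference full lengths in bp.
#' @return per-reference TPM values; all zero when no reads aligned.
#' @export
tpm <- function(counts, lengths) {
  stopifnot(all(lengths > 0), length(counts) == length(lengths))
  rate <- counts / lengths
  s <- sum(rate)
  if (s == 0) return(rep(0, length(counts)))
  rate * 1e6 / s
}

#' MetaBAT-adjusted depth and variance
#'
#' Mean and sample variance of per-base depth over the 75 bp end-excluded
#' region, computed from alignments that additionally pass a 97% identity
#' filter (the upstream MetaBAT tool's default), independent of any user
#' filters. The caller supplies depths already built from such alignments;
#' this helper performs the reduction.
#'
#' @param depths per-base depth vector built from >= 0.97-identity
#'   alignments.
#' @param end_exclusion bases excluded at each end (default 75).
#' @return list with `depth` and `variance`.
#' @export
metabat_adjusted <- function(depths, end_exclusion = 75L) {
  h <- depth_histogram(.effective_depths(depths, end_exclusion))
  list(depth = hist_mean(h), variance = hist_variance(h))
}
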