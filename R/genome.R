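#' Genome definition: mapping contigs to genomes
#'
#' Exactly one of the three conventions must be supplied:
#' \describe{
#'   \item{`fasta_files`}{per-genome FASTA files; each file's record names
#'     map to the file's stem (extension stripped).}
#'   \item{`separator`}{single character; a contig's genome is its name up
#'     to the first occurrence of the separator. Requires `contigs`, the
#'     contig names to resolve (e.g. `names(reference_dictionary(bam))`).}
#'   \item{`definition_file`}{two-column TSV, genome then contig, no
#'     header.}
#' }
#'
#' @param fasta_files character vector of genome FASTA paths.
#' @param separator single-character genome/contig name separator.
#' @param definition_file path to a genome-definition TSV.
#' @param contigs contig names to resolve (separator mode only).
#' @return object of class `genome_definition`: list with
#'   `contig_to_genome` (named character vector) and `genomes` (genome
#'   names in definition order).
#' @examples
#' gd <- genome_definition(separator = "~",
#'                         contigs = c("g1~c1", "g1~c2", "g2~c1"))
#' gd$contig_to_genome
#' @export
genome_definition <- function(fasta_files = NULL, separator = NULL,
                              definition_file = NULL, contigs = NULL) {
  modes <- !c(is.null(fasta_files), is.null(separator),
              is.null(definition_file))
  if (sum(modes) != 1L) {
    stop("supply exactly one of fasta_files, separator, definition_file")
  }
  if (!is.null(fasta_files)) {
    maps <- lapply(fasta_files, function(f) {
      genome <- sub("\\.(fa|fna|fasta)(\\.gz)?$", "", basename(f),
                    ignore.case = TRUE)
      ## record id = name up to first whitespace
      nm <- sub("\\s.*$", "", names(Biostrings::readDNAStringSet(f)))
      stats::setNames(rep(genome, length(nm)), nm)
    })
    map <- do.call(c, maps)
    genomes <- unique(unname(map))
  } else if (!is.null(separator)) {
    if (nchar(separator) != 1L) stop("separator must be one character")
    if (is.null(contigs)) stop("separator mode requires contig names")
    hit <- regexpr(separator, contigs, fixed = TRUE)
    if (any(hit < 0L)) {
      stop("contig name lacks separator '", separator, "': ",
           contigs[which(hit < 0L)[1L]])
    }
    map <- stats::setNames(substr(contigs, 1L, hit - 1L), contigs)
    genomes <- unique(unname(map))
  } else {
    tab <- utils::read.table(definition_file, sep = "\t", header = FALSE,
                             colClasses = "character", quote = "",
                             comment.char = "")
    if (ncol(tab) < 2L) stop("genome definition file needs two columns")
    map <- stats::setNames(tab[[1L]], tab[[2L]])
    genomes <- unique(tab[[1L]])
  }
  if (anyDuplicated(names(map))) {
    dup <- names(map)[duplicated(names(map))][1L]
    stop("contig claimed by two genomes: ", dup)
  }
  structure(list(contig_to_genome = map, genomes = genomes),
            class = "genome_definition")
}

#' Aggregate per-contig coverage evidence into per-genome inputs
#'
#' Pools the effective-region (end-excluded) depth multisets of each
#' genome's contigs. The genome mean is the effective-length-weighted
#' contig mean, i.e. the mean over all pooled bases; trimmed mean,
#' variance and covered fraction/bases likewise treat all bases of the
#' genome together. Length and count are sums over contigs. Contigs absent
#' from the definition are dropped with a warning.
#'
#' @param contig_stats data.frame with one row per contig: `contig`,
#'   `length`, `count`, and the per-contig effective-region histogram in
#'   list column `hist` with `eff_length`.
#' @param def a [genome_definition()].
#' @return data.frame, one row per genome in definition order: `genome`,
#'   `length`, `eff_length`, `count`, `mean`, `trimmed_mean`, `variance`,
#'   `covered_bases`, `covered_fraction`, plus list column `hist`.
#' @param trim_lower,trim_upper per-tail trim fractions for the pooled
#'   trimmed mean.
#' @export
aggregate_genomes <- function(contig_stats, def,
                              trim_lower = 0.05, trim_upper = 0.05) {
  g <- unname(def$contig_to_genome[contig_stats$contig])
  if (anyNA(g)) {
    orphans <- contig_stats$contig[is.na(g)]
    warning(length(orphans), " contig(s) absent from the genome ",
            "definition were excluded from genome mode (e.g. ",
            orphans[1L], ")")
    contig_stats <- contig_stats[!is.na(g), , drop = FALSE]
    g <- g[!is.na(g)]
  }
  rows <- lapply(def$genomes, function(gn) {
    cs <- contig_stats[g == gn, , drop = FALSE]
    h <- Reduce(add_histograms, cs$hist, integer())
    eff <- sum(vapply(cs$hist, hist_n, numeric(1)))
    data.frame(
      genome = gn,
      length = sum(cs$length),
      eff_length = eff,
      count = sum(cs$count),
      mean = hist_mean(h),
      trimmed_mean = hist_trimmed_mean(h, trim_lower, trim_upper),
      variance = hist_variance(h),
      covered_bases = hist_covered(h),
      covered_fraction = if (eff > 0) hist_covered(h) / eff else 0,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Minimum-covered-fraction presence gate
#'
#' Genomes whose covered fraction (over the effective genome length) falls
#' below the threshold are deemed absent: their coverage-type metrics —
#' mean, trimmed mean, variance, covered bases/fraction — and their read
#' count are zeroed, so their reads drop out of the aligned-read numerator
#' of relative abundance. The comparison is inclusive: exactly at the
#' threshold is retained.
#'
#' @param genome_stats data.frame from [aggregate_genomes()].
#' @param threshold minimum covered fraction in \[0, 1\] (default 0.10).
#' @return `genome_stats` with gated genomes zeroed and a logical
#'   `detected` column.
#' @export
apply_min_covered_fraction <- function(genome_stats, threshold = 0.10) {
  detected <- genome_stats$covered_fraction >= threshold
  zero_cols <- c("count", "mean", "trimmed_mean", "variance",
                 "covered_bases", "covered_fraction")
  genome_stats[!detected, zero_cols] <- 0
  genome_stats$detected <- detected
  genome_stats
}

#' Relative abundance of genomes
#'
#' Each genome's share of total mean coverage, scaled by the fraction of
#' the sequencing library that aligned, as a percentage:
#' `RA_i = mean_i / sum_j(mean_j) * aligned_reads / total_reads * 100`.
#' The unaligned remainder, `100 - sum(RA)`, is the "unmapped" mass. When
#' no genome has coverage all abundances are 0.
#'
#' @param means per-genome mean coverages (post-gate).
#' @param aligned_reads reads aligning to any retained genome.
#' @param total_reads total reads in the sequencing library.
#' @return list with `abundance` (named like `means`, percent) and
#'   `unmapped` (percent).
#' @examples
#' relative_abundance(c(A = 2, B = 6), aligned_reads = 800,
#'                    total_reads = 1000)
#' @export
relative_abundance <- function(means, aligned_reads, total_reads) {
  if (total_reads <= 0) stop("empty library: total_reads must be positive")
  stopifnot(aligned_reads <= total_reads, all(means >= 0))
  s <- sum(means)
  ra <- if (s == 0) rep(0, length(means)) else
    means / s * (aligned_reads / total_reads) * 100
  names(ra) <- names(means)
  list(abundance = ra, unmapped = 100 - sum(ra))
}
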