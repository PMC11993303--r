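## Contig and genome pipelines.
##
## Each BAM is read once; filtered alignments are resolved to covered
## spans, reduced per contig to a delta array, prefix-summed to depth, and
## immediately collapsed to an effective-region depth histogram. Only the
## histograms, lengths and counts survive to metric assembly, so memory
## stays bounded by one contig's depth vector at a time.

.CONTIG_METHODS <- c("mean", "trimmed_mean", "variance", "metabat",
                     "covered_fraction", "covered_bases", "length",
                     "count", "reads_per_base", "rpkm", "tpm")
.GENOME_METHODS <- c("relative_abundance", .CONTIG_METHODS[
  .CONTIG_METHODS != "metabat"])

## identity threshold the MetaBAT coverage tool applies by default
.METABAT_MIN_IDENTITY <- 0.97

## One sample -> per-contig evidence: effective-depth histograms, counts.
.process_sample <- function(aln, cfg, end_exclusion, with_metabat = FALSE) {
  kept <- apply_filters(aln, cfg)
  aln$counts$passing_filters <- nrow(kept)
  refs <- aln$refs

  kept_mb <- NULL
  if (with_metabat) {
    kept_mb <- kept[percent_identity(kept) >= .METABAT_MIN_IDENTITY, ,
                    drop = FALSE]
  }

  contig_hist <- function(records, ct) {
    sub <- records[records$rname == ct, , drop = FALSE]
    if (nrow(sub) == 0L) {
      return(depth_histogram(.effective_depths(
        integer(refs[[ct]]), end_exclusion)))
    }
    sp <- covered_spans(sub)
    arr <- build_mosdepth_array(sp$start, sp$end, refs[[ct]], ct)
    depth_histogram(.effective_depths(depth_vector(arr), end_exclusion))
  }

  cts <- names(refs)
  counts <- table(factor(kept$rname, levels = cts))
  stats <- data.frame(
    contig = cts,
    length = unname(refs),
    count = as.integer(counts),
    stringsAsFactors = FALSE
  )
  stats$hist <- lapply(cts, function(ct) contig_hist(kept, ct))
  if (with_metabat) {
    stats$mb_hist <- lapply(cts, function(ct) contig_hist(kept_mb, ct))
  }
  list(stats = stats, counts = aln$counts, sample = aln$sample)
}

.check_dictionaries <- function(alns) {
  ref0 <- alns[[1L]]$refs
  for (a in alns[-1L]) {
    if (!identical(a$refs, ref0)) {
      stop("mismatched reference dictionaries across BAM files (",
           alns[[1L]]$sample, " vs ", a$sample, ")")
    }
  }
  ref0
}

.sample_names <- function(alns) {
  make.unique(vapply(alns, `[[`, character(1), "sample"))
}

#' Per-contig coverage statistics across samples
#'
#' Streams each BAM once and computes the selected metrics for every contig
#' of the shared reference dictionary, one column block per sample. Contigs
#' with no reads are reported with zeros, not omitted.
#'
#' @param bam_files paths to coordinate-sorted SAM/BAM files, one per
#'   sample.
#' @param methods subset of `mean`, `trimmed_mean`, `variance`, `metabat`,
#'   `covered_fraction`, `covered_bases`, `length`, `count`,
#'   `reads_per_base`, `rpkm`, `tpm`.
#' @param filters a [filter_config()].
#' @param end_exclusion bases ignored at each contig end for depth metrics
#'   (default 75).
#' @param trim_lower,trim_upper per-tail trim fractions for `trimmed_mean`
#'   (default 0.05 each).
#' @param min_covered_fraction presence gate threshold (default 0 in contig
#'   mode).
#' @param total_read_count optional per-sample override of library size
#'   (recycled).
#' @return a `coverage_table`: data.frame with column `Contig` then one
#'   column per sample x metric (`metabat` yields a depth and a variance
#'   column).
#' @export
run_contig_mode <- function(bam_files,
                            methods = "mean",
                            filters = filter_config(),
                            end_exclusion = 75L,
                            trim_lower = 0.05, trim_upper = 0.05,
                            min_covered_fraction = 0,
                            total_read_count = NULL) {
  methods <- match.arg(methods, .CONTIG_METHODS, several.ok = TRUE)
  stopifnot(length(bam_files) >= 1L)
  tot <- if (is.null(total_read_count)) rep(list(NULL), length(bam_files))
         else as.list(rep_len(total_read_count, length(bam_files)))
  alns <- Map(read_alignments, bam_files, tot)
  refs <- .check_dictionaries(alns)
  samples <- .sample_names(alns)
  with_mb <- "metabat" %in% methods

  out <- data.frame(Contig = names(refs), stringsAsFactors = FALSE)
  for (si in seq_along(alns)) {
    ps <- .process_sample(alns[[si]], filters, end_exclusion, with_mb)
    st <- ps$stats
    eff_n <- vapply(st$hist, hist_n, numeric(1))
    covb <- vapply(st$hist, hist_covered, numeric(1))
    covf <- ifelse(eff_n > 0, covb / eff_n, 0)
    detected <- covf >= min_covered_fraction
    count <- ifelse(detected, st$count, 0L)
    passing <- ps$counts$passing_filters
    for (m in methods) {
      cols <- switch(
        m,
        mean = list(mean = ifelse(detected,
          vapply(st$hist, hist_mean, numeric(1)), 0)),
        trimmed_mean = list(trimmed_mean = ifelse(detected,
          vapply(st$hist, hist_trimmed_mean, numeric(1),
                 trim_lower, trim_upper), 0)),
        variance = list(variance = ifelse(detected,
          vapply(st$hist, hist_variance, numeric(1)), 0)),
        metabat = list(
          metabat_depth = ifelse(detected,
            vapply(st$mb_hist, hist_mean, numeric(1)), 0),
          metabat_variance = ifelse(detected,
            vapply(st$mb_hist, hist_variance, numeric(1)), 0)),
        covered_fraction = list(covered_fraction = ifelse(detected, covf, 0)),
        covered_bases = list(covered_bases = ifelse(detected, covb, 0)),
        length = list(length = st$length),
        count = list(count = count),
        reads_per_base = list(reads_per_base =
          reads_per_base(count, st$length)),
        rpkm = list(rpkm = rpkm(count, st$length, passing)),
        tpm = list(tpm = tpm(count, st$length))
      )
      for (cn in names(cols)) {
        out[[paste(samples[si], cn)]] <- unname(cols[[cn]])
      }
    }
  }
  structure(out, class = c("coverage_table", "data.frame"),
            mode = "contig", methods = methods, samples = samples)
}

#' Per-genome coverage statistics and relative abundance
#'
#' Aggregates contig evidence into genomes (all bases of a genome pooled),
#' applies the minimum-covered-fraction presence gate (default: at least
#' 10% of the genome's effective length covered by at least one read), and
#' computes the selected per-genome metrics. With `relative_abundance`
#' (the default) an `unmapped` row is reported first, carrying the
#' percentage of the library aligning to no retained genome.
#'
#' @inheritParams run_contig_mode
#' @param genomes a [genome_definition()], or a single separator character
#'   (resolved against the BAM header contig names).
#' @param methods subset of `relative_abundance`, `mean`, `trimmed_mean`,
#'   `variance`, `covered_fraction`, `covered_bases`, `length`, `count`,
#'   `reads_per_base`, `rpkm`, `tpm`.
#' @param min_covered_fraction presence gate threshold as a fraction
#'   (default 0.10).
#' @return a `coverage_table`: data.frame with column `Genome` then one
#'   column per sample x metric.
#' @export
run_genome_mode <- function(bam_files, genomes,
                            methods = "relative_abundance",
                            filters = filter_config(),
                            end_exclusion = 75L,
                            trim_lower = 0.05, trim_upper = 0.05,
                            min_covered_fraction = 0.10,
                            total_read_count = NULL) {
  methods <- match.arg(methods, .GENOME_METHODS, several.ok = TRUE)
  stopifnot(length(bam_files) >= 1L)
  tot <- if (is.null(total_read_count)) rep(list(NULL), length(bam_files))
         else as.list(rep_len(total_read_count, length(bam_files)))
  alns <- Map(read_alignments, bam_files, tot)
  refs <- .check_dictionaries(alns)
  if (is.character(genomes) && length(genomes) == 1L &&
      !inherits(genomes, "genome_definition")) {
    genomes <- genome_definition(separator = genomes,
                                 contigs = names(refs))
  }
  stopifnot(inherits(genomes, "genome_definition"))
  if (!any(names(refs) %in% names(genomes$contig_to_genome))) {
    stop("no contig of any genome is present in the BAM header")
  }
  samples <- .sample_names(alns)
  with_ra <- "relative_abundance" %in% methods

  rows <- if (with_ra) c("unmapped", genomes$genomes) else genomes$genomes
  out <- data.frame(Genome = rows, stringsAsFactors = FALSE)
  for (si in seq_along(alns)) {
    ps <- .process_sample(alns[[si]], filters, end_exclusion)
    gs <- aggregate_genomes(ps$stats, genomes, trim_lower, trim_upper)
    gs <- apply_min_covered_fraction(gs, min_covered_fraction)
    passing <- ps$counts$passing_filters
    total <- ps$counts$total_reads
    ## an empty library has nothing to apportion: report 100% unmapped
    ## rather than tripping relative_abundance()'s empty-library error
    ra <- if (total == 0L) {
      list(abundance = stats::setNames(rep(0, nrow(gs)), gs$genome),
           unmapped = 100)
    } else {
      relative_abundance(
        stats::setNames(gs$mean, gs$genome),
        aligned_reads = sum(gs$count), total_reads = total
      )
    }
    for (m in methods) {
      col <- switch(
        m,
        relative_abundance = unname(ra$abundance),
        mean = gs$mean,
        trimmed_mean = gs$trimmed_mean,
        variance = gs$variance,
        covered_fraction = gs$covered_fraction,
        covered_bases = gs$covered_bases,
        length = gs$length,
        count = gs$count,
        reads_per_base = reads_per_base(gs$count, gs$length),
        rpkm = rpkm(gs$count, gs$length, passing),
        tpm = tpm(gs$count, gs$length)
      )
      if (with_ra) {
        col <- c(if (m == "relative_abundance") ra$unmapped else 0, col)
      }
      out[[paste(samples[si], m)]] <- col
    }
  }
  structure(out, class = c("coverage_table", "data.frame"),
            mode = "genome", methods = methods, samples = samples)
}

#' Write a coverage table as TSV
#'
#' Tab-separated UTF-8 text, header first; floats with six decimal places,
#' count-like metrics (`length`, `count`, `covered_bases`) as integers.
#' Byte output is deterministic for identical inputs.
#'
#' @param table a `coverage_table` from [run_contig_mode()] or
#'   [run_genome_mode()].
#' @param dest output file path or connection (default standard output).
#' @return `dest`, invisibly.
#' @export
write_coverage_table <- function(table, dest = stdout()) {
  stopifnot(inherits(table, "coverage_table"))
  int_cols <- grepl(" (length|count|covered_bases)$", names(table))
  cells <- lapply(seq_along(table), function(j) {
    x <- table[[j]]
    if (j == 1L) as.character(x)
    else if (int_cols[j]) sprintf("%d", as.integer(x))
    else sprintf("%.6f", x)
  })
  lines <- c(paste(names(table), collapse = "\t"),
             do.call(paste, c(cells, sep = "\t")))
  if (nrow(table) == 0L) lines <- lines[1L]
  writeLines(lines, dest, useBytes = TRUE)
  invisible(dest)
}

#' @export
print.coverage_table <- function(x, ...) {
  cat(sprintf("coverage_table (%s mode): %d references x %d samples\n",
              attr(x, "mode"), nrow(x), length(attr(x, "samples"))))
  print.data.frame(x, ...)
  invisible(x)
}
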