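## Synthetic fixtures with known truth.
##
## Everything here is seed-controlled and regenerable byte-identically.
## The generator computes per-base depth truth by direct pileup while
## emitting reads — an accounting entirely separate from the delta-array
## engine — and the pileup oracle re-derives depth from any SAM/record set
## with a plain increment loop, again with no delta arrays.

#' Write records as a coordinate-sorted SAM file
#'
#' Mapped records are sorted by reference (header order) and position;
#' unmapped records follow. The NM tag is emitted where `nm` is not `NA`.
#'
#' @param records data.frame with `qname`, `flag`, `rname`, `start`
#'   (0-based; ignored for unmapped), `cigar` (`NA` for unmapped) and
#'   optionally `nm`, `seq`.
#' @param refs named integer vector of reference lengths (header order).
#' @param path output path (`.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, refs, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refs), unname(refs)))
  n <- nrow(records)
  if (n > 0L) {
    unmapped <- bitwAnd(records$flag, 0x4L) != 0L
    ord <- order(unmapped,
                 match(records$rname, names(refs)),
                 records$start)
    records <- records[ord, , drop = FALSE]
    unmapped <- unmapped[ord]
    nm <- if (is.null(records$nm)) rep(NA_integer_, n) else records$nm
    seq <- if (is.null(records$seq)) rep("*", n) else records$seq
    body <- sprintf(
      "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*%s",
      records$qname, records$flag,
      ifelse(unmapped, "*", records$rname),
      ifelse(unmapped, 0L, records$start + 1L),
      ifelse(unmapped, 0L, 60L),
      ifelse(unmapped, "*", records$cigar),
      seq,
      ifelse(is.na(nm) | unmapped, "", sprintf("\tNM:i:%d", nm))
    )
  } else {
    body <- character()
  }
  writeLines(c(hdr, body), path, useBytes = TRUE)
  invisible(path)
}

## random valid CIGAR with reference span in [1, max_span]; query length
## bounded by read_length; op mix includes S, I, D and (optionally) N
.random_cigar <- function(max_span, read_length = 150L,
                          with_skips = TRUE) {
  shape <- sample(c("simple", "clipped", "indel", "skip"), 1L,
                  prob = c(0.45, 0.2, 0.2, if (with_skips) 0.15 else 0))
  m <- sample.int(min(max_span, read_length), 1L)
  switch(shape,
    simple = sprintf("%dM", m),
    clipped = {
      s1 <- sample.int(20L, 1L)
      s2 <- sample.int(20L, 1L)
      sprintf("%dS%dM%dS", s1, m, s2)
    },
    indel = {
      m1 <- m %/% 2L
      m2 <- m - m1
      if (m1 < 1L || m2 < 1L) return(sprintf("%dM", m))
      if (stats::runif(1) < 0.5) {
        i <- sample.int(10L, 1L)
        sprintf("%dM%dI%dM", m1, i, m2)
      } else {
        d <- sample.int(min(10L, max(1L, max_span - m1 - m2)), 1L)
        if (m1 + d + m2 > max_span) sprintf("%dM", m)
        else sprintf("%dM%dD%dM", m1, d, m2)
      }
    },
    skip = {
      m1 <- m %/% 2L
      m2 <- m - m1
      if (m1 < 1L || m2 < 1L) return(sprintf("%dM", m))
      nmax <- max_span - m1 - m2
      if (nmax < 1L) sprintf("%dM", m)
      else sprintf("%dM%dN%dM", m1, sample.int(min(200L, nmax), 1L), m2)
    })
}

#' Random alignment set for property testing
#'
#' Draws contigs and mapped records with randomised CIGARs (M, I, D, N, S
#' operations) under the caller's RNG state. Reads always fit within their
#' contig.
#'
#' @param max_contigs,max_length,max_reads upper bounds on the number of
#'   contigs, contig length (bp) and record count.
#' @param with_skips include N operations.
#' @return list with `refs` (named lengths) and `records` (data.frame as
#'   accepted by [covered_spans()] and [write_sam()]).
#' @export
random_alignments <- function(max_contigs = 3L, max_length = 10000L,
                              max_reads = 500L, with_skips = TRUE) {
  nc <- sample.int(max_contigs, 1L)
  refs <- stats::setNames(
    as.integer(sample(200:max_length, nc, replace = TRUE)),
    sprintf("c%d", seq_len(nc)))
  n <- sample.int(max_reads + 1L, 1L) - 1L
  if (n == 0L) {
    rec <- data.frame(qname = character(), flag = integer(),
                      rname = character(), start = integer(),
                      cigar = character(), nm = integer(),
                      read_length = integer(), stringsAsFactors = FALSE)
  } else {
    rname <- sample(names(refs), n, replace = TRUE)
    start <- integer(n)
    cigar <- character(n)
    for (i in seq_len(n)) {
      len <- refs[[rname[i]]]
      start[i] <- sample.int(len, 1L) - 1L
      cigar[i] <- .random_cigar(len - start[i], with_skips = with_skips)
    }
    rec <- data.frame(
      qname = sprintf("r%05d", seq_len(n)), flag = 0L,
      rname = rname, start = start, cigar = cigar,
      nm = 0L, stringsAsFactors = FALSE)
    rec$read_length <- cigar_query_length(cigar)
  }
  list(refs = refs, records = rec)
}

#' Generate a synthetic reference + alignment fixture with depth truth
#'
#' Emits a FASTA of random contigs, a coordinate-sorted SAM, and a JSON
#' truth sidecar holding exact per-base depth arrays (computed by direct
#' pileup during generation) and read counts. Read counts per contig are
#' Poisson(`depth * length / read_length`); read starts are uniform;
#' per-read edit distances are Binomial(`read_length`, `error_rate`).
#' Unmapped records are appended so that the expected unmapped fraction of
#' the library is `fraction_unmapped`.
#'
#' @param dir output directory (created if needed).
#' @param contigs data.frame with `name` and `length`; default two 10 kb
#'   contigs `g1~c1`, `g2~c1` (separator-convention genome names).
#' @param depth target mean depth; a single value or a named vector keyed
#'   by genome (requires `genome_map`).
#' @param genome_map named character vector contig -> genome; default
#'   derived from the `~` separator in contig names.
#' @param read_length read length in bp (default 150).
#' @param error_rate per-base error rate feeding NM (default 0.01).
#' @param fraction_unmapped expected fraction of the library left
#'   unmapped (default 0.2).
#' @param reads optional explicit data.frame of reads (`rname`, `start`,
#'   `cigar`, optionally `nm`, `flag`, `qname`) overriding the generative
#'   model.
#' @param prefix file-name prefix (default `"fixture"`).
#' @return invisibly, a list: `fasta`, `sam`, `truth_json` (paths) and
#'   `truth` (list with `depths` per contig, `contig_read_counts`,
#'   `aligned_reads`, `unmapped_reads`, `total_reads`).
#' @export
simulate_fixture <- function(dir,
                             contigs = data.frame(
                               name = c("g1~c1", "g2~c1"),
                               length = c(10000L, 10000L),
                               stringsAsFactors = FALSE),
                             depth = 5,
                             genome_map = NULL,
                             read_length = 150L,
                             error_rate = 0.01,
                             fraction_unmapped = 0.2,
                             reads = NULL,
                             prefix = "fixture") {
  stopifnot(fraction_unmapped >= 0, fraction_unmapped < 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  refs <- stats::setNames(as.integer(contigs$length), contigs$name)
  if (is.null(genome_map)) {
    genome_map <- stats::setNames(sub("~.*$", "", contigs$name),
                                  contigs$name)
  }

  if (is.null(reads)) {
    per <- lapply(contigs$name, function(ct) {
      len <- refs[[ct]]
      d <- if (length(depth) == 1L && is.null(names(depth))) depth
           else depth[[genome_map[[ct]]]]
      if (len < read_length) return(NULL)
      n <- stats::rpois(1L, d * len / read_length)
      if (n == 0L) return(NULL)
      data.frame(
        rname = ct,
        start = sample.int(len - read_length + 1L, n, replace = TRUE) - 1L,
        cigar = sprintf("%dM", read_length),
        nm = stats::rbinom(n, read_length, error_rate),
        stringsAsFactors = FALSE)
    })
    reads <- do.call(rbind, per)
    if (is.null(reads)) {
      reads <- data.frame(rname = character(), start = integer(),
                          cigar = character(), nm = integer(),
                          stringsAsFactors = FALSE)
    }
  }
  n_aligned <- nrow(reads)
  if (is.null(reads$flag)) reads$flag <- rep(0L, n_aligned)
  if (is.null(reads$qname)) {
    reads$qname <- sprintf("read%06d", seq_len(n_aligned))
  }
  if (is.null(reads$nm)) reads$nm <- rep(0L, n_aligned)

  ## truth by direct pileup, walking each CIGAR with its own cursor
  depths <- lapply(refs, function(len) integer(len))
  counts <- stats::setNames(integer(length(refs)), names(refs))
  if (n_aligned > 0L) {
    for (i in seq_len(n_aligned)) {
      ct <- reads$rname[i]
      counts[[ct]] <- counts[[ct]] + 1L
      pos <- reads$start[i]
      for (tok in regmatches(reads$cigar[i],
             gregexpr("\\d+[MIDNSHP=X]", reads$cigar[i]))[[1L]]) {
        op <- substr(tok, nchar(tok), nchar(tok))
        len <- as.integer(substr(tok, 1L, nchar(tok) - 1L))
        if (op %in% c("M", "=", "X", "D")) {
          if (pos + len > refs[[ct]]) {
            stop("generated read exceeds contig bounds on ", ct)
          }
          depths[[ct]][(pos + 1L):(pos + len)] <-
            depths[[ct]][(pos + 1L):(pos + len)] + 1L
          pos <- pos + len
        } else if (op == "N") {
          pos <- pos + len
        }
      }
    }
  }

  n_unmapped <- if (fraction_unmapped > 0 && n_aligned > 0L) {
    as.integer(round(n_aligned * fraction_unmapped / (1 - fraction_unmapped)))
  } else 0L
  if (n_unmapped > 0L) {
    unm <- data.frame(
      rname = NA_character_, start = 0L, cigar = NA_character_,
      nm = NA_integer_, flag = 4L,
      qname = sprintf("unmapped%06d", seq_len(n_unmapped)),
      stringsAsFactors = FALSE)
    unm$seq <- vapply(seq_len(n_unmapped), function(i)
      paste(sample(c("A", "C", "G", "T"), read_length, replace = TRUE),
            collapse = ""), character(1))
    reads$seq <- "*"
    reads <- rbind(reads[names(unm)], unm)
  }

  fasta <- file.path(dir, paste0(prefix, ".fasta"))
  seqs <- Biostrings::DNAStringSet(vapply(refs, function(len)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1)))
  names(seqs) <- names(refs)
  Biostrings::writeXStringSet(seqs, fasta)

  sam <- file.path(dir, paste0(prefix, ".sam"))
  write_sam(reads, refs, sam)

  truth <- list(
    depths = depths,
    contig_read_counts = as.list(counts),
    aligned_reads = n_aligned,
    unmapped_reads = n_unmapped,
    total_reads = n_aligned + n_unmapped
  )
  truth_json <- file.path(dir, paste0(prefix, "_truth.json"))
  jsonlite::write_json(truth, truth_json, auto_unbox = TRUE, digits = NA)
  invisible(list(fasta = fasta, sam = sam, truth_json = truth_json,
                 truth = truth))
}

#' Brute-force pileup oracle
#'
#' Re-derives per-contig per-base depth with a direct increment loop over
#' every filtered alignment's reference footprint — no delta arrays, no
#' prefix sums. This is the independent check for the Mosdepth engine.
#'
#' @param x path to a SAM/BAM file, a `sample_alignments` object, or a
#'   list with `refs` and `records` (as from [random_alignments()]).
#' @param filters a [filter_config()] applied before counting.
#' @return named list of integer depth vectors, one per reference.
#' @export
pileup_oracle <- function(x, filters = filter_config()) {
  if (is.character(x)) x <- read_alignments(x)
  refs <- x$refs
  kept <- apply_filters(x$records, filters)
  depths <- lapply(refs, function(len) integer(len))
  for (i in seq_len(nrow(kept))) {
    ct <- kept$rname[i]
    pos <- kept$start[i]
    toks <- regmatches(kept$cigar[i],
                       gregexpr("\\d+[MIDNSHP=X]", kept$cigar[i]))[[1L]]
    for (tok in toks) {
      op <- substr(tok, nchar(tok), nchar(tok))
      len <- as.integer(substr(tok, 1L, nchar(tok) - 1L))
      if (op %in% c("M", "=", "X", "D")) {
        depths[[ct]][(pos + 1L):(pos + len)] <-
          depths[[ct]][(pos + 1L):(pos + len)] + 1L
        pos <- pos + len
      } else if (op == "N") {
        pos <- pos + len
      }
    }
  }
  depths
}
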