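#' Read a coordinate-sorted SAM/BAM file into an alignment table
#'
#' Parses every record of a SAM (text) or BAM file into a normalised table,
#' validates that mapped records are coordinate-sorted (grouped by reference,
#' non-decreasing position within each reference, no reference revisited),
#' and tallies per-sample read counts. SAM input is converted in place via
#' [Rsamtools::asBam()] (no re-sorting), BAM is read directly with
#' [Rsamtools::scanBam()].
#'
#' Positions are converted to 0-based half-open coordinates at parse time.
#' "Total reads" counts primary records only (neither secondary 0x100 nor
#' supplementary 0x800), mapped or not, so it can serve as the library-size
#' denominator for relative abundance; an externally known library size can
#' be supplied for BAMs whose unmapped reads were dropped.
#'
#' @param path path to a `.sam` or `.bam` file with `@SQ` header lines.
#' @param total_read_count optional integer overriding the library size
#'   (total primary reads) counted from the file.
#' @return an object of class `sample_alignments`: a list with
#'   \describe{
#'     \item{records}{data.frame, one row per record, file order: `qname`,
#'       `flag`, `rname`, `start` (0-based), `cigar`, `nm` (NA when the NM
#'       tag is absent), `read_length`, and flag-derived logicals `is_paired`,
#'       `is_proper_pair`, `is_unmapped`, `is_secondary`, `is_supplementary`,
#'       `is_first_in_pair`.}
#'     \item{refs}{named integer vector: reference lengths in header order.}
#'     \item{counts}{list with `total_records`, `total_reads`,
#'       `mapped_primary`, `passing_filters` (NA until filters are applied).}
#'     \item{sample}{sample name (file stem).}
#'   }
#' @examples
#' sam <- tempfile(fileext = ".sam")
#' writeLines(c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:c1\tLN:1000",
#'   "r1\t0\tc1\t11\t60\t100M\t*\t0\t0\t*\t*\tNM:i:2"), sam)
#' aln <- read_alignments(sam)
#' aln$counts$total_reads
#' @export
read_alignments <- function(path, total_read_count = NULL) {
  bam <- .as_bam_path(path)
  refs <- reference_dictionary(bam)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "qwidth", "seq"),
    tag = "NM"
  )
  b <- Rsamtools::scanBam(bam, param = param)[[1L]]

  flag <- b$flag
  is_unmapped <- bitwAnd(flag, 0x4L) != 0L
  rec <- data.frame(
    qname = b$qname,
    flag = flag,
    rname = as.character(b$rname),
    start = b$pos - 1L,
    cigar = b$cigar,
    nm = if (is.null(b$tag$NM)) rep(NA_integer_, length(flag)) else
      as.integer(b$tag$NM),
    stringsAsFactors = FALSE
  )
  rec$is_paired <- bitwAnd(flag, 0x1L) != 0L
  rec$is_proper_pair <- bitwAnd(flag, 0x2L) != 0L
  rec$is_unmapped <- is_unmapped
  rec$is_secondary <- bitwAnd(flag, 0x100L) != 0L
  rec$is_supplementary <- bitwAnd(flag, 0x800L) != 0L
  rec$is_first_in_pair <- bitwAnd(flag, 0x40L) != 0L

  ## read length including soft clips: CIGAR-derived where mapped,
  ## sequence length otherwise
  rl <- b$qwidth
  noq <- is.na(rl)
  if (any(noq)) rl[noq] <- Biostrings::width(b$seq)[noq]
  rec$read_length <- as.integer(rl)

  .check_sorted(rec)
  .check_mapped_records(rec, refs)

  primary <- !rec$is_secondary & !rec$is_supplementary
  counts <- list(
    total_records = nrow(rec),
    total_reads = sum(primary),
    mapped_primary = sum(primary & !rec$is_unmapped),
    passing_filters = NA_integer_
  )
  if (!is.null(total_read_count)) {
    counts$total_reads <- as.integer(total_read_count)
  }

  structure(
    list(records = rec, refs = refs, counts = counts,
         sample = .sample_name(path)),
    class = "sample_alignments"
  )
}

#' Reference dictionary of a SAM/BAM header
#'
#' @param path path to a SAM or BAM file.
#' @return named integer vector of reference lengths, preserving `@SQ`
#'   header order.
#' @export
reference_dictionary <- function(path) {
  bam <- .as_bam_path(path)
  targets <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  if (is.null(targets) || length(targets) == 0L) {
    stop("no @SQ reference lines in header of ", path)
  }
  if (any(targets <= 0L)) {
    stop("non-positive reference length in header of ", path, ": ",
         names(targets)[which(targets <= 0L)[1L]])
  }
  storage.mode(targets) <- "integer"
  targets
}

.as_bam_path <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "bam") return(path)
  if (ext != "sam") stop("expected a .sam or .bam file: ", path)
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(path, dest, indexDestination = FALSE, overwrite = TRUE)
}

.sample_name <- function(path) {
  sub("\\.(sam|bam)$", "", basename(path), ignore.case = TRUE)
}

## Coordinate-sort validation: mapped records grouped by reference with
## non-decreasing positions; a reference must not reappear once left.
.check_sorted <- function(rec) {
  m <- which(!rec$is_unmapped)
  if (length(m) < 2L) return(invisible(TRUE))
  rn <- rec$rname[m]
  runs <- rle(rn)
  if (anyDuplicated(runs$values)) {
    dup <- runs$values[duplicated(runs$values)][1L]
    second <- m[cumsum(runs$lengths)[which(runs$values == dup)[2L] - 1L] + 1L]
    stop("unsorted BAM: reference ", dup, " reappears at record ",
         rec$qname[second], " after records for another reference")
  }
  pos <- rec$start[m]
  same <- rn[-1L] == rn[-length(rn)]
  dec <- same & pos[-1L] < pos[-length(pos)]
  if (any(dec)) {
    i <- m[which(dec)[1L] + 1L]
    stop("unsorted BAM: record ", rec$qname[i], " on ", rec$rname[i],
         " at position ", rec$start[i], " is out of coordinate order")
  }
  invisible(TRUE)
}

.check_mapped_records <- function(rec, refs) {
  m <- !rec$is_unmapped
  if (!any(m)) return(invisible(TRUE))
  if (anyNA(rec$cigar[m]) || any(rec$cigar[m] == "*")) {
    stop("mapped record without a CIGAR: ",
         rec$qname[m][which(is.na(rec$cigar[m]) | rec$cigar[m] == "*")[1L]])
  }
  if (any(rec$start[m] < 0L)) {
    stop("mapped record with invalid position: ",
         rec$qname[m][which(rec$start[m] < 0L)[1L]])
  }
  span <- cigar_reference_span(rec$cigar[m])
  if (any(span <= 0L)) {
    stop("mapped record with empty reference span: ",
         rec$qname[m][which(span <= 0L)[1L]])
  }
  ends <- rec$start[m] + span
  lim <- unname(refs[rec$rname[m]])
  if (anyNA(lim)) {
    stop("mapped record on reference absent from header: ",
         rec$rname[m][which(is.na(lim))[1L]])
  }
  if (any(ends > lim)) {
    i <- which(ends > lim)[1L]
    stop("malformed alignment: record ", rec$qname[m][i],
         " extends past the end of ", rec$rname[m][i])
  }
  invisible(TRUE)
}
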