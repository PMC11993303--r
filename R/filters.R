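#' Alignment filter configuration
#'
#' Thresholds deciding which mapped primary alignments contribute to
#' coverage. All comparisons are inclusive (`>=`). With `pair_mode =
#' "together"` a read pair contributes only if both mates pass; unpaired
#' reads (and orphans whose mate is never seen) are judged alone in both
#' modes.
#'
#' @param min_percent_identity minimum per-alignment identity as a fraction
#'   in \[0, 1\], or `NULL` to disable. Identity is `1 - NM /
#'   aligned_length`, with insertions counting as potential errors.
#' @param min_aligned_length minimum aligned length in bp, or `NULL`.
#' @param min_aligned_percent minimum `aligned_length / read_length` as a
#'   fraction in \[0, 1\], or `NULL`.
#' @param proper_pairs_only require the proper-pair SAM flag.
#' @param pair_mode `"independent"` (each record judged alone) or
#'   `"together"` (mates judged jointly).
#' @param exclude_supplementary drop supplementary (0x800) records; default
#'   `TRUE`. Secondary (0x100) records are always dropped.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(min_percent_identity = NULL,
                          min_aligned_length = NULL,
                          min_aligned_percent = NULL,
                          proper_pairs_only = FALSE,
                          pair_mode = c("independent", "together"),
                          exclude_supplementary = TRUE) {
  pair_mode <- match.arg(pair_mode)
  for (f in list(min_percent_identity, min_aligned_percent)) {
    if (!is.null(f) && (f < 0 || f > 1)) {
      stop("fractional thresholds must lie in [0, 1]")
    }
  }
  structure(
    list(min_percent_identity = min_percent_identity,
         min_aligned_length = min_aligned_length,
         min_aligned_percent = min_aligned_percent,
         proper_pairs_only = isTRUE(proper_pairs_only),
         pair_mode = pair_mode,
         exclude_supplementary = isTRUE(exclude_supplementary)),
    class = "filter_config"
  )
}

#' Aligned length of mapped records
#'
#' Bases of the read participating in the alignment: M, `=`, X columns plus
#' inserted bases (I). Clips, deletions and reference skips are excluded.
#'
#' @param records data.frame of mapped records with a `cigar` column (as in
#'   [read_alignments()]), or a character vector of CIGAR strings.
#' @return integer vector of aligned lengths in bp.
#' @examples
#' aligned_length(c("100M", "10S80M10S", "50M2I48M"))
#' @export
aligned_length <- function(records) {
  cig <- if (is.character(records)) records else records$cigar
  .cigar_opsum(cig, c("M", "=", "X", "I"))
}

#' Percent identity of mapped records
#'
#' `1 - NM / aligned_length`, the conventional gap-inclusive per-alignment
#' identity: the NM edit distance counts mismatches and indel bases, the
#' denominator is the aligned length (M/`=`/X + I).
#'
#' @param records data.frame of mapped records with `cigar` and `nm`
#'   columns.
#' @return numeric vector of identities in \[0, 1\].
#' @export
percent_identity <- function(records) {
  if (anyNA(records$nm)) {
    stop("NM tag absent for record ",
         records$qname[which(is.na(records$nm))[1L]],
         "; an identity filter requires NM")
  }
  1 - records$nm / aligned_length(records)
}

#' Per-record filter decision
#'
#' Judges each mapped primary record alone against the active thresholds
#' (pair mode is handled by [apply_filters()]).
#'
#' @param records data.frame of mapped records.
#' @param cfg a [filter_config()].
#' @return logical vector, `TRUE` where every active threshold is met.
#' @export
passes_filters <- function(records, cfg) {
  ok <- rep(TRUE, nrow(records))
  if (nrow(records) == 0L) return(ok)
  records <- .flag_columns(records)
  al <- NULL
  if (!is.null(cfg$min_percent_identity)) {
    ok <- ok & percent_identity(records) >= cfg$min_percent_identity
  }
  if (!is.null(cfg$min_aligned_length)) {
    al <- aligned_length(records)
    ok <- ok & al >= cfg$min_aligned_length
  }
  if (!is.null(cfg$min_aligned_percent)) {
    if (is.null(al)) al <- aligned_length(records)
    ok <- ok & al / records$read_length >= cfg$min_aligned_percent
  }
  if (cfg$proper_pairs_only) ok <- ok & records$is_proper_pair
  ok
}

#' Apply alignment filters to a record table
#'
#' Restricts to mapped primary records (dropping secondary and, by default,
#' supplementary records), then applies the thresholds in `cfg`. In
#' `"together"` pair mode mates are matched by query name and
#' first/second-in-pair flag over the whole table; a pair is kept only if
#' both mates pass, while orphans (mate unmapped, filtered out upstream, or
#' absent) are judged alone and counted in the `n_orphans` attribute.
#'
#' @param records data.frame of records from [read_alignments()], or a
#'   `sample_alignments` object.
#' @param cfg a [filter_config()].
#' @return the kept subset of `records`, with attribute `n_orphans`.
#' @export
apply_filters <- function(records, cfg) {
  if (inherits(records, "sample_alignments")) records <- records$records
  records <- .flag_columns(records)
  keep <- !records$is_unmapped & !records$is_secondary
  if (cfg$exclude_supplementary) keep <- keep & !records$is_supplementary
  cand <- records[keep, , drop = FALSE]
  ok <- passes_filters(cand, cfg)
  n_orphans <- 0L

  if (cfg$pair_mode == "together" && nrow(cand) > 0L) {
    paired <- cand$is_paired
    key <- paste0(cand$qname, "/", ifelse(cand$is_first_in_pair, 1L, 2L))
    mate_key <- paste0(cand$qname, "/", ifelse(cand$is_first_in_pair, 2L, 1L))
    mate_idx <- match(mate_key, key)
    has_mate <- paired & !is.na(mate_idx)
    ok[has_mate] <- ok[has_mate] & ok[mate_idx[has_mate]]
    n_orphans <- sum(paired & !has_mate)
    if (n_orphans > 0L) {
      warning(n_orphans,
              " paired record(s) had no mapped mate; judged alone")
    }
  }
  out <- cand[ok, , drop = FALSE]
  attr(out, "n_orphans") <- n_orphans
  out
}

## derive any missing flag-based logical columns from the flag field
.flag_columns <- function(records) {
  bits <- c(is_paired = 0x1L, is_proper_pair = 0x2L, is_unmapped = 0x4L,
            is_first_in_pair = 0x40L, is_secondary = 0x100L,
            is_supplementary = 0x800L)
  for (col in names(bits)) {
    if (is.null(records[[col]])) {
      records[[col]] <- bitwAnd(records$flag, bits[[col]]) != 0L
    }
  }
  records
}
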