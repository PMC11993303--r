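## Mosdepth delta arrays.
##
## A delta array for a contig of length L has L+1 integer slots: +1 at each
## covered-segment start, -1 at each segment end (half-open). The prefix sum
## at base p is the number of segments covering p. The extra slot means a
## segment ending at the contig end needs no special casing.

#' Reference intervals covered by alignments
#'
#' Resolves each record's CIGAR into half-open 0-based reference intervals.
#' One interval per maximal run of reference positions covered by M/`=`/X or
#' D operations; reference skips (N) split intervals; clips and insertions
#' consume no reference. Deletions count as covered: a deleted base is still
#' spanned by the mapped segment.
#'
#' @param records data.frame of mapped records with `rname`, `start`,
#'   `cigar` columns.
#' @return data.frame with columns `idx` (row of `records`), `rname`,
#'   `start`, `end` (half-open, 0-based).
#' @examples
#' r <- data.frame(rname = "c1", start = 10L,
#'                 cigar = c("50M", "20M100N20M"))
#' covered_spans(r)
#' @export
covered_spans <- function(records) {
  n <- nrow(records)
  if (n == 0L) {
    return(data.frame(idx = integer(), rname = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  has_n <- grepl("N", records$cigar, fixed = TRUE)

  out <- vector("list", 2L)
  if (any(!has_n)) {
    ## no skip: a single interval spanning the full reference footprint
    i <- which(!has_n)
    span <- cigar_reference_span(records$cigar[i])
    out[[1L]] <- data.frame(
      idx = i, rname = records$rname[i],
      start = records$start[i], end = records$start[i] + span,
      stringsAsFactors = FALSE
    )
  }
  if (any(has_n)) {
    i <- which(has_n)
    tab <- parse_cigar(records$cigar[i])
    pieces <- lapply(seq_along(i), function(k) {
      ops <- tab[tab$idx == k, , drop = FALSE]
      pos <- records$start[i[k]]
      starts <- integer()
      ends <- integer()
      open <- NA_integer_
      for (j in seq_len(nrow(ops))) {
        op <- ops$op[j]
        len <- ops$len[j]
        if (op %in% c("M", "=", "X", "D")) {
          if (is.na(open)) open <- pos
          pos <- pos + len
        } else if (op == "N") {
          if (!is.na(open) && pos > open) {
            starts <- c(starts, open)
            ends <- c(ends, pos)
          }
          open <- NA_integer_
          pos <- pos + len
        }
        ## I, S, H, P consume no reference
      }
      if (!is.na(open) && pos > open) {
        starts <- c(starts, open)
        ends <- c(ends, pos)
      }
      data.frame(idx = rep.int(i[k], length(starts)),
                 rname = rep.int(records$rname[i[k]], length(starts)),
                 start = starts, end = ends, stringsAsFactors = FALSE)
    })
    out[[2L]] <- do.call(rbind, pieces)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  res <- res[order(res$idx), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build a Mosdepth delta array from covered spans
#'
#' For each half-open span `(s, e)`, `deltas[s] += 1` and `deltas[e] -= 1`
#' (0-based slots 0..length).
#'
#' @param starts,ends integer vectors of half-open 0-based span bounds on
#'   one contig.
#' @param length contig length in bp.
#' @param contig_name contig name carried on the result.
#' @return object of class `mosdepth_array`: list with `contig_name`,
#'   `length` and integer `deltas` of size `length + 1`.
#' @examples
#' a <- build_mosdepth_array(c(2L, 3L), c(5L, 7L), 10L)
#' depth_vector(a)
#' @export
build_mosdepth_array <- function(starts, ends, length, contig_name = "") {
  stopifnot(length(starts) == length(ends))
  if (any(starts < 0L) || any(ends > length) || any(ends < starts)) {
    stop("malformed alignment: span outside contig [0, ", length, ")")
  }
  deltas <- tabulate(starts + 1L, nbins = length + 1L) -
    tabulate(ends + 1L, nbins = length + 1L)
  structure(
    list(contig_name = contig_name, length = as.integer(length),
         deltas = as.integer(deltas)),
    class = "mosdepth_array"
  )
}

#' Per-base depth from a Mosdepth delta array
#'
#' Prefix-sums the delta array, truncated to the contig length.
#'
#' @param array a `mosdepth_array` from [build_mosdepth_array()].
#' @return integer vector of length `array$length`; `depths[p]` is the
#'   number of covering segments at 0-based position `p - 1`.
#' @export
depth_vector <- function(array) {
  stopifnot(inherits(array, "mosdepth_array"))
  d <- cumsum(array$deltas)[seq_len(array$length)]
  if (length(d) && min(d) < 0L) {
    stop("internal consistency error: negative running depth on ",
         array$contig_name)
  }
  as.integer(d)
}
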