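## CIGAR arithmetic.
##
## All helpers here are vectorised over character vectors of CIGAR strings;
## per-op tables are produced once and reduced with rowsum(). Op classes
## follow the SAM specification:
##   query-consuming:     M I S = X
##   reference-consuming: M D N = X
##   aligned columns:     M = X (plus I for the identity denominator)

.CIGAR_OPS <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")

#' Parse CIGAR strings into a per-operation table
#'
#' @param cigar character vector of CIGAR strings (`"*"` or `NA` not allowed).
#' @return data.frame with columns `idx` (index into `cigar`), `op`
#'   (single-character operation) and `len` (integer length), in operation
#'   order within each record.
#' @keywords internal
parse_cigar <- function(cigar) {
  if (any(is.na(cigar) | cigar == "*" | cigar == "")) {
    stop("missing or '*' CIGAR where an explicit CIGAR is required")
  }
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar, perl = TRUE)
  tok <- regmatches(cigar, m)
  ntok_chars <- vapply(tok, function(x) sum(nchar(x)), integer(1))
  bad <- ntok_chars != nchar(cigar)
  if (any(bad)) {
    stop("invalid CIGAR string: ", cigar[which(bad)[1L]])
  }
  idx <- rep.int(seq_along(cigar), lengths(tok))
  tok <- unlist(tok, use.names = FALSE)
  nc <- nchar(tok)
  data.frame(
    idx = idx,
    op = substr(tok, nc, nc),
    len = as.integer(substr(tok, 1L, nc - 1L)),
    stringsAsFactors = FALSE
  )
}

## Sum of op lengths restricted to `ops`, returned aligned with `cigar`.
.cigar_opsum <- function(cigar, ops) {
  tab <- parse_cigar(cigar)
  out <- integer(length(cigar))
  sel <- tab$op %in% ops
  if (any(sel)) {
    s <- rowsum(tab$len[sel], tab$idx[sel])
    out[as.integer(rownames(s))] <- as.integer(s[, 1L])
  }
  out
}

#' Reference span of an alignment from its CIGAR
#'
#' Number of reference positions consumed (M, D, N, `=`, X).
#' @param cigar character vector of CIGAR strings.
#' @return integer vector of reference spans in bp.
#' @keywords internal
cigar_reference_span <- function(cigar) {
  .cigar_opsum(cigar, c("M", "D", "N", "=", "X"))
}

#' Query length from a CIGAR, including soft clips
#'
#' Hard-clipped bases are absent from the stored sequence and are not
#' counted.
#' @param cigar character vector of CIGAR strings.
#' @return integer vector of read lengths in bp.
#' @keywords internal
cigar_query_length <- function(cigar) {
  .cigar_opsum(cigar, c("M", "I", "S", "=", "X"))
}
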