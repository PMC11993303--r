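# In-code SAM fixtures. All tests build their inputs here; nothing is
# stored on disk.

# Write a SAM file from raw record lines (tab-joined fields).
make_sam <- function(records = character(),
                     refs = c(c1 = 1000L, c2 = 500L),
                     path = tempfile(fileext = ".sam")) {
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", names(refs), unname(refs)),
               records),
             path, useBytes = TRUE)
  path
}

# One SAM record line. pos is 1-based (as in the file format).
sam_line <- function(qname, flag, rname, pos, cigar, nm = NA,
                     seq = "*", mapq = 60) {
  line <- paste(qname, flag, rname, pos, mapq, cigar, "*", 0, 0, seq, "*",
                sep = "\t")
  if (!is.na(nm)) line <- paste0(line, "\tNM:i:", nm)
  line
}

# Minimal mapped-record table for unit tests that bypass file parsing.
rec_table <- function(rname, start, cigar, nm = 0L, flag = 0L,
                      qname = NULL) {
  n <- max(length(rname), length(start), length(cigar))
  d <- data.frame(
    qname = if (is.null(qname)) sprintf("r%03d", seq_len(n)) else qname,
    flag = rep_len(flag, n),
    rname = rep_len(rname, n),
    start = rep_len(as.integer(start), n),
    cigar = rep_len(cigar, n),
    nm = rep_len(as.integer(nm), n),
    stringsAsFactors = FALSE
  )
  d$read_length <- covstats:::cigar_query_length(d$cigar)
  d
}

# Independent sort-and-slice trimmed mean (test oracle).
oracle_trimmed_mean <- function(depths, trim_lower, trim_upper) {
  n <- length(depths)
  if (n == 0L) return(0)
  s <- sort(depths)
  lo <- floor(trim_lower * n)
  hi <- floor(trim_upper * n)
  kept <- s[seq.int(lo + 1L, n - hi)]
  if (length(kept) == 0L) 0 else mean(kept)
}

# Naive per-base pileup from half-open spans (test oracle).
oracle_pileup <- function(starts, ends, len) {
  d <- integer(len)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) {
      d[(starts[i] + 1L):ends[i]] <- d[(starts[i] + 1L):ends[i]] + 1L
    }
  }
  d
}
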