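# Full-length non-chimeric (FLnc) read classification: a read is FLnc iff
# the 5' primer, the 3' primer and a poly(A) tail are all found in one
# consistent orientation; reads with internal primer hits are chimeric and
# therefore non-full-length.

#' Classify one long read as FLnc or nFL
#'
#' Searches both orientations of the read. A primer "hit" is an approximate
#' match (edit distance <= `max_edits`, indels allowed) inside a terminal
#' window; the poly(A) tail is a run of at least `min_polya` A's immediately
#' 5' of the 3'-primer hit, tolerating at most one non-A per 10 nt of run.
#' The insert (primers and tail removed) is reported in transcript
#' orientation.
#'
#' @param seq Read sequence (character scalar).
#' @param primer5,primer3 Primer sequences as they appear in the cDNA
#'   (the read carries `primer5` at its 5' end and the reverse complement of
#'   `primer3` at its 3' end).
#' @param min_polya Minimum poly(A) run length.
#' @param max_edits Maximum edit distance for a primer hit.
#' @param window Terminal search window in nt.
#' @return List: `category` (`"FLnc"`/`"nFL"`), `strand` (`"+"` if the read
#'   is already in transcript orientation, `"-"` if its reverse complement
#'   is), `insert`, `polya_len`, `found` (named logical for primer5, primer3,
#'   polya) and `chimeric`.
#' @export
classify_read <- function(seq, primer5, primer3, min_polya = 20L,
                          max_edits = 3L, window = 100L) {
  stopifnot(nzchar(primer5), nzchar(primer3), min_polya >= 1L)
  seq <- toupper(seq)
  best <- NULL
  for (orient in c("+", "-")) {
    s <- if (orient == "+") seq else revcomp(seq)
    r <- classify_oriented(s, primer5, primer3, min_polya, max_edits, window)
    r$strand <- orient
    if (is.null(best) || sum(r$found) > sum(best$found) ||
        (sum(r$found) == sum(best$found) && r$chimeric < best$chimeric))
      best <- r
  }
  best$category <- if (all(best$found) && !best$chimeric) "FLnc" else "nFL"
  if (best$category == "nFL") {
    best$insert <- ""
  }
  best[c("category", "strand", "insert", "polya_len", "found", "chimeric")]
}

classify_oriented <- function(s, primer5, primer3, min_polya, max_edits,
                              window) {
  n <- nchar(s)
  p3rc <- revcomp(primer3)
  w5 <- min(n, window + nchar(primer5))
  w3 <- max(1L, n - window - nchar(primer3) + 1L)

  hit5 <- approx_hits(primer5, substr(s, 1L, w5), max_edits)
  end5 <- if (length(hit5)) min(IRanges::end(hit5)) else NA_integer_

  tail_region <- substr(s, w3, n)
  hit3 <- approx_hits(p3rc, tail_region, max_edits)
  start3 <- if (length(hit3)) w3 - 1L + max(IRanges::start(hit3)) else
    NA_integer_

  # chimera check: additional primer occurrences outside the terminal windows
  chim <- FALSE
  if (n > 2L * (window + nchar(primer5))) {
    interior <- substr(s, w5 + 1L, w3 - 1L)
    if (nchar(interior) >= min(nchar(primer5), nchar(primer3))) {
      chim <- length(approx_hits(primer5, interior, max_edits)) > 0L ||
        length(approx_hits(p3rc, interior, max_edits)) > 0L
    }
  }

  # poly(A): scan backwards from just before the 3'-primer hit (or from the
  # read end when the 3' primer is absent)
  scan_from <- if (!is.na(start3)) start3 - 1L else n
  pa <- polya_run(s, scan_from, min_polya)

  insert <- ""
  if (!is.na(end5) && pa$len >= min_polya && pa$start > end5 + 1L)
    insert <- substr(s, end5 + 1L, pa$start - 1L)
  list(found = c(primer5 = !is.na(end5),
                 primer3 = !is.na(start3),
                 polya = pa$len >= min_polya),
       insert = insert, polya_len = pa$len, chimeric = chim)
}

approx_hits <- function(pattern, subject, max_edits) {
  if (nchar(subject) < 1L) return(IRanges::IRanges())
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(subject),
                                max.mismatch = max_edits, with.indels = TRUE)
  methods::as(m, "IRanges")
}

# Greedy backwards scan for a poly(A) run ending at position `from`
# (1-based, inclusive), tolerating one non-A per 10 nt of run length, then
# trimming 5'-terminal non-A bases.
polya_run <- function(s, from, min_polya) {
  if (from < 1L) return(list(len = 0L, start = NA_integer_))
  chars <- strsplit(substr(s, 1L, from), NULL)[[1]]
  len <- 0L; nonA <- 0L
  i <- from
  while (i >= 1L) {
    if (chars[i] == "A") {
      len <- len + 1L
    } else if (nonA + 1L <= (len + 1L) %/% 10L) {
      nonA <- nonA + 1L; len <- len + 1L
    } else break
    i <- i - 1L
  }
  start <- from - len + 1L
  while (len > 0L && chars[start] != "A") {
    start <- start + 1L; len <- len - 1L
  }
  if (len == 0L) start <- NA_integer_
  list(len = len, start = start)
}

#' Classify a set of reads
#'
#' Vectorised wrapper around [classify_read()].
#'
#' @param reads Named character vector of read sequences.
#' @inheritParams classify_read
#' @return List with `report` (data frame: read, category, strand,
#'   polya_len, found_primer5, found_primer3, found_polya, chimeric,
#'   insert_length) and `inserts` (named character vector for FLnc reads,
#'   transcript orientation).
#' @export
classify_reads <- function(reads, primer5, primer3, min_polya = 20L,
                           max_edits = 3L, window = 100L) {
  res <- lapply(reads, classify_read, primer5 = primer5, primer3 = primer3,
                min_polya = min_polya, max_edits = max_edits, window = window)
  report <- data.frame(
    read = names(reads),
    category = vapply(res, `[[`, "", "category"),
    strand = vapply(res, `[[`, "", "strand"),
    polya_len = vapply(res, function(r) as.integer(r$polya_len), 0L),
    found_primer5 = vapply(res, function(r) r$found[["primer5"]], TRUE),
    found_primer3 = vapply(res, function(r) r$found[["primer3"]], TRUE),
    found_polya = vapply(res, function(r) r$found[["polya"]], TRUE),
    chimeric = vapply(res, function(r) isTRUE(r$chimeric), TRUE),
    insert_length = vapply(res, function(r) nchar(r$insert), 0L),
    stringsAsFactors = FALSE, row.names = NULL)
  flnc <- report$category == "FLnc"
  inserts <- vapply(res[flnc], `[[`, "", "insert")
  names(inserts) <- report$read[flnc]
  list(report = report, inserts = inserts)
}
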