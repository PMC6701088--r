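# ORF detection on oriented transcript sequences, representative selection,
# Markov-chain coding scores and non-coding RNA candidate flagging.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find open reading frames in a transcript sequence
#'
#' Scans the three forward frames (full-length reads are oriented). An ORF
#' runs from an ATG to the next in-frame stop codon (the stop is required);
#' within a frame, overlapping ORFs sharing a stop are resolved to the
#' 5'-most ATG. Only ORFs of at least `min_aa` amino acids are retained.
#'
#' @param seq Transcript DNA in sense orientation.
#' @param min_aa Minimum ORF length in amino acids (stop codon excluded).
#' @param both_strands Also scan the reverse complement (for unoriented
#'   input); reported coordinates then refer to the scanned strand's
#'   sequence with `strand = "-"`.
#' @return Data frame sorted by transcript start: frame (0/1/2), start, end
#'   (0-based half-open on the transcript; start at the A of ATG, end one
#'   past the stop codon), aa_length, strand.
#' @export
find_orfs <- function(seq, min_aa = 100L, both_strands = FALSE) {
  seq <- toupper(seq)
  scan1 <- function(s, strand) {
    n <- nchar(s)
    rows <- list()
    for (frame in 0:2) {
      n_cod <- (n - frame) %/% 3L
      if (n_cod < 2L) next
      cods <- substring(s, frame + 1L + 3L * (0:(n_cod - 1L)),
                        frame + 3L + 3L * (0:(n_cod - 1L)))
      start_i <- NA_integer_
      for (k in seq_len(n_cod)) {
        if (is.na(start_i) && cods[k] == "ATG") start_i <- k
        if (!is.na(start_i) && cods[k] %in% STOP_CODONS) {
          aa <- k - start_i
          if (aa >= min_aa) {
            rows[[length(rows) + 1L]] <- data.frame(
              frame = frame,
              start = frame + 3L * (start_i - 1L),
              end = frame + 3L * k,
              aa_length = aa, strand = strand)
          }
          start_i <- NA_integer_
        }
      }
    }
    rows
  }
  rows <- scan1(seq, "+")
  if (both_strands) rows <- c(rows, scan1(revcomp(seq), "-"))
  if (length(rows) == 0L)
    return(data.frame(frame = integer(0), start = integer(0),
                      end = integer(0), aa_length = integer(0),
                      strand = character(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, -out$aa_length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Representative ORF of a transcript
#'
#' The first (5'-most) ORF; ties on start position resolve to the longest.
#'
#' @param orfs Data frame from [find_orfs()] (non-empty).
#' @return Single-row data frame.
#' @export
representative_orf <- function(orfs) {
  if (nrow(orfs) == 0L) stop("no ORFs to choose a representative from")
  orfs <- orfs[order(orfs$start, -orfs$aa_length), , drop = FALSE]
  orfs[1L, , drop = FALSE]
}

#' Locus representative isoform
#'
#' The isoform whose longest ORF is maximal; ties resolve to the
#' lexicographically smaller isoform id.
#'
#' @param orfs_by_isoform Named list of [find_orfs()] results, one per
#'   isoform; at least one must be non-empty.
#' @return The chosen isoform id.
#' @export
locus_representative <- function(orfs_by_isoform) {
  longest <- vapply(orfs_by_isoform, function(o)
    if (nrow(o) == 0L) -Inf else max(o$aa_length), numeric(1))
  if (all(!is.finite(longest)))
    stop("no coding isoform in locus")
  ids <- names(orfs_by_isoform)
  ids[order(-longest, ids)][1L]
}

#' Train a k-th order nucleotide Markov model
#'
#' Counts all m-mers for m = 1..order+1 with add-one smoothing at scoring
#' time. The first `order` positions of a scored sequence condition on the
#' shorter available context.
#'
#' @param seqs Character vector of training sequences.
#' @param order Markov order (default 5).
#' @return List of class `markov_model`.
#' @export
train_markov <- function(seqs, order = 5L) {
  seqs <- toupper(seqs)
  tabs <- vector("list", order + 1L)
  for (m in seq_len(order + 1L)) {
    kmers <- unlist(lapply(seqs, function(s) {
      n <- nchar(s)
      if (n < m) return(character(0))
      substring(s, 1:(n - m + 1L), m:n)
    }))
    tabs[[m]] <- table(kmers)
  }
  structure(list(order = order, tabs = tabs), class = "markov_model")
}

markov_count <- function(model, kmer) {
  tab <- model$tabs[[nchar(kmer)]]
  v <- tab[kmer]
  if (is.na(v)) 0 else as.numeric(v)
}

#' Per-position log likelihood of a sequence under a Markov model
#'
#' @param seq DNA string.
#' @param model A `markov_model` from [train_markov()].
#' @return Numeric vector of per-position natural-log probabilities
#'   (add-one smoothed); their sum is the sequence log likelihood.
#' @export
markov_loglik <- function(seq, model) {
  seq <- toupper(seq)
  n <- nchar(seq)
  vapply(seq_len(n), function(i) {
    k <- min(i - 1L, model$order)
    ctx <- substr(seq, i - k, i - 1L)
    num <- markov_count(model, paste0(ctx, substr(seq, i, i))) + 1
    # denominator: observed continuations of this context, +4 smoothing
    den <- if (k == 0L) sum(model$tabs[[1L]]) + 4
           else sum(vapply(c("A", "C", "G", "T"), function(b)
             markov_count(model, paste0(ctx, b)), numeric(1))) + 4
    log(num / den)
  }, numeric(1))
}

#' Coding log-likelihood-ratio score of an ORF
#'
#' `log P(orf | coding) - log P(orf | background)`, base e, using
#' add-one-smoothed k-th order Markov chains.
#'
#' @param seq Transcript sequence containing the ORF.
#' @param orf Single-row data frame from [find_orfs()].
#' @param coding_model,background_model `markov_model`s from
#'   [train_markov()].
#' @return Log-likelihood ratio (positive supports coding).
#' @export
markov_score <- function(seq, orf, coding_model, background_model) {
  if (coding_model$order != background_model$order)
    stop("models must share the same order")
  orf_seq <- substr(seq, orf$start + 1L, orf$end)
  if (nchar(orf_seq) < coding_model$order + 1L)
    stop("ORF shorter than model order + 1")
  sum(markov_loglik(orf_seq, coding_model)) -
    sum(markov_loglik(orf_seq, background_model))
}

#' Flag non-coding RNA candidates per locus
#'
#' A locus with any retained ORF is `coding`; otherwise it is a
#' `lncRNA-candidate` if its longest isoform exceeds 200 nt and a
#' `short-ncRNA-candidate` if not.
#'
#' @param locus_lengths Named numeric vector: longest isoform length (nt)
#'   per locus.
#' @param has_orf Named logical vector: does the locus have any isoform with
#'   a retained ORF (same names).
#' @return Data frame: locus, length, category.
#' @export
flag_ncrna <- function(locus_lengths, has_orf) {
  stopifnot(setequal(names(locus_lengths), names(has_orf)))
  has_orf <- has_orf[names(locus_lengths)]
  category <- ifelse(has_orf, "coding",
                     ifelse(locus_lengths > 200, "lncRNA-candidate",
                            "short-ncRNA-candidate"))
  data.frame(locus = names(locus_lengths),
             length = as.numeric(locus_lengths),
             category = unname(category), row.names = NULL,
             stringsAsFactors = FALSE)
}
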