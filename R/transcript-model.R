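#' @keywords internal
"_PACKAGE"

# Internal coordinate convention: 0-based half-open genomic intervals
# everywhere. GTF (1-based closed) and SJ tables (1-based inclusive intron
# bounds) are converted at the I/O boundary only. An intron is keyed by
# (donor, acceptor) = (end of upstream exon, start of downstream exon) in
# genomic orientation regardless of strand; biological donor/acceptor roles
# are resolved by strand at use sites.

#' Construct a transcript model
#'
#' A transcript model is a strand-aware exon chain on one contig: the atom of
#' isoform collapse, alternative-splicing detection and ORF analysis.
#'
#' @param id Transcript identifier.
#' @param contig Contig (chromosome) name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column numeric matrix of exon `(start, end)` intervals,
#'   0-based half-open, sorted in genomic order.
#' @param gene Gene/locus identifier carried through GTF output
#'   (defaults to `id`).
#' @param source Provenance tag, e.g. `"annotated"` or `"collapsed"`.
#' @param coverage,identity Optional aligner-reported query coverage and
#'   identity in `[0, 1]`; `NA` means not available (treated as 1 downstream).
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(id, contig, strand, exons, gene = id,
                             source = "annotated",
                             coverage = NA_real_, identity = NA_real_) {
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-' for transcript ", id)
  if (nrow(exons) == 0L) stop("transcript ", id, " has no exons")
  if (any(exons[, 1] >= exons[, 2]))
    stop("exon with start >= end in transcript ", id)
  if (nrow(exons) > 1L) {
    o <- order(exons[, 1])
    exons <- exons[o, , drop = FALSE]
    gaps <- exons[-1L, 1] - exons[-nrow(exons), 2]
    if (any(gaps < 1))
      stop("overlapping or adjacent exons in transcript ", id)
  }
  structure(
    list(id = id, contig = contig, strand = strand, exons = exons,
         gene = gene, source = source, coverage = coverage,
         identity = identity),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s  %s:%d-%d(%s)  %d exon(s), %d nt\n",
              x$id, x$contig, tx_span(x)[1], tx_span(x)[2], x$strand,
              nrow(x$exons), tx_length(x)))
  invisible(x)
}

#' Intron chain of a transcript model
#'
#' @param model A [transcript_model()].
#' @return Two-column matrix of `(donor, acceptor)` intron coordinates in
#'   genomic orientation (0-based; donor = first intron base, acceptor = one
#'   past the last intron base). Zero rows for single-exon models.
#' @export
tx_introns <- function(model) {
  ex <- model$exons
  n <- nrow(ex)
  if (n < 2L)
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("donor", "acceptor"))))
  cbind(donor = ex[-n, 2], acceptor = ex[-1L, 1])
}

#' @rdname tx_introns
#' @export
tx_span <- function(model)
  unname(c(model$exons[1L, 1], model$exons[nrow(model$exons), 2]))

#' @rdname tx_introns
#' @export
tx_length <- function(model) sum(model$exons[, 2] - model$exons[, 1])

# Genomic coordinate of the strand-aware 3' end (half-open end on +,
# start on -). Used for collapse 3'-tolerance and APA.
tx_end3 <- function(model) {
  unname(if (model$strand == "+") model$exons[nrow(model$exons), 2]
         else model$exons[1L, 1])
}

tx_start5 <- function(model) {
  unname(if (model$strand == "+") model$exons[1L, 1]
         else model$exons[nrow(model$exons), 2])
}

# Identity key of an intron chain ("" for single-exon models).
intron_chain_key <- function(model) {
  ic <- tx_introns(model)
  if (nrow(ic) == 0L) return("")
  paste(ic[, 1], ic[, 2], sep = "-", collapse = ";")
}

junction_key <- function(contig, donor, acceptor, strand) {
  if (length(contig) == 0L) return(character(0))
  paste0(contig, ":", donor, "-", acceptor, ":", strand)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

# Safe contig lookup on a named character vector or list.
get_contig <- function(genome, name) {
  if (!name %in% names(genome)) stop("unknown contig: ", name)
  genome[[name]]
}

#' Spliced transcript sequence from a genome
#'
#' Extracts and concatenates the exon sequence of a model, reverse
#' complementing for minus-strand transcripts, so the result is in transcript
#' (sense) orientation.
#'
#' @param genome Named character vector of contig sequences (see
#'   [make_genome()]).
#' @param model A [transcript_model()].
#' @return A single DNA string.
#' @export
spliced_seq <- function(genome, model) {
  contig <- get_contig(genome, model$contig)
  if (tx_span(model)[2] > nchar(contig))
    stop("transcript ", model$id, " extends beyond contig ", model$contig)
  pieces <- substring(contig, model$exons[, 1] + 1, model$exons[, 2])
  s <- paste(pieces, collapse = "")
  if (model$strand == "-") revcomp(s) else s
}

# Map a transcript-orientation position (0-based) to a genomic position.
tx_to_genome <- function(model, tpos) {
  w <- model$exons[, 2] - model$exons[, 1]
  if (model$strand == "-") w <- rev(w)
  off <- cumsum(c(0, w))
  j <- findInterval(tpos, off, rightmost.closed = FALSE)
  within <- tpos - off[j]
  if (model$strand == "+") {
    model$exons[j, 1] + within
  } else {
    k <- nrow(model$exons) + 1L - j
    model$exons[k, 2] - 1 - within
  }
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# In-place substring write on a contig string (0-based half-open target).
write_at <- function(seq, start0, value) {
  substr(seq, start0 + 1, start0 + nchar(value)) <- value
  seq
}
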