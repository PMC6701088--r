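# Readers/writers for FASTA, GTF, BED12, SAM spliced alignments and
# STAR-style SJ tables. All readers convert to the package's 0-based
# half-open convention; GTF is the only 1-based surface.

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read transcript models from a GTF file
#'
#' Exon features are grouped by `transcript_id`, converted from 1-based
#' closed to 0-based half-open coordinates and validated (sorted,
#' non-overlapping exons).
#'
#' @param path Path to a GTF file whose exon features carry `transcript_id`
#'   (and optionally `gene_id`) attributes.
#' @return Named list of [transcript_model()] objects.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) return(list())
  tid <- as.character(gr$transcript_id)
  if (anyNA(tid)) stop("exon feature without transcript_id in ", path)
  gid <- if (!is.null(gr$gene_id)) as.character(gr$gene_id) else tid
  starts <- GenomicRanges::start(gr) - 1L
  ends <- GenomicRanges::end(gr)
  contig <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  idx <- split(seq_along(gr), tid)
  models <- lapply(names(idx), function(t) {
    i <- idx[[t]]
    ex <- cbind(starts[i], ends[i])
    ex <- ex[order(ex[, 1]), , drop = FALSE]
    if (nrow(ex) > 1L && any(ex[-1L, 1] < ex[-nrow(ex), 2]))
      stop("overlapping exons within transcript ", t, " in ", path)
    transcript_model(t, contig[i[1L]], strand[i[1L]], ex,
                     gene = gid[i[1L]], source = "annotated")
  })
  names(models) <- names(idx)
  models
}

#' Write transcript models to GTF
#'
#' Emits one exon feature per exon with `gene_id` and `transcript_id`
#' attributes, converting back to 1-based closed coordinates.
#' `read_gtf(write_gtf(x))` is the identity on valid models.
#'
#' @param models List of [transcript_model()] objects.
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @export
write_gtf <- function(models, path, source = "isoatlas") {
  lines <- unlist(lapply(models, function(m) {
    sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
            m$contig, source, m$exons[, 1] + 1L, m$exons[, 2], m$strand,
            m$gene, m$id)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Write transcript models to BED12
#'
#' @param models List of [transcript_model()] objects.
#' @param path Output path.
#' @param scores Optional numeric vector of scores (recycled; default 0).
#' @export
write_bed12 <- function(models, path, scores = 0) {
  scores <- rep_len(scores, length(models))
  lines <- vapply(seq_along(models), function(i) {
    m <- models[[i]]
    sp <- tx_span(m)
    sizes <- m$exons[, 2] - m$exons[, 1]
    rel <- m$exons[, 1] - sp[1]
    sprintf("%s\t%d\t%d\t%s\t%g\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            m$contig, sp[1], sp[2], m$id, scores[i], m$strand, sp[1], sp[2],
            nrow(m$exons),
            paste0(paste(sizes, collapse = ","), ","),
            paste0(paste(rel, collapse = ","), ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read spliced alignments from SAM or BED12
#'
#' SAM records are converted via their CIGAR strings: `N` operations become
#' introns, `M`/`I`/`D` shape the exon blocks, soft clips are discarded and
#' unmapped records are skipped (their count is attached as the
#' `"skipped_unmapped"` attribute). BED12 blocks are taken as exons directly.
#'
#' @param path Path to a `.sam` or `.bed` file.
#' @param format `"auto"` (by extension), `"sam"` or `"bed"`.
#' @return Named list of [transcript_model()] objects (source `"aligned"`),
#'   with attribute `skipped_unmapped`.
#' @export
read_alignments <- function(path, format = c("auto", "sam", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("sam", "bam")) "sam" else "bed"
  }
  if (format == "sam") read_alignments_sam(path) else read_alignments_bed(path)
}

read_alignments_sam <- function(path) {
  bam <- path
  if (tolower(tools::file_ext(path)) != "bam") {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = TRUE)
  }
  gal <- GenomicAlignments::readGAlignments(bam, use.names = TRUE)
  cig <- GenomicAlignments::cigar(gal)
  ops <- GenomicAlignments::cigarOpTable(cig)
  bad <- colnames(ops)[!colnames(ops) %in% c("M", "I", "D", "N", "S")]
  bad <- bad[colSums(ops[, bad, drop = FALSE]) > 0]
  if (length(bad))
    stop("unsupported CIGAR operation(s): ", paste(bad, collapse = ", "))
  n_unmapped <- Rsamtools::countBam(
    bam, param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE)))$records
  blocks <- GenomicAlignments::grglist(gal)  # splits on N, keeps D merged
  contigs <- as.character(GenomicAlignments::seqnames(gal))
  strands <- as.character(GenomicAlignments::strand(gal))
  ids <- names(gal)
  if (is.null(ids)) ids <- paste0("aln", seq_along(gal))
  ids <- make.unique(ids)
  models <- lapply(seq_along(gal), function(i) {
    b <- blocks[[i]]
    ex <- cbind(GenomicRanges::start(b) - 1L, GenomicRanges::end(b))
    ex <- ex[order(ex[, 1]), , drop = FALSE]
    st <- strands[i]
    if (st == "*") st <- "+"
    transcript_model(ids[i], contigs[i], st, ex, source = "aligned")
  })
  names(models) <- ids
  attr(models, "skipped_unmapped") <- n_unmapped
  models
}

read_alignments_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  blocks <- rtracklayer::blocks(gr)
  ids <- gr$name
  if (is.null(ids)) ids <- paste0("aln", seq_along(gr))
  ids <- make.unique(as.character(ids))
  contigs <- as.character(GenomicRanges::seqnames(gr))
  strands <- as.character(GenomicRanges::strand(gr))
  models <- lapply(seq_along(gr), function(i) {
    b <- blocks[[i]]
    ex <- cbind(GenomicRanges::start(b) - 1L, GenomicRanges::end(b))
    ex <- ex[order(ex[, 1]), , drop = FALSE]
    st <- strands[i]
    if (st == "*") st <- "+"
    transcript_model(ids[i], contigs[i], st, ex, source = "aligned")
  })
  names(models) <- ids
  attr(models, "skipped_unmapped") <- 0L
  models
}

#' Read a STAR-style splice-junction table
#'
#' Nine tab-separated columns: contig, intron first base (1-based), intron
#' last base (1-based), strand code (0 undetermined / 1 `+` / 2 `-`), motif
#' code, annotated flag, unique-read count, multi-read count, max overhang.
#' Only the unique-read count (column 7) is used as support; coordinates are
#' converted to the internal 0-based `(donor, acceptor)` convention.
#'
#' @param path Path to an SJ table.
#' @return Data frame with columns `contig`, `donor`, `acceptor`, `strand`
#'   (`"+"`, `"-"` or `"*"` for undetermined) and `support`.
#' @export
read_sj_tab <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(contig = character(0), donor = numeric(0),
                      acceptor = numeric(0), strand = character(0),
                      support = numeric(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop("malformed SJ row at line ", which(nf != 9L)[1L], " in ", path)
  m <- do.call(rbind, fields)
  first <- suppressWarnings(as.numeric(m[, 2]))
  last <- suppressWarnings(as.numeric(m[, 3]))
  code <- suppressWarnings(as.integer(m[, 4]))
  support <- suppressWarnings(as.numeric(m[, 7]))
  bad <- which(is.na(first) | is.na(last) | is.na(code) | is.na(support) |
                 !code %in% 0:2)
  if (length(bad)) stop("malformed SJ row at line ", bad[1L], " in ", path)
  if (any(first > last))
    stop("inverted intron coordinates at line ", which(first > last)[1L],
         " in ", path)
  data.frame(contig = m[, 1],
             donor = first - 1,
             acceptor = last,
             strand = c("*", "+", "-")[code + 1L],
             support = support,
             stringsAsFactors = FALSE)
}

#' Write a splice-junction table in SJ-tab dialect
#'
#' @param sj Data frame as returned by [read_sj_tab()], optionally with
#'   `motif_code`, `annotated`, `multi` and `overhang` columns.
#' @param path Output path.
#' @export
write_sj_tab <- function(sj, path) {
  code <- match(sj$strand, c("*", "+", "-")) - 1L
  motif <- if ("motif_code" %in% names(sj)) sj$motif_code else 0L
  ann <- if ("annotated" %in% names(sj)) sj$annotated else 1L
  multi <- if ("multi" %in% names(sj)) sj$multi else 0L
  over <- if ("overhang" %in% names(sj)) sj$overhang else 50L
  lines <- sprintf("%s\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%d",
                   sj$contig, as.integer(sj$donor + 1), as.integer(sj$acceptor),
                   code, as.integer(rep_len(motif, nrow(sj))),
                   as.integer(rep_len(ann, nrow(sj))),
                   as.integer(sj$support),
                   as.integer(rep_len(multi, nrow(sj))),
                   as.integer(rep_len(over, nrow(sj))))
  writeLines(lines, path)
  invisible(path)
}
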