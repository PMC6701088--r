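# Splice-junction extraction, motif classification, short-read validation
# and removal of isoforms carrying presumptive false junctions.

#' Classify a 4-letter splice motif
#'
#' @param motif Character vector of 4-letter motifs (first two + last two
#'   intron bases, transcript orientation).
#' @return `"GT-AG"`, `"GC-AG"`, `"AT-AC"` or `"other"`.
#' @export
classify_motif <- function(motif) {
  out <- rep("other", length(motif))
  out[motif == "GTAG"] <- "GT-AG"
  out[motif == "GCAG"] <- "GC-AG"
  out[motif == "ATAC"] <- "AT-AC"
  out
}

#' Extract splice junctions from transcript models
#'
#' One junction per distinct `(contig, donor, acceptor, strand)`. The motif
#' is read from the genome and reverse complemented for minus-strand
#' junctions so it is always reported in transcript orientation.
#'
#' @param models List of [transcript_model()]s (or an `isoform_clusters`
#'   object, in which case representatives are used).
#' @param genome Named character vector of contig sequences.
#' @return Data frame: contig, donor, acceptor, strand, motif, motif_class,
#'   sr_support (initialised to 0).
#' @export
extract_junctions <- function(models, genome) {
  if (inherits(models, "isoform_clusters"))
    models <- lapply(models, `[[`, "model")
  rows <- lapply(models, function(m) {
    ic <- tx_introns(m)
    if (nrow(ic) == 0L) return(NULL)
    data.frame(contig = m$contig, donor = ic[, 1], acceptor = ic[, 2],
               strand = m$strand, stringsAsFactors = FALSE)
  })
  jx <- unique(do.call(rbind, rows))
  if (is.null(jx) || nrow(jx) == 0L)
    return(data.frame(contig = character(0), donor = numeric(0),
                      acceptor = numeric(0), strand = character(0),
                      motif = character(0), motif_class = character(0),
                      sr_support = numeric(0)))
  jx <- jx[order(jx$contig, jx$donor, jx$acceptor, jx$strand), , drop = FALSE]
  rownames(jx) <- NULL
  motif <- character(nrow(jx))
  for (i in seq_len(nrow(jx))) {
    contig <- get_contig(genome, jx$contig[i])
    if (jx$acceptor[i] > nchar(contig) || jx$donor[i] < 0)
      stop("junction beyond contig bounds: ", jx$contig[i], ":",
           jx$donor[i], "-", jx$acceptor[i])
    don2 <- substr(contig, jx$donor[i] + 1, jx$donor[i] + 2)
    acc2 <- substr(contig, jx$acceptor[i] - 1, jx$acceptor[i])
    motif[i] <- if (jx$strand[i] == "+") paste0(don2, acc2)
                else revcomp(paste0(don2, acc2))
  }
  jx$motif <- motif
  jx$motif_class <- classify_motif(motif)
  jx$sr_support <- 0
  jx
}

#' Attach short-read support to junctions
#'
#' Support is the sum of unique-read counts over all supplied SJ tables for
#' rows matching the junction coordinates; rows with undetermined strand
#' match either strand.
#'
#' @param junctions Data frame from [extract_junctions()].
#' @param sj A data frame from [read_sj_tab()] or a list of them
#'   (one per sample).
#' @return `junctions` with `sr_support` filled in.
#' @export
attach_support <- function(junctions, sj) {
  if (is.data.frame(sj)) sj <- list(sj)
  all_sj <- do.call(rbind, sj)
  if (is.null(all_sj) || nrow(all_sj) == 0L) return(junctions)
  support <- numeric(nrow(junctions))
  coord <- paste(junctions$contig, junctions$donor, junctions$acceptor)
  sj_coord <- paste(all_sj$contig, all_sj$donor, all_sj$acceptor)
  for (i in seq_len(nrow(junctions))) {
    hit <- sj_coord == coord[i] &
      (all_sj$strand == junctions$strand[i] | all_sj$strand == "*")
    support[i] <- sum(all_sj$support[hit])
  }
  junctions$sr_support <- support
  junctions
}

#' Remove isoforms containing presumptive false splice junctions
#'
#' A junction is presumed false iff its motif class is not canonical GT-AG
#' *and* its short-read support is below `min_support`; canonical junctions
#' are never removed for lack of support (they may simply be expressed in
#' tissues not sampled by the short reads). An isoform is removed iff it
#' contains at least one false junction.
#'
#' @param clusters An `isoform_clusters` object.
#' @param junctions Data frame from [attach_support()] covering every
#'   junction used by the clusters.
#' @param min_support Minimum unique-read support for a non-canonical
#'   junction to be kept.
#' @return List with `kept` and `removed` (`isoform_clusters`) and `report`
#'   (data frame per motif class: total, supported, removed junction counts).
#' @export
filter_isoforms <- function(clusters, junctions, min_support = 1L) {
  jkey <- junction_key(junctions$contig, junctions$donor,
                       junctions$acceptor, junctions$strand)
  false_j <- junctions$motif_class != "GT-AG" &
    junctions$sr_support < min_support
  names(false_j) <- jkey
  removed <- vapply(clusters, function(cl) {
    ic <- tx_introns(cl$model)
    if (nrow(ic) == 0L) return(FALSE)
    keys <- junction_key(cl$model$contig, ic[, 1], ic[, 2], cl$model$strand)
    if (!all(keys %in% jkey))
      stop("cluster ", cl$id, " uses junction(s) absent from the junction set")
    any(false_j[keys])
  }, logical(1))
  report <- do.call(rbind, lapply(
    c("GT-AG", "GC-AG", "AT-AC", "other"), function(cls) {
      sel <- junctions$motif_class == cls
      data.frame(motif_class = cls, total = sum(sel),
                 supported = sum(sel & junctions$sr_support >= min_support),
                 removed = sum(sel & false_j))
    }))
  kept <- clusters[!removed]
  dropped <- clusters[removed]
  class(kept) <- class(dropped) <- "isoform_clusters"
  list(kept = kept, removed = dropped, report = report)
}
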