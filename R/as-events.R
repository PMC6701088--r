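# Detection and classification of alternative-splicing events among the
# isoforms of one locus, into the five major types: intron retention (IR),
# exon skipping (ES), alternative acceptor (AA), alternative donor (AD) and
# mutually exclusive exons (MX). Events are detected pairwise and
# deduplicated by (type, variant coordinates); structures matching none of
# the five predicates are left uncounted (complex events). Transcript 5'/3'
# end differences never create events.

# Structural predicates (all coordinates genomic, strand resolved at type
# assignment):
#  IR - one isoform has intron (d,a) strictly contained in an exon of the
#       other; the retaining isoform is the inclusion form.
#  ES - one isoform has an exon (s,e) flanked by introns (d,s) and (e,a)
#       while the other has the single intron (d,a).
#  AA/AD - two introns share one boundary and differ at the other; the
#       differing segment must be fully exonic in the shorter-intron
#       isoform. A shared genomic-left boundary means a shared donor on '+'
#       (so the event is AA) and a shared acceptor on '-' (AD), and vice
#       versa for a shared genomic-right boundary.
#  MX - isoform one has internal exon X only, the other internal exon Y
#       only, X and Y disjoint, flanked by shared outer introns from d to a.

#' Detect alternative-splicing events within one locus
#'
#' @param locus A locus from [assign_loci()] (or any list with `id`,
#'   `contig`, `strand` and either `clusters` or `isoforms`, the latter a
#'   list of [transcript_model()]s sharing contig and strand).
#' @return Data frame of events: event, type, locus, contig, strand,
#'   variant (comma-joined variant coordinates), flank_left, flank_right,
#'   inclusion_junctions, exclusion_junctions (semicolon-joined keys),
#'   ir_intron (key for intron-body coverage, IR only), witnesses.
#' @export
detect_events <- function(locus) {
  isoforms <- if (!is.null(locus$isoforms)) locus$isoforms
              else lapply(locus$clusters, `[[`, "model")
  strands <- unique(vapply(isoforms, `[[`, "", "strand"))
  if (length(strands) > 1L)
    stop("mixed-strand locus: ", locus$id)
  if (length(isoforms) < 2L) return(empty_events())
  contig <- isoforms[[1L]]$contig
  strand <- strands
  found <- list()
  n <- length(isoforms)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      evs <- pair_events(isoforms[[i]], isoforms[[j]], contig, strand)
      found <- c(found, evs)
    }
  }
  if (length(found) == 0L) return(empty_events())
  keys <- vapply(found, function(e) paste(e$type, e$key), character(1))
  first <- !duplicated(keys)
  wit <- split(vapply(found, `[[`, "", "witnesses"), keys)
  found <- found[first]
  ord <- order(vapply(found, function(e) min(e$variant), numeric(1)),
               vapply(found, `[[`, "", "type"))
  found <- found[ord]
  out <- do.call(rbind, lapply(seq_along(found), function(k) {
    e <- found[[k]]
    data.frame(
      event = sprintf("%s.e%d", if (is.null(locus$id)) "locus" else locus$id,
                      k),
      type = e$type,
      locus = if (is.null(locus$id)) NA_character_ else locus$id,
      contig = contig, strand = strand,
      variant = paste(e$variant, collapse = ","),
      flank_left = e$flank[1], flank_right = e$flank[2],
      inclusion_junctions = e$inc, exclusion_junctions = e$exc,
      ir_intron = e$ir,
      witnesses = paste(unique(unlist(wit[[paste(e$type, e$key)]])),
                        collapse = ";"),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

empty_events <- function() {
  data.frame(event = character(0), type = character(0), locus = character(0),
             contig = character(0), strand = character(0),
             variant = character(0), flank_left = numeric(0),
             flank_right = numeric(0), inclusion_junctions = character(0),
             exclusion_junctions = character(0), ir_intron = character(0),
             witnesses = character(0))
}

pair_events <- function(A, B, contig, strand) {
  exA <- A$exons; exB <- B$exons
  inA <- tx_introns(A); inB <- tx_introns(B)
  jk <- function(d, a) junction_key(contig, d, a, strand)
  wit <- paste(A$id, B$id, sep = ",")
  out <- list()
  add <- function(type, variant, flank, inc, exc, ir = "") {
    out[[length(out) + 1L]] <<- list(
      type = type, variant = variant, key = paste(variant, collapse = ","),
      flank = flank, inc = inc, exc = exc, ir = ir, witnesses = wit)
  }
  exon_contains <- function(ex, s, e) any(ex[, 1] < s & ex[, 2] > e)
  in_single_exon <- function(ex, s, e) any(ex[, 1] <= s & ex[, 2] >= e)

  # IR: intron of one fully inside an exon of the other
  for (r in seq_len(nrow(inA))) {
    d <- inA[r, 1]; a <- inA[r, 2]
    if (exon_contains(exB, d, a))
      add("IR", c(d, a), c(d, a), inc = "", exc = jk(d, a), ir = jk(d, a))
  }
  for (r in seq_len(nrow(inB))) {
    d <- inB[r, 1]; a <- inB[r, 2]
    if (exon_contains(exA, d, a))
      add("IR", c(d, a), c(d, a), inc = "", exc = jk(d, a), ir = jk(d, a))
  }

  # ES: internal exon of one bridged by a single intron of the other
  es_scan <- function(exI, inI, inO) {
    nI <- nrow(exI)
    if (nI < 3L) return(invisible())
    for (k in 2:(nI - 1L)) {
      s <- exI[k, 1]; e <- exI[k, 2]
      d <- exI[k - 1L, 2]; a <- exI[k + 1L, 1]
      if (any(inO[, 1] == d & inO[, 2] == a))
        add("ES", c(s, e), c(d, a),
            inc = paste(jk(d, s), jk(e, a), sep = ";"), exc = jk(d, a))
    }
  }
  es_scan(exA, inA, inB)
  es_scan(exB, inB, inA)

  # AA / AD: introns sharing exactly one boundary
  if (nrow(inA) && nrow(inB)) {
    for (r in seq_len(nrow(inA))) {
      for (q in seq_len(nrow(inB))) {
        dA <- inA[r, 1]; aA <- inA[r, 2]
        dB <- inB[q, 1]; aB <- inB[q, 2]
        if (dA == dB && aA != aB) {
          lo <- min(aA, aB); hi <- max(aA, aB)
          short_ex <- if (aA < aB) exA else exB
          if (in_single_exon(short_ex, lo, hi)) {
            type <- if (strand == "+") "AA" else "AD"
            add(type, c(lo, hi), c(dA, hi),
                inc = jk(dA, lo), exc = jk(dA, hi))
          }
        } else if (aA == aB && dA != dB) {
          lo <- min(dA, dB); hi <- max(dA, dB)
          short_ex <- if (dA > dB) exA else exB
          if (in_single_exon(short_ex, lo, hi)) {
            type <- if (strand == "+") "AD" else "AA"
            add(type, c(lo, hi), c(lo, aA),
                inc = jk(hi, aA), exc = jk(lo, aA))
          }
        }
      }
    }
  }

  # MX: mutually exclusive internal exons between shared outer sites
  nA <- nrow(exA); nB <- nrow(exB)
  if (nA >= 3L && nB >= 3L) {
    for (k in 2:(nA - 1L)) {
      xs <- exA[k, 1]; xe <- exA[k, 2]
      d <- exA[k - 1L, 2]; a <- exA[k + 1L, 1]
      for (q in 2:(nB - 1L)) {
        ys <- exB[q, 1]; ye <- exB[q, 2]
        if (exB[q - 1L, 2] != d || exB[q + 1L, 1] != a) next
        if (!(xe <= ys || ye <= xs)) next           # disjoint
        if (xs == ys && xe == ye) next
        overlaps <- function(ex, s, e) any(ex[, 1] < e & ex[, 2] > s)
        if (overlaps(exB, xs, xe) || overlaps(exA, ys, ye)) next
        v <- sort(c(xs, xe, ys, ye))
        left_first <- xs < ys   # inclusion = form with genomic-left exon
        inc_ex <- if (left_first) c(xs, xe) else c(ys, ye)
        exc_ex <- if (left_first) c(ys, ye) else c(xs, xe)
        add("MX", v, c(d, a),
            inc = paste(jk(d, inc_ex[1]), jk(inc_ex[2], a), sep = ";"),
            exc = paste(jk(d, exc_ex[1]), jk(exc_ex[2], a), sep = ";"))
      }
    }
  }
  out
}

#' Detect events across a whole locus set
#'
#' @param loci A `locus_set` from [assign_loci()].
#' @return Combined event data frame (see [detect_events()]).
#' @export
detect_events_all <- function(loci) {
  out <- do.call(rbind, lapply(loci, detect_events))
  if (is.null(out)) empty_events() else out
}

#' Summarise AS event types
#'
#' @param events Event data frame from [detect_events()].
#' @return Data frame with count and proportion for each of the five types
#'   plus the total.
#' @export
summarize_types <- function(events) {
  types <- c("IR", "ES", "AA", "AD", "MX")
  counts <- vapply(types, function(t) sum(events$type == t), 0L)
  total <- sum(counts)
  data.frame(type = c(types, "total"),
             count = c(counts, total),
             proportion = if (total > 0) c(counts / total, 1) else
               rep(0, length(types) + 1L))
}

#' Distribution of loci by isoform count
#'
#' @param loci A `locus_set`.
#' @param cap Counts at or above `cap` are pooled into one bucket
#'   (default 10, i.e. a ">=10" bucket).
#' @return Data frame: bucket ("1", "2", ..., ">=cap"), n_loci.
#' @export
isoform_histogram <- function(loci, cap = 10L) {
  if (length(loci) == 0L)
    return(data.frame(bucket = character(0), n_loci = integer(0)))
  n_iso <- vapply(loci, function(l) length(l$cluster_ids), 0L)
  bucket <- ifelse(n_iso >= cap, paste0(">=", cap), as.character(n_iso))
  tab <- table(bucket)
  lev <- c(as.character(seq_len(cap - 1L)), paste0(">=", cap))
  lev <- lev[lev %in% names(tab)]
  data.frame(bucket = lev, n_loci = as.integer(tab[lev]), row.names = NULL)
}
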