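# Collapse of aligned full-length isoforms into non-redundant transcript
# models, locus assignment by exonic overlap, and rarefaction curves.

#' Collapse parameters
#'
#' @param min_coverage Minimum aligner query coverage to keep an alignment.
#' @param min_identity Minimum aligner identity to keep an alignment.
#' @param ignore5 Ignore 5' end differences when collapsing (default TRUE).
#' @param tol3 3'-end tolerance in nt: reads with identical intron chains
#'   merge only if their 3' ends are within this distance (single-linkage),
#'   so genuine alternative-polyadenylation isoforms remain separable.
#' @param single_exon_overlap Minimum reciprocal overlap fraction for merging
#'   single-exon reads.
#' @return List of class `collapse_params`.
#' @export
collapse_params <- function(min_coverage = 0.8, min_identity = 0.7,
                            ignore5 = TRUE, tol3 = 100,
                            single_exon_overlap = 0.5) {
  stopifnot(min_coverage > 0, min_coverage <= 1,
            min_identity > 0, min_identity <= 1, tol3 >= 0,
            single_exon_overlap > 0, single_exon_overlap <= 1)
  structure(list(min_coverage = min_coverage, min_identity = min_identity,
                 ignore5 = ignore5, tol3 = tol3,
                 single_exon_overlap = single_exon_overlap),
            class = "collapse_params")
}

#' Filter alignments by coverage and identity
#'
#' Keeps alignments with query coverage and identity at or above the
#' thresholds (inclusive). Alignments without the metadata (`NA`) are
#' treated as coverage/identity 1.
#'
#' @param models List of aligned [transcript_model()]s carrying `coverage`
#'   and `identity` fields.
#' @param params A [collapse_params()] object.
#' @return The kept models, with attribute `discarded` (count).
#' @export
filter_alignments <- function(models, params = collapse_params()) {
  cov <- vapply(models, function(m) {
    if (is.null(m$coverage)) stop("alignment ", m$id, " lacks coverage metadata")
    if (is.na(m$coverage)) 1 else m$coverage
  }, numeric(1))
  ident <- vapply(models, function(m) {
    if (is.null(m$identity)) stop("alignment ", m$id, " lacks identity metadata")
    if (is.na(m$identity)) 1 else m$identity
  }, numeric(1))
  keep <- cov >= params$min_coverage & ident >= params$min_identity
  out <- models[keep]
  attr(out, "discarded") <- sum(!keep)
  out
}

#' Collapse aligned reads into non-redundant isoform clusters
#'
#' Multi-exon reads merge iff their intron chains are identical and their 3'
#' ends lie within `tol3` of each other (single-linkage); 5' differences are
#' ignored. Single-exon reads merge iff they share a strand and reciprocally
#' overlap by at least `single_exon_overlap` (transitively). The cluster
#' representative spans the widest genomic extent of its members.
#'
#' @param models List of aligned [transcript_model()]s.
#' @param params A [collapse_params()] object.
#' @return List of class `isoform_clusters`; each element has `id`, `model`
#'   (representative), `members` (read ids) and `fl_count`. Deterministic
#'   order (contig, start, intron chain).
#' @export
collapse_isoforms <- function(models, params = collapse_params()) {
  if (length(models) == 0L)
    return(structure(list(), class = "isoform_clusters"))
  multi <- vapply(models, function(m) nrow(m$exons) > 1L, logical(1))
  groups <- list()

  if (any(multi)) {
    mm <- models[multi]
    key <- vapply(mm, function(m)
      paste(m$contig, m$strand, intron_chain_key(m), sep = "|"), character(1))
    for (k in unique(key)) {
      members <- mm[key == k]
      e3 <- vapply(members, tx_end3, numeric(1))
      o <- order(e3)
      brk <- c(0, which(diff(e3[o]) > params$tol3), length(members))
      for (b in seq_len(length(brk) - 1L)) {
        idx <- o[(brk[b] + 1L):brk[b + 1L]]
        groups[[length(groups) + 1L]] <- members[idx]
      }
    }
  }
  if (any(!multi)) {
    sm <- models[!multi]
    skey <- vapply(sm, function(m) paste(m$contig, m$strand, sep = "|"),
                   character(1))
    for (k in unique(skey)) {
      members <- sm[skey == k]
      ir <- IRanges::IRanges(
        start = vapply(members, function(m) m$exons[1, 1] + 1, numeric(1)),
        end = vapply(members, function(m) m$exons[1, 2], numeric(1)))
      hits <- IRanges::findOverlaps(ir, ir)
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      ov <- IRanges::width(IRanges::pintersect(ir[qi], ir[si]))
      ok <- ov / IRanges::width(ir)[qi] >= params$single_exon_overlap &
        ov / IRanges::width(ir)[si] >= params$single_exon_overlap
      g <- igraph::graph_from_data_frame(
        data.frame(from = qi[ok], to = si[ok]), directed = FALSE,
        vertices = data.frame(name = seq_along(members)))
      comp <- igraph::components(g)$membership
      for (cmp in unique(comp))
        groups[[length(groups) + 1L]] <- members[comp == cmp]
    }
  }

  clusters <- lapply(groups, function(members) {
    lo <- min(vapply(members, function(m) tx_span(m)[1], numeric(1)))
    hi <- max(vapply(members, function(m) tx_span(m)[2], numeric(1)))
    m1 <- members[[1L]]
    ic <- tx_introns(m1)
    if (nrow(ic) == 0L) ex <- cbind(lo, hi)
    else ex <- cbind(c(lo, ic[, 2]), c(ic[, 1], hi))
    rep_model <- transcript_model("rep", m1$contig, m1$strand, ex,
                                  gene = m1$gene, source = "collapsed")
    list(model = rep_model,
         members = vapply(members, `[[`, "", "id"),
         fl_count = length(members))
  })
  ord <- order(vapply(clusters, function(cl) cl$model$contig, character(1)),
               vapply(clusters, function(cl) tx_span(cl$model)[1], numeric(1)),
               vapply(clusters, function(cl) intron_chain_key(cl$model),
                      character(1)),
               vapply(clusters, function(cl) cl$model$strand, character(1)))
  clusters <- clusters[ord]
  for (i in seq_along(clusters)) {
    clusters[[i]]$id <- sprintf("PB.%d", i)
    clusters[[i]]$model$id <- clusters[[i]]$id
  }
  names(clusters) <- vapply(clusters, `[[`, "", "id")
  structure(clusters, class = "isoform_clusters")
}

#' @export
print.isoform_clusters <- function(x, ...) {
  cat(sprintf("<isoform_clusters> %d cluster(s), %d member read(s)\n",
              length(x), sum(vapply(x, `[[`, 0L, "fl_count"))))
  invisible(x)
}

#' Assign isoform clusters to transcript loci
#'
#' Two same-strand clusters belong to the same locus iff their exons overlap
#' by at least 1 bp, taken to transitive closure (connected components):
#' the "gene" unit of the reconstruction.
#'
#' @param clusters An `isoform_clusters` object.
#' @return List of class `locus_set`: each locus has `id`, `contig`,
#'   `strand`, `cluster_ids` and `clusters` (the member cluster objects).
#'   Locus ids are ordered by genomic position, stable under input order.
#' @export
assign_loci <- function(clusters) {
  if (length(clusters) == 0L) return(structure(list(), class = "locus_set"))
  exon_gr <- do.call(rbind, lapply(seq_along(clusters), function(i) {
    ex <- clusters[[i]]$model$exons
    cbind(i, ex)
  }))
  keys <- paste(vapply(clusters, function(cl) cl$model$contig, character(1)),
                vapply(clusters, function(cl) cl$model$strand, character(1)))
  edges <- NULL
  for (k in unique(keys)) {
    sel <- which(keys == k)
    rows <- exon_gr[exon_gr[, 1] %in% sel, , drop = FALSE]
    ir <- IRanges::IRanges(start = rows[, 2] + 1, end = rows[, 3])
    hits <- IRanges::findOverlaps(ir, ir)
    qi <- rows[S4Vectors::queryHits(hits), 1]
    si <- rows[S4Vectors::subjectHits(hits), 1]
    edges <- rbind(edges, unique(cbind(qi, si)))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]), directed = FALSE,
    vertices = data.frame(name = seq_along(clusters)))
  comp <- igraph::components(g)$membership
  loci <- lapply(unique(comp), function(cmp) {
    sel <- which(comp == cmp)
    cls <- clusters[sel]
    list(contig = cls[[1L]]$model$contig, strand = cls[[1L]]$model$strand,
         start = min(vapply(cls, function(cl) tx_span(cl$model)[1],
                            numeric(1))),
         cluster_ids = vapply(cls, `[[`, "", "id"),
         clusters = cls)
  })
  ord <- order(vapply(loci, `[[`, "", "contig"),
               vapply(loci, `[[`, 0, "start"),
               vapply(loci, `[[`, "", "strand"))
  loci <- loci[ord]
  for (i in seq_along(loci)) loci[[i]]$id <- sprintf("L%04d", i)
  names(loci) <- vapply(loci, `[[`, "", "id")
  structure(loci, class = "locus_set")
}

#' @export
print.locus_set <- function(x, ...) {
  cat(sprintf("<locus_set> %d locus/loci, %d cluster(s)\n", length(x),
              sum(lengths(lapply(x, `[[`, "cluster_ids")))))
  invisible(x)
}

#' Rarefaction curves of isoform and locus discovery
#'
#' Subsamples reads without replacement at each fraction and reports the
#' mean and SD of the number of distinct clusters and loci discovered,
#' to assess saturation of sequencing depth.
#'
#' @param assignments Data frame with columns `read`, `cluster` and
#'   optionally `locus` (defaults to `cluster`).
#' @param fractions Subsampling fractions in (0, 1].
#' @param reps Random subsamples per fraction.
#' @param seed Seed for the subsampling RNG.
#' @return Data frame: fraction, n_reads, mean/SD of distinct clusters and
#'   loci.
#' @export
rarefaction <- function(assignments, fractions = seq(0.1, 1, by = 0.1),
                        reps = 50L, seed = 1L) {
  if (nrow(assignments) == 0L) stop("empty read-to-cluster map")
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  if (is.null(assignments$locus)) assignments$locus <- assignments$cluster
  set.seed(seed)
  n <- nrow(assignments)
  out <- lapply(fractions, function(f) {
    m <- max(1L, round(f * n))
    cl <- numeric(reps); lc <- numeric(reps)
    for (r in seq_len(reps)) {
      idx <- if (m == n) seq_len(n) else sample.int(n, m)
      cl[r] <- length(unique(assignments$cluster[idx]))
      lc[r] <- length(unique(assignments$locus[idx]))
    }
    data.frame(fraction = f, n_reads = m,
               mean_clusters = mean(cl), sd_clusters = stats::sd(cl),
               mean_loci = mean(lc), sd_loci = stats::sd(lc))
  })
  do.call(rbind, out)
}
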