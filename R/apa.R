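# Poly(A)-site calling from FLnc read 3' ends, internal-priming filtering,
# per-gene APA summaries, flanking nucleotide composition and upstream
# poly(A)-signal motif discovery (exhaustive hexamer count or
# one-occurrence-per-sequence EM).

#' Call poly(A) cleavage sites from FLnc 3' ends
#'
#' Per gene, 3'-end positions are clustered by single linkage with gaps of
#' at most `cluster_window`; each cluster becomes one site positioned at the
#' modal end (ties resolved to the most distal 3' position). A site is
#' flagged as potential internal priming iff the 20 genomic nt immediately
#' downstream (strand-aware) contain >= 12 A's or an A-run of >= 8.
#'
#' @param ends Data frame with columns `gene`, `contig`, `strand`, `pos`
#'   (cleavage position: 0-based, one past the last transcribed base on `+`,
#'   the first transcribed base on `-`), one row per FLnc read.
#' @param genome Named character vector of contig sequences.
#' @param cluster_window Maximum gap (nt) joining ends into one cluster.
#' @param min_support Minimum reads per site.
#' @return Data frame: gene, contig, strand, position, support,
#'   internal_priming.
#' @export
call_polya_sites <- function(ends, genome, cluster_window = 24L,
                             min_support = 1L) {
  if (nrow(ends) == 0L)
    return(data.frame(gene = character(0), contig = character(0),
                      strand = character(0), position = numeric(0),
                      support = numeric(0), internal_priming = logical(0)))
  missing_contigs <- setdiff(unique(ends$contig), names(genome))
  if (length(missing_contigs))
    stop("unknown contig: ", missing_contigs[1L])
  out <- list()
  for (g in sort(unique(ends$gene))) {
    sub <- ends[ends$gene == g, , drop = FALSE]
    pos <- sort(sub$pos)
    brk <- c(0, which(diff(pos) > cluster_window), length(pos))
    for (b in seq_len(length(brk) - 1L)) {
      cl <- pos[(brk[b] + 1L):brk[b + 1L]]
      tab <- table(cl)
      modal <- as.numeric(names(tab)[tab == max(tab)])
      site <- if (sub$strand[1L] == "+") max(modal) else min(modal)
      if (length(cl) < min_support) next
      out[[length(out) + 1L]] <- data.frame(
        gene = g, contig = sub$contig[1L], strand = sub$strand[1L],
        position = site, support = length(cl),
        internal_priming = is_internal_priming(
          genome[[sub$contig[1L]]], site, sub$strand[1L]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

is_internal_priming <- function(contig, site, strand, width = 20L,
                                min_a = 12L, min_run = 8L) {
  n <- nchar(contig)
  if (strand == "+") {
    w <- substr(contig, site + 1, min(n, site + width))
  } else {
    w <- revcomp(substr(contig, max(1, site - width + 1), site))
  }
  ch <- strsplit(w, NULL)[[1]]
  if (sum(ch == "A") >= min_a) return(TRUE)
  r <- rle(ch)
  any(r$values == "A" & r$lengths >= min_run)
}

#' Per-gene APA summary
#'
#' @param sites Data frame from [call_polya_sites()].
#' @param exclude_internal Drop internal-priming sites first (default TRUE).
#' @return List: `per_gene` (gene, n_sites, apa flag), `distribution`
#'   (sites-per-gene buckets 1,2,3,4,>=5), `n_genes` (with >= 1 site),
#'   `n_apa_genes` (>= 2 sites), `mean_sites_per_gene` (mean over genes with
#'   >= 1 site) and `total_over_genes` (total sites / genes, the raw
#'   division).
#' @export
apa_summary <- function(sites, exclude_internal = TRUE) {
  if (exclude_internal) sites <- sites[!sites$internal_priming, , drop = FALSE]
  if (nrow(sites) == 0L)
    return(list(per_gene = data.frame(gene = character(0), n_sites = integer(0),
                                      apa = logical(0)),
                distribution = data.frame(bucket = character(0),
                                          n_genes = integer(0)),
                n_genes = 0L, n_apa_genes = 0L,
                mean_sites_per_gene = NaN, total_over_genes = NaN))
  tab <- table(sites$gene)
  per_gene <- data.frame(gene = names(tab), n_sites = as.integer(tab),
                         apa = as.integer(tab) >= 2L, row.names = NULL)
  bucket <- ifelse(per_gene$n_sites >= 5L, ">=5",
                   as.character(per_gene$n_sites))
  lev <- c("1", "2", "3", "4", ">=5")
  dist <- data.frame(bucket = lev,
                     n_genes = vapply(lev, function(b) sum(bucket == b), 0L),
                     row.names = NULL)
  list(per_gene = per_gene, distribution = dist,
       n_genes = nrow(per_gene), n_apa_genes = sum(per_gene$apa),
       mean_sites_per_gene = mean(per_gene$n_sites),
       total_over_genes = nrow(sites) / nrow(per_gene))
}

#' Nucleotide composition around cleavage sites
#'
#' Strand-aware extraction centred on the cleavage position: column 0 is the
#' first base downstream of cleavage, negative positions are upstream
#' (transcribed) bases. Sites closer than `flank` to a contig edge are
#' skipped (count in attribute `skipped`).
#'
#' @param sites Data frame from [call_polya_sites()].
#' @param genome Named character vector of contig sequences.
#' @param flank Flank size in nt (window width `2 * flank + 1`).
#' @return 4 x (2*flank+1) matrix of per-position base frequencies
#'   (rows A, C, G, T; each column sums to 1).
#' @export
nucleotide_profile <- function(sites, genome, flank = 30L) {
  stopifnot(flank >= 1L)
  width <- 2L * flank + 1L
  counts <- matrix(0, nrow = 4, ncol = width,
                   dimnames = list(c("A", "C", "G", "T"),
                                   as.character(seq(-flank, flank))))
  skipped <- 0L
  for (i in seq_len(nrow(sites))) {
    contig <- genome[[sites$contig[i]]]
    c0 <- sites$position[i]
    if (sites$strand[i] == "+") {
      lo <- c0 - flank; hi <- c0 + flank + 1
      if (lo < 0 || hi > nchar(contig)) { skipped <- skipped + 1L; next }
      w <- substr(contig, lo + 1, hi)
    } else {
      lo <- c0 - flank - 1; hi <- c0 + flank
      if (lo < 0 || hi > nchar(contig)) { skipped <- skipped + 1L; next }
      w <- revcomp(substr(contig, lo + 1, hi))
    }
    ch <- strsplit(w, NULL)[[1]]
    for (j in seq_len(width)) {
      if (ch[j] %in% rownames(counts))
        counts[ch[j], j] <- counts[ch[j], j] + 1
    }
  }
  sums <- colSums(counts)
  sums[sums == 0] <- 1
  freq <- sweep(counts, 2, sums, "/")
  attr(freq, "skipped") <- skipped
  freq
}

#' Find the poly(A) signal motif in upstream sequences
#'
#' `hexamer` mode exhaustively counts all w-mers and returns the most
#' frequent as a one-hot position weight matrix with the per-sequence offset
#' of its first occurrence. `em` mode fits a one-occurrence-per-sequence
#' (OOPS) EM with a uniform background, 5 seeded restarts, up to 50
#' iterations or an objective change below 1e-6, keeping the best restart.
#' The M-step uses a small Dirichlet pseudocount, so the monotone objective
#' is the posterior (penalised) log likelihood; it is recorded per iteration
#' in `objective_trace`.
#'
#' Offsets are reported as the distance upstream of the cleavage position of
#' the motif's 3'-most base: an offset of 25 for a hexamer in a 50-nt window
#' means the match occupies window positions 20..25 (0-based 20..26),
#' i.e. genomic cleavage-30..cleavage-25.
#'
#' @param upstream_seqs Character vector of upstream sequences, each ending
#'   at (exclusive of) the cleavage position, transcript orientation.
#' @param width Motif width (>= 4).
#' @param mode `"hexamer"` (exhaustive count) or `"em"`.
#' @param seed Seed for EM restarts.
#' @return List: `consensus`, `pwm` (4 x width, columns sum to 1),
#'   `offsets` (per sequence, NA when no occurrence in hexamer mode),
#'   `offset_table`, and for EM `objective_trace` and `loglik`.
#' @export
find_signal_motif <- function(upstream_seqs, width = 6L,
                              mode = c("hexamer", "em"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(width >= 4L)
  if (any(nchar(upstream_seqs) < width))
    stop("all sequences must be at least `width` long")
  if (mode == "hexamer") motif_by_count(upstream_seqs, width)
  else motif_by_em(upstream_seqs, width, seed)
}

upstream_offset <- function(seq_len, start0, width) seq_len - start0 - width + 1L

motif_by_count <- function(seqs, w) {
  kmers <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    substring(s, 1:(n - w + 1L), w:n)
  }))
  tab <- table(kmers)
  top <- names(tab)[order(-as.numeric(tab), names(tab))][1L]  # ties: alphabetical
  pwm <- matrix(0, 4, w, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(w)) pwm[substr(top, j, j), j] <- 1
  offsets <- vapply(seqs, function(s) {
    hit <- regexpr(top, s, fixed = TRUE)[1]
    if (hit < 0) NA_integer_
    else as.integer(upstream_offset(nchar(s), hit - 1L, w))
  }, NA_integer_)
  list(consensus = top, pwm = pwm, offsets = unname(offsets),
       offset_table = table(offsets))
}

motif_by_em <- function(seqs, w, seed, n_restarts = 5L, max_iter = 50L,
                        tol = 1e-6, pseudo = 0.5) {
  bases <- c("A", "C", "G", "T")
  enc <- lapply(seqs, function(s) match(strsplit(s, NULL)[[1]], bases))
  n_off <- vapply(enc, length, 0L) - w + 1L
  # restarts are seeded from the most frequent w-mers (plus random jitter),
  # the classic subsequence-seeding strategy for one-motif EM
  kmers <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    substring(s, 1:(n - w + 1L), w:n)
  }))
  tab <- table(kmers)
  seeds_km <- names(tab)[order(-as.numeric(tab), names(tab))]
  seeds_km <- seeds_km[seq_len(min(n_restarts, length(seeds_km)))]
  best <- NULL
  set.seed(seed)
  for (r in seq_along(seeds_km)) {
    pwm <- matrix(0.1, 4, w)
    idx <- match(strsplit(seeds_km[r], NULL)[[1]], bases)
    pwm[cbind(idx, seq_len(w))] <- 0.7
    pwm <- pwm + matrix(stats::runif(4 * w, 0, 0.02), 4, w)
    pwm <- sweep(pwm, 2, colSums(pwm), "/")
    trace <- numeric(0)
    prev <- -Inf
    for (it in seq_len(max_iter)) {
      lpwm <- log(pwm)
      resp <- vector("list", length(enc))
      ll <- 0
      for (i in seq_along(enc)) {
        x <- enc[[i]]
        lw <- vapply(seq_len(n_off[i]), function(o)
          sum(lpwm[cbind(x[o:(o + w - 1L)], seq_len(w))]) - w * log(0.25),
          numeric(1))
        m <- max(lw)
        p <- exp(lw - m)
        resp[[i]] <- p / sum(p)
        # full-sequence loglik: uniform background everywhere + motif ratio
        ll <- ll + length(x) * log(0.25) + m + log(mean(p))
      }
      # M-step with Dirichlet(1 + pseudo) prior
      cnt <- matrix(pseudo, 4, w)
      for (i in seq_along(enc)) {
        x <- enc[[i]]
        ri <- resp[[i]]
        for (o in seq_len(n_off[i])) {
          idx <- cbind(x[o:(o + w - 1L)], seq_len(w))
          cnt[idx] <- cnt[idx] + ri[o]
        }
      }
      pwm_new <- sweep(cnt, 2, colSums(cnt), "/")
      obj <- ll + sum(pseudo * log(pwm))  # penalised objective (log posterior)
      trace <- c(trace, obj)
      if (it > 1L && abs(obj - prev) < tol) { pwm <- pwm_new; break }
      prev <- obj
      pwm <- pwm_new
    }
    final <- list(pwm = pwm, trace = trace, loglik = ll)
    if (is.null(best) || final$trace[length(final$trace)] >
          best$trace[length(best$trace)])
      best <- final
  }
  pwm <- best$pwm
  rownames(pwm) <- bases
  lpwm <- log(pwm)
  offsets <- vapply(seq_along(enc), function(i) {
    x <- enc[[i]]
    lw <- vapply(seq_len(n_off[i]), function(o)
      sum(lpwm[cbind(x[o:(o + w - 1L)], seq_len(w))]), numeric(1))
    o <- which.max(lw)
    as.integer(upstream_offset(length(x), o - 1L, w))
  }, NA_integer_)
  consensus <- paste(bases[apply(pwm, 2, which.max)], collapse = "")
  list(consensus = consensus, pwm = pwm, offsets = offsets,
       offset_table = table(offsets), objective_trace = best$trace,
       loglik = best$loglik)
}

#' Upstream sequences of poly(A) sites
#'
#' @param sites Data frame from [call_polya_sites()].
#' @param genome Named character vector of contig sequences.
#' @param len Window length upstream of cleavage (default 50 nt).
#' @return Character vector of transcript-orientation upstream windows
#'   (sites too close to a contig edge are dropped).
#' @export
upstream_windows <- function(sites, genome, len = 50L) {
  out <- character(0)
  for (i in seq_len(nrow(sites))) {
    contig <- genome[[sites$contig[i]]]
    c0 <- sites$position[i]
    if (sites$strand[i] == "+") {
      if (c0 - len < 0) next
      out <- c(out, substr(contig, c0 - len + 1, c0))
    } else {
      if (c0 + len > nchar(contig)) next
      out <- c(out, revcomp(substr(contig, c0 + 1, c0 + len)))
    }
  }
  out
}
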