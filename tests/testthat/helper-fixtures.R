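# Shared fixture builders: everything is generated in code at test time.

tm <- function(id, exons, strand = "+", contig = "chr1", ...) {
  transcript_model(id, contig, strand, do.call(rbind, exons), ...)
}

# Random multi-isoform locus built from a shared pool of splice-site
# positions, so isoforms frequently share boundaries (the interesting case
# for AS detection). <= max_iso isoforms, <= max_exons exons each.
random_locus <- function(n_iso = NULL, max_iso = 4L, max_exons = 6L,
                         span = 1000L) {
  if (is.null(n_iso)) n_iso <- sample(2:max_iso, 1L)
  pool <- sort(sample(seq(10L, span, by = 5L), 14L))
  isoforms <- lapply(seq_len(n_iso), function(i) {
    repeat {
      n_ex <- sample(1:max_exons, 1L)
      sites <- sort(sample(pool, 2L * n_ex))
      ex <- matrix(sites, ncol = 2, byrow = TRUE)
      if (all(ex[, 2] > ex[, 1]) &&
          (nrow(ex) < 2L || all(ex[-1L, 1] - ex[-nrow(ex), 2] >= 1)))
        return(transcript_model(paste0("iso", i), "chrR", "+", ex))
    }
  })
  list(id = "Lrand", contig = "chrR", strand = "+", isoforms = isoforms)
}

# A tiny deterministic genome with one planted junction for motif tests.
motif_genome <- function(don, acc, intron_len = 50L) {
  left <- strrep("C", 30)
  mid <- strrep("G", intron_len - 4L)
  right <- strrep("C", 30)
  c(chrM = paste0(left, don, mid, acc, right))
}
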