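# Synthetic-truth generator: genomes, gene models with planted AS events and
# poly(A) signals, full-length long reads and junction-count tables, all with
# machine-readable truth so the downstream pipeline can be tested against
# known answers.

#' Simulation parameters
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' statistical structure of a plant Iso-Seq study: an intron-retention
#' dominated AS-type mix (IR 68.85%, AA 15.64%, AD 9.31%, ES 3.10%,
#' MX 3.10%), 5'-truncated full-length reads carrying primers and a poly(A)
#' tail, and cleavage sites with an AATAAA signal whose 3' end sits 25 nt
#' upstream of the cleavage position.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param n_genes Number of gene loci to plant.
#' @param contig_lengths Named integer vector of contig lengths; `NULL`
#'   sizes a single contig to fit `n_genes`.
#' @param gc Target GC content of background sequence.
#' @param iso_dist Probabilities of a gene having 1, 2, ... isoforms
#'   (one planted AS event per isoform beyond the first).
#' @param as_mix Named proportions over the five AS event types
#'   (must sum to 1).
#' @param frac_noncanonical Fraction of intron slots given a non-GT-AG motif
#'   (drawn uniformly from GC-AG, AT-AC and an "other" motif).
#' @param frac_single_exon Fraction of genes that are single-exon
#'   (such genes get exactly one isoform and no AS events).
#' @param frac_coding Fraction of genes with a planted ORF
#'   (ATG + >= 110 biased sense codons + stop) in the reference isoform.
#' @param fl_depth Full-length reads simulated per isoform.
#' @param max_trunc_frac Maximum 5' truncation as a fraction of transcript
#'   length (additionally capped inside the first exon so error-free reads
#'   keep complete intron chains).
#' @param nfl_frac Fraction of reads rendered non-full-length by omitting
#'   exactly one of 5' primer, 3' primer or poly(A) tail.
#' @param primer5,primer3 Primer sequences (30-mers by default).
#' @param polya_len Length of the appended poly(A) tail.
#' @param polya_signal_offset Distance (nt) from the 3'-most base of the
#'   planted AATAAA hexamer to the cleavage position.
#' @param p_apa Probability that an isoform beyond the first uses its own
#'   proximal cleavage site (3' end shifted upstream in 150-nt steps).
#' @param sj_depth Short-read depth per junction and per AS event.
#' @param n_samples Number of short-read samples.
#' @param p_differential Probability that an event's true PSI differs between
#'   sample 1 and later samples (by +/- 0.4, clamped to `[0.05, 0.95]`).
#' @param error_rate Uniform substitution error rate for reads (default 0:
#'   error-free).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(seed = 1L,
                       n_genes = 30L,
                       contig_lengths = NULL,
                       gc = 0.42,
                       iso_dist = c(0.49, 0.26, 0.15, 0.10),
                       as_mix = c(IR = 0.6885, AA = 0.1564, AD = 0.0931,
                                  ES = 0.0310, MX = 0.0310),
                       frac_noncanonical = 0,
                       frac_single_exon = 0.1,
                       frac_coding = 0.85,
                       fl_depth = 10L,
                       max_trunc_frac = 0.2,
                       nfl_frac = 0.1,
                       primer5 = "ATGCGGTACTTAGCCGTACGTTCAGGTCCA",
                       primer3 = "GCAATGCCGTTAGACCTGTTCAGCCAGTAC",
                       polya_len = 30L,
                       polya_signal_offset = 25L,
                       p_apa = 0.4,
                       sj_depth = 100L,
                       n_samples = 2L,
                       p_differential = 0.3,
                       error_rate = 0) {
  p <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
            contig_lengths = contig_lengths, gc = gc, iso_dist = iso_dist,
            as_mix = as_mix, frac_noncanonical = frac_noncanonical,
            frac_single_exon = frac_single_exon, frac_coding = frac_coding,
            fl_depth = as.integer(fl_depth), max_trunc_frac = max_trunc_frac,
            nfl_frac = nfl_frac, primer5 = toupper(primer5),
            primer3 = toupper(primer3), polya_len = as.integer(polya_len),
            polya_signal_offset = as.integer(polya_signal_offset),
            p_apa = p_apa, sj_depth = as.integer(sj_depth),
            n_samples = as.integer(n_samples),
            p_differential = p_differential, error_rate = error_rate)
  validate_sim_params(p)
  if (is.null(p$contig_lengths))
    p$contig_lengths <- c(chrS = max(10000L, p$n_genes * 9000L))
  class(p) <- "sim_params"
  p
}

validate_sim_params <- function(p) {
  if (abs(sum(p$as_mix) - 1) > 1e-9)
    stop("as_mix proportions must sum to 1")
  if (!setequal(names(p$as_mix), c("IR", "ES", "AA", "AD", "MX")))
    stop("as_mix must be named IR, ES, AA, AD, MX")
  if (abs(sum(p$iso_dist) - 1) > 1e-9) stop("iso_dist must sum to 1")
  counts <- c(p$n_genes, p$fl_depth, p$polya_len, p$sj_depth, p$n_samples)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (!is.null(p$contig_lengths) && any(p$contig_lengths <= 0))
    stop("contig lengths must be positive")
  fracs <- c(p$gc, p$frac_noncanonical, p$frac_single_exon, p$frac_coding,
             p$max_trunc_frac, p$nfl_frac, p$p_apa, p$p_differential,
             p$error_rate)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  invisible(p)
}

#' Generate a random reference genome
#'
#' @param params A [sim_params()] object (uses `seed`, `contig_lengths`
#'   and `gc`).
#' @return Named character vector of uppercase contig sequences.
#' @export
make_genome <- function(params) {
  validate_sim_params(params)
  if (any(params$contig_lengths < 1)) stop("contig lengths must be >= 1")
  set.seed(params$seed)
  out <- vapply(params$contig_lengths, function(n) random_dna(n, params$gc),
                character(1))
  names(out) <- names(params$contig_lengths)
  out
}

MOTIF_PAIRS <- list("GT-AG" = c("GT", "AG"),
                    "GC-AG" = c("GC", "AG"),
                    "AT-AC" = c("AT", "AC"),
                    "other" = c("AA", "TT"))

# Write the terminal dinucleotides of intron [d, a) so that, read in
# transcript orientation, the motif matches `class`.
set_intron_motif <- function(seq, d, a, strand, class) {
  pair <- MOTIF_PAIRS[[class]]
  if (strand == "+") {
    seq <- write_at(seq, d, pair[1])
    seq <- write_at(seq, a - 2, pair[2])
  } else {
    seq <- write_at(seq, a - 2, revcomp(pair[1]))
    seq <- write_at(seq, d, revcomp(pair[2]))
  }
  seq
}

# Codons excluding stops, weighted toward a G/C-rich wobble position so the
# planted coding sequence has measurable composition bias.
biased_codons <- function() {
  b <- c("A", "C", "G", "T")
  cods <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  cods <- cods[!cods %in% c("TAA", "TAG", "TGA")]
  w <- ifelse(substr(cods, 3, 3) %in% c("G", "C"), 3, 1)
  list(codons = cods, weights = w / sum(w))
}

#' Plant gene models with known AS events and poly(A) sites into a genome
#'
#' Genes are placed non-overlapping, each on a uniformly chosen strand.
#' Every planted intron receives the requested terminal dinucleotides
#' (GT..AG unless its slot was drawn non-canonical), every planted AS event
#' is realised by exactly one (reference, variant) isoform pair, and every
#' signal-bearing cleavage site gets the AATAAA hexamer written at the
#' configured upstream offset, a non-A U-rich tract immediately upstream and
#' a mildly A-rich (but never internal-priming-like) tract downstream.
#'
#' @param genome Genome from [make_genome()].
#' @param params A [sim_params()] object.
#' @return A list with elements `genome` (the edited genome), `models`
#'   (named list of [transcript_model()]s) and `truth` (list of data frames:
#'   `genes`, `isoforms`, `events`, `sites`, `junctions`, plus the
#'   event-by-sample `psi` matrix).
#' @export
plant_genes <- function(genome, params) {
  validate_sim_params(params)
  set.seed(params$seed + 1L)
  contig_name <- names(genome)[1L]
  seq <- genome[[contig_name]]
  glen <- nchar(seq)

  models <- list()
  genes <- list(); isoforms <- list(); events <- list()
  sites <- list(); junctions <- list()
  cursor <- 500
  ev_n <- 0L

  for (g in seq_len(params$n_genes)) {
    gene_id <- sprintf("G%03d", g)
    strand <- sample(c("+", "-"), 1L)
    single <- runif(1) < params$frac_single_exon

    if (single) {
      n_iso <- 1L
      exon_lens <- 800 + sample(0:400, 1L)
      n_slots <- 0L
      ev_types <- character(0)
    } else {
      n_iso <- sample(seq_along(params$iso_dist), 1L, prob = params$iso_dist)
      n_slots <- 5L
      ev_types <- if (n_iso > 1L)
        sample(names(params$as_mix), n_iso - 1L, replace = TRUE,
               prob = params$as_mix) else character(0)
    }

    # --- blueprint in genomic (plus) orientation -------------------------
    # 6 anchor exons separated by 5 slots; each AS event occupies its own
    # slot. Slot geometry depends on the event type planted there.
    n_anchor <- if (single) 1L else 6L
    exon_len <- if (single) exon_lens else sample(120:200, n_anchor, replace = TRUE)
    last_exon_extra <- 450 + 150 * (n_iso - 1L)
    # index of the transcript-terminal exon in genomic order
    if (strand == "+") exon_len[n_anchor] <- last_exon_extra
    else exon_len[1L] <- last_exon_extra

    slot_of_event <- if (length(ev_types))
      sample.int(n_slots, length(ev_types)) else integer(0)
    slot_type <- rep("plain", max(n_slots, 0L))
    slot_type[slot_of_event] <- ev_types

    # lay out segments left to right
    starts <- numeric(n_anchor); ends <- numeric(n_anchor)
    slot_info <- vector("list", n_slots)
    pos <- cursor
    for (k in seq_len(n_anchor)) {
      starts[k] <- pos; ends[k] <- pos + exon_len[k]; pos <- ends[k]
      if (k < n_anchor) {
        st <- slot_type[k]
        if (st == "ES") {
          i1 <- 120; ce <- 90; i2 <- 120
          slot_info[[k]] <- list(type = "ES",
                                 cass = c(pos + i1, pos + i1 + ce))
          pos <- pos + i1 + ce + i2
        } else if (st == "MX") {
          slot_info[[k]] <- list(type = "MX",
                                 x = c(pos + 100, pos + 180),
                                 y = c(pos + 280, pos + 360))
          pos <- pos + 460
        } else {
          slot_info[[k]] <- list(type = st)
          pos <- pos + 150
        }
        slot_info[[k]]$d <- ends[k]   # genomic-left intron boundary
        slot_info[[k]]$a <- pos       # genomic-right intron boundary
      }
    }
    gene_end <- pos
    if (gene_end + 400 > glen)
      stop("insufficient genome space for ", params$n_genes, " genes ",
           "(contig ", contig_name, " too short)")

    # --- reference isoform exons (includes cassette and MX 'X' exons) ----
    ref_exons <- NULL
    for (k in seq_len(n_anchor)) {
      ref_exons <- rbind(ref_exons, c(starts[k], ends[k]))
      if (k < n_anchor) {
        si <- slot_info[[k]]
        if (si$type == "ES") ref_exons <- rbind(ref_exons, si$cass)
        if (si$type == "MX") ref_exons <- rbind(ref_exons, si$x)
      }
    }

    # --- variant isoforms, one planted event each ------------------------
    iso_exons <- list(ref_exons)
    ev_local <- list()
    for (v in seq_along(ev_types)) {
      ty <- ev_types[v]; k <- slot_of_event[v]; si <- slot_info[[k]]
      ex <- ref_exons
      row_L <- which(ex[, 2] == si$d)   # exon ending at slot's left boundary
      row_R <- which(ex[, 1] == si$a)   # exon starting at slot's right boundary
      if (ty == "IR") {
        # variant retains the intron: merge flanking exons
        ex[row_L, 2] <- ex[row_R, 2]
        ex <- ex[-row_R, , drop = FALSE]
        variant <- c(si$d, si$a)
        inc_iso <- "variant"  # retaining form is the inclusion form
      } else if (ty == "ES") {
        cass_row <- which(ex[, 1] == si$cass[1])
        ex <- ex[-cass_row, , drop = FALSE]
        variant <- si$cass
        inc_iso <- "reference"
      } else if (ty == "MX") {
        x_row <- which(ex[, 1] == si$x[1])
        ex[x_row, ] <- si$y
        variant <- c(si$x, si$y)
        inc_iso <- "reference"  # form with the genomic-left variant exon
      } else {
        # AA varies the transcript acceptor, AD the donor; resolve which
        # genomic boundary that is on this strand.
        vary_right <- (ty == "AA") == (strand == "+")
        if (vary_right) {
          ex[row_R, 1] <- si$a + 30
          variant <- c(si$a, si$a + 30)
        } else {
          ex[row_L, 2] <- si$d - 30
          variant <- c(si$d - 30, si$d)
        }
        inc_iso <- "reference"  # shorter-intron form keeps more exon
      }
      iso_exons[[v + 1L]] <- ex
      ev_local[[v]] <- list(type = ty, slot = k, variant = variant,
                            inc_iso = inc_iso)
    }

    # --- APA: proximal cleavage sites for some non-reference isoforms ----
    site_offsets <- numeric(n_iso)  # upstream shift of each isoform's 3' end
    n_prox <- 0L
    if (n_iso > 1L) {
      for (v in 2:n_iso) {
        if (runif(1) < params$p_apa) {
          n_prox <- n_prox + 1L
          site_offsets[v] <- 150 * n_prox
        }
      }
    }
    for (v in seq_len(n_iso)) {
      off <- site_offsets[v]
      if (off > 0) {
        ex <- iso_exons[[v]]
        if (strand == "+") ex[nrow(ex), 2] <- ex[nrow(ex), 2] - off
        else ex[1L, 1] <- ex[1L, 1] + off
        iso_exons[[v]] <- ex
      }
    }

    # --- build models + truth rows --------------------------------------
    iso_ids <- sprintf("%s.i%d", gene_id, seq_len(n_iso))
    for (v in seq_len(n_iso)) {
      models[[iso_ids[v]]] <- transcript_model(
        iso_ids[v], contig_name, strand, iso_exons[[v]], gene = gene_id,
        source = "planted")
    }

    # plant ORF in the reference isoform of coding genes; motifs are written
    # afterwards (a variant splice boundary can fall inside reference exon
    # sequence), so the ORF is re-verified once all edits are in
    orf_len <- 0L
    if (!single && runif(1) < params$frac_coding) {
      ref <- models[[iso_ids[1L]]]
      txlen <- tx_length(ref)
      max_aa <- floor((txlen - 600 - 100) / 3) - 2
      if (max_aa >= 110) {
        aa <- sample(110:min(max_aa, 300), 1L)
        bc <- biased_codons()
        orf_seq <- paste0("ATG",
                          paste(sample(bc$codons, aa, TRUE, bc$weights),
                                collapse = ""), "TAA")
        seq <- write_tx_segment(seq, ref, 100, orf_seq)
        orf_len <- nchar(orf_seq)
      }
    }

    # intron motifs: one class per distinct intron boundary pair, the slot's
    # class shared between reference and variant intron at that slot
    all_introns <- unique(do.call(rbind, lapply(iso_ids, function(i)
      tx_introns(models[[i]]))))
    slot_class <- vapply(seq_len(max(n_slots, 0L)), function(k) {
      if (runif(1) < params$frac_noncanonical)
        sample(c("GC-AG", "AT-AC", "other"), 1L) else "GT-AG"
    }, character(1))
    if (nrow(all_introns)) {
      for (r in seq_len(nrow(all_introns))) {
        d <- all_introns[r, 1]; a <- all_introns[r, 2]
        k <- which(vapply(slot_info, function(si)
          !is.null(si) && (si$d == d || si$a == a ||
                             (d >= si$d && a <= si$a)), logical(1)))[1]
        cls <- if (!is.na(k)) slot_class[k] else "GT-AG"
        seq <- set_intron_motif(seq, d, a, strand, cls)
        junctions[[length(junctions) + 1L]] <- data.frame(
          gene = gene_id, contig = contig_name, strand = strand,
          donor = d, acceptor = a, class = cls, stringsAsFactors = FALSE)
      }
    }

    # verify the planted ORF survived the motif writes
    orf_planted <- FALSE
    if (orf_len > 0L) {
      tmp_genome <- genome
      tmp_genome[[contig_name]] <- seq
      tx <- spliced_seq(tmp_genome, models[[iso_ids[1L]]])
      cod <- substring(substr(tx, 101, 100 + orf_len),
                       seq(1, orf_len, 3), seq(3, orf_len, 3))
      orf_planted <- cod[1L] == "ATG" &&
        cod[length(cod)] %in% c("TAA", "TAG", "TGA") &&
        !any(cod[-length(cod)] %in% c("TAA", "TAG", "TGA"))
    }

    # poly(A) sites: one per distinct isoform 3' end
    ends3 <- vapply(iso_ids, function(i) tx_end3(models[[i]]), numeric(1))
    for (cpos in unique(ends3)) {
      sup_iso <- iso_ids[ends3 == cpos]
      seq <- plant_polya_site(seq, cpos, strand,
                              params$polya_signal_offset, params$gc)
      sites[[length(sites) + 1L]] <- data.frame(
        gene = gene_id, contig = contig_name, strand = strand,
        position = cpos, signal_offset = params$polya_signal_offset,
        isoforms = paste(sup_iso, collapse = ";"), stringsAsFactors = FALSE)
    }

    span_lo <- min(vapply(iso_ids, function(i) tx_span(models[[i]])[1],
                          numeric(1)))
    genes[[g]] <- data.frame(
      gene = gene_id, contig = contig_name, strand = strand,
      start = span_lo, end = gene_end, n_isoforms = n_iso,
      single_exon = single, orf_planted = orf_planted,
      stringsAsFactors = FALSE)
    for (v in seq_len(n_iso)) {
      isoforms[[length(isoforms) + 1L]] <- data.frame(
        isoform = iso_ids[v], gene = gene_id, contig = contig_name,
        strand = strand, n_exons = nrow(iso_exons[[v]]),
        length = tx_length(models[[iso_ids[v]]]),
        end3 = ends3[v], stringsAsFactors = FALSE)
    }
    for (v in seq_along(ev_local)) {
      ev_n <- ev_n + 1L
      e <- ev_local[[v]]
      jx <- event_truth_junctions(e, slot_info[[e$slot]], contig_name, strand)
      ref_id <- iso_ids[1L]; var_id <- iso_ids[v + 1L]
      inc_id <- if (e$inc_iso == "reference") ref_id else var_id
      events[[ev_n]] <- data.frame(
        event = sprintf("T%04d", ev_n), gene = gene_id, type = e$type,
        contig = contig_name, strand = strand,
        variant = paste(e$variant, collapse = ","),
        inclusion_isoform = inc_id,
        exclusion_isoform = setdiff(c(ref_id, var_id), inc_id),
        inclusion_junctions = jx$inc, exclusion_junctions = jx$exc,
        ir_intron = jx$ir, stringsAsFactors = FALSE)
    }

    cursor <- gene_end + 400 + sample(0:200, 1L)
  }

  truth_events <- if (ev_n) do.call(rbind, events) else
    data.frame(event = character(0), gene = character(0), type = character(0),
               contig = character(0), strand = character(0),
               variant = character(0), inclusion_isoform = character(0),
               exclusion_isoform = character(0),
               inclusion_junctions = character(0),
               exclusion_junctions = character(0), ir_intron = character(0))

  # true PSI per event and sample
  psi <- matrix(numeric(0), nrow = nrow(truth_events), ncol = params$n_samples)
  if (nrow(truth_events) && params$n_samples > 0) {
    base <- runif(nrow(truth_events), 0.15, 0.85)
    psi[, 1] <- base
    if (params$n_samples > 1) {
      for (s in 2:params$n_samples) {
        shift <- ifelse(runif(nrow(truth_events)) < params$p_differential,
                        ifelse(base > 0.5, -0.4, 0.4), 0)
        psi[, s] <- pmin(0.95, pmax(0.05, base + shift))
      }
    }
    rownames(psi) <- truth_events$event
    colnames(psi) <- paste0("sample", seq_len(params$n_samples))
  }

  genome[[contig_name]] <- seq
  truth <- list(genes = do.call(rbind, genes),
                isoforms = do.call(rbind, isoforms),
                events = truth_events,
                sites = do.call(rbind, sites),
                junctions = if (length(junctions)) do.call(rbind, junctions)
                            else NULL,
                psi = psi)
  list(genome = genome, models = models, truth = truth)
}

# Truth junction key sets for one planted event (semicolon-joined).
event_truth_junctions <- function(e, si, contig, strand) {
  jk <- function(d, a) junction_key(contig, d, a, strand)
  switch(e$type,
    IR = list(inc = "", exc = jk(si$d, si$a), ir = jk(si$d, si$a)),
    ES = list(inc = paste(jk(si$d, si$cass[1]), jk(si$cass[2], si$a),
                          sep = ";"),
              exc = jk(si$d, si$a), ir = ""),
    MX = list(inc = paste(jk(si$d, si$x[1]), jk(si$x[2], si$a), sep = ";"),
              exc = paste(jk(si$d, si$y[1]), jk(si$y[2], si$a), sep = ";"),
              ir = ""),
    AA = ,
    AD = {
      lo <- min(e$variant); hi <- max(e$variant)
      # boundaries of the two introns at this slot: shared side unchanged
      if (lo >= si$a || hi > si$a) {    # right boundary varied
        list(inc = jk(si$d, lo), exc = jk(si$d, hi), ir = "")
      } else {                          # left boundary varied
        list(inc = jk(hi, si$a), exc = jk(lo, si$a), ir = "")
      }
    })
}

# Write a transcript-orientation sequence segment starting at transcript
# position tpos into the genomic contig string.
write_tx_segment <- function(seq, model, tpos, value) {
  n <- nchar(value)
  w <- model$exons[, 2] - model$exons[, 1]
  if (model$strand == "-") w <- rev(w)
  off <- cumsum(c(0, w))
  t0 <- tpos
  vpos <- 1
  while (vpos <= n) {
    j <- findInterval(t0, off)
    avail <- off[j + 1] - t0
    take <- min(avail, n - vpos + 1)
    chunk <- substr(value, vpos, vpos + take - 1)
    if (model$strand == "+") {
      gstart <- model$exons[j, 1] + (t0 - off[j])
      seq <- write_at(seq, gstart, chunk)
    } else {
      k <- nrow(model$exons) + 1L - j
      ghi <- model$exons[k, 2] - (t0 - off[j])  # one past first base written
      seq <- write_at(seq, ghi - take, revcomp(chunk))
    }
    t0 <- t0 + take
    vpos <- vpos + take
  }
  seq
}

# Plant the poly(A) signal and flanking composition around cleavage position
# cpos (strand-aware): AATAAA with its 3' end `offset` nt upstream, a strictly
# non-A (U-rich) tract at upstream distances 1..12, and a mildly A-rich
# downstream tract that is post-edited so it can never look like internal
# priming (< 12 A in 20 nt, no A-run >= 8).
plant_polya_site <- function(seq, cpos, strand, offset, gc) {
  up_nonA <- paste(sample(c("C", "G", "T"), 12, TRUE, c(0.2, 0.2, 0.6)),
                   collapse = "")
  down <- sample(c("A", "C", "G", "T"), 20, TRUE, c(0.5, 0.17, 0.17, 0.16))
  # cap downstream A content below the internal-priming thresholds
  a_idx <- which(down == "A")
  if (length(a_idx) > 10) down[a_idx[-seq_len(10)]] <- "C"
  r <- rle(down)
  if (any(r$values == "A" & r$lengths >= 6)) {
    pos <- cumsum(r$lengths) - r$lengths + 1
    for (i in which(r$values == "A" & r$lengths >= 6))
      down[pos[i] + 5] <- "C"
  }
  down <- paste(down, collapse = "")
  if (strand == "+") {
    seq <- write_at(seq, cpos - 12, up_nonA)
    seq <- write_at(seq, cpos - offset - 5, "AATAAA")
    seq <- write_at(seq, cpos, down)
  } else {
    seq <- write_at(seq, cpos, revcomp(up_nonA))
    seq <- write_at(seq, cpos + offset - 1, revcomp("AATAAA"))
    seq <- write_at(seq, cpos - 20, revcomp(down))
  }
  seq
}

#' Simulate full-length long reads from planted isoforms
#'
#' A full-length non-chimeric read is `5' primer + (possibly 5'-truncated)
#' transcript + poly(A) + revcomp(3' primer)`, randomly strand-flipped.
#' Non-full-length reads omit exactly one of the three diagnostic elements;
#' the truth table records which.
#'
#' @param sim Result of [plant_genes()].
#' @param params A [sim_params()] object.
#' @return List with `reads` (named character vector), `read_info` (truth
#'   data frame: read id, source isoform/gene, FLnc status, missing element,
#'   flip, truncation, insert length) and `alignments` (per-read
#'   [transcript_model()]s of the insert on the genome, the error-free
#'   stand-in for a spliced aligner).
#' @export
simulate_fl_reads <- function(sim, params) {
  validate_sim_params(params)
  if (length(sim$models) == 0L) stop("no isoforms to simulate from")
  set.seed(params$seed + 2L)
  reads <- character(0); info <- list(); alns <- list()
  k <- 0L
  p3rc <- revcomp(params$primer3)
  tail_a <- strrep("A", params$polya_len)
  genes_of <- vapply(sim$models, `[[`, "", "gene")
  for (iso in names(sim$models)) {
    m <- sim$models[[iso]]
    full <- spliced_seq(sim$genome, m)
    txlen <- nchar(full)
    # truncation must stay inside the first exon AND upstream of any sibling
    # isoform's splice boundary that falls within it (e.g. the donor of a
    # retained intron), so planted structural evidence survives in every read
    sib <- sim$models[genes_of == m$gene]
    sib_sites <- sort(unique(unlist(lapply(sib, function(x) tx_introns(x)))))
    if (m$strand == "+") {
      s <- m$exons[1, 1]; e <- m$exons[1, 2]
      inner <- sib_sites[sib_sites > s & sib_sites < e]
      margin <- if (length(inner)) min(inner) - s else e - s
    } else {
      n_ex <- nrow(m$exons)
      s <- m$exons[n_ex, 1]; e <- m$exons[n_ex, 2]
      inner <- sib_sites[sib_sites > s & sib_sites < e]
      margin <- if (length(inner)) e - max(inner) else e - s
    }
    max_t <- max(0L, min(floor(params$max_trunc_frac * txlen),
                         as.integer(margin) - 10L))
    for (r in seq_len(params$fl_depth)) {
      k <- k + 1L
      rid <- sprintf("read%05d", k)
      trunc <- if (max_t > 0) sample(0:max_t, 1L) else 0L
      insert <- substr(full, trunc + 1L, txlen)
      is_nfl <- runif(1) < params$nfl_frac
      missing <- if (is_nfl) sample(c("primer5", "primer3", "polya"), 1L)
                 else "none"
      parts <- c(if (missing != "primer5") params$primer5,
                 insert,
                 if (missing != "polya") tail_a,
                 if (missing != "primer3") p3rc)
      rseq <- paste(parts, collapse = "")
      if (params$error_rate > 0) {
        n <- nchar(rseq)
        hit <- which(runif(n) < params$error_rate)
        if (length(hit)) {
          ch <- strsplit(rseq, NULL)[[1]]
          ch[hit] <- vapply(ch[hit], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
          rseq <- paste(ch, collapse = "")
        }
      }
      flipped <- runif(1) < 0.5
      if (flipped) rseq <- revcomp(rseq)
      reads[rid] <- rseq
      ex <- m$exons
      if (trunc > 0) {
        if (m$strand == "+") ex[1, 1] <- ex[1, 1] + trunc
        else ex[nrow(ex), 2] <- ex[nrow(ex), 2] - trunc
      }
      alns[[rid]] <- transcript_model(rid, m$contig, m$strand, ex,
                                      gene = m$gene, source = "aligned")
      info[[k]] <- data.frame(
        read = rid, isoform = iso, gene = m$gene, strand = m$strand,
        flnc = !is_nfl, missing = missing, flipped = flipped,
        truncation = trunc, insert_length = nchar(insert),
        stringsAsFactors = FALSE)
    }
  }
  list(reads = reads, read_info = do.call(rbind, info), alignments = alns)
}

#' Simulate short-read splice-junction count tables
#'
#' For each planted AS event and sample, the inclusion count is drawn
#' `Binomial(depth, PSI)` and the exclusion count is `depth - inclusion`;
#' constitutive junctions receive the full depth. Intron-retention inclusion
#' evidence (intron-body coverage, which junction tables cannot carry) is
#' returned as a separate intron-coverage table.
#'
#' @param sim Result of [plant_genes()].
#' @param params A [sim_params()] object.
#' @return List with `sj` (per-sample data frames in [read_sj_tab()] layout)
#'   and `intron_cov` (per-sample data frames: contig, donor, acceptor,
#'   strand, support).
#' @export
simulate_sj_counts <- function(sim, params) {
  validate_sim_params(params)
  psi <- sim$truth$psi
  if (nrow(sim$truth$events) && (any(psi < 0) || any(psi > 1)))
    stop("PSI values must lie in [0, 1]")
  set.seed(params$seed + 3L)
  depth <- params$sj_depth
  ev <- sim$truth$events
  jx <- sim$truth$junctions

  all_keys <- if (!is.null(jx))
    junction_key(jx$contig, jx$donor, jx$acceptor, jx$strand) else character(0)
  motif_code <- function(cls, strand) {
    # STAR motif codes for the plus-strand dinucleotides
    if (cls == "GT-AG") return(if (strand == "+") 1L else 2L)
    if (cls == "GC-AG") return(if (strand == "+") 3L else 4L)
    if (cls == "AT-AC") return(if (strand == "+") 5L else 6L)
    0L
  }

  sj_out <- list(); cov_out <- list()
  for (s in seq_len(params$n_samples)) {
    support <- stats::setNames(rep(depth, length(all_keys)), all_keys)
    cov_rows <- list()
    if (nrow(ev)) {
      n_inc <- stats::rbinom(nrow(ev), depth, psi[, s])
      for (i in seq_len(nrow(ev))) {
        inc <- strsplit(ev$inclusion_junctions[i], ";", fixed = TRUE)[[1]]
        exc <- strsplit(ev$exclusion_junctions[i], ";", fixed = TRUE)[[1]]
        inc <- inc[nzchar(inc)]; exc <- exc[nzchar(exc)]
        support[inc] <- n_inc[i]
        support[exc] <- depth - n_inc[i]
        if (nzchar(ev$ir_intron[i])) {
          parts <- strsplit(ev$ir_intron[i], ":", fixed = TRUE)[[1]]
          da <- as.numeric(strsplit(parts[2], "-", fixed = TRUE)[[1]])
          cov_rows[[length(cov_rows) + 1L]] <- data.frame(
            contig = parts[1], donor = da[1], acceptor = da[2],
            strand = parts[3], support = n_inc[i], stringsAsFactors = FALSE)
        }
      }
    }
    sj_df <- if (!is.null(jx)) data.frame(
      contig = jx$contig, donor = jx$donor, acceptor = jx$acceptor,
      strand = jx$strand, support = as.numeric(support[all_keys]),
      motif_code = mapply(motif_code, jx$class, jx$strand),
      stringsAsFactors = FALSE)
    else data.frame(contig = character(0), donor = numeric(0),
                    acceptor = numeric(0), strand = character(0),
                    support = numeric(0))
    sj_out[[paste0("sample", s)]] <- sj_df
    cov_out[[paste0("sample", s)]] <- if (length(cov_rows))
      do.call(rbind, cov_rows) else
      data.frame(contig = character(0), donor = numeric(0),
                 acceptor = numeric(0), strand = character(0),
                 support = numeric(0))
  }
  list(sj = sj_out, intron_cov = cov_out)
}

#' Generate a complete synthetic data set
#'
#' Convenience wrapper chaining [make_genome()], [plant_genes()],
#' [simulate_fl_reads()] and [simulate_sj_counts()].
#'
#' @param params A [sim_params()] object.
#' @return List with `params`, `genome`, `models`, `truth`, `reads`,
#'   `read_info`, `alignments`, `sj`, `intron_cov`.
#' @export
simulate_dataset <- function(params = sim_params()) {
  genome <- make_genome(params)
  planted <- plant_genes(genome, params)
  reads <- simulate_fl_reads(planted, params)
  counts <- simulate_sj_counts(planted, params)
  c(list(params = params), planted, reads, counts)
}

#' Write a synthetic data set to disk
#'
#' Emits genome FASTA, annotation GTF, reads FASTA, per-read alignment BED12,
#' per-sample SJ tables and intron-coverage TSVs, and truth CSVs.
#'
#' @param dataset Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "annotation.gtf"),
    reads = file.path(dir, "reads.fa"),
    alignments = file.path(dir, "alignments.bed"))
  write_fasta(dataset$genome, paths$genome)
  write_gtf(dataset$models, paths$annotation)
  write_fasta(dataset$reads, paths$reads)
  write_bed12(dataset$alignments, paths$alignments)
  paths$sj <- character(0)
  paths$intron_cov <- character(0)
  for (s in names(dataset$sj)) {
    p <- file.path(dir, paste0("SJ_", s, ".tab"))
    write_sj_tab(dataset$sj[[s]], p)
    paths$sj <- c(paths$sj, p)
    pc <- file.path(dir, paste0("intron_cov_", s, ".tsv"))
    utils::write.table(dataset$intron_cov[[s]], pc, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$intron_cov <- c(paths$intron_cov, pc)
  }
  for (t in c("genes", "isoforms", "events", "sites", "junctions")) {
    p <- file.path(dir, paste0("truth_", t, ".csv"))
    utils::write.csv(dataset$truth[[t]], p, row.names = FALSE)
    paths[[paste0("truth_", t)]] <- p
  }
  p <- file.path(dir, "truth_psi.csv")
  utils::write.csv(dataset$truth$psi, p, row.names = TRUE)
  paths$truth_psi <- p
  p <- file.path(dir, "truth_reads.csv")
  utils::write.csv(dataset$read_info, p, row.names = FALSE)
  paths$truth_reads <- p
  paths
}
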