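# End-to-end orchestration: FLnc classification -> collapse -> junction QC
# -> AS catalog -> APA -> PSI/differential -> ORF/ncRNA, from one declarative
# config, with a machine-readable manifest of the count funnel.

#' Build a pipeline configuration
#'
#' @param genome,reads,alignments Paths to genome FASTA, read FASTA and
#'   spliced alignments (SAM or BED12) of the reads.
#' @param sj Character vector of SJ-tab paths (one per short-read sample).
#' @param intron_cov Optional character vector of intron-coverage TSVs
#'   parallel to `sj`.
#' @param out_dir Output directory.
#' @param seed Global seed (rarefaction subsampling, EM restarts).
#' @param flnc,collapse,junction,apa,psi,orf Named lists overriding stage
#'   parameters (see the stage functions for meanings and defaults).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, reads, alignments, sj = character(0),
                            intron_cov = NULL, out_dir = tempfile("isoatlas"),
                            seed = 1L, flnc = list(), collapse = list(),
                            junction = list(), apa = list(), psi = list(),
                            orf = list()) {
  defaults <- list(
    flnc = list(primer5 = "ATGCGGTACTTAGCCGTACGTTCAGGTCCA",
                primer3 = "GCAATGCCGTTAGACCTGTTCAGCCAGTAC",
                min_polya = 20L, max_edits = 3L, window = 100L),
    collapse = list(min_coverage = 0.8, min_identity = 0.7, tol3 = 100,
                    single_exon_overlap = 0.5),
    junction = list(min_support = 1L),
    apa = list(cluster_window = 24L, min_support = 1L, flank = 30L,
               upstream_len = 50L, motif_width = 6L, motif_mode = "hexamer"),
    psi = list(min_delta = 0.20, min_bf = 10),
    orf = list(min_aa = 100L))
  cfg <- list(genome = genome, reads = reads, alignments = alignments,
              sj = sj, intron_cov = intron_cov, out_dir = out_dir,
              seed = as.integer(seed),
              flnc = utils::modifyList(defaults$flnc, flnc),
              collapse = utils::modifyList(defaults$collapse, collapse),
              junction = utils::modifyList(defaults$junction, junction),
              apa = utils::modifyList(defaults$apa, apa),
              psi = utils::modifyList(defaults$psi, psi),
              orf = utils::modifyList(defaults$orf, orf))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with the fields of [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

validate_config <- function(cfg) {
  for (f in c("genome", "reads", "alignments")) {
    if (!file.exists(cfg[[f]])) stop("missing input file (", f, "): ",
                                     cfg[[f]])
  }
  for (p in c(cfg$sj, cfg$intron_cov))
    if (!file.exists(p)) stop("missing input file: ", p)
  invisible(cfg)
}

stage_msg <- function(...) message("[isoatlas] ", ...)

#' Run the full pipeline
#'
#' Executes FLnc classification, isoform collapse, junction QC, AS event
#' detection, APA analysis, PSI/differential quantification and ORF/ncRNA
#' flagging in order, writing each stage's outputs before the next starts,
#' and returns a manifest with the count funnel
#' (reads -> FLnc -> non-redundant isoforms -> filtered isoforms -> loci ->
#' events).
#'
#' @param cfg A `pipeline_config` (or path to a YAML config).
#' @return The manifest (invisibly written to `manifest.json` in the output
#'   directory).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  validate_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(cfg$out_dir, name)
  manifest <- list(parameters = cfg[c("flnc", "collapse", "junction", "apa",
                                      "psi", "orf", "seed")],
                   funnel = list(), outputs = list())

  stage_msg("reading genome and reads")
  genome <- read_fasta(cfg$genome)
  reads <- read_fasta(cfg$reads)
  manifest$funnel$reads <- length(reads)

  stage_msg("stage flnc: classifying ", length(reads), " reads")
  fl <- classify_reads(reads, cfg$flnc$primer5, cfg$flnc$primer3,
                       cfg$flnc$min_polya, cfg$flnc$max_edits,
                       cfg$flnc$window)
  utils::write.table(fl$report, out("flnc_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(fl$inserts)) write_fasta(fl$inserts, out("flnc.fa"))
  flnc_ids <- fl$report$read[fl$report$category == "FLnc"]
  manifest$funnel$flnc <- length(flnc_ids)
  manifest$outputs$flnc <- out("flnc_report.tsv")

  stage_msg("stage collapse: ", length(flnc_ids), " FLnc alignments")
  aln <- read_alignments(cfg$alignments)
  aln <- aln[names(aln) %in% flnc_ids]
  cp <- collapse_params(min_coverage = cfg$collapse$min_coverage,
                        min_identity = cfg$collapse$min_identity,
                        tol3 = cfg$collapse$tol3,
                        single_exon_overlap = cfg$collapse$single_exon_overlap)
  aln <- filter_alignments(aln, cp)
  clusters <- collapse_isoforms(aln, cp)
  manifest$funnel$isoforms <- length(clusters)
  abundance <- data.frame(
    cluster = names(clusters),
    fl_count = vapply(clusters, `[[`, 0L, "fl_count"))
  utils::write.table(abundance, out("abundance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gtf(lapply(clusters, `[[`, "model"), out("collapsed.gtf"))
  manifest$outputs$collapsed <- out("collapsed.gtf")

  stage_msg("stage junction_qc")
  jx <- extract_junctions(clusters, genome)
  sj_samples <- lapply(cfg$sj, read_sj_tab)
  names(sj_samples) <- if (length(cfg$sj))
    paste0("sample", seq_along(cfg$sj)) else character(0)
  jx <- attach_support(jx, sj_samples)
  utils::write.table(jx, out("junctions.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  filt <- filter_isoforms(clusters, jx, cfg$junction$min_support)
  utils::write.table(filt$report, out("junction_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  kept <- filt$kept
  manifest$funnel$filtered_isoforms <- length(kept)
  write_gtf(lapply(kept, `[[`, "model"), out("filtered.gtf"))
  manifest$outputs$filtered <- out("filtered.gtf")

  stage_msg("assigning loci")
  loci <- assign_loci(kept)
  manifest$funnel$loci <- length(loci)
  cluster_locus <- do.call(rbind, lapply(loci, function(l)
    data.frame(cluster = l$cluster_ids, locus = l$id)))
  utils::write.table(cluster_locus, out("loci.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # rarefaction on the read -> cluster -> locus map
  read_map <- do.call(rbind, lapply(names(kept), function(cid)
    data.frame(read = kept[[cid]]$members, cluster = cid)))
  read_map$locus <- cluster_locus$locus[match(read_map$cluster,
                                              cluster_locus$cluster)]
  rar <- rarefaction(read_map, seed = cfg$seed)
  utils::write.csv(rar, out("rarefaction.csv"), row.names = FALSE)

  stage_msg("stage as_catalog")
  events <- detect_events_all(loci)
  utils::write.table(events, out("events.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(summarize_types(events), out("event_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(isoform_histogram(loci), out("isoform_histogram.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$funnel$events <- nrow(events)
  manifest$outputs$events <- out("events.tsv")

  stage_msg("stage apa")
  aln_by_read <- aln[names(aln) %in% unlist(lapply(kept, `[[`, "members"))]
  read_cluster <- read_map$cluster[match(names(aln_by_read), read_map$read)]
  read_locus <- read_map$locus[match(names(aln_by_read), read_map$read)]
  ends <- data.frame(
    gene = read_locus,
    contig = vapply(aln_by_read, `[[`, "", "contig"),
    strand = vapply(aln_by_read, `[[`, "", "strand"),
    pos = vapply(aln_by_read, tx_end3, numeric(1)),
    stringsAsFactors = FALSE)
  sites <- call_polya_sites(ends, genome, cfg$apa$cluster_window,
                            cfg$apa$min_support)
  utils::write.table(sites, out("polya_sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  apa <- apa_summary(sites)
  utils::write.table(apa$per_gene, out("apa_per_gene.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  prof <- nucleotide_profile(sites[!sites$internal_priming, , drop = FALSE],
                             genome, cfg$apa$flank)
  utils::write.csv(as.data.frame(prof), out("polya_profile.csv"))
  ups <- upstream_windows(sites[!sites$internal_priming, , drop = FALSE],
                          genome, cfg$apa$upstream_len)
  motif <- if (length(ups))
    find_signal_motif(ups, cfg$apa$motif_width, cfg$apa$motif_mode,
                      seed = cfg$seed) else NULL
  if (!is.null(motif)) {
    utils::write.csv(as.data.frame(motif$pwm), out("polya_motif_pwm.csv"))
    utils::write.csv(data.frame(offset = motif$offsets),
                     out("polya_motif_offsets.csv"), row.names = FALSE)
  }
  manifest$outputs$polya_sites <- out("polya_sites.tsv")
  manifest$apa <- list(n_sites = nrow(sites), n_genes = apa$n_genes,
                       n_apa_genes = apa$n_apa_genes,
                       mean_sites_per_gene = apa$mean_sites_per_gene,
                       signal_consensus = if (!is.null(motif))
                         motif$consensus else NA)

  stage_msg("stage splice_quant")
  cov_samples <- NULL
  if (!is.null(cfg$intron_cov)) {
    cov_samples <- lapply(cfg$intron_cov, function(p)
      utils::read.table(p, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE))
    names(cov_samples) <- names(sj_samples)[seq_along(cov_samples)]
  }
  psi <- NULL
  if (nrow(events) && length(sj_samples)) {
    psi <- psi_table(events, sj_samples, cov_samples)
    utils::write.table(psi, out("psi.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (length(sj_samples) >= 2L) {
      dif <- differential_table(psi, names(sj_samples)[1L],
                                names(sj_samples)[2L],
                                min_delta = cfg$psi$min_delta,
                                min_bf = cfg$psi$min_bf)
      utils::write.table(dif, out("differential.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      manifest$differential_events <- sum(dif$passes)
    }
  }

  stage_msg("stage orf_ncrna")
  orfs_by_cluster <- lapply(kept, function(cl)
    find_orfs(spliced_seq(genome, cl$model), cfg$orf$min_aa))
  orf_rows <- do.call(rbind, lapply(names(orfs_by_cluster), function(cid) {
    o <- orfs_by_cluster[[cid]]
    if (nrow(o) == 0L) return(NULL)
    cbind(data.frame(cluster = cid), o)
  }))
  if (!is.null(orf_rows))
    utils::write.table(orf_rows, out("orfs.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  locus_len <- vapply(loci, function(l)
    max(vapply(l$clusters, function(cl) tx_length(cl$model), numeric(1))),
    numeric(1))
  locus_orf <- vapply(loci, function(l)
    any(vapply(l$cluster_ids, function(cid)
      nrow(orfs_by_cluster[[cid]]) > 0L, logical(1))), logical(1))
  nc <- flag_ncrna(locus_len, locus_orf)
  utils::write.table(nc, out("ncrna_flags.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest$ncrna <- as.list(table(nc$category))

  manifest$outputs$manifest <- out("manifest.json")
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  stage_msg("done: ", cfg$out_dir)
  invisible(manifest)
}

#' Generate a synthetic data set and run the full pipeline on it
#'
#' @param out_dir Output directory (data under `data/`, results under
#'   `results/`).
#' @param seed Seed for both the generator and the pipeline.
#' @param params Optional [sim_params()] (its seed is overridden by `seed`).
#' @return List: `manifest`, `truth`, `dataset`, `paths`, and `expected`
#'   (the funnel implied by the truth tables).
#' @export
isoatlas_demo <- function(out_dir = tempfile("isoatlas_demo"), seed = 42L,
                          params = NULL) {
  if (is.null(params)) params <- sim_params(seed = seed)
  else params$seed <- as.integer(seed)
  dataset <- simulate_dataset(params)
  data_dir <- file.path(out_dir, "data")
  paths <- write_dataset(dataset, data_dir)
  cfg <- pipeline_config(
    genome = paths$genome, reads = paths$reads,
    alignments = paths$alignments, sj = paths$sj,
    intron_cov = paths$intron_cov,
    out_dir = file.path(out_dir, "results"), seed = seed,
    flnc = list(primer5 = params$primer5, primer3 = params$primer3))
  manifest <- run_pipeline(cfg)
  list(manifest = manifest, truth = dataset$truth, dataset = dataset,
       paths = paths, expected = expected_funnel(dataset))
}

#' Funnel counts implied by a synthetic truth table
#'
#' The reference expectation for the demo manifest: reads and FLnc reads
#' from the read table, isoforms as those with at least one FLnc read,
#' loci as genes with at least one observed isoform, and events as planted
#' events whose two witness isoforms are both observed.
#'
#' @param dataset Result of [simulate_dataset()].
#' @return Named list of expected funnel counts.
#' @export
expected_funnel <- function(dataset) {
  info <- dataset$read_info
  obs_iso <- unique(info$isoform[info$flnc])
  obs_gene <- unique(info$gene[info$flnc])
  ev <- dataset$truth$events
  ev_ok <- if (nrow(ev)) sum(ev$inclusion_isoform %in% obs_iso &
                               ev$exclusion_isoform %in% obs_iso) else 0L
  list(reads = nrow(info), flnc = sum(info$flnc),
       isoforms = length(obs_iso), filtered_isoforms = length(obs_iso),
       loci = length(obs_gene), events = ev_ok)
}
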