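test_that("genome generation is seeded, composition-controlled bookkeeping", {
  p <- sim_params(seed = 1, contig_lengths = c(c1 = 10000))
  g1 <- make_genome(p)
  g2 <- make_genome(p)
  expect_identical(g1, g2)                    # seeded determinism
  gc <- mean(strsplit(g1[[1]], NULL)[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - p$gc), 0.02)

  pure <- make_genome(sim_params(seed = 2, gc = 1,
                                 contig_lengths = c(c1 = 2000)))
  expect_true(all(strsplit(pure[[1]], NULL)[[1]] %in% c("G", "C")))

  two <- make_genome(sim_params(seed = 3,
                                contig_lengths = c(a = 5000, b = 5000)))
  expect_equal(unname(nchar(two)), c(5000, 5000))
  expect_equal(names(two), c("a", "b"))

  expect_error(make_genome(sim_params(contig_lengths = c(a = -5))),
               "positive")
})

test_that("sim_params validates proportions and counts", {
  expect_error(sim_params(as_mix = c(IR = 0.5, AA = 0.2, AD = 0.2,
                                     ES = 0.2, MX = 0.2)), "sum to 1")
  expect_error(sim_params(fl_depth = -1), ">= 0|fractions|counts")
  expect_error(sim_params(nfl_frac = 1.5), "fractions")
})

test_that("planted genes realise the requested AS mix and motifs", {
  p <- sim_params(seed = 5, n_genes = 10, frac_single_exon = 0,
                  iso_dist = c(0, 1), as_mix = c(IR = 1, AA = 0, AD = 0,
                                                 ES = 0, MX = 0))
  sim <- plant_genes(make_genome(p), p)
  expect_equal(nrow(sim$truth$events), 10)
  expect_true(all(sim$truth$events$type == "IR"))

  # all intron dinucleotides canonical on the transcribed strand
  jx <- extract_junctions(sim$models, sim$genome)
  expect_true(all(jx$motif_class == "GT-AG"))

  # AATAAA hexamer at cleavage-30..-25 for every signal-bearing site
  for (i in seq_len(nrow(sim$truth$sites))) {
    s <- sim$truth$sites[i, ]
    contig <- sim$genome[[s$contig]]
    hex <- if (s$strand == "+")
      substr(contig, s$position - 29, s$position - 24)
    else revcomp(substr(contig, s$position + 25, s$position + 30))
    expect_equal(unname(hex), "AATAAA")
  }
})

test_that("planted non-canonical fractions carry their declared classes", {
  p <- sim_params(seed = 8, n_genes = 12, frac_noncanonical = 0.5,
                  frac_single_exon = 0)
  sim <- plant_genes(make_genome(p), p)
  jx <- extract_junctions(sim$models, sim$genome)
  tj <- sim$truth$junctions
  m <- match(paste(tj$donor, tj$acceptor),
             paste(jx$donor, jx$acceptor))
  expect_true(all(tj$class == jx$motif_class[m]))
  expect_gt(sum(tj$class != "GT-AG"), 0)
})

test_that("capacity errors surface when the genome cannot hold the genes", {
  p <- sim_params(seed = 1, n_genes = 10, contig_lengths = c(tiny = 2000))
  expect_error(plant_genes(make_genome(p), p), "insufficient genome space")
})

test_that("read simulation respects depth, truncation and nFL bookkeeping", {
  p <- sim_params(seed = 6, n_genes = 3, frac_single_exon = 0,
                  iso_dist = c(1), fl_depth = 20, nfl_frac = 0,
                  max_trunc_frac = 0)
  sim <- plant_genes(make_genome(p), p)
  reads <- simulate_fl_reads(sim, p)
  expect_equal(length(reads$reads), 3 * 20)   # depth bookkeeping
  expect_true(all(reads$read_info$flnc))
  expect_true(all(reads$read_info$truncation == 0))
  # truncation 0: insert equals the source transcript exactly
  i <- 1
  iso <- reads$read_info$isoform[i]
  full <- spliced_seq(sim$genome, sim$models[[iso]])
  r <- reads$reads[[reads$read_info$read[i]]]
  if (reads$read_info$flipped[i]) r <- revcomp(r)
  expect_equal(substr(r, nchar(p$primer5) + 1,
                      nchar(p$primer5) + nchar(full)), full)
})

test_that("generator output is byte-identical under a fixed seed", {
  p <- sim_params(seed = 9, n_genes = 4)
  d1 <- simulate_dataset(p)
  d2 <- simulate_dataset(p)
  expect_identical(d1$genome, d2$genome)
  expect_identical(d1$reads, d2$reads)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$sj, d2$sj)

  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  p1 <- write_dataset(d1, dir1); p2 <- write_dataset(d2, dir2)
  for (f in c("genome", "annotation", "reads", "alignments"))
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  expect_identical(readLines(p1$sj[1]), readLines(p2$sj[1]))
})

test_that("junction counts follow Binomial(depth, PSI) semantics", {
  p <- sim_params(seed = 10, n_genes = 6, frac_single_exon = 0,
                  iso_dist = c(0, 1), sj_depth = 10000, n_samples = 1,
                  p_differential = 0)
  sim <- plant_genes(make_genome(p), p)
  sim$truth$psi[] <- 0.5
  counts <- simulate_sj_counts(sim, p)
  ev <- sim$truth$events
  sj <- counts$sj$sample1
  key <- junction_key <- paste0(sj$contig, ":", sj$donor, "-", sj$acceptor,
                                ":", sj$strand)
  for (i in seq_len(nrow(ev))) {
    exc <- strsplit(ev$exclusion_junctions[i], ";")[[1]][1]
    n_exc <- sj$support[key == exc]
    frac_inc <- (10000 - n_exc) / 10000
    # exact binomial tail bound: P(|X/n - 0.5| > 0.01) < 1e-8 at n = 10000
    expect_gt(frac_inc, 0.49)
    expect_lt(frac_inc, 0.51)
  }

  # degenerate PSI values force degenerate counts
  sim$truth$psi[] <- 1
  c1 <- simulate_sj_counts(sim, p)
  for (i in seq_len(nrow(ev))) {
    exc <- strsplit(ev$exclusion_junctions[i], ";")[[1]][1]
    expect_equal(c1$sj$sample1$support[key == exc], 0)
  }
  sim$truth$psi[] <- 0
  c0 <- simulate_sj_counts(sim, p)
  inc_keys <- unlist(strsplit(ev$inclusion_junctions, ";"))
  inc_keys <- inc_keys[nzchar(inc_keys)]
  expect_true(all(c0$sj$sample1$support[key %in% inc_keys] == 0))

  sim$truth$psi[] <- 1.5
  expect_error(simulate_sj_counts(sim, p), "\\[0, 1\\]")
})

test_that("nFL fraction 0 closes the loop with the FLnc classifier", {
  p <- sim_params(seed = 12, n_genes = 3, nfl_frac = 0, fl_depth = 5)
  ds <- simulate_dataset(p)
  cl <- classify_reads(ds$reads, p$primer5, p$primer3)
  expect_true(all(cl$report$category == "FLnc"))
})
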