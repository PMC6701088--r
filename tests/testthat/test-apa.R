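flat_genome <- function(n = 3000) c(chrA = strrep("C", n))

test_that("3' ends cluster to the modal position with distal tie-breaks", {
  g <- flat_genome()
  ends <- data.frame(gene = "g1", contig = "chrA", strand = "+",
                     pos = rep(c(1000, 1001, 1002), c(4, 3, 3)))
  s <- call_polya_sites(ends, g)
  expect_equal(nrow(s), 1)
  expect_equal(s$position, 1000)     # mode within the window
  expect_equal(s$support, 10)

  # tie at 4:4 resolves to the most distal 3' position
  tie <- data.frame(gene = "g1", contig = "chrA", strand = "+",
                    pos = rep(c(1000, 1002), c(4, 4)))
  expect_equal(call_polya_sites(tie, g)$position, 1002)
  tie$strand <- "-"
  expect_equal(call_polya_sites(tie, g)$position, 1000)
})

test_that("gaps above the cluster window split sites", {
  g <- flat_genome()
  ends <- data.frame(gene = "g1", contig = "chrA", strand = "+",
                     pos = c(rep(1000, 3), rep(1050, 2)))
  s <- call_polya_sites(ends, g, cluster_window = 24)
  expect_equal(nrow(s), 2)
  expect_equal(sort(s$position), c(1000, 1050))
  expect_equal(sum(s$support), nrow(ends))  # conservation at min_support 1
})

test_that("A-rich downstream tracts are flagged as internal priming", {
  g <- c(chrA = paste0(strrep("C", 1000), strrep("A", 15), strrep("C", 100)))
  ends <- data.frame(gene = "g1", contig = "chrA", strand = "+", pos = 1000)
  expect_true(call_polya_sites(ends, g)$internal_priming)
  # 11 A's scattered (below 12/20) and runs < 8: not flagged
  g2 <- c(chrA = paste0(strrep("C", 1000),
                        strrep("AC", 10), "A", strrep("C", 100)))
  expect_false(call_polya_sites(ends, g2)$internal_priming)
  expect_error(call_polya_sites(
    data.frame(gene = "g", contig = "nope", strand = "+", pos = 5), g),
    "contig")
})

test_that("APA summaries count sites per gene and flag APA genes", {
  sites <- data.frame(gene = rep(c("g1", "g2", "g3"), c(1, 2, 5)),
                      contig = "chrA", strand = "+",
                      position = 1:8 * 100, support = 1,
                      internal_priming = FALSE)
  s <- apa_summary(sites)
  expect_equal(s$n_apa_genes, 2)
  expect_equal(s$mean_sites_per_gene, 8 / 3)
  expect_equal(s$total_over_genes, 8 / 3)
  expect_equal(s$distribution$n_genes,
               c(1, 1, 0, 0, 1))  # buckets 1,2,3,4,>=5

  none <- apa_summary(sites[1, , drop = FALSE])
  expect_equal(none$n_apa_genes, 0)
  empty <- apa_summary(sites[0, , drop = FALSE])
  expect_equal(empty$n_genes, 0)
})

test_that("nucleotide profiles are strand-aware indicators for one site", {
  # genome: ...TTTTT | cleavage | GGGGG...
  g <- c(chrA = paste0(strrep("T", 50), strrep("G", 50)))
  plus <- data.frame(gene = "g", contig = "chrA", strand = "+",
                     position = 50, support = 1, internal_priming = FALSE)
  prof <- nucleotide_profile(plus, g, flank = 5)
  expect_equal(unname(prof["T", as.character(-5:-1)]), rep(1, 5))
  expect_equal(unname(prof["G", as.character(0:5)]), rep(1, 6))
  expect_true(all(abs(colSums(prof) - 1) < 1e-12))

  # minus strand: upstream bases are the revcomp side
  g2 <- c(chrA = paste0(strrep("C", 50), strrep("A", 50)))
  minus <- data.frame(gene = "g", contig = "chrA", strand = "-",
                      position = 50, support = 1, internal_priming = FALSE)
  prof2 <- nucleotide_profile(minus, g2, flank = 5)
  expect_equal(unname(prof2["T", as.character(-5:-1)]), rep(1, 5))  # revcomp A
  expect_equal(unname(prof2["G", as.character(0:5)]), rep(1, 6))   # revcomp C
})

test_that("profile asymmetry of planted sites shows downstream-A enrichment", {
  p <- sim_params(seed = 51, n_genes = 15)
  sim <- plant_genes(make_genome(p), p)
  sites <- data.frame(gene = sim$truth$sites$gene,
                      contig = sim$truth$sites$contig,
                      strand = sim$truth$sites$strand,
                      position = sim$truth$sites$position,
                      support = 1, internal_priming = FALSE)
  prof <- nucleotide_profile(sites, sim$genome, flank = 10)
  upA <- mean(prof["A", as.character(-10:-1)])
  dnA <- mean(prof["A", as.character(1:10)])
  upT <- mean(prof["T", as.character(-10:-1)])
  expect_gt(dnA, upA)   # direct-counting oracle of the generator design
  expect_gt(upT, 0.4)
})

test_that("hexamer counting recovers a planted AATAAA at offset 25", {
  set.seed(52)
  seqs <- vapply(1:40, function(i) {
    s <- paste(sample(c("C", "G", "T"), 50, TRUE), collapse = "")
    substr(s, 21, 26) <- "AATAAA"
    s
  }, "")
  m <- find_signal_motif(seqs, 6, "hexamer")
  expect_equal(m$consensus, "AATAAA")
  expect_true(all(m$offsets == 25))
  expect_true(all(abs(colSums(m$pwm) - 1) < 1e-9))
})

test_that("width equal to sequence length degenerates to base frequencies", {
  seqs <- c("AATAAA", "AATAAA", "CATAAA")
  m <- find_signal_motif(seqs, 6, "hexamer")
  expect_equal(m$consensus, "AATAAA")
  expect_true(all(m$offsets[1:2] == 1))
  expect_error(find_signal_motif(c("ACGT"), 6), "at least")
})

test_that("EM mode is seeded-deterministic, monotone, and finds the signal", {
  set.seed(53)
  seqs <- vapply(1:30, function(i) {
    s <- paste(sample(c("C", "G", "T"), 50, TRUE), collapse = "")
    substr(s, 21, 26) <- "AATAAA"
    s
  }, "")
  m1 <- find_signal_motif(seqs, 6, "em", seed = 3)
  m2 <- find_signal_motif(seqs, 6, "em", seed = 3)
  expect_identical(m1$pwm, m2$pwm)
  expect_equal(m1$consensus, "AATAAA")
  expect_true(all(diff(m1$objective_trace) > -1e-8))  # monotone EM objective
  modal <- as.integer(names(which.max(table(m1$offsets))))
  expect_lte(abs(modal - 25), 2)
})

test_that("upstream windows end exactly at the cleavage position", {
  g <- c(chrA = paste0(strrep("C", 90), "AATAAA", strrep("G", 30),
                       strrep("T", 50)))
  # plus site at 120: upstream window covers the hexamer at offset 25
  sites <- data.frame(gene = "g", contig = "chrA", strand = "+",
                      position = 120, support = 1, internal_priming = FALSE)
  w <- upstream_windows(sites, g, 50)
  expect_equal(nchar(w), 50)
  expect_equal(substr(w, 21, 26), "AATAAA")
})
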