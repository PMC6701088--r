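codon_seq <- function(n, codon = "GCT") strrep(codon, n)

test_that("ORF detection enforces the 100-aa boundary exactly", {
  # aa_length counts the initiator Met and excludes the stop:
  # ATG + 99 codons + TAA is a 100-aa ORF
  s100 <- paste0("ATG", codon_seq(99), "TAA")
  orfs <- find_orfs(s100, min_aa = 100)
  expect_equal(nrow(orfs), 1)
  expect_equal(orfs$aa_length, 100)
  expect_equal(orfs$start, 0)
  expect_equal(orfs$end, nchar(s100))
  expect_equal((orfs$end - orfs$start) %% 3, 0)

  s99 <- paste0("ATG", codon_seq(98), "TAA")
  expect_equal(nrow(find_orfs(s99, min_aa = 100)), 0)
})

test_that("ORFs require a stop and use the 5'-most ATG per stop", {
  no_stop <- paste0("ATG", codon_seq(150))
  expect_equal(nrow(find_orfs(no_stop, min_aa = 100)), 0)
  expect_equal(nrow(find_orfs(strrep("C", 600), min_aa = 1)), 0)  # no ATG

  # two in-frame ATGs before one stop: the 5'-most wins
  s <- paste0("ATG", codon_seq(5), "ATG", codon_seq(110), "TAA")
  orfs <- find_orfs(s, min_aa = 100)
  expect_equal(nrow(orfs), 1)
  expect_equal(orfs$start, 0)
})

test_that("all three frames are scanned", {
  for (off in 0:2) {
    s <- paste0(strrep("C", off), "ATG", codon_seq(120), "TGA")
    orfs <- find_orfs(s, min_aa = 100)
    expect_equal(orfs$frame, off)
    expect_equal(orfs$start, off)
  }
})

test_that("output is invariant to sequence appended after the stop", {
  s <- paste0("ATG", codon_seq(120), "TAA")
  o1 <- find_orfs(s, min_aa = 100)
  o2 <- find_orfs(paste0(s, "CCCCGGGTTTACG"), min_aa = 100)
  expect_equal(o1[, c("frame", "start", "end", "aa_length")],
               o2[, c("frame", "start", "end", "aa_length")])
})

test_that("representative ORF is the 5'-most, longest on ties", {
  orfs <- data.frame(frame = c(1, 0), start = c(10, 400), end = c(340, 730),
                     aa_length = c(109, 109), strand = "+")
  expect_equal(representative_orf(orfs)$start, 10)

  ties <- data.frame(frame = 0, start = c(10, 10), end = c(373, 463),
                     aa_length = c(120, 150), strand = "+")
  expect_equal(representative_orf(ties)$aa_length, 150)
  expect_error(representative_orf(orfs[0, ]), "no ORFs")
})

test_that("locus representative has the longest ORF, smaller id on ties", {
  mk <- function(aa) data.frame(frame = 0, start = 0, end = 3 * (aa + 1),
                                aa_length = aa, strand = "+")
  expect_equal(locus_representative(list(i1 = mk(150), i2 = mk(300))), "i2")
  expect_equal(locus_representative(list(only = mk(120))), "only")
  expect_equal(locus_representative(list(b = mk(200), a = mk(200))), "a")
  empty <- data.frame(frame = integer(0), start = integer(0),
                      end = integer(0), aa_length = integer(0),
                      strand = character(0))
  expect_error(locus_representative(list(x = empty)), "no coding")
})

test_that("identical Markov models score zero and log-likelihoods add", {
  set.seed(71)
  train <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""), "")
  m <- train_markov(train, order = 5)
  orf <- data.frame(start = 0, end = 60)
  s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  expect_equal(markov_score(s, orf, m, m), 0)

  # per-position log-likelihoods sum to the total (additivity)
  ll <- markov_loglik(s, m)
  expect_equal(sum(ll[1:30]) + sum(ll[31:60]), sum(ll), tolerance = 1e-9)
  expect_error(markov_score("ACG", data.frame(start = 0, end = 3), m, m),
               "order")
})

test_that("coding bias separates true ORFs from shuffled ones", {
  set.seed(72)
  bc <- isoatlas:::biased_codons()
  coding <- vapply(1:30, function(i)
    paste(sample(bc$codons, 150, TRUE, bc$weights), collapse = ""), "")
  background <- vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T"), 450, TRUE), collapse = ""), "")
  cm <- train_markov(coding, 5)
  bm <- train_markov(background, 5)
  score <- function(s) markov_score(s, data.frame(start = 0, end = nchar(s)),
                                    cm, bm)
  true_orfs <- vapply(1:15, function(i)
    paste(sample(bc$codons, 120, TRUE, bc$weights), collapse = ""), "")
  shuffled <- vapply(true_orfs, function(s)
    paste(sample(strsplit(s, NULL)[[1]]), collapse = ""), "")
  expect_gt(mean(vapply(true_orfs, score, 0)),
            mean(vapply(shuffled, score, 0)))
})

test_that("ncRNA flags partition loci by the ORF and 200-nt rules", {
  lens <- c(L1 = 1500, L2 = 180, L3 = 900, L4 = 201)
  orf <- c(L1 = FALSE, L2 = FALSE, L3 = TRUE, L4 = FALSE)
  fl <- flag_ncrna(lens, orf)
  expect_equal(fl$category[fl$locus == "L1"], "lncRNA-candidate")
  expect_equal(fl$category[fl$locus == "L2"], "short-ncRNA-candidate")
  expect_equal(fl$category[fl$locus == "L3"], "coding")
  expect_equal(fl$category[fl$locus == "L4"], "lncRNA-candidate")  # > 200 nt
  # exactly one category per locus
  expect_equal(nrow(fl), 4)
  expect_true(all(fl$category %in% c("coding", "lncRNA-candidate",
                                     "short-ncRNA-candidate")))
  # the 200-nt rule boundary: exactly 200 is not a lncRNA candidate
  b <- flag_ncrna(c(Lx = 200), c(Lx = FALSE))
  expect_equal(b$category, "short-ncRNA-candidate")
})

test_that("planted ORFs in the generator are recovered as coding", {
  p <- sim_params(seed = 73, n_genes = 8, frac_coding = 1,
                  frac_single_exon = 0)
  sim <- plant_genes(make_genome(p), p)
  planted <- sim$truth$genes$gene[sim$truth$genes$orf_planted]
  expect_gt(length(planted), 0)
  for (g in planted) {
    iso <- sim$truth$isoforms$isoform[sim$truth$isoforms$gene == g][1]
    orfs <- find_orfs(spliced_seq(sim$genome, sim$models[[iso]]),
                      min_aa = 100)
    expect_gt(nrow(orfs), 0)
  }
})
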