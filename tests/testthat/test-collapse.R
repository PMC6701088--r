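test_that("alignment filter applies inclusive coverage/identity thresholds", {
  mk <- function(id, cov, ident)
    transcript_model(id, "chr1", "+", cbind(0, 100),
                     coverage = cov, identity = ident)
  models <- list(mk("a", 0.85, 0.75), mk("b", 0.79, 0.99),
                 mk("c", 0.80, 0.70), mk("d", 0.9, 0.69),
                 mk("e", NA, NA))
  kept <- filter_alignments(models, collapse_params())
  expect_setequal(vapply(kept, `[[`, "", "id"), c("a", "c", "e"))
  expect_equal(attr(kept, "discarded"), 2)

  nomet <- list(structure(list(id = "x", contig = "chr1", strand = "+",
                               exons = cbind(0, 100)),
                          class = "transcript_model"))
  expect_error(filter_alignments(nomet), "coverage metadata")
})

test_that("identical intron chains merge regardless of 5' differences", {
  a <- tm("a", list(c(0, 100), c(200, 300)))
  b <- tm("b", list(c(300 - 300, 100), c(200, 300)))  # same chain
  b <- tm("b", list(c(80, 100), c(200, 300)))         # 5' start differs by 80
  c_ <- tm("c", list(c(0, 100), c(200, 800)))         # 3' end differs by 500
  cl <- collapse_isoforms(list(a = a, b = b, c = c_))
  expect_equal(length(cl), 2)
  big <- cl[[which(vapply(cl, `[[`, 0L, "fl_count") == 2)]]
  expect_setequal(big$members, c("a", "b"))
  # representative spans the widest extent
  expect_equal(tx_span(big$model), c(0, 300))
})

test_that("3' ends within tolerance merge; beyond they stay distinct", {
  a <- tm("a", list(c(0, 100), c(200, 300)))
  b <- tm("b", list(c(0, 100), c(200, 390)))   # 3' diff 90 <= 100
  cl <- collapse_isoforms(list(a = a, b = b))
  expect_equal(length(cl), 1)
  expect_equal(tx_span(cl[[1]]$model), c(0, 390))

  c_ <- tm("c", list(c(0, 100), c(200, 410)))  # 110 > 100 from a
  cl2 <- collapse_isoforms(list(a = a, c = c_))
  expect_equal(length(cl2), 2)
})

test_that("single-exon reads merge by reciprocal overlap", {
  a <- tm("a", list(c(0, 100)))
  b <- tm("b", list(c(40, 140)))   # reciprocal overlap 0.6
  c_ <- tm("c", list(c(90, 290)))  # overlap 10/100 and 10/200
  d <- tm("d", list(c(0, 100)), strand = "-")
  cl <- collapse_isoforms(list(a = a, b = b, c = c_, d = d))
  members <- lapply(cl, `[[`, "members")
  expect_equal(length(cl), 3)
  expect_true(any(vapply(members, function(m) setequal(m, c("a", "b")),
                         TRUE)))
})

test_that("reads from planted isoforms collapse back to them exactly", {
  p <- sim_params(seed = 31, n_genes = 1, frac_single_exon = 0,
                  iso_dist = c(0, 0, 1), fl_depth = 67, nfl_frac = 0,
                  p_apa = 0)
  ds <- simulate_dataset(p)
  expect_equal(length(ds$models), 3)
  expect_gte(length(ds$reads), 200)
  cl <- collapse_isoforms(ds$alignments)
  expect_equal(length(cl), 3)                                   # 3 clusters
  expect_equal(sum(vapply(cl, `[[`, 0L, "fl_count")), 201)      # conservation
  # idempotence: collapsing the representatives again changes nothing
  reps <- lapply(cl, `[[`, "model")
  cl2 <- collapse_isoforms(reps)
  expect_equal(length(cl2), length(cl))
  expect_equal(lapply(cl2, function(x) x$model$exons),
               lapply(cl, function(x) x$model$exons))
})

test_that("empty input collapses to an empty cluster set", {
  expect_equal(length(collapse_isoforms(list())), 0)
})

test_that("loci are connected components of same-strand exonic overlap", {
  mk <- function(id, exons, strand = "+")
    list(id = id, model = tm(id, exons, strand = strand), members = id,
         fl_count = 1L)
  cl <- structure(list(
    A = mk("A", list(c(0, 100), c(200, 300))),
    B = mk("B", list(c(250, 400))),            # overlaps A's second exon
    C = mk("C", list(c(390, 500))),            # overlaps B, not A
    D = mk("D", list(c(0, 100)), strand = "-"),# same span, opposite strand
    E = mk("E", list(c(1000, 1100)))),
    class = "isoform_clusters")
  loci <- assign_loci(cl)
  expect_equal(length(loci), 3)
  sets <- lapply(loci, `[[`, "cluster_ids")
  expect_true(any(vapply(sets, function(s) setequal(s, c("A", "B", "C")),
                         TRUE)))  # transitive closure A~B~C
  expect_true(any(vapply(sets, function(s) setequal(s, "D"), TRUE)))
  # partition: each cluster in exactly one locus
  expect_setequal(unlist(sets), names(cl))
  expect_equal(length(unlist(sets)), length(cl))
})

test_that("rarefaction is exact at fraction 1 and rejects bad fractions", {
  asg <- data.frame(read = paste0("r", 1:10),
                    cluster = rep(c("c1", "c2", "c3"), c(5, 3, 2)),
                    locus = rep(c("l1", "l2"), c(8, 2)))
  out <- rarefaction(asg, fractions = 1, reps = 10, seed = 1)
  expect_equal(out$mean_clusters, 3)
  expect_equal(out$sd_clusters, 0)
  expect_equal(out$mean_loci, 2)
  expect_error(rarefaction(asg, fractions = c(0.5, 1.2)), "\\(0, 1\\]")

  one <- data.frame(read = paste0("r", 1:5), cluster = "c1")
  curve <- rarefaction(one, fractions = c(0.2, 0.6, 1), reps = 5, seed = 1)
  expect_true(all(curve$mean_clusters == 1))
})

test_that("rarefaction means match the exhaustive expectation on a toy", {
  sizes <- c(5, 3, 2)
  asg <- data.frame(read = paste0("r", 1:10),
                    cluster = rep(c("c1", "c2", "c3"), sizes))
  out <- rarefaction(asg, fractions = c(0.3, 0.5, 0.8), reps = 4000,
                     seed = 7)
  for (i in seq_len(nrow(out))) {
    exp_val <- oracle_rarefaction_expectation(sizes, out$n_reads[i])
    expect_lt(abs(out$mean_clusters[i] - exp_val), 0.05)
  }
  # monotone non-decreasing in fraction at modest reps
  out50 <- rarefaction(asg, fractions = seq(0.2, 1, 0.2), reps = 50,
                       seed = 11)
  expect_true(all(diff(out50$mean_clusters) > -0.3))
})
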