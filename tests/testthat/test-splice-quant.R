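sj_of <- function(donors, acceptors, supports, strand = "+") {
  data.frame(contig = "chr1", donor = donors, acceptor = acceptors,
             strand = strand, support = supports)
}

test_that("event read counting sums junction support per side", {
  ev <- data.frame(
    event = "e1", type = "ES",
    inclusion_junctions = "chr1:100-200:+;chr1:250-400:+",
    exclusion_junctions = "chr1:100-400:+", ir_intron = "")
  sj <- sj_of(c(100, 250, 100), c(200, 400, 400), c(12, 8, 30))
  ct <- count_event_reads(ev, sj)
  expect_equal(unname(ct), c(20, 30))

  # absent from the SJ map: zero counts, filtered later
  none <- count_event_reads(ev, sj_of(900, 950, 5))
  expect_equal(unname(none), c(0, 0))

  # AA event: counts come from the two distinct acceptor junctions
  aa <- data.frame(event = "e2", type = "AA",
                   inclusion_junctions = "chr1:100-200:+",
                   exclusion_junctions = "chr1:100-260:+", ir_intron = "")
  ct2 <- count_event_reads(aa, sj_of(c(100, 100), c(200, 260), c(40, 10)))
  expect_equal(unname(ct2), c(40, 10))

  # IR inclusion comes from intron-body coverage when supplied, else 0
  ir <- data.frame(event = "e3", type = "IR", inclusion_junctions = "",
                   exclusion_junctions = "chr1:100-200:+",
                   ir_intron = "chr1:100-200:+")
  expect_equal(unname(count_event_reads(ir, sj_of(100, 200, 25))), c(0, 25))
  cov <- data.frame(contig = "chr1", donor = 100, acceptor = 200,
                    strand = "+", support = 60)
  expect_equal(unname(count_event_reads(ir, sj_of(100, 200, 25), cov)),
               c(60, 25))
})

test_that("PSI posterior follows Beta(n_inc+1, n_exc+1)", {
  e0 <- estimate_psi(0, 0)
  expect_equal(e0$psi_mean, 0.5)
  expect_equal(e0$ci_low, qbeta(0.025, 1, 1))
  expect_equal(round(e0$ci_low, 3), 0.025)
  expect_equal(round(e0$ci_high, 3), 0.975)
  expect_false(e0$present)

  e <- estimate_psi(30, 10)
  expect_equal(e$psi_mean, 31 / 42)
  expect_false(e$present)   # interval wider than 0.2 at 40 reads

  # CI endpoints match numerical quadrature of the Beta density
  expect_lt(abs(e$ci_low - oracle_beta_quantile(0.025, 31, 11)), 1e-6)
  expect_lt(abs(e$ci_high - oracle_beta_quantile(0.975, 31, 11)), 1e-6)

  # presence filter: needs both counts, sum >= 10 and a narrow interval
  expect_false(estimate_psi(10, 0)$present)
  expect_false(estimate_psi(5, 4)$present)
  expect_false(estimate_psi(6, 5)$present)   # CI wider than 0.2
  expect_true(estimate_psi(90, 70)$present)
})

test_that("Bayes factors match closed forms and are symmetric", {
  expect_equal(bayes_factor(0, 0, 0, 0), 1)          # B(1,1)^2 / B(1,1)
  expect_lt(abs(bayes_factor(5, 5, 5, 5) - 0.505), 0.001)
  expect_gt(bayes_factor(50, 0, 0, 50), 10)          # overwhelming evidence
  expect_equal(bayes_factor(12, 3, 4, 9), bayes_factor(4, 9, 12, 3))
})

test_that("log-space Bayes factor matches the quadrature oracle", {
  set.seed(61)
  for (i in 1:100) {
    ct <- sample(0:200, 4, replace = TRUE)
    bf <- bayes_factor(ct[1], ct[2], ct[3], ct[4])
    ob <- oracle_bayes_factor(ct[1], ct[2], ct[3], ct[4])
    expect_lt(abs(bf - ob) / ob, 1e-6)
  }
})

test_that("differential calls apply the full filter set", {
  a <- estimate_psi(40, 10); b <- estimate_psi(10, 40)
  d <- call_differential(a, b)
  expect_gt(abs(d$delta_psi), 0.5)
  expect_gt(d$bayes_factor, 10)
  expect_true(d$passes)

  same <- call_differential(estimate_psi(25, 25), estimate_psi(25, 25))
  expect_equal(same$delta_psi, 0)
  expect_false(same$passes)

  # one sample failing the sum filter blocks the call
  low <- call_differential(estimate_psi(4, 4), estimate_psi(40, 2))
  expect_false(low$passes)

  pa <- cbind(event = "x", estimate_psi(40, 10))
  pb <- cbind(event = "y", estimate_psi(10, 40))
  expect_error(call_differential(pa, pb), "mismatched event ids")
})

test_that("PSI estimation is calibrated at depth 100", {
  set.seed(62)
  truths <- seq(0.1, 0.9, by = 0.1)
  nrep <- 500; depth <- 100
  errs <- c(); covered <- c()
  for (p in truths) {
    k <- rbinom(nrep, depth, p)
    est <- estimate_psi(k, depth - k)
    errs <- c(errs, est$psi_mean - p)
    covered <- c(covered, est$ci_low <= p & est$ci_high >= p)
  }
  expect_lte(sqrt(mean(errs^2)), 0.05)
  cov <- mean(covered)   # pooled across the nine true PSI values
  expect_gte(cov, 0.93)
  expect_lte(cov, 0.97)
})

test_that("the differential filter is conservative under the null and
           powerful at a 0.4 PSI shift", {
  set.seed(63)
  n <- 1000; depth <- 100
  ps <- runif(n, 0.2, 0.8)
  a <- rbinom(n, depth, ps); b <- rbinom(n, depth, ps)
  ea <- estimate_psi(a, depth - a); eb <- estimate_psi(b, depth - b)
  bf <- bayes_factor(a, depth - a, b, depth - b)
  ok <- function(x) x >= 1 & (depth - x) >= 1
  null_rate <- mean(abs(ea$psi_mean - eb$psi_mean) >= 0.20 & bf >= 10 &
                      ok(a) & ok(b))
  expect_lte(null_rate, 0.05)

  a2 <- rbinom(n, depth, 0.7); b2 <- rbinom(n, depth, 0.3)
  ea2 <- estimate_psi(a2, depth - a2); eb2 <- estimate_psi(b2, depth - b2)
  bf2 <- bayes_factor(a2, depth - a2, b2, depth - b2)
  power <- mean(abs(ea2$psi_mean - eb2$psi_mean) >= 0.20 & bf2 >= 10 &
                  ok(a2) & ok(b2))
  expect_gte(power, 0.90)
})

test_that("FPKM follows its closed form and validates inputs", {
  expect_equal(fpkm(10, 1000, 1e6), 10)
  expect_equal(fpkm(0, 500, 2e6), 0)
  expect_equal(fpkm(5, 500, 2e6), 5)
  expect_error(fpkm(1, 0, 1e6), "length")
  expect_error(fpkm(1, 100, 0), "total")
})
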