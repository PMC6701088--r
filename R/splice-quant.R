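# PSI estimation from junction counts with Beta posteriors, Bayes-factor
# differential splicing, and FPKM expression. The inclusion/exclusion
# evidence of an event are both single-junction counts (equal effective
# lengths), so no length correction is applied; PSI follows the conjugate
# Beta(n_inc + 1, n_exc + 1) posterior under a uniform prior.

#' Count inclusion/exclusion reads for one event
#'
#' Sums unique-read junction support over the event's inclusion and
#' exclusion junction sets. Intron-retention inclusion evidence cannot be
#' carried by junction tables; it is taken from an optional intron-coverage
#' table (zero when absent — a documented limitation of junction-only
#' counting).
#'
#' @param event One row of an event data frame from [detect_events()].
#' @param sj Data frame from [read_sj_tab()] (one sample).
#' @param intron_cov Optional data frame (contig, donor, acceptor, strand,
#'   support) of intron-body coverage for IR events.
#' @return Named numeric `c(n_inc, n_exc)`.
#' @export
count_event_reads <- function(event, sj, intron_cov = NULL) {
  sj_key <- junction_key(sj$contig, sj$donor, sj$acceptor, sj$strand)
  sj_key_any <- junction_key(sj$contig, sj$donor, sj$acceptor, "*")
  support_of <- function(keys) {
    keys <- keys[nzchar(keys)]
    if (length(keys) == 0L) return(0)
    sum(vapply(keys, function(k) {
      k_any <- sub(":[+-]$", ":*", k)
      sum(sj$support[sj_key == k | sj_key_any == k_any & sj$strand == "*"])
    }, numeric(1)))
  }
  inc_keys <- strsplit(event$inclusion_junctions, ";", fixed = TRUE)[[1]]
  exc_keys <- strsplit(event$exclusion_junctions, ";", fixed = TRUE)[[1]]
  n_inc <- support_of(inc_keys)
  if (!is.na(event$ir_intron) && nzchar(event$ir_intron)) {
    if (!is.null(intron_cov) && nrow(intron_cov)) {
      ck <- junction_key(intron_cov$contig, intron_cov$donor,
                         intron_cov$acceptor, intron_cov$strand)
      n_inc <- n_inc + sum(intron_cov$support[ck == event$ir_intron])
    }
  }
  c(n_inc = n_inc, n_exc = support_of(exc_keys))
}

#' PSI point estimate and credible interval from junction counts
#'
#' Posterior is `Beta(n_inc + 1, n_exc + 1)`; the point estimate is the
#' posterior mean and the interval is the central `level` credible interval.
#' An event is "present" in a sample iff `n_inc >= 1`, `n_exc >= 1`,
#' `n_inc + n_exc >= 10` and the interval is no wider than 0.2.
#'
#' @param n_inc,n_exc Non-negative read counts (vectorised).
#' @param level Credible level (default 0.95).
#' @return Data frame: n_inc, n_exc, psi_mean, ci_low, ci_high, present.
#' @export
estimate_psi <- function(n_inc, n_exc, level = 0.95) {
  stopifnot(all(n_inc >= 0), all(n_exc >= 0))
  a <- n_inc + 1; b <- n_exc + 1
  alpha <- (1 - level) / 2
  psi <- a / (a + b)
  lo <- stats::qbeta(alpha, a, b)
  hi <- stats::qbeta(1 - alpha, a, b)
  data.frame(n_inc = n_inc, n_exc = n_exc, psi_mean = psi,
             ci_low = lo, ci_high = hi,
             present = n_inc >= 1 & n_exc >= 1 & (n_inc + n_exc) >= 10 &
               (hi - lo) <= 0.2)
}

#' Bayes factor for differential PSI between two samples
#'
#' Evidence ratio of independent per-sample PSIs (H1) against a shared PSI
#' (H0) under uniform priors:
#' `BF = B(aI+1, aE+1) B(bI+1, bE+1) / B(aI+bI+1, aE+bE+1)`,
#' computed in log space. Symmetric in the two samples.
#'
#' @param a_inc,a_exc,b_inc,b_exc Non-negative counts (vectorised).
#' @param log Return the natural-log Bayes factor.
#' @return Numeric vector of (log) Bayes factors.
#' @export
bayes_factor <- function(a_inc, a_exc, b_inc, b_exc, log = FALSE) {
  stopifnot(all(c(a_inc, a_exc, b_inc, b_exc) >= 0))
  lbf <- lbeta(a_inc + 1, a_exc + 1) + lbeta(b_inc + 1, b_exc + 1) -
    lbeta(a_inc + b_inc + 1, a_exc + b_exc + 1)
  if (log) lbf else exp(lbf)
}

#' Differential AS call between two samples
#'
#' Applies the full filter set: per-sample count filters
#' (`n_inc >= 1`, `n_exc >= 1`, `n_inc + n_exc >= 10` in each sample),
#' `|delta PSI| >= 0.20` and `Bayes factor >= 10`.
#'
#' @param ps_a,ps_b Single-row PSI estimates from [estimate_psi()] for the
#'   same event in samples A and B (may carry an `event` column).
#' @param min_delta,min_bf,min_inc,min_exc,min_sum Filter thresholds.
#' @return Data frame: delta_psi, bayes_factor, passes.
#' @export
call_differential <- function(ps_a, ps_b, min_delta = 0.20, min_bf = 10,
                              min_inc = 1, min_exc = 1, min_sum = 10) {
  if (!is.null(ps_a$event) && !is.null(ps_b$event) &&
      !identical(ps_a$event, ps_b$event))
    stop("mismatched event ids: ", ps_a$event, " vs ", ps_b$event)
  counts_ok <- function(ps)
    ps$n_inc >= min_inc & ps$n_exc >= min_exc &
      (ps$n_inc + ps$n_exc) >= min_sum
  delta <- ps_a$psi_mean - ps_b$psi_mean
  bf <- bayes_factor(ps_a$n_inc, ps_a$n_exc, ps_b$n_inc, ps_b$n_exc)
  data.frame(delta_psi = delta, bayes_factor = bf,
             passes = counts_ok(ps_a) & counts_ok(ps_b) &
               abs(delta) >= min_delta & bf >= min_bf)
}

#' Fragments per kilobase per million mapped fragments
#'
#' @param fragments Fragment count for the gene.
#' @param effective_length_nt Effective transcript length in nt (> 0).
#' @param total_mapped_fragments Library size (> 0).
#' @return FPKM value(s).
#' @export
fpkm <- function(fragments, effective_length_nt, total_mapped_fragments) {
  if (any(effective_length_nt <= 0)) stop("effective length must be > 0")
  if (any(total_mapped_fragments <= 0)) stop("total fragments must be > 0")
  fragments / ((effective_length_nt / 1000) * (total_mapped_fragments / 1e6))
}

#' PSI table for a set of events across samples
#'
#' @param events Event data frame from [detect_events()].
#' @param sj_samples Named list of SJ data frames (one per sample).
#' @param intron_cov Optional named list of intron-coverage data frames.
#' @return Long data frame: event, type, sample, counts and PSI estimate.
#' @export
psi_table <- function(events, sj_samples, intron_cov = NULL) {
  rows <- list()
  for (s in names(sj_samples)) {
    cov <- if (!is.null(intron_cov)) intron_cov[[s]] else NULL
    for (i in seq_len(nrow(events))) {
      ct <- count_event_reads(events[i, ], sj_samples[[s]], cov)
      est <- estimate_psi(ct[["n_inc"]], ct[["n_exc"]])
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(event = events$event[i], type = events$type[i],
                   sample = s, stringsAsFactors = FALSE), est)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise differential calls between two samples from a PSI table
#'
#' @param psi Long PSI table from [psi_table()].
#' @param sample_a,sample_b Sample names to compare.
#' @inheritParams call_differential
#' @return Data frame: event, per-sample PSI, delta, BF, passes.
#' @export
differential_table <- function(psi, sample_a, sample_b, min_delta = 0.20,
                               min_bf = 10) {
  pa <- psi[psi$sample == sample_a, ]
  pb <- psi[psi$sample == sample_b, ]
  pb <- pb[match(pa$event, pb$event), ]
  out <- lapply(seq_len(nrow(pa)), function(i) {
    d <- call_differential(pa[i, ], pb[i, ], min_delta = min_delta,
                           min_bf = min_bf)
    data.frame(event = pa$event[i], type = pa$type[i],
               psi_a = pa$psi_mean[i], psi_b = pb$psi_mean[i], d,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
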