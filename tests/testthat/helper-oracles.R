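# Independent oracles, deliberately written as plain nested-loop
# transcriptions of the structural definitions, separate from the package's
# implementations.

event_keys <- function(ev) {
  if (nrow(ev) == 0L) return(character(0))
  sort(unique(paste0(ev$type, "|", ev$variant)))
}

# ---- brute-force AS event enumerator --------------------------------------
# Returns a character set of "type|v1,v2,..." keys for a list of isoform
# transcript models sharing contig and strand.
oracle_events <- function(isoforms, strand = "+") {
  introns_of <- function(m) {
    ex <- m$exons
    if (nrow(ex) < 2L) return(matrix(numeric(0), ncol = 2))
    cbind(ex[-nrow(ex), 2], ex[-1L, 1])
  }
  keys <- character(0)
  n <- length(isoforms)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    A <- isoforms[[i]]; B <- isoforms[[j]]
    inA <- introns_of(A); inB <- introns_of(B)
    exA <- A$exons; exB <- B$exons
    # IR: intron of A strictly inside an exon of B
    if (nrow(inA)) for (r in 1:nrow(inA)) {
      d <- inA[r, 1]; a <- inA[r, 2]
      for (q in 1:nrow(exB)) {
        if (exB[q, 1] < d && exB[q, 2] > a)
          keys <- c(keys, paste0("IR|", d, ",", a))
      }
    }
    # ES: internal exon k of A with flanking introns (d,s),(e,a); B has (d,a)
    if (nrow(exA) >= 3L && nrow(inB)) for (k in 2:(nrow(exA) - 1L)) {
      s <- exA[k, 1]; e <- exA[k, 2]
      d <- exA[k - 1L, 2]; a <- exA[k + 1L, 1]
      for (q in 1:nrow(inB)) {
        if (inB[q, 1] == d && inB[q, 2] == a)
          keys <- c(keys, paste0("ES|", s, ",", e))
      }
    }
    # AA/AD: shared boundary, differing boundary, differing segment exonic
    # in the shorter-intron isoform
    if (nrow(inA) && nrow(inB)) for (r in 1:nrow(inA)) for (q in 1:nrow(inB)) {
      dA <- inA[r, 1]; aA <- inA[r, 2]; dB <- inB[q, 1]; aB <- inB[q, 2]
      if (dA == dB && aA != aB) {
        lo <- min(aA, aB); hi <- max(aA, aB)
        sh <- if (aA < aB) exA else exB
        ok <- FALSE
        for (x in 1:nrow(sh)) if (sh[x, 1] <= lo && sh[x, 2] >= hi) ok <- TRUE
        if (ok) {
          ty <- if (strand == "+") "AA" else "AD"
          keys <- c(keys, paste0(ty, "|", lo, ",", hi))
        }
      }
      if (aA == aB && dA != dB) {
        lo <- min(dA, dB); hi <- max(dA, dB)
        sh <- if (dA > dB) exA else exB
        ok <- FALSE
        for (x in 1:nrow(sh)) if (sh[x, 1] <= lo && sh[x, 2] >= hi) ok <- TRUE
        if (ok) {
          ty <- if (strand == "+") "AD" else "AA"
          keys <- c(keys, paste0(ty, "|", lo, ",", hi))
        }
      }
    }
    # MX: internal exons X (A only) and Y (B only), disjoint, shared flanks
    if (nrow(exA) >= 3L && nrow(exB) >= 3L)
      for (k in 2:(nrow(exA) - 1L)) for (q in 2:(nrow(exB) - 1L)) {
        xs <- exA[k, 1]; xe <- exA[k, 2]
        ys <- exB[q, 1]; ye <- exB[q, 2]
        d <- exA[k - 1L, 2]; a <- exA[k + 1L, 1]
        if (exB[q - 1L, 2] != d || exB[q + 1L, 1] != a) next
        if (!(xe <= ys || ye <= xs)) next
        if (xs == ys && xe == ye) next
        ovB <- FALSE
        for (x in 1:nrow(exB)) if (exB[x, 1] < xe && exB[x, 2] > xs) ovB <- TRUE
        ovA <- FALSE
        for (x in 1:nrow(exA)) if (exA[x, 1] < ye && exA[x, 2] > ys) ovA <- TRUE
        if (ovB || ovA) next
        v <- sort(c(xs, xe, ys, ye))
        keys <- c(keys, paste0("MX|", paste(v, collapse = ",")))
      }
  }
  unique(keys)
}

# ---- Simpson-quadrature Beta integrals ------------------------------------
# Integral of p^a (1-p)^b over (0,1), computed on a log-scaled grid with
# composite Simpson's rule; independent of lbeta().
simpson_beta_integral <- function(a, b, n = 40000L) {
  p <- seq(0, 1, length.out = n + 1L)
  logf <- ifelse(p %in% c(0, 1),
                 ifelse((p == 0 & a > 0) | (p == 1 & b > 0), -Inf,
                        ifelse(p == 0, b * log1p(-p), a * log(p))),
                 a * log(p) + b * log1p(-p))
  logf[1] <- if (a > 0) -Inf else b * log1p(-0)
  logf[n + 1L] <- if (b > 0) -Inf else 0
  M <- max(logf[is.finite(logf)])
  f <- exp(logf - M)
  f[!is.finite(f)] <- 0
  h <- 1 / n
  w <- rep(c(4, 2), length.out = n - 1L)
  s <- (h / 3) * (f[1] + sum(w * f[2:n]) + f[n + 1L])
  list(log = log(s) + M, value = s * exp(M))
}

oracle_bayes_factor <- function(ai, ae, bi, be) {
  num <- simpson_beta_integral(ai, ae)$log + simpson_beta_integral(bi, be)$log
  den <- simpson_beta_integral(ai + bi, ae + be)$log
  exp(num - den)
}

# Quantile of Beta(a, b) via cumulative trapezoid on a fine grid.
oracle_beta_quantile <- function(q, a, b, n = 2e6) {
  p <- seq(0, 1, length.out = n + 1L)
  logf <- (a - 1) * log(p) + (b - 1) * log1p(-p)
  logf[1] <- if (a > 1) -Inf else if (a == 1) (b - 1) * log1p(0) else Inf
  logf[n + 1L] <- if (b > 1) -Inf else if (b == 1) 0 else Inf
  f <- exp(logf - max(logf[is.finite(logf)]))
  f[!is.finite(f)] <- 0
  cum <- cumsum((f[-1L] + f[-(n + 1L)]) / 2)
  cum <- cum / cum[length(cum)]
  i <- findInterval(q, cum)
  # linear interpolation between grid points
  x0 <- p[i + 1L]; c0 <- cum[i]; c1 <- cum[i + 1L]
  x0 + (q - c0) / (c1 - c0) * (p[i + 2L] - x0)
}

# ---- rarefaction closed-form expectation ----------------------------------
# E[#distinct groups] when m of N reads are drawn without replacement.
oracle_rarefaction_expectation <- function(group_sizes, m) {
  N <- sum(group_sizes)
  sum(1 - choose(N - group_sizes, m) / choose(N, m))
}
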