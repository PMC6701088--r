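---
title: "isoatlas: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{isoatlas: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models, conventions and design decisions behind
`isoatlas`, in the spirit of a methods supplement: what each stage assumes,
which knobs matter, and what the synthetic-truth tests do and do not
demonstrate about real data.

## Coordinates and containers

All internal coordinates are 0-based half-open genomic intervals; GTF
(1-based closed) is converted at the I/O boundary only, and SJ tables
(1-based inclusive intron bounds) likewise. An intron is keyed by
`(donor, acceptor) = (end of upstream exon, start of downstream exon)` in
genomic orientation regardless of strand; the biological donor/acceptor
roles are resolved by strand where a type decision needs them. This single
convention lets junctions extracted from models, junctions parsed from SJ
tables, and junctions referenced by AS events be compared by exact key
equality with no fuzziness (a merge window is deliberately not applied;
synthetic truth makes wobble unnecessary, and a tolerance would complicate
the exactness guarantees the tests rely on).

## FLnc classification

A read is full-length non-chimeric iff three diagnostic elements are found
in one consistent orientation: the 5′ primer near the 5′ end, the reverse
complement of the 3′ primer near the 3′ end, and a poly(A) tail immediately
upstream of the 3′ primer hit. Defaults: 30-mer primers, terminal search
window 100 nt, edit distance ≤ 3 (indels allowed, via approximate pattern
matching), poly(A) run ≥ 20 nt tolerating one non-A per 10 nt of run
(trimmed back to an A at its 5′ end). Primer hits strictly between the
terminal windows mark a read chimeric, hence non-full-length. All
thresholds are configuration surface: vendor demultiplexers make these
choices internally, so a reimplementation must make them explicit.

## Collapse and loci

Alignments are first filtered by aligner-reported query coverage ≥ 0.8 and
identity ≥ 0.7 (inclusive comparisons, documented as such; alignments
without the metadata — e.g. truth alignments from the generator — count as
1.0). Multi-exon reads merge iff their intron chains are identical and
their 3′ ends lie within `tol3 = 100` nt (single linkage); 5′ differences
are ignored entirely, reflecting 5′ degradation of long reads. `tol3`
exists so genuinely distinct alternative-polyadenylation isoforms (planted
≥ 150 nt apart by the generator) remain separable at the model level while
small 3′ scatter merges; APA site calling itself uses raw FLnc ends, not
collapsed models. Single-exon reads merge by reciprocal overlap ≥ 0.5 on
the same strand. The cluster representative spans the widest extent of its
members over the shared chain.

A transcript locus is a connected component of same-strand clusters whose
exons overlap by ≥ 1 bp (transitive closure). Exonic overlap rather than
shared junctions is used so single-exon genes form loci too, matching the
gene-unit granularity of locus counts. Rarefaction subsamples the
read-to-cluster map without replacement (50 replicates by default) and is
checked in the tests against the closed-form expectation
`E[distinct] = Σ_c (1 − C(N − n_c, m) / C(N, m))`.

## Junction QC

Motifs are the first two plus last two intron bases, reverse complemented
on the minus strand so GT–AG always denotes the canonical pair in
transcript orientation. Short-read support is the sum of unique-read counts
(column 7 of the SJ dialect; multi-mapped counts are ignored as
non-conservative) over all samples, with undetermined-strand rows matching
either strand. The filter removes an isoform iff it uses a junction that is
simultaneously non-canonical and unsupported (`min_support = 1` by
default). Canonical-by-motif junctions are never removed for lack of
support: unsupported canonical junctions are plausibly tissue-specific
expression not sampled by the short reads, whereas unsupported
non-canonical junctions are presumed alignment artifacts. The per-class
report (total / supported / removed) lets a user audit the stricter policy
instead.

## AS event classification

Events are detected pairwise within a locus and deduplicated by
`(type, variant coordinates)`. The five predicates (genomic coordinates,
strand resolved only for the AA/AD naming):

* **IR** — one isoform has an intron strictly contained in an exon of the
  other; the *retaining* isoform is the inclusion form, so IR inclusion
  evidence is intron-body coverage rather than a junction.
* **ES** — an internal exon flanked by two introns in one isoform is
  bridged by the single outer intron in the other.
* **AA/AD** — two introns share one boundary and differ at the other, and
  the differing segment is fully exonic in the shorter-intron isoform.
  This exonic-containment condition is what separates a genuine
  alternative splice site from the shared-donor pair that an exon-skipping
  or mutually-exclusive structure would otherwise mimic. A shared
  genomic-left boundary is a shared donor on `+` (event type AA) and a
  shared acceptor on `-` (AD), and symmetrically for the right boundary.
* **MX** — internal exons X (one isoform only) and Y (other isoform only),
  disjoint, between shared outer donor and acceptor. The form containing
  the genomically left exon is labelled inclusion (a strand-free
  convention shared with the generator so PSI orientation is consistent).

Structures matching none of the predicates (multi-exon skips, nested
differences) are left uncounted: the summary concerns the five major types
only. Transcript end differences never create events; end variation
belongs to collapse and APA. Equivalence with an independently coded
brute-force enumerator is asserted on 500 random loci (≤ 4 isoforms, ≤ 6
exons) in the acceptance suite.

## APA

FLnc 3′ ends are clustered per gene by single linkage with gaps ≤ 24 nt;
the site position is the modal end with ties resolved to the most distal 3′
position, and support is the cluster size. Internal priming is flagged when
the 20 genomic nt immediately downstream contain ≥ 12 A or an A-run ≥ 8 —
values in line with common practice for oligo-dT artifact filtering; the
upstream tools this step emulates do not publish theirs, so all three
numbers are exposed. The per-gene summary reports both the mean sites per
gene over genes with ≥ 1 site and the raw total/genes division, because the
two definitions can legitimately differ in published summaries and the
package does not adjudicate between them.

The signal search takes 50 nt upstream of each cleavage site (enough to
contain a signal ~25 nt upstream). Offsets are reported as the upstream
distance of the motif's 3′-most base: an offset of 25 with width 6 means
the hexamer occupies cleavage−30..−25. Two modes: exhaustive w-mer counting
(deterministic; ties alphabetical), and a one-occurrence-per-sequence EM
over a 4×w PWM with uniform background. EM restarts are seeded from the
five most frequent w-mers (the classic subsequence-seeding strategy — a
purely random PWM start often converges to a background-composition
optimum), run at most 50 iterations or to an objective change < 1e-6, and
the best restart wins. The M-step uses a Dirichlet pseudocount of 0.5, so
the quantity that is provably non-decreasing is the penalised (posterior)
objective; that is the trace the code records and the tests assert on,
alongside the final data log likelihood.

## PSI and differential splicing

The quantification deliberately replaces a full generative read model and
MCMC with a junction-count Beta–binomial: inclusion and exclusion evidence
are both single-junction counts with equal effective lengths, so no length
correction is needed, the posterior is conjugate
(`Beta(n_inc + 1, n_exc + 1)`), and every reported quantity (posterior
mean, central 95% credible interval, Bayes factor) has a closed form that
can be verified against quadrature to 1e-6. The presence and differential
filters preserve the published semantics exactly: present iff
`n_inc ≥ 1 ∧ n_exc ≥ 1 ∧ n_inc + n_exc ≥ 10 ∧ CI width ≤ 0.2`; a
differential call passes iff both samples pass the count filters,
|ΔPSI| ≥ 0.20 and BF ≥ 10. The 95% interval level follows the common
default since the level is rarely stated alongside the width threshold. No
multiple-testing correction is applied — calling is filter-based by
design. Two caveats are documented rather than hidden: (1) IR inclusion
evidence cannot be carried by junction tables, so IR events are quantified
only when an intron-body coverage table is supplied (the generator emits
one); (2) for ES events the two inclusion junctions are summed, which
double-counts inclusion molecules relative to the single exclusion
junction — a bias inherent to junction-sum counting, noted so users do not
interpret ES PSI as unbiased.

Calibration at depth 100 (the scale of the filters): RMSE of the posterior
mean ≤ 0.05 over true PSI 0.1–0.9; interval coverage is asserted pooled
across the nine true-PSI values, because the exact coverage of an
equal-tailed Beta interval under binomial sampling oscillates with
discreteness at any single PSI while the pooled value is stable near 0.94.

## ORF and ncRNA rules

ORFs are scanned in the three sense frames only (FLnc inserts are
oriented; `both_strands = TRUE` exists for unoriented input), require a
stop codon (a full-length transcript should contain its complete CDS — a
documented divergence from tools that report 3′-partial ORFs), resolve
overlapping starts to the 5′-most ATG per stop, and are retained at ≥ 100
amino acids (the initiator Met counts, the stop does not: ATG + 99 codons
+ stop is exactly 100 aa). The transcript representative is the 5′-most
ORF (ties → longest); the locus representative is the isoform with the
longest ORF (ties → lexicographically smaller id). A locus with no
retained ORF is a lncRNA candidate iff longer than 200 nt, else a short
ncRNA candidate. Where the published workflow delegated coding potential
to external classifiers and homology databases, this package provides the
ORF rule plus an optional 5th-order Markov log-likelihood ratio trained on
user-supplied labelled sequences (add-one smoothing; shorter contexts for
the first k positions); score ≤ 0 supports non-coding.

## The synthetic-data generator

The generator is the package's measurement instrument, not a fixture: its
defaults are the study conditions under which every acceptance property is
asserted.

* **Gene structure** — six anchor exons (120–200 nt) with five intron
  slots; each planted event occupies its own slot, so any isoform pair
  differs in exactly the planted variants and detected events deduplicate
  onto truth. 10% of genes are single-exon (one isoform, no events).
  Genes are placed non-overlapping on one uniformly chosen strand so locus
  assignment has unambiguous truth.
* **AS mix** — events are drawn as IR 68.85%, AA 15.64%, AD 9.31%,
  ES 3.10%, MX 3.10%: the intron-retention-dominated mix typical of plant
  long-read transcriptomes, with the residual split evenly between ES and
  MX. Isoform counts per gene default to probabilities (0.49, 0.26, 0.15,
  0.10) for 1–4 isoforms, echoing the roughly half-single-isoform gene
  distribution such studies report.
* **Motifs** — every planted intron receives its terminal dinucleotides in
  transcript orientation (GT..AG unless its slot was drawn non-canonical
  from GC–AG/AT–AC/other), written into the genome so extraction
  round-trips exactly.
* **Poly(A) sites** — each isoform's cleavage site is its 3′ end; extra
  isoforms take proximal sites in 150 nt steps with probability 0.4, which
  keeps distinct sites separable both by the 24 nt cluster window and the
  100 nt collapse tolerance. Every site gets AATAAA ending 25 nt upstream,
  a strictly non-A (U-rich) tract at upstream distances 1–12 and a mildly
  A-rich downstream tract post-edited to stay below the internal-priming
  thresholds. The non-A upstream tract also guarantees that the greedy
  poly(A) trimming of error-free reads stops exactly at the appended tail,
  so site recovery is positionally exact.
* **Reads** — FLnc reads are primer + 5′-truncated transcript + 30 A +
  reverse-complemented primer, randomly strand-flipped; nFL reads omit
  exactly one element, recorded in truth. Truncation is uniform up to 20%
  of the transcript but confined to the first exon and kept upstream of any
  sibling isoform's splice boundary inside that exon (such as the donor of
  a retained intron), so error-free reads keep complete intron chains *and*
  preserve the planted structural evidence; collapse and event truth
  closure are then exact — real degradation can of course cross junctions,
  which is precisely the case the collapse tests do not claim to cover. Reads are error-free by
  default (an optional substitution rate exists); error correction is
  upstream of this package's scope.
* **Counts** — per event and sample, inclusion ~ Binomial(depth, PSI) with
  exclusion the complement at fixed depth 100; constitutive junctions get
  full depth; IR inclusion goes into a separate intron-coverage table. No
  overdispersion is simulated — the simplest model consistent with the
  Beta-binomial inference stage, which means the calibration results say
  nothing about overdispersed real libraries.
* **ORFs** — 85% of multi-exon genes get a planted ORF (ATG + 110–300
  biased codons + stop) written across exons of the reference isoform and
  re-verified after motif writes (a variant splice boundary can fall
  inside reference exon sequence and, rarely, disrupt it; truth records
  the verified outcome).

What the generator does **not** emulate: sequencing error, chimeric and
internally primed reads, expression-level variation beyond fixed
per-isoform depth, overdispersed junction counts, intron-crossing 5′
degradation, genes on both strands of the same interval, and alignment
ambiguity (alignments are emitted from truth, standing in for a spliced
aligner). Green tests therefore certify the algorithms and their
contracts, not robustness to these real-data phenomena.

## Problem sizes

The shipped checks run at deliberate desk scale: the end-to-end demo uses
30 genes (~570 reads, ~60 isoforms) and completes in about a minute;
classifier-vs-oracle equivalence uses 500 random loci; planted-event
recovery uses 100 three-isoform genes (200 events); PSI calibration uses
500 replicates per true PSI at depth 100 and 1000 replicate pairs for the
null and power checks. These sizes make every property exactly checkable
while keeping a full run of the suite within a few minutes.
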