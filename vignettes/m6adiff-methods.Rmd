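---
title: "Statistical methods and design choices in m6adiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods and design choices in m6adiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`m6adiff` analyzes the downstream tables of a two-condition direct RNA
sequencing experiment — wild type versus a methyltransferase mutant — to
find sites whose m6A modification rate drops in the mutant and to relate
those sites to 3′-end usage, poly(A) tails and expression. This vignette
explains each procedure, its assumptions, the tunable parameters, the
synthetic-data model used for validation, and the design choices made
where more than one reasonable convention exists.

## Data model and coordinates

All coordinates are 0-based, half-open, in transcript orientation
(5′→3′). Genomic strand handling is confined to the GTF reader, which
derives 5′UTR/CDS/3′UTR lengths from exon-minus-CDS extents and flips
minus-strand transcripts into this frame, so every downstream computation
lives in a single unambiguous coordinate system. Transcripts without a
CDS are flagged non-coding: segments are undefined for them, so they are
excluded from metagene and motif stages but retained for 3′-end and
poly(A) analyses.

Gene-level 3′-end analyses run in the representative transcript's frame;
when isoforms differ we take the gene locus as `[0, max total_len)` over
the gene's transcripts. The choice of representative frame is a
convention — annotations rarely pin down which isoform anchors a gene's
coordinates — and only affects reporting, not the tests, because all
reads of a gene are compared within one frame.

## Calling hypomethylated sites

Modification calls arrive as counts: per site, condition and replicate,
`n_reads` and `n_modified`. The per-replicate statistic is the pooled
two-proportion z-test on the rates; its square is the 2×2 chi-square
without continuity correction, which the test suite verifies to 1e-10
against `chisq.test`. The model assumption is that reads are independent
Bernoulli draws of modification status — reasonable for direct RNA reads,
where each read is one molecule.

A site is called hypomethylated when **every** replicate pair meets the
coverage floor, has two-sided p < α, and has DMR > 0. Parameters:

* `alpha = 0.01` — a raw per-replicate threshold. Requiring all
  replicates to pass individually is itself a stringent conjunction
  (under the null the joint rate is on the order of (α/2)³ once the sign
  constraint is counted), which is why no multiplicity correction is
  applied by default; `adjust = "BH"` thresholds per-replicate
  BH-adjusted values instead for users who prefer explicit FDR control,
  and `pool_replicates = TRUE` gives the alternative reading in which
  counts are summed across replicates and one pooled test decides.
* `min_cov = 20` reads per condition per replicate. A proportion from
  fewer than ~20 reads is too unstable for a normal-approximation test;
  sites failing the floor in any replicate are excluded and counted
  rather than tested noisily.
* Degenerate pooled rates (0 or 1 in both groups) return z = 0, p = 1:
  no between-group difference is demonstrable from such a table.

The DMR reported per site is the mean of per-replicate DMRs; with equal
coverage it estimates the true rate difference with standard error
`sqrt((p_wt q_wt + p_mut q_mut) / (R * cov))` for R replicates.

## Metagene mapping

Segments are half-open: position `utr5_len` is the first coding base and
the stop codon's three bases belong to the CDS, which keeps "peaks before
the stop codon" interpretable without a boundary ambiguity. The metagene
coordinate rescales each segment to one unit of a 0–3 axis. The density
is an unweighted per-site histogram with 30 bins per segment (90 total);
length-weighting by segment size is deliberately not applied, since the
question is where sites sit relative to landmarks, not per-nucleotide
density. When a site's containing segment has zero length its coordinate
is undefined and the site is reported with segment only.

## Motif derivation and enrichment

Sites carry their A-centered 5-mer. The consensus is built from the
per-position nucleotide frequency matrix: at each position, every base
with frequency ≥ 0.20 is included and covered by the minimal IUPAC code.
The 0.20 threshold reproduces two- and three-letter codes (Y, H) from
skewed matrices while keeping a dominant single base unambiguous; a base
at 10% does not enter the code. Enrichment is a one-sided binomial test
of the number of site k-mers matching the derived motif against the
background matching frequency, with the background taken as all
A-centered 5-mers of the supplied transcript sequences. This is a
deliberately simple, fully specified enrichment — not a ZOOPS/log-odds
motif-discovery score — so its null hypothesis (sites are background
positions) is explicit and its p-value exactly reproducible. All
sequences are stored in the DNA alphabet with U normalized to T.

## Alternative 3′-end usage

The procedure per gene:

1. Reads overlapping the gene locus by less than 20% of the **read's**
   aligned length are removed. The read-length denominator matters: a
   locus-length denominator would discard every read of a long gene.
   A fraction of exactly 0.2 is kept (the rule removes strictly below).
2. Replicates are pooled within condition and the two conditions'
   3′-end position multisets are compared with one two-sample
   Kolmogorov–Smirnov test per gene. A per-position KS test is not well
   defined — KS compares whole distributions — so position-level detail
   enters at the classification step instead.
3. P-values are BH-adjusted across genes; genes with fewer than
   `min_reads = 10` reads in either condition are excluded.
4. For FDR < 0.05 genes, Δ(pos) = usage_mut − usage_wt over observed
   positions locates the most-reduced (argmin Δ) and most-increased
   (argmax Δ) sites. Positions supported by fewer than 2 reads in both
   conditions are collapsed into 10-nt bins first, which stops a single
   stray read end from claiming an extreme; exact ties at an extreme
   break toward the position nearest the annotated 3′ end. The shift is
   proximal when the increased site lies upstream of the reduced one,
   and the distance is their coordinate difference — invariant under
   translation of the coordinate frame, as the tests check.

## Poly(A) lengths and expression

Per-gene poly(A) comparisons use the two-sided Mann–Whitney test with BH
across genes. For both the Mann–Whitney and KS tests the package takes
the `stats` defaults: exact p-values for small untied samples,
tie-corrected asymptotic otherwise. Exact-where-feasible matches the
permutation-oracle checks in the test suite (e.g. p = 0.1 for
{1,2,3} vs {4,5,6}) while remaining O(n log n) at scale; discrete 3′-end
positions always carry ties, so large-sample KS p-values there are the
standard conservative asymptotic ones.

`simple_de()` is a documented stand-in for a dedicated DE model: log2
counts-per-million with pseudocount 1, per-gene two-sample t-test, BH.
It exists so the pipeline is self-contained on simulated data; for real
experiments an externally fitted DE table is supplied via
`read_de_table()` and flows through association and overlap
classification identically. The association background is all genes
present in the DE table; genes absent from it are excluded, not imputed.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with planted, recoverable truth:

* 500 coding transcripts (one gene each), segment lengths uniform on
  50–150 / 300–900 / 150–350 nt.
* 5 candidate A-centered sites per transcript, the containing segment
  drawn with probabilities 5% / 80% / 15% (5′UTR/CDS/3′UTR) — the
  CDS-dominated placement typical of writer-dependent sites. 10% of
  sites carry a planted effect: wild-type rate 0.2 + 0.4, mutant rate
  0.2, consistent with mostly-moderate DMR magnitudes; other sites sit
  at a 0.02 background rate in both conditions. Coverage is Poisson
  with mean 100 per replicate and condition, 3 replicates.
* Effect sites are written into the transcript sequence as concrete
  `YHAGA` instances; other candidate sites as random A-centered 5-mers.
* 100 reads per gene and condition draw 3′ ends from a distal/proximal
  two-site mixture (proximal weight 0.1, sites 100 nt apart) with ±5 nt
  uniform end jitter to emulate end-calling noise; in 10% of genes the
  mutant moves 0.3 of the usage mass to the proximal site.
* Poly(A) lengths are truncated normal (mean 100, sd 25 nt); 6% of
  genes get a −20 nt location shift in the mutant — a mild effect, as
  poly(A) differences in this setting tend to be.
* Counts are Poisson around a log-normal baseline with log2-scale noise
  (sd 0.5) and a planted −0.5 log2 fold change on hypomethylated genes.
  Note −0.5 is below the |FC| > 1.5 overlap threshold by design: the
  planted expression effect is a distributional shift detectable by the
  association test, not a set of strong DE calls.

It does **not** emulate: isoform structure and splicing, non-coding
transcripts, sequencing error or coverage–expression coupling,
positional coverage decay along transcripts, or dependence between a
site's methylation and its own gene's 3′-end behaviour. Passing
recovery tests therefore demonstrate that the estimators and decision
rules are correct under the stated sampling model — not that real
nanopore artefacts are handled; those enter upstream of this package.

## Validation strategy and problem sizes

The test suite checks every statistic against an independent oracle
(chi-square identity to 1e-10 on 1000 tables; brute-force ECDF supremum
to 1e-12 on 1000 pairs; exhaustive permutation for group sizes ≤ 8; a
direct step-up implementation of BH on 1000 random vectors), and the
decision rules against their nominal error rates: per-replicate type-I
error at α = 0.01 over 10,000 null sites at coverage 100; the
all-replicates intersection rule over 20,000 simulator-generated null
sites (its joint rate is bounded well below the per-replicate α,
consistent with the (α/2)³ law, whose 1.25e-7 magnitude is below what a
desk-scale simulation can estimate directly); and the realized BH false
discovery proportion over 500 simulations of 5000 null-uniform p-values,
tested against its 0.05 target with a two-standard-error Monte Carlo
allowance, since under a global null the expected FDP sits exactly on
the bound.

Recovery is validated at the configured magnitudes: DMR 0.4 at coverage
200 within three binomial standard errors for ≥ 99% of sites; proximal
shifts (mass 0.3, 100 reads per condition) detected with correct
direction in ≥ 90% of 500 planted genes; consensus recovery within the
`YHAGA` expansion at enrichment p < 1e-6; and the default end-to-end run
recovering ≥ 90% of planted sites at ≤ 10% false-discovery proportion,
bit-identically across reruns under a fixed seed. One power caveat is
worth stating: on the *mixed* default configuration (50 shifted genes
among 450 nulls) BH across all genes tightens the per-gene threshold, so
end-to-end proximal-shift recall typically lands somewhat below the
all-planted figure — `scripts/acceptance.R` computes exactly this number
(`apa_direction_recall`) along with the null false-positive rate, rather
than reporting only the easier all-planted setting.

## Known limitations

* The site caller tests rates, not signal: it presumes an upstream
  modification caller produced well-calibrated per-read counts.
* The KS test on discrete 3′-end positions is conservative in the
  presence of heavy ties; with very peaked usage distributions power is
  lost relative to a position-aware test.
* The Δ-based shift classification reports the two extreme positions
  only; multi-site reorganizations are summarized by their largest
  changes.
* `simple_de()` ignores overdispersion and is unsuitable as a primary
  DE method on real counts; supply a dedicated DE table instead.
* Segment fractions and metagene densities are per-site and unweighted;
  comparing them across annotation versions with different UTR calls
  requires care.
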