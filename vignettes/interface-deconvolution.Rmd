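---
title: "Methods: mixed-species transcriptome deconvolution and interface analysis"
author: "parastx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-species transcriptome deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`parastx` deconvolves mixed-species RNA-seq from the parasite–host
interface of a parasitic plant: the sample contains parasite transcripts,
host transcripts, and occasional microbial material, and every downstream
claim depends on separating them correctly. The package treats the
separation as a percent-identity classification problem. Its core
assumptions:

* Host and parasite are divergent enough that best-hit nucleotide identity
  against a host reference is bimodal: a high-identity mode from genuinely
  host-derived sequences and a lower, *incidental* mode from parasite
  genes that merely have host homologs. The threshold between them is an
  empirical property of the species pair, which is why it is calibrated
  rather than assumed.
* Identity is computed BLAST-style — matches over alignment columns, gap
  columns included — because the screening thresholds in this literature
  were established against that reporting convention.
* One category per unigene, decided by a fixed stage order, so that count
  accounting is exact at every stage.

# The similarity engine

Screening and mapping run on the package's own k-mer seeded banded
aligner (Rcpp) rather than an external BLAST/mapper binary, keeping the
whole analysis reproducible from a single install. Alignment uses linear
gap penalties with match +1, mismatch −2, insertion −3, deletion −3 (the
mismatch/indel costs follow the read-mapping parameterisation this
workflow replays; the +1 match reward is the package's choice). Two
modes:

* **global** (unigene vs reference): the band is a corridor around the
  shifted diagonal that always contains both endpoints, so a path always
  exists; with the default half-width of 32 the banded optimum equals the
  full dynamic program whenever true divergence keeps the optimal path
  in-band (asserted against an independent full-DP oracle in the tests).
* **local** (read vs transcript): Smith–Waterman banded around the modal
  seed diagonal. A read maps when the aligned fraction is ≥
  `length_fraction` (default 0.5) and identity on the aligned part is ≥
  `min_similarity` (default 0.8); each mapped read counts toward exactly
  one transcript, its best hit.

Seeding uses exact 11-mers on both strands (the query is
reverse-complemented; the index is strand-naive). Significance is a raw
score floor (`min_score`, default 20) standing in for an e-value cutoff:
Karlin–Altschul statistics are deliberately out of scope, and 20 ≈ twenty
matching bases is well above chance for the reference sizes the package
targets. Ties break by score, then identity, then alignment length, then
lexicographically smallest subject id — fully deterministic.

# Threshold calibration

`select_threshold()` formalises what is usually done by eye. Inputs are
two best-hit identity histograms (1-point bins over [0, 100]): a
*host-positive* distribution — known host sequences (an EST-style
collection of the host) queried against the host reference — and a
*control* distribution — a non-parasitic relative of the parasite queried
against the same reference, measuring incidental identity. For each
candidate boundary τ the combined error is

> host mass strictly below τ (contamination kept) +
> control mass at/above τ (parasite-like sequence lost),

both as fractions of queries with hits; queries with no hit cannot be host
contamination by this criterion and contribute to neither mass. τ
minimises the sum. Between well-separated modes the minimising set is a
flat zero plateau; the package returns the **upper median** boundary of
the plateau. Both ends of the plateau have identical error, so the
tie-break is free; the upper choice favours parasite retention, matching
the stated aim of minimising host contamination *while retaining*
parasite transcripts. Distributions whose minimised sum exceeds
`overlap_ceiling` (default 0.1) are flagged non-separable; τ is still
reported, with a warning. A fixed τ (e.g. 95) can always be supplied
instead of calibrating.

# Read QC and host screening

End trimming strips the maximal prefix and suffix of bases below the
quality floor (default Q20) — the simplest reading of "trim low-quality
ends", and the one that is oracle-testable; interior low-quality bases
are untouched. A read survives only if it keeps at least
`min_survival_fraction` (default 0.5) of its original length. Pairs are
reconstructed afterwards; single survivors become orphans, and the
accounting identity 2·pairs + orphans + discarded = 2·input pairs is
asserted, not assumed.

Read screening maps reads against the host reference with the calibrated
identity threshold as `min_similarity`. Two declared choices:

* Pairs with exactly one host-assigned mate are removed entirely
  (conservative against chimeric carry-through) and counted separately as
  `half_host_pairs`.
* The pipeline's contamination *estimate* counts a pair as host only when
  **both** mates are host-assigned. Local alignment of a short read can
  occasionally clear the identity bar on a lucky sub-window, so per-read
  false-positive rates do not vanish; requiring both mates squares that
  rate while true host pairs, near-identical to the reference, still map
  twice.

# Classification cascade

Stage order is host screen, then parasite screen, then labeled-database
lookup, then no-hit. Unigenes at/above both nucleotide thresholds go to
*host* — conservative against contamination — and are reported as the
order-sensitive ambiguous band. The third stage accepts either a
kingdom-labeled reference searched with the package's own engine or a
precomputed per-unigene label table; both share the same decision logic.
Plant-labeled and no-hit unigenes are pooled with parasite positives into
the putative-parasite pool, mirroring the count structure of the study
tables this package replays.

Assembly post-processing: exact-duplicate/containment removal (either
strand, longest representative kept) and an ORF-fraction translatability
filter — keep iff the longest stop-free codon run across six frames spans
at least `min_orf_fraction` (default 0.3) of the codon-aligned length.
The default is a deliberately permissive stand-in for HMM-based
frame-shift screening: random sequence has a stop roughly every 21
codons, so genuine coding sequence clears 0.3 easily while random
sequence essentially never does. Sequences shorter than one codon are
dropped with a logged reason.

# Comparative and expression layers

The Venn partition over (interface-A, interface-B, above-ground) is plain
set arithmetic into seven disjoint regions; interface-only percentages
are rounded to the nearest percent from exact rationals. GO Slim
proportionality uses the Pearson chi-square (no continuity correction —
the tables are large R×C), Pearson residuals `(O − E)/√E`, and a ±4
residual flag bound; "no GO Slim category" is an explicit row because
unannotated genes are a finding, not missing data. Zero-margin rows or
columns are dropped with a message; cells with expected counts below 5
are listed as caveats rather than silently trusted. No multiple-testing
correction is applied across the enrichment tables by default, matching
the replayed analysis; `p.adjust` can always be applied downstream.

RPKM is 10⁹·C/(N·L) with N the mapped-read total of the library and
ambiguous reads resolved to their best hit, never fractionally split — the
simplest defensible rule where the original tooling's default is
unknowable. Cross-library correlation defaults to log₂(RPKM+1), the
variance-stabilised scale; the raw scale is a flag away because the
original transform is unstated. Ranking ties break by unigene id.

For qPCR, ΔCt is the difference of technical-replicate mean Cts, ΔΔCt is
relative to the mean control ΔCt, the summary fold is the geometric mean
(2^−mean ΔΔCt), and the Welch one-tailed test runs on ΔCt values — the
approximately normal scale behind 2^−ΔΔCt reporting; testing on the fold
scale would compare lognormal variates with a t statistic.

# The synthetic-data generator

The generator defines the study conditions every test runs under. What it
emulates:

* transcript pools with explicit homology: a parasite assembly, a
  parasite reference at 2 % divergence, two hosts at 20 % divergence
  (putting the incidental identity mode near 80 %), an EST-style
  collection per host at 1 % within-host divergence (the host-positive
  calibration queries), a non-parasitic control at 2 % from the parasite
  (so its incidental identity to hosts matches the parasite's — exactly
  what makes it a valid control), and microbial sequences;
* transcripts built as short UTRs around a stop-free CDS of random
  non-stop codons, so ORF-based filtering behaves as on real mRNA;
* 83×83 bp paired-end libraries with uniform insert sizes, Phred+33
  qualities, a probabilistic low-quality 3′ tail (exercising the
  trimmer), uniform substitution errors, and a known host fraction *f*
  (default 0.1) — *f* is a free parameter because no ground-truth
  contamination rate exists to match;
* an orthogroup/GO Slim label universe whose seven Venn-region
  probabilities follow the published partition proportions, at one-tenth
  scale (1100 orthogroups, ~2 unigenes per orthogroup per transcriptome)
  — large enough that a planted log-odds-1 enrichment of the
  "no_category" row in the interface-shared region is detectable at the
  ±4 residual bound;
* Ct tables with a configurable true fold change (default 120), shared
  per-replicate loading offsets (which cancel in ΔCt) and target-only
  biological variation (which does not).

What it does **not** emulate: indels in homolog evolution (substitution
only, keeping expected identity analytic at ≈ 1−d; an indel rate would be
a straightforward extension), chimeric mis-assemblies, amplification
length bias, and machine-specific error profiles. Passing tests therefore
demonstrate correctness of the *procedures* under controlled divergence
and contamination, not robustness to every artefact of real libraries.

# Problem sizes and determinism

Default conditions: 120 parasite families, 80 host transcripts per host,
2 000 read pairs, 1100-orthogroup label universe — sizes chosen so a full
pipeline run completes in about two minutes on one core while leaving
every statistical recovery comfortably powered (e.g. 3 binomial standard
errors on f = 0.1 at ~1 800 surviving pairs is ±0.021). Unit tests use
smaller replicas (30 families, 400 pairs). All randomness flows from the
configuration seed; identical configurations produce byte-identical
outputs, which the tests assert on written FASTA/TSV artifacts.

# Known limitations

* Identity thresholds calibrated at the unigene scale are applied to
  reads, where window variance is larger; the pair-level estimator
  compensates for screening, but single-end (orphan) host calls retain a
  higher false-positive rate.
* The significance surrogate is a raw score floor, not an e-value; it is
  appropriate at desk scale but not calibrated across reference sizes.
* The translatability heuristic is not a frame-shift model; it
  under-penalises sequences with one long ORF plus scrambled remainder.
* Orthogroup assignment inherits the best hit's label only; secondary
  hits are never consulted, matching the replayed workflow.
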