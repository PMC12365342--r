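---
title: "Designing SSR-Seq marker panels for non-invasive genotyping"
author: "SSRseqDesign authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing SSR-Seq marker panels for non-invasive genotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SSRseqDesign)
```

## The problem

Non-invasive samples — feces, shed hair — are often the only realistic
DNA source for endangered, hard-to-capture animals, but they yield small
amounts of degraded DNA. Microsatellites (SSRs) genotyped by sequencing
short amplicons (SSR-Seq) remain the marker of choice for individual
identification, parentage, and population structure under these
constraints, provided the markers are designed for the failure modes of
low-quality template: stutter (replication slippage producing artifact
alleles offset by whole repeat units), allele dropout, and non-specific
amplification in multiplex reactions.

This package turns a draft genome assembly into a multiplex-ready
SSR-Seq panel, and an aligned set of mitochondrial sequences into a
short, maximally informative barcode amplicon. Every stage is an
ordinary R function over Bioconductor containers (`DNAStringSet`,
`GRanges`), so the pipeline can be run end to end
(`runDesignPipeline`, `runDiversityPipeline`) or stage by stage.

## SSR scanning

`scanContig` reports every *maximal perfect* tandem repeat of a 1–6 bp
motif whose whole-copy count meets a per-motif-length threshold
(`scanThresholds`; defaults 10, 5, 4, 3, 3, 3 repeats for mono- through
hexanucleotides, the thresholds commonly used to characterize primate
genomes). Conventions that matter for reproducibility:

* A tract is reported once, under its **shortest period**:
  `ATATATAT...` is a dinucleotide AT locus, never a tetranucleotide
  ATAT locus. Repeat units that are powers of a shorter string are
  rejected, which (by the Fine–Wilf periodicity argument) suffices for
  any tract of two or more copies.
* Motifs are canonicalized to the lexicographically smallest cyclic
  rotation; reverse complements are **not** collapsed, so plus- and
  minus-strand repeat classes remain distinguishable and per-class
  counts match the grouping that standard SSR survey tools produce.
* Tracts are reported from the leftmost base at which the periodicity
  begins, spanning the whole motif copies that fit; a trailing partial
  copy extends neither the coordinates nor the repeat count. On a
  reverse-complemented contig this makes coordinates mirror up to the
  sub-motif phase remainder — the motif class and repeat count mirror
  exactly.
* `N` (or any non-ACGT character) terminates a tract and can never sit
  inside a motif. Lowercase input is uppercased; soft-masking case is
  deliberately *not* interpreted as a mask. Repeat/TE masking instead
  travels on an explicit interval channel (BED via `readMaskBED`),
  which keeps scanning independent of masking dialects.
* Coordinates are 1-based inclusive in all tables and GFF3 output;
  BED output is 0-based half-open per that format's standard, with the
  conversion delegated to `rtracklayer`.

The scanner is validated against an independent brute-force enumerator
(every start position, every motif length, explicit copy-by-copy
extension) on hundreds of random contigs per test run.

## Design filters

The filter cascade encodes the precautions that make SSR-Seq work on
degraded template, each as a separate auditable stage with counts
recorded in the run manifest:

* only tetra- and pentanucleotide motifs, with at least 12 and 10
  repeats respectively — long motifs reduce stutter, long tracts keep
  the locus polymorphic;
* contigs must exceed 10 kb, avoiding loci selected from short,
  repeat-dense contigs that tend to be physically clustered;
* the allele (repeat tract) may not exceed 150 bp and the amplicon must
  fit 90–250 bp, so one short sequencing read spans the product;
* exact duplicate candidate windows are removed, *including
  reverse-complement duplicates*, because an assembler may emit either
  strand of the same region;
* motifs whose realized tract contains `AAA` — evaluated on the tract
  as written, so runs spanning motif junctions (e.g. `ATAA|ATAA`) are
  caught — and motifs whose alphabet is a subset of {A, T} are
  excluded as slippage-prone. The adenine rule is strand-specific to
  the reported motif by default; a `checkComplementTTT` flag extends it
  to the complement strand.

Primer enumeration then tests every 17–24 bp window of each flank
against all constraints jointly: melting temperature 48–62 °C, GC
35–50 %, the tract-proximal primer edge at least 20 bp from the repeat
(slippage near the tract shifts apparent allele sizes), no overlap with
a masked interval, and — as an added stutter guard beyond the core
criteria, on by default and configurable — no mononucleotide run of
five or more inside the primer. Pairs are ranked by a documented
penalty: `|Tm_f − Tm_r| + 1·(self-dimer deficit below −5 kcal/mol) +
0.5·|amplicon − 170|/100`, with deterministic tie-breaking, and one
pair per locus is kept. Loci with no admissible pair are reported as
such, not dropped silently: the count of designed loci is always
≤ the candidate count, and the manifest asserts the monotonicity at run
time.

## Thermodynamics

Melting temperatures use the unified nearest-neighbor parameter set
(SantaLucia 1998), shipped as a plain-text table
(`inst/extdata/nn_santalucia1998.tsv`) so an alternative table can be
swapped in. Conditions default to 50 mM monovalent salt (entropic
correction `0.368 (n−1) ln[Na+]`), 250 nM total strand concentration,
and `x = 4` for non-self-complementary duplexes (`x = 1` plus the
−1.4 cal/(mol·K) symmetry entropy otherwise). The implementation
reproduces an independent evaluation of the same published table to
within 0.01 °C.

Dimer screening is deliberately a *screen*, not a hybridization
partition function: every ungapped antiparallel offset of one oligo
against the other is scanned for contiguous Watson–Crick runs of at
least 3 bp (configurable; shorter runs have negligible ΔG and create
noise), each run is scored as the sum of its stack free energies at
37 °C plus two initiation terms, and the most negative run is reported,
0 when none. All stack ΔG are negative at 37 °C, so extending a run
never weakens it, and the minimum over maximal runs equals the minimum
over all sub-runs. Bulged duplexes, mismatch extension and hairpins are
out of scope. The screening thresholds used downstream (−5 kcal/mol for
cross-dimers, −6 for self-dimers) are exposed as arguments, so users
calibrating against a different dimer predictor can move the cut rather
than the model.

## Multiplex partitioning

Panel entries (designed SSR pairs plus any externally designed
mtDNA-barcode or sex-determination pairs, all treated identically) are
first prefiltered: an entry is excluded when either oligo has self-dimer
energy strictly below −6 kcal/mol or Tm strictly below 48 °C — both
thresholds strict, matching the "less than" phrasing of the criteria
they encode; a Tm of exactly 48.0 survives. Conflict edges connect
entries whose worst oligo-pairing cross-dimer goes strictly below
−5 kcal/mol or whose oligo Tm gap exceeds 5 °C.

Partitioning is a deterministic greedy coloring: vertices by descending
conflict degree (ties lexicographic by id, after an id-sort that makes
the result independent of input record order), each placed in the
lowest-numbered set with no internal conflict, at most 12 pairs, and a
whole-set Tm span within 5 °C. The span re-check is enforced *in
addition to* pairwise Tm edges because pairwise gaps alone cannot bound
the span of a set — the stricter of the two possible readings of a
"maximum Tm difference" rule, applied as both. Exact (ILP-style)
chromatic minimization is a non-goal; on small random graphs the greedy
count stays within one color of the brute-force chromatic number, and
`validatePanel` — an auditor that recomputes every set invariant from
scratch — runs on all partitioner output.

## Nucleotide diversity and barcode selection

`pairwisePi` computes per-site nucleotide diversity with **pairwise
deletion**: a column counts for a sequence pair only when both rows hold
an unambiguous base. Complete deletion would discard most columns of a
gappy multi-species mitogenome alignment, which is exactly the input
this module targets. Each pair contributes differences divided by its
own valid-site count; π is the mean over pairs with at least one valid
site (pairs with none are excluded from numerator and denominator, and
an alignment with no valid pair returns 0).

`slidingPi` tiles windows of 100 columns every 25 columns (the
profiling resolution used for mitogenome-scale scans), dropping — not
rescaling — a trailing partial window, since edge handling differs
between versions of the standard desktop tools and a partial window's π
is not comparable to a full one's. Window midpoints are
`start + ⌊window/2⌋ − 1`, making the midpoint/π table layout
reproducible. Hotspots are maximal unions of windows whose π *strictly*
exceeds `hotspotFactor ×` the median window π (factor 2 by default).
The threshold is read as 2× the median of *per-window* π values — the
quantity such profiles actually plot — rather than of per-site values;
with an all-identical alignment the median is 0 and the strict
inequality correctly yields no hotspots.

`selectAmplicon` does an exhaustive scan of every column interval whose
length is within a tolerance of the target (default 199 ± 10 bp, a
product one short read covers), maximizing mean per-site π via
cumulative per-pair difference counts (O(pairs) per interval), ties
resolved to the target length and then the leftmost start.
`speciesDiagnosticSites` reports columns fixed for different bases
between two labeled groups, to verify a chosen barcode can distinguish
sister species.

## Synthetic data: what it emulates, and what it does not

The generators define the conditions under which the pipeline is
tested:

* `generateGenome` plants perfect SSR tracts verbatim at declared
  positions in i.i.d. background sequence of a given GC (default 0.40,
  a typical primate genome-wide value; the worked examples use 0.42).
  Flanks are **rejection-sampled**: a contig is regenerated (up to a
  cap of 1000 attempts, then a loud failure) until scanning it yields
  exactly the planted loci that meet the thresholds — no accidental
  SSR, no planted tract extended or shifted by its flank. This keeps
  planted truth exact, at the cost of a slight bias against
  repeat-like flank sequence.
* `generateAlignment` applies site-independent substitutions to a
  random reference at a background rate, with an elevated rate inside a
  declared hotspot interval — no indels, no rate heterogeneity beyond
  the hotspot, no phylogenetic correlation among sequences. Gap
  handling is therefore exercised separately with hand-built gapped
  alignments. Test conditions follow the module contracts: hotspot
  recovery uses 12 sequences × 600 columns with rates 0.25 vs 0.01
  over 20 replicate seeds; per-site counts are checked against the
  binomial model by a chi-squared test.
* `generatePrimerPanel` builds oligo panels with *engineered* conflict
  structure: each requested conflict edge receives a pair of mutually
  complementary 8 bp 3' tags (cross-dimer < −5 kcal/mol), while all
  other pairs — including each oligo against itself — are free of
  complementary stretches of 4 bp or more. The construction is mostly
  analytic: bodies use a purine (A/G) alphabet, which cannot base-pair
  with itself; tags come from a fixed codebook of purine 8-mers with
  pairwise-disjoint 4-mer sets, because a purine stretch can pair with
  a tag complement only if it shares a contiguous 4-mer with the
  underlying tag; the few remaining free bases are enumerated
  exhaustively. Oligos are tuned into a 53–58 °C band — inside the
  48–62 °C primer window and no wider than the 5 °C multiplex window —
  so a panel with no requested edges is genuinely conflict-free. The
  codebook supports up to 3 edges and 2 edges per oligo; larger
  requests fail loudly as unconstructible rather than degrade.

All generator randomness flows from one explicit integer seed through
an internal scope that saves and restores the caller's RNG state:
identical spec and seed give byte-identical output, and no generator
perturbs the global random stream.

Passing tests on these fixtures demonstrates algorithmic correctness —
exact recovery of known truth, agreement with brute-force oracles,
invariant preservation — not field performance on a real genome:
real assemblies have interrupted and compound repeats, transposon
context, assembly errors and coverage gaps that the generators
deliberately omit (interrupted/compound SSR merging is likewise left
out of the scanner by design: only perfect repeats are reported, and
the stated criteria are all in whole perfect-repeat counts).

## Numerical and degenerate-input choices

* Dimer energies are capped at 0 (no predicted duplex ⇒ exactly 0, not
  a small positive initiation-only value).
* Empty results are valid everywhere: an empty contig scans to an empty
  table, a genome with no design-grade loci produces an empty panel and
  a successful manifest, a profile with no window above threshold has
  zero hotspots.
* All table/report writes are atomic (temp file, then rename), so an
  interrupted run never leaves a truncated output.
* Problem sizes in the shipped test suite (contigs up to 10 kb,
  alignments up to 20 × 600, 50-locus planted genomes, 100 random
  conflict graphs) were chosen so that each brute-force oracle remains
  exact and the whole suite runs in a few minutes on one CPU.

## Known limitations

* The scanner reports perfect repeats only; imperfect or compound SSRs
  are split at every interruption.
* The dimer model is an ungapped screen; a full hybridization partition
  function (bulges, internal loops, dangling ends) would change
  energies near the thresholds.
* Greedy coloring is near-optimal, not optimal; a pathological conflict
  graph could use more multiplex sets than necessary.
* Candidate deduplication uses exact window identity (plus reverse
  complement); near-duplicate paralogous regions are not clustered.
* The diversity module requires a pre-aligned input and computes no
  haplotype statistics (Tajima's D and relatives are out of scope).
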