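---
title: "Genome architecture and infection transcriptomics of nematode-trapping fungi: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parasitome)
```

## The scientific setting

Nematode-trapping fungi (Orbiliomycetes) capture free-living nematodes with
specialised infection structures — adhesive knobs, nets, branches or
constricting rings. Comparative genomics of these fungi points at two
genomic mechanisms behind the adaptation to parasitism: gene duplication
followed by rapid divergence, and differential regulation of orthologous
genes between species. Both mechanisms leave quantitative fingerprints
that this package measures:

* **Repeat-induced point mutation (RIP)** — a fungal genome-defence
  mechanism, active during the sexual cycle, that mutates C to T in
  duplicated sequence, preferentially at CpA dinucleotides (and, on the
  opposite strand, TpG to TpA when read forward). RIP erodes young
  duplicates, biases dinucleotide composition, and can introduce premature
  TAA/TAG stop codons — shortening secreted proteins into small secreted
  proteins (SSPs).
* **Tandem duplication** — adjacent genes of the same ortholog family,
  expected from unequal crossover; its excess over chance is measured by a
  gene-order permutation test.
* **Secreted-protein gene clusters** — runs of adjacent secreted genes,
  a genome organisation first described for smut fungi.
* **Infection transcriptomics** — fold-change regulation sets and
  top-decile expression cohorts from count data, with hypergeometric
  enrichment of secreted/SSP/category classes, and a cross-species
  comparison of ortholog expression.

## Statistics and conventions

### RIP indices

For a sequence with dinucleotide counts $N(\cdot)$ (overlapping windows;
windows containing N are skipped):

* TpA/ApT index: $N(TA)/N(AT)$; values $\ge 0.89$ are called
  RIP-affected. The index measures the *product* of RIP while correcting
  for AT bias.
* Composite index: $(N(CA)+N(TG))/(N(AC)+N(GT))$; values $\le 1.03$ are
  called affected. It measures the *depletion of RIP targets*.

Both indices are invariant under reverse complement (TA and AT are their
own reverse complements; CA+TG and AC+GT are revcomp-closed pairs), so the
orientation of the sequence unit does not matter. Per-gene calls are made
on the CDS in coding orientation: the per-gene analysis targets coding
genes, and strand symmetry makes the choice immaterial. A gene whose index
denominator is zero is *undefined*: it counts in the denominator of an
affected fraction but never as affected — the conservative reading of
fractions quoted over "all genes". Zero-denominator indices are returned
as `NA` rather than an error.

Affected fractions of two gene sets are compared with a one-sided Fisher
exact test (`compare_rip_fractions()`); the hypergeometric tail is the
natural exact test for a difference in proportions of this form and is
verified against exhaustive enumeration in the test suite.

### Stop-codon census

The stop codon is the final three nucleotides of the CDS, uppercased; a
CDS not ending in TAA/TAG/TGA counts as `other`. RIP creates TA
dinucleotides, so RIP-exposed gene sets are expected to show elevated
TAA/TGA (and TAG/TGA) ratios — TGA is the one stop codon containing no TA.
Ratios are reported half-up to one decimal and are undefined when the TGA
count is zero.

### Rounding

All reported percentages and ratios use round-half-up
(`round_half_up()`), not R's default half-to-even, so printed summary
values are reproducible digit-for-digit from the underlying counts at the
stated precision.

### Tandem duplications and the permutation null

Two consecutive genes (in the start-sorted order of a contig, regardless
of strand or intergenic distance) sharing a non-null family id form a
tandem pair; maximal same-family stretches form runs, with the arithmetic
identity pairs = genes − runs. The permutation test shuffles family labels
uniformly over all gene positions genome-wide, holding per-contig gene
counts fixed — the simplest exchangeable null for "random reordering of
the genes"; a per-contig shuffle is available as an option. The P-value
uses the add-one Monte-Carlo estimator $(1+k)/(1+n)$ so it is never
exactly zero; with 1,000 permutations the floor is $1/1001 < 0.001$.

TE proximity is measured edge-to-edge (0 for overlap), with a strict
`< 10000` bp threshold. Midpoint-to-midpoint was the other defensible
reading; edge-to-edge was chosen because "located near a transposon" most
plausibly refers to the gap between features.

### Recent duplicates

RIP only recognises duplicates that are long and still similar, so the
recent-duplicate screen keeps pairs of genes whose CDS are both strictly
longer than 400 bp and globally alignable at ≥ 80% identity (inclusive,
following the wording "at least 80%"). Identity is matches over alignment
columns of a Needleman–Wunsch global alignment with match +1, mismatch −1
and affine gap cost (open 2 + 1 per position). The published analysis used
a clustering heuristic whose internal identity definition is not
reproducible; emulating that tool is a non-goal, so the scoring scheme is
explicit and configurable instead. When several alignments are co-optimal
the score is unique but the reported identity refers to the returned
alignment; the test suite therefore checks scores against an independent
dynamic-programming oracle exactly, and checks identity for consistency
with the returned alignment.

The `recent_duplicates()` operation is all-vs-all exact. The *pipeline*
stage, however, defaults to scanning only genes with a family assignment
(`recent_scope = "families"`): an all-vs-all alignment of even a modest
600-gene genome is ~180k kb-scale alignments, far beyond a desk-scale run,
and in this package's synthetic world duplicates exist only within
families. `recent_scope = "all"` restores the full scan.

### Secreted-gene clusters

The published rule has two prongs ("at least three adjacent secreted
genes" / "more than three genes with at most one non-secreted gene in
between"). These unify into one rule: maximal chains of secreted genes in
which consecutive secreted genes are separated by at most one non-secreted
gene, reported when the chain has ≥ 3 secreted members. The pure-secreted
prong is the zero-gap special case, and any chain with a gap necessarily
spans ≥ 4 genes. Clusters are trimmed to start and end on secreted genes
(flanking non-secreted genes have no support in the rule) and never cross
contig boundaries. The detector is verified against a brute-force
enumeration of all contiguous windows on random annotations.

### Expression analysis

Counts are normalized by median-of-ratios size factors (the DESeq
estimator; verified against `DESeq2::estimateSizeFactorsForMatrix`).
Dispersion modelling, testing and multiple-testing correction are out of
scope — externally computed q-values are accepted as a pass-through input
column, because fold-change selection (not testing) drives the gene sets
in scope.

Fold change is mean normalized infection over mean normalized control
expression. Thresholds are strict ("more than two-fold/ten-fold"): FC = 2
is not in `up2`. A gene silent in the control with infection signal has
FC = +Inf and belongs to all up sets; a gene silent in both is excluded.
The top-decile set ranks genes with nonzero mean normalized expression in
the condition and takes the top `floor(0.1 * n_expressed)`, ties broken by
ascending gene id. The published "10% most highly expressed (1,069
genes)" matches neither 10% of all genes nor of expressed genes, so the
selection universe is unrecoverable; the floor rule over expressed genes
is this package's declared convention and 1,069 is not a target.

Enrichment of a class within a cohort is the one-sided hypergeometric
upper tail against the genome-wide background (equivalently one-sided
Fisher), the conventional choice where the source analysis names only
"significantly enriched". The cross-species ortholog comparison classifies
pairs by the ratio of mean normalized infection expression with strict
10-fold thresholds; size factors are computed within species, so
cross-species comparability of normalized scales is the caller's
responsibility. Two time-point samples of one species are treated as two
replicates of a single infection condition.

## The synthetic world

`generate_genome()` emulates the published genome profile at desk scale:
GC 45% (observed 45.2/44.5%), 15.2% secreted genes, 41.7% of secreted
genes SSP-sized (695/1,666), mean protein ≈ 400 aa (between the published
core and species-specific means), single-exon genes with ATG starts,
stop-free bodies, sampled TAA/TAG/TGA stops (configurable probabilities so
stop-bias tests can plant known ratios), and intergenic spacers of ~1.5 kb
(gene density of ~270 genes/Mb). Category, orphan, Pfam and
expanded-family labels are drawn at the published marginal rates
(62/20/16% core/lineage/species-specific, 71% orphans among
species-specific, ~8–12% expanded-family membership among Pfam-labelled
genes). It is a stated world, not a fit: none of these knobs are adjusted
to make tests pass.

Planted structure is what makes the generator testable:

* **Tandem runs** are blocks of adjacent genes sharing a fresh family id;
  copies after the first are RIP-mutated duplicates of the first, so the
  tandem scan, the RIP metrics and the recent-duplicate screen see a
  consistent story. Background "scattered families" are placed with a
  non-adjacency constraint so the ground-truth pair count is exact.
* **Clusters** are secreted runs with a configured number of single-gene
  non-secreted interruptions. Two forced non-secreted buffer genes flank
  each planted structure — without them a background secreted gene two
  positions away would legally extend the chain and change the planted
  member set.
* **RIP** (`apply_rip()`) is one left-to-right pass over the original
  sequence: each forward CpA loses its C to T, each forward TpG its G to A,
  independently with the configured rate (a separate TpG rate is exposed
  because the two real genomes differ in CpA depletion; no asymmetry is
  assumed by default). Targets are identified on the original sequence, so
  the operator is order-independent and never chains within a pass —
  matching one round of the sexual cycle. Every mutation converts a CA or
  TG window into TA, which gives the tested invariant that TA counts never
  decrease.

What the generator does **not** emulate: introns, codon-usage structure
beyond GC content, read-level data, assembly artefacts, and realistic
family-size or expression-mean distributions beyond a log-normal baseline.
A green planted-recovery test therefore establishes correctness of the
detectors' logic on well-separated signal, not performance on borderline
real data.

### Planted fold changes and the open-class boundary

The regulation classes are open sets ("more than ten-fold"). A gene whose
infection mean is exactly 10x its control mean lies on the class boundary:
an unbiased fold-change estimate falls below 10 about half the time at any
noise level, and even noiseless counts give FC = 10, which the strict
inequality excludes. Planting the truth at the boundary of the set that is
supposed to recover it is a self-contradiction, so the generator plants
class members at twice the class threshold by default
(`fold_up10 = 20`, `fold_up2 = 4`; 4 < 10 keeps 2x-class genes out of the
10x class). Both multipliers are config knobs. This was decided from the
boundary analysis above, before running the recovery tests.

## Worked-example fixtures

Summary statistics of the kind this package reports are pure functions of
class counts. The `fixture_*()` constructors assemble annotations with a
prescribed composition — n genes of which k RIP-affected, given stop-codon
tallies, planted run/cluster profiles, cohort compositions — so a published
count profile can be replayed through the real code paths and the
reported statistic checked digit-for-digit (see
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`). The
fixture sequences are minimal synthetic templates, not biological
sequences; what is being tested is the statistic pipeline, not sequence
realism.

## Numerical and degenerate-input choices

* Indices and ratios with zero denominators are `NA` ("undefined"), never
  errors; fractions over empty classes are `NA` percentages.
* Dinucleotide windows containing N are skipped; counts over a
  concatenation joined by one N equal the sum of per-piece counts.
* Monte-Carlo P-values use the add-one estimator and are never 0.
* All generators are pure functions of (config, seed); the pipeline
  derives per-stage seeds from one master seed so stages can be re-run
  individually. Seeds stay below 2^31.
* Ties in the top-expression ranking break by ascending gene id;
  duplicate gene ids anywhere are a hard error.
* The loader does not re-apply the 48-aa minimum length filter used at
  gene-prediction time in the source study; whether downstream tables
  re-applied it is unstated, and filtering at load would silently change
  denominators.

## Known limitations

* Genome-wide RIP index values of real assemblies depend on the full
  repeat complement; this package's per-gene calls and fractions are the
  supported quantities, and whole-assembly index values are not a target.
* The all-vs-all recent-duplicate scan is exact but quadratic; use the
  pipeline's family scope (default) for large gene sets.
* Cross-species expression comparability is assumed, not enforced.
* Internally inconsistent printed fractions in the source material (e.g. a
  cluster/upregulation fraction whose numerator and denominator do not
  yield the printed percentage) are excluded as targets; the summary
  operations report computed values only.
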