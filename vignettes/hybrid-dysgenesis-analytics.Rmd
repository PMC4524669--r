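---
title: "Hybrid dysgenesis TE/piRNA analytics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid dysgenesis TE/piRNA analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dysgenTE)
```

## Scope and model of the system

`dysgenTE` analyses intraspecific hybrid dysgenesis of the *D. virilis*
kind: an inducer strain carries several TE families in excess over a
reactive strain, paternal transmission of those families outruns the
maternal piRNA pool, and the resulting germline damage leaves measurable
traces — asymmetric TE copy number, shifted piRNA pools and ping-pong
signatures, increased genic piRNA production, transgenerational expression
changes, and a polygenic architecture of maternal protection. Each stage of
the package corresponds to one of those measurements. This vignette
documents the quantitative definitions, the tunable parameters with their
defaults and rationale, the synthetic-data model used to validate
everything, and the design decisions taken where the methodology was
genuinely open.

## Coordinates and read-level conventions

All coordinates are 1-based and closed, the native convention of
IRanges/GenomicRanges and SAM; BED-style half-open input would be converted
at the boundary. This is a deliberate choice: a single internal convention,
shared with the containers the package is built on, prevents off-by-one
drift. Two further conventions matter throughout:

* a minus-strand read's 5′ end is the **rightmost** base of its span
  (required by the ping-pong overlap rule);
* per-million denominators are **read-level** totals — a multi-mapped read
  counts once, not once per placement — matching normalisation "by reads
  mapping to the genome, multimappers included".

The fixture-scale mapper `align_exact()` is exact and ungapped. It exists
so tests and simulations run without an external aligner; real data is
expected to enter pre-aligned through `load_alignments()` (SAM/BAM), and
the mismatch tolerance of a production aligner is deliberately not
reproduced.

## TE landscape

**Abundance.** `compute_abundance()` counts each read once toward its best
family (ties broken by first family name, so results are order-independent)
and reports reads per million genome-mapped reads.

**Homogeneity (age) statistic.** For each family,
`compute_homogeneity()` piles reads on the consensus and averages the major
nucleotide variant's frequency over covered positions. Young, recently
active families have near-identical copies and score near 1; old residents
accumulate substitutions among copies and score lower. Choices made here:

* *min_coverage* defaults to 4. Single-read positions contribute a trivial
  major-variant frequency of 1.0 and would bias sparse families upward;
  requiring modest depth suppresses that. Setting `min_coverage = 1`
  reproduces the literal "all covered positions" reading.
* Non-ACGT pileup columns (Ns) are excluded from both numerator and
  denominator.
* The statistic is scale-invariant (duplicating all reads changes nothing)
  and equals 1 exactly when every read matches the consensus.

**Enrichment and scenarios.** `call_enrichment()` uses a pseudocounted
ratio `(pm_A + 0.1) / (pm_B + 0.1)` with a 3-fold default cutoff. The
pseudocount (0.1 per-million units) keeps ratios finite at zero counts; the
source methodology states no value, so it is explicit and tunable.
`classify_scenario()` encodes the interpretation grid: enrichment plus high
homogeneity (`hom_high`, default 0.98) plus a clear homogeneity gap
(`hom_gap`, default 0.03) reads as strain-specific re-activation; if the
other strain is additionally essentially devoid of the element
(`absent_pm`, default 1 per million) the call becomes an invasion not yet
shared — the grid distinguishes these because a family "entirely absent in
one strain" is the hallmark of a new invasion. Enrichment with similar
homogeneity in both strains is a shared recent invasion when both are young
and an old resident otherwise. The thresholds are explicit stand-ins for a
qualitative visual classification and are all configurable.

## Small RNAs and the ping-pong signature

`class_small_rnas()` filters against structural-RNA libraries first, then
classes by length: piRNA 23–30 nt, siRNA exactly 21 nt.

**Pair counting.** The ping-pong amplification cycle produces
opposite-strand pairs whose 5′ ends overlap by exactly 10 nt. With
`c+(p)` plus-strand 5′ counts and `c−(q)` minus-strand 5′ counts,
`pingpong_pairs()` returns `sum_p min(c+(p), c−(p+9))`. Because each plus
position has exactly one partner position, this per-position `min()` *is*
the maximum bipartite matching in which each read is used at most once —
the "non-redundant pairs, counting each read only once" definition — and
the test suite verifies equality with an explicit augmenting-path matcher
on hundreds of random libraries. Percent ping-pong counts reads having *at
least one candidate partner* (not only matched reads), the literal reading
of "had a corresponding read on the opposite strand".

**Densities.** Two normalisations are reported side by side, as both are in
field use: pairs per kb of consensus, and pairs per million piRNAs mapped
in the library (read-level denominator).

**1U/10A biases.** `signature_bias()` reports the fraction of reads with
U at position 1 and A at position 10. The baseline is the mean per-position
frequency of the focal base over all *other* positions (off-position
composition); whether published baselines are off-position or whole-read
composition is ambiguous, so the whole-read variant is available via
`background = "whole_read"`. For typical read sets the two differ by less
than a percentage point.

**Z-scores.** `row_zscores()` uses the population (n-denominator) standard
deviation by default — a display normalisation, not an inference — with the
sample variant available; constant rows map to zeros and are flagged.

## Genic piRNA targeting

`genic_density()` uses unique mappers only (`n_hits == 1`), counts a read
for a gene when its span intersects a CDS interval, and normalises per
million genome-mapped reads. The per-million denominator includes
multimappers while the numerator is unique-only; this asymmetry is
implemented literally as specified for the genic tables. A read overlapping
two genes' CDS counts for both — no fractional assignment, because
fractions would make the ≥ 5 per-million target threshold depend on
annotation overlap structure. Genes without CDS hits are excluded (logged),
and `select_targets()` additionally requires a *D. melanogaster* ortholog
by default to screen out TEs mis-annotated as genes. Selection uses the
maximum density over libraries ("at least 5 per million in *either*
library") and is provably monotone in the threshold.

`exon_intron_contrast()` is a paired t-test across genes of exon vs intron
density (exon enrichment indicates cytoplasmic processing of spliced
transcripts); a degenerate all-equal sample returns t = 0 rather than NaN.
`chip_enrichment()` collapses duplicate reads (same target, start, strand,
length), keeps unique mappers and reports per-million-normalised IP:Input
ratios, undefined where input coverage is zero.

## Expression analytics

RPKM is `count * 1e9 / (length * mapped_total)`. Folds are computed on
condition-mean RPKM with a 0.01 pseudocount, making `fold(A,B) *
fold(B,A) = 1` exactly; when replicates exist the condition mean (not
per-library folds) is used, with per-library RPKM still exportable.
Features with fewer than 40 reads total across all samples are removed
before any testing. Differential-expression testing itself is a pluggable
external stage (count matrices out, results tables in): re-implementing a
negative-binomial GLM would add risk without adding any methodology that is
specific to this system.

**TE typology.** `classify_te_type()` encodes the six-way classification of
dysgenesis-responsive TEs by (copy-number side, piRNA side, F1 ping-pong
fate). The thresholds — `tau_abund = 0` (any log2 excess), `tau_pirna = 1`
(2-fold), `maternal_ratio = 2` — are the unique simple values consistent
with every row of the published reference table bundled as
`dysgenic_te_profiles()` (the categories are stated only verbally in the
source); the acceptance suite checks all fourteen rows reproduce exactly.

**Allelism.** `allele_counts()` partitions reads overlapping a diagnostic
SNP by the observed base, ignoring (and reporting) non-diagnostic bases;
`allele_contingency_test()` is a two-sided Fisher's exact test contrasting
allele counts between tissues.

## Protection genetics

**Ancestry painting.** `build_pseudodiploid()` concatenates the two
strains' scaffold consensi into one haplotype each; `assign_reads()`
accepts a read as donor-derived only with a sole, confident placement
(`mapq_min`, default 30 — the contract is "sole best placement above a
stringent confidence threshold"; the exact numeric scale is
aligner-specific, so it is a parameter rather than a constant).
`paint_ancestry()` tiles scaffolds with 10 kb windows, calls a window
heterozygous-for-donor when its unique-donor base-pair density reaches
`min_density_fraction` (default 0.25) of the genome-wide mean, and smooths
runs shorter than `min_run` (default 3) windows. Threshold/run-length
smoothing was chosen over an HMM deliberately: the underlying published
calls were made from density valleys by eye, and a transparent two-state
rule with documented knobs is easier to audit against that. With zero
unique reads the painting is no-call rather than all-recipient.

**Induction and QTL.** `induction_logodds()` is a logistic GLM
(binomial/logit) on paternal chromosome indicators with Wald intervals;
complete separation is detected and flagged with infinite intervals.
`single_marker_qtl()` regresses the dysgenic-testes proportion on each
marker (statistic |t|); the genome-wide threshold is the 95th percentile of
the max-statistic over phenotype permutations (default 5000), which is
robust to the non-normal proportion phenotype. Monomorphic markers are
skipped, and the max-statistic construction makes the threshold rise with
marker count, as the property tests verify.

**Candidate elimination.** `eliminate_candidates()` implements the
two-step argument: only TEs with more inducer-strain piRNA than
reactive-strain piRNA qualify as candidate drivers; then any candidate for
which at least one fully protective female carries that TE's piRNA at or
below the reactive baseline is ruled out — she protects without it. The
boundary is "less than or equal to" by definition; a tolerance band
(default 0) is available for borderline noise. Adding protective females
can only shrink the surviving set.

## The synthetic-data model

Every stage is validated on generated data with planted parameters:

* **Strain genomes** are a shared random background plus full-length TE
  copies, each copy independently substituted at rate *d* (no indels).
  Substitution-only divergence gives the homogeneity statistic a
  closed-form expectation of about `1 - d*(k-1)/k` for *k* equal-frequency
  copies at high coverage, which the tests check to ±0.02.
* **Pre-aligned TE mappings** (`simulate_te_alignments()`) place uniform
  reads on each genome and record reads falling wholly inside a planted
  copy as consensus alignments, emulating data that enters pre-aligned.
  Note that per-million normalisation divides by the whole genome's read
  count, so strains with very different total TE content have slightly
  biased abundance ratios; recovery tests plant a strain-B-specific filler
  family to keep genome sizes equal, and real genomes (where single-copy
  sequence dominates) sit close to that regime.
* **Small-RNA libraries** draw lengths from a distribution with an siRNA
  peak at 21 nt and piRNA mass at 23–30 nt, emit a planted fraction *f* of
  piRNA reads as exact 10-nt 5′–5′ overlap pairs, and give primary reads a
  1U bias (default 0.33) and pair partners a 10A bias (default 0.25)
  against a slightly GC-rich composition (U 0.21, A 0.22). The default
  simulated repeat library has 200 families of 2–8 kb (about 1 Mb of
  consensus), sized like a curated *D. virilis* repeat library; at the
  10,000-read library size used in recovery tests this keeps chance
  10-nt-overlap collisions well under one percent, so the planted *f* is
  identifiable. These choices were fixed once as the study conditions.
* **F3 panels** model the protection design: a fully heterozygous F1
  backcrossed twice into the recipient, female meioses with Poisson
  crossover counts (mean 1 per chromosome) at uniform positions — a
  standard minimal model, since no specific map function is prescribed —
  and a phenotype that is binomial (40 testes) around a logistic function
  of planted locus effects. Karyotype defaults are six *D. virilis*-like
  elements (2–30 Mb) with telomeric, pericentric and euchromatic markers.
* **Induction panels** exploit the absence of crossing over in *Drosophila*
  males: paternal chromosomes are transmitted whole, Bernoulli(1/2).
* **Donor-unique origins** for painting place reads at 2×10⁻³ per base
  inside heterozygous blocks and 2×10⁻⁶ outside — under stringent unique
  filtering essentially no read from a recipient-homozygous region maps
  uniquely to the donor haplotype.

What passing these tests shows — and does not show. The generators plant
exactly the signal each statistic measures, with none of the confounders of
real libraries: no sequencing error, no PCR duplicates, no indels, no
mapping bias, no shared subsequences between TE families, no LD structure
beyond the backcross design. Recovery therefore demonstrates that the
implementations measure what they claim, with correct normalisation and
calibrated error rates; it does not demonstrate robustness to real-data
artefacts, which enter upstream of this package (trimming, mapping,
deduplication).

## Problem sizes and numerical choices

The shipped tests and the acceptance script use deliberately desk-scale
conditions, chosen as the smallest sizes at which each planted parameter is
identifiable at its stated tolerance: 10,000-read small-RNA libraries over
the 200-family library; 20-copy families at 50× coverage for homogeneity;
10× coverage and 2 kb consensi for copy-ratio recovery; 100-female panels
with 500 permutations and 200 replicates for QTL calibration (the
permutation threshold is unbiased at any permutation count; 500 merely
widens the quantile's noise). Headline numbers of the motivating study
(e.g. counts of differentially expressed TEs or of genic targets in
specific libraries) depend on unreleased sequencing libraries and are not
reproducible at desk scale; the acceptance layer is therefore
property-based, anchored by the in-paper worked values that *are*
reproducible (the fourteen-row typology and the pseudocounted fold of its
most extreme element).

Degenerate inputs are handled explicitly rather than coerced: empty read
sets class to empty; zero mapped totals are errors (a per-million figure
would be meaningless); a family with no qualifying pileup positions has
*undefined* homogeneity, not 0; percent ping-pong with no mapped piRNAs is
undefined while densities are 0; an all-zero contingency table is an error;
separated logistic fits are flagged instead of reporting absurd intervals.

## Known limitations

* `align_exact()` is exact-match only; diverged reads must enter
  pre-aligned.
* Scenario classification needs pileups in both strains; a family absent
  from one strain can only be classified through the `absent_pm` branch.
* The painting smoother is resolution-limited to `min_run` windows;
  introgressed blocks shorter than that are invisible by construction.
* The panel simulator's uniform crossover model ignores interference and
  centromere suppression; marker-level genotype frequencies are still
  exact, which is all the QTL calibration uses.
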