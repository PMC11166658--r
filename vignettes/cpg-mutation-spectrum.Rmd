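---
title: "Methods: CpG-centric mutation spectrum analysis for clonal genomes"
author: "cpgmutspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CpG-centric mutation spectrum analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpgmutspec)
```

## The scientific problem

Clonally derived cell lines — induced pluripotent stem cells (iPSCs) are
the motivating case — accumulate hundreds to thousands of de novo single
nucleotide variants (SNVs) per genome. Two questions dominate their
interpretation: are the variants truly de novo (as opposed to pre-existing
sub-clonally in the parental cell population), and what mutational process
produced them? The diagnostic fingerprint for the second question is the
strand-collapsed mutation spectrum: C>T transitions at CpG dinucleotides
(the substrate of DNA methylation, where deamination of 5-methylcytosine
is a known hotspot mechanism) behave differently from C>T at other
cytosines (plain cytosine deamination), and their regional distribution —
CpG islands, transcription start sites, differentially methylated regions,
retrotransposon subfamilies such as AluY — carries information about
methylation-coupled mutagenesis during reprogramming.

This package implements the complete desk-side statistical pipeline:
candidate filtering, spectrum normalization, sister-clone sharing
analysis, regional enrichment, codon-level consequences — plus a seeded
synthetic-data generator so that every statistic can be verified against
a known ground truth.

## The identification filters

A candidate SNV carries read-level metrics computed by the upstream
caller: depth, variant-allele count, the phred quality of the central
base, the mean quality over an 11-base window, and the gap+mismatch count
in that window. The filters (defaults in `filter_params()`) are:

* central base quality >= 30; mean surrounding quality >= 15 (11-base
  window); gaps+mismatches <= 2; depth >= 20;
* exclusion of variants with >= 2 variant-allele reads in the parental
  sample, or in any sister clone (the sister rule is switched **off**
  for shared-SNV analysis);
* exclusion of known (dbSNP) variants, simple-repeat and homopolymer
  positions;
* variant allele frequency within 35–65%, both bounds inclusive — the
  heterozygous band. We read "35–65%" as a closed interval; a candidate
  at exactly 0.35 or 0.65 is accepted.

Acceptance is a conjunction of independent predicates and therefore
order-free; the removal *report* attributes each rejected record to the
first failing predicate in the order listed above, which mirrors the
order in which the protocol lists them.

Design choices where the protocol is silent:

* **Homopolymer** is defined as a single-base run of length >= 7
  (configurable). The exclusion is named in the protocol without a
  length; 7 is the shortest run at which indel-induced miscalls dominate
  in short-read data.
* **Visual curation** of alignment-error regions is not automated; it is
  represented as an optional user-supplied blacklist track
  (`apply_filters(..., blacklist = )`).
* The surrounding-quality mean is modeled as one scalar per candidate,
  computed over the full window as supplied by the caller; whether the
  upstream tool excludes the central base from that mean is not
  recoverable from its output.
* dbSNP membership arrives as a per-record flag, not a live lookup.

## The 24-category spectrum and its normalization

Every substitution is collapsed to a pyrimidine reference: a `G>A` call
is read off the reverse-complement strand as `C>T`, and its "3'
neighbor" is the complement of the base 5' of the variant. Six classes
times four 3' neighbors gives 24 categories; `is_cpg` means class `C>*`
with neighbor `G`. Counts alone are not comparable across categories
because contexts differ in genomic abundance, so each cell is divided by
the number of corresponding dinucleotide sites and scaled per 1e9 bases:

$$\mathrm{rate}[c, b] = \frac{\mathrm{count}[c, b]}
{\mathrm{abundance}[\mathrm{pyr}(c), b]} \times 10^9 .$$

Abundance is counted on **both strands** with the same pyrimidine
collapse as the numerator: an occurrence of dinucleotide XY on the plus
strand and an occurrence whose reverse complement is XY each contribute
one site. CG and TA are their own reverse complements, so each
occurrence contributes two sites — exactly matching the two mutable
cytosines of a CpG. Overlapping occurrences count; windows containing
`N` are excluded from both the numerator (such calls are flagged and
tallied separately, never silently dropped) and the denominator.

Two invariances pin the convention down and are tested: the spectrum is
identical under reverse complementation of the genome (with remapped
calls), and normalized rates are unchanged when genome and call set are
duplicated.

## Synthetic data: the stated world

The generator emulates exactly the features the statistics consume, and
no more.

* **Genome** (`generate_genome()`): a first-order Markov chain over
  bases. The transition matrix comes from a target joint dinucleotide
  distribution $Q = \pi \otimes \pi + c\, u \otimes v$ (with $u = e_C -
  \pi$, $v = e_G - \pi$), which has marginals exactly $\pi$ and CpG cell
  exactly $\mathrm{o/e} \cdot \pi_C \pi_G$; the chain built as $P = Q /
  \pi$ is stationary at $\pi$, so the realized CpG frequency converges
  to its target with no bias. Defaults GC = 0.41 and CpG o/e = 0.2
  mirror a mammalian genome. Infeasible (GC, o/e) pairs are rejected
  with the feasible bound. CpG observed/expected is the single sequence
  property the abundance normalization depends on, which is why the
  generator controls it and nothing subtler (no isochores, no repeats in
  the sequence itself).
* **Annotations** (`generate_annotations()`): disjoint windows per track
  with realistic default fractions (SINE 10% of the genome in ~300-bp
  elements, LINE 15%, LTR 5%, CGI 0.7%, DMR 2%); CGIs sit on the most
  CpG-dense windows, and SINE placement is CpG-biased by default
  (`cpg_bias_in_sine`), echoing the CpG richness of Alu elements. The
  SINE subfamily mix defaults to an AluJ/AluS/AluY composition
  (~23/62/15) in the range reported for the human genome.
* **Mutations** (`simulate_mutations()`): sites are drawn *without
  replacement* with probability proportional to their context rate
  (exponential-key weighted sampling — vectorized, exact, deterministic
  under a seed), so a site mutates at most once. The default
  `rate_table()` is a flat background with the CpG C>T cell raised
  10-fold, matching the observed >10-fold CpG transition efficiency.
* **Clone families** (`simulate_clone_family()`): private mutations per
  clone (default 742, the mean per-line burden observed across 35 mouse
  sister clones), designated shared subsets, and pre-existing sub-clonal
  variants that appear in the parental allele table at cell fraction
  $f$ (allele count drawn Binomial(depth, $f/2$)) and in the clones
  descending from that sub-clone. True VAF is Beta(50, 50) around 0.5 —
  consistent with the 35–65% heterozygous acceptance band — and the
  observed count is Binomial(depth, VAF); depth is Poisson around 40
  (roughly 130 Gb on a 3 Gb genome). With `metric_noise = FALSE` every
  record gets clean passing metrics, giving an exact no-false-removal
  baseline. A `fail_fraction` of records is deliberately forced to fail
  a named filter, rotating through all ten failure modes; the truth
  ledger records, for every emitted record, its origin and the filter
  expected to remove it (computed by plain inline comparisons,
  independent of the filtering module).

What a green test does *not* establish: the generator has no read-level
error model (no FASTQ/BAM), no mapping artifacts, no copy-number or
clustered-mutation structure, and annotation tracks are placed rather
than evolved. Conclusions transfer to real data only through the
filters' and statistics' contracts, not through realism of the noise.

## Sister-clone statistics

Shared SNVs are exact key matches (contig, position, ref, alt) across
call sets produced with the sister filter off. Because "fraction shared"
is ambiguous when a variant occurs in more than two clones, both
definitions are computed: unique shared keys over all distinct keys, and
shared call-set entries over all entries. Neither is asserted as the
published definition (the published count is consistent with an
instance-based reading).

Reference-swap concordance between two identifications of the same clone
is the Jaccard index on keys, in percent. The published figure prints a
"concordance rate" without a formula; Jaccard is symmetric, equals 100
for identical sets, and reproduces the 99.0–100% framing. The asymmetric
|A∩B|/|A| variant is available as an option. In the synthetic
reference-swap model, using a sister as reference makes exactly the
variants that the sister also carries invisible; a homogeneous parental
population contributes no further differences.

## Enrichment statistics

* **Compartments**: precedence CDS > intron > intergenic (the protocol
  does not state a hierarchy; coding consequence outranks position).
  Intron means inside a transcript span but outside its CDS.
* **Retrotransposon classes**: percentages of CpG and non-CpG C>T calls
  falling in LINE/SINE/LTR, compared per class with the pooled
  two-proportion Z-test. Because the natural denominator is ambiguous,
  both "share of C>T calls of that CpG status" and "share of all calls"
  are emitted.
* **Alu subfamilies**: per-subfamily share of CpG C>T calls within whole
  SINEs, for the test cohort and a germline comparator; the
  test/germline ratio is rescaled so AluJ (sum of AluJ* subfamilies,
  the oldest family) equals 1. Groupings: AluJ*, AluS* sums, AluY
  alone, AluYa–AluYk sum. A variant inside overlapping repeats counts
  once per class, with the longest-overlap subfamily winning.
* **DMR ratio**: C>T rates inside vs outside DMRs, normalized per
  available site — CpG cytosines for CpG C>T, other cytosines for
  non-CpG C>T, both strands — so the ratio is 1 under uniform
  per-site mutation regardless of how CpG-dense the DMRs are.
* **CGI shores**: ±5 kb flanks minus any CGI, clipped at contig ends.
* **TSS distance**: strandless |position − TSS| minimized over all TSSs
  (verified against an exhaustive scan), histogrammed over configurable
  bins, with an optional per-clone/per-individual ratio against a
  germline cohort. The germline comparator used in tests is simulated
  with abundance-proportional (uniform-rate) placement, reflecting the
  observation that germline CpG C>T tracks CpG abundance.

## Coding consequences

Calls in CDS exons are mapped into spliced coding coordinates
(minus-strand transcripts reverse-complemented), the codon rebuilt, and
the change classified under the standard genetic code (nonsense >
missense > silent for per-variant summaries across overlapping
transcripts). `cpg_ct_codon_census()` enumerates — with no inputs —
every codon change reachable by a CpG-context C>T on either strand,
stating the required flanking base when the CpG partner lies in the
neighboring codon. Two structural facts fall out of the enumeration and
are asserted in tests: CGA→TGA is the *only* coding-strand CpG C>T that
creates a stop, and all four CGN arginine codons are CpG-initial, which
is why arginine dominates the substitution census. (A published
description of the Glu→Lys change calls Glu "glutamine"; biochemically
the CpG-consistent change is glutamate GAA/GAG with a 5' C going to
lysine, and that is what the census reports.)

## Numerical and statistical choices

* Coordinates: variants are 1-based (VCF), intervals 0-based half-open
  (BED) at I/O and 1-based closed (GRanges) internally.
* The Z-test is the classic pooled two-proportion statistic without
  continuity correction; degenerate pooled proportions (0 or 1) are
  flagged rather than returning an arbitrary p.
* Ratios with a zero denominator are `NA` and flagged
  (`undefined`/`degenerate` fields), never silently 0.
* Pearson correlations across clones are `NA`-flagged when a variance
  is zero.
* All randomness flows through explicit integer seeds; sampling is
  integer-indexed (no hash or iteration-order dependence), so output is
  reproducible across platforms.
* In null-calibration tests the asymptotic Z-test is exercised at
  expected cell counts of ~50 (CpG-rich genome, 30% SINE fraction);
  at the original desk-scale counts (~1 expected call) the normal
  approximation is not in its validity regime and no calibration claim
  would be meaningful.

## Known limitations

* No read-level simulation; metric noise is distributional, not
  alignment-derived. The filters' behavior on mapping artifacts is
  exercised only through the blacklist mechanism.
* The sister-reference concordance model treats the sister's consensus
  as reference; it does not simulate caller behavior at sites where the
  reference itself is heterozygous.
* Splice-site consequences are out of scope, as are signature
  decompositions beyond the 24-category scheme (no 96-context NMF).
* DMRs are consumed as a track; the package does not derive them from
  methylation data.
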