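# cpgmutspec

Statistical toolkit for de novo point mutations in clonally derived
genomes — induced pluripotent stem cell (iPSC) lines are the motivating
case — with a focus on C>T transitions at CpG dinucleotides, the substrate
of DNA methylation. It is aimed at researchers who already have candidate
SNV calls (plus read-level metrics) and annotation tracks, and who want
the downstream identification filters and CpG-centric statistics as
tested, reusable code.

## What it computes

* **Identification filters** (`apply_filters`): central base quality ≥ 30,
  mean surrounding quality ≥ 15 over an 11-base window, gaps+mismatches
  ≤ 2, depth ≥ 20; exclusion of variants with ≥ 2 variant alleles in the
  parental sample or any sister clone, known (dbSNP) variants,
  simple-repeat/homopolymer positions; VAF within the inclusive 35–65%
  heterozygous band. Removal counts are reported per filter.
* **Strand-collapsed 24-category spectrum** (`build_spectrum`): every
  substitution is represented with a pyrimidine reference and its 3'
  neighbor (6 classes × 4 neighbors); each cell is normalized by the
  genomic abundance of its dinucleotide counted on both strands,

  rate[c, b] = count[c, b] / abundance[pyr(c), b] × 10⁹ (per 10⁹ bases),

  so CpG C>T (class `C>T`, neighbor `G`) is directly comparable with every
  other context.
* **CpG partition and correlations** (`cpg_partition`,
  `correlate_partition`): per-clone percentages of CpG and non-CpG C>T
  and their Pearson correlation with total SNV burden across clones.
* **Sister-clone analysis** (`shared_snvs`,
  `reference_swap_concordance`): exact-key shared variants across clones
  (both shared-fraction definitions), and Jaccard concordance between
  identifications of one clone against different reference samples.
* **Regional enrichment** (`assign_regions`, `retrotransposon_rates`,
  `sine_subfamily_enrichment`, `dmr_ratio`, `cgi_shore_counts`,
  `tss_distance_profile`, `z_test_two_proportions`): CDS/intron/intergenic
  compartments, LINE/SINE/LTR percentages with pooled two-proportion
  Z-tests, Alu-subfamily enrichment relative to a germline cohort
  (rescaled to AluJ = 1), per-site-normalized C>T rate ratios inside vs
  outside DMRs, CGI and ±5 kb shore counts, distance-to-TSS profiles.
* **Coding consequences** (`annotate_coding`, `cpg_ct_codon_census`,
  `summarize_effects`): codon-level nonsense/missense/silent calls under
  the standard genetic code, and a closed-form census of every codon
  change reachable by a CpG-context C>T (whose structure explains why
  CGA→TGA is the unique coding-strand CpG nonsense change and why
  arginine dominates).
* **Synthetic data** (`generate_genome`, `generate_annotations`,
  `simulate_mutations`, `simulate_clone_family`): a seeded generator with
  controllable GC content and CpG observed/expected ratio, annotation
  tracks, context-specific mutation rates, sister-clone families with
  shared/private/pre-existing variants, read-metric noise, and a complete
  truth ledger.

File formats: FASTA genomes (Biostrings), VCF 4.2 candidates/calls with
documented custom INFO tags (VariantAnnotation), BED-style tracks
(0-based half-open), JSON configs. See the methods vignette
(`vignettes/cpg-mutation-spectrum.Rmd`) for the model, conventions, and
design decisions.

## Worked example

```r
library(cpgmutspec)

genome <- generate_genome(1e6, seed = 1)       # GC 0.41, CpG o/e 0.2
ann    <- generate_annotations(genome, seed = 2)
fam <- simulate_clone_family(
  genome, rate_table(cpg_ct_fold = 10),        # CpG C>T 10x enriched
  clone_family_config(n_clones = 3, n_private_per_clone = 300,
                      shared = list(list(clones = c(1, 2), n = 5)),
                      fail_fraction = 0.1, seed = 3))

res <- apply_filters(fam$clones[[1]], filter_params(), genome = genome)
res$report
#> filter_report: 305 candidates -> 247 accepted
#>   removed by depth          3
#>   removed by central_qual   3
#>   removed by surround_qual  3
#>   removed by gap_mismatch   3
#>   removed by parental       3
#>   removed by known          3
#>   removed by sister         5
#>   removed by simple_repeat  3
#>   removed by homopolymer    3
#>   removed by vaf            29
```

The 30 deliberately corrupted records (10% of 305) are each caught by
their intended filter; the 5 designed shared variants fall to the sister
filter; the extra VAF removals are true heterozygous calls whose binomial
sampling at depth ~40 landed outside 35–65% — the same attrition the
filter inflicts on real data.

```r
build_spectrum(genome, res$accepted)
#> spectrum_table: 247 classified SNVs (0 excluded, N context)
#> normalized rate per 1e9 bases (rows: class, cols: 3' neighbor):
#>            A         C         G        T
#> C>A 75487.24  19640.38  58775.13 68709.63
#> C>G 82349.71  78561.54  58775.13 75580.60
#> C>T 54899.81 117842.31 999177.15 75580.60
#> T>A 60716.45 104579.72  96074.66 72846.92
#> T>C 72859.74  78434.79  68624.76 54635.19
#> T>G 97146.33 122009.67  75487.24 84988.07
```

The CpG C>T cell (`C>T`, `G`) stands ~10-fold above the background cells
— the simulated fold, recovered after abundance normalization even though
CpG sites are rare (raw CpG C>T calls are only 6.9% of the total here).

```r
calls <- lapply(fam$clones, function(cl)
  apply_filters(cl, filter_params(exclude_sisters = FALSE),
                genome = genome)$accepted)
shared_snvs(calls)$pairwise
#>        clone1 clone2 clone3
#> clone1      0      2      0
#> clone2      2      0      0
#> clone3      0      0      0
```

Shared-variant detection requires `exclude_sisters = FALSE` (otherwise
the sister filter removes exactly what is being looked for). With metric
noise on, 2 of the 5 designed shared variants survive filtering in both
carriers; with `metric_noise = FALSE` the recovery is exact (that setting
is what the acceptance tests assert against the truth ledger).

An end-to-end run from a JSON config (`run_pipeline`) writes per-statistic
TSVs plus a manifest; a command-line front end is in
`inst/cli/cpgmutspec.R`.

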