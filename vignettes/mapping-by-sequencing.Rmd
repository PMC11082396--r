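---
title: "Mapping-by-sequencing with oatmap: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping-by-sequencing with oatmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oatmap)
```

## The mapping problem

A chemically mutagenized (EMS) line carries hundreds of induced point
mutations, one of which causes a recessive phenotype of interest — here the
motivating case is a short-kernel, brassinosteroid-insensitive cereal mutant.
Crossing the mutant to wild type and selfing the F1 yields an F2 population in
which the phenotype reappears in roughly one quarter of individuals (the 1:3
recessive expectation, testable with `segregation_chisq()`).

Pooling the phenotype-positive F2 individuals and sequencing the pool as one
library turns meiotic recombination into a mapping signal. Every selected
individual is homozygous mutant at the causal locus, so the mutant allele
frequency (AF) in the pool is exactly 1 there. At a marker at map distance $d$
Morgans from the causal locus, each selected gamete carries the mutant allele
with probability $1 - r$, where under the Haldane (no-interference) map
function

$$ r = \tfrac{1}{2}\left(1 - e^{-2d}\right), $$

so the expected pooled AF decays from 1 at the causal locus to 0.5 on unlinked
chromosomes. Scanning the genome for the region where AF stays near 1
localizes the mutation; variant-level filters then reduce the linked mutations
to a handful of candidate genes.

## The analysis pipeline

`run_pipeline()` chains the stages; each is usable on its own.

1. **Input** — `read_vcf()` admits biallelic SNPs with allelic depths (`AD`),
   summing depths across samples; indels, multi-allelic records and records
   with missing `AD` are counted and skipped. `read_gff()`, `read_fasta()`,
   `read_expression()` and `read_orthogroups()` load the remaining inputs.
2. **Background subtraction** — `subtract_background()` removes variants also
   observed in the parents or in independent sibling mutant lines (matched on
   chromosome, position and both alleles); shared variants cannot be causal.
3. **Allele-frequency scan** — `sliding_median()` computes, per chromosome,
   the median AF of sliding windows of 100 consecutive variants (step 1),
   after discarding variants with total allelic depth below 15. The median is
   robust to individual noisy sites; the even-window median is the mean of the
   two central order statistics. `call_regions()` reports maximal runs of at
   least 5 windows with median AF ≥ 0.9.
4. **Effect annotation** — `annotate_variants()` classifies each SNP against
   every overlapping transcript (intergenic, intron, splice site within 2 bp
   of an intron boundary, UTRs, and codon-level consequences computed in
   transcription order with minus-strand alleles complemented), assigning the
   four-tier MODIFIER/LOW/MODERATE/HIGH impact scheme used by common
   annotators. Protein changes use three-letter notation (e.g. `Pro303Leu`),
   numbering residues from the initiator methionine.
5. **Candidate funnel** — `apply_funnel()` applies, in order: (i) impact ≥
   MODERATE; (ii) location on the mapped chromosome or inside a called
   region; (iii) read support `ad_alt >= 15` and `ad_ref <= 0`; (iv)
   expression > 0.5 TPM in every seed, glume and spikelet sample. A gene
   qualifies only if one variant passes (i)–(iii) simultaneously — two
   variants each passing a different subset do not combine — and per-step
   surviving gene counts are recorded. Because the final set is the
   conjunction of all four conditions, reordering the steps changes the
   intermediate counts but never the final candidates.
6. **Orthogroup screen** — `orthogroup_screen()` maps foreign proteins with
   known effects on the trait to their orthogroups, collects the
   focal-species members, and intersects them with the impacted genes —
   an independent, homology-driven route to the same candidates.
7. **Statistics** — `segregation_chisq()` and `wilcoxon_rank_sum()` /
   `summary_table()` cover the segregation test and group-wise phenotype
   comparisons.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `window_size` | 100 variants | resolution/robustness trade-off of the scan |
| `min_total_depth` | 15 reads | depth floor for a variant to enter a window |
| `min_alt_depth` | 15 reads | funnel step iii, alternate support |
| `max_ref_depth` | 0 reads | funnel step iii, reference support allowed |
| `impact_min` | MODERATE | funnel step i |
| `tpm_min` | 0.5 TPM | funnel step iv, strict inequality, every sample |
| `af_min`, `min_windows` | 0.9, 5 | region calling on the window track |

The step-(iii) defaults encode the strong prior that the causal variant is
fixed in the pool: any reference-supporting read disqualifies a variant. This
filter is exact for noiseless data but brittle under sequencing error: with
per-read allele-flip probability $e$ and Poisson depth $\lambda$, a truly
fixed site shows zero reference reads with probability $e^{-\lambda e}$ —
about 0.97 at $\lambda = 30$, $e = 10^{-3}$, but only about 0.74 at
$e = 10^{-2}$. On error-prone data, raising `max_ref_depth` to 1–2 trades a
modestly longer candidate list for robustness; the package keeps the strict
default and leaves the trade-off to the user.

### Choosing the target chromosome

The funnel's location filter needs a target. Classically it is read off the
AF plot: one chromosome stands out. `apply_funnel()` automates this as the
chromosome carrying the genome-wide maximum window median, falling back to
the highest-AF called region, with an explicit `target_chrom` override.
Region calling itself interacts with marker density: a window of 100 variants
spans `100 / density` cM, and when that span is large relative to the linkage
scale (tens of cM), window medians mix linked and recombined markers and
plateau below the 0.9 region threshold even though the causal chromosome is
clearly elevated. Chromosome mode is therefore the default; region mode is
most useful on dense maps where windows span a few cM.

## The simulator

`simulate_experiment()` generates a full synthetic experiment with known
truth, used throughout the test suite:

* **Genome and genes** — uniform random chromosomes; non-overlapping genes of
  1–3 exons on random strands, CDS beginning with ATG, free of internal stop
  codons and ending in a stop codon. Exons coincide with CDS (no UTRs are
  simulated, though the annotator classifies them when present in real gene
  models).
* **Mutations** — `n_mutations` distinct SNPs; a fraction `ems_fraction`
  (default 0.99, the canonical EMS bias) are C→T or G→A transitions placed on
  C/G sites. Exactly one mutation, redrawn until it is a CDS missense change,
  is causal.
* **Meiosis** — gametes are crossover mosaics with Poisson crossover counts
  (`chrom_cM`/100 per chromosome), uniform breakpoints in genetic position and
  no interference, i.e. exactly the Haldane model the analysis assumes. An F2
  is two independent gametes; the phenotype is fully penetrant and monogenic
  (homozygous mutant at the causal locus), and the first `pool_size`
  positives among `n_f2` simulated individuals form the pool.
* **Reads** — per site, depth is Poisson(`mean_depth`); each read carries the
  mutant allele with probability equal to the pooled AF and flips to the
  other allele with probability `seq_error`.
* **Side tables** — log-normal TPM expression over 3 seed, 7 glume and 8
  spikelet samples (the causal gene forced above threshold everywhere, a
  fraction of other genes forced below it somewhere); random orthogroups with
  the causal gene's group linked to a foreign known trait gene; a background
  variant set sharing `n_background` non-causal mutations; and a two-genotype
  kernel-length phenotype table.

Default scale is a desk-scale stand-in for a hexaploid oat experiment:
3 chromosomes × 5 Mb at 150 cM, 300 genes, 600 mutations, a pool of 15 from
150 F2s, 30× depth. `n_f2 = 150` rather than a smaller population is a
reliability choice: with ~69 F2s the expected number of phenotype-positive
segregants (≈17) sits close enough to the pool size of 15 that pool selection
would fail by chance in roughly a quarter of runs; observed field counts
enter the segregation test as data, not as simulator settings. The test
suite and `scripts/acceptance.R` use this desk scale (20 replicates), plus
200 replicate two-locus pools for the linkage-decay check and 1000 random
CDS SNPs for the annotation oracle — sizes chosen so the full suite completes
in a few minutes.

### What the simulator does not emulate

Read mapping artifacts, copy-number and structural variation, subgenome
homoeology of a polyploid, crossover interference, segregation distortion,
incomplete penetrance, and phenotyping error. Passing the recovery suite
therefore shows the analysis is correct under its own model assumptions, not
that those assumptions hold for any particular real dataset.

## Numerical and design notes

* Coordinates are 1-based inclusive everywhere internally (the R/Bioconductor
  convention); parsed intervals written back to VCF/GFF3 are unchanged.
* The exact Wilcoxon p-value enumerates the permutation distribution of the
  rank sum (midranks for ties) with a shift-algorithm convolution; the
  two-sided p doubles the smaller tail and is capped at 1. `stats::wilcox.test`
  cannot compute exact p-values with ties, which is why the enumeration is
  implemented here; it serves as an independent cross-check in the tests. The
  normal branch (combined n > 25) uses tie-corrected variance and a 0.5
  continuity correction.
* The segregation chi-square uses no continuity correction, the standard for
  goodness-of-fit tests; with the classic 15-of-69 counts the statistic is
  0.391 (p = 0.53). A corrected statistic would be 0.209 — materially
  different, so the choice is consequential and deliberate.
* Median of an even window = mean of the two central order statistics
  (`stats::median`).
* Zero-depth sites are representable (`AD 0,0`) but excluded from AF
  computation by the depth filter; `allele_frequency()` refuses them.
* The annotator hard-errors when a variant's `ref` disagrees with the genome
  base — silent coordinate drift between a VCF and FASTA is the classic
  failure mode of this analysis.
* When a gene has several transcripts, all effects are kept and
  `gene_max_impact()` aggregates to the most severe per gene.
* Determinism: every simulator output and the pipeline report (minus its
  timestamp) are byte-identical under a fixed seed; `run_pipeline()` derives
  per-stage seeds from the global seed so stages can be rerun independently.

## Known limitations

* SNPs only; indel and structural-variant consequences are out of scope.
* The standard genetic code only.
* Expression filtering treats the TPM table as given; no normalization is
  performed.
* The orthogroup screen transfers annotations by group membership only; it
  does not align sequences or build trees.
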