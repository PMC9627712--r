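---
title: "Quantifying inbreeding and mutation load from SNP genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying inbreeding and mutation load from SNP genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rohload` implements the genomic toolkit used to characterise severely
bottlenecked populations — the motivating case being desert pupfishes such
as the Devils Hole pupfish, where a handful of surviving individuals carry
the genetic record of decades of small population size. The package takes a
multi-sample biallelic SNP matrix plus reference resources (contig table or
FASTA, GFF3 gene models, optional structural-variant calls, census counts)
and produces: per-individual runs of homozygosity (ROH) and inbreeding
coefficients, tract-age estimates, polarized genotype-class mutation-load
profiles for synonymous / missense / stop-gain variants, enrichment tests
of loss-of-function (LOF) variants inside ROHs, group-private fixed-variant
and deletion filters, Weir–Cockerham F~st~, and harmonic-mean effective
population size. A seeded simulator generates cohorts with known truth so
that every stage is testable without any external download.

```{r, eval = FALSE}
library(rohload)
sim <- simulate_cohort(sim_config(seed = 42))
scan <- roh_scan(sim$gm, sim$genome)
summary(scan)
```

## The ROH model

Autozygosity is inferred per sample and contig with a two-state hidden
Markov model over the ordered SNP sites, decoded by the Viterbi algorithm.
The observation at each non-missing site is collapsed to heterozygous
versus homozygous: homozygous-reference and homozygous-alternate calls are
equivalent evidence, because an autozygous tract is homozygous for
*whichever* allele the shared ancestral haplotype carried.

* **Inside** an autozygous tract, a heterozygote appears only through
  genotyping error (or gene conversion): `P(HET) = eps`, default
  `eps = 0.005`.
* **Outside**, the heterozygote probability is `2p(1-p)` under
  Hardy–Weinberg at the site's alternate-allele frequency `p`. By default
  `roh_scan()` estimates `p` from the cohort itself, mirroring how
  likelihood-based ROH callers consume population allele frequencies; a
  constant fallback (`hom_outside = 0.7`) covers the no-frequency case.
  Estimated frequencies are clamped so that monomorphic-looking sites
  cannot produce infinite emission weights.
* **Transitions** are distance-dependent. Over a gap of `d` bp the switch
  probability is `(1 - exp(-2 r d))/2` with `r = transition_rate/1e6` per
  bp — the symmetric two-state continuous-time chain, which behaves as
  `r d` for small gaps and saturates at 1/2 for huge ones. The default
  `transition_rate = 0.1` expected switches per Mb favours tract
  contiguity; it is deliberately sticky so that isolated discordant calls
  do not shatter tracts, and it is fully configurable.

Missing genotypes are skipped but still contribute distance, so
missingness widens gaps rather than deleting evidence. Decoded segments
are trimmed to their first and last supporting SNP, must span at least
`min_sites = 10` informative sites, and are reported at *any* length —
the 100 kb threshold belongs to the summary statistics, so the length
tables and dating analysis see exactly the segment set the summary uses.

The HMM consumes hard genotype calls, not genotype likelihoods; `eps`
absorbs call error. This matches the downstream statistics, which are all
defined on hard genotypes.

### Summaries

`compute_froh()` defines the inbreeding coefficient F~ROH~ as the summed
length of merged ROHs at least 100 kb long divided by total genome size.
`bin_roh_lengths()` partitions tracts into half-open length classes
[0.1, 1), [1, 10) and [10, Inf) Mb whose genome fractions sum exactly to
F~ROH~. Lower-closed bins were chosen so the classes partition cleanly: a
tract of exactly 10 Mb falls in the top class.

### Dating tracts

A tract whose two haplotypes coalesce `g` generations ago has expected
genetic length `100/(2g)` cM, so `date_roh()` inverts the observed length:
`g = 100 / (2 L_cM)`, with `L_cM = length_bp * rate / 1e6`. The mean
recombination rate comes from `recombination_rate(map_cM, genome_bp)`;
with a 5330 cM map on a 1.16 Gb genome the rate is ~4.6 cM/Mb, and 1 Mb
and 0.1 Mb tracts date to 11 and 109 generations respectively (rounded
half-up for display; computations keep full precision). Note the formula
is sometimes typeset ambiguously as "100/2 × length"; read literally that
would *grow* with tract length and cannot reproduce the 11–109 range, so
the reciprocal reading is used here.

## Effect classification and polarization

`classify_effects()` classifies each SNP against the single longest CDS
per gene (multi-isoform resolution is out of scope): the codon containing
the site is located strand- and phase-aware, including codons split across
exon junctions; reference and alternate codons are translated under the
standard nuclear code. Amino acid unchanged → `SYN`; changed without a
gained stop → `NSYN`; a gained stop where the reference codon is not a
stop → `LOF`. The LOF definition is deliberately conservative —
*stop-gained only*. Stop-loss and splice variants are not LOF (there is no
separate bin in the three-class scheme, so stop-loss lands in `NSYN`;
stop-retained changes are `SYN`). Sites in several overlapping genes take
the most severe class, matching annotation-tool convention.
`parse_snpeff_ann()` offers a compatibility path for VCFs already
annotated with SnpEff-style `ANN` fields.

`polarize()` converts genotypes to ancestral/derived classes using the
reference genome as the ancestral proxy — the operational choice when the
reference is an outgroup species. This is known to mispolarize a fraction
of sites (the reference lineage has its own derived alleles); an
ancestral-allele table can override the proxy per site, and the simulator
has a `mispolarize_rate` switch for probing sensitivity.

## Mutation-load statistics

`genotype_class_proportions()` computes, per sample and mutation class,
the proportions of hom-ancestral / het / hom-derived genotypes over that
sample's non-missing calls at sites segregating across the analysed
cohort. Proportions rather than raw counts are used because raw derived
counts scale with coverage and missingness; per-sample denominators make
the statistic robust to both (the suite verifies that doubling simulated
missingness moves the expected proportions by less than Monte-Carlo
noise). The per-sample denominator convention (all non-missing calls at
the class's segregating sites) is recorded alongside `n_sites` so other
conventions can be recomputed. Group comparisons use one-way fixed-effects
ANOVA plus Tukey HSD (Tukey–Kramer under unequal n); contrasts against
single-sample groups are flagged low-power rather than suppressed, and
group summaries report mean ± 2 SE over member samples.

`lof_frequency_filter()` equalises sampling before comparing LOF allele
frequencies across three focal species: a variant is kept only when every
species has ≥ 4 genotyped individuals *and* the derived allele is present
(frequency > 0) in at least two of the three species. "Present" is read
as carrying the derived allele, not merely genotyped.

`roh_lof_enrichment()` asks, per individual, whether its LOF positions
fall inside its ROHs more or less often than expected: successes = LOF
positions (non-missing genotype) inside merged ROHs ≥ 100 kb, trials =
all non-missing LOF positions, null probability = the individual's
F~ROH~. The p-value is the exact two-sided binomial by the
minimum-likelihood rule (sum of all outcomes with pmf ≤ observed) — the
same convention as `binom.test()` — because both significant enrichment
and significant depletion are of interest; a one-sided alternative is
available. The test is undefined (returned as `NA` with a reason) when
F~ROH~ is 0 or 1.

## Population metrics

`unique_fixed_lof()` retains LOF sites where every *non-missing* focal
sample is homozygous-derived (at least one genotyped focal sample
required — "for which genotypic information was available") and no
genotyped background sample carries a derived allele.
`unique_deletions()` keeps deletion calls carried by all focal samples
and no background sample; "carriage" is any non-reference SV genotype, in
either the SV-VCF or BED-with-carriers dialect. Calls are annotated with
distance to the nearest gene (0 when overlapping; the window default is
2 kb) and calls longer than 1 Mb are flagged as likely caller artefacts —
a deterministic stand-in for manual inspection of outlandish calls; they
are flagged, never silently dropped.

`weir_cockerham_fst()` computes the Weir & Cockerham (1984) variance
components a, b, c per site from genotype counts, using observed
heterozygosity. The headline genome-wide value is the ratio of sums
`Σa / Σ(a+b+c)` (the "weighted" convention); the mean of per-site ratios
is also reported since the two only coincide in the equal-weight limit.
Monomorphic sites and sites with fewer than two genotyped individuals in
either group are skipped and counted.

`harmonic_mean_ne()` estimates variance effective population size per
season as the harmonic mean of that season's census counts — dominated by
bottleneck minima, never exceeding the arithmetic mean, and undefined for
zero counts.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates cohorts with the statistical structure the
analyses assume:

* **Autozygosity mosaics**: per sample, tracts arrive as a Poisson process
  with exponential lengths of mean `100/(2g)` cM (converted to bp at the
  configured recombination rate), overlaps merged, until the realized
  fraction *equals* `target_F` (the final tract is truncated; tracts are
  clipped at contig ends). Realized F is therefore exact, which makes
  truth-recovery tests sharp.
* **Genotypes**: inside tracts, homozygous for a single drawn haplotype
  allele, flipped to HET with probability `het_error_inside_roh`; outside,
  Hardy–Weinberg draws at Beta(0.5, 3) alternate-allele frequencies (a
  rare-allele-skewed spectrum); independent missingness.
* **Coding variation**: genes with 1–3 CDS exons (exon boundaries
  deliberately off codon frame so junction-spanning codons occur) on both
  strands; planted variants built from codon templates so their
  SYN/NSYN/LOF class is guaranteed by construction; background SNPs are
  placed outside CDS so the coding variant set is exactly the planted one.
  Privacy patterns (shared, group-private, fixed-in-one-group) are
  enforced on the genotypes; shared-pattern sites follow each sample's
  autozygosity mosaic and see normal missingness, while privacy-pattern
  sites are fully observed so the planted truth sets are exact.
* **Deletions**: intervals with explicit carrier sets, some private to the
  focal group, some mixed; some placed within 2 kb of genes, some far.

Default conditions: a 20 Mb two-contig genome, 500 SNPs/Mb, three species
of four samples each at target F = 0.6 / 0.12 / 0.3 with tract ages g =
10 / 18 / 12 generations, 3% missingness, 0.2% in-tract het error, 4.6
cM/Mb. The density is scaled down from the several-thousand-per-Mb density
of real whole-genome SNP sets to keep test cohorts fast; truth-recovery
checks across F ∈ {0.1, 0.3, 0.6, 0.8} use 30 Mb at 1000 SNPs/Mb, where
per-sample |F̂ − F| stays well under 0.02 and base-level Jaccard with the
true tracts exceeds 0.95.

The simulator is deliberately *not* a population-genetic forward
simulation: there is no linkage disequilibrium beyond the autozygosity
mosaic itself (ROH inference depends on homozygosity runs, not LD fine
structure), no selection, no recombination-map heterogeneity, and the
reference allele is ancestral by construction (except under
`mispolarize_rate`). Passing tests on simulated cohorts therefore
demonstrate correctness of the *estimators* under their own model, not
robustness to every property of real resequencing data — reference bias,
batch-variable coverage, or correlated genotyping error must be judged on
real data.

## Numerical choices and degenerate inputs

* Viterbi runs in log space; ties between state paths are broken by the
  `which.max` convention (earlier state preferred). The suite checks the
  decoded path probability against exhaustive enumeration of all 2^n
  paths for n ≤ 15.
* Bin edges lower-closed; rounding of displayed generations is half-up;
  full precision is kept internally.
* All-missing contigs decode to no segments; empty inputs produce empty,
  well-typed tables; F~ROH~ of 0/1 makes the enrichment null degenerate
  and is reported as `NA` with a reason; zero census counts and
  non-positive rates/lengths are errors.
* Coordinates are 0-based half-open internally everywhere; VCF and GFF3
  convert at the boundary (this is why BED output needs no conversion).
  Multiallelic records and indels are skipped with a logged count, not
  decomposed.

## Known limitations

Hard-call genotypes only (no genotype-likelihood HMM); no identity-by-
descent phasing or pedigree inference; single-transcript effect
classification; no frameshift/splice/UTR annotation; no SV discovery —
deletion calls are consumed, not generated; no GERP/phyloP-weighted or
fitness-calibrated load. The reference-as-ancestral proxy shares the known
mispolarization risk of the field-standard approach.
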