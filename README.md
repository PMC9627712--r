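# rohload

Inbreeding and mutation load from multi-sample SNP genotypes, for
conservation genomics of small, isolated populations — desert pupfishes
being the motivating case. When a population persists for decades at tens
to hundreds of individuals, its genomes accumulate long runs of
homozygosity (ROH) and deleterious variants drift to high frequency;
`rohload` measures both sides of that process from a biallelic SNP matrix
plus standard reference resources (contig table/FASTA, GFF3 gene models,
optional deletion calls, census counts).

## What it computes

* **ROH / inbreeding** — a two-state hidden Markov model (autozygous vs
  not) over each sample's ordered genotypes, decoded by Viterbi.
  Emissions: inside a tract `P(HET) = ε` (default 0.005); outside,
  Hardy–Weinberg heterozygosity `2p(1−p)` at the site's allele frequency.
  Transitions are distance-dependent. Summaries: the inbreeding
  coefficient `F_ROH = Σ length(ROH ≥ 100 kb) / genome size`, genome
  fractions in the [0.1, 1), [1, 10), [10, ∞) Mb length classes, and
  tract ages `g = 100 / (2 L_cM)` generations with
  `L_cM = length_bp × rate / 10^6`.
* **Mutation load** — coding SNPs classified SYN / NSYN / LOF (LOF =
  stop-gained only) against the reference and annotation, genotypes
  polarized with the reference as ancestral proxy, and per-sample
  proportions of hom-ancestral / het / hom-derived genotypes at
  segregating sites per class, compared across species with ANOVA +
  Tukey HSD; a sampling-balanced LOF allele-frequency table; and exact
  binomial tests (minlike two-sided) for enrichment of LOF variants
  inside each individual's ROHs with null probability `F_ROH`.
* **Population metrics** — fixed LOF variants and deletions private to a
  focal group (with a 2 kb gene-proximity window), Weir–Cockerham F_st
  (ratio-of-sums `Σa / Σ(a+b+c)`), and harmonic-mean effective population
  size per census season.
* **Synthetic cohorts** — a seeded generator producing VCF + FASTA + GFF3
  + deletion calls plus exact truth tables (tract mosaics of controllable
  F, planted coding variants of guaranteed class, group-private
  deletions), so the whole pipeline is testable offline.

See the vignette `vignettes/inbreeding-and-mutation-load.Rmd` for the
models, parameter semantics and design choices.

## Worked example

```r
library(rohload)

sim  <- simulate_cohort(sim_config(seed = 42))   # 12 samples, 3 species
scan <- roh_scan(sim$gm, sim$genome)
summary(scan)
#>  sample   froh f_0.1_1Mb f_1_10Mb f_10Mb_plus
#>   spA_1 0.6068   0.07765  0.52914           0
#>   spA_2 0.5970   0.08306  0.51393           0
#>   ...
#>   spB_1 0.1187   0.05566  0.06307           0
#>   spC_1 0.2985   0.20864  0.08985           0
```

`froh` is the fraction of the genome in ROHs ≥ 100 kb: the `spA` samples
were simulated at target F = 0.6 and recover ≈ 0.60, mostly in 1–10 Mb
tracts (recent shared ancestry); `spB` at 0.12, mostly short tracts.
Dating tracts with the rate derived from a 5330 cM map on a 1.16 Gb
genome:

```r
rate <- recombination_rate(5330, 1.16e9)   # 4.59 cM/Mb
roh_age_table(data.frame(length = c(1e6, 2.5e5, 1e5)), rate)
#>    length        g g_rounded
#> 1 1000000  10.8818        11
#> 2  250000  43.5272        44
#> 3  100000 108.8180       109
```

A 1 Mb tract coalesces ~11 generations back; a 100 kb tract ~109 — short
tracts record old inbreeding, long tracts recent bottlenecks. Load
profiles and group tests:

```r
pol  <- polarize(sim$gm)
cl   <- classify_effects(sim$gm, sim$annotation, sim$sequences)
prof <- genotype_class_proportions(pol, cl)
grp  <- setNames(sim$gm$sample_table$group, sim$gm$sample_table$sample_id)
subset(compare_load_groups(prof, grp)$tukey, class == "LOF" & category == "der")
#>    class category contrast        diff         lo          hi       p_adj
#> 25   LOF      der  spB-spA -0.32196970 -0.5378900 -0.10604934 0.006186123
#> 26   LOF      der  spC-spA -0.23674242 -0.4526628 -0.02082207 0.032858863
#> 27   LOF      der  spC-spB  0.08522727 -0.1306931  0.30114763 0.536512440
```

The inbred focal species carries a significantly higher proportion of
homozygous-derived LOF genotypes than either neighbour — the
recessive-load signature. Private fixed LOF variants recover the three
planted in the simulation:

```r
focal <- names(grp)[grp == "spA"]
u <- unique_fixed_lof(pol, which(cl == "LOF"), focal, setdiff(names(grp), focal))
sim$gm$sites[u, c("contig", "pos", "ref", "alt")]
#>      contig     pos ref alt
#> 951    chr1 1790871   G   T
#> 6349   chr2  661349   C   A
#> 9082   chr2 6011068   G   T
```

A thin command-line front end over the same functions ships in
`inst/cli/rohload.R` (subcommands `simulate`, `roh`, `effects`, `load`,
`enrich`, `uniques`, `ne`, `fst`).

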