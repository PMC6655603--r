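# eqpopgen

Population-genomic analysis of dense SNP-array panels in pedigreed
livestock, written around the analyses that characterize modern
Thoroughbred horse genomics: a closed, intensely selected breed with deep
pedigree records, large paternal half-sib families sired by ungenotyped
stallions, and array data on a few hundred individuals across a focal
breed, a closely related sister cohort, and a pool of other breeds.

The package provides, as composable functions over a plain
`genotype_matrix` / `haplotype_matrix` data model:

* **Sliding-window conditional nucleotide diversity** — per-site expected
  heterozygosity `2p(1-p)` over the fixed array site set, averaged in 1 Mb
  windows sliding by 200 kb (`site_heterozygosity`, `make_windows`,
  `window_mean`, `chromosome_average`).
* **Differentiation and the PBS selection scan** — windowed pairwise Hudson
  FST (ratio of averages; Weir–Cockerham behind a switch), the
  divergence-time transform `T = -log(1 - F_ST)`, and the population branch
  statistic for focal (f), sister (s) and outgroup (o) groups,

      PBS = (T_fs + T_fo - T_so) / 2,

  with merged, ranked top regions (`window_fst`, `divergence_time`, `pbs`,
  `pbs_scan`).
* **Runs of homozygosity and F_ROH** — segment-level ROH calling with the
  standard array rules (≥ 80 homozygous SNPs, ≤ 1 heterozygote and
  ≤ 2 missing calls per segment, inter-SNP gaps ≤ 100 kb, density ≥ 1 SNP /
  50 kb, site MAF ≥ 0.01, minimum span 0.5 or 5 Mb), and
  `F_ROH = L_ROH / L_genome` with the 2,243,000 kb equine autosome default
  (`detect_roh`, `roh_rules`, `f_roh`).
* **Pedigree inbreeding** — Wright's coefficient by recursive kinship,
  truncated at 5 or 10 generations, and its correlation with F_ROH
  (`pedigree_f`, `pedigree_f_table`, `f_correlation`).
* **Half-sib sire reconstruction** — phasing of an ungenotyped sire's two
  haplotypes from ≥ 10 genotyped half-sibs via opposing-homozygote logic,
  per-offspring strand blocks, and recombination counting
  (`detect_families`, `infer_sire_phase`, `summarize_recombination`).
* **LD decay** — haplotype-based r² for all pairs within 1 Mb, pooled into
  1 kb distance bins, with the threshold-crossing distance
  (`pair_r2`, `decay_curve`).
* **A pedigreed multi-population simulator** — Balding–Nichols drift around
  array-ascertained ancestral frequencies, branch-specific sweeps,
  half-sib families and textbook consanguineous loops, and Poisson gene
  dropping that records every crossover and autozygous tract as ground
  truth (`sim_config`, `simulate_panel`, `gene_drop`, ...). Every analysis
  stage is therefore testable against known truth without external data.

`run_stage()` orchestrates the stages (`simulate`, `diversity`, `fst-pbs`,
`roh`, `pedf`, `phase-halfsib`, `ld-decay`, `all`) over a shared
`run_config()`, writing BED-like TSV tracks plus a JSON manifest per stage.

## Worked example

Simulate a small two-chromosome panel (20 unrelated focal + one 12-offspring
half-sib family + one full-sib-mating offspring, 15 sister, 20 outgroup
samples; a focal sweep planted at chr2:8–10 Mb), then scan it:

```r
library(eqpopgen)
cfg <- sim_config(n_chrom = 2, chrom_length_bp = c(3e7, 2.5e7),
                  n_sites_per_chrom = c(3000, 2500),
                  n_pop = c(FOCAL = 20, SISTER = 15, OUTGROUP = 20),
                  families = c(12), loops = "fullsib",
                  drift_F = c(FOCAL = 0.05, SISTER = 0.05, OUTGROUP = 0.15),
                  sweep_specs = list(list(population = "FOCAL",
                                          chrom = "2",
                                          start = 8e6, end = 1e7)),
                  seed = 11)
panel <- simulate_panel(cfg)
panel$geno
#> geno_matrix: 5500 sites x 68 samples on 2 chromosome(s)

w <- make_windows(setNames(cfg$chrom_length_bp, c("1", "2")), 1e6, 2e5)
head(pbs_scan(panel$geno, panel$samples, w)$top_regions, 1)
#>   rank chrom start     end max_pbs n_windows
#> 1    1     2 8e+06 9400000   0.396         3
```

The top PBS region is the planted sweep. The full-sib-mating offspring
(`L01X`, expected pedigree F = 0.25) carries a detectable autozygous run:

```r
detect_roh(panel$geno, "L01X")[, c("chrom", "start", "end", "n_snps")]
#>   chrom   start     end n_snps
#> 1     2 8966411 9826068     84
f_roh(detect_roh(panel$geno, "L01X"),
      genome_length_kb = sum(cfg$chrom_length_bp) / 1000)$f_roh
#> [1] 0.01563521 0.00000000
pedigree_f(panel$ped, "L01X")
#> [1] 0.25
```

(At this desk scale the single 0.86 Mb segment covers 1.6% of the toy
genome; the realized autozygous fraction of any one individual scatters
widely around its pedigree expectation — the acceptance suite shows the
mean over 500 gene drops is 0.25.) The half-sib family reconstructs its
ungenotyped sire and counts recombinations per offspring:

```r
fam <- detect_families(panel$geno, panel$samples, 10)[[1]]
ph <- infer_sire_phase(fam, chrom_lengths = setNames(cfg$chrom_length_bp,
                                                     c("1", "2")))
summarize_recombination(list(ph),
                        setNames(cfg$chrom_length_bp, c("1", "2")))$per_chrom
#>   chrom length_bp mean_recomb prop_zero
#> 1     1   3.0e+07      0.0833     0.917
#> 2     2   2.5e+07      0.1667     0.833
```

Short chromosomes (0.3 and 0.25 Morgans here) mostly transmit without a
crossover, as expected from the Poisson meiosis model.

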