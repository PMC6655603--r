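---
title: "Methods: pedigreed SNP-array population genomics with eqpopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigreed SNP-array population genomics with eqpopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eqpopgen)
```

This vignette is the package's account of its science: the models and rule
sets each stage implements, the parameters that matter and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical conventions adopted where the field leaves a
choice open. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The setting

The package targets the analysis situation of a closed, intensely selected
livestock breed genotyped on a dense SNP array: several hundred individuals
of a focal breed (with complete multi-generation pedigrees and large
paternal half-sib families whose sires are not themselves genotyped), a
small cohort of the same breed from another source, and a pooled panel of
other breeds. Three questions drive the five analysis stages: where has
selection reduced diversity or shifted allele frequencies on the focal
branch; how inbred are the genomes relative to what the recent pedigree
records; and how do chromosomes recombine through the sires of half-sib
families.

## Data model and coordinates

Genotypes are dosages of the alternate allele (0/1/2, `NA` missing) over a
biallelic variant table; phased data adds a sites × (2·samples) haplotype
matrix whose pair sums must equal the dosages. VCF positions are 1-based;
every internal interval — windows, ROH segments, sweep intervals, ancestry
tracts, phase blocks — is 0-based half-open, converted only at I/O
boundaries. Chromosome labels are taken verbatim from the input (no "chr"
normalization); the autosome filter drops labels matching X/Y/MT patterns.
Missing genotypes are excluded per site per statistic (allele frequencies,
call rates, FST terms and heterozygosity all use only the non-missing calls
at that site); this is the conventional array practice, and the alternative
(listwise deletion) would discard most sites at realistic missingness.

## Diversity scan

Per-site heterozygosity is expected heterozygosity `2p(1-p)` with `p` the
alternate-allele frequency among non-missing calls of the chosen sample
subset; averaged over the fixed array site set this is a *conditional*
nucleotide diversity — conditional on the array's ascertained sites, hence
comparable between groups on the same array but not an absolute diversity.
Observed heterozygosity and the small-sample factor `n/(n-1)` are available
behind flags (`observed`, `corrected`), defaulting off: a relative,
array-conditioned quantity gains nothing from the correction, and expected
heterozygosity is less sensitive to genotyping error than the observed
fraction. Windows are anchored at position 0 of every chromosome (the
convention had to be fixed somewhere; anchoring at 0 makes window sets
reproducible across subsets), default 1 Mb sliding by 200 kb, and a window
needs `min_sites = 10` contributing sites or it is reported `NA` — means
over fewer array sites are dominated by single-site noise.

## Differentiation and the PBS scan

Pairwise FST uses Hudson's estimator with *ratio-of-averages* aggregation:
per site, numerator `(pA - pB)^2 - pA(1-pA)/(nA-1) - pB(1-pB)/(nB-1)` and
denominator `pA(1-pB) + pB(1-pA)` with `nA`, `nB` the non-missing
haplotype counts; sums over a window are divided once. Two reasons: the
ratio of averages is the stable recommendation for windowed FST (an
average of per-site ratios explodes in low-diversity windows), and the
estimator is unbiased under the simulator's drift model, so the test suite
can demand recovery of a known drift parameter to ±0.01. Weir–Cockerham is
available via `estimator = "wc"` for users who want the other convention.

Each pairwise FST is clipped to `[0, 1 - 1e-12]` and transformed to a
divergence time `T = -log(1 - FST)`; clipping maps small negative
finite-sample estimates to zero rather than producing negative times, and
keeps fixation finite. The focal branch length is
`PBS = (T_fs + T_fo - T_so)/2`, reported unfloored — a negative PBS is
informative (sister-branch change) and flooring it would bias genome-wide
summaries.

One subtlety the test suite makes explicit: under *symmetric* drift (all
three groups drifted equally from a common ancestor) PBS is not zero — each
group owns a real branch of length `-log(1-F)/2`, and that is what the scan
estimates. The "no differentiation" null, under which the PBS track centres
at zero, is zero drift in all groups; both facts are asserted in the tests.

Because sliding windows overlap, the top-regions report merges: windows
with PBS at or above the `top_quantile` (default 0.99) are grouped into
maximal runs of mutually overlapping windows, each region scored by its
maximum PBS, ranked, and the top `top_k = 10` returned. The merging rule is
this package's construction (a "region" needs a definition once windows
overlap) and is stated in the output header.

## Runs of homozygosity and F_ROH

ROH calling is segment-level, with every rule applied to the reported
segment: at most 1 heterozygous and 2 missing calls, inter-SNP gaps at most
100 kb, span at least 0.5 Mb (or 5 Mb for the long-segment class), at least
80 homozygous SNPs, and average density at least one SNP per 50 kb; only
sites with panel MAF ≥ 0.01 enter the scan. The scan semantics are: split
each chromosome at over-long gaps; sweep a cursor left to right; the
candidate at the cursor is the *longest* run starting there that respects
the heterozygote/missing allowances (these constraints are hereditary, so a
single forward pointer finds it); trim the candidate to homozygous
endpoints (a boundary heterozygote or missing call adds no evidence of
autozygosity); report it if it passes the span/count/density rules; jump
the cursor past its end. Segments are therefore disjoint by construction,
and the whole procedure admits an exact brute-force oracle (explicit
enumeration of admissible runs), which the tests run on 200 random
chromosomes. An earlier variant that reported only globally maximal runs
and then removed overlaps greedily was rejected after it provably lost most
of a long tract whenever an overlapping maximal run shadowed the region
behind the first pick.

Note that PLINK's classic `--homozyg` implementation is a sliding-window
*vote* heuristic approximating these segment rules; this package implements
the segment rules themselves, exactly, so results on real data will be
close to but not identical with a PLINK run, and published cohort values
should be treated as approximate targets.

`F_ROH` divides the summed segment lengths above a threshold (> 0.5 Mb and
> 5 Mb by default) by the genome length, default 2,243,000 kb — the equine
autosomal scale (a published figure of "2243 Gb" is off by three orders of
magnitude and is read as 2,243 Mb; the value is configurable).

Boundary precision: with error-free genotypes, an allowed heterozygote lets
a segment extend past a true autozygous tract edge by construction (the run
absorbs the het and continues to the next one), so the tract-recovery test
that asserts boundary error ≤ one inter-SNP spacing disables the allowance
(`max_het = 0`); the allowance exists to tolerate genotyping error, and a
companion check at a 0.2% error rate uses the default rules and asserts
recovery of each tract's extent. Chance homozygosity also blurs edges in
ordinary panels; the boundary test uses founder haplotypes engineered so
that any two distinct founder haplotypes disagree at two of every three
sites, making chance homozygous runs outside true tracts single isolated
sites.

## Pedigree inbreeding

`F_PED` is Wright's coefficient computed as the kinship of the parents by
the standard recursion `phi(x,x) = (1 + F_x)/2`,
`phi(x,y) = (phi(sire_x, y) + phi(dam_x, y))/2`, recursing on the
individual of greater generation depth, memoized, with founders and
unknown parents unrelated and non-inbred. Truncation at `g` generations
prunes the pedigree to ancestors reachable within `g` meioses of the
individual (parents are generation 1); ancestors sitting exactly at the
horizon become founders. An ancestor reachable at several depths is kept if
*any* path is within the horizon — the pruned pedigree is a subgraph, which
matches how truncated pedigrees are extracted in practice from ragged
records. Textbook checks are exact: full-sib mating 0.25, half-sib 0.125,
first cousins 0.0625, and a loop whose only common ancestor is six
generations deep gives `2^-11` untruncated and 0 at a 5-generation horizon.

## Half-sib sire reconstruction

At a biallelic site where both offspring homozygote classes occur, the sire
must be heterozygous (every offspring carries one sire allele), and each
*homozygous* offspring's transmitted sire allele is its own allele;
heterozygous or missing offspring are uninformative at that site. Strand
assignment is an online left-to-right scan per chromosome: the first
determinable offspring seeds strand 0; at each informative site the
strand-0 allele is voted by the currently assigned offspring; an offspring
keeps its strand until `support_k` *consecutive* determinable sites all
conflict, at which point a recombination is placed at the midpoint between
the last concordant and first conflicting informative site and the strand
flips; shorter conflict runs are discarded as genotyping error; tied votes
leave a site unused. After the scan, the sire's two allele sequences are
re-voted per site from the final block assignments (majority, `NA` on
ties).

`support_k = 3` suppresses isolated bad calls while resolving crossovers at
array informative-site density (one per 10–50 kb); the midpoint convention
for boundaries is declared (nothing in the field fixes one); dams are
ignored — with no dam genotypes a heterozygous offspring simply stays
uninformative. Two structural consequences, visible in the recovery tests:
a crossover inside the last `support_k - 1` informative sites of a
chromosome cannot be confirmed, and two crossovers of one meiosis falling
within `support_k` informative sites of each other cancel; both are rare at
the tested density (~95% of meioses recover their exact truth crossover
count, mean ≈ 1 per 1-Morgan chromosome, zero-recombination fraction ≈
`exp(-1)`). Families are phased independently per chromosome, and the
minimum family size is 10 (read as ≥ 10).

## LD decay

`r^2` is the squared allelic correlation from phased haplotype frequencies,
`(p_AB - p_A p_B)^2 / (p_A(1-p_A) p_B(1-p_B))`, with haplotypes missing at
either site excluded pairwise and monomorphic sites undefined. All
intra-chromosomal pairs within 1 Mb are pooled genome-wide into 1 kb
distance bins (distance = difference of 1-based positions). The
threshold-crossing distance (the classic "r² drops below 0.2 at ..."
summary) is read from a 5-bin running mean because raw 1 kb bins are noisy;
width and threshold are arguments. Under independence the expected sample
r² is ≈ 1/n haplotypes, which the tests use as the floor calibration.

## The synthetic-data generator

The generator emulates the study design, not the organism: a site grid of
evenly spaced "array" SNPs on up to 31 chromosomes at equine autosome
lengths; ancestral frequencies Uniform on `[0.05, 0.95]` as a proxy for
common-SNP array ascertainment; per-population frequencies from the
Balding–Nichols distribution `Beta(p(1-F)/F, (1-p)(1-F)/F)`, chosen because
it gives a closed-form drift target the FST estimator should recover;
sweeps encoded as near-fixation (0.99 of the ancestrally major allele —
not 1.0, so swept sites stay polymorphic elsewhere and survive MAF
filters); half-sib families and consanguineous loop templates dropped
through Poisson meioses (crossover count ~ Poisson(Morgans), breakpoints
uniform, no interference — sufficient for the count statistics tested
here); and per-call missingness/error applied last. Ancestry is propagated
as founder-haplotype interval tracks, so crossovers and autozygous tracts
are recorded exactly in bp, independent of the site grid. Default study
shape: families of 31/25/19/17/15/10 offspring, 253 additional unrelated
focal samples, 24 sister and 287 outgroup samples, drift 0.05/0.05/0.2
(two closely related cohorts of one breed versus a pooled outgroup), 1
cM/Mb, 0.2% missingness.

What it does **not** emulate — and hence what passing tests do not show
about real data: background LD (founder haplotypes are drawn independently
per site, so LD arises only from the pedigree; the LD-decay test builds a
multi-generation random-mating pool on a dense genetic map to create a
decaying curve), mutation, genotyping-error structure (errors are
uniform), real ascertainment bias, crossover interference, and sex
chromosomes. All randomness flows from the single seed in `sim_config`.

## Problem sizes

The test suite and acceptance script run at desk scale, chosen to keep the
Monte-Carlo error of each assertion a few times smaller than its tolerance:
50,000 sites × 100 diploids for drift recovery; 20 seeded replicates of a
six-chromosome, 12,000-site panel for sweep ranking; 200 random 500-SNP
chromosomes for the ROH oracle; 8 gene drops on an 8,000-site chromosome
for tract recovery; 500 four-chromosome gene drops for realized
autozygosity; three 20-offspring families × five 1-Morgan chromosomes (300
meioses, ~2,000 informative sites per chromosome) for phasing recovery.

## Known limitations

ROH segments are not PLINK-identical (see above); the pedigree coefficient
assumes non-inbred, unrelated founders beyond the recorded horizon, so it
is a lower bound in breeds with deep shared ancestry; the sire vote leaves
sites `NA` where offspring of one strand are all uninformative; the PBS
region report depends on the declared merging quantile; and the pipeline
reads whole VCFs into memory, which is the right trade-off for array-scale
panels (hundreds of thousands of sites) but not for sequencing-scale data.
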