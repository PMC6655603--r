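Package: eqpopgen
Title: Population Genomics of Pedigreed Horse Breeds from SNP Array Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-genomic analysis of dense SNP-array panels
    in pedigreed livestock, built around the analyses typical of Thoroughbred
    horse studies: sliding-window conditional nucleotide diversity, pairwise
    Hudson FST with the population branch statistic (PBS) selection scan,
    runs-of-homozygosity (ROH) detection with segment-level rules and the
    F_ROH inbreeding coefficient, Wright's pedigree inbreeding coefficient
    truncated at a fixed generation depth, haplotype-based linkage
    disequilibrium decay, and reconstruction of ungenotyped sire haplotypes
    from half-sib families with per-offspring recombination counts. A
    pedigreed multi-population genotype simulator (Balding-Nichols drift,
    Poisson gene dropping with full crossover and autozygosity ground truth)
    makes every stage verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
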