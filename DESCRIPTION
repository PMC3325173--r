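Package: rohscan
Title: Homozygosity Mapping and Recessive Candidate-Gene Discovery in Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering candidate recessive disease genes from
    family genotype and exome variant data. Implements run-of-homozygosity
    (ROH) detection with explicit heterozygote-tolerance rules, pairwise
    relatedness statistics (IBS state counts, IBS2*_ratio, method-of-moments
    IBD estimates), a variant filtration cascade with Mendelian segregation
    tests under homozygous-recessive, compound-heterozygous and X-linked
    models, ROH-overlay candidate prioritization, and a case/control
    recessive burden test. A pedigree simulator with consanguinity loops,
    recombination on a genetic map, and implanted causal variants provides
    ground-truth data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
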