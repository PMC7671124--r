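Package: poolpat
Title: Parentage Inference from Pooled-Offspring Microsatellite Data
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for genetic parentage analysis of broods genotyped as
    pooled offspring, where only the union of alleles per locus is observed.
    Implements minimum-sire-number estimation from non-maternal allele
    counts, classification of broods from pair-living animals as consistent
    with sexual monogamy or showing extra-pair paternity, microsatellite
    panel diagnostics (heterozygosity, Hardy-Weinberg tests, null-allele
    frequency, parentage exclusion probabilities), a Monte Carlo model of
    the probability of detecting multiple paternity (PrDM) with an exact
    enumeration oracle, and a synthetic mating-system simulator for
    hermaphroditic, pair-living gastropods that provides ground truth for
    validating the estimators. Ships a worked microsatellite dataset from a
    rocky-intertidal limpet population.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
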