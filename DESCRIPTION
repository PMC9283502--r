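Package: kdrmonitor
Title: Genotyping and Monitoring of Knockdown-Resistance (kdr) Mutations in Soybean Aphid
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for monitoring pyrethroid resistance in Aphis glycines via
    voltage-gated sodium channel (vgsc) markers. Simulates the BstEII PCR-RFLP
    assay for the L1014F kdr mutation and the ligase-chain-reaction (LCR) assay
    for the M918I super-kdr mutation on IUPAC consensus sequences, classifies
    two-locus diploid genotypes, computes resistant allele frequencies, exact
    genotype-phenotype association tests, allele-count odds ratios with
    equal-weight pooling over locations via a binomial logit model, and fits
    three-parameter log-logistic dose-mortality curves (LC50, resistance and
    synergist ratios) by binomial maximum likelihood. Includes a synthetic-data
    generator producing reference transcripts, per-individual consensus
    sequences, selection experiments and bioassay tables with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    stats,
    utils
Suggests:
    emmeans,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
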