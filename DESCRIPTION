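Package: mhcamplicon
Title: MHC Class II Amplicon Genotyping and Immunogenetic Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Validation of alleles from deep-sequenced MHC class II amplicons
    and downstream immunogenetic analysis. Implements per-amplicon (RPAF) and
    across-amplicon (MPAF) allele frequency indices, classification of
    sequencing artifacts (point errors, homopolymer indels, PCR chimeras) and
    cross-amplicon carryover contaminants, locus copy-number assessment from
    rank-frequency profiles, an exact multinomial model of the minimum
    sequencing depth needed for confident genotyping, and replicate-based
    genotype resolution. Downstream tools cover exact Hardy-Weinberg U-score
    tests, EM estimation of null-allele frequency, likelihood-ratio tests of
    linkage disequilibrium on unphased genotypes, Weir-Cockerham
    F-statistics, Nei-Gojobori dN/dS with Jukes-Cantor correction and
    codon-based Z-tests, neighbour-joining phylogenies with Poisson
    correction and bootstrap support, and rarefaction of allelic richness.
    A synthetic amplicon generator emulating pyrosequencing artifact
    structure supports end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    seqinr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
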