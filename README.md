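# mhcamplicon

Genotyping highly polymorphic immune genes (MHC class II DRB/DQB) from deep
amplicon sequencing, and the immunogenetic analyses that follow. Each PCR
product ("amplicon" = one individual × locus × run) yields reads spread over
many unique variants, of which only 1–2 are true alleles; the rest are PCR
point errors, homopolymer indels, template-switching chimeras, or carryover
of true alleles from other samples. Global frequency cut-offs throw away
rare true alleles and keep run-specific artifacts, so this package scores
every variant on two axes instead:

* **RPAF** — the variant's share of reads *within* an amplicon,
* **MPAF** — the mean of those shares *across* the amplicons possessing it,

and classifies variants by a deterministic cascade (parental attribution by
sequence similarity, chimera breakpoint detection, the high-MPAF/low-RPAF
carryover signature), resolving suspects by replicate amplicons rather than
by thresholding. Around this core: locus copy-number assessment from
rank-frequency profiles, an exact multinomial model of the minimum read
depth for confident genotyping, exact Hardy–Weinberg U-score tests
(heterozygote-excess alternative), EM null-allele estimation, a
likelihood-ratio test of linkage disequilibrium on unphased genotypes,
Weir–Cockerham F<sub>ST</sub>, Nei–Gojobori pathway d<sub>N</sub>/d<sub>S</sub>
with Jukes–Cantor correction and codon-based Z-tests on ABS/PSS site masks,
Poisson-corrected neighbour-joining trees with bootstrap supports, and
rarefaction of allelic richness. A synthetic amplicon generator with a
truth ledger makes the whole pipeline testable end to end.

## Worked example

```r
library(mhcamplicon)

# a cohort like the study design: 17-allele DRB locus, 100 individuals
pool  <- generate_allele_pool("DRB", 17, 162, seed = 11)
truth <- generate_population(pool, 100, rep(1/17, 17), seed = 12)
amps  <- generate_amplicons(truth, sim_config(), seed = 13)
amps
#> <amplicon_set> 100 amplicons, 388 variants, 19705 reads

rank_frequency_profile(amps)$verdict     # locus duplicated?
#> [1] "single-locus"

cls   <- classify_variants(amps)
table(cls$label)
#>     ARTIFACT_CHIMERA ARTIFACT_HOMOPOLYMER       ARTIFACT_POINT
#>                  114                  119                  167
#>  CONTAMINANT_SUSPECT          TRUE_ALLELE
#>                    5                  196

calls <- call_genotypes(amps, classification = cls)
genotype_accuracy(calls, truth)
#> [1] 1

st    <- compute_variant_stats(amps)
after <- st[st$variant_id %in% validated_variants(cls), ]
d     <- sorting_diagnostics(st, after)
round(c(before = d$before$r, after = d$after$r), 2)
#> before  after
#>   0.93  -0.24

min_reads_for_confidence(n_alleles = 2, min_copies = 5, confidence = 0.95)
#> [1] 17

hwe_u_test(truth$genotypes, "DRB", n_mc = 10000, seed = 14)
#> HWE U-score test (heterozygote excess): U = 24.7619, p = 0.3581 (10000 MC arrays)
#>   Ho = 0.9600, He = 0.9410, Fis(W&C) = -0.0203, n = 100
```

Reading: the cohort's 388 raw variants collapse to the true alleles
(recovery 100% here); the MPAF-versus-amplicon-count correlation drops from
0.93 to −0.24 once artifacts are discarded — the signature of successful
sorting; 17 reads suffice for a two-allele genotype at 0.95 confidence
(≥ 5 reads per allele); and the panmictic cohort shows no heterozygote
excess (Ho ≈ He, Fis ≈ 0).

`run_pipeline(pipeline_config(...))` chains all stages (simulate → stats →
classify → genotype → popgen/selection/tree/rarefaction) and writes
TSV/FASTA/Newick outputs stamped with a config hash; reruns under the same
config are byte-identical.

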