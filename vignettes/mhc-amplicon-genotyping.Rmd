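---
title: "Validating MHC class II alleles from deep amplicon sequencing"
author: "mhcamplicon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating MHC class II alleles from deep amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Deep amplicon sequencing of highly polymorphic immune genes — here the MHC
class II loci DRB and DQB of small primates — returns, for every PCR product
("amplicon", one individual at one locus in one run), a pool of reads spread
over many unique sequence variants. Only one or two of those variants are
the individual's true alleles. The rest are PCR or sequencing artifacts
(point errors, indels at homopolymer runs, template-switching chimeras of
the two parental alleles) or cross-amplicon carryover of true alleles from
other samples. Global frequency cut-offs discard rare true alleles and keep
run-specific artifacts; this package instead scores every variant both
within and across amplicons and resolves the ambiguous cases by replication.

## The two frequency indices

For a variant $v$ in amplicon $a$ with read counts $c_{va}$:

* **RPAF** (relative per-amplicon frequency): $r_{va} = c_{va} / \sum_w c_{wa}$,
  the within-amplicon share of the variant.
* **MPAF** (mean per-amplicon frequency): the unweighted mean of $r_{va}$
  over the amplicons that possess $v$.

True alleles have high MPAF and high RPAF. Artifacts are rare on both axes
and are tied by sequence similarity to a parental allele in the same
amplicon. Carryover contaminants show the characteristic dissociation —
high MPAF (they are real alleles elsewhere) with low RPAF locally.

## The classification cascade

`classify_variants()` labels every variant of every amplicon, in order:

1. The two most abundant variants are provisional parentals (ties broken by
   variant id). A second parental that is itself a small edit or a
   homopolymer indel of the first is demoted to an artifact; the amplicon is
   then effectively homozygous. Without this demotion the largest artifact
   in a homozygous amplicon would masquerade as a parental and escape
   labelling.
2. A non-parental variant that is (a) a homopolymer indel of a parental
   (single-base indel touching a run of length ≥ 3), (b) within edit
   distance ≤ 2 of a parental (two edits cover doubled pyrosequencing
   errors; configurable), or (c) a single-breakpoint chimera of the two
   parentals becomes `ARTIFACT_HOMOPOLYMER` / `ARTIFACT_POINT` /
   `ARTIFACT_CHIMERA`, with parental attribution and, for chimeras, the
   breakpoint.
3. A remaining variant with MPAF ≥ 0.05 but RPAF < 0.10 here, while the
   same sequence reaches RPAF ≥ 0.25 in another amplicon, is a
   `CONTAMINANT_SUSPECT`. The 0.05 MPAF value is a descriptive flag, not an
   automatic filter: suspects are resolved by replicates
   (`resolve_with_replicates()`), never auto-dropped, to avoid manufacturing
   allelic dropout.
4. Remaining variants with MPAF ≥ 0.05 and adequate RPAF are `TRUE_ALLELE`.
5. Everything else is `UNRESOLVED`.

The cascade is a declared, deterministic approximation of a procedure that
in the original workflow included manual alignment judgement; the manual
step cannot be automated faithfully, which is why every threshold is
exposed in `ampsort_config()`.

Two cohort-level diagnostics accompany the cascade. The rank-frequency
profile (`rank_frequency_profile()`) averages the within-amplicon frequency
of the 1st…k-th most common variant; a single (non-duplicated) locus shows a
sharp drop after rank 2, quantified as the rank-2/rank-3 ratio with verdict
threshold 3. Amplicons with fewer than r variants contribute frequency 0 at
rank r, keeping the per-rank means comparable across amplicons. And the
Pearson correlation between MPAF and the number of amplicons possessing a
variant (`sorting_diagnostics()`) should be strongly positive before
sorting — artifacts are rare *and* private — and should collapse once
artifacts are removed.

## Minimum sequencing depth

`min_reads_for_confidence(n_alleles, min_copies, confidence, artifact_rate)`
computes the smallest depth $T$ such that, under a multinomial split of $T$
reads among equifrequent true alleles plus an artifact class, every true
allele receives at least `min_copies` reads with the requested probability.
The tail probability is computed exactly by sequential-binomial dynamic
programming, not simulation. The published 18-read threshold for a
two-allele genotype at 0.95 confidence depends on a parameterisation
(minimum copies per allele, artifact mass) that the original program does
not print; the operation is therefore parameter-explicit — e.g. two alleles,
five copies each, no artifact mass gives 17.

## The synthetic cohort generator

Every stage is validated against `generate_amplicons()`, which emulates the
artifact structure of a 454-style experiment and logs the origin of every
variant in a truth ledger:

* depth per amplicon ~ negative binomial (mean 200, dispersion 10) — the
  scale of a GS Junior run;
* heterozygote balance ~ Beta(20, 20), mimicking mild amplification bias
  (the within-amplicon balance of true alleles is not documented for the
  original data; a symmetric Beta is the neutral choice);
* per-read corruption: 1–2 bp substitution derivatives (rate 0.02),
  single-base indels at homopolymer runs ≥ 3 (rate 0.01), single-breakpoint
  chimeras in heterozygotes only (rate 0.01);
* per-amplicon carryover of a foreign pool allele (rate 0.05) at ~5% of
  reads.

The per-class artifact rates are not reported for the original experiment;
the defaults were chosen once to reproduce the qualitative pattern that
artifacts are clearly rarer than true alleles, and they are deliberately
*harsher* than needed for the headline checks (≈6% of reads are corrupted).
What the generator does **not** emulate: base-quality structure, flowgram
noise, primer/barcode sequences, run batch effects, or alignment ambiguity
beyond single indels. Passing tests therefore demonstrate the internal
consistency and statistical calibration of the pipeline, not its error rate
on real flowgram data.

Allele pools are built from sense codons only (universal code), so frame-0
stop codons never occur; a configurable fraction of alleles carries a
shared in-frame 6-bp (two-codon) insertion, reproducing the fragment-length
polymorphism of DQB; non-carriers are gapped at that position by
`align_pool()`.

## Population genetics

* `hwe_u_test()`: the score statistic for heterozygote excess,
  $U = n_{het} - \sum_i n_{ii}(1-p_i)/p_i$, against a Monte-Carlo Levene
  null (random re-pairing of the observed allele copies). All permutation
  p-values in the package use the $(b+1)/(m+1)$ estimator, so a reported p
  is never exactly zero.
* `null_allele_em()`: EM treating apparent homozygotes as a mixture of true
  homozygotes and null-carrier heterozygotes, with the unseen null-null
  class imputed per iteration.
* `ld_lrt()`: EM haplotype frequencies for unphased two-locus genotypes
  (Slatkin–Excoffier style), LR against the product of single-locus HWE
  likelihoods, significance by permuting one locus across individuals.
  Degrees of freedom are reported as $(k_A-1)(k_B-1)$; df bookkeeping for
  unphased EM LRTs differs across programs, so inference should rest on the
  permutation p. The EM and its permutation null run in C++ — the
  calibration checks alone fit one million EM runs.
* `pairwise_fst()`: Weir–Cockerham variance components (the estimator
  family used by standard software; the primary description cites Wright
  but prints no formula), label-permutation p-values.
* Missing genotypes are excluded listwise per locus pair for LD and per
  locus elsewhere.

## Selection and phylogeny

`ng86_pair()` implements Nei–Gojobori pathway counting: all substitution
orders between two codons are enumerated, pathways through stop codons are
discarded, and synonymous/nonsynonymous steps are averaged with equal
weights over the surviving pathways; if every pathway is blocked the codon
is excluded and flagged. Site counts exclude changes to stops from the
numerators while keeping the three-changes-per-position denominator, so a
codon's site total is 3 minus the stop-adjusted mass. Proportions are
Jukes–Cantor corrected; `partition_dnds()` restricts the analysis to a
user-supplied site mask (ABS/non-ABS, PSS/non-PSS — PSS identification
itself, a codon-model inference, is out of scope and consumed as input) and
applies complete deletion of gap-containing codon columns alignment-wide.
Standard errors come from a bootstrap over codon sites (default 1000
replicates); the analytical NG86 variance is not used because the reference
implementation's choice is not documented. The codon-based Z-test is
one-tailed for positive selection by default (`dN > dS`); the two-sided
variant is a flag, since the original direction is not stated.

Phylogeny: Poisson-corrected amino-acid distances ($d = -\ln(1-p)$,
complete deletion), neighbour joining via `ape::nj` (its deterministic tie
rule replaces the lexical rule sketched at design time — the testable
guarantee, exact recovery of additive matrices, holds either way), supports
by column-bootstrap with bipartition counting, Newick output hiding
supports below a display threshold (conventionally 50%). Negative NJ branch
lengths are retained and flagged rather than clamped, so additive-recovery
checks stay exact.

`rarefaction_curve()` draws individuals without replacement (replicates
independent), counts distinct alleles, and reports mean ± SD per effort; the
SD is across replicates (zero at full effort). Its mean is checked against
the closed-form hypergeometric expectation
$\sum_a 1 - \binom{N-k_a}{n}/\binom{N,n}$.

## Numerical choices and sizes

Fixed-seed reproducibility everywhere: every stochastic function takes a
`seed`; `run_pipeline()` derives all streams from one global seed and
stamps outputs with a config hash instead of timestamps, so reruns are
byte-identical. Ties are broken lexically by variant id. Frequency vectors
are validated to sum to 1 within 1e-12 (1e-8 for user-supplied input). EM
convergence: absolute log-likelihood change < 1e-8, capped iterations with
a non-convergence flag. The test suite calibrates the HWE and LD tests on
1000 panmictic cohorts of 50 individuals with 1000 Monte-Carlo draws each
(type-I error required within [0.03, 0.07] at nominal 0.05), verifies NG86
against exhaustive enumeration over all 61 × 61 sense-codon pairs, NJ on
100 random additive matrices, and the depth model against a 100 000-draw
Monte-Carlo oracle; cohort-level checks use 100 individuals and two loci at
the defaults above. These sizes are the package's validation design.

## Known limitations

* The cascade attributes each artifact to the first matching parental
  mechanism; a variant that is simultaneously a plausible point derivative
  and a chimera is counted once, under the earlier label.
* Contaminant evidence requires the sequence to reach RPAF ≥ 0.25 somewhere
  else in the cohort; an allele whose only appearances are carryover events
  is left `UNRESOLVED` rather than identified.
* `min_reads_for_confidence()` models equifrequent alleles; strong
  amplification bias calls for a larger safety margin.
* The LD LRT's χ² df is nominal; use the permutation p.
* Richness comparisons between species are qualitative: the generator can
  emulate pools of different sizes, but no empirical cross-species data
  ship with the package.
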