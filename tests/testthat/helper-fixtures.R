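# Fixture builders used across the suite. Everything is generated in code;
# no stored data.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# random in-frame stop-free sequence
rand_cds <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  paste(sample(names(gc)[gc != "*"], n_codons, TRUE), collapse = "")
}

# Hand-built amplicon_set for one locus. `amps` is a named list:
# amplicon_id -> named integer vector of counts (names = variant ids);
# `sequences` maps variant id -> sequence. Individual defaults to the part
# of the amplicon id before "|".
make_aset <- function(amps, sequences, locus = "L") {
  rows <- lapply(names(amps), function(a) {
    cnt <- amps[[a]]
    ind <- sub("\\|.*$", "", a)
    data.frame(amplicon_id = a, individual = ind, locus = locus,
               run = "run1", replicate = 1L, variant_id = names(cnt),
               count = as.integer(cnt), stringsAsFactors = FALSE)
  })
  reads <- do.call(rbind, rows)
  variants <- data.frame(variant_id = names(sequences), locus = locus,
                         sequence = unname(sequences),
                         stringsAsFactors = FALSE)
  structure(list(reads = reads, variants = variants, ledger = NULL),
            class = "amplicon_set")
}

# genotype table from explicit allele pairs
make_table <- function(pairs, locus = "L", subpop = "P1") {
  n <- length(pairs)
  data.frame(individual = sprintf("i%03d", seq_len(n)),
             subpop = rep_len(subpop, n), locus = locus,
             allele1 = vapply(pairs, function(p) sort(p)[1], ""),
             allele2 = vapply(pairs, function(p) sort(p)[2], ""),
             stringsAsFactors = FALSE)
}

# a small default-rate simulated cohort shared by several tests
sim_cohort <- function(n_ind = 40, n_alleles = 12, seed = 101,
                       config = sim_config(), locus = "DRB") {
  pool <- generate_allele_pool(locus, n_alleles, 162, seed = seed)
  truth <- generate_population(pool, n_ind, rep(1 / n_alleles, n_alleles),
                               seed = seed + 1)
  aset <- generate_amplicons(truth, config, seed = seed + 2)
  list(pool = pool, truth = truth, aset = aset)
}
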