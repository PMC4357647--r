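# Shared readers/writers (FASTA via Biostrings, TSV interchange) and the
# pipeline driver chaining simulate -> stats -> classify -> genotype ->
# popgen / selection / tree / rarefaction. TSV dialect: tab-separated,
# header row, '#' comment lines; codon coordinates are 1-based.

.iupac_dna <- c("A", "C", "G", "T", "U", "M", "R", "W", "S", "Y", "K",
                "V", "H", "D", "B", "N", "-")

#' Read a FASTA file
#'
#' Thin wrapper around `Biostrings::readBStringSet` with validation: ids must
#' be unique and sequences restricted to the alphabet of `type`. Failures
#' name the offending record.
#'
#' @param path FASTA file path.
#' @param type `"dna"` (IUPAC nucleotide codes), `"aa"` or `"any"`.
#' @return Named character vector of sequences (order preserved); an empty
#'   file gives an empty vector.
#' @export
read_fasta <- function(path, type = c("dna", "aa", "any")) {
  type <- match.arg(type)
  if (file.size(path) == 0) return(setNames(character(0), character(0)))
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- setNames(toupper(as.character(x)), ids)
  if (type != "any") {
    ok_chars <- if (type == "dna") .iupac_dna
                else c(strsplit("ACDEFGHIKLMNPQRSTVWYBXZJUO*", "")[[1]], "-")
    bad <- vapply(seqs, function(s)
      any(!strsplit(s, "", fixed = TRUE)[[1]] %in% ok_chars), logical(1))
    if (any(bad))
      stop("non-", toupper(type), " characters in record(s): ",
           paste(ids[bad], collapse = ", "))
  }
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::BStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

.write_tsv <- function(df, path, header_lines = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  read.delim(path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE)
}

#' Write an amplicon set as TSV + FASTA
#'
#' Emits `reads.tsv` (amplicon_id, individual, locus, run, replicate,
#' variant_id, count), `variants.fasta`, and `ledger.tsv` when a truth
#' ledger is present.
#'
#' @param aset An `amplicon_set`.
#' @param dir Output directory (created if needed).
#' @param stamp Optional character lines stamped as `#` comments.
#' @return The directory, invisibly.
#' @export
write_amplicons <- function(aset, dir, stamp = character(0)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_tsv(aset$reads, file.path(dir, "reads.tsv"), stamp)
  write_fasta(setNames(aset$variants$sequence, aset$variants$variant_id),
              file.path(dir, "variants.fasta"))
  if (!is.null(aset$ledger))
    .write_tsv(aset$ledger, file.path(dir, "ledger.tsv"), stamp)
  invisible(dir)
}

#' Read an amplicon set from TSV + FASTA
#'
#' @param reads_tsv Path to the reads table.
#' @param variants_fasta Path to the variant sequences.
#' @param ledger_tsv Optional truth-ledger path.
#' @return An `amplicon_set`.
#' @export
read_amplicons <- function(reads_tsv, variants_fasta, ledger_tsv = NULL) {
  reads <- .read_tsv(reads_tsv)
  need <- c("amplicon_id", "individual", "locus", "run", "replicate",
            "variant_id", "count")
  if (!all(need %in% names(reads)))
    stop("reads table must have columns: ", paste(need, collapse = ", "))
  seqs <- read_fasta(variants_fasta)
  miss <- setdiff(unique(reads$variant_id), names(seqs))
  if (length(miss)) stop("variants missing from FASTA: ",
                         paste(head(miss, 5L), collapse = ", "))
  loc <- reads$locus[match(names(seqs), reads$variant_id)]
  variants <- data.frame(variant_id = names(seqs), locus = loc,
                         sequence = unname(seqs), stringsAsFactors = FALSE)
  variants <- variants[!is.na(variants$locus), , drop = FALSE]
  ledger <- if (!is.null(ledger_tsv)) .read_tsv(ledger_tsv) else NULL
  structure(list(reads = reads, variants = variants, ledger = ledger),
            class = "amplicon_set")
}

#' Write / read a genotype table TSV
#' @param table Genotype table data frame.
#' @param path File path.
#' @param stamp Optional `#` comment lines.
#' @export
write_genotypes <- function(table, path, stamp = character(0)) {
  .write_tsv(table, path, stamp)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) .read_tsv(path)

# deterministic FNV-style hash of a deparsed R object, for output stamping;
# kept within 31 bits so base bitwXor stays exact
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 2166136261 %% 2147483647
  for (b in bytes) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' Validated bundle of the simulation settings, sorting thresholds, test
#' sizes and global seed for [run_pipeline()]. Serialises losslessly via
#' `dput`/`dget` of the underlying list.
#'
#' @param n_individuals Individuals to simulate.
#' @param loci Named list: per-locus `n_alleles` and `insertion_fraction`.
#' @param allele_freq_alpha Dirichlet concentration for the true allele
#'   frequencies (1 = uniform simplex draw).
#' @param sim A [sim_config()].
#' @param sort A [ampsort_config()].
#' @param n_perm Permutations for HWE/LD/FST stages.
#' @param n_boot Bootstrap replicates for dN/dS and tree supports.
#' @param rarefaction_step,rarefaction_reps Rarefaction grid settings.
#' @param seed Global seed; every stage derives its stream from it.
#' @param out_dir Output directory.
#' @return A `pipeline_config` list with a stable `hash`.
#' @export
pipeline_config <- function(n_individuals = 100L,
                            loci = list(DRB = list(n_alleles = 17L,
                                                   insertion_fraction = 0),
                                        DQB = list(n_alleles = 22L,
                                                   insertion_fraction = 7 / 22)),
                            allele_freq_alpha = 1,
                            sim = sim_config(),
                            sort = ampsort_config(),
                            n_perm = 1000L, n_boot = 200L,
                            rarefaction_step = 10L, rarefaction_reps = 100L,
                            seed = 1L, out_dir = tempfile("mhcamp_")) {
  cfg <- list(n_individuals = as.integer(n_individuals), loci = loci,
              allele_freq_alpha = allele_freq_alpha,
              sim = unclass(sim), sort = unclass(sort),
              n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
              rarefaction_step = as.integer(rarefaction_step),
              rarefaction_reps = as.integer(rarefaction_reps),
              seed = as.integer(seed), out_dir = out_dir)
  cfg$hash <- .config_hash(cfg[setdiff(names(cfg), "out_dir")])
  class(cfg) <- "pipeline_config"
  cfg
}

# Dirichlet draw via gammas
.rdirichlet1 <- function(k, alpha) {
  x <- stats::rgamma(k, shape = alpha)
  x / sum(x)
}

#' Run the full synthetic-cohort pipeline
#'
#' Simulates allele pools, a panmictic population and artifact-laden
#' amplicons, then runs allele sorting, genotype calling, the
#' population-genetic test battery, divergence/selection summaries, the
#' amino-acid NJ tree and the rarefaction curve, writing every artifact
#' under `config$out_dir`. All outputs are stamped with the config hash and
#' seed (no timestamps), so a rerun with the same config is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results and output paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- c(paste0("config_hash: ", config$hash),
             paste0("seed: ", config$seed))
  sim <- do.call(sim_config, config$sim)
  srt <- do.call(ampsort_config, config$sort)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  pools <- lapply(names(config$loci), function(L) {
    spec <- config$loci[[L]]
    generate_allele_pool(L, spec$n_alleles, length = 162,
                         insertion_fraction = spec$insertion_fraction)
  })
  names(pools) <- names(config$loci)
  freqs <- lapply(pools, function(p)
    .rdirichlet1(nrow(p), config$allele_freq_alpha))
  truth <- generate_population(pools, config$n_individuals, freqs)
  aset <- generate_amplicons(truth, sim)
  write_amplicons(aset, file.path(config$out_dir, "amplicons"), stamp)
  note("simulate: %d amplicons, %d variants",
       length(unique(aset$reads$amplicon_id)), nrow(aset$variants))

  stats_by_locus <- lapply(names(pools), function(L)
    compute_variant_stats(aset, L))
  names(stats_by_locus) <- names(pools)
  for (L in names(pools))
    .write_tsv(stats_by_locus[[L]][, c("variant_id", "sequence", "mpaf",
                                       "n_amplicons")],
               file.path(config$out_dir, paste0("variant_stats_", L, ".tsv")),
               stamp)

  cls <- classify_variants(aset, stats_by_locus, srt)
  .write_tsv(cls, file.path(config$out_dir, "classification.tsv"), stamp)
  note("classify: %s", paste(names(table(cls$label)), table(cls$label),
                             sep = "=", collapse = ", "))

  calls <- call_genotypes(aset, srt, cls)
  gt <- calls$genotypes
  gt$subpop <- truth$genotypes$subpop[match(gt$individual,
                                            truth$genotypes$individual)]
  write_genotypes(gt, file.path(config$out_dir, "genotypes.tsv"), stamp)
  note("genotype: %s", paste(names(calls$qc$status_counts),
                             calls$qc$status_counts,
                             sep = "=", collapse = ", "))

  diag_list <- list(); popgen <- list(); curves <- list()
  for (L in names(pools)) {
    st <- stats_by_locus[[L]]
    valid <- validated_variants(cls[cls$locus == L, ])
    after <- st[st$variant_id %in% valid, , drop = FALSE]
    diag_list[[L]] <- if (nrow(after) >= 3L)
      sorting_diagnostics(st, after) else NULL
    popgen[[L]] <- list(
      freqs = allele_frequencies(truth$genotypes, L),
      hwe = hwe_u_test(truth$genotypes, L, n_mc = config$n_perm),
      null_allele = null_allele_em(truth$genotypes, L))
    curves[[L]] <- rarefaction_curve(truth$genotypes, L,
                                     step = config$rarefaction_step,
                                     n_reps = config$rarefaction_reps)
    .write_tsv(curves[[L]], file.path(config$out_dir,
                                      paste0("rarefaction_", L, ".tsv")), stamp)
  }
  ld <- ld_lrt(truth$genotypes, names(pools)[1L], names(pools)[2L],
               n_perm = config$n_perm)
  note("popgen: LD LR = %.2f (p = %.3g)", ld$statistic, ld$p)

  selection <- list(); trees <- list()
  for (L in names(pools)) {
    aln <- codon_alignment(align_pool(pools[[L]]))
    msk <- site_mask(aln$n_codons, abs_sites = integer(0))
    dn <- z_test_selection(partition_dnds(aln, msk, "All",
                                          n_boot = config$n_boot))
    selection[[L]] <- list(
      dnds_all = dn,
      divergence_nt = mean_pairwise_distance(aln, "nucleotide"),
      divergence_aa = mean_pairwise_distance(aln, "amino_acid"),
      varsites_nt = variable_sites(aln, "nucleotide"))
    aa <- .translate_alignment(aln)
    if (length(aa) >= 4L) {
      tr <- bootstrap_support(aa, n_reps = config$n_boot)
      write_newick(tr, file.path(config$out_dir, paste0("tree_", L, ".nwk")),
                   min_support_display = 50)
      trees[[L]] <- tr
    }
    note("selection %s: dN = %.3f, dS = %.3f (Z = %.2f, p = %.3g)",
         L, dn$dN, dn$dS, dn$Z, dn$p)
  }

  writeLines(c(paste0("# config_hash: ", config$hash),
               paste0("# seed: ", config$seed), log_lines),
             file.path(config$out_dir, "pipeline.log"))
  invisible(list(truth = truth, amplicons = aset, stats = stats_by_locus,
                 classification = cls, calls = calls, diagnostics = diag_list,
                 popgen = popgen, ld = ld, selection = selection,
                 trees = trees, rarefaction = curves,
                 out_dir = config$out_dir))
}
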