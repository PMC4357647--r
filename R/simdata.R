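# Synthetic MHC amplicon data: allele pools, populations and per-amplicon
# read sets with a truth ledger, emulating the artifact structure of 454-style
# deep amplicon sequencing (point errors, homopolymer indels, PCR chimeras,
# cross-amplicon carryover of true alleles).

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

#' Simulation configuration for amplicon read sets
#'
#' Bundles the per-read artifact rates and depth law used by
#' [generate_amplicons()]. All rates are probabilities in `[0, 1]`.
#'
#' @param depth_mean,depth_dispersion Mean and dispersion (negative binomial
#'   `size`) of the per-amplicon read depth.
#' @param err_point Per-read probability of being replaced by a 1-2 bp
#'   substitution derivative of its parental allele.
#' @param err_homopolymer Per-read probability of a single-base indel adjacent
#'   to a homopolymer run of length >= `homopolymer_min_run` in the parent.
#' @param chimera_rate Per-read probability (heterozygous amplicons only) of a
#'   single-breakpoint chimera of the two parental alleles.
#' @param contamination_rate Per-amplicon probability that a foreign true
#'   allele (drawn from the pool minus the amplicon's own genotype) is carried
#'   over into the read set.
#' @param contamination_frac Expected fraction of reads captured by the
#'   contaminant when carryover occurs.
#' @param balance_shape Shape of the symmetric Beta distribution used for the
#'   within-amplicon proportion of the two alleles of a heterozygote.
#' @param homopolymer_min_run Minimum run length that can seed a homopolymer
#'   indel artifact.
#' @param n_replicates Number of independent read sets per individual x locus.
#' @param n_runs Number of sequencing runs replicates are spread over.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(depth_mean = 200, depth_dispersion = 10,
                       err_point = 0.02, err_homopolymer = 0.01,
                       chimera_rate = 0.01, contamination_rate = 0.05,
                       contamination_frac = 0.05, balance_shape = 20,
                       homopolymer_min_run = 3, n_replicates = 1L,
                       n_runs = 2L) {
  rates <- c(err_point = err_point, err_homopolymer = err_homopolymer,
             chimera_rate = chimera_rate, contamination_rate = contamination_rate,
             contamination_frac = contamination_frac)
  if (any(rates < 0 | rates > 1))
    stop("all rates must be probabilities in [0, 1]")
  if (depth_mean <= 0) stop("depth_mean must be > 0")
  if (depth_dispersion <= 0) stop("depth_dispersion must be > 0")
  structure(list(depth_mean = depth_mean, depth_dispersion = depth_dispersion,
                 err_point = err_point, err_homopolymer = err_homopolymer,
                 chimera_rate = chimera_rate,
                 contamination_rate = contamination_rate,
                 contamination_frac = contamination_frac,
                 balance_shape = balance_shape,
                 homopolymer_min_run = homopolymer_min_run,
                 n_replicates = as.integer(n_replicates),
                 n_runs = as.integer(n_runs)),
            class = "sim_config")
}

#' Generate a pool of distinct in-frame alleles for one locus
#'
#' Sequences are built from sense codons (universal code), so frame-0 internal
#' stop codons never occur. A fraction of alleles can carry a shared 6-bp
#' (two-codon) in-frame insertion, producing the fragment-length polymorphism
#' seen at MHC-DQB; its codon position is recorded so downstream alignments
#' can gap the non-carriers.
#'
#' @param locus_id Locus label, e.g. `"DRB"`.
#' @param n_alleles Number of distinct alleles (>= 1).
#' @param length Base length of the non-carrier alleles; must be a multiple
#'   of 3 (study amplicons span 162-170 bp after primer trimming).
#' @param insertion_fraction Fraction of alleles carrying the +6 bp insertion.
#' @param seed Optional integer seed for reproducibility.
#' @return An `allele_pool`: data frame with columns `allele_id`, `sequence`,
#'   `has_insertion`, plus attributes `locus_id`, `insertion_codon` (codon
#'   index after which the insertion sits) and `insertion_motif`.
#' @export
generate_allele_pool <- function(locus_id, n_alleles, length = 162,
                                 insertion_fraction = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_alleles < 1) stop("n_alleles must be >= 1")
  if (length %% 3 != 0) stop("length must be divisible by 3 (in-frame fragment)")
  n_codons <- length / 3L
  codons <- sense_codons()
  if (log(n_alleles) > n_codons * log(length(codons)))
    stop("n_alleles exceeds the available sequence space")

  draw <- function(k) {
    vapply(seq_len(k), function(i)
      paste(sample(codons, n_codons, replace = TRUE), collapse = ""),
      character(1))
  }
  seqs <- draw(n_alleles)
  while (anyDuplicated(seqs)) {
    dup <- duplicated(seqs)
    seqs[dup] <- draw(sum(dup))
  }

  n_ins <- round(insertion_fraction * n_alleles)
  carriers <- if (n_ins > 0) sort(sample.int(n_alleles, n_ins)) else integer(0)
  ins_codon <- if (n_codons >= 26L) 24L else max(1L, floor(n_codons / 2))
  motif <- paste(sample(codons, 2L, replace = TRUE), collapse = "")
  if (n_ins > 0) {
    cut <- ins_codon * 3L
    seqs[carriers] <- paste0(substr(seqs[carriers], 1L, cut), motif,
                             substring(seqs[carriers], cut + 1L))
  }

  ids <- sprintf("%s*%03d", locus_id, seq_len(n_alleles))
  pool <- data.frame(allele_id = ids, sequence = seqs,
                     has_insertion = seq_len(n_alleles) %in% carriers,
                     stringsAsFactors = FALSE)
  structure(pool, locus_id = locus_id, insertion_codon = ins_codon,
            insertion_motif = motif, class = c("allele_pool", "data.frame"))
}

#' Gapped alignment of an allele pool
#'
#' Non-carriers of the 6-bp insertion receive a 6-base gap at the insertion
#' point, yielding equal-length, in-frame aligned sequences.
#'
#' @param pool An `allele_pool`.
#' @return Named character vector of aligned sequences.
#' @export
align_pool <- function(pool) {
  seqs <- setNames(pool$sequence, pool$allele_id)
  if (!any(pool$has_insertion)) return(seqs)
  cut <- attr(pool, "insertion_codon") * 3L
  idx <- !pool$has_insertion
  seqs[idx] <- paste0(substr(seqs[idx], 1L, cut), "------",
                      substring(seqs[idx], cut + 1L))
  seqs
}

#' Draw diploid genotypes for a population
#'
#' Each individual receives two independent allele draws per locus
#' (Hardy-Weinberg sampling); the pair is stored unordered
#' (`allele1 <= allele2`), with homozygotes duplicating the allele.
#'
#' @param pool An `allele_pool` or named list of pools (one per locus).
#' @param n_individuals Number of individuals.
#' @param allele_freqs Frequency vector (or list of vectors, matching
#'   `pool`) summing to 1 per locus.
#' @param seed Optional integer seed.
#' @param subpops Optional named integer vector of subpopulation sizes summing
#'   to `n_individuals`; default is a single panmictic group `"P1"`.
#' @return A `truth_set`: list with `genotypes` (data frame `individual`,
#'   `subpop`, `locus`, `allele1`, `allele2`) and `pools`.
#' @export
generate_population <- function(pool, n_individuals, allele_freqs, seed = NULL,
                                subpops = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pools <- if (inherits(pool, "allele_pool")) {
    setNames(list(pool), attr(pool, "locus_id"))
  } else pool
  freqs <- if (is.list(allele_freqs)) allele_freqs else list(allele_freqs)
  if (length(freqs) != length(pools))
    stop("allele_freqs must match the number of loci")
  if (is.null(subpops)) subpops <- c(P1 = n_individuals)
  if (sum(subpops) != n_individuals)
    stop("subpop sizes must sum to n_individuals")

  inds <- sprintf("ind%04d", seq_len(n_individuals))
  pop <- rep(names(subpops), subpops)
  rows <- lapply(seq_along(pools), function(k) {
    p <- pools[[k]]
    f <- freqs[[k]]
    if (length(f) != nrow(p)) stop("frequency vector length must equal pool size")
    if (abs(sum(f) - 1) > 1e-8) stop("allele frequencies must sum to 1")
    a1 <- sample(p$allele_id, n_individuals, replace = TRUE, prob = f)
    a2 <- sample(p$allele_id, n_individuals, replace = TRUE, prob = f)
    swap <- a2 < a1
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
    data.frame(individual = inds, subpop = pop, locus = names(pools)[k],
               allele1 = a1, allele2 = a2, stringsAsFactors = FALSE)
  })
  structure(list(genotypes = do.call(rbind, rows), pools = pools),
            class = "truth_set")
}

# -- internal sequence corrupters ------------------------------------------

.mutate_point <- function(seq, n_sub) {
  bases <- c("A", "C", "G", "T")
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(ch), n_sub)
  for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
  paste(ch, collapse = "")
}

.homopolymer_runs <- function(seq, min_run) {
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_run
  data.frame(base = r$values[keep], start = starts[keep], end = ends[keep],
             len = r$lengths[keep], stringsAsFactors = FALSE)
}

.mutate_homopolymer <- function(seq, min_run) {
  runs <- .homopolymer_runs(seq, min_run)
  if (!nrow(runs)) return(NULL)
  i <- if (nrow(runs) == 1L) 1L else sample.int(nrow(runs), 1L)
  s <- runs$start[i]
  if (runif(1) < 0.5) {
    paste0(substr(seq, 1L, s - 1L), substring(seq, s + 1L))       # deletion
  } else {
    paste0(substr(seq, 1L, s), runs$base[i], substring(seq, s + 1L)) # insertion
  }
}

.make_chimera <- function(a, b) {
  if (nchar(a) != nchar(b)) return(NULL)
  L <- nchar(a)
  for (try in 1:5) {
    bp <- sample.int(L - 1L, 1L)
    cand <- paste0(substr(a, 1L, bp), substring(b, bp + 1L))
    if (cand != a && cand != b) return(cand)
  }
  NULL
}

#' Simulate per-amplicon read sets from a truth set
#'
#' For every individual x locus x replicate, a read depth is drawn from a
#' negative binomial law and split between the 1-2 true alleles at a
#' Beta-balanced proportion. Reads are then corrupted at the configured rates:
#' point-mutation derivatives and homopolymer indels of their parental allele,
#' single-breakpoint chimeras of the two parentals (heterozygotes only), and
#' per-amplicon carryover of a foreign true allele at low within-amplicon
#' frequency. Every variant in every amplicon is recorded in a truth ledger
#' with its origin label.
#'
#' @param truth A `truth_set` from [generate_population()].
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return An `amplicon_set`: list with `reads` (data frame `amplicon_id`,
#'   `individual`, `locus`, `run`, `replicate`, `variant_id`, `count`),
#'   `variants` (`variant_id`, `locus`, `sequence`) and `ledger`
#'   (`amplicon_id`, `variant_id`, `origin`, `parent`), where `origin` is one
#'   of `true`, `point`, `homopolymer`, `chimera`, `contaminant`.
#' @export
generate_amplicons <- function(truth, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(truth, "truth_set"), inherits(config, "sim_config"))
  gt <- truth$genotypes
  pools <- truth$pools

  reads <- vector("list", nrow(gt) * config$n_replicates)
  ledger <- vector("list", length(reads))
  k <- 0L
  for (i in seq_len(nrow(gt))) {
    locus <- gt$locus[i]
    pool <- pools[[locus]]
    seq_of <- setNames(pool$sequence, pool$allele_id)
    own <- unique(c(gt$allele1[i], gt$allele2[i]))
    for (rep_i in seq_len(config$n_replicates)) {
      k <- k + 1L
      amp_id <- sprintf("%s|%s|r%d", gt$individual[i], locus, rep_i)
      run_id <- sprintf("run%d", ((rep_i - 1L) %% config$n_runs) + 1L)
      depth <- max(1L, rnbinom(1L, mu = config$depth_mean,
                               size = config$depth_dispersion))

      # carryover contaminant takes its share of the depth first
      cont_id <- NA_character_
      n_cont <- 0L
      if (length(seq_of) > length(own) &&
          runif(1) < config$contamination_rate) {
        cont_id <- sample(setdiff(names(seq_of), own), 1L)
        n_cont <- rbinom(1L, depth, config$contamination_frac)
      }
      n_parent <- depth - n_cont

      # split remaining reads between the true alleles
      if (length(own) == 2L) {
        prop <- rbeta(1L, config$balance_shape, config$balance_shape)
        n1 <- rbinom(1L, n_parent, prop)
        alloc <- setNames(c(n1, n_parent - n1), own)
      } else {
        alloc <- setNames(n_parent, own)
      }

      seqs <- character(0); cnts <- integer(0)
      orig <- character(0); par <- character(0)
      if (n_cont > 0L) {
        seqs <- seq_of[[cont_id]]; cnts <- n_cont
        orig <- "contaminant"; par <- cont_id
      }
      het <- length(own) == 2L
      for (a in names(alloc)) {
        n_a <- alloc[[a]]
        if (n_a == 0L) next
        p_err <- c(config$err_point, config$err_homopolymer,
                   if (het) config$chimera_rate else 0)
        split <- rmultinom(1L, n_a, c(p_err, 1 - sum(p_err)))[, 1L]
        n_pt <- split[1L]; n_hp <- split[2L]; n_ch <- if (het) split[3L] else 0L
        n_clean <- n_a - n_pt - n_hp - n_ch
        if (n_pt > 0L) {
          seqs <- c(seqs, .mutate_point(seq_of[[a]], sample(1:2, 1L)))
          cnts <- c(cnts, n_pt); orig <- c(orig, "point"); par <- c(par, a)
        }
        if (n_hp > 0L) {
          hp <- .mutate_homopolymer(seq_of[[a]], config$homopolymer_min_run)
          if (is.null(hp)) n_clean <- n_clean + n_hp
          else {
            seqs <- c(seqs, hp); cnts <- c(cnts, n_hp)
            orig <- c(orig, "homopolymer"); par <- c(par, a)
          }
        }
        if (n_ch > 0L) {
          other <- setdiff(own, a)
          ch <- .make_chimera(seq_of[[a]], seq_of[[other]])
          if (is.null(ch)) n_clean <- n_clean + n_ch
          else {
            seqs <- c(seqs, ch); cnts <- c(cnts, n_ch)
            orig <- c(orig, "chimera"); par <- c(par, paste(a, other, sep = "+"))
          }
        }
        if (n_clean > 0L) {
          seqs <- c(seqs, seq_of[[a]]); cnts <- c(cnts, n_clean)
          orig <- c(orig, "true"); par <- c(par, a)
        }
      }

      # aggregate by sequence; 'true' outranks 'contaminant' outranks artifacts
      prio <- c(true = 1, contaminant = 2, chimera = 3, homopolymer = 4, point = 5)
      o <- order(match(orig, names(prio)))
      seqs <- seqs[o]; cnts <- cnts[o]; orig <- orig[o]; par <- par[o]
      first <- !duplicated(seqs)
      tot <- tapply(cnts, factor(seqs, levels = unique(seqs)), sum)
      seqs_u <- unique(seqs)
      reads[[k]] <- data.frame(
        amplicon_id = amp_id, individual = gt$individual[i], locus = locus,
        run = run_id, replicate = rep_i, sequence = seqs_u,
        count = as.integer(tot[seqs_u]), stringsAsFactors = FALSE)
      ledger[[k]] <- data.frame(
        amplicon_id = amp_id, sequence = seqs_u,
        origin = orig[first], parent = par[first], stringsAsFactors = FALSE)
    }
  }
  reads <- do.call(rbind, reads)
  ledger <- do.call(rbind, ledger)

  # assign variant ids per locus: pool alleles keep their id, artifacts get
  # sequential ids in order of first appearance
  reads$variant_id <- NA_character_
  variants <- vector("list", length(pools))
  for (li in seq_along(pools)) {
    locus <- names(pools)[li]
    pool <- pools[[li]]
    idx <- reads$locus == locus
    seqs_u <- unique(reads$sequence[idx])
    id_map <- setNames(pool$allele_id, pool$sequence)
    novel <- setdiff(seqs_u, names(id_map))
    if (length(novel))
      id_map[novel] <- sprintf("%s.v%04d", locus, seq_along(novel))
    reads$variant_id[idx] <- unname(id_map[reads$sequence[idx]])
    variants[[li]] <- data.frame(variant_id = unname(id_map[seqs_u]),
                                 locus = locus, sequence = seqs_u,
                                 stringsAsFactors = FALSE)
  }
  vmap <- do.call(rbind, variants)
  seq2id <- setNames(vmap$variant_id, paste(vmap$locus, vmap$sequence))
  led_locus <- reads$locus[match(ledger$amplicon_id, reads$amplicon_id)]
  ledger$variant_id <- unname(seq2id[paste(led_locus, ledger$sequence)])
  ledger <- ledger[, c("amplicon_id", "variant_id", "origin", "parent")]
  reads <- reads[, c("amplicon_id", "individual", "locus", "run", "replicate",
                     "variant_id", "count")]
  structure(list(reads = reads, variants = vmap, ledger = ledger),
            class = "amplicon_set")
}

#' @export
print.amplicon_set <- function(x, ...) {
  cat("<amplicon_set>", length(unique(x$reads$amplicon_id)), "amplicons,",
      nrow(x$variants), "variants,",
      sum(x$reads$count), "reads\n")
  invisible(x)
}

#' @export
print.allele_pool <- function(x, ...) {
  cat("<allele_pool>", attr(x, "locus_id"), ":", nrow(x), "alleles,",
      sum(x$has_insertion), "with +6bp insertion\n")
  invisible(x)
}
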