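# Allele sorting: MPAF/RPAF indices, artifact/contaminant classification,
# locus copy-number assessment, minimum sequencing depth, replicate
# resolution and genotype calling.

#' Classification and genotyping thresholds
#'
#' @param mpaf_flag MPAF below which a variant is never promoted to a true
#'   allele (descriptive flag, default 0.05; suspects are resolved by
#'   replicates, never auto-dropped).
#' @param rpaf_susp Within-amplicon frequency below which a globally frequent
#'   variant is suspected to be a carryover contaminant (default 0.10).
#' @param d_max Maximum edit distance to a parental sequence for point-error
#'   attribution (default 2).
#' @param depth_min Minimum read depth for a reliable genotype (default 18,
#'   the 0.95-confidence threshold of the multinomial depth model for a
#'   two-allele genotype).
#' @param rpaf_contam_evidence RPAF the same sequence must reach in some other
#'   amplicon for the carryover interpretation (default 0.25).
#' @param drop_ratio_threshold Rank-2/rank-3 mean frequency ratio above which
#'   the rank profile is called single-locus (default 3).
#' @param homopolymer_min_run Minimum homopolymer run length (default 3).
#' @return An object of class `ampsort_config`.
#' @export
ampsort_config <- function(mpaf_flag = 0.05, rpaf_susp = 0.10, d_max = 2L,
                           depth_min = 18L, rpaf_contam_evidence = 0.25,
                           drop_ratio_threshold = 3,
                           homopolymer_min_run = 3L) {
  stopifnot(mpaf_flag >= 0, mpaf_flag <= 1, rpaf_susp >= 0, rpaf_susp <= 1,
            d_max >= 0, depth_min >= 1)
  structure(list(mpaf_flag = mpaf_flag, rpaf_susp = rpaf_susp,
                 d_max = as.integer(d_max), depth_min = as.integer(depth_min),
                 rpaf_contam_evidence = rpaf_contam_evidence,
                 drop_ratio_threshold = drop_ratio_threshold,
                 homopolymer_min_run = as.integer(homopolymer_min_run)),
            class = "ampsort_config")
}

#' Relative per-amplicon frequencies (RPAF)
#'
#' The proportion of reads retrieved for each variant within one amplicon.
#'
#' @param counts Named vector of positive read counts (one entry per variant).
#' @return Named numeric vector summing to 1.
#' @export
compute_rpaf <- function(counts) {
  if (!length(counts)) stop("empty read set")
  if (any(counts < 0)) stop("read counts must be non-negative")
  tot <- sum(counts)
  if (tot == 0) stop("zero total reads in amplicon")
  counts / tot
}

.reads_frame <- function(x) {
  if (inherits(x, "amplicon_set")) x$reads
  else if (is.data.frame(x)) x
  else stop("expected an amplicon_set or a reads data frame")
}

#' Per-variant MPAF statistics across a cohort of amplicons
#'
#' For each distinct variant of one locus, computes its MPAF (the unweighted
#' mean of its within-amplicon frequencies over the amplicons possessing it)
#' and the number of amplicons possessing it.
#'
#' @param x An `amplicon_set` or a reads data frame with columns
#'   `amplicon_id`, `locus`, `variant_id`, `count`.
#' @param locus Locus to summarise; mandatory when `x` spans several loci.
#' @return A `variant_stats` data frame (`variant_id`, `sequence`, `mpaf`,
#'   `n_amplicons`) sorted by `variant_id`, with the long per-amplicon RPAF
#'   table in attribute `"rpaf"`.
#' @export
compute_variant_stats <- function(x, locus = NULL) {
  reads <- .reads_frame(x)
  loci <- unique(reads$locus)
  if (is.null(locus)) {
    if (length(loci) > 1L)
      stop("read sets span multiple loci; supply `locus`")
    locus <- loci
  }
  reads <- reads[reads$locus == locus, , drop = FALSE]
  if (!nrow(reads)) stop("no reads for locus ", locus)
  if (anyDuplicated(paste(reads$amplicon_id, reads$variant_id)))
    stop("duplicated variant within an amplicon")
  tot <- ave(reads$count, reads$amplicon_id, FUN = sum)
  if (any(tot == 0)) stop("zero total reads in amplicon")
  rpaf <- reads$count / tot
  f <- factor(reads$variant_id)
  stats <- data.frame(
    variant_id = levels(f),
    mpaf = as.numeric(tapply(rpaf, f, mean)),
    n_amplicons = as.integer(tapply(rpaf, f, length)),
    stringsAsFactors = FALSE)
  if (inherits(x, "amplicon_set")) {
    stats$sequence <- x$variants$sequence[
      match(stats$variant_id, x$variants$variant_id)]
  } else stats$sequence <- NA_character_
  stats <- stats[order(stats$variant_id),
                 c("variant_id", "sequence", "mpaf", "n_amplicons")]
  rownames(stats) <- NULL
  attr(stats, "rpaf") <- data.frame(amplicon_id = reads$amplicon_id,
                                    variant_id = reads$variant_id,
                                    rpaf = rpaf, stringsAsFactors = FALSE)
  attr(stats, "locus") <- locus
  class(stats) <- c("variant_stats", "data.frame")
  stats
}

#' Rank-frequency profile and locus copy-number verdict
#'
#' Averages, across amplicons, the within-amplicon frequency of the most
#' common through `k_max`-th most common variant. Amplicons with fewer than
#' `r` variants contribute 0 at rank `r`, keeping the means comparable. A
#' pronounced drop between ranks 2 and 3 indicates a single (non-duplicated)
#' locus: at most two true alleles per amplicon.
#'
#' @param x An `amplicon_set` or reads data frame.
#' @param k_max Number of ranks to profile (>= 3).
#' @param locus Locus, when `x` spans several.
#' @param config An [ampsort_config()] (supplies the drop-ratio threshold).
#' @return A `rank_profile` list: `profile` data frame (`rank`, `mean_rpaf`,
#'   `mean_mpaf`), `drop_ratio` (rank-2 over rank-3 mean RPAF; `Inf` when
#'   rank 3 is empty) and `verdict` (`"single-locus"` or `"ambiguous"`).
#' @export
rank_frequency_profile <- function(x, k_max = 6L, locus = NULL,
                                   config = ampsort_config()) {
  if (k_max < 3L) stop("k_max must be >= 3")
  stats <- compute_variant_stats(x, locus)
  rp <- attr(stats, "rpaf")
  if (!nrow(rp)) stop("empty input")
  mpaf_of <- setNames(stats$mpaf, stats$variant_id)
  amps <- unique(rp$amplicon_id)
  m_rpaf <- matrix(0, length(amps), k_max)
  m_mpaf <- matrix(0, length(amps), k_max)
  for (i in seq_along(amps)) {
    sub <- rp[rp$amplicon_id == amps[i], , drop = FALSE]
    o <- order(-sub$rpaf, sub$variant_id)        # ties broken lexically
    kk <- min(k_max, nrow(sub))
    m_rpaf[i, seq_len(kk)] <- sub$rpaf[o][seq_len(kk)]
    m_mpaf[i, seq_len(kk)] <- mpaf_of[sub$variant_id[o][seq_len(kk)]]
  }
  prof <- data.frame(rank = seq_len(k_max),
                     mean_rpaf = colMeans(m_rpaf),
                     mean_mpaf = colMeans(m_mpaf))
  drop_ratio <- if (prof$mean_rpaf[3L] == 0) Inf
                else prof$mean_rpaf[2L] / prof$mean_rpaf[3L]
  verdict <- if (drop_ratio >= config$drop_ratio_threshold) "single-locus"
             else "ambiguous"
  structure(list(profile = prof, drop_ratio = drop_ratio, verdict = verdict),
            class = "rank_profile")
}

#' Detect a single-breakpoint chimera of two parental sequences
#'
#' Tests whether `candidate` equals a prefix of one parent joined to the
#' suffix of the other at a single breakpoint (gap-free alignment). A
#' candidate identical to either parent is not a chimera.
#'
#' @param candidate,parent_a,parent_b Nucleotide strings; parents distinct.
#' @return The smallest breakpoint index `i` (candidate = first `i` bases of
#'   one parent + remainder of the other), with attribute `orientation`
#'   (`"ab"` or `"ba"`); `NA` if no composition works.
#' @export
detect_chimera <- function(candidate, parent_a, parent_b) {
  if (parent_a == parent_b) stop("parents must be distinct")
  if (candidate == parent_a || candidate == parent_b) return(NA_integer_)
  bp_of <- function(a, b) {
    # candidate = a[1..i] + b[(i+1)..]; requires equal lengths
    if (nchar(candidate) != nchar(a) || nchar(candidate) != nchar(b))
      return(NA_integer_)
    ca <- strsplit(candidate, "", fixed = TRUE)[[1]]
    va <- strsplit(a, "", fixed = TRUE)[[1]]
    vb <- strsplit(b, "", fixed = TRUE)[[1]]
    L <- length(ca)
    pre <- cumprod(ca == va) == 1              # prefix match with a
    sufr <- rev(cumprod(rev(ca == vb)) == 1)   # suffix match with b
    ok <- which(pre[seq_len(L - 1L)] & sufr[2:L])
    if (length(ok)) ok[1L] else NA_integer_
  }
  i_ab <- bp_of(parent_a, parent_b)
  i_ba <- bp_of(parent_b, parent_a)
  if (is.na(i_ab) && is.na(i_ba)) return(NA_integer_)
  if (is.na(i_ba) || (!is.na(i_ab) && i_ab <= i_ba))
    structure(i_ab, orientation = "ab")
  else structure(i_ba, orientation = "ba")
}

# is `cand` the parent with one base inserted into / deleted from a
# homopolymer run of length >= min_run?
.is_homopolymer_indel <- function(cand, parent, min_run) {
  if (abs(nchar(cand) - nchar(parent)) != 1L) return(FALSE)
  runs <- .homopolymer_runs(parent, min_run)
  if (!nrow(runs)) return(FALSE)
  for (i in seq_len(nrow(runs))) {
    s <- runs$start[i]
    del <- paste0(substr(parent, 1L, s - 1L), substring(parent, s + 1L))
    ins <- paste0(substr(parent, 1L, s), runs$base[i], substring(parent, s + 1L))
    if (cand == del || cand == ins) return(TRUE)
  }
  FALSE
}

# artifact attribution of `cand` to a single parent (steps 2a-2b of the
# cascade); returns NULL or list(label, parent)
.artifact_vs_parent <- function(cand, parent_seq, parent_id, config) {
  if (.is_homopolymer_indel(cand, parent_seq, config$homopolymer_min_run))
    return(list(label = "ARTIFACT_HOMOPOLYMER", parent = parent_id))
  if (utils::adist(cand, parent_seq) <= config$d_max)
    return(list(label = "ARTIFACT_POINT", parent = parent_id))
  NULL
}

#' Classify every variant in every amplicon
#'
#' Deterministic cascade evaluated per amplicon, using both within-amplicon
#' (RPAF) and across-amplicon (MPAF) evidence rather than a global frequency
#' cut-off: (1) the two most abundant variants are provisional parentals
#' (ties broken by variant id); a second parental that is itself a 1-2-edit or
#' homopolymer derivative of the first is demoted to an artifact (the amplicon
#' is then treated as homozygous); (2) a non-parental variant that is a small
#' edit of a parental, a homopolymer indel of it, or a single-breakpoint
#' chimera of the two parentals receives the matching `ARTIFACT_*` label with
#' parental attribution; (3) a remaining variant with high MPAF but low RPAF
#' here, while the same sequence reaches high RPAF in another amplicon, is a
#' `CONTAMINANT_SUSPECT` (carryover signature); (4) remaining variants with
#' MPAF >= `mpaf_flag` and adequate RPAF are `TRUE_ALLELE`; (5) anything else
#' is `UNRESOLVED`.
#'
#' @param x An `amplicon_set` (sequences are required).
#' @param stats Optional precomputed [compute_variant_stats()] for the locus
#'   (or a list keyed by locus); computed when missing.
#' @param config An [ampsort_config()].
#' @return A `classification` data frame: `amplicon_id`, `locus`,
#'   `variant_id`, `label`, `parent`, `breakpoint`, `rpaf`, `mpaf`.
#' @export
classify_variants <- function(x, stats = NULL, config = ampsort_config()) {
  stopifnot(inherits(x, "amplicon_set"))
  out <- lapply(unique(x$reads$locus), function(locus) {
    st <- if (is.null(stats)) compute_variant_stats(x, locus)
          else if (inherits(stats, "variant_stats")) stats
          else stats[[locus]]
    .classify_locus(x, locus, st, config)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("classification", "data.frame")
  res
}

.classify_locus <- function(x, locus, stats, config) {
  reads <- x$reads[x$reads$locus == locus, , drop = FALSE]
  rp <- attr(stats, "rpaf")
  if (is.null(rp)) stop("stats must carry the per-amplicon RPAF table")
  miss <- setdiff(unique(reads$variant_id), stats$variant_id)
  if (length(miss)) stop("missing global stats for variant(s): ",
                         paste(miss, collapse = ", "))
  seq_of <- setNames(x$variants$sequence[x$variants$locus == locus],
                     x$variants$variant_id[x$variants$locus == locus])
  mpaf_of <- setNames(stats$mpaf, stats$variant_id)

  # per-variant top and second RPAF across amplicons, for "high RPAF
  # elsewhere" evidence with the focal amplicon excluded
  o <- order(rp$variant_id, -rp$rpaf)
  rs <- rp[o, ]
  first <- !duplicated(rs$variant_id)
  top1 <- rs[first, ]
  rs2 <- rs[!first, ]
  second <- rs2[!duplicated(rs2$variant_id), ]
  top1_rpaf <- setNames(top1$rpaf, top1$variant_id)
  top1_amp <- setNames(top1$amplicon_id, top1$variant_id)
  top2_rpaf <- setNames(second$rpaf, second$variant_id)

  res <- vector("list", length(unique(reads$amplicon_id)))
  amps <- unique(reads$amplicon_id)
  for (ai in seq_along(amps)) {
    amp <- amps[ai]
    sub <- reads[reads$amplicon_id == amp, , drop = FALSE]
    ord <- order(-sub$count, sub$variant_id)
    vids <- sub$variant_id[ord]
    rpafs <- sub$count[ord] / sum(sub$count)
    lab <- setNames(rep(NA_character_, length(vids)), vids)
    parent <- setNames(rep(NA_character_, length(vids)), vids)
    bp <- setNames(rep(NA_integer_, length(vids)), vids)

    parentals <- vids[seq_len(min(2L, length(vids)))]
    if (length(parentals) == 2L) {
      hit <- .artifact_vs_parent(seq_of[[parentals[2L]]],
                                 seq_of[[parentals[1L]]], parentals[1L], config)
      if (!is.null(hit)) {
        lab[parentals[2L]] <- hit$label
        parent[parentals[2L]] <- hit$parent
        parentals <- parentals[1L]
      }
    }

    for (v in vids) {
      if (!is.na(lab[v])) next
      if (!(v %in% parentals)) {
        hit <- NULL
        for (p in parentals) {
          hit <- .artifact_vs_parent(seq_of[[v]], seq_of[[p]], p, config)
          if (!is.null(hit)) break
        }
        if (is.null(hit) && length(parentals) == 2L) {
          b <- detect_chimera(seq_of[[v]], seq_of[[parentals[1L]]],
                              seq_of[[parentals[2L]]])
          if (!is.na(b)) {
            hit <- list(label = "ARTIFACT_CHIMERA",
                        parent = paste(parentals, collapse = "+"))
            bp[v] <- as.integer(b)
          }
        }
        if (!is.null(hit)) {
          lab[v] <- hit$label; parent[v] <- hit$parent
          next
        }
      }
      rpaf_v <- rpafs[match(v, vids)]
      elsewhere <- if (identical(unname(top1_amp[v]), amp))
        top2_rpaf[v] else top1_rpaf[v]
      elsewhere <- if (is.na(elsewhere)) 0 else unname(elsewhere)
      if (mpaf_of[v] >= config$mpaf_flag && rpaf_v < config$rpaf_susp &&
          elsewhere >= config$rpaf_contam_evidence) {
        lab[v] <- "CONTAMINANT_SUSPECT"
      } else if (mpaf_of[v] >= config$mpaf_flag && rpaf_v >= config$rpaf_susp) {
        lab[v] <- "TRUE_ALLELE"
      } else {
        lab[v] <- "UNRESOLVED"
      }
    }
    res[[ai]] <- data.frame(amplicon_id = amp, locus = locus,
                            variant_id = vids, label = unname(lab),
                            parent = unname(parent), breakpoint = unname(bp),
                            rpaf = unname(rpafs),
                            mpaf = unname(mpaf_of[vids]),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Variant ids validated as true alleles anywhere in a classification
#' @param classification A `classification` data frame.
#' @return Character vector of variant ids.
#' @export
validated_variants <- function(classification) {
  sort(unique(classification$variant_id[
    classification$label == "TRUE_ALLELE"]))
}

#' Resolve a genotype from replicated amplicons
#'
#' The validated genotype is the intersection of the replicates' true-allele
#' sets. A contaminant suspect that reappears as a true allele in another
#' replicate is promoted; a suspect absent from the other replicate is
#' demoted to a contaminant and dropped. More than two alleles persisting
#' across replicates excludes the amplicon; an empty intersection leaves it
#' unresolved (never silently averaged).
#'
#' @param reps List (length >= 2) of per-replicate calls, each a list with
#'   character vectors `true` and `suspect`.
#' @return List with `alleles`, `status` (`OK`, `EXCLUDED` or `UNRESOLVED`),
#'   `dropped` (demoted suspects) and `reason`.
#' @export
resolve_with_replicates <- function(reps) {
  if (length(reps) < 2L) stop("need >= 2 replicates")
  resolved <- lapply(seq_along(reps), function(i) {
    others_true <- unique(unlist(lapply(reps[-i], `[[`, "true")))
    union(reps[[i]]$true, intersect(reps[[i]]$suspect, others_true))
  })
  inter <- Reduce(intersect, resolved)
  all_suspects <- unique(unlist(lapply(reps, `[[`, "suspect")))
  dropped <- setdiff(all_suspects, inter)
  if (length(inter) == 0L)
    return(list(alleles = character(0), status = "UNRESOLVED",
                dropped = dropped, reason = "replicates disagree"))
  if (length(inter) > 2L)
    return(list(alleles = sort(inter), status = "EXCLUDED", dropped = dropped,
                reason = "more than two alleles persist across replicates"))
  list(alleles = sort(inter), status = "OK", dropped = dropped, reason = NA_character_)
}

#' Minimum sequencing depth for confident genotyping
#'
#' Smallest total read count `T` such that, when `T` reads fall on
#' `n_alleles` equifrequent true alleles plus an artifact class of mass
#' `artifact_rate` (multinomial model), every true allele receives at least
#' `min_copies` reads with probability at least `confidence`. The tail is
#' computed exactly by sequential-binomial dynamic programming.
#'
#' @param n_alleles Number of true alleles (>= 1).
#' @param min_copies Reads required per true allele.
#' @param confidence Required coverage probability in (0, 1).
#' @param artifact_rate Multinomial mass captured by artifacts, in `[0, 1)`.
#' @param t_max Search cap.
#' @return Integer depth threshold.
#' @export
min_reads_for_confidence <- function(n_alleles, min_copies, confidence,
                                     artifact_rate = 0, t_max = 10000L) {
  stopifnot(n_alleles >= 1, min_copies >= 0,
            confidence > 0, confidence < 1,
            artifact_rate >= 0, artifact_rate < 1)
  p <- rep((1 - artifact_rate) / n_alleles, n_alleles)
  for (T in max(1L, n_alleles * min_copies):t_max) {
    if (.prob_all_at_least(T, p, min_copies) >= confidence) return(T)
  }
  stop("no depth below t_max reaches the requested confidence")
}

# P(all of the n category counts >= m) for a multinomial(T, p) with an
# implicit remainder category of mass 1 - sum(p)
.prob_all_at_least <- function(T, p, m) {
  f <- c(1, rep(0, T))                        # f[t+1] = P(first j cats use t reads, all >= m)
  mass_left <- 1
  for (j in seq_along(p)) {
    pj <- p[j] / mass_left
    g <- rep(0, T + 1L)
    for (t in 0:T) {
      if (f[t + 1L] == 0) next
      rem <- T - t
      if (rem < m) next
      xs <- m:rem
      g[t + xs + 1L] <- g[t + xs + 1L] + f[t + 1L] * dbinom(xs, rem, pj)
    }
    f <- g
    mass_left <- mass_left - p[j]
  }
  sum(f)
}

#' Call genotypes across a classified cohort
#'
#' Applies the depth threshold, resolves replicated amplicons, and emits one
#' genotype per individual x locus with a QC status. Amplicons below the
#' depth threshold are used only when no adequate replicate exists (status
#' `LOW_DEPTH`). Unreplicated amplicons with contaminant suspects are called
#' from their true alleles but flagged `NEEDS_REPLICATE`.
#'
#' @param x An `amplicon_set`.
#' @param config An [ampsort_config()].
#' @param classification Optional precomputed [classify_variants()] result.
#' @return A `genotype_calls` list: `genotypes` (data frame `individual`,
#'   `locus`, `allele1`, `allele2`, `status`, `reason`; homozygotes duplicate
#'   the allele) and `qc` (status counts and classification label counts).
#' @export
call_genotypes <- function(x, config = ampsort_config(),
                           classification = NULL) {
  stopifnot(inherits(x, "amplicon_set"))
  if (is.null(classification)) classification <- classify_variants(x, config = config)
  reads <- x$reads
  depth <- tapply(reads$count, reads$amplicon_id, sum)
  amp_info <- unique(reads[, c("amplicon_id", "individual", "locus")])
  keys <- unique(amp_info[, c("individual", "locus")])

  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    ind <- keys$individual[i]; locus <- keys$locus[i]
    amps <- amp_info$amplicon_id[amp_info$individual == ind &
                                 amp_info$locus == locus]
    ok_depth <- amps[depth[amps] >= config$depth_min]
    use <- if (length(ok_depth)) ok_depth else amps
    calls <- lapply(use, function(a) {
      cl <- classification[classification$amplicon_id == a, , drop = FALSE]
      list(true = cl$variant_id[cl$label == "TRUE_ALLELE"],
           suspect = cl$variant_id[cl$label == "CONTAMINANT_SUSPECT"])
    })
    if (!length(ok_depth)) {
      status <- "LOW_DEPTH"; reason <- "all replicates below depth threshold"
      alleles <- sort(unique(unlist(lapply(calls, `[[`, "true"))))
      if (length(alleles) > 2L) alleles <- character(0)
    } else if (length(use) == 1L) {
      tr <- calls[[1L]]$true
      if (length(tr) == 0L) {
        status <- "EXCLUDED"; reason <- "no validated alleles"; alleles <- character(0)
      } else if (length(tr) > 2L) {
        status <- "EXCLUDED"; reason <- "more than two true alleles"
        alleles <- character(0)
      } else {
        alleles <- sort(tr)
        if (length(calls[[1L]]$suspect)) {
          status <- "NEEDS_REPLICATE"; reason <- "unresolved contaminant suspect"
        } else { status <- "OK"; reason <- NA_character_ }
      }
    } else {
      r <- resolve_with_replicates(calls)
      alleles <- r$alleles; status <- r$status; reason <- r$reason
      if (status != "OK") alleles <- character(0)
    }
    a1 <- if (length(alleles)) alleles[1L] else NA_character_
    a2 <- if (length(alleles) == 2L) alleles[2L] else a1
    rows[[i]] <- data.frame(individual = ind, locus = locus,
                            allele1 = a1, allele2 = a2,
                            status = status, reason = reason,
                            stringsAsFactors = FALSE)
  }
  genotypes <- do.call(rbind, rows)
  qc <- list(status_counts = table(genotypes$status),
             label_counts = table(classification$label),
             n_amplicons = length(depth),
             n_low_depth = sum(depth < config$depth_min))
  structure(list(genotypes = genotypes, qc = qc), class = "genotype_calls")
}

#' Exact-genotype recovery against a simulation truth set
#'
#' @param calls A `genotype_calls` object.
#' @param truth A `truth_set`.
#' @return Fraction of individual x locus genotypes recovered exactly
#'   (unordered allele pair; uncalled or excluded genotypes count as misses).
#' @export
genotype_accuracy <- function(calls, truth) {
  g <- calls$genotypes
  t <- truth$genotypes
  m <- merge(t, g, by = c("individual", "locus"),
             suffixes = c(".true", ".call"), all.x = TRUE)
  hit <- !is.na(m$allele1.call) &
    m$allele1.true == m$allele1.call & m$allele2.true == m$allele2.call
  mean(hit)
}

#' Allele-sorting efficiency diagnostics
#'
#' Pearson correlation between each variant's MPAF and the number of
#' amplicons possessing it, computed before and after allele sorting.
#' Artifacts have both low MPAF and low amplicon counts, so the correlation
#' is expected to be positive before sorting and to shrink once artifacts
#' are discarded.
#'
#' @param stats_before,stats_after `variant_stats` data frames (the latter
#'   typically restricted to validated variants).
#' @return A `sorting_diagnostics` list with elements `before` and `after`,
#'   each `(r, p, n, undefined)`; `undefined` flags a zero-variance input.
#' @export
sorting_diagnostics <- function(stats_before, stats_after) {
  one <- function(st) {
    n <- nrow(st)
    if (n < 3L) stop("need >= 3 variants")
    if (sd(st$mpaf) == 0 || sd(st$n_amplicons) == 0)
      return(list(r = NA_real_, p = NA_real_, n = n, undefined = TRUE))
    ct <- cor.test(st$mpaf, st$n_amplicons)
    list(r = unname(ct$estimate), p = ct$p.value, n = n, undefined = FALSE)
  }
  structure(list(before = one(stats_before), after = one(stats_after)),
            class = "sorting_diagnostics")
}

#' Bookkeeping of an allele-sorting campaign
#'
#' Arithmetic of the sorting tallies for one locus: starting from the total
#' number of unique sequences, removes the low-MPAF fraction and the
#' high-MPAF sequences identified as artifacts or contaminants, and reports
#' retained/eliminated counts and percentages.
#'
#' @param total Unique sequences retrieved.
#' @param low_mpaf Sequences below the MPAF flag, all eliminated.
#' @param artifacts_high,contaminants_high High-MPAF sequences eliminated as
#'   artifacts resp. contaminants.
#' @return List with `retained`, `eliminated`, `high_mpaf`, `pct_low_mpaf`,
#'   `pct_eliminated`.
#' @export
sorting_tally <- function(total, low_mpaf, artifacts_high, contaminants_high) {
  stopifnot(total >= low_mpaf + artifacts_high + contaminants_high)
  retained <- total - low_mpaf - artifacts_high - contaminants_high
  list(retained = retained,
       eliminated = total - retained,
       high_mpaf = total - low_mpaf,
       pct_low_mpaf = 100 * low_mpaf / total,
       pct_eliminated = 100 * (total - retained) / total)
}
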