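# Codon-level selection analysis: Nei-Gojobori (1986) pathway counting with
# Jukes-Cantor correction, codon-based Z-tests on site partitions (antigen
# binding sites, positively selected sites), variable-site counts and mean
# pairwise divergence.

.genetic_code <- function() {
  if (is.null(.mhc_cache$gc)) .mhc_cache$gc <- Biostrings::GENETIC_CODE
  .mhc_cache$gc
}

.is_stop <- function(codon) .genetic_code()[[codon]] == "*"

.aa_of <- function(codon) .genetic_code()[[codon]]

#' In-frame codon alignment container
#'
#' @param sequences Named character vector of aligned nucleotide sequences
#'   (equal lengths, multiple of 3; `-` marks alignment gaps, e.g. the 6-bp
#'   insertion region in non-carrier alleles). Gap-free sequences must be
#'   free of internal stop codons.
#' @return A `codon_alignment` list: `seqs`, `n_codons`.
#' @export
codon_alignment <- function(sequences) {
  if (!length(sequences)) stop("empty alignment")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must have unique names")
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("aligned sequences must have equal length")
  if (L %% 3L != 0L) stop("alignment length must be divisible by 3")
  gc <- .genetic_code()
  for (id in names(sequences)) {
    s <- sequences[[id]]
    if (grepl("-", s, fixed = TRUE)) next
    cods <- substring(s, seq(1L, L, 3L), seq(3L, L, 3L))
    if (any(gc[cods] == "*"))
      stop("internal stop codon in sequence ", id)
  }
  structure(list(seqs = sequences, n_codons = L / 3L),
            class = "codon_alignment")
}

#' Site partitions over codon positions
#'
#' Builds the complementary partitions used for selection tests: antigen
#' binding sites (ABS) vs non-ABS, and (optionally) positively selected
#' sites (PSS) vs non-PSS, plus `All`. PSS positions are consumed as a
#' user-supplied mask (e.g. from a Bayes Empirical Bayes analysis run
#' elsewhere); they are inputs here, not inferences.
#'
#' @param n_codons Total codons in the alignment (1-based indices).
#' @param abs_sites Integer codon indices of the ABS.
#' @param pss_sites Optional integer codon indices of the PSS.
#' @return A `site_mask` named list of index vectors.
#' @export
site_mask <- function(n_codons, abs_sites, pss_sites = NULL) {
  chk <- function(x) {
    x <- sort(unique(as.integer(x)))
    if (length(x) && (min(x) < 1L || max(x) > n_codons))
      stop("site indices must lie in 1..n_codons")
    x
  }
  abs_sites <- chk(abs_sites)
  m <- list(All = seq_len(n_codons), ABS = abs_sites,
            nonABS = setdiff(seq_len(n_codons), abs_sites))
  if (!is.null(pss_sites)) {
    pss_sites <- chk(pss_sites)
    m$PSS <- pss_sites
    m$nonPSS <- setdiff(seq_len(n_codons), pss_sites)
  }
  structure(m, n_codons = n_codons, class = "site_mask")
}

#' Nei-Gojobori synonymous and nonsynonymous site counts of a codon
#'
#' Each of the three positions contributes the fraction of its three possible
#' single-base changes that are synonymous (resp. nonsynonymous); changes to
#' termination codons are excluded from the counts, so the site totals are
#' `3` minus the stop-adjusted mass.
#'
#' @param codon A sense codon (universal code).
#' @return Numeric vector `c(syn = , nonsyn = )`.
#' @export
ng86_sites <- function(codon) {
  codon <- toupper(codon)
  if (is.null(.mhc_cache$sites)) .mhc_cache$sites <- list()
  hit <- .mhc_cache$sites[[codon]]
  if (!is.null(hit)) return(hit)
  gc <- .genetic_code()
  if (!codon %in% names(gc) || gc[[codon]] == "*" ||
      grepl("[^ACGT]", codon))
    stop("not a sense codon: ", codon)
  bases <- c("A", "C", "G", "T")
  aa0 <- gc[[codon]]
  s <- n <- 0
  ch <- strsplit(codon, "")[[1]]
  for (pos in 1:3) for (b in setdiff(bases, ch[pos])) {
    mut <- ch; mut[pos] <- b
    aa <- gc[[paste(mut, collapse = "")]]
    if (aa == "*") next
    if (aa == aa0) s <- s + 1 / 3 else n <- n + 1 / 3
  }
  out <- c(syn = s, nonsyn = n)
  .mhc_cache$sites[[codon]] <- out
  out
}

# all orders in which the differing positions can be substituted
.perm_list <- list(
  `1` = list(1L),
  `2` = list(c(1L, 2L), c(2L, 1L)),
  `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
             c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

# synonymous/nonsynonymous differences between two sense codons, averaged
# with equal weight over all evolutionary pathways that avoid stop codons;
# returns c(sd, nd) or NULL when every pathway is blocked
.ng86_codon_pair <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  key <- paste0(c1, c2)
  if (is.null(.mhc_cache$pairs)) .mhc_cache$pairs <- list()
  hit <- .mhc_cache$pairs[[key]]
  if (!is.null(hit)) return(if (is.logical(hit)) NULL else hit)
  gc <- .genetic_code()
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  diffs <- which(a != b)
  d <- length(diffs)
  tot_s <- tot_n <- 0; n_path <- 0L
  for (ord in .perm_list[[d]]) {
    cur <- a; s <- n <- 0; ok <- TRUE
    for (k in ord) {
      pos <- diffs[k]
      nxt <- cur; nxt[pos] <- b[pos]
      aa_cur <- gc[[paste(cur, collapse = "")]]
      aa_nxt <- gc[[paste(nxt, collapse = "")]]
      if (aa_nxt == "*") { ok <- FALSE; break }
      if (aa_cur == aa_nxt) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (ok) { tot_s <- tot_s + s; tot_n <- tot_n + n; n_path <- n_path + 1L }
  }
  out <- if (n_path == 0L) NULL
         else c(sd = tot_s / n_path, nd = tot_n / n_path)
  .mhc_cache$pairs[[key]] <- if (is.null(out)) TRUE else out
  out
}

#' Nei-Gojobori pathway counts for a pair of sequences
#'
#' Averaged site counts (`S`, `N`) of the two sequences and pathway-averaged
#' synonymous/nonsynonymous differences (`sd`, `nd`), treating all stop-free
#' substitution pathways through each differing codon as equally probable.
#' Codons whose pathways all pass through stops are excluded and flagged.
#'
#' @param seqA,seqB Equal-length, in-frame, gap-free nucleotide strings.
#' @return List `(S, N, sd, nd, pS, pN, excluded_codons)`.
#' @export
ng86_pair <- function(seqA, seqB) {
  seqA <- toupper(seqA); seqB <- toupper(seqB)
  if (nchar(seqA) != nchar(seqB)) stop("sequences must have equal length")
  if (nchar(seqA) %% 3L != 0L) stop("length must be divisible by 3")
  starts <- seq(1L, nchar(seqA), 3L)
  ca <- substring(seqA, starts, starts + 2L)
  cb <- substring(seqB, starts, starts + 2L)
  S <- N <- sd_ <- nd_ <- 0
  excluded <- integer(0)
  for (i in seq_along(ca)) {
    d <- .ng86_codon_pair(ca[i], cb[i])
    if (is.null(d)) { excluded <- c(excluded, i); next }
    sa <- ng86_sites(ca[i]); sb <- ng86_sites(cb[i])
    S <- S + (sa["syn"] + sb["syn"]) / 2
    N <- N + (sa["nonsyn"] + sb["nonsyn"]) / 2
    sd_ <- sd_ + d["sd"]; nd_ <- nd_ + d["nd"]
  }
  list(S = unname(S), N = unname(N), sd = unname(sd_), nd = unname(nd_),
       pS = unname(if (S > 0) sd_ / S else NA_real_),
       pN = unname(if (N > 0) nd_ / N else NA_real_),
       excluded_codons = excluded)
}

#' Jukes-Cantor multiple-hit correction
#'
#' `d = -(3/4) log(1 - 4p/3)`, defined for `p < 3/4`; saturated proportions
#' return `NA` with a warning.
#'
#' @param p Proportion(s) of differing sites.
#' @return Corrected distance(s), `d >= p` with equality iff `p = 0`.
#' @export
jukes_cantor <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p >= 0 & p < 0.75
  out[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  if (any(!is.na(p) & p >= 0.75))
    warning("saturated proportion(s) p >= 3/4; returning NA")
  out
}

# split aligned sequences into a codon matrix (codons x sequences) and apply
# complete deletion of codon columns containing gaps or ambiguity
.codon_matrix <- function(aln) {
  L <- nchar(aln$seqs[[1L]])
  starts <- seq(1L, L, 3L)
  m <- vapply(aln$seqs, function(s) substring(s, starts, starts + 2L),
              character(length(starts)))
  if (length(starts) == 1L) m <- matrix(m, nrow = 1L,
                                        dimnames = list(NULL, names(aln$seqs)))
  m
}

.complete_deletion <- function(cod_mat) {
  bad <- apply(cod_mat, 1L, function(r) any(grepl("[^ACGT]", r)))
  which(!bad)
}

#' Partitioned dN/dS by the Nei-Gojobori pathway method
#'
#' Mean pairwise dN and dS (Jukes-Cantor corrected proportions of
#' nonsynonymous and synonymous differences per site) over all sequence
#' pairs, restricted to one partition of a [site_mask()]. Codon columns
#' containing alignment gaps are removed alignment-wide (complete deletion)
#' before masking. Standard errors come from a bootstrap over the
#' partition's codon sites.
#'
#' @param aln A [codon_alignment()] with >= 2 sequences.
#' @param mask A [site_mask()] on the alignment's codon coordinates.
#' @param partition Partition name (`"All"`, `"ABS"`, `"nonABS"`, `"PSS"`,
#'   `"nonPSS"`).
#' @param n_boot Bootstrap replicates for the standard errors.
#' @param seed Optional integer seed.
#' @return A `dnds_result` list: `partition`, `n_codons` (codons analysed
#'   after deletion), `n_pairs`, `dN`, `dS`, `se_dN`, `se_dS`, `n_boot`.
#' @export
partition_dnds <- function(aln, mask, partition, n_boot = 1000L,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(aln, "codon_alignment"))
  if (!partition %in% names(mask)) stop("unknown partition: ", partition)
  if (length(aln$seqs) < 2L) stop("need >= 2 sequences")
  cm <- .codon_matrix(aln)
  kept <- .complete_deletion(cm)
  idx <- intersect(mask[[partition]], kept)
  if (length(idx) < 2L) stop("partition has fewer than 2 analysable codons")
  cm <- cm[idx, , drop = FALSE]
  nseq <- ncol(cm)
  prs <- combn(nseq, 2L)
  npair <- ncol(prs)
  nc <- length(idx)

  # per-sequence per-codon site counts
  Smat <- matrix(0, nc, nseq); Nmat <- matrix(0, nc, nseq)
  for (j in seq_len(nseq)) for (i in seq_len(nc)) {
    st <- ng86_sites(cm[i, j])
    Smat[i, j] <- st["syn"]; Nmat[i, j] <- st["nonsyn"]
  }
  # per-pair per-codon differences and averaged sites
  SD <- ND <- SS <- NN <- matrix(0, npair, nc)
  for (p in seq_len(npair)) {
    a <- prs[1L, p]; b <- prs[2L, p]
    for (i in seq_len(nc)) {
      d <- .ng86_codon_pair(cm[i, a], cm[i, b])
      if (is.null(d)) next                       # blocked codon: excluded
      SD[p, i] <- d["sd"]; ND[p, i] <- d["nd"]
      SS[p, i] <- (Smat[i, a] + Smat[i, b]) / 2
      NN[p, i] <- (Nmat[i, a] + Nmat[i, b]) / 2
    }
  }
  mean_d <- function(cols) {
    pS <- rowSums(SD[, cols, drop = FALSE]) / rowSums(SS[, cols, drop = FALSE])
    pN <- rowSums(ND[, cols, drop = FALSE]) / rowSums(NN[, cols, drop = FALSE])
    c(dS = mean(jukes_cantor(pS), na.rm = TRUE),
      dN = mean(jukes_cantor(pN), na.rm = TRUE))
  }
  est <- suppressWarnings(mean_d(seq_len(nc)))
  boot <- matrix(NA_real_, n_boot, 2L)
  if (n_boot > 0L) {
    for (r in seq_len(n_boot)) {
      cols <- sample.int(nc, nc, replace = TRUE)
      boot[r, ] <- suppressWarnings(mean_d(cols))
    }
  }
  res <- list(partition = partition, n_codons = nc, n_pairs = npair,
              dN = unname(est["dN"]), dS = unname(est["dS"]),
              se_dN = if (n_boot > 0) sd(boot[, 2L], na.rm = TRUE) else NA_real_,
              se_dS = if (n_boot > 0) sd(boot[, 1L], na.rm = TRUE) else NA_real_,
              n_boot = as.integer(n_boot))
  class(res) <- "dnds_result"
  res
}

#' Codon-based Z-test of positive selection
#'
#' `Z = (dN - dS) / sqrt(SE(dN)^2 + SE(dS)^2)` with a normal approximation;
#' the default alternative is positive selection (`dN > dS`, one-tailed), so
#' a negative `Z` gives `p > 0.5`.
#'
#' @param result A `dnds_result` from [partition_dnds()].
#' @param alternative `"greater"` (positive selection) or `"two.sided"`.
#' @return The result with `Z`, `p` and `alternative` added; zero variance
#'   with unequal rates is flagged via `undefined`.
#' @export
z_test_selection <- function(result, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  v <- result$se_dN^2 + result$se_dS^2
  diff <- result$dN - result$dS
  if (!is.finite(v) || v == 0) {
    if (!is.na(diff) && diff == 0) {
      result$Z <- 0; result$p <- if (alternative == "greater") 0.5 else 1
      result$undefined <- FALSE
    } else {
      result$Z <- NA_real_; result$p <- NA_real_; result$undefined <- TRUE
    }
  } else {
    z <- diff / sqrt(v)
    result$Z <- z
    result$p <- if (alternative == "greater") pnorm(z, lower.tail = FALSE)
                else 2 * pnorm(-abs(z))
    result$undefined <- FALSE
  }
  result$alternative <- alternative
  result
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf("%s (%d codons, %d pairs): dN = %.3f +/- %.3f, dS = %.3f +/- %.3f",
              x$partition, x$n_codons, x$n_pairs, x$dN, x$se_dN, x$dS, x$se_dS))
  if (!is.null(x$Z)) cat(sprintf(", Z = %.3f, p = %.4g", x$Z, x$p))
  cat("\n")
  invisible(x)
}

# translate aligned codons; codons containing gaps/ambiguity become "-"
.translate_alignment <- function(aln) {
  cm <- .codon_matrix(aln)
  gc <- .genetic_code()
  apply(cm, 2L, function(col) {
    aa <- ifelse(grepl("[^ACGT]", col), "-", unname(gc[col]))
    paste(aa, collapse = "")
  })
}

.char_matrix <- function(seqs) {
  do.call(cbind, strsplit(unname(seqs), "", fixed = TRUE))
}

#' Count variable sites in an alignment
#'
#' Columns with at least two distinct non-gap states, at the nucleotide or
#' amino-acid level; the proportion is over all columns carrying at least one
#' non-gap state.
#'
#' @param aln A [codon_alignment()].
#' @param level `"nucleotide"` or `"amino_acid"`.
#' @return List `(n_variable, n_sites, proportion)`.
#' @export
variable_sites <- function(aln, level = c("nucleotide", "amino_acid")) {
  level <- match.arg(level)
  seqs <- if (level == "nucleotide") aln$seqs else .translate_alignment(aln)
  m <- .char_matrix(seqs)             # columns = sequences, rows = sites
  states <- apply(m, 1L, function(r) length(unique(r[r != "-"])))
  counted <- states >= 1L
  list(n_variable = sum(states >= 2L), n_sites = sum(counted),
       proportion = sum(states >= 2L) / sum(counted))
}

#' Mean pairwise divergence (number of differences)
#'
#' Raw count-of-differences divergence over all unordered sequence pairs,
#' after complete deletion of gap-containing columns; reported as mean and
#' standard deviation across pairs.
#'
#' @inheritParams variable_sites
#' @return List `(mean, sd, n_pairs, n_sites)`.
#' @export
mean_pairwise_distance <- function(aln, level = c("nucleotide", "amino_acid")) {
  level <- match.arg(level)
  seqs <- if (level == "nucleotide") aln$seqs else .translate_alignment(aln)
  if (length(seqs) < 2L) stop("need >= 2 sequences")
  m <- .char_matrix(seqs)
  keep <- apply(m, 1L, function(r) all(r != "-"))
  m <- m[keep, , drop = FALSE]
  prs <- combn(ncol(m), 2L)
  d <- apply(prs, 2L, function(ij) sum(m[, ij[1L]] != m[, ij[2L]]))
  list(mean = mean(d), sd = if (length(d) > 1L) sd(d) else 0,
       n_pairs = length(d), n_sites = nrow(m))
}
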