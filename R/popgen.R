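# Population-genetic statistics on validated genotype tables: allele
# frequencies, heterozygosity, exact HWE U-score test (heterozygote-excess
# alternative), EM null-allele frequency, two-locus LD likelihood-ratio test
# on unphased genotypes, and pairwise Weir-Cockerham FST with permutation
# p-values.

# complete genotypes for one locus (optionally one subpopulation)
.locus_genotypes <- function(table, locus, group = NULL) {
  g <- table[table$locus == locus, , drop = FALSE]
  if (!is.null(group)) g <- g[g$subpop %in% group, , drop = FALSE]
  g <- g[!is.na(g$allele1) & !is.na(g$allele2), , drop = FALSE]
  g
}

#' Allele frequencies at a locus
#'
#' Counts each allele copy (homozygotes contribute two); missing genotypes
#' are ignored.
#'
#' @param table Genotype table: data frame with columns `individual`,
#'   `subpop` (optional grouping), `locus`, `allele1`, `allele2`.
#' @param locus Locus id.
#' @param group Optional subpopulation label(s) to restrict to.
#' @return Named frequency vector summing to 1.
#' @export
allele_frequencies <- function(table, locus, group = NULL) {
  g <- .locus_genotypes(table, locus, group)
  if (!nrow(g)) stop("no typed individuals for locus ", locus,
                     if (!is.null(group)) paste0(" in group ", group))
  tab <- table(c(g$allele1, g$allele2))
  p <- as.numeric(tab) / sum(tab)
  setNames(p, names(tab))
}

# Weir & Cockerham (1984) variance components summed over alleles.
# g: data frame with allele1/allele2; pops: factor of subpopulation labels.
.wc_components <- function(a1, a2, pops) {
  pops <- droplevels(factor(pops))
  r <- nlevels(pops)
  n_i <- as.numeric(table(pops))
  n_bar <- mean(n_i)
  n_tot <- sum(n_i)
  alleles <- sort(unique(c(a1, a2)))
  n_c <- if (r > 1) (n_tot - sum(n_i^2) / n_tot) / (r - 1) else n_bar
  A <- B <- C <- 0
  for (u in alleles) {
    cnt <- (a1 == u) + (a2 == u)
    p_iu <- tapply(cnt, pops, sum) / (2 * n_i)
    h_iu <- tapply(cnt == 1L, pops, sum) / n_i
    p_bar <- sum(n_i * p_iu) / n_tot
    h_bar <- sum(n_i * h_iu) / n_tot
    s2 <- if (r > 1) sum(n_i * (p_iu - p_bar)^2) / ((r - 1) * n_bar) else 0
    b <- n_bar / (n_bar - 1) *
      (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
    cc <- h_bar / 2
    a <- if (r > 1) {
      n_bar / n_c * (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) /
                       (n_bar - 1))
    } else 0
    A <- A + a; B <- B + b; C <- C + cc
  }
  c(a = A, b = B, c = C)
}

#' Observed and expected heterozygosity with Weir-Cockerham Fis
#'
#' `Ho` is the fraction of heterozygous individuals; `He` the unbiased
#' expected heterozygosity `2n/(2n-1) * (1 - sum p^2)`; `Fis` the single-locus
#' Weir-Cockerham within-population estimate `1 - c/(b + c)`.
#'
#' @inheritParams allele_frequencies
#' @return List `(Ho, He, Fis, n)`; at a monomorphic locus `He = 0` and `Fis`
#'   is `NA` (flagged via `undefined = TRUE`).
#' @export
heterozygosity <- function(table, locus, group = NULL) {
  g <- .locus_genotypes(table, locus, group)
  n <- nrow(g)
  if (n < 2L) stop("need >= 2 typed individuals")
  p <- allele_frequencies(table, locus, group)
  ho <- mean(g$allele1 != g$allele2)
  he <- (2 * n) / (2 * n - 1) * (1 - sum(p^2))
  if (length(p) < 2L)
    return(list(Ho = ho, He = 0, Fis = NA_real_, n = n, undefined = TRUE))
  comp <- .wc_components(g$allele1, g$allele2, rep("pop", n))
  fis <- 1 - comp["c"] / (comp["b"] + comp["c"])
  list(Ho = ho, He = he, Fis = unname(fis), n = n, undefined = FALSE)
}

#' Exact U-score test of Hardy-Weinberg equilibrium (heterozygote excess)
#'
#' The score statistic for the heterozygote-excess alternative,
#' `U = n_het - sum_i n_ii (1 - p_i)/p_i`, evaluated against the Levene
#' distribution of genotypic arrays conditional on the observed allele
#' counts, approximated by Monte-Carlo re-pairing of allele copies. The
#' one-sided p-value is the proportion of null arrays (plus the observed one)
#' with `U >= U_obs`, i.e. the `(b + 1)/(m + 1)` estimator.
#'
#' @inheritParams allele_frequencies
#' @param n_mc Number of Monte-Carlo genotypic arrays.
#' @param seed Optional integer seed.
#' @return An `hwe_result` list: `U`, `p`, `n_mc`, `Ho`, `He`, `Fis`, `n`.
#'   A monomorphic locus gives `p = 1` by convention.
#' @export
hwe_u_test <- function(table, locus, group = NULL, n_mc = 10000L,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- .locus_genotypes(table, locus, group)
  n <- nrow(g)
  if (n < 2L) stop("need >= 2 typed individuals")
  het <- heterozygosity(table, locus, group)
  alleles <- sort(unique(c(g$allele1, g$allele2)))
  if (length(alleles) < 2L) {
    res <- list(U = NA_real_, p = 1, n_mc = 0L, Ho = het$Ho, He = het$He,
                Fis = het$Fis, n = n)
    class(res) <- "hwe_result"
    return(res)
  }
  code1 <- match(g$allele1, alleles) - 1L
  code2 <- match(g$allele2, alleles) - 1L
  cnt <- tabulate(c(code1, code2) + 1L, nbins = length(alleles))
  p_i <- cnt / (2 * n)
  w <- (1 - p_i) / p_i
  hom <- tabulate(code1[code1 == code2] + 1L, nbins = length(alleles))
  u_obs <- sum(code1 != code2) - sum(hom * w)
  u_null <- cpp_hwe_null_u(c(code1, code2), w, as.integer(n_mc))
  p <- (sum(u_null >= u_obs - 1e-12) + 1) / (n_mc + 1)
  res <- list(U = u_obs, p = p, n_mc = as.integer(n_mc), Ho = het$Ho,
              He = het$He, Fis = het$Fis, n = n)
  class(res) <- "hwe_result"
  res
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE U-score test (heterozygote excess): U = %.4f, p = %.4g (%d MC arrays)\n",
              x$U, x$p, x$n_mc))
  cat(sprintf("  Ho = %.4f, He = %.4f, Fis(W&C) = %.4f, n = %d\n",
              x$Ho, x$He, x$Fis, x$n))
  invisible(x)
}

#' EM estimate of the null-allele frequency at a locus
#'
#' Maximum-likelihood (EM) estimate of the frequency of a non-amplifying
#' allele, treating observed homozygotes as a mixture of true homozygotes and
#' heterozygotes carrying one null copy, with the unobserved null-null class
#' imputed each iteration.
#'
#' @inheritParams allele_frequencies
#' @param tol Convergence tolerance on the null-frequency change.
#' @param max_iter Iteration cap; non-convergence is flagged, not an error.
#' @return List `(estimate, converged, n_iter, freqs)`.
#' @export
null_allele_em <- function(table, locus, group = NULL, tol = 1e-8,
                           max_iter = 1000L) {
  g <- .locus_genotypes(table, locus, group)
  n <- nrow(g)
  if (n < 2L) stop("need >= 2 typed individuals")
  alleles <- sort(unique(c(g$allele1, g$allele2)))
  hom <- g$allele1 == g$allele2
  H <- table(factor(g$allele1[hom], levels = alleles))        # apparent homs
  het_copies <- table(factor(c(g$allele1[!hom], g$allele2[!hom]),
                             levels = alleles))
  p <- as.numeric(table(factor(c(g$allele1, g$allele2), levels = alleles)))
  p <- p / sum(p)
  r <- 0.05
  conv <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    m <- n * r^2 / (1 - r^2)                  # expected unseen null homs
    w <- p^2 / (p^2 + 2 * p * r)              # P(true hom | apparent hom)
    w[!is.finite(w)] <- 1
    c_i <- as.numeric(het_copies) + as.numeric(H) * (2 * w + (1 - w))
    c_null <- sum(as.numeric(H) * (1 - w)) + 2 * m
    tot <- 2 * (n + m)
    r_new <- c_null / tot
    p <- c_i / tot
    p <- p / sum(p) * (1 - r_new)             # guard tiny numeric drift
    if (abs(r_new - r) < tol) { r <- r_new; conv <- TRUE; break }
    r <- r_new
  }
  list(estimate = r, converged = conv, n_iter = it,
       freqs = setNames(p, alleles))
}

# allele codes and marginal HWE log-likelihood helpers for the LD machinery
.two_locus_codes <- function(table, locusA, locusB) {
  ga <- .locus_genotypes(table, locusA)
  gb <- .locus_genotypes(table, locusB)
  ids <- intersect(ga$individual, gb$individual)     # listwise deletion
  ga <- ga[match(ids, ga$individual), ]
  gb <- gb[match(ids, gb$individual), ]
  aA <- sort(unique(c(ga$allele1, ga$allele2)))
  aB <- sort(unique(c(gb$allele1, gb$allele2)))
  geno <- cbind(match(ga$allele1, aA), match(ga$allele2, aA),
                match(gb$allele1, aB), match(gb$allele2, aB)) - 1L
  list(geno = geno, allelesA = aA, allelesB = aB, n = length(ids))
}

.hwe_marginal_logl <- function(codes1, codes2) {
  k <- max(codes1, codes2) + 1L
  cnt <- tabulate(c(codes1, codes2) + 1L, nbins = k)
  p <- cnt / sum(cnt)
  het <- codes1 != codes2
  sum(log(ifelse(het, 2 * p[codes1 + 1L] * p[codes2 + 1L],
                 p[codes1 + 1L]^2)))
}

#' EM haplotype frequencies for two unphased loci
#'
#' Resolves the phase ambiguity of double heterozygotes by EM under
#' haplotype-level Hardy-Weinberg equilibrium. With no double heterozygotes
#' the estimate equals direct gamete counting.
#'
#' @param table Genotype table (see [allele_frequencies()]).
#' @param locusA,locusB Locus ids; individuals typed at both loci are used.
#' @param tol Absolute log-likelihood convergence tolerance.
#' @param max_iter Iteration cap.
#' @return List: `haplotypes` (frequency matrix, alleles of `locusA` in rows),
#'   `logL`, `trace` (per-iteration log-likelihoods, non-decreasing),
#'   `converged`, `n`.
#' @export
em_haplotype_freqs <- function(table, locusA, locusB, tol = 1e-8,
                               max_iter = 1000L) {
  z <- .two_locus_codes(table, locusA, locusB)
  if (z$n < 1L) stop("no individuals typed at both loci")
  fit <- cpp_em_haplo(z$geno, length(z$allelesA), length(z$allelesB),
                      tol, as.integer(max_iter))
  h <- fit$h
  dimnames(h) <- list(z$allelesA, z$allelesB)
  list(haplotypes = h, logL = fit$logL, trace = fit$trace,
       converged = fit$converged, n = z$n)
}

#' Likelihood-ratio test of linkage disequilibrium between two loci
#'
#' Compares the EM-maximised haplotype likelihood against the null of no
#' gametic association (haplotype frequencies equal to the product of the
#' marginal allele frequencies). Significance is assessed by permuting one
#' locus's genotypes among individuals, which preserves both single-locus
#' arrays. Degrees of freedom are reported as `(kA - 1)(kB - 1)`;
#' bookkeeping for unphased EM LRTs varies across programs, so `df` is
#' nominal and inference should rest on the permutation p-value.
#'
#' @inheritParams em_haplotype_freqs
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return An `ld_result` list: `statistic`, `df`, `p`, `n_perm`,
#'   `haplotypes`, `logL_linked`, `logL_independent`, `n`.
#' @export
ld_lrt <- function(table, locusA, locusB, n_perm = 10000L, seed = NULL,
                   tol = 1e-8, max_iter = 1000L) {
  if (!is.null(seed)) set.seed(seed)
  z <- .two_locus_codes(table, locusA, locusB)
  kA <- length(z$allelesA); kB <- length(z$allelesB)
  if (kA < 2L || kB < 2L) stop("need >= 2 alleles at each locus")
  fit <- cpp_em_haplo(z$geno, kA, kB, tol, as.integer(max_iter))
  logl_indep <- .hwe_marginal_logl(z$geno[, 1L], z$geno[, 2L]) +
    .hwe_marginal_logl(z$geno[, 3L], z$geno[, 4L])
  stat <- max(0, 2 * (fit$logL - logl_indep))
  perm_logl <- cpp_ld_perm_logl(z$geno, kA, kB, as.integer(n_perm),
                                tol, as.integer(max_iter))
  perm_stat <- pmax(0, 2 * (perm_logl - logl_indep))
  p <- (sum(perm_stat >= stat - 1e-9) + 1) / (n_perm + 1)
  h <- fit$h
  dimnames(h) <- list(z$allelesA, z$allelesB)
  res <- list(statistic = stat, df = (kA - 1L) * (kB - 1L), p = p,
              n_perm = as.integer(n_perm), haplotypes = h,
              logL_linked = fit$logL, logL_independent = logl_indep,
              n = z$n)
  class(res) <- "ld_result"
  res
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("LD likelihood-ratio test: LR = %.3f, df = %d, permutation p = %.4g (%d perms, n = %d)\n",
              x$statistic, x$df, x$p, x$n_perm, x$n))
  invisible(x)
}

#' Pairwise FST between subpopulations with permutation p-values
#'
#' Weir-Cockerham theta for every pair of subpopulations at one locus;
#' p-values from permuting subpopulation labels among the pair's individuals
#' (`(b + 1)/(m + 1)` estimator, one-sided for differentiation).
#'
#' @inheritParams allele_frequencies
#' @param n_perm Number of label permutations per pair.
#' @param seed Optional integer seed.
#' @param min_group Smallest usable subpopulation (pairs with a smaller group
#'   are excluded and flagged).
#' @return An `fst_result` list: symmetric `fst` matrix (diagonal 0), `p`
#'   matrix, `excluded` character vector of skipped groups, `n_perm`.
#' @export
pairwise_fst <- function(table, locus, n_perm = 10000L, seed = NULL,
                         min_group = 2L) {
  if (!is.null(seed)) set.seed(seed)
  g <- .locus_genotypes(table, locus)
  sizes <- table(g$subpop)
  pops <- names(sizes)[sizes >= min_group]
  excluded <- setdiff(names(sizes), pops)
  if (length(pops) < 2L) stop("need >= 2 subpopulations with >= ", min_group,
                              " individuals")
  k <- length(pops)
  fst <- matrix(0, k, k, dimnames = list(pops, pops))
  pmat <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  theta_of <- function(a1, a2, lab) {
    comp <- .wc_components(a1, a2, lab)
    if (comp["a"] + comp["b"] + comp["c"] == 0) return(0)
    unname(comp["a"] / (comp["a"] + comp["b"] + comp["c"]))
  }
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    sub <- g[g$subpop %in% c(pops[i], pops[j]), , drop = FALSE]
    th <- theta_of(sub$allele1, sub$allele2, sub$subpop)
    perm <- replicate(n_perm, {
      theta_of(sub$allele1, sub$allele2, sample(sub$subpop))
    })
    pv <- (sum(perm >= th - 1e-12) + 1) / (n_perm + 1)
    fst[i, j] <- fst[j, i] <- th
    pmat[i, j] <- pmat[j, i] <- pv
  }
  res <- list(fst = fst, p = pmat, excluded = excluded,
              n_perm = as.integer(n_perm))
  class(res) <- "fst_result"
  res
}
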