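test_that("allele frequencies count copies and respect groups", {
  tab <- make_table(list(c("A", "A"), c("A", "B")))
  expect_equal(allele_frequencies(tab, "L"), c(A = 0.75, B = 0.25))
  mono <- make_table(list(c("A", "A"), c("A", "A")))
  expect_equal(allele_frequencies(mono, "L"), c(A = 1.0))
  expect_error(allele_frequencies(tab, "L", group = "nope"), "no typed")
  # law of large numbers against the generator truth
  pool <- generate_allele_pool("L", 5, 162, seed = 201)
  f <- c(0.4, 0.25, 0.15, 0.12, 0.08)
  truth <- generate_population(pool, 1e4, f, seed = 202)
  est <- allele_frequencies(truth$genotypes, "L")
  expect_lt(max(abs(est[pool$allele_id] - f)), 0.02)
})

test_that("heterozygosity and Fis behave at the boundaries and under HWE", {
  allhet <- make_table(replicate(20, c("A", "B"), simplify = FALSE))
  h <- heterozygosity(allhet, "L")
  expect_equal(h$Ho, 1)
  expect_equal(h$Fis, -1)
  allhom <- make_table(replicate(10, c("A", "A"), simplify = FALSE))
  h2 <- heterozygosity(allhom, "L")
  expect_equal(h2$Ho, 0)
  expect_equal(h2$He, 0)
  expect_true(h2$undefined)
  # unbiased He for a known configuration: {AA, AB}: p = (.75, .25)
  tab <- make_table(list(c("A", "A"), c("A", "B")))
  expect_equal(heterozygosity(tab, "L")$He, (4 / 3) * (1 - 0.625))
  # HWE simulation oracle: Fis centred on zero (mean over replicates of
  # n = 500, two alleles at 0.5/0.5)
  pool <- generate_allele_pool("L", 2, 162, seed = 203)
  fis <- vapply(1:50, function(i) {
    truth <- generate_population(pool, 500, c(0.5, 0.5), seed = 203 + i)
    heterozygosity(truth$genotypes, "L")$Fis
  }, numeric(1))
  expect_lt(abs(mean(fis)), 0.05)
})

test_that("HWE U-score test agrees with full Levene enumeration", {
  # 3 individuals, alleles A and B with 3 copies each, all heterozygous
  tab <- make_table(list(c("A", "B"), c("A", "B"), c("A", "B")))
  res <- hwe_u_test(tab, "L", n_mc = 20000, seed = 1)
  # enumeration oracle over all 15 pairings of the 6 copies
  copies <- c(1L, 1L, 1L, 2L, 2L, 2L)
  w <- (1 - c(0.5, 0.5)) / c(0.5, 0.5)
  p_exact <- oracle_levene_p(copies, w, res$U)
  expect_equal(p_exact, 6 / 15)            # only all-het pairings reach U = 3
  expect_lt(abs(res$p - p_exact), 0.02)
  # direction: all homozygotes cannot show excess
  hom <- make_table(c(replicate(5, c("A", "A"), simplify = FALSE),
                      replicate(5, c("B", "B"), simplify = FALSE)))
  expect_gt(hwe_u_test(hom, "L", n_mc = 2000, seed = 2)$p, 0.95)
  # reproducibility under a fixed seed
  expect_identical(hwe_u_test(tab, "L", n_mc = 500, seed = 3)$p,
                   hwe_u_test(tab, "L", n_mc = 500, seed = 3)$p)
  # monomorphic convention
  expect_equal(hwe_u_test(make_table(replicate(5, c("A", "A"),
                                               simplify = FALSE)),
                          "L", n_mc = 100)$p, 1)
})

test_that("null-allele EM recovers simulated null frequencies", {
  # HWE table without homozygote excess
  pool <- generate_allele_pool("L", 6, 162, seed = 205)
  truth <- generate_population(pool, 500, rep(1 / 6, 6), seed = 206)
  est0 <- null_allele_em(truth$genotypes, "L")
  expect_true(est0$converged)
  expect_lt(est0$estimate, 0.01)
  # simulated null allele at 0.15: null carriers look homozygous, null-null
  # individuals are untyped
  set.seed(207)
  alleles <- c(sprintf("a%02d", 1:5), "null")
  f <- c(rep(0.17, 5), 0.15)
  draw <- function() sample(alleles, 2, TRUE, prob = f)
  pairs <- replicate(500, draw(), simplify = FALSE)
  obs <- lapply(pairs, function(p) {
    if (all(p == "null")) c(NA, NA)
    else if (any(p == "null")) rep(p[p != "null"][1], 2)
    else p
  })
  keep <- !vapply(obs, function(p) any(is.na(p)), logical(1))
  tab <- make_table(obs[keep])
  est <- null_allele_em(tab, "L")
  expect_lt(abs(est$estimate - 0.15), 0.05)
  # zero observed homozygotes pin the estimate at zero
  nohom <- make_table(replicate(30, c("A", "B"), simplify = FALSE))
  expect_lt(null_allele_em(nohom, "L")$estimate, 1e-6)
})

test_that("haplotype EM equals gamete counting when phase is known", {
  # no double heterozygotes: phase fully determined
  gA <- list(c("A", "A"), c("A", "A"), c("A", "B"), c("B", "B"))
  gB <- list(c("x", "y"), c("x", "x"), c("y", "y"), c("x", "y"))
  tab <- rbind(make_table(gA, locus = "LA"), make_table(gB, locus = "LB"))
  em <- em_haplotype_freqs(tab, "LA", "LB")
  # gametes: (Ax, Ay), (Ax, Ax), (Ay, By), (Bx, By)
  counts <- c("A x" = 3, "A y" = 2, "B x" = 1, "B y" = 2) / 8
  expect_equal(em$haplotypes["A", "x"], unname(counts["A x"]), tolerance = 1e-6)
  expect_equal(em$haplotypes["A", "y"], unname(counts["A y"]), tolerance = 1e-6)
  expect_equal(em$haplotypes["B", "y"], unname(counts["B y"]), tolerance = 1e-6)
  expect_equal(sum(em$haplotypes), 1, tolerance = 1e-12)
  expect_true(all(diff(em$trace) > -1e-8))   # monotone log-likelihood
  # independent loci: haplotype freqs approach the product of marginals
  poolA <- generate_allele_pool("LA", 4, 162, seed = 208)
  poolB <- generate_allele_pool("LB", 3, 162, seed = 209)
  truth <- generate_population(list(LA = poolA, LB = poolB), 500,
                               list(rep(0.25, 4), c(0.5, 0.3, 0.2)),
                               seed = 210)
  em2 <- em_haplotype_freqs(truth$genotypes, "LA", "LB")
  pa <- allele_frequencies(truth$genotypes, "LA")
  pb <- allele_frequencies(truth$genotypes, "LB")
  expect_lt(max(abs(em2$haplotypes - outer(pa, pb))), 0.03)
})

test_that("LD likelihood-ratio test detects coupling and stays non-negative", {
  # perfectly coupled loci: haplotypes AB / ab only
  pairs <- c(replicate(25, c("A", "A"), simplify = FALSE),
             replicate(25, c("A", "B"), simplify = FALSE))
  tabA <- make_table(pairs, locus = "LA")
  tabB <- make_table(lapply(pairs, function(p) chartr("AB", "ab", p)),
                     locus = "LB")
  tab <- rbind(tabA, tabB)
  res <- ld_lrt(tab, "LA", "LB", n_perm = 200, seed = 211)
  expect_lte(res$p, 1 / 201 + 1e-12)
  expect_gte(res$statistic, 0)
  expect_equal(res$df, 1L)
  # independent simulation keeps the statistic modest
  poolA <- generate_allele_pool("LA", 3, 162, seed = 212)
  poolB <- generate_allele_pool("LB", 3, 162, seed = 213)
  truth <- generate_population(list(LA = poolA, LB = poolB), 100,
                               list(rep(1 / 3, 3), rep(1 / 3, 3)), seed = 214)
  res2 <- ld_lrt(truth$genotypes, "LA", "LB", n_perm = 300, seed = 215)
  expect_gte(res2$statistic, 0)
  expect_gt(res2$p, 0.01)
})

test_that("pairwise FST matches the variance-components oracle", {
  # two identical subpopulations: theta ~ 0, p large
  pool <- generate_allele_pool("L", 5, 162, seed = 216)
  truth <- generate_population(pool, 60, rep(0.2, 5), seed = 217,
                               subpops = c(A = 30, B = 30))
  res <- pairwise_fst(truth$genotypes, "L", n_perm = 300, seed = 218)
  expect_lt(res$fst["A", "B"], 0.05)
  expect_gt(res$p["A", "B"], 0.05)
  expect_equal(res$fst, t(res$fst))
  expect_equal(diag(res$fst), c(A = 0, B = 0))
  # fixed alternative alleles: theta ~ 1
  fixed <- rbind(make_table(replicate(10, c("A", "A"), simplify = FALSE),
                            subpop = "P1"),
                 make_table(replicate(10, c("B", "B"), simplify = FALSE),
                            subpop = "P2"))
  fixed$individual <- sprintf("i%03d", seq_len(nrow(fixed)))
  resf <- pairwise_fst(fixed, "L", n_perm = 100, seed = 219)
  expect_gt(resf$fst["P1", "P2"], 0.98)
  # direct formula evaluation on a small table
  g <- truth$genotypes[1:10, ]
  g$subpop <- rep(c("A", "B"), each = 5)
  th_oracle <- oracle_wc_theta(g$allele1, g$allele2, g$subpop)
  resg <- pairwise_fst(g, "L", n_perm = 50, seed = 220)
  expect_equal(resg$fst["A", "B"], th_oracle, tolerance = 1e-12)
  # undersized groups are excluded and flagged
  g2 <- truth$genotypes
  g2$subpop[1] <- "tiny"
  resx <- pairwise_fst(g2, "L", n_perm = 50, seed = 221)
  expect_identical(resx$excluded, "tiny")
})
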