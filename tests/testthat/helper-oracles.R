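# Independent oracles: brute-force / closed-form computations kept separate
# from the implementation paths they check.

# translation via seqinr, independent of Biostrings::GENETIC_CODE
oracle_translate <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]])
}

# NG86 site fractions by direct enumeration of the nine single-base changes
oracle_ng86_sites <- function(codon) {
  bases <- c("a", "c", "g", "t")
  ch <- tolower(strsplit(codon, "")[[1]])
  aa0 <- oracle_translate(codon)
  s <- n <- 0
  for (pos in 1:3) for (b in bases[bases != ch[pos]]) {
    mut <- ch; mut[pos] <- b
    aa <- seqinr::translate(mut)
    if (aa == "*") next
    if (aa == aa0) s <- s + 1 / 3 else n <- n + 1 / 3
  }
  c(syn = s, nonsyn = n)
}

# all stop-free substitution pathways between two sense codons, by depth-first
# recursion over the remaining differing positions; returns the averaged
# (syn, nonsyn) step counts or NULL when all pathways are blocked
oracle_ng86_path <- function(c1, c2) {
  walk <- function(cur, target) {
    if (cur == target) return(list(c(s = 0, n = 0)))
    cv <- strsplit(cur, "")[[1]]; tv <- strsplit(target, "")[[1]]
    out <- list()
    for (pos in which(cv != tv)) {
      nxt <- cv; nxt[pos] <- tv[pos]
      nxt_c <- paste(nxt, collapse = "")
      if (oracle_translate(nxt_c) == "*") next
      step_syn <- oracle_translate(cur) == oracle_translate(nxt_c)
      for (tail in walk(nxt_c, target)) {
        out <- c(out, list(tail + c(s = as.numeric(step_syn),
                                    n = as.numeric(!step_syn))))
      }
    }
    out
  }
  paths <- walk(c1, c2)
  if (!length(paths)) return(NULL)
  m <- do.call(rbind, paths)
  c(sd = mean(m[, "s"]), nd = mean(m[, "n"]))
}

# exhaustive single-breakpoint chimera check
oracle_chimera <- function(cand, a, b) {
  L <- nchar(cand)
  if (cand == a || cand == b) return(NA_integer_)
  hits <- integer(0)
  for (i in 1:(L - 1)) {
    if (paste0(substr(a, 1, i), substring(b, i + 1)) == cand ||
        paste0(substr(b, 1, i), substring(a, i + 1)) == cand)
      hits <- c(hits, i)
  }
  if (length(hits)) min(hits) else NA_integer_
}

# full enumeration of the Levene distribution: all perfect pairings of the
# allele copies, equal weight; returns P(U >= u_obs)
oracle_levene_p <- function(copies, w, u_obs) {
  us <- c()
  recurse <- function(left, n_het, hom_counts) {
    if (!length(left)) {
      us <<- c(us, n_het - sum(hom_counts * w))
      return(invisible())
    }
    a <- left[1]
    rest <- left[-1]
    for (j in seq_along(rest)) {
      b <- rest[j]
      hc <- hom_counts
      nh <- n_het
      if (a == b) hc[a] <- hc[a] + 1 else nh <- nh + 1
      recurse(rest[-j], nh, hc)
    }
  }
  recurse(copies, 0L, rep(0L, length(w)))
  mean(us >= u_obs - 1e-12)
}

# Weir & Cockerham (1984) theta written as an explicit per-population loop,
# kept stylistically independent of the package implementation
oracle_wc_theta <- function(a1, a2, pops) {
  pops <- as.character(pops)
  pop_ids <- unique(pops)
  r <- length(pop_ids)
  n_i <- sapply(pop_ids, function(p) sum(pops == p))
  nbar <- mean(n_i)
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  alleles <- unique(c(a1, a2))
  num <- den <- 0
  for (al in alleles) {
    p_i <- h_i <- numeric(r)
    for (k in seq_len(r)) {
      sel <- pops == pop_ids[k]
      p_i[k] <- (sum(a1[sel] == al) + sum(a2[sel] == al)) / (2 * n_i[k])
      h_i[k] <- sum((a1[sel] == al) != (a2[sel] == al)) / n_i[k]
    }
    pbar <- sum(n_i * p_i) / sum(n_i)
    hbar <- sum(n_i * h_i) / sum(n_i)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    a_c <- nbar / nc *
      (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b_c <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    c_c <- hbar / 2
    num <- num + a_c
    den <- den + a_c + b_c + c_c
  }
  num / den
}

# exact expected rarefied richness: for each allele with k carriers among N
# individuals, P(seen in a draw of n) = 1 - C(N-k, n)/C(N, n)
oracle_rarefaction_mean <- function(table, locus, n) {
  g <- table[table$locus == locus & !is.na(table$allele1), ]
  alleles <- unique(c(g$allele1, g$allele2))
  N <- nrow(g)
  sum(vapply(alleles, function(a) {
    k <- sum(g$allele1 == a | g$allele2 == a)
    1 - choose(N - k, n) / choose(N, n)
  }, numeric(1)))
}

# Monte-Carlo minimum-depth oracle: smallest T whose estimated coverage
# probability reaches `conf`, scanning around a starting point
oracle_min_reads_mc <- function(n_alleles, m, conf, artifact_rate,
                                t_from, t_to, n_draws = 1e5) {
  p <- c(rep((1 - artifact_rate) / n_alleles, n_alleles), artifact_rate)
  p <- p[p > 0]
  for (T in t_from:t_to) {
    draws <- rmultinom(n_draws, T, p)
    cov <- mean(apply(draws[seq_len(n_alleles), , drop = FALSE], 2, min) >= m)
    if (cov >= conf) return(T)
  }
  Inf
}
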