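# Rarefaction of allelic richness versus sampling effort, and grouped
# allele-count tabulations.

#' Rarefaction curve of allelic richness
#'
#' For each sampling effort (multiples of `step`, always including the full
#' sample), draws `n_reps` random subsets of individuals without replacement
#' and counts the distinct alleles among their genotypes; reports the mean
#' and SD across replicates. Individuals untyped at the locus are excluded
#' before drawing.
#'
#' @param table Genotype table (see [allele_frequencies()]).
#' @param locus Locus id.
#' @param step Effort increment in individuals (default 10).
#' @param n_reps Replicates per effort (default 100).
#' @param seed Optional integer seed.
#' @param max_effort Optional cap; efforts beyond the number of typed
#'   individuals are truncated with a warning.
#' @return A `rarefaction_curve` data frame (`effort`, `mean`, `sd`) with
#'   attributes `n_reps`, `locus` and `n_individuals`. At full effort the
#'   mean equals the total allele count and the SD is 0.
#' @export
rarefaction_curve <- function(table, locus, step = 10L, n_reps = 100L,
                              seed = NULL, max_effort = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (step < 1L) stop("step must be >= 1")
  g <- .locus_genotypes(table, locus)
  N <- nrow(g)
  if (!N) stop("no typed individuals at locus ", locus)
  if (!is.null(max_effort) && max_effort > N) {
    warning("max_effort exceeds the number of typed individuals; truncated to ", N)
    max_effort <- N
  }
  top <- if (is.null(max_effort)) N else max_effort
  efforts <- unique(c(seq(step, top, by = step), top))
  efforts <- efforts[efforts >= 1L]
  rows <- lapply(efforts, function(n_eff) {
    counts <- replicate(n_reps, {
      idx <- sample.int(N, n_eff)
      length(unique(c(g$allele1[idx], g$allele2[idx])))
    })
    data.frame(effort = n_eff, mean = mean(counts), sd = sd(counts))
  })
  out <- do.call(rbind, rows)
  attr(out, "n_reps") <- n_reps
  attr(out, "locus") <- locus
  attr(out, "n_individuals") <- N
  class(out) <- c("rarefaction_curve", "data.frame")
  out
}

#' Allele copy counts by group
#'
#' Tabulates allele copies (homozygotes contribute two) per group; column
#' sums equal twice the number of typed individuals in each group.
#'
#' @param table Genotype table.
#' @param locus Locus id.
#' @param grouping Name of the column of `table` holding group labels
#'   (e.g. `"subpop"`), or a vector of labels aligned with the locus rows.
#' @return Integer matrix, alleles x groups.
#' @export
allele_counts_by_group <- function(table, locus, grouping = "subpop") {
  g <- .locus_genotypes(table, locus)
  labels <- if (is.character(grouping) && length(grouping) == 1L) {
    if (!grouping %in% names(g)) stop("unknown grouping column: ", grouping)
    g[[grouping]]
  } else {
    if (length(grouping) != nrow(g))
      stop("grouping vector must match the number of typed individuals")
    grouping
  }
  tab <- table(allele = c(g$allele1, g$allele2), group = rep(labels, 2L))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  m
}
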