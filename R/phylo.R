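# Amino-acid distance matrices, neighbour-joining trees with Poisson
# correction, column-bootstrap support and Newick IO. Tree construction and
# serialisation delegate to ape; the distances and the bootstrap resampling
# scheme are defined here.

#' Poisson-corrected amino-acid distance between two sequences
#'
#' `d = -log(1 - p)` with `p` the fraction of differing sites; shared gap
#' columns are excluded pairwise.
#'
#' @param seqA,seqB Equal-length amino-acid strings.
#' @return The corrected distance; `p = 1` is saturated and returns `NA`
#'   with a warning.
#' @export
poisson_distance <- function(seqA, seqB) {
  if (nchar(seqA) != nchar(seqB)) stop("sequences must have equal length")
  a <- strsplit(seqA, "", fixed = TRUE)[[1]]
  b <- strsplit(seqB, "", fixed = TRUE)[[1]]
  keep <- a != "-" & b != "-"
  if (!any(keep)) stop("no comparable sites")
  p <- mean(a[keep] != b[keep])
  if (p >= 1) { warning("saturated distance (p = 1)"); return(NA_real_) }
  -log(1 - p)
}

#' Poisson-corrected distance matrix for aligned amino-acid sequences
#'
#' Columns containing a gap in any sequence are removed first (complete
#' deletion), so all pairs are scored on the same sites.
#'
#' @param seqs Named character vector of aligned amino-acid sequences.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
poisson_dist_matrix <- function(seqs) {
  if (length(seqs) < 2L) stop("need >= 2 sequences")
  m <- .char_matrix(seqs)
  keep <- apply(m, 1L, function(r) all(r != "-"))
  m <- m[keep, , drop = FALSE]
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    p <- mean(m[, i] != m[, j])
    d[i, j] <- d[j, i] <- if (p >= 1) NA_real_ else -log(1 - p)
  }
  if (anyNA(d)) warning("saturated entries (p = 1) set to NA")
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via `ape::nj`). For an additive matrix the tree
#' metric reproduces the input exactly. Negative branch lengths are retained
#' but flagged with a warning, not clamped.
#'
#' @param d Symmetric distance matrix (>= 3 labelled taxa, finite, zero
#'   diagonal).
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need >= 3 taxa")
  if (is.null(rownames(d))) stop("distance matrix must be labelled")
  if (anyNA(d) || any(!is.finite(d))) stop("distance matrix contains NA/Inf")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("diagonal must be zero")
  tr <- ape::nj(stats::as.dist(d))
  if (any(tr$edge.length < 0))
    warning("negative branch length(s) retained")
  tr
}

#' Neighbour-joining tree with bootstrap support from an alignment
#'
#' Builds the full-data NJ tree from Poisson-corrected distances, then
#' resamples alignment columns with replacement `n_reps` times, rebuilds the
#' tree, and maps bipartition frequencies (percent) onto the internal edges
#' of the full-data tree as node labels.
#'
#' @param seqs Named character vector of aligned amino-acid sequences
#'   (>= 4 for meaningful supports).
#' @param n_reps Bootstrap replicates; `0` returns the tree without supports.
#' @param seed Optional integer seed.
#' @return A `phylo` tree; with `n_reps > 0`, `node.label` holds supports in
#'   `[0, 100]` (root label empty).
#' @export
bootstrap_support <- function(seqs, n_reps = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- .char_matrix(seqs)
  keep <- apply(m, 1L, function(r) all(r != "-"))
  m <- m[keep, , drop = FALSE]
  colnames(m) <- names(seqs)
  dist_of <- function(mat) {
    n <- ncol(mat)
    d <- matrix(0, n, n, dimnames = list(colnames(mat), colnames(mat)))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      p <- mean(mat[, i] != mat[, j])
      d[i, j] <- d[j, i] <- if (p >= 1) 3 - log(1e-3) else -log(1 - p)
    }
    d
  }
  tree <- nj_tree(dist_of(m))
  if (n_reps <= 0L) return(tree)
  boots <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    rows <- sample.int(nrow(m), nrow(m), replace = TRUE)
    # transient negative lengths in replicates are routine; only the
    # full-data tree warns
    boots[[r]] <- suppressWarnings(nj_tree(dist_of(m[rows, , drop = FALSE])))
  }
  cl <- ape::prop.clades(tree, boots, rooted = FALSE)
  cl[is.na(cl)] <- 0L
  sup <- round(100 * cl / n_reps)
  lab <- as.character(sup)
  lab[1L] <- ""                      # root node carries no bipartition
  tree$node.label <- lab
  tree
}

#' Write a tree as Newick, hiding weak bootstrap supports
#'
#' @param tree A `phylo` tree, optionally with numeric `node.label` supports.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @param min_support_display Supports strictly below this percentage are
#'   omitted from the output (e.g. `50` reproduces the usual "only supports
#'   exceeding 50% shown" convention).
#' @return The Newick string (invisibly when written to `file`).
#' @export
write_newick <- function(tree, file = NULL, min_support_display = 0) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (!is.null(tree$node.label) && min_support_display > 0) {
    sup <- suppressWarnings(as.numeric(tree$node.label))
    hide <- !is.na(sup) & sup < min_support_display
    tree$node.label[hide] <- ""
  }
  txt <- ape::write.tree(tree)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Read a Newick tree
#' @param file Path or a Newick string.
#' @return A `phylo` tree.
#' @export
read_newick <- function(file) {
  if (grepl(";", file, fixed = TRUE) && !file.exists(file))
    ape::read.tree(text = file)
  else ape::read.tree(file)
}
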