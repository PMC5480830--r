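#' p-distance matrix of an alignment
#'
#' `d(a, b) = 1 - pairwise identity`, with identity computed per the pair
#' rule of [mean_pairwise_identity()] (gap-vs-base mismatches, gap-vs-gap
#' excluded). A pair with no comparable columns is an error.
#'
#' @param alignment Named character vector of gapped rows (>= 2).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(alignment) {
  stopifnot(length(alignment) >= 2, !is.null(names(alignment)))
  m <- .aln_matrix(alignment)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      a <- m[i, ]; b <- m[j, ]
      comp <- a != "-" | b != "-"
      if (!any(comp)) {
        stop("no comparable columns between ", rownames(m)[i], " and ",
             rownames(m)[j])
      }
      d[i, j] <- d[j, i] <- 1 - sum(a == b & a != "-") / sum(comp)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor joining (via \pkg{ape}); on additive distances the
#' generating tree metric is recovered exactly. Negative branch lengths
#' are clamped to zero and flagged.
#'
#' @param dm Symmetric distance matrix with >= 3 labelled taxa.
#' @return Newick string; attributes `tree` (the `phylo` object) and
#'   `clamped` (TRUE if any branch length was negative).
#' @export
nj_tree <- function(dm) {
  stopifnot(is.matrix(dm))
  if (nrow(dm) < 3) stop("neighbor joining requires at least 3 taxa")
  if (is.null(rownames(dm))) stop("distance matrix must have taxa labels")
  tree <- ape::nj(stats::as.dist(dm))
  clamped <- any(tree$edge.length < 0)
  tree$edge.length <- pmax(tree$edge.length, 0)
  nwk <- ape::write.tree(tree)
  attr(nwk, "tree") <- tree
  attr(nwk, "clamped") <- clamped
  nwk
}
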