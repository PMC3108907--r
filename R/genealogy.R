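#' Neighbor-joining genealogy
#'
#' Distance-based genealogy surrogate via the standard neighbor-joining
#' Q-criterion agglomeration (the [ape::nj()] core). Negative branch
#' lengths — an occasional NJ artifact — are floored at zero with the
#' deficit shifted to the sibling edge so path lengths are preserved.
#'
#' @param dm a [pairwise_distances()] object or symmetric labelled matrix.
#' @return Unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  d <- dist_matrix_of(dm)
  if (nrow(d) < 3L) {
    abort("Neighbor-joining needs at least three labels.",
          class = "mito_tree_error")
  }
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1L]
    sibs <- which(tr$edge[, 1L] == parent & seq_len(nrow(tr$edge)) != e)
    if (length(sibs)) {
      tr$edge.length[sibs[1L]] <- tr$edge.length[sibs[1L]] + tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  tr
}

#' Test monophyly of a tip set (unrooted convention)
#'
#' TRUE iff some edge bipartition of the unrooted tree isolates exactly
#' the given tips.
#'
#' @param tree `ape::phylo`.
#' @param tips character vector of tip labels (proper non-empty subset).
#' @return Logical flag.
#' @export
is_monophyletic <- function(tree, tips) {
  tips <- unique(tips)
  if (!all(tips %in% tree$tip.label)) {
    abort("Some tips are not in the tree.", class = "mito_tree_error")
  }
  n <- length(tree$tip.label)
  if (length(tips) == 0L || length(tips) == n) {
    abort("Tip set must be a proper non-empty subset.",
          class = "mito_tree_error")
  }
  if (length(tips) == 1L || length(tips) == n - 1L) return(TRUE)
  target <- sort(match(tips, tree$tip.label))
  parts <- ape::prop.part(tree)
  for (p in parts) {
    if (length(p) == length(target) && all(sort(p) == target)) return(TRUE)
    comp <- setdiff(seq_len(n), p)
    if (length(comp) == length(target) && all(sort(comp) == target)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Robinson-Foulds distance
#'
#' Symmetric-difference count of non-trivial bipartitions between two trees
#' on the same tip set (via [phangorn::RF.dist()]).
#'
#' @param t1,t2 `ape::phylo` trees with identical tip sets.
#' @return Integer count.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    abort("Trees must share the same tip set.", class = "mito_tree_error")
  }
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                               check.labels = TRUE))
}
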