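#' Read a newick tree
#'
#' Thin validated wrapper over [ape::read.tree()]: rejects unparseable
#' strings and duplicated tip labels.
#'
#' @param path path to a newick file (first tree is used).
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) {
    abort("Could not parse newick file.", class = "mito_format_error")
  }
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  if (anyDuplicated(tr$tip.label)) {
    abort("Duplicate tip labels in tree.", class = "mito_tree_error")
  }
  tr
}

#' Write a newick tree
#'
#' @param tree an `ape::phylo` tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# check that a tree's tips cover exactly / are a subset of alignment samples
check_tree_tips <- function(tree, aln, subset = FALSE) {
  extra <- setdiff(tree$tip.label, sample_ids(aln))
  if (length(extra)) {
    abort(paste0("Tree tips not in alignment: ",
                 paste(head(extra, 5), collapse = ", ")),
          class = "mito_tree_error")
  }
  if (!subset) {
    missing <- setdiff(sample_ids(aln), tree$tip.label)
    if (length(missing)) {
      abort(paste0("Alignment samples missing from tree: ",
                   paste(head(missing, 5), collapse = ", ")),
            class = "mito_tree_error")
    }
  }
  invisible(TRUE)
}
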