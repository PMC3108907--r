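#' Per-site parsimony homoplasy indices
#'
#' For every segregating site, computes the observed Fitch step count s on
#' the given tree, the minimum conceivable steps m = (number of observed
#' states - 1), the maximum steps g on a star tree (number of genomes with
#' data minus the count of the most frequent state), and the classical
#' indices
#' \deqn{CI = m/s, \quad HI = 1 - CI, \quad RI = (g-s)/(g-m), \quad
#'       RC = CI \times RI,}
#' with the convention RI = 1 (hence RC = CI) for parsimony-uninformative
#' sites where g = m; such sites are flagged. State counts for g are taken
#' over genomes: when the tree's tips are haplotype representatives,
#' per-tip frequency weights restore genome counts.
#'
#' The indices are tree-conditional: any tree over the samples (a
#' neighbor-joining surrogate or an externally estimated topology) is
#' accepted.
#'
#' @param tree `ape::phylo` whose tips are alignment samples (or haplotype
#'   representatives).
#' @param aln a [mito_alignment()].
#' @param parts optional partition tibble for locus lookup.
#' @param weights optional named per-tip genome counts (haplotype
#'   frequencies); default 1 per tip.
#' @param report optional [segregating_sites()] output restricted to the
#'   tree's tips.
#' @return Tibble with `position`, `locus`, `locus_position`, `states`,
#'   `changes` (s), `min_steps` (m), `max_steps` (g), `ci`, `hi`, `ri`,
#'   `rc`, `uninformative`.
#' @export
site_indices <- function(tree, aln, parts = NULL, weights = NULL,
                         report = NULL) {
  check_tree_tips(tree, aln, subset = TRUE)
  sub <- unclass(aln)[tree$tip.label, , drop = FALSE]
  if (is.null(weights)) {
    weights <- setNames(rep(1, length(tree$tip.label)), tree$tip.label)
  }
  if (!all(tree$tip.label %in% names(weights))) {
    abort("`weights` must cover every tip.", class = "mito_tree_error")
  }
  if (is.null(report)) {
    report <- segregating_sites(mito_alignment(sub))
  }
  if (!nrow(report)) {
    return(tibble::tibble(position = integer(0)))
  }
  loc <- if (!is.null(parts)) {
    locate_positions(validate_partitions(parts, aln), report$position)
  } else {
    tibble::tibble(position = report$position, locus = NA_character_,
                   locus_position = NA_integer_)
  }
  w <- weights[tree$tip.label]
  purrr::map_dfr(seq_len(nrow(report)), function(k) {
    j <- report$position[k]
    site <- setNames(sub[, j], tree$tip.label)
    s <- fitch_steps(tree, site)
    informative_tip <- site %in% BASES
    cnt <- vapply(BASES, function(b) sum(w[informative_tip & site == b]),
                  numeric(1))
    present <- cnt[cnt > 0]
    m <- length(present) - 1L
    g <- sum(present) - max(present)
    ci <- m / s
    uninf <- g == m
    ri <- if (uninf) 1 else (g - s) / (g - m)
    tibble::tibble(position = j,
                   locus = loc$locus[loc$position == j][1],
                   locus_position = loc$locus_position[loc$position == j][1],
                   states = report$states[k],
                   changes = s, min_steps = m, max_steps = g,
                   ci = ci, hi = 1 - ci, ri = ri, rc = ci * ri,
                   uninformative = uninf)
  })
}
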