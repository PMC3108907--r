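# Fitch parsimony on nucleotide characters, with state sets encoded as
# 4-bit masks (A=1, C=2, G=4, T=8; N and - carry the full set).

STATE_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 15L, `-` = 15L)

#' Fitch parsimony step count for one site
#'
#' Minimum number of state changes needed to explain the tip states on the
#' tree, counted by the Fitch down-pass (one step per empty intersection).
#' The tree may be rooted or unrooted (ape's basal multifurcation is
#' resolved sequentially, which leaves the count invariant to the rooting
#' choice). `N`/`-` tips carry the full state set and never force a step.
#'
#' @param tree `ape::phylo`.
#' @param site named character vector of tip states (names = tip labels),
#'   over `A C G T N -`.
#' @return Integer step count.
#' @export
fitch_steps <- function(tree, site) {
  fitch_down(tree, site)$steps
}

# shared down-pass: returns per-node state-set masks and the step count
fitch_down <- function(tree, site) {
  tips <- tree$tip.label
  if (!all(tips %in% names(site))) {
    abort("Every tip needs a state assignment.", class = "mito_tree_error")
  }
  states <- toupper(site[tips])
  if (any(!states %in% names(STATE_MASK))) {
    abort("Tip states must be A/C/G/T/N/-.", class = "mito_tree_error")
  }
  ntip <- length(tips)
  nnode <- ntip + tree$Nnode
  mask <- integer(nnode)
  mask[seq_len(ntip)] <- STATE_MASK[states]
  steps <- 0L
  po <- ape::reorder.phylo(tree, "postorder")
  edges <- po$edge
  # combine children into parents sequentially (handles multifurcations)
  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1L]; child <- edges[e, 2L]
    if (mask[parent] == 0L) {
      mask[parent] <- mask[child]
    } else {
      inter <- bitwAnd(mask[parent], mask[child])
      if (inter == 0L) {
        mask[parent] <- bitwOr(mask[parent], mask[child])
        steps <- steps + 1L
      } else {
        mask[parent] <- inter
      }
    }
  }
  list(mask = mask, steps = steps, edges = edges, ntip = ntip)
}

# deterministic ancestral assignment: root takes the lowest bit of its
# down-pass set; each child keeps the parent state when allowed, otherwise
# its lowest bit. Flags sites where a choice among several states was made.
fitch_ancestral <- function(tree, site) {
  dn <- fitch_down(tree, site)
  mask <- dn$mask
  ntip <- dn$ntip
  nnode <- length(mask)
  state <- integer(nnode)
  lowest_bit <- function(m) bitwAnd(m, -m)
  root <- ntip + 1L
  state[root] <- lowest_bit(mask[root])
  ambiguous <- bitwAnd(mask[root], mask[root] - 1L) != 0L
  pre <- dn$edges[rev(seq_len(nrow(dn$edges))), , drop = FALSE]
  for (e in seq_len(nrow(pre))) {
    parent <- pre[e, 1L]; child <- pre[e, 2L]
    if (bitwAnd(mask[child], state[parent]) != 0L) {
      state[child] <- state[parent]
    } else {
      state[child] <- lowest_bit(mask[child])
      if (bitwAnd(mask[child], mask[child] - 1L) != 0L) ambiguous <- TRUE
    }
  }
  base_of <- setNames(1:4, c(1L, 2L, 4L, 8L))
  changes <- which(state[pre[, 1L]] != state[pre[, 2L]])
  change_tbl <- tibble::tibble(
    parent = pre[changes, 1L], child = pre[changes, 2L],
    from = BASES[base_of[as.character(state[pre[changes, 1L]])]],
    to = BASES[base_of[as.character(state[pre[changes, 2L]])]])
  list(state = state, changes = change_tbl,
       steps = dn$steps, ambiguous = ambiguous)
}
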