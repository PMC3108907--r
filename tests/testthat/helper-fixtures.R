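# shared fixture builders and independent oracles

`%||%` <- function(x, y) if (is.null(x)) y else x

aln_from_strings <- function(x) {
  mat <- do.call(rbind, strsplit(unname(x), "", fixed = TRUE))
  rownames(mat) <- names(x)
  mito_alignment(mat)
}

# small partition layout for fast simulations: 3,000 columns with the same
# class structure as the full genome (protein span divisible by 3)
small_partitions <- function() {
  tibble::tribble(
    ~locus,   ~class,    ~start, ~end,  ~frame,      ~strand,
    "rrn",    "rRNA",    1L,     500L,  NA_integer_, "+",
    "trn",    "tRNA",    501L,   800L,  NA_integer_, "+",
    "cds",    "protein", 801L,   2399L, 801L,        "+",
    "dloop",  "dloop",   2400L,  2698L, NA_integer_, "+",
    "rest",   "other",   2699L,  3000L, NA_integer_, "+")
}

small_config <- function(n_per_pop = 3L, n_pops = 4L, rate_mult = 1,
                         hotspot_weight = 25, dloop_mult = 9.06) {
  pops <- tibble::tibble(
    population = sprintf("P%d", seq_len(n_pops)),
    subspecies = rep(sprintf("G%d", seq_len(ceiling(n_pops / 2))),
                     each = 2L)[seq_len(n_pops)],
    n = n_per_pop)
  base <- 6.5e-4 * rate_mult
  sim_config(
    populations = pops,
    genome_length = 3000L,
    partitions = small_partitions(),
    class_rates = c(protein = base, rRNA = base, tRNA = base,
                    dloop = dloop_mult * base, other = base),
    hotspots = if (hotspot_weight > 1) {
      tibble::tibble(position = c(2450L, 2500L, 2550L),
                     weight = hotspot_weight)
    } else {
      tibble::tibble(position = integer(0), weight = numeric(0))
    })
}

# exhaustive parsimony oracle: minimum changes over all labelings of the
# internal nodes (feasible up to ~7 tips)
brute_force_steps <- function(tree, site) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  masks <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 15L, `-` = 15L)
  tipmask <- masks[toupper(site[tree$tip.label])]
  combos <- as.matrix(expand.grid(rep(list(1:4), nnode)))
  bit <- c(1L, 2L, 4L, 8L)
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    lab <- combos[r, ]
    changes <- 0L
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
      pm <- bit[lab[p - ntip]]
      cm <- if (ch <= ntip) tipmask[ch] else bit[lab[ch - ntip]]
      if (bitwAnd(pm, cm) == 0L) changes <- changes + 1L
    }
    if (changes < best) best <- changes
  }
  best
}

# nested sums of squares computed from 1-D coordinates (independent of the
# distance-matrix decomposition): for d_ij = |x_i - x_j| the AMOVA SS equal
# classical deviation sums
deviation_ss <- function(x, pop, ssp) {
  ss_dev <- function(v) sum((v - mean(v))^2)
  total <- ss_dev(x)
  wp <- sum(tapply(x, pop, ss_dev))
  wg <- sum(tapply(x, ssp, ss_dev))
  list(total = total, among_ssp = total - wg, among_pop = wg - wp,
       within = wp)
}
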