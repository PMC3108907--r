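#' Default mitogenome partition layout
#'
#' A synthetic partition layout mirroring the structure of a carnivore
#' mitogenome alignment: two rRNA genes (2,528 bp), a tRNA fraction
#' (1,515 bp), 13 protein-coding genes (11,397 bp, ND6 on the reverse
#' strand), a 299-bp D-loop amplicon and a 551-bp residual control region,
#' totalling 16,290 aligned columns.
#'
#' @return A validated partition tibble.
#' @export
default_partitions <- function() {
  parts <- tibble::tribble(
    ~locus,        ~class,    ~start,  ~end,    ~frame,       ~strand,
    "12S_rRNA",    "rRNA",    1L,      974L,    NA_integer_,  "+",
    "16S_rRNA",    "rRNA",    975L,    2528L,   NA_integer_,  "+",
    "tRNA_blockA", "tRNA",    2529L,   3283L,   NA_integer_,  "+",
    "tRNA_blockB", "tRNA",    3284L,   4043L,   NA_integer_,  "+",
    "ND1",         "protein", 4044L,   5000L,   4044L,        "+",
    "ND2",         "protein", 5001L,   6044L,   5001L,        "+",
    "COX1",        "protein", 6045L,   7589L,   6045L,        "+",
    "COX2",        "protein", 7590L,   8273L,   7590L,        "+",
    "ATP8",        "protein", 8274L,   8474L,   8274L,        "+",
    "ATP6",        "protein", 8475L,   9155L,   8475L,        "+",
    "COX3",        "protein", 9156L,   9941L,   9156L,        "+",
    "ND3",         "protein", 9942L,   10289L,  9942L,        "+",
    "ND4L",        "protein", 10290L,  10586L,  10290L,       "+",
    "ND4",         "protein", 10587L,  11963L,  10587L,       "+",
    "ND5",         "protein", 11964L,  13784L,  11964L,       "+",
    "ND6",         "protein", 13785L,  14312L,  14312L,       "-",
    "CYTB",        "protein", 14313L,  15440L,  14313L,       "+",
    "D_loop",      "dloop",   15441L,  15739L,  NA_integer_,  "+",
    "control_rem", "other",   15740L,  16290L,  NA_integer_,  "+"
  )
  validate_partitions(parts, 16290L)
}

#' Simulation configuration
#'
#' Bundles every knob of the mitogenome simulator. Defaults emulate the
#' fisher study conditions: 40 samples in 6 populations nested in 3
#' subspecies, a 16,290-bp genome with the standard partition layout,
#' a strong D-loop rate excess (about 9x the protein-coding rate), a high
#' transition:transversion ratio, and recurrent-mutation hotspots in the
#' hypervariable D-loop plus one protein-coding site. Branch lengths are in
#' expected-substitution units per unit class rate; calendar conversion is
#' the clock module's job.
#'
#' @param populations tibble with columns `population`, `subspecies`, `n`.
#' @param genome_length aligned columns.
#' @param partitions partition tibble (validated against `genome_length`).
#' @param class_rates named per-class substitution rates per site per unit
#'   branch length.
#' @param hotspots tibble with columns `position`, `weight`
#'   (multiplicative rate weight for recurrent-mutation hotspots).
#' @param kappa transition:transversion rate ratio (transition probability
#'   `kappa / (kappa + 2)` per mutation draw).
#' @param base_freqs root-sequence base composition (A, C, G, T).
#' @param depths list with elements `subspecies`, `population`, `within`:
#'   divergence depths of the hierarchy levels.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(populations = NULL,
                       genome_length = 16290L,
                       partitions = default_partitions(),
                       class_rates = c(protein = 6.5e-4,
                                       rRNA   = 6.25e-4,
                                       tRNA   = 2.3e-4,
                                       dloop  = 58.9e-4,
                                       other  = 9.75e-4),
                       hotspots = tibble::tibble(
                         position = c(15536L, 15571L, 15648L, 9166L),
                         weight = c(25, 25, 25, 25)),
                       kappa = 10,
                       base_freqs = c(A = 0.33, C = 0.27, G = 0.14, T = 0.26),
                       depths = list(subspecies = 1.0, population = 0.5,
                                     within = 0.15)) {
  if (is.null(populations)) {
    populations <- tibble::tribble(
      ~population,        ~subspecies,  ~n,
      "S_California",     "pacifica",    7L,
      "N_California",     "pacifica",    5L,
      "Idaho_Montana",    "columbiana", 10L,
      "British_Columbia", "columbiana", 11L,
      "Great_Lakes_MN",   "pennanti",    2L,
      "Great_Lakes_WI",   "pennanti",    5L)
  }
  populations <- tibble::as_tibble(populations)
  if (any(populations$n < 1L)) {
    abort("Every population needs at least one sample.",
          class = "mito_config_error")
  }
  if (any(class_rates < 0)) {
    abort("Class rates must be non-negative.", class = "mito_config_error")
  }
  if (nrow(hotspots) && (any(hotspots$position < 1L) ||
                         any(hotspots$position > genome_length))) {
    abort("Hotspot columns outside the genome.", class = "mito_config_error")
  }
  partitions <- validate_partitions(partitions, genome_length)
  structure(list(populations = populations,
                 genome_length = as.integer(genome_length),
                 partitions = partitions,
                 class_rates = class_rates,
                 hotspots = tibble::as_tibble(hotspots),
                 kappa = kappa,
                 base_freqs = base_freqs / sum(base_freqs),
                 depths = depths),
            class = "sim_config")
}

#' Sample table implied by a simulation configuration
#'
#' @param config a [sim_config()].
#' @return Tibble with `sample`, `subspecies`, `population`.
#' @export
sim_samples <- function(config) {
  purrr::pmap_dfr(config$populations, function(population, subspecies, n) {
    tibble::tibble(sample = sprintf("%s.%02d", population, seq_len(n)),
                   subspecies = subspecies, population = population)
  })
}

# sequentially join clade fragments (newick strings without ';') that stand
# at known heights, at increasing join heights; returns fragment + height
join_clades <- function(frags, heights, join_heights) {
  k <- length(frags)
  if (k == 1L) return(list(frag = frags[[1L]], h = heights[[1L]]))
  ord <- sample.int(k)
  frags <- frags[ord]; heights <- heights[ord]
  cur <- frags[[1L]]; curh <- heights[[1L]]
  for (j in 2:k) {
    H <- join_heights[j - 1L]
    cur <- sprintf("(%s:%.10g,%s:%.10g)", cur, H - curh,
                   frags[[j]], H - heights[[j]])
    curh <- H
  }
  list(frag = cur, h = curh)
}

#' Simulate a population-structured genealogy
#'
#' Builds a rooted, binary, ultrametric tree over the configured samples:
#' random coalescent subtrees within populations (rescaled to the
#' within-population depth), populations joined within their subspecies at
#' the population depth, and subspecies joined at the root depth.
#' Deterministic under a fixed seed.
#'
#' @param config a [sim_config()].
#' @param seed integer random seed.
#' @return An `ape::phylo` tree whose tip labels are the sample IDs of
#'   [sim_samples()].
#' @export
simulate_tree <- function(config, seed = 1L) {
  set.seed(seed)
  d <- config$depths
  samples <- sim_samples(config)
  ssp_frags <- list(); ssp_heights <- numeric(0)
  for (ssp in unique(config$populations$subspecies)) {
    pops <- dplyr::filter(config$populations, .data$subspecies == ssp)
    pop_frags <- list(); pop_heights <- numeric(0)
    for (i in seq_len(nrow(pops))) {
      labs <- samples$sample[samples$population == pops$population[i]]
      n <- length(labs)
      if (n == 1L) {
        pop_frags <- c(pop_frags, labs); pop_heights <- c(pop_heights, 0)
      } else {
        t <- ape::rcoal(n, tip.label = labs)
        h0 <- max(ape::node.depth.edgelength(t))
        t$edge.length <- t$edge.length * d$within / h0
        frag <- sub(";$", "", ape::write.tree(t))
        pop_frags <- c(pop_frags, frag)
        pop_heights <- c(pop_heights, d$within)
      }
    }
    k <- length(pop_frags)
    jh <- if (k > 1L) d$population * seq(0.9, 1, length.out = k - 1L) else numeric(0)
    joined <- join_clades(pop_frags, pop_heights, jh)
    ssp_frags <- c(ssp_frags, joined$frag)
    ssp_heights <- c(ssp_heights, joined$h)
  }
  k <- length(ssp_frags)
  jh <- if (k > 1L) d$subspecies * seq(0.9, 1, length.out = k - 1L) else numeric(0)
  root <- join_clades(ssp_frags, ssp_heights, jh)
  ape::read.tree(text = paste0(root$frag, ";"))
}

# per-column mutation rate (class rate of the covering entry; the D-loop
# entry wins on cross-class overlap because it is assigned last) times the
# hotspot weight
column_rates <- function(config) {
  L <- config$genome_length
  rate <- rep(unname(config$class_rates["other"]), L)
  parts <- config$partitions
  ord <- order(match(parts$class, c("other", "rRNA", "tRNA", "protein", "dloop")))
  for (i in ord) {
    rate[parts$start[i]:parts$end[i]] <- config$class_rates[[parts$class[i]]]
  }
  if (nrow(config$hotspots)) {
    rate[config$hotspots$position] <-
      rate[config$hotspots$position] * config$hotspots$weight
  }
  rate
}

BASES <- c("A", "C", "G", "T")
# transition partners under the two-class (K2P-style) kernel
TS_PARTNER <- c(3L, 4L, 1L, 2L) # A<->G, C<->T

#' Evolve an alignment along a tree
#'
#' Places mutations as a Poisson process per branch per column with rate =
#' class rate x hotspot weight, drawing transitions with probability
#' `kappa / (kappa + 2)`. Recurrent mutation arises naturally at hotspot
#' columns. Returns both the tip alignment and a complete truth record
#' (per-branch per-column mutation log, per-column change counts, true tree
#' and haplotype assignment).
#'
#' @param tree `ape::phylo` whose tips are the configured samples.
#' @param config a [sim_config()].
#' @param seed integer random seed.
#' @return List with elements `alignment` ([mito_alignment()]) and `truth`
#'   (class `mito_truth`: `tree`, `mutations` tibble with columns
#'   `edge`, `parent`, `child`, `position`, `from`, `to`; `changes`
#'   integer vector of per-column change counts; `haplotypes`; `seed`).
#' @export
evolve_alignment <- function(tree, config, seed = 1L) {
  set.seed(seed)
  L <- config$genome_length
  rate <- column_rates(config)
  total_rate <- sum(rate)
  p_ts <- config$kappa / (config$kappa + 2)

  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  seqs <- vector("list", nnode)
  seqs[[root]] <- sample.int(4L, L, replace = TRUE, prob = config$base_freqs)

  po <- ape::reorder.phylo(tree, "postorder")
  edges <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]  # preorder
  elens <- po$edge.length[rev(seq_len(nrow(po$edge)))]

  logs <- vector("list", nrow(edges))
  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1L]; child <- edges[e, 2L]
    s <- seqs[[parent]]
    n_mut <- if (total_rate > 0) rpois(1L, elens[e] * total_rate) else 0L
    if (n_mut > 0L) {
      cols <- sample.int(L, n_mut, replace = TRUE, prob = rate)
      from <- integer(n_mut); to <- integer(n_mut)
      for (m in seq_len(n_mut)) {
        cur <- s[cols[m]]
        new <- if (runif(1L) < p_ts) {
          TS_PARTNER[cur]
        } else {
          tv <- setdiff(1:4, c(cur, TS_PARTNER[cur]))
          tv[sample.int(2L, 1L)]
        }
        from[m] <- cur; to[m] <- new
        s[cols[m]] <- new
      }
      logs[[e]] <- tibble::tibble(edge = e, parent = parent, child = child,
                                  position = cols,
                                  from = BASES[from], to = BASES[to])
    }
    seqs[[child]] <- s
  }
  mutations <- dplyr::bind_rows(logs)
  changes <- integer(L)
  if (nrow(mutations)) {
    tab <- table(mutations$position)
    changes[as.integer(names(tab))] <- as.integer(tab)
  }
  mat <- do.call(rbind, lapply(seq_len(ntip), function(i) BASES[seqs[[i]]]))
  rownames(mat) <- tree$tip.label
  aln <- mito_alignment(mat)
  truth <- structure(list(tree = tree, mutations = mutations,
                          changes = changes,
                          haplotypes = collapse_haplotypes(aln),
                          seed = seed),
                     class = "mito_truth")
  list(alignment = aln, truth = truth)
}

#' Simulate a full study data set
#'
#' Convenience wrapper: genealogy + sequence evolution + metadata, all from
#' one configuration and seed.
#'
#' @inheritParams evolve_alignment
#' @return List with `alignment`, `samples`, `partitions`, `tree`, `truth`.
#' @export
simulate_mitogenomes <- function(config = sim_config(), seed = 1L) {
  tree <- simulate_tree(config, seed = seed)
  ev <- evolve_alignment(tree, config, seed = seed + 1L)
  list(alignment = ev$alignment, samples = sim_samples(config),
       partitions = config$partitions, tree = tree, truth = ev$truth)
}

#' Deterministic alignment fixture with exact site counts
#'
#' Constructs, without randomness, an alignment with exactly the requested
#' number of segregating sites in each partition class and the requested
#' shared/singleton split. Variant columns carry an A->G substitution;
#' shared sites place the minor state in two genomes, singleton sites in
#' one. Defaults reproduce the fisher study totals: 66 segregating sites
#' (42 protein, 10 D-loop, 9 rRNA, 2 tRNA, 3 other), 19 shared and 47
#' singletons, over 40 samples.
#'
#' @param n_samples number of samples.
#' @param counts named integer vector of segregating-site counts per class.
#' @param n_shared number of sites whose minor state occurs in two genomes;
#'   the remaining `sum(counts) - n_shared` are singletons.
#' @param partitions partition tibble defining the class spans.
#' @param genome_length aligned length.
#' @return A [mito_alignment()].
#' @export
make_fixture <- function(n_samples = 40L,
                         counts = c(protein = 42L, rRNA = 9L, tRNA = 2L,
                                    dloop = 10L, other = 3L),
                         n_shared = 19L,
                         partitions = default_partitions(),
                         genome_length = 16290L) {
  n_total <- sum(counts)
  if (n_shared > n_total || n_shared < 0L) {
    abort("n_shared must be between 0 and sum(counts).",
          class = "mito_config_error")
  }
  if (n_shared > 0L && n_samples < 5L) {
    abort("Shared sites (minor count 2) need at least 5 samples.",
          class = "mito_config_error")
  }
  if (n_total > n_shared && n_samples < 3L) {
    abort("Singleton sites need at least 3 samples.",
          class = "mito_config_error")
  }
  partitions <- validate_partitions(partitions, genome_length)
  membership <- class_membership(partitions, genome_length)
  cols <- integer(0)
  for (cl in names(counts)) {
    avail <- which(membership[cl, ])
    # keep clear of other-class overlaps so per-class counts stay exact
    avail <- avail[colSums(membership[, avail, drop = FALSE]) == 1L]
    if (counts[[cl]] > length(avail)) {
      abort(paste0("Requested ", counts[[cl]], " sites in class '", cl,
                   "' but only ", length(avail), " usable columns."),
            class = "mito_config_error")
    }
    cols <- c(cols, avail[seq_len(counts[[cl]])])
  }
  cols <- sort(cols)
  mat <- matrix("A", nrow = n_samples, ncol = genome_length,
                dimnames = list(sprintf("S%02d", seq_len(n_samples)), NULL))
  shared_cols <- cols[seq_len(n_shared)]
  singleton_cols <- setdiff(cols, shared_cols)
  for (k in seq_along(shared_cols)) {
    i <- ((k - 1L) %% (n_samples - 1L)) + 1L
    mat[c(i, i + 1L), shared_cols[k]] <- "G"
  }
  for (k in seq_along(singleton_cols)) {
    i <- ((k - 1L) %% n_samples) + 1L
    mat[i, singleton_cols[k]] <- "G"
  }
  mito_alignment(mat)
}

#' Synthetic stand-in for the deposited fisher haplotype sequences
#'
#' The study's 40 samples map onto 15 distinct GenBank accessions
#' (see [fisher_samples()]). This constructs a synthetic 40-sample
#' alignment in which samples sharing an accession receive identical
#' sequences and distinct accessions differ: each accession carries a
#' deterministic private A->G variant. It stands in for the deposited
#' sequences (which the package does not download) wherever only the
#' identity structure matters, e.g. haplotype collapsing.
#'
#' @param genome_length aligned length.
#' @return List with `alignment` ([mito_alignment()]) and `samples`
#'   (tibble `sample`, `subspecies`, `population`, `accession`).
#' @export
synthetic_fisher_alignment <- function(genome_length = 16290L) {
  samples <- fisher_samples()
  accs <- sort(unique(samples$accession))
  mat <- matrix("A", nrow = nrow(samples), ncol = genome_length,
                dimnames = list(samples$sample, NULL))
  for (k in seq_along(accs)) {
    rows <- samples$sample[samples$accession == accs[k]]
    mat[rows, 100L + 7L * k] <- "G"
  }
  list(alignment = mito_alignment(mat), samples = samples)
}
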