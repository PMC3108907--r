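test_that("neighbor joining recovers additive and ultrametric structure", {
  # additive matrix from tree ((a:1,b:2):1,(c:3,d:1)); split ab|cd
  labs <- c("a", "b", "c", "d")
  d <- matrix(c(0, 3, 5, 3,
                3, 0, 6, 4,
                5, 6, 0, 4,
                3, 4, 4, 0), 4, 4, dimnames = list(labs, labs))
  tr <- nj_tree(d)
  expect_true(is_monophyletic(tr, c("a", "b")))
  expect_true(is_monophyletic(tr, c("c", "d")))
  expect_false(is_monophyletic(tr, c("a", "c")))
  expect_true(all(tr$edge.length >= 0))

  # three taxa: the unique unrooted topology
  d3 <- d[1:3, 1:3]
  expect_equal(length(nj_tree(d3)$tip.label), 3L)

  # ultrametric two-clade matrix
  labs6 <- sprintf("t%d", 1:6)
  d6 <- matrix(2, 6, 6); d6[1:3, 1:3] <- 1; d6[4:6, 4:6] <- 1; diag(d6) <- 0
  dimnames(d6) <- list(labs6, labs6)
  tr6 <- nj_tree(d6)
  expect_true(is_monophyletic(tr6, labs6[1:3]))

  expect_error(nj_tree(d[1:2, 1:2]), class = "mito_tree_error")
  dns <- d; dns[1, 2] <- 9
  expect_error(nj_tree(dns), class = "mito_format_error")
})

test_that("monophyly uses the unrooted bipartition convention", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  expect_true(is_monophyletic(tr, c("a", "b")))
  expect_false(is_monophyletic(tr, c("a", "c")))
  expect_true(is_monophyletic(tr, "a"))
  expect_true(is_monophyletic(tr, c("a", "c", "d")))  # complement of {b}... {a,c,d}
  expect_error(is_monophyletic(tr, character(0)), class = "mito_tree_error")
  expect_error(is_monophyletic(tr, c("a", "b", "c", "d")),
               class = "mito_tree_error")
  expect_error(is_monophyletic(tr, "zz"), class = "mito_tree_error")
})

test_that("planted population clades are detected on simulated data", {
  cfg <- small_config(n_per_pop = 4L, n_pops = 2L)
  sim <- simulate_mitogenomes(cfg, seed = 5)
  for (p in unique(sim$samples$population)) {
    tips <- sim$samples$sample[sim$samples$population == p]
    expect_true(is_monophyletic(sim$truth$tree, tips))
  }
})

test_that("Robinson-Foulds distance behaves as a bipartition metric", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(rf_distance(t1, t1), 0L)
  expect_equal(rf_distance(t1, t2), 2L)
  expect_equal(rf_distance(t2, t1), 2L)
  set.seed(8)
  r1 <- ape::rtree(12); r2 <- ape::rtree(12)
  expect_lte(rf_distance(r1, r2), 2L * (12L - 3L))
  expect_error(rf_distance(t1, ape::read.tree(text = "((a,b),(c,e));")),
               class = "mito_tree_error")
})

test_that("Fitch counts match forced examples and stay rooting-invariant", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(fitch_steps(tr, c(A = "T", B = "A", C = "A", D = "T")), 2L)
  expect_equal(fitch_steps(tr, c(A = "A", B = "A", C = "A", D = "A")), 0L)
  expect_equal(fitch_steps(tr, c(A = "T", B = "T", C = "A", D = "A")), 1L)
  # N never forces a step
  expect_equal(fitch_steps(tr, c(A = "T", B = "N", C = "A", D = "A")), 1L)
  expect_error(fitch_steps(tr, c(A = "T", B = "A", C = "A")),
               class = "mito_tree_error")
  # rooting invariance
  set.seed(3)
  tr7 <- ape::rtree(7)
  site <- setNames(sample(c("A", "C", "G", "T"), 7, TRUE), tr7$tip.label)
  s_rooted <- fitch_steps(tr7, site)
  expect_equal(fitch_steps(ape::unroot(tr7), site), s_rooted)
})

test_that("Fitch equals the exhaustive labeling minimum on small trees", {
  set.seed(11)
  for (rep in 1:12) {
    n <- sample(4:7, 1)
    tr <- ape::rtree(n)
    site <- setNames(sample(c("A", "C", "G", "T"), n, TRUE), tr$tip.label)
    expect_equal(fitch_steps(tr, site), brute_force_steps(tr, site))
  }
})

test_that("Fitch agrees with an independent implementation on many sites", {
  set.seed(13)
  tr <- ape::rtree(8)
  sites <- replicate(40, setNames(sample(c("A", "C", "G", "T"), 8, TRUE),
                                  tr$tip.label))
  ours <- apply(sites, 2, function(s) fitch_steps(tr, s))
  pd <- phangorn::phyDat(sites, type = "DNA")
  theirs <- phangorn::fitch(tr, pd, site = "site")[attr(pd, "index")]
  expect_equal(unname(ours), as.integer(theirs))
})

test_that("per-site homoplasy indices follow the published conventions", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  aln <- aln_from_strings(c(A = "TA", B = "AA", C = "AA", D = "TA"))
  idx <- site_indices(tr, aln)
  # column 1: binary, minor count 2, two steps forced
  expect_equal(idx$changes[1], 2L)
  expect_equal(idx$ci[1], 0.5)
  expect_equal(idx$hi[1], 0.5)
  expect_equal(idx$ri[1], 0)     # g = s = 2, m = 1
  expect_equal(idx$rc[1], 0)

  aln2 <- aln_from_strings(c(A = "T", B = "A", C = "A", D = "A"))
  idx2 <- site_indices(tr, aln2)
  expect_equal(idx2$ci, 1)
  expect_equal(idx2$ri, 1)       # uninformative convention
  expect_equal(idx2$rc, 1)
  expect_true(idx2$uninformative)
})

test_that("retention index reflects genome counts on a 40-tip tree", {
  # minor state on a 5-tip clade plus a 2-tip clade: s = 2, g = 7, m = 1
  labs <- sprintf("t%02d", 1:40)
  nw <- sprintf("(((%s),(%s)),((%s),(%s)));",
                paste(labs[1:5], collapse = ","),
                paste(labs[6:20], collapse = ","),
                paste(labs[21:22], collapse = ","),
                paste(labs[23:40], collapse = ","))
  tr <- ape::read.tree(text = nw)
  states <- rep("A", 40); states[c(1:5, 21:22)] <- "G"
  aln <- mito_alignment(matrix(states, 40, 1, dimnames = list(labs, NULL)))
  idx <- site_indices(tr, aln)
  expect_equal(idx$changes, 2L)
  expect_equal(idx$max_steps, 7)
  expect_equal(round(idx$ri, 3), 0.833)
  expect_equal(round(idx$rc, 3), 0.417)
})

test_that("haplotype-frequency weights restore genome counts for g", {
  tr <- ape::read.tree(text = "((H1,H2),(H3,H4));")
  aln <- aln_from_strings(c(H1 = "G", H2 = "A", H3 = "A", H4 = "G"))
  w <- c(H1 = 5, H2 = 15, H3 = 18, H4 = 2)
  idx <- site_indices(tr, aln, weights = w)
  expect_equal(idx$max_steps, 7)   # 40 genomes minus 33 majors
  expect_equal(round(idx$ri, 3), 0.833)
})

test_that("planted hotspot recurrence erodes the consistency index", {
  cfg <- small_config(rate_mult = 2, hotspot_weight = 120)
  hits <- 0L
  for (s in 1:6) {
    sim <- simulate_mitogenomes(cfg, seed = 200 + s)
    dm <- pairwise_distances(sim$alignment, model = "p")
    idx <- site_indices(nj_tree(dm), sim$alignment, sim$partitions)
    hot <- idx[idx$position %in% cfg$hotspots$position, ]
    if (nrow(hot) && any(hot$ci < 1)) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
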