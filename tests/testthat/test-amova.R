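mk_groups <- function(pop, ssp, labs = NULL) {
  labs <- labs %||% sprintf("s%02d", seq_along(pop))
  tibble::tibble(sample = labs, subspecies = ssp, population = pop)
}

mk_dist <- function(m, labs) {
  dimnames(m) <- list(labs, labs)
  m
}

test_that("perfect differentiation forces Phi_PT = 1", {
  labs <- c("a1", "a2", "b1", "b2")
  d <- matrix(1, 4, 4); d[1:2, 1:2] <- 0; d[3:4, 3:4] <- 0; diag(d) <- 0
  groups <- mk_groups(c("A", "A", "B", "B"), c("X", "X", "Y", "Y"), labs)
  fit <- amova(mk_dist(d, labs), groups, n_perm = 0)
  phi_pt <- fit$phi$value[fit$phi$statistic == "phi_pt"]
  expect_equal(phi_pt, 1)
  expect_equal(sum(fit$table$df[1:3]), 3L)  # N - 1
})

test_that("sums of squares match independent deviation sums and are additive", {
  set.seed(9)
  for (rep in 1:5) {
    N <- sample(6:12, 1)
    pop <- sample(c("p1", "p2", "p3", "p4"), N, replace = TRUE)
    # ensure every population occupied and nested 2-2 in subspecies
    pop[1:4] <- c("p1", "p2", "p3", "p4")
    ssp <- ifelse(pop %in% c("p1", "p2"), "g1", "g2")
    x <- rnorm(N)
    d <- as.matrix(stats::dist(x))
    labs <- sprintf("s%02d", seq_len(N))
    dimnames(d) <- list(labs, labs)
    fit <- amova(d, mk_groups(pop, ssp, labs), n_perm = 0)
    oracle <- deviation_ss(x, pop, ssp)
    expect_equal(fit$table$SS[1], oracle$among_ssp, tolerance = 1e-9)
    expect_equal(fit$table$SS[2], oracle$among_pop, tolerance = 1e-9)
    expect_equal(fit$table$SS[3], oracle$within, tolerance = 1e-9)
    # SS additivity
    expect_equal(sum(fit$table$SS[1:3]), fit$table$SS[4], tolerance = 1e-9)
    # percents sum to 100
    expect_equal(sum(fit$table$pct[1:3]), 100, tolerance = 1e-9)
  }
})

test_that("balanced designs agree with textbook closed-form components", {
  set.seed(21)
  n <- 4L                      # samples per population
  q <- 2L                      # populations per subspecies
  pop <- rep(c("p1", "p2", "p3", "p4"), each = n)
  ssp <- rep(c("g1", "g2"), each = n * q)
  x <- rnorm(length(pop)) + rep(c(0, 0.5, 2, 2.6), each = n)
  labs <- sprintf("s%02d", seq_along(pop))
  d <- as.matrix(stats::dist(x)); dimnames(d) <- list(labs, labs)
  fit <- amova(d, mk_groups(pop, ssp, labs), n_perm = 0)
  o <- deviation_ss(x, pop, ssp)
  ms_a <- o$among_ssp / 1; ms_b <- o$among_pop / 2
  ms_c <- o$within / (length(x) - 4L)
  sigma_c <- ms_c
  sigma_b <- (ms_b - ms_c) / n
  sigma_a <- (ms_a - ms_c - n * sigma_b) / (n * q)
  expect_equal(fit$table$variance[1:3], c(sigma_a, sigma_b, sigma_c),
               tolerance = 1e-9)
})

test_that("flat distance matrices give near-zero Phi and honest negatives", {
  labs <- sprintf("s%d", 1:8)
  d <- matrix(1, 8, 8); diag(d) <- 0
  groups <- mk_groups(rep(c("A", "B"), each = 4),
                      rep(c("X", "Y"), each = 4), labs)
  fit <- amova(mk_dist(d, labs), groups, n_perm = 99, seed = 1)
  phi_pt <- fit$phi$value[fit$phi$statistic == "phi_pt"]
  expect_lt(abs(phi_pt), 0.25)
  expect_lte(phi_pt, 0)    # all-equal distances: no among-group variance
  floored <- fit$phi$value_floored[fit$phi$statistic == "phi_pt"]
  expect_gte(floored, 0)
})

test_that("published variance components reproduce the published Phi_PT", {
  phi <- phi_statistics(0.00012, 0.00008, 0.00023)
  expect_equal(phi$value[phi$statistic == "phi_pt"], 0.4649,
               tolerance = 0.001 / 0.4649)
  expect_equal(phi$value[phi$statistic == "phi_rt"], 0.2715, tolerance = 0.03)
  expect_equal(phi$value[phi$statistic == "phi_pr"], 0.2655, tolerance = 0.03)
})

test_that("permutation p-values are deterministic and match exact enumeration", {
  labs <- c("a1", "a2", "b1", "b2")
  d <- matrix(1, 4, 4); d[1:2, 1:2] <- 0; d[3:4, 3:4] <- 0; diag(d) <- 0
  groups <- mk_groups(c("A", "A", "B", "B"), c("X", "X", "Y", "Y"), labs)
  p1 <- permutation_test(mk_dist(d, labs), groups, "phi_pt",
                         n_perm = 2999, seed = 4)
  p2 <- permutation_test(mk_dist(d, labs), groups, "phi_pt",
                         n_perm = 2999, seed = 4)
  expect_identical(p1$p_value, p2$p_value)
  # exact enumeration: 2 of the 6 distinct 2+2 assignments reach Phi_PT = 1
  expect_equal(p1$p_value, 1 / 3, tolerance = 0.12)

  # exchangeable distances: every relabeling ties the observed statistic
  dflat <- matrix(1, 4, 4); diag(dflat) <- 0
  pflat <- permutation_test(mk_dist(dflat, labs), groups, "phi_pt",
                            n_perm = 199, seed = 1)
  expect_equal(pflat$p_value, 1)
})

test_that("pairwise Phi_PT mirrors the published table layout", {
  labs <- c(sprintf("a%d", 1:3), sprintf("b%d", 1:3), sprintf("c%d", 1:3))
  pop <- rep(c("A", "B", "C"), each = 3)
  ssp <- rep("X", 9)
  # A and B identical and monomorphic; C fixed different
  d <- matrix(0, 9, 9)
  d[1:6, 7:9] <- 1; d[7:9, 1:6] <- 1
  dimnames(d) <- list(labs, labs)
  res <- pairwise_phi_pt(d, mk_groups(pop, ssp, labs), n_perm = 99, seed = 2)
  pairs <- tidy(res)
  ab <- pairs[pairs$population1 == "A" & pairs$population2 == "B", ]
  expect_true(ab$degenerate)
  expect_equal(ab$phi_pt, 0)
  ac <- pairs[pairs$population1 == "A" & pairs$population2 == "C", ]
  expect_equal(ac$phi_pt, 1)
  expect_false(is.na(res$matrix["C", "A"]))   # Phi below diagonal
  expect_false(is.na(res$matrix["A", "C"]))   # p above diagonal
})

test_that("pairwise Phi_PT rises with simulated divergence depth", {
  phis <- sapply(c(0.1, 0.8, 3), function(depth) {
    cfg <- small_config(n_per_pop = 4L, n_pops = 2L, rate_mult = 2)
    cfg$depths <- list(subspecies = depth, population = depth,
                       within = 0.05)
    vals <- sapply(1:6, function(s) {
      sim <- simulate_mitogenomes(cfg, seed = 100 + s)
      dm <- pairwise_distances(sim$alignment, model = "p")
      res <- pairwise_phi_pt(dm, sim$samples, n_perm = 0, seed = s)
      res$pairs$phi_pt[1]
    })
    mean(vals, na.rm = TRUE)
  })
  expect_true(all(diff(phis) >= -0.05))  # non-decreasing up to noise
  expect_gt(phis[3], phis[1])
})
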