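#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Partitions the variance of squared pairwise distances across a two-level
#' hierarchy (subspecies > populations > individuals), following the
#' classical sums-of-squares decomposition on distance matrices. With d the
#' pairwise distance and N individuals,
#' \deqn{SS_{total} = \frac{1}{N}\sum_{i<j} d_{ij}^2,}
#' within-population and within-subspecies sums of squares are computed the
#' same way inside each unit, the among-level sums follow by subtraction,
#' and variance components are solved from the expected mean squares with
#' the unequal-sample-size coefficients n', n'', n'''. The Phi statistics
#' are
#' \deqn{\Phi_{RT} = \sigma^2_a/\sigma^2_T,\quad
#'       \Phi_{PR} = \sigma^2_b/(\sigma^2_b+\sigma^2_c),\quad
#'       \Phi_{PT} = (\sigma^2_a+\sigma^2_b)/\sigma^2_T.}
#' Negative variance components are reported as estimated and flagged; Phi
#' statistics are additionally reported with components floored at zero
#' (the convention of the common AMOVA software). Significance comes from
#' non-parametric permutation with the `(1 + k)/(1 + n_perm)` estimator,
#' each statistic under its own permutation scheme: individuals among all
#' populations (Phi_PT), individuals among populations within their
#' subspecies (Phi_PR), and whole populations among subspecies (Phi_RT).
#'
#' @param dm a [pairwise_distances()] object, or a symmetric numeric
#'   matrix with row/column names.
#' @param groups sample table (columns `sample`, `subspecies`,
#'   `population`) covering every distance label.
#' @param n_perm number of permutations (0 skips the tests).
#' @param seed integer seed for the permutation stream.
#' @return Object of class `mito_amova`: list with `table` (source, df,
#'   SS, MS, variance, pct), `phi` (statistic, value, value_floored,
#'   p_value), `n_perm`, `seed`.
#' @export
amova <- function(dm, groups, n_perm = 10000L, seed = 1L) {
  d <- dist_matrix_of(dm)
  groups <- validate_samples(groups)
  labs <- rownames(d)
  missing <- setdiff(labs, groups$sample)
  if (length(missing)) {
    abort(paste0("Samples missing from group table: ",
                 paste(head(missing, 5), collapse = ", ")),
          class = "mito_sample_error")
  }
  groups <- groups[match(labs, groups$sample), , drop = FALSE]
  pop <- groups$population
  ssp <- groups$subspecies
  if (length(unique(ssp)) < 2L) {
    warn("Single subspecies: Phi_RT undefined.")
  }
  obs <- amova_components(d^2, pop, ssp)

  phi_p <- rep(NA_real_, 3L)
  if (n_perm > 0L) {
    set.seed(seed)
    N <- length(labs)
    eps <- 1e-12
    k_pt <- k_pr <- k_rt <- 0L
    pop_of_ssp <- tapply(pop, ssp, unique, simplify = FALSE)
    pops_all <- unique(pop)
    ssp_of_pop <- setNames(ssp[!duplicated(pop)], pop[!duplicated(pop)])
    for (b in seq_len(n_perm)) {
      # Phi_PT: permute individuals among populations
      prm <- sample.int(N)
      c_pt <- amova_components(d^2, pop[prm], ssp[prm])
      if (!is.na(c_pt$phi_pt) && c_pt$phi_pt >= obs$phi_pt - eps) {
        k_pt <- k_pt + 1L
      }
      # Phi_PR: permute individuals among populations within subspecies
      pop_pr <- pop
      for (g in unique(ssp)) {
        idx <- which(ssp == g)
        pop_pr[idx] <- pop_pr[idx][sample.int(length(idx))]
      }
      c_pr <- amova_components(d^2, pop_pr, ssp)
      if (!is.na(c_pr$phi_pr) && !is.na(obs$phi_pr) &&
          c_pr$phi_pr >= obs$phi_pr - eps) {
        k_pr <- k_pr + 1L
      }
      # Phi_RT: permute whole populations among subspecies
      new_ssp_of_pop <- setNames(sample(unname(ssp_of_pop)), names(ssp_of_pop))
      c_rt <- amova_components(d^2, pop, unname(new_ssp_of_pop[pop]))
      if (!is.na(c_rt$phi_rt) && !is.na(obs$phi_rt) &&
          c_rt$phi_rt >= obs$phi_rt - eps) {
        k_rt <- k_rt + 1L
      }
    }
    phi_p <- (1 + c(k_rt, k_pr, k_pt)) / (1 + n_perm)
  }

  total_var <- obs$sigma_a + obs$sigma_b + obs$sigma_c
  tbl <- tibble::tibble(
    source = c("Among subspecies", "Among populations within subspecies",
               "Within populations", "Total"),
    df = c(obs$df_a, obs$df_b, obs$df_c, obs$df_a + obs$df_b + obs$df_c),
    SS = c(obs$ss_a, obs$ss_b, obs$ss_c, obs$ss_total),
    MS = c(obs$ms_a, obs$ms_b, obs$ms_c, NA_real_),
    variance = c(obs$sigma_a, obs$sigma_b, obs$sigma_c, total_var),
    pct = 100 * c(obs$sigma_a, obs$sigma_b, obs$sigma_c, total_var) /
      total_var)
  phi <- tibble::tibble(
    statistic = c("phi_rt", "phi_pr", "phi_pt"),
    value = c(obs$phi_rt, obs$phi_pr, obs$phi_pt),
    value_floored = c(obs$phi_rt_fl, obs$phi_pr_fl, obs$phi_pt_fl),
    p_value = phi_p)
  structure(list(table = tbl, phi = phi, n_perm = n_perm, seed = seed,
                 negative_components = any(c(obs$sigma_a, obs$sigma_b,
                                             obs$sigma_c) < 0)),
            class = "mito_amova")
}

dist_matrix_of <- function(dm) {
  d <- if (inherits(dm, "mito_dist")) dm$d else as.matrix(dm)
  if (is.null(rownames(d))) {
    abort("Distance matrix needs row/column names.",
          class = "mito_format_error")
  }
  if (any(is.na(d))) {
    abort("Distance matrix contains NA (saturated pairs?).",
          class = "mito_format_error")
  }
  if (max(abs(d - t(d))) > 1e-8) {
    abort("Distance matrix is not symmetric.", class = "mito_format_error")
  }
  d
}

# SS within a set of indices, normalised by set size
ss_within <- function(d2, idx) {
  if (length(idx) < 2L) return(0)
  sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
}

amova_components <- function(d2, pop, ssp) {
  N <- nrow(d2)
  pops <- unique(pop)
  ssps <- unique(ssp)
  P <- length(pops); G <- length(ssps)
  n_p <- table(pop); n_g <- table(ssp)
  ssp_of_pop <- setNames(ssp[!duplicated(pop)], pop[!duplicated(pop)])

  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_wp <- sum(vapply(pops, function(p) ss_within(d2, which(pop == p)),
                      numeric(1)))
  ss_wg <- sum(vapply(ssps, function(g) ss_within(d2, which(ssp == g)),
                      numeric(1)))
  ss_b <- ss_wg - ss_wp
  ss_a <- ss_total - ss_wg

  df_a <- G - 1L; df_b <- P - G; df_c <- N - P
  ms_a <- if (df_a > 0) ss_a / df_a else NA_real_
  ms_b <- if (df_b > 0) ss_b / df_b else NA_real_
  ms_c <- if (df_c > 0) ss_wp / df_c else NA_real_

  # unequal-size coefficients of the expected mean squares
  sum_np2_over_ng <- sum(vapply(ssps, function(g) {
    sum(n_p[names(ssp_of_pop)[ssp_of_pop == g]]^2) / n_g[[g]]
  }, numeric(1)))
  nprime <- if (df_b > 0) (N - sum_np2_over_ng) / df_b else NA_real_
  ndblprime <- if (df_a > 0) {
    (sum_np2_over_ng - sum(n_p^2) / N) / df_a
  } else NA_real_
  ntrpprime <- if (df_a > 0) (N - sum(n_g^2) / N) / df_a else NA_real_

  sigma_c <- ms_c
  sigma_b <- if (df_b > 0) (ms_b - sigma_c) / nprime else 0
  sigma_a <- if (df_a > 0) {
    (ms_a - sigma_c - ndblprime * sigma_b) / ntrpprime
  } else 0

  phi <- phi_from_components(sigma_a, sigma_b, sigma_c)
  fl <- phi_from_components(max(sigma_a, 0), max(sigma_b, 0),
                            max(sigma_c, 0))
  if (df_a == 0L) phi$phi_rt <- fl$phi_rt <- NA_real_
  if (df_b == 0L) phi$phi_pr <- fl$phi_pr <- NA_real_

  list(ss_total = ss_total, ss_a = ss_a, ss_b = ss_b, ss_c = ss_wp,
       df_a = df_a, df_b = df_b, df_c = df_c,
       ms_a = ms_a, ms_b = ms_b, ms_c = ms_c,
       sigma_a = sigma_a, sigma_b = sigma_b, sigma_c = sigma_c,
       phi_rt = phi$phi_rt, phi_pr = phi$phi_pr, phi_pt = phi$phi_pt,
       phi_rt_fl = fl$phi_rt, phi_pr_fl = fl$phi_pr, phi_pt_fl = fl$phi_pt)
}

phi_from_components <- function(sigma_a, sigma_b, sigma_c) {
  tot <- sigma_a + sigma_b + sigma_c
  list(phi_rt = if (tot > 0) sigma_a / tot else NA_real_,
       phi_pr = if ((sigma_b + sigma_c) != 0) {
         sigma_b / (sigma_b + sigma_c)
       } else NA_real_,
       phi_pt = if (tot > 0) (sigma_a + sigma_b) / tot else NA_real_)
}

#' Phi statistics from variance components
#'
#' Computes Phi_RT, Phi_PR and Phi_PT directly from the three variance
#' components (among subspecies, among populations within subspecies,
#' within populations), e.g. to check published AMOVA tables.
#'
#' @param sigma_a,sigma_b,sigma_c variance components.
#' @return Tibble `statistic`, `value`.
#' @export
phi_statistics <- function(sigma_a, sigma_b, sigma_c) {
  phi <- phi_from_components(sigma_a, sigma_b, sigma_c)
  tibble::tibble(statistic = c("phi_rt", "phi_pr", "phi_pt"),
                 value = c(phi$phi_rt, phi$phi_pr, phi$phi_pt))
}

#' @export
print.mito_amova <- function(x, ...) {
  cat("<mito_amova> (", x$n_perm, " permutations, seed ", x$seed, ")\n",
      sep = "")
  print(as.data.frame(x$table), row.names = FALSE, digits = 5)
  print(as.data.frame(x$phi), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @rdname amova
#' @param x a `mito_amova` object.
#' @param ... unused.
#' @export
tidy.mito_amova <- function(x, ...) x$table

#' @rdname amova
#' @export
glance.mito_amova <- function(x, ...) {
  tidyr::pivot_wider(
    dplyr::select(x$phi, "statistic", "value"),
    names_from = "statistic", values_from = "value") |>
    dplyr::mutate(n_perm = x$n_perm, seed = x$seed)
}

#' Standalone permutation test for one Phi statistic
#'
#' @inheritParams amova
#' @param statistic one of `"phi_rt"`, `"phi_pr"`, `"phi_pt"`.
#' @return Tibble with `statistic`, `observed`, `p_value`, `n_perm`.
#' @export
permutation_test <- function(dm, groups, statistic = c("phi_pt", "phi_pr",
                                                       "phi_rt"),
                             n_perm = 10000L, seed = 1L) {
  statistic <- match.arg(statistic)
  fit <- amova(dm, groups, n_perm = n_perm, seed = seed)
  row <- dplyr::filter(fit$phi, .data$statistic == !!statistic)
  tibble::tibble(statistic = statistic, observed = row$value,
                 p_value = row$p_value, n_perm = n_perm)
}

# one-level AMOVA (populations in total) for a pair or set of populations
amova_one_level <- function(d2, pop) {
  N <- nrow(d2)
  pops <- unique(pop)
  G <- length(pops)
  n_p <- table(pop)
  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_w <- sum(vapply(pops, function(p) ss_within(d2, which(pop == p)),
                     numeric(1)))
  ss_a <- ss_total - ss_w
  df_a <- G - 1L; df_w <- N - G
  ms_a <- ss_a / df_a
  ms_w <- if (df_w > 0) ss_w / df_w else 0
  n0 <- (N - sum(n_p^2) / N) / df_a
  sigma_w <- ms_w
  sigma_a <- (ms_a - ms_w) / n0
  tot <- sigma_a + sigma_w
  phi <- if (tot > 0) sigma_a / tot else NA_real_
  list(phi_pt = phi, sigma_a = sigma_a, sigma_w = sigma_w)
}

#' Pairwise population differentiation (Phi_PT matrix)
#'
#' Runs a one-level AMOVA for every pair of populations and reports
#' Phi_PT below the diagonal with the permutation p-value above it, the
#' layout of published pairwise differentiation tables. A pair in which
#' both populations are monomorphic and identical has no variance to
#' partition; its Phi_PT is reported as 0 and flagged.
#'
#' @inheritParams amova
#' @return Object of class `phi_pt_matrix`: list with `pairs` (tibble
#'   `population1`, `population2`, `phi_pt`, `p_value`, `degenerate`) and
#'   `matrix` (Phi below / p above the diagonal).
#' @export
pairwise_phi_pt <- function(dm, groups, n_perm = 999L, seed = 1L) {
  d <- dist_matrix_of(dm)
  groups <- validate_samples(groups)
  labs <- rownames(d)
  groups <- groups[match(labs, groups$sample), , drop = FALSE]
  pops <- unique(groups$population)
  if (length(pops) < 2L) {
    abort("Need at least two populations.", class = "mito_sample_error")
  }
  set.seed(seed)
  pairs <- utils::combn(pops, 2L, simplify = FALSE)
  rows <- purrr::map_dfr(pairs, function(pr) {
    idx <- which(groups$population %in% pr)
    dsub2 <- d[idx, idx]^2
    popsub <- groups$population[idx]
    degenerate <- sum(dsub2) == 0
    if (degenerate) {
      return(tibble::tibble(population1 = pr[1], population2 = pr[2],
                            phi_pt = 0, p_value = NA_real_,
                            degenerate = TRUE))
    }
    obs <- amova_one_level(dsub2, popsub)$phi_pt
    k <- 0L
    for (b in seq_len(n_perm)) {
      stat <- amova_one_level(dsub2, sample(popsub))$phi_pt
      if (!is.na(stat) && stat >= obs - 1e-12) k <- k + 1L
    }
    tibble::tibble(population1 = pr[1], population2 = pr[2],
                   phi_pt = obs, p_value = (1 + k) / (1 + n_perm),
                   degenerate = FALSE)
  })
  mat <- matrix(NA_real_, length(pops), length(pops),
                dimnames = list(pops, pops))
  for (r in seq_len(nrow(rows))) {
    i <- match(rows$population1[r], pops)
    j <- match(rows$population2[r], pops)
    mat[max(i, j), min(i, j)] <- rows$phi_pt[r]
    mat[min(i, j), max(i, j)] <- rows$p_value[r]
  }
  structure(list(pairs = rows, matrix = mat, n_perm = n_perm, seed = seed),
            class = "phi_pt_matrix")
}

#' @export
print.phi_pt_matrix <- function(x, ...) {
  cat("<phi_pt_matrix> Phi_PT below diagonal, permutation p above (",
      x$n_perm, " permutations)\n", sep = "")
  print(round(x$matrix, 3))
  invisible(x)
}

#' @rdname pairwise_phi_pt
#' @param x a `phi_pt_matrix`.
#' @param ... unused.
#' @export
tidy.phi_pt_matrix <- function(x, ...) x$pairs
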