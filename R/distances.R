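#' Pairwise sequence distances
#'
#' Computes pairwise distances between all samples under the uncorrected
#' p model and the Kimura 2-parameter (K2P) model. For each pair only
#' pairwise-complete columns are used (columns with `N`/`-` in either
#' member are excluded for that pair). Letting P and Q be the transition
#' and transversion mismatch proportions,
#' \deqn{p = P + Q, \qquad
#'       d_{K2P} = -\tfrac12 \log\big((1 - 2P - Q)\sqrt{1 - 2Q}\big).}
#' Both P and Q are retained per pair. Saturated pairs, for which the K2P
#' logarithm argument is non-positive, are flagged and reported as `NA`.
#'
#' @param aln a [mito_alignment()].
#' @param model `"p"` or `"K2P"`; selects which matrix the `d` element
#'   (and downstream consumers) use. Both are always computed.
#' @return Object of class `mito_dist`: list with `labels`, `d` (selected
#'   model), `p`, `k2p`, `P`, `Q`, `n_compared`, `model`, `saturated`
#'   (logical matrix).
#' @export
pairwise_distances <- function(aln, model = c("K2P", "p")) {
  model <- match.arg(model)
  n <- n_samples(aln)
  if (n < 2L) {
    abort("Need at least two samples for pairwise distances.",
          class = "mito_format_error")
  }
  labs <- sample_ids(aln)
  m <- unclass(aln)
  code <- matrix(match(m, BASES), nrow = n)   # NA for N/-
  purine <- matrix(code %in% c(1L, 3L), nrow = n)
  zero <- matrix(0, n, n, dimnames = list(labs, labs))
  P <- Q <- p <- k2p <- zero
  ncmp <- matrix(ncol(m), n, n, dimnames = list(labs, labs))
  sat <- matrix(FALSE, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(code[i, ]) & !is.na(code[j, ])
      nc <- sum(ok)
      if (nc == 0L) {
        abort(paste0("No comparable columns between ", labs[i], " and ",
                     labs[j], "."), class = "mito_format_error")
      }
      diff <- ok & (code[i, ] != code[j, ])
      ts <- sum(diff & (purine[i, ] == purine[j, ]))
      tv <- sum(diff) - ts
      Pij <- ts / nc; Qij <- tv / nc
      arg <- (1 - 2 * Pij - Qij) * sqrt(1 - 2 * Qij)
      P[i, j] <- P[j, i] <- Pij
      Q[i, j] <- Q[j, i] <- Qij
      p[i, j] <- p[j, i] <- Pij + Qij
      ncmp[i, j] <- ncmp[j, i] <- nc
      if (arg <= 0) {
        sat[i, j] <- sat[j, i] <- TRUE
        k2p[i, j] <- k2p[j, i] <- NA_real_
      } else {
        k2p[i, j] <- k2p[j, i] <- -0.5 * log(arg)
      }
    }
  }
  if (any(sat)) {
    warn("Saturated pair(s): K2P distance undefined, reported as NA.")
  }
  structure(list(labels = labs,
                 d = if (model == "p") p else k2p,
                 p = p, k2p = k2p, P = P, Q = Q,
                 n_compared = ncmp, model = model, saturated = sat),
            class = "mito_dist")
}

#' @export
print.mito_dist <- function(x, ...) {
  cat("<mito_dist> ", length(x$labels), " samples, model = ", x$model,
      if (any(x$saturated)) " (saturated pairs present)", "\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.mito_dist <- function(x, ...) x$d

#' @export
as.dist.mito_dist <- function(m, ...) stats::as.dist(m$d)

#' @importFrom stats as.dist
#' @export
stats::as.dist

#' Tidy a distance object into long form
#' @param x a `mito_dist`.
#' @param ... unused.
#' @return Tibble `sample1`, `sample2`, `p`, `k2p`, `P`, `Q` over unordered
#'   pairs.
#' @export
tidy.mito_dist <- function(x, ...) {
  idx <- which(upper.tri(x$p), arr.ind = TRUE)
  tibble::tibble(sample1 = x$labels[idx[, 1L]],
                 sample2 = x$labels[idx[, 2L]],
                 p = x$p[idx], k2p = x$k2p[idx],
                 P = x$P[idx], Q = x$Q[idx])
}

#' Nucleotide diversity and mean pairwise difference count
#'
#' The nucleotide diversity pi is the mean of uncorrected p distances over
#' all unordered sample pairs; multiplied by the aligned length it gives
#' the expected number of differences between two randomly chosen genomes.
#'
#' @param dm a [pairwise_distances()] object (the p matrix is used).
#' @param length aligned length in bp.
#' @return Tibble with `pi`, `length`, `mean_differences`.
#' @export
mean_pairwise_stats <- function(dm, length) {
  if (!inherits(dm, "mito_dist")) {
    abort("`dm` must be a mito_dist object.", class = "mito_format_error")
  }
  if (base::length(dm$labels) < 2L) {
    abort("Need at least two samples.", class = "mito_format_error")
  }
  pi <- mean(dm$p[upper.tri(dm$p)])
  tibble::tibble(pi = pi, length = length, mean_differences = pi * length)
}
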