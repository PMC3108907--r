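# vertebrate mitochondrial genetic code (Biostrings table id "2":
# ATA=Met, TGA=Trp, AGA/AGG=Stop; otherwise standard)
mito_code <- local({
  code <- NULL
  function() {
    if (is.null(code)) code <<- Biostrings::getGeneticCode("2")
    code
  }
})

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Stop")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")

#' Translate codons under the vertebrate mitochondrial code
#'
#' @param codons character vector of 3-letter codons over `A C G T`.
#' @return One-letter amino acids (`*` = stop); `NA` for codons containing
#'   characters other than A/C/G/T (undefined translation).
#' @export
translate_mito <- function(codons) {
  codons <- toupper(codons)
  aa <- unname(mito_code()[codons])
  aa[!codons %in% names(mito_code())] <- NA_character_
  aa
}

#' Three-letter amino acid names
#' @param aa one-letter amino acid codes (`*` = stop).
#' @return Three-letter names (`Stop` for `*`).
#' @export
aa_three <- function(aa) unname(AA3[aa])

# codon context of an alignment column inside a protein entry:
# codon index, codon position (1-3 in reading direction) and the three
# alignment columns of the codon in reading order
codon_context <- function(entry, pos) {
  if (entry$strand == "+") {
    offset <- pos - entry$frame
    if (offset < 0L) return(NULL)
    idx <- offset %/% 3L
    cols <- entry$frame + idx * 3L + 0:2
    if (cols[3L] > entry$end) return(NULL)
    list(codon_index = idx + 1L, codon_position = offset %% 3L + 1L,
         cols = cols)
  } else {
    offset <- entry$frame - pos
    if (offset < 0L) return(NULL)
    idx <- offset %/% 3L
    cols <- entry$frame - idx * 3L - c(0L, 1L, 2L)
    if (cols[3L] < entry$start) return(NULL)
    list(codon_index = idx + 1L, codon_position = offset %% 3L + 1L,
         cols = cols)
  }
}

# codon strings for a set of row sequences given reading-order columns;
# reverse-strand codons are complemented (columns are already in reading
# order, i.e. descending)
codon_strings <- function(m, cols, strand) {
  cs <- m[, cols, drop = FALSE]
  if (strand == "-") {
    cs[] <- COMPLEMENT[cs]
  }
  paste0(cs[, 1L], cs[, 2L], cs[, 3L])
}

#' Classify substitutions at protein-coding sites
#'
#' For every segregating site inside a protein partition, enumerates the
#' observed codon states, translates them under the vertebrate
#' mitochondrial code (reverse-strand loci are complemented first) and
#' classifies each minor codon against the major codon as `synonymous` or
#' `replacement`. Sites outside protein loci yield no record. Codons
#' containing `N`/`-` are flagged `undefined` rather than classified;
#' changes creating a premature stop are flagged, not dropped.
#'
#' @param aln a [mito_alignment()].
#' @param parts validated partition tibble with protein frames.
#' @param report optional [segregating_sites()] output.
#' @return Tibble with `position`, `locus`, `codon_index`,
#'   `codon_position`, `from_codon`, `to_codon`, `from_aa`, `to_aa`,
#'   `aa_change` (e.g. `"Ala > Thr"`), `class`, `n_from`, `n_to`,
#'   `premature_stop`, and list-column `carriers` (samples holding the
#'   minor codon).
#' @export
classify_substitutions <- function(aln, parts, report = NULL) {
  parts <- validate_partitions(parts, aln)
  if (is.null(report)) report <- segregating_sites(aln)
  m <- unclass(aln)
  prot <- dplyr::filter(parts, .data$class == "protein")
  out <- list()
  for (i in seq_len(nrow(prot))) {
    entry <- as.list(prot[i, ])
    span_sites <- report$position[report$position >= entry$start &
                                    report$position <= entry$end]
    for (pos in span_sites) {
      ctx <- codon_context(entry, pos)
      if (is.null(ctx)) next
      cods <- codon_strings(m, ctx$cols, entry$strand)
      defined <- !grepl("[^ACGT]", cods)
      tab <- sort(table(cods[defined]), decreasing = TRUE)
      if (length(tab) < 2L) next
      major <- names(tab)[1L]
      major_aa <- translate_mito(major)
      for (minor in names(tab)[-1L]) {
        # only pairs that actually differ at this site
        site_pos_in_codon <- ctx$codon_position
        if (substr(minor, site_pos_in_codon, site_pos_in_codon) ==
            substr(major, site_pos_in_codon, site_pos_in_codon)) next
        minor_aa <- translate_mito(minor)
        cls <- if (identical(major_aa, minor_aa)) "synonymous" else "replacement"
        out[[length(out) + 1L]] <- tibble::tibble(
          position = pos, locus = entry$locus,
          codon_index = ctx$codon_index,
          codon_position = ctx$codon_position,
          from_codon = major, to_codon = minor,
          from_aa = major_aa, to_aa = minor_aa,
          aa_change = paste(aa_three(major_aa), ">", aa_three(minor_aa)),
          class = cls,
          n_from = as.integer(tab[[major]]),
          n_to = as.integer(tab[[minor]]),
          premature_stop = identical(minor_aa, "*"),
          carriers = list(rownames(m)[defined & cods == minor]))
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(position = integer(0), locus = character(0),
                          codon_index = integer(0),
                          codon_position = integer(0),
                          from_codon = character(0), to_codon = character(0),
                          from_aa = character(0), to_aa = character(0),
                          aa_change = character(0), class = character(0),
                          n_from = integer(0), n_to = integer(0),
                          premature_stop = logical(0), carriers = list()))
  }
  dplyr::bind_rows(out)
}

#' Per-branch synonymous and replacement change counts
#'
#' Assigns ancestral states to every segregating site by deterministic
#' Fitch refinement (root takes the alphabetically lowest state of its
#' down-pass set; children keep the parent state whenever allowed), maps
#' each inferred change to its branch, and classifies protein-coding
#' changes as synonymous or replacement using the reconstructed codon on
#' either side of the branch. Sites whose ancestral assignment involved an
#' arbitrary choice are counted separately in `n_ambiguous`.
#'
#' @param tree `ape::phylo` over alignment samples (or haplotype
#'   representatives).
#' @param aln a [mito_alignment()].
#' @param parts validated partition tibble.
#' @return Tibble with one row per tree edge: `parent`, `child`,
#'   `child_label` (tip label or `NA`), `n_syn`, `n_rep`, `n_other`
#'   (non-protein changes), `n_ambiguous`. Attribute `"changes"` holds the
#'   per-change detail.
#' @export
branch_changes <- function(tree, aln, parts) {
  check_tree_tips(tree, aln, subset = TRUE)
  parts <- validate_partitions(parts, aln)
  sub <- unclass(aln)[tree$tip.label, , drop = FALSE]
  report <- segregating_sites(mito_alignment(sub))
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode

  # ancestral state per node for every segregating column
  anc <- list()
  ambig <- logical(nrow(report))
  for (k in seq_len(nrow(report))) {
    j <- report$position[k]
    fa <- fitch_ancestral(tree, setNames(sub[, j], tree$tip.label))
    anc[[as.character(j)]] <- fa
    ambig[k] <- fa$ambiguous
  }
  base_of_mask <- setNames(BASES, c(1L, 2L, 4L, 8L))
  node_base <- function(pos, node) {
    key <- as.character(pos)
    if (!is.null(anc[[key]])) {
      base_of_mask[[as.character(anc[[key]]$state[node])]]
    } else {
      sub[1L, pos]  # monomorphic (or N-only variation): take first row
    }
  }
  prot <- dplyr::filter(parts, .data$class == "protein")
  entry_of <- function(pos) {
    h <- which(prot$start <= pos & prot$end >= pos)
    if (length(h)) as.list(prot[h[1L], ]) else NULL
  }

  edge_tbl <- tibble::tibble(
    parent = tree$edge[, 1L], child = tree$edge[, 2L],
    child_label = ifelse(tree$edge[, 2L] <= ntip,
                         tree$tip.label[tree$edge[, 2L]], NA_character_),
    n_syn = 0L, n_rep = 0L, n_other = 0L, n_ambiguous = 0L)
  detail <- list()
  for (k in seq_len(nrow(report))) {
    j <- report$position[k]
    fa <- anc[[as.character(j)]]
    if (!nrow(fa$changes)) next
    entry <- entry_of(j)
    for (r in seq_len(nrow(fa$changes))) {
      pn <- fa$changes$parent[r]; cn <- fa$changes$child[r]
      e <- which(edge_tbl$parent == pn & edge_tbl$child == cn)
      if (ambig[k]) {
        edge_tbl$n_ambiguous[e] <- edge_tbl$n_ambiguous[e] + 1L
      }
      if (is.null(entry)) {
        edge_tbl$n_other[e] <- edge_tbl$n_other[e] + 1L
        cls <- "other"
      } else {
        ctx <- codon_context(entry, j)
        if (is.null(ctx)) {
          edge_tbl$n_other[e] <- edge_tbl$n_other[e] + 1L
          cls <- "other"
        } else {
          from_cod <- paste0(vapply(ctx$cols, node_base, "", node = pn),
                             collapse = "")
          to_cod <- paste0(vapply(ctx$cols, node_base, "", node = cn),
                           collapse = "")
          if (entry$strand == "-") {
            from_cod <- paste0(COMPLEMENT[strsplit(from_cod, "")[[1L]]],
                               collapse = "")
            to_cod <- paste0(COMPLEMENT[strsplit(to_cod, "")[[1L]]],
                             collapse = "")
          }
          cls <- if (identical(translate_mito(from_cod),
                               translate_mito(to_cod))) {
            "synonymous"
          } else "replacement"
          if (cls == "synonymous") {
            edge_tbl$n_syn[e] <- edge_tbl$n_syn[e] + 1L
          } else {
            edge_tbl$n_rep[e] <- edge_tbl$n_rep[e] + 1L
          }
        }
      }
      detail[[length(detail) + 1L]] <- tibble::tibble(
        position = j, parent = pn, child = cn, class = cls,
        ambiguous = ambig[k])
    }
  }
  attr(edge_tbl, "changes") <- dplyr::bind_rows(detail)
  edge_tbl
}

#' Regional excess of unique amino-acid replacements
#'
#' Tests whether one region carries more region-unique amino-acid
#' replacements, relative to its region-unique changes, than expected
#' under exchangeability. A change is unique to a region when every
#' sample carrying its minor codon belongs to that region. The statistic
#' is the focal region's unique-replacement proportion (when `region` is
#' not given, the maximum over regions); the null distribution is built by
#' permuting region labels over haplotypes (over samples when `haps` is
#' not supplied), and `p = (1 + k)/(1 + n_perm)`.
#'
#' @param changes output of [classify_substitutions()].
#' @param groups sample table (`sample`, `subspecies`, `population`).
#' @param haps optional [collapse_haplotypes()] table; if supplied, the
#'   permutation unit is the haplotype.
#' @param level grouping column used as "region": `"population"` or
#'   `"subspecies"`.
#' @param region optional focal region; default: region with the highest
#'   observed proportion (the permutation statistic is then the maximum
#'   over regions).
#' @param n_perm permutations.
#' @param seed integer seed.
#' @return Object of class `replacement_excess`: list with `regions`
#'   (region, n_unique_changes, n_unique_replacements, proportion,
#'   excluded), `grand_mean`, `region`, `observed`, `p_value`, `n_perm`,
#'   `seed`.
#' @export
replacement_excess_test <- function(changes, groups, haps = NULL,
                                    level = c("population", "subspecies"),
                                    region = NULL, n_perm = 10000L,
                                    seed = 1L) {
  level <- match.arg(level)
  groups <- validate_samples(groups)
  if (!nrow(changes) || !any(changes$class == "replacement")) {
    abort("Need at least one replacement change.", class = "mito_config_error")
  }
  region_of_sample <- setNames(groups[[level]], groups$sample)
  regions <- sort(unique(groups[[level]]))
  if (length(regions) < 2L) {
    abort("Need at least two regions.", class = "mito_config_error")
  }
  carriers <- changes$carriers
  is_rep <- changes$class == "replacement"

  region_stats <- function(rmap) {
    # rmap: sample -> region
    uniq_region <- vapply(carriers, function(cs) {
      rs <- unique(unname(rmap[cs]))
      if (length(rs) == 1L) rs else NA_character_
    }, character(1))
    U <- vapply(regions, function(r) sum(uniq_region == r, na.rm = TRUE),
                numeric(1))
    R <- vapply(regions, function(r) {
      sum(uniq_region == r & is_rep, na.rm = TRUE)
    }, numeric(1))
    prop <- ifelse(U > 0, R / U, NA_real_)
    list(U = U, R = R, prop = prop)
  }

  obs <- region_stats(region_of_sample)
  if (is.null(region)) {
    focal <- regions[which.max(obs$prop)]
    obs_stat <- max(obs$prop, na.rm = TRUE)
    perm_stat <- function(st) suppressWarnings(max(st$prop, na.rm = TRUE))
  } else {
    focal <- region
    obs_stat <- obs$prop[[match(region, regions)]]
    perm_stat <- function(st) st$prop[[match(region, regions)]]
  }

  # permutation units
  if (!is.null(haps)) {
    unit_of_sample <- setNames(haps$haplotype, haps$sample)
  } else {
    unit_of_sample <- setNames(groups$sample, groups$sample)
  }
  units <- unique(unname(unit_of_sample))
  unit_region <- vapply(units, function(u) {
    region_of_sample[[names(unit_of_sample)[unit_of_sample == u][1L]]]
  }, character(1))

  set.seed(seed)
  k <- 0L
  for (b in seq_len(n_perm)) {
    perm_unit_region <- setNames(sample(unit_region), units)
    rmap <- setNames(unname(perm_unit_region[unit_of_sample[groups$sample]]),
                     groups$sample)
    st <- perm_stat(region_stats(rmap))
    if (!is.na(st) && st >= obs_stat - 1e-12) k <- k + 1L
  }
  structure(list(
    regions = tibble::tibble(region = regions,
                             n_unique_changes = as.integer(obs$U),
                             n_unique_replacements = as.integer(obs$R),
                             proportion = obs$prop,
                             excluded = obs$U == 0),
    grand_mean = mean(obs$prop, na.rm = TRUE),
    region = focal, observed = obs_stat,
    p_value = (1 + k) / (1 + n_perm),
    n_perm = n_perm, seed = seed),
    class = "replacement_excess")
}

#' @export
print.replacement_excess <- function(x, ...) {
  cat("<replacement_excess> focal region: ", x$region,
      ", proportion ", round(x$observed, 3),
      " (grand mean ", round(x$grand_mean, 3), "), p = ",
      signif(x$p_value, 3), "\n", sep = "")
  print(as.data.frame(x$regions), row.names = FALSE)
  invisible(x)
}

#' @rdname replacement_excess_test
#' @param x a `replacement_excess` object.
#' @param ... unused.
#' @export
tidy.replacement_excess <- function(x, ...) x$regions

#' @rdname replacement_excess_test
#' @export
glance.replacement_excess <- function(x, ...) {
  tibble::tibble(region = x$region, observed = x$observed,
                 grand_mean = x$grand_mean, p_value = x$p_value,
                 n_perm = x$n_perm, seed = x$seed)
}
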