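#' Collapse samples into haplotypes
#'
#' Samples with identical sequences share a haplotype. Identity is exact
#' over all columns (the supported alphabet is unambiguous apart from `N`,
#' which is compared literally; deposited mitogenome haplotypes carry no
#' ambiguity, and literal comparison keeps the relation transitive).
#'
#' @param aln a [mito_alignment()].
#' @return A tibble of class `haplotype_table` with columns `sample`,
#'   `haplotype` (H01, H02, ... in order of first occurrence); attribute
#'   `representative` maps each haplotype to the row index of its first
#'   carrier.
#' @export
collapse_haplotypes <- function(aln) {
  keys <- seq_strings(aln)
  first <- !duplicated(keys)
  hap_ids <- setNames(sprintf("H%02d", seq_len(sum(first))), keys[first])
  out <- tibble::tibble(sample = sample_ids(aln),
                        haplotype = unname(hap_ids[keys]))
  attr(out, "representative") <- setNames(which(first), hap_ids)
  class(out) <- c("haplotype_table", class(out))
  out
}

#' Haplotype frequencies
#' @param haps a [collapse_haplotypes()] table.
#' @return Tibble `haplotype`, `n`.
#' @export
haplotype_frequencies <- function(haps) {
  dplyr::count(tibble::as_tibble(haps), .data$haplotype, name = "n")
}

# per-column counts of A/C/G/T over genomes (N and - excluded)
base_counts <- function(aln) {
  m <- unclass(aln)
  counts <- vapply(BASES, function(b) colSums(m == b), numeric(ncol(m)))
  if (is.null(dim(counts))) {
    counts <- matrix(counts, nrow = 1L, dimnames = list(NULL, BASES))
  }
  counts
}

#' Identify and classify segregating sites
#'
#' Lists every polymorphic column (two or more of A/C/G/T observed; columns
#' whose only variation involves `N`/`-` are not segregating) and classifies
#' each as `singleton` — the minor state found in exactly one genome — or
#' `shared` — found in two or more genomes. Both the genome-level and the
#' haplotype-level carrier counts of the minor state are reported, since
#' published counts phrase singletons at the genome level and sharing at the
#' haplotype level.
#'
#' @param aln a [mito_alignment()].
#' @param haps optional [collapse_haplotypes()] table (computed if absent).
#' @return Tibble with columns `position`, `states` (e.g. `"A/G"`),
#'   `n_states`, `major_state`, `minor_genomes`, `minor_haplotypes`,
#'   `classification`.
#' @export
segregating_sites <- function(aln, haps = NULL) {
  if (is.null(haps)) haps <- collapse_haplotypes(aln)
  counts <- base_counts(aln)   # L x 4
  n_states <- rowSums(counts > 0)
  poly <- which(n_states >= 2L)
  if (!length(poly)) {
    return(tibble::tibble(position = integer(0), states = character(0),
                          n_states = integer(0), major_state = character(0),
                          minor_genomes = integer(0),
                          minor_haplotypes = integer(0),
                          classification = character(0)))
  }
  hap_of <- haps$haplotype
  m <- unclass(aln)
  purrr::map_dfr(poly, function(j) {
    cnt <- counts[j, ]
    present <- which(cnt > 0)
    major <- present[which.max(cnt[present])]
    minors <- setdiff(present, major)
    minor_counts <- cnt[minors]
    carrier <- m[, j] %in% BASES[minors]
    tibble::tibble(
      position = j,
      states = paste(BASES[present], collapse = "/"),
      n_states = length(present),
      major_state = BASES[major],
      minor_genomes = as.integer(sum(minor_counts)),
      minor_haplotypes = length(unique(hap_of[carrier])),
      classification = if (all(minor_counts == 1L)) "singleton" else "shared")
  })
}

#' Per-partition segregating-site densities
#'
#' Counts segregating sites falling within each partition class, divides by
#' the class length, and appends a genome-wide total. Columns covered by no
#' partition entry are assigned to class `other` (never dropped); a column
#' covered by entries of several classes (e.g. a D-loop amplicon
#' overlapping tRNA) is counted in each.
#'
#' @param aln a [mito_alignment()].
#' @param parts validated partition tibble.
#' @param report optional [segregating_sites()] output (computed if absent).
#' @return Tibble with `class`, `n_sites`, `length`, `density` (= S/L).
#' @export
partition_density <- function(aln, parts, report = NULL) {
  parts <- validate_partitions(parts, aln)
  if (is.null(report)) report <- segregating_sites(aln)
  membership <- class_membership(parts, aln_length(aln))
  lens <- rowSums(membership)
  out <- purrr::map_dfr(PARTITION_CLASSES, function(cl) {
    tibble::tibble(class = cl,
                   n_sites = sum(membership[cl, report$position]),
                   length = as.integer(lens[[cl]]))
  })
  out <- dplyr::filter(out, .data$length > 0L)
  out <- dplyr::bind_rows(out, tibble::tibble(
    class = "genome", n_sites = nrow(report),
    length = aln_length(aln)))
  dplyr::mutate(out, density = .data$n_sites / .data$length)
}
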