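#' Sample metadata tables
#'
#' A sample table records the two-level grouping hierarchy used throughout:
#' each sample belongs to one population, and each population is nested in
#' exactly one subspecies. Columns: `sample`, `subspecies`, `population`.
#'
#' @param tbl data frame with columns `sample`, `subspecies`, `population`.
#' @param aln optional [mito_alignment()]; if supplied, every alignment
#'   sample must appear exactly once.
#' @return Validated tibble.
#' @export
validate_samples <- function(tbl, aln = NULL) {
  tbl <- tibble::as_tibble(tbl)
  req <- c("sample", "subspecies", "population")
  if (!all(req %in% names(tbl))) {
    abort(paste0("Sample table must have columns: ", paste(req, collapse = ", ")),
          class = "mito_format_error")
  }
  tbl <- dplyr::mutate(tbl, dplyr::across(dplyr::all_of(req), as.character))
  if (anyDuplicated(tbl$sample)) {
    abort("Duplicated sample IDs in sample table.",
          class = "mito_sample_error")
  }
  nesting <- dplyr::distinct(tbl, .data$population, .data$subspecies)
  if (anyDuplicated(nesting$population)) {
    dup <- nesting$population[duplicated(nesting$population)]
    abort(paste0("Population(s) listed under more than one subspecies: ",
                 paste(unique(dup), collapse = ", ")),
          class = "mito_sample_error")
  }
  if (!is.null(aln)) {
    missing <- setdiff(sample_ids(aln), tbl$sample)
    if (length(missing)) {
      abort(paste0("Alignment samples absent from sample table: ",
                   paste(head(missing, 5), collapse = ", ")),
            class = "mito_sample_error")
    }
  }
  tbl
}

#' Read a sample metadata table (TSV)
#'
#' @param path tab-delimited file with header columns `sample`,
#'   `subspecies`, `population`.
#' @inheritParams validate_samples
#' @return Validated tibble.
#' @export
read_sample_table <- function(path, aln = NULL) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         progress = FALSE, comment = "#")
  validate_samples(tbl, aln)
}

#' Fisher study sample metadata
#'
#' The 40-sample collection table of the fisher mitogenome study
#' (sample, subspecies, geographic population, GenBank accession), shipped
#' as a plain-text fixture. The 40 samples collapse to 15 distinct
#' accessions.
#'
#' @return Tibble with columns `sample`, `subspecies`, `population`,
#'   `accession`.
#' @export
fisher_samples <- function() {
  path <- system.file("extdata", "fisher_samples.tsv", package = "mitolineage")
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
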