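#' Alignment container
#'
#' A `mito_alignment` is a character matrix of aligned nucleotides with one
#' row per sample (row names are sample IDs) and one column per aligned
#' position (1-based). The alphabet is restricted to `A C G T N -`;
#' IUPAC ambiguity codes other than `N` are rejected rather than coerced,
#' so fixture bugs surface instead of being silently masked.
#'
#' @param mat character matrix of single characters, with unique row names.
#' @return An object of class `mito_alignment`.
#' @export
mito_alignment <- function(mat) {
  if (!is.matrix(mat) || !is.character(mat)) {
    abort("`mat` must be a character matrix.", class = "mito_format_error")
  }
  if (ncol(mat) < 1L || nrow(mat) < 1L) {
    abort("Alignment must have at least one sample and one column.",
          class = "mito_format_error")
  }
  ids <- rownames(mat)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids))) {
    abort("Sample IDs (row names) must be present and unique.",
          class = "mito_format_error")
  }
  mat[] <- toupper(mat)
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad)) {
    abort(paste0("Disallowed characters in alignment: ",
                 paste(bad, collapse = ", "),
                 " (only A/C/G/T/N/- are accepted)."),
          class = "mito_alphabet_error")
  }
  structure(mat, class = c("mito_alignment", "matrix", "array"))
}

#' @export
print.mito_alignment <- function(x, ...) {
  cat("<mito_alignment> ", nrow(x), " samples x ", ncol(x), " columns\n",
      sep = "")
  cat("samples: ", paste(head(rownames(x), 6), collapse = ", "),
      if (nrow(x) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

n_samples <- function(aln) nrow(aln)
aln_length <- function(aln) ncol(aln)
sample_ids <- function(aln) rownames(aln)

seq_strings <- function(aln) {
  apply(unclass(aln), 1L, paste0, collapse = "")
}

#' Read a FASTA alignment
#'
#' Reads an aligned multi-FASTA file into a [mito_alignment()]. Record order
#' is preserved and sequences are uppercased. Ragged record lengths,
#' duplicated identifiers, empty files and ambiguity characters other than
#' `N` are errors.
#'
#' @param path path to a FASTA file.
#' @return A `mito_alignment`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "mito_format_error")
  }
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) {
                   abort(paste0("Could not parse FASTA: ", conditionMessage(e)),
                         class = "mito_format_error")
                 })
  if (length(ss) == 0L) {
    abort("FASTA file contains no records.", class = "mito_format_error")
  }
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    abort("Duplicate sequence identifiers in FASTA.",
          class = "mito_format_error")
  }
  lens <- Biostrings::width(ss)
  if (length(unique(lens)) != 1L) {
    abort(paste0("Sequences have unequal lengths (",
                 paste(range(lens), collapse = "-"),
                 "); input must be aligned."),
          class = "mito_alignment_error")
  }
  if (lens[1] == 0L) {
    abort("Zero-length sequences.", class = "mito_format_error")
  }
  mat <- do.call(rbind, strsplit(toupper(as.character(ss)), "", fixed = TRUE))
  rownames(mat) <- ids
  mito_alignment(mat)
}

#' Write a FASTA alignment
#'
#' @param aln a [mito_alignment()].
#' @param path output path.
#' @param width characters per sequence line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path, width = 70L) {
  seqs <- seq_strings(aln)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
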