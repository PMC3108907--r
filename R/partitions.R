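#' Partition tables
#'
#' A partition table assigns aligned columns to loci and functional classes.
#' It is a tibble with columns `locus`, `class` (one of `protein`, `rRNA`,
#' `tRNA`, `dloop`, `other`), `start`, `end` (1-based, inclusive, on the
#' aligned matrix), `frame` (for protein loci: the alignment column of the
#' first codon position; `NA` otherwise) and `strand` (`"+"` or `"-"`;
#' reverse-strand loci such as ND6 are reverse-complemented before
#' translation). Entries of different classes may overlap (the D-loop
#' amplicon typically overlaps tRNA-Pro/tRNA-Thr); entries within one class
#' may not.
#'
#' @name partition-table
NULL

PARTITION_CLASSES <- c("protein", "rRNA", "tRNA", "dloop", "other")

#' Validate a partition table against an alignment
#'
#' @param parts a data frame with columns `locus`, `class`, `start`, `end`,
#'   and optionally `frame` and `strand`.
#' @param aln a [mito_alignment()] (or an integer alignment length).
#' @return The validated partition tibble.
#' @export
validate_partitions <- function(parts, aln) {
  L <- if (inherits(aln, "mito_alignment")) aln_length(aln) else as.integer(aln)
  parts <- tibble::as_tibble(parts)
  req <- c("locus", "class", "start", "end")
  if (!all(req %in% names(parts))) {
    abort(paste0("Partition table must have columns: ",
                 paste(req, collapse = ", ")),
          class = "mito_format_error")
  }
  if (!"frame" %in% names(parts)) parts$frame <- NA_integer_
  if (!"strand" %in% names(parts)) parts$strand <- "+"
  parts <- dplyr::mutate(parts,
    start = as.integer(.data$start), end = as.integer(.data$end),
    frame = as.integer(.data$frame),
    strand = dplyr::coalesce(as.character(.data$strand), "+"))

  bad_class <- setdiff(unique(parts$class), PARTITION_CLASSES)
  if (length(bad_class)) {
    abort(paste0("Unknown partition class: ", paste(bad_class, collapse = ", ")),
          class = "mito_partition_error")
  }
  if (any(parts$end < parts$start)) {
    abort("Partition entries with end < start.", class = "mito_partition_error")
  }
  if (any(parts$start < 1L) || any(parts$end > L)) {
    abort(paste0("Partition coordinates outside 1..", L, "."),
          class = "mito_partition_error")
  }
  if (!all(parts$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'.", class = "mito_partition_error")
  }
  # protein entries: frame inside the span, span codon-complete after the
  # frame offset is honored (reading direction depends on strand)
  pr <- dplyr::filter(parts, .data$class == "protein")
  if (nrow(pr)) {
    if (any(is.na(pr$frame))) {
      abort("Protein entries require a frame column.",
            class = "mito_partition_error")
    }
    fwd <- pr$strand == "+"
    ok_frame <- ifelse(fwd,
      pr$frame >= pr$start & pr$frame <= pr$start + 2L,
      pr$frame <= pr$end & pr$frame >= pr$end - 2L)
    span <- ifelse(fwd, pr$end - pr$frame + 1L, pr$frame - pr$start + 1L)
    if (any(!ok_frame) || any(span %% 3L != 0L)) {
      abort("Protein partition not codon-complete for its frame/strand.",
            class = "mito_partition_error")
    }
  }
  # no overlap within a class
  by_class <- split(parts, parts$class)
  for (p in by_class) {
    p <- p[order(p$start), , drop = FALSE]
    if (nrow(p) > 1L && any(p$start[-1L] <= p$end[-nrow(p)])) {
      abort(paste0("Overlapping entries within class '", p$class[1], "'."),
            class = "mito_partition_error")
    }
  }
  parts
}

#' Read a partition table (TSV)
#'
#' @inheritParams validate_partitions
#' @param path path to a tab-delimited file with a header row and columns
#'   `locus`, `class`, `start`, `end`, `frame` (and optionally `strand`).
#' @return A validated partition tibble.
#' @export
read_partition_table <- function(path, aln) {
  parts <- readr::read_tsv(path, show_col_types = FALSE,
                           progress = FALSE, comment = "#")
  validate_partitions(parts, aln)
}

#' Write a partition table (TSV)
#' @param parts partition tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition_table <- function(parts, path) {
  readr::write_tsv(parts, path, progress = FALSE)
  invisible(path)
}

# logical membership matrix: classes x columns (a column can belong to
# several classes because the D-loop amplicon may overlap tRNA entries)
class_membership <- function(parts, L) {
  m <- matrix(FALSE, nrow = length(PARTITION_CLASSES), ncol = L,
              dimnames = list(PARTITION_CLASSES, NULL))
  for (i in seq_len(nrow(parts))) {
    m[parts$class[i], parts$start[i]:parts$end[i]] <- TRUE
  }
  # uncovered columns fall in "other" (never dropped)
  m["other", !colSums(m) > 0] <- TRUE
  m
}

# per-class length: covered columns per class, plus implicit "other"
class_lengths <- function(parts, L) {
  m <- class_membership(parts, L)
  rowSums(m)
}

#' Locate a genomic position within its locus
#'
#' Returns the locus name and 1-based within-locus position for alignment
#' columns, preferring gene entries over the D-loop amplicon when spans
#' overlap (matching how published variant tables label such sites).
#'
#' @param parts validated partition tibble.
#' @param positions integer vector of alignment columns.
#' @return Tibble with `position`, `locus`, `class`, `locus_position`.
#' @export
locate_positions <- function(parts, positions) {
  pref <- c(protein = 1L, rRNA = 2L, tRNA = 3L, other = 4L, dloop = 5L)
  parts <- parts[order(pref[parts$class]), , drop = FALSE]
  purrr::map_dfr(positions, function(pos) {
    hit <- which(parts$start <= pos & parts$end >= pos)
    if (!length(hit)) {
      return(tibble::tibble(position = pos, locus = "intergenic",
                            class = "other", locus_position = NA_integer_))
    }
    h <- hit[1L]
    tibble::tibble(position = pos, locus = parts$locus[h],
                   class = parts$class[h],
                   locus_position = pos - parts$start[h] + 1L)
  })
}
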