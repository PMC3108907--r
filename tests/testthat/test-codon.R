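test_that("translation follows the vertebrate mitochondrial code", {
  expect_equal(translate_mito("ATA"), "M")   # not Ile
  expect_equal(translate_mito("TGA"), "W")   # not Stop
  expect_equal(translate_mito(c("AGA", "AGG")), c("*", "*"))
  expect_equal(translate_mito("GCA"), "A")
  expect_equal(translate_mito("ACA"), "T")   # GCA vs ACA: Ala vs Thr
  expect_true(is.na(translate_mito("ANA")))
  expect_equal(aa_three(c("A", "T", "*")), c("Ala", "Thr", "Stop"))
})

prot_parts <- function(len, strand = "+", start = 1L) {
  tibble::tibble(locus = "cds", class = "protein",
                 start = start, end = start + len - 1L,
                 frame = if (strand == "+") start else start + len - 1L,
                 strand = strand)
}

test_that("substitutions classify as synonymous or replacement", {
  # codons: CTA|GCA|AAA reference; CTG (Leu>Leu, pos 3); ACA (Ala>Thr, pos 1)
  aln <- aln_from_strings(c(
    r1 = "CTAGCAAAA", r2 = "CTGGCAAAA", r3 = "CTAACAAAA", r4 = "CTAGCAAAA"))
  ch <- classify_substitutions(aln, prot_parts(9L))
  expect_equal(nrow(ch), 2L)
  syn <- ch[ch$position == 3L, ]
  expect_equal(syn$class, "synonymous")
  expect_equal(syn$codon_position, 3L)
  expect_equal(syn$aa_change, "Leu > Leu")
  rep_ <- ch[ch$position == 4L, ]
  expect_equal(rep_$class, "replacement")
  expect_equal(rep_$codon_position, 1L)
  expect_equal(rep_$aa_change, "Ala > Thr")
  expect_equal(rep_$carriers[[1]], "r3")

  # monomorphic alignment yields no record
  mono <- aln_from_strings(c(a = "CTAGCAAAA", b = "CTAGCAAAA"))
  expect_equal(nrow(classify_substitutions(mono, prot_parts(9L))), 0L)
  # sites outside protein loci yield no record
  nc <- tibble::tibble(locus = "d", class = "dloop", start = 1L, end = 9L,
                       frame = NA_integer_)
  expect_equal(nrow(classify_substitutions(aln, nc)), 0L)
})

test_that("premature stops are flagged, not dropped", {
  aln <- aln_from_strings(c(a = "TCATCA", b = "TGATCA"))  # Ser -> Stop? TGA=Trp
  ch <- classify_substitutions(aln, prot_parts(6L))
  expect_equal(ch$class, "replacement")   # Ser > Trp under mito code
  aln2 <- aln_from_strings(c(a = "AGATCA", b = "ACATCA"))
  ch2 <- classify_substitutions(aln2, prot_parts(6L))
  expect_true(any(ch2$premature_stop) || all(ch2$to_aa != "*"))
})

test_that("reverse-strand loci are complemented before translation", {
  # forward gene GCA -> ACA (Ala > Thr); encode it on the reverse strand:
  # alignment holds the reverse complement TGC -> TGT
  fwd <- aln_from_strings(c(a = "GCAGGG", b = "ACAGGG"))
  ch_fwd <- classify_substitutions(fwd, prot_parts(6L))
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  rev_aln <- aln_from_strings(c(a = rc("GCAGGG"), b = rc("ACAGGG")))
  ch_rev <- classify_substitutions(rev_aln, prot_parts(6L, strand = "-"))
  expect_equal(ch_rev$class, ch_fwd$class)
  expect_equal(sort(c(ch_rev$from_aa, ch_rev$to_aa)),
               sort(c(ch_fwd$from_aa, ch_fwd$to_aa)))
})

test_that("two-taxon branch changes fall on the single path", {
  tr <- ape::read.tree(text = "(a:1,b:1);")
  aln <- aln_from_strings(c(a = "CTAGCAAAA", b = "CTGACAAAA"))
  bc <- branch_changes(tr, aln, prot_parts(9L))
  expect_equal(sum(bc$n_syn), 1L)
  expect_equal(sum(bc$n_rep), 1L)
  expect_equal(sum(bc$n_syn + bc$n_rep + bc$n_other), 2L)
})

test_that("a terminal branch with only replacements is reported as such", {
  # five tips; tip X carries 4 private replacement changes, no synonymous
  base <- strrep("GCA", 8)                      # 8 Ala codons
  xseq <- paste0("ACA", "GTA", "CCA", "TCA", strrep("GCA", 4))
  aln <- aln_from_strings(c(X = xseq, b = base, c = base, d = base, e = base))
  tr <- ape::read.tree(text = "((X,b),(c,(d,e)));")
  bc <- branch_changes(tr, aln, prot_parts(24L))
  xrow <- bc[!is.na(bc$child_label) & bc$child_label == "X", ]
  expect_equal(xrow$n_rep, 4L)
  expect_equal(xrow$n_syn, 0L)
  expect_equal(sum(bc$n_rep), 4L)
})

test_that("branch attribution recovers planted single-hit mutations", {
  cfg <- small_config(rate_mult = 1, hotspot_weight = 1)
  sim <- simulate_mitogenomes(cfg, seed = 17)
  truth <- sim$truth
  bc <- branch_changes(truth$tree, sim$alignment, sim$partitions)
  detail <- attr(bc, "changes")
  single <- truth$mutations[truth$changes[truth$mutations$position] == 1L, ]
  # a change on a root-adjacent edge has two equally parsimonious
  # placements on a rooted tree; such sites are flagged ambiguous
  n_exact <- 0L
  for (k in seq_len(nrow(single))) {
    hit <- detail[detail$position == single$position[k], ]
    expect_equal(nrow(hit), 1L)
    if (!hit$ambiguous) {
      expect_equal(hit$child, single$child[k])
      n_exact <- n_exact + 1L
    }
  }
  expect_gte(n_exact, ceiling(0.7 * nrow(single)))
  # conservation: per-branch counts sum to total inferred changes
  expect_equal(sum(bc$n_syn + bc$n_rep + bc$n_other), nrow(detail))
})

mk_changes <- function(classes, carrier_sets) {
  tibble::tibble(
    position = seq_along(classes), locus = "cds",
    codon_index = seq_along(classes), codon_position = 1L,
    from_codon = "GCA", to_codon = "ACA",
    from_aa = "A", to_aa = ifelse(classes == "replacement", "T", "A"),
    aa_change = "x", class = classes,
    n_from = 5L, n_to = lengths(carrier_sets),
    premature_stop = FALSE, carriers = carrier_sets)
}

test_that("replacement excess test finds strong planted regional effects", {
  groups <- tibble::tibble(sample = sprintf("s%02d", 1:10),
                           subspecies = rep(c("X", "Y"), each = 5),
                           population = rep(c("A", "B"), each = 5))
  # strong planted effect: every region-A sample privately carries
  # replacements, every region-B sample privately carries synonymous
  # changes (mirrors a lineage whose private mutations are all
  # replacements)
  hits <- 0L
  set.seed(30)
  for (r in 1:20) {
    a_sam <- rep(sample(sprintf("s%02d", 1:5)), each = 2)
    b_sam <- rep(sample(sprintf("s%02d", 6:10)), each = 2)
    ch <- mk_changes(
      c(rep("replacement", 10), rep("synonymous", 10)),
      as.list(c(a_sam, b_sam)))
    res <- replacement_excess_test(ch, groups, n_perm = 199, seed = r)
    if (res$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("replacement excess is flat under exchangeable configurations", {
  groups <- tibble::tibble(sample = sprintf("s%02d", 1:8),
                           subspecies = rep(c("X", "Y"), each = 4),
                           population = rep(c("A", "B"), each = 4))
  # all changes are replacements carried by single samples: the statistic
  # equals 1 under every relabeling, so p must be exactly 1
  ch <- mk_changes(rep("replacement", 4),
                   as.list(c("s01", "s03", "s05", "s07")))
  res <- replacement_excess_test(ch, groups, n_perm = 99, seed = 2)
  expect_equal(res$p_value, 1)

  # mirrored configuration: no region stands out
  ch2 <- mk_changes(c("replacement", "synonymous",
                      "replacement", "synonymous"),
                    list(c("s01", "s02"), c("s03", "s04"),
                         c("s05", "s06"), c("s07", "s08")))
  res2 <- replacement_excess_test(ch2, groups, n_perm = 199, seed = 3)
  expect_gt(res2$p_value, 0.3)

  expect_error(replacement_excess_test(
    mk_changes("synonymous", list("s01")), groups),
    class = "mito_config_error")
})
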