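# mitolineage

Population-level analysis of complete mitochondrial genome alignments, built
for conservation-genetics questions about maternal lineages: how much
variation a genome partition carries, how that variation is structured across
a subspecies/population hierarchy, whether a short genotyping amplicon (the
D-loop) tells the same genealogical story as the full genome, and how much
whole-genome data sharpen divergence-date estimates.

The motivating setting is a threatened carnivore with very low mitogenomic
diversity, where recurrent (homoplasious) mutation in the hypervariable
D-loop can mask exactly the lineages of greatest conservation concern. The
package provides every analysis stage as a tidyverse-style function (data
frames in, tibbles out), plus a simulator that generates alignments with
known truth so the whole pipeline is testable end to end.

## What it computes

* **Diversity** — haplotype collapsing; segregating sites S with
  shared/singleton classification; per-partition densities S/L for protein,
  rRNA, tRNA, D-loop and other columns; nucleotide diversity
  π = mean pairwise p-distance, and π × L mean genome differences.
* **Distances** — p and Kimura 2-parameter distances with per-pair
  transition (P) and transversion (Q) proportions retained:
  d = −½ ln((1 − 2P − Q)·√(1 − 2Q)).
* **AMOVA** — hierarchical variance decomposition of squared distances with
  unequal-size coefficients, variance components σ²a, σ²b, σ²c,
  Φ_RT = σ²a/σ²T, Φ_PR = σ²b/(σ²b+σ²c), Φ_PT = (σ²a+σ²b)/σ²T, permutation
  p-values per statistic (individuals among populations, individuals within
  subspecies, whole populations among subspecies), and a pairwise Φ_PT
  matrix (Φ below the diagonal, p above).
* **Genealogy & homoplasy** — neighbor-joining surrogate trees, monophyly
  tests, Robinson–Foulds conflict between partition trees, and per-site
  Fitch parsimony indices: observed steps s, minimum m, star-tree maximum
  g, CI = m/s, HI = 1 − CI, RI = (g−s)/(g−m) (RI := 1 when g = m),
  RC = CI·RI.
* **Codon-level change** — translation under the vertebrate mitochondrial
  code (ATA = Met, TGA = Trp, AGA/AGG = Stop), synonymous vs replacement
  classification (reverse-strand loci complemented first), per-branch
  syn/rep counts from Fitch ancestral states, and a permutation test for a
  regional excess of region-unique replacements.
* **Divergence clock** — waiting times t = 1/(rL) from per-species
  third-codon rates, closed-form lognormal MLE (μ, σ of ln t), point
  estimate from the mode exp(μ − σ²), interval from the fitted 2.5%/97.5%
  quantiles, and divergence dates T = k × mode for k synonymous
  differences.
* **Simulator** — hierarchical coalescent-style genealogies, Poisson
  mutation placement with per-class rates, a κ-weighted
  transition/transversion kernel, recurrent-mutation hotspots, and a full
  truth record (per-branch per-column mutation log).

## Worked example

A deterministic fixture with the study-scale structure (40 samples,
16,290 bp, 66 segregating sites split 47 singleton / 19 shared):

```r
library(mitolineage)

aln <- make_fixture()
partition_density(aln, default_partitions())
#> # A tibble: 6 × 4
#>   class   n_sites length density
#> 1 protein      42  11397 0.00369
#> 2 rRNA          9   2528 0.00356
#> 3 tRNA          2   1515 0.00132
#> 4 dloop        10    299 0.0334
#> 5 other         3    551 0.00544
#> 6 genome       66  16290 0.00405
```

The D-loop carries roughly nine-fold more variation per site than the
protein fraction (0.0334 vs 0.00369) — yet it is only 299 bp, which is why
D-loop-only genotyping resolves so little. The 40-sample study metadata
(`fisher_samples()`) collapse to 15 haplotypes:

```r
fix <- synthetic_fisher_alignment()
dplyr::n_distinct(collapse_haplotypes(fix$alignment)$haplotype)
#> [1] 15
```

The clock module, reconstructing a published cytochrome-b fit from its
interval endpoints and rescaling from 379 to 3,796 third-codon sites:

```r
fit <- fit_from_quantiles(50115, 173914, sites = 379)
mode_and_ci(fit)
#> # A tibble: 1 × 3
#>     mode  q025    q975
#> 1 84410. 50115 173914.
mode_and_ci(fit)$mode * 379 / 3796
#> [1] 8427.7
```

One expected synonymous substitution every ~84 ky at gene scale becomes one
every ~8.4 ky at genome scale: a ten-fold gain in dating resolution from
sequencing the whole organelle.

A full simulated study, end to end:

```r
sim <- simulate_mitogenomes(sim_config(), seed = 1)
dm  <- pairwise_distances(sim$alignment)           # K2P + p, P, Q retained
mean_pairwise_stats(dm, 16290)                     # pi and mean differences
fit <- amova(dm, sim$samples, n_perm = 999, seed = 1)
glance(fit)                                        # Phi_RT, Phi_PR, Phi_PT
tree <- nj_tree(dm)
site_indices(tree, sim$alignment, sim$partitions)  # per-site CI/HI/RI/RC
```

`run_pipeline()` chains all stages and writes tab-delimited reports (a
variance table, the pairwise Φ matrix, a per-site homoplasy table, codon
changes, clock fits) plus a run log; `inst/cli/mitolineage.R` is a thin
Rscript wrapper around it.

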