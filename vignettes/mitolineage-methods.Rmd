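---
title: "Methods: mitogenome matrilineage analysis in mitolineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitogenome matrilineage analysis in mitolineage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitolineage)
```

# The problem

Mitochondrial haplotyping in wildlife conservation has historically leaned
on a short hypervariable amplicon, the displacement (D) loop. Its high
mutation rate is a double-edged sword: it generates the polymorphism that
makes genotyping cheap, but the same rate drives *recurrent* mutation —
the same nucleotide state arising independently on unrelated lineages — and
in taxa with very low overall mitogenomic divergence that homoplasy can
erase or fabricate haplotype identities. `mitolineage` implements the full
chain of analyses needed to quantify this: partitioned diversity, distance-
based population structure (AMOVA), genealogy comparison between genome
partitions, per-site homoplasy indices, codon-level replacement analysis,
and a waiting-time model for how genome scale improves divergence dating.
Every stage runs on synthetic data with known truth, so each claim the
package makes is testable without any sequence download.

# Diversity statistics

**Haplotypes.** Samples with identical sequences share a haplotype.
Identity is literal over the full alphabet `A C G T N -`; we deliberately
reject IUPAC ambiguity codes other than `N` at parse time rather than
coercing them, because deposited population-level mitogenome haplotypes are
unambiguous and silent coercion hides fixture bugs. Comparing `N` literally
(rather than as a wildcard) keeps haplotype identity a transitive relation.

**Segregating sites.** A column is segregating when two or more of
`A C G T` are observed; columns whose only variation involves `N`/`-` are
not segregating. A site is a *singleton* when its minor (least frequent)
state occurs in exactly one genome and *shared* when it occurs in two or
more. Published counts phrase singletons at the genome level and sharing at
the haplotype level; the two coincide for data shaped like the study's
(minor counts of 1 vs 2), but the report carries both the genome-level and
haplotype-level carrier counts so any divergence between the phrasings is
visible rather than hidden.

**Partition densities.** Each partition class (protein, rRNA, tRNA, D-loop,
other) reports S, L and S/L. Columns covered by no entry are assigned to
`other` — never dropped — and a column covered by entries of two classes
(the D-loop amplicon typically overlaps tRNA genes) is counted in both.
One published value is knowingly not reproduced: the tRNA density printed
as 0.00079 substitutions per site is inconsistent with its own inputs
(2 SNPs over 1,515 bp = 0.00132); the package reports S/L and nothing else.

**Distances.** p-distance and the Kimura 2-parameter correction
$d = -\tfrac12\,\ln\!\big((1-2P-Q)\sqrt{1-2Q}\big)$ are always both
computed, with the per-pair transition proportion $P$ and transversion
proportion $Q$ retained. Columns with `N`/`-` in either member of a pair
are excluded for that pair only (pairwise-complete columns). Nucleotide
diversity π is the mean *p*-distance over unordered pairs — the identity
π × L ≈ mean pairwise differences only holds for the uncorrected model —
while AMOVA consumes K2P distances, matching how the two statistics are
conventionally produced. Pairs for which the K2P logarithm is undefined
(saturation) are flagged and reported as `NA` rather than truncated.

# AMOVA

The two-level hierarchical decomposition follows the classical
distance-matrix formulation: with $d_{ij}$ the pairwise distance and $N$
samples, $SS_{total} = \frac1N \sum_{i<j} d_{ij}^2$, the within-unit sums
are computed identically inside populations and subspecies, the among-level
sums follow by subtraction, and variance components are solved from the
expected mean squares with the standard unequal-size coefficients
$n'$, $n''$, $n'''$. Negative components are legitimate estimates under
this method-of-moments solution, so they are *reported* and flagged; the
Φ statistics are additionally computed with components floored at zero,
the convention of the widely used AMOVA software, and both columns appear
in the output.

Each Φ statistic gets its own permutation scheme: Φ_PT permutes individuals
among populations, Φ_PR permutes individuals among populations within their
subspecies, and Φ_RT permutes whole populations among subspecies. P-values
use the $(1+k)/(1+B)$ estimator so that $B = 10{,}000$ permutations can
never produce a spuriously exact $p = 0$; a reported floor of 0.001 in a
published table corresponds to $p \le (1+0)/(1+B)$ here. The default
permutation count is 10,000 with a mandatory seed; every permutation stream
in the package is reproducible bit for bit.

# Genealogies and homoplasy

Tree estimation itself is not this package's contribution: maximum
likelihood topologies are accepted as user-supplied newick files, and a
neighbor-joining tree (Q-criterion agglomeration, with NJ's occasional
negative branch lengths floored at zero and the deficit shifted to the
sibling edge) serves as the default distance-based surrogate. Conflict
between the genealogy of a sub-partition (the D-loop) and the whole genome
is quantified with the Robinson–Foulds bipartition distance and unrooted
monophyly flags rather than bootstrap support.

Per-site homoplasy uses Fitch parsimony. For each segregating site the
observed step count $s$ comes from the Fitch down-pass (state sets as
4-bit masks; `N`/`-` carries the full set and never forces a step; the
count is invariant to the arbitrary rooting). With $m$ = (number of
observed states − 1) and $g$ = (genomes with data − count of the most
frequent state), the indices are CI = m/s, HI = 1 − CI,
RI = (g−s)/(g−m) and RC = CI·RI. Two conventions matter and are applied
deliberately: parsimony-uninformative sites ($g = m$) print RI = 1 and
RC = CI, matching published per-site tables, and are flagged; and $g$ is
computed on *genome* counts — when the tree's tips are haplotype
representatives, per-tip frequency weights restore the genome counts (a
published RI of 0.833 at a doubly-hit site implies $g = 7$, i.e. seven
minor-state genomes, not two minor-state haplotypes). The indices are
tree-conditional by construction, exactly as in published tables; on a
different topology, topology-sensitive sites can legitimately change their
step counts.

# Codon-level analysis

Protein partitions carry a reading frame (the alignment column of the
first codon position) and a strand; reverse-strand genes (ND6 in vertebrate
mitogenomes) are complemented before translation. Translation uses the
vertebrate mitochondrial code (ATA = Met, TGA = Trp, AGA/AGG = Stop).
Substitutions at segregating protein sites are classified against the major
codon as synonymous or replacement; codons containing `N`/`-` are flagged
undefined, and changes creating a premature stop are flagged rather than
dropped. Branch attribution reconstructs ancestral states by deterministic
Fitch refinement — the root takes the alphabetically lowest member of its
down-pass set and children keep the parent state whenever allowed — which
yields a most-parsimonious reconstruction with exactly $s$ changes; sites
where that refinement had to make an arbitrary choice (e.g. a change on a
root-adjacent edge, which has two equally parsimonious placements on a
rooted tree) are flagged and tallied separately per branch.

The regional replacement-excess test addresses the observation that one
lineage's private changes can be overwhelmingly replacements. No published
description names the exact test, so the package implements a transparent
label-permutation test and documents it as such: a change is *unique* to a
region when every carrier of its minor codon belongs to that region; each
region's statistic is its unique-replacement proportion (unique
replacements / unique changes); the null permutes region labels over
haplotypes (over samples when no haplotype table is supplied); and the
p-value is $(1+k)/(1+B)$ against the focal region's proportion, or the
maximum over regions when no focal region is named (the permutation
statistic is then also the maximum, keeping the test honest about
selection). Regions with no unique changes are excluded and flagged. The
published percentage itself (41.7% vs a grand mean of 18.2%) depends on a
denominator the source text leaves ambiguous (5/12 vs 5/11), so the
package reports the raw counts and proportions instead of asserting any
single printed percentage.

# The waiting-time clock

Given per-species neutral rates $r_i$ (substitutions/site/year, typically
third-codon rates) and $L$ surveyed sites, the waiting time until one
expected substitution is $t_i = 1/(r_i L)$ — exact, so the entire fitted
object scales inversely in $L$ and the package asserts that identity to
machine precision. A lognormal is fit to the $t_i$ by closed-form maximum
likelihood on the log scale (μ = mean, σ = sd with denominator $n$ of
$\ln t$); the point estimate is the mode $e^{\mu-\sigma^2}$ and the 95%
interval the fitted quantiles $e^{\mu \pm 1.96\sigma}$. The MLE (rather
than histogram curve fitting) was chosen because it is closed-form,
assumption-minimal, and reproduces the internal relationships of published
mode/interval pairs: inverting a published cytochrome-b interval of
50,115–173,914 years gives a mode of 84,410 — within 0.1% of the printed
84,411 — and rescaling by 379/3,796 third-codon sites gives 8,427.7 against
a printed 8,428. Divergence dates are then $T = k \times$ mode for $k$
mean synonymous differences from the common ancestor, with the interval
scaled the same way. One published date (16.7 kya from $k = 1.8$) does not
equal $k \times$ the printed genome-scale mode (15.2 kyr) and the source
does not state the computation behind it, so it is documented here and not
asserted. The package ships a *synthetic* rate-table generator
(`simulate_rate_table()`) whose defaults resemble the spread of published
carnivore third-codon rates; it is a stand-in for demonstrations, not the
published 131-species compilation.

# The simulator

`sim_config()` defaults define the study conditions the package is tested
under: 40 samples in 6 populations nested in 3 subspecies (7 + 5 Pacific,
10 + 11 Rocky Mountain, 2 + 5 Great Lakes), a 16,290-column genome
partitioned 11,397 / 2,528 / 1,515 / 299 / 551 bp (protein / rRNA / tRNA /
D-loop / other), a D-loop rate 9.06× the protein rate (the ratio of the
published per-class densities), transition:transversion ratio κ = 10
(transition probability κ/(κ+2) ≈ 0.83 per draw, the two-class kernel that
matches the downstream K2P assumption), and recurrent-mutation hotspots —
three hypervariable D-loop columns and one protein-coding column, each
with a 25× rate weight — so that homoplasy arises at planted, known
positions. Genealogies are ultrametric: random coalescent subtrees within
populations (depth 0.15), populations joined within subspecies near depth
0.5, subspecies near depth 1.0, in expected-substitution branch-length
units; calendar time belongs to the clock module alone. The absolute class
rates were set once so that the expected segregating-site count over the
default genealogy depth matches the study-scale ~66 (the realized mean
across seeds is ~70, with ~15–25 haplotypes).

What the simulator does *not* emulate: indels (the deposited alignment is
treated as indel-free), rate variation beyond the class/hotspot structure
(no gamma-distributed site rates), base-composition evolution, migration
or admixture beyond the fixed hierarchy, and realistic Φ magnitudes — the
default depths produce stronger population structure than the study data,
because the calibration target is the *count* spectrum, not the variance
decomposition. Passing tests on synthetic data therefore demonstrate
algorithmic correctness (counts, conservation laws, recovery of planted
signal), not that real fisher data would yield any particular Φ or p.

Determinism is a hard invariant: identical configuration and seed give
bit-identical alignments, truth records and downstream reports. The truth
record logs every planted mutation (branch, column, from, to), so tests
can verify conservation (per-column change counts equal planted
multiplicities; polymorphic columns always trace to ≥1 planted mutation)
and branch-attribution correctness for single-hit sites.

`make_fixture()` is the simulator's deterministic sibling: it constructs,
without randomness, an alignment with exact per-class segregating-site
counts and an exact shared/singleton split (defaults: 42 protein, 9 rRNA,
2 tRNA, 10 D-loop, 3 other; 19 shared / 47 singletons over 40 samples).
Published tables report site *counts* per partition but not all site
positions, so fixtures target counts, not positions.

# Numerical and design choices

* Coordinates are 1-based and inclusive on the aligned matrix; the
  circular genome is treated as linearized.
* The D-loop amplicon is its own partition entry and may overlap tRNA
  entries; overlap is forbidden only within a class. Locus lookup for
  reporting prefers gene entries over the amplicon, matching how published
  variant tables label sites inside the overlap.
* SS additivity in AMOVA is asserted to 1e−9 relative tolerance; the
  permutation tie comparison uses a 1e−12 guard so exact ties count as
  "as extreme".
* NJ tie-breaking follows the deterministic behavior of the underlying
  agglomeration; negative branches are floored with the deficit moved to
  the sibling so path lengths are preserved.
* Degenerate inputs are reported, not silently repaired: a population pair
  with zero total variance gets Φ_PT = 0 with a `degenerate` flag; a
  zero-variance waiting-time sample gets σ = 0 with a warning; saturated
  K2P pairs are `NA` + flag.
* Test problem sizes were chosen for desk-scale runs: simulation-based
  property tests use a 3,000-column genome with 8–16 samples and 6–20
  replicates; permutation tests in examples use 199–2,999 permutations
  (the package default remains 10,000).

# Known limitations

* AMOVA supports exactly the two-level nested hierarchy (plus the
  one-level pairwise case); deeper hierarchies and frequency-only (distance-
  free) AMOVA are out of scope.
* Homoplasy indices are conditional on the supplied topology; no attempt
  is made to integrate over tree uncertainty (no bootstrap).
* The codon module counts raw synonymous/replacement events; it is not a
  codon substitution model and estimates no dN/dS rates.
* The clock assumes a strict molecular clock and rate-table units of
  substitutions/site/year; no fossil calibration or time-dependency
  correction is applied.
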