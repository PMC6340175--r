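---
title: "Retroposon presence-absence phylogenomics: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retroposon presence-absence phylogenomics: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrophylo)
```

## The marker and its model

A mobile-element insertion (MEI) at a given genomic site is a binary
character: a genome either carries the element or it does not. Insertion
at an orthologous position twice independently is vanishingly rare, and
precise excision is essentially unknown, so the natural evolutionary model
is **Dollo parsimony**: each character may be gained exactly once
(0 → 1) and lost any number of times (1 → 0). The ancestral state at the
root is "absent", because the marker set is ascertained against a
reference genome (an outgroup) that carries none of the insertions.

This package analyses such markers end to end: genotype calls → a
presence/absence matrix → trees → conflict quantification → insertion
dynamics, plus a coalescent simulator that generates data with the same
statistical structure so every stage can be validated without external
downloads.

## From genotypes to the matrix

Diploid genotype calls are coded 0 (0/0), 1 (0/1), 2 (1/1), NA (./.).
Conventions, each chosen once and applied everywhere:

* **Any non-zero allele index counts as presence.** MEI genotypers emit
  biallelic records; this is defensive handling of multi-allelic edge
  cases.
* **Half-calls ("./1") are missing.** Conservative: no presence is
  claimed from an uncertain call.
* **Column-drop rule.** Loci present in *no* sample are dropped — they
  carry no insertion signal against the reference. Loci present in
  *every* sample are kept: they are synapomorphies of the whole ingroup
  relative to the reference and constitute the strongest signal class.
* **Heterozygosity sidecar.** Binary NEXUS symbols cannot encode
  heterozygosity, so het flags travel in a TSV sidecar
  (`write_het_sidecar`); the branch-dynamics stage needs them to measure
  which branches contributed unfixed insertions.
* Coordinates stay 1-based (VCF convention) throughout; only BED export
  converts to 0-based half-open.

Two summary numbers deliberately coexist and must not be conflated: the
*total number of genotyped calls* (summing per-sample call counts over
samples; `per_sample_counts`) and the *number of orthologous loci*
(matrix columns). Shared insertions make the former much larger.

## Dollo scoring, search, and the consistency index

For a rooted tree and a character with presence set \(P\), the Dollo
score is \(1 + L\), where the single gain sits on the stem of the MRCA of
\(P\) and \(L\) is the minimal number of maximal all-absent subtrees
inside the gain clade. Missing states are free: a dynamic programme over
the tree (linear in nodes, vectorised over characters) resolves each `?`
to whichever state minimises losses; this is verified against an
exhaustive oracle that enumerates every single-gain/any-loss assignment
on trees of up to 6 leaves. Placing the gain at the MRCA is optimal
because any higher placement only adds non-negative loss terms; the
implementation nevertheless minimises over all containing ancestors.

**Rooting.** Dollo needs a direction. `dollo_search` roots on a
user-named outgroup taxon when one exists; otherwise it augments the
matrix with an implicit all-absent ancestor (the reference genome's
state), searches with that pseudo-taxon fixed as the root, and removes it
from the returned tree.

**Search.** Random taxon-addition starting trees followed by
hill-climbing branch swaps. The neighbourhood is NNI by default, with a
tip-prune-and-regraft SPR option. A full TBR swap is deliberately
omitted: at the 8–12 taxa typical of this data the search space is tiny
and random addition + NNI reaches the global optimum — checked against
exhaustive enumeration of all 15 topologies at 5 taxa. Ties (equal
scores) keep the first tree found under the seeded replicate order, so
results are reproducible bit-for-bit given `seed`.

**Consistency index.** CI = (sum of per-character minima) / (tree
length). Every character with at least one present taxon has a Dollo
minimum of one step, so CI = 1 iff every presence set is a clade.
All-present characters always take exactly one step; whether to count
them is a genuine convention choice, so both are available
(`include_constant`, default `TRUE` — excluding them can only lower CI).

**Neighbor-joining** uses the mean character difference (proportion of
differing characters among those non-missing in both taxa — pairwise
deletion), mirroring the standard-data default of classic parsimony
software; negative NJ branch lengths are clamped to zero. A taxon pair
sharing no scored character is an error, not a guess.

**Bootstrap** resamples characters with replacement; support of an
internal branch is the fraction of replicate trees containing the same
bipartition (unrooted comparison). On conflict-free data with adequate
per-branch signal all supports are 1; note that a branch spanned by only
a handful of characters will *correctly* receive reduced support (the
resampling may miss its characters entirely) — that is sampling
uncertainty, not conflict.

## Quantifying conflict

`collapse_to_species` reduces individuals to species. Under the
conservative rule (`"all"`), a species is present only when *every*
individual carries the insertion; mixed presence scores the species
absent (the number of affected loci is reported as a diagnostic, keeping
the choice auditable), and unanimity that cannot be verified because of
missing genotypes propagates as missing. Under `"any"`, one carrier
suffices. Loci left with no present species are dropped and counted.

`intersection_counts` tallies each locus to its *exact* presence set
(UpSet "distinct" semantics), so counts partition the fully-observed
loci; loci with a missing species state are skipped and reported. The
three counts around a focal branching (`conflict_triple`) must name
pairwise incompatible clades — overlapping, neither nested nor disjoint.

**Polytomy test.** Under a hard polytomy each of the three resolutions is
equally likely, so the counts are trinomial with probabilities 1/3. Two
tail probabilities are reported:

* `p_value` = \(P(X \ge n_1)\) with \(X \sim \mathrm{Bin}(n, 1/3)\) and
  \(n_1\) the largest count — the convention used in published
  retroposon bifurcation tests, reported for comparability with that
  literature.
* `p_max` = \(P(\max \text{count} \ge n_1)\), computed exactly by
  inclusion–exclusion. Because `p_value` conditions on the *largest*
  count it is anti-conservative as a decision rule (its rejection rate
  at nominal 0.05 is ~0.15 under the null); `p_max` is a valid p-value
  (measured type-I error ≈ 0.047 at α = 0.05). Decisions at level α
  should therefore use `p_max`; `p_value` is the comparable published
  quantity. A Monte-Carlo trinomial mode cross-checks both closed forms.

**Asymmetry test.** Under pure ILS the two tree-incongruent resolutions
are exchangeable, so their counts follow Bin(n₂+n₃, 1/2); a two-sided
exact binomial departure indicates a directional process such as
introgression. With the whale-scale counts 465 vs 444, p ≈ 0.51 — no
asymmetry.

## Insertion dynamics on a dated tree

`assign_branches` maps each locus to one branch: a presence set equal to
a clade goes to that clade's stem; a tree-incongruent set is interpreted
as ILS and goes to the stem of the MRCA of its carriers (ancestral
polymorphism must predate that ancestor); an all-species locus goes to
the root stem. `branch_rates` then reports per-branch counts,
heterozygosity fractions, and rates.

The implemented rate is
\[
\mu = \frac{n}{b / g}
\]
insertions per generation, with \(n\) the branch's insertion count,
\(b\) its duration in years and \(g\) the generation time (default
24.4 years, the mean over extant baleen whales). A published form of
this equation multiplies instead of dividing by \(b\); that form is
dimensionally inconsistent with "insertions per generation" and does not
reproduce the reported rate magnitudes, so the quotient form is used.

Heterozygosity per branch is ambiguous between two readings, so both are
implemented: the default `"locus"` mode is the fraction of the branch's
loci that are unfixed (heterozygous in ≥ 1 carrier individual);
`"call"` mode is the fraction of heterozygous genotype calls among
present calls.

## The synthetic-data generator

`simulate_insertion_matrix` emulates the generative process the analysis
assumes. For each locus, a gene tree of all sampled haplotypes (2 per
diploid individual) is drawn under the standard multispecies coalescent:
within each species-tree branch, lineages coalesce pairwise at rate
\(1/(2N_e)\) per generation, constrained by the species tree; the
ancestral population continues above the root until one lineage remains.
A single insertion is then placed uniformly at random on the gene tree in
proportion to branch length; its carriers are the descendant haplotypes.
This produces, with no extra machinery, exactly the features real MEI
data show: ILS-driven tree-incongruent presence patterns (more frequent
when internal branches are short in coalescent units \(t/2N_e\)),
unfixed heterozygous insertions on recent and on deep conflicted
branches, and fixed clade markers elsewhere.

Validation anchors the simulator to coalescent theory: for a quartet
with internal branch \(t\) and ancestral size \(N_e\), the probability
that the gene-tree triplet is incongruent is
\((2/3)e^{-t/(2N_e)}\). This formula concerns *gene-tree topologies*;
insertion presence patterns are additionally weighted by internal-branch
lengths, which differ between concordant and discordant genealogies, so
the theory check is asserted on the recorded triplet resolutions
(haploid sampling, one lineage per species) and pattern-level checks
assert the symmetry of the two incongruent classes instead.

Choices and limits worth knowing:

* Insertion placement is uniform over the whole gene tree (neutral,
  clock-like retrotransposition); per-branch placement weights
  (`edge_weights`) support burst experiments such as a rate increase on
  one ancestral branch.
* Loci whose insertion would predate the sample-wide TMRCA (present in
  every haplotype) are not generated — the stem above the TMRCA is not
  part of the gene tree. All-present *species* patterns still arise
  whenever all sampled haplotypes below the TMRCA carry the insertion.
* Two sampling modes: `n_loci` (one insertion per gene tree — pattern
  frequencies) and `rate` + `n_gene_trees` (Poisson(rate × tree length)
  insertions per genealogy — rate-recovery experiments; the aggregate
  per-generation rate is `rate × n_gene_trees`).
* No recombination within a locus, no population structure within
  species, exchangeable haplotypes within individuals.

**Detection noise** (`apply_detection_noise`) emulates a short-read MEI
caller at genotype level: each present genotype is detected with
probability TPR(coverage) — a logistic curve calibrated so TPR(5X) = 0.99,
the empirical sensitivity plateau of joint MEI genotyping — and detected
genotypes are miscalled to the other present state with rates
`het_to_hom` and `hom_to_het` (defaults 0.08, i.e. 92% of called
insertions correctly genotyped). Undetected genotypes become absent (or
missing), and optional background missingness and false-positive rates
are available. The full read-simulation/mapping/calling loop is out of
scope; `spike_reference` exists so real callers can be benchmarked
externally and fed back through the evaluator.

**Evaluation** (`match_calls`, `compute_metrics`) matches calls to truth
positions greedily by distance within a window (default 50 bp —
MEI breakpoints are imprecise), one-to-one. Greedy matching equals the
optimal bipartite matching whenever truth positions are separated by more
than twice the window, which the spiking generator's minimum spacing
(default 500 bp) guarantees; for arbitrarily clustered truth sets it is a
heuristic. Metric naming follows the MEI-benchmarking convention in
which TPR is computed *from the detected calls* (a precision);
unambiguous aliases `sensitivity` and `precision` are always included.

## Numerical and reproducibility choices

* Every stochastic operation takes an explicit integer seed and is
  bit-reproducible given it; the pipeline manifest records all seeds and
  output checksums.
* Tie-breaking: NJ follows the implementation order of the classic
  algorithm; tree search keeps the first optimum found under the seeded
  replicate order; matching breaks distance ties by lower truth, then
  call, coordinate.
* Degenerate inputs fail loudly rather than silently: taxa absent from
  trees, empty presence sets, zero-variance PCA matrices, non-positive
  branch durations, taxon pairs with no shared scored characters.
* PCA uses 0/1/2 dosages (genotypes exist, so binary coding would
  discard information; a binary mode is available), per-locus mean
  imputation of missing calls, centring, optional variance scaling
  (off by default, since allele-frequency standardisation conventions
  differ between tools), and a fixed sign convention
  (largest-magnitude loading positive).

**Problem sizes used in the automated checks** (chosen as comfortable
for the statistics involved): conflict-free recovery uses 8 species ×
2,000 loci on a tree whose every internal branch carries expected signal
of ≥ 100 characters; the coalescent-theory check uses 3,000–10,000 loci
(3 standard-error tolerance); rate recovery uses ≈ 5,000 loci over 6,500
genealogies; caller-accuracy recovery uses 10 replicates of 200 spiked
insertions; the polytomy type-I calibration uses 10,000 simulated
triples of total 1,419. The demo species tree uses literature-scale
baleen-whale divergence times (radiation ≈ 8 Mya, minke split
≈ 10.5 Mya, right-whale split ≈ 28 Mya) with a large ancestral
population at the radiation; exact published branch times for the whale
study are inputs the user supplies, so per-branch rate values on real
data are reproduced as properties (range and scaling), not as fixed
constants.

## Known limitations

* The Dollo machinery assumes a perfect 0-ascertainment root; marker
  sets called against an ingroup reference would need re-polarisation.
* The polytomy test treats loci as independent; linked insertions would
  inflate all counts equally but shrink effective sample size.
* The simulator's detection noise is genotype-level; it does not emulate
  reference-side filter artefacts (low-complexity regions etc.), which
  affect all samples equally and therefore cancel in tree inference but
  matter for absolute sensitivity claims.
* `collapse_to_species` under `"all"` discards real within-species
  polymorphism by design (conservatism against genotyping error); the
  diagnostics quantify how many loci this affects so the cost is
  visible.
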