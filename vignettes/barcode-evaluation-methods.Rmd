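---
title: "Methods: four-criteria evaluation of DNA barcoding loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: four-criteria evaluation of DNA barcoding loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

DNA barcoding identifies species by comparing short standardized loci (for
plants typically ITS, matK, rbcL and psbA-trnH) against a reference library.
Whether a locus works for a given genus is an empirical question, and the
community answers it with a recurring battery of four criteria. `barcodegap`
implements that battery end to end — distances, trees, identification tests
and a calibrated simulator — so each criterion is computed by code this
package controls and tests, rather than stitched together from external
tools. This vignette records the exact algorithms, the parameter defaults,
and the reasoning behind each choice.

## 1. Sequence characterization

`locus_stats()` reports per-locus alignment length, per-sequence GC content
(G+C over unambiguous A/C/G/T, in percent), the number of *variable* sites
(columns with at least two unambiguous states) and of *parsimony-informative*
sites (columns with at least two states each present in at least two
sequences). Gaps, `N` and IUPAC ambiguity codes never count as states.

## 2. K2P distances and the barcoding gap

`k2p_distance()` implements the Kimura 2-parameter distance

$$ d = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q), $$

where $P$ and $Q$ are the proportions of transitions (A↔G, C↔T) and
transversions among *mutually unambiguous* sites of the pair (pairwise
deletion: a column is dropped for a pair when either sequence has a gap,
`N`, or an ambiguity code there). The distance is undefined — reported as
`NA` with a validity flag — when no sites remain or a logarithm argument is
non-positive (substitutional saturation). Pairwise deletion is chosen over
complete deletion because length-variable spacers such as psbA-trnH would
otherwise discard most of the alignment for every pair.

`k2p_distance_matrix()` computes all pairs via indicator-matrix cross
products, so the per-pair definition above is the specification and the
matrix code is an optimization; the test suite holds the two equal to
1e−12 and cross-checks against `ape::dist.dna(model = "K80")`.

`partition_distances()` splits valid ingroup pairs into intraspecific and
interspecific sets (outgroups excluded from both), and `gap_statistics()`
summarizes them on the percent scale: means, ranges, a 0.5-point histogram,
the *gap* (minimum interspecific minus maximum intraspecific) and the
*overlap fraction* (share of intraspecific distances at or above the
minimum interspecific distance). A negative gap is meaningful — it is
exactly what species pairs with shared haplotypes produce.

## 3. Neighbour-joining trees, bootstrap, monophyly

`nj_tree()` is a from-scratch neighbour-joining implementation: at each
step it joins the pair minimizing
$Q(i,j) = (r-2)\,d(i,j) - R_i - R_j$ with branch lengths
$b_i = d(i,j)/2 + (R_i - R_j)/(2(r-2))$. Ties in $Q$ are broken
deterministically by the lexicographically smallest member tip of each
cluster, so results never depend on input order. Negative branch lengths
are clamped to zero with the deficit moved to the sister branch,
preserving path lengths between tips. The matrix must be fully valid;
the pipeline first drops the fewest samples needed
(`prune_invalid`) and logs them.

`bootstrap_support()` resamples alignment columns with replacement — within
each locus block when the alignment is a concatenation, so each locus keeps
its own column budget — rebuilds the NJ tree per replicate, and scores each
internal edge of the point-estimate tree by the percentage of replicate
trees containing the same bipartition. Replicates whose resampled matrix
contains an invalid distance are discarded; more than 10% discarded aborts
the analysis rather than quietly reporting support from a biased sample.

`species_discrimination()` calls a species *discriminated* when its
individuals form a clade whose defining edge has bootstrap support strictly
greater than the threshold (default 50; 60 is a common stricter preset, and
both are exposed). With outgroups present the clade must also exclude every
outgroup tip, which roots the monophyly test. Singletons are trivially
monophyletic, so the `singleton_policy` makes the choice explicit:
`"exclude"` (default — they leave the denominator), `"fail"` or
`"succeed"`.

## 4. Distance- and similarity-based identification

`best_match()` performs leave-one-out nearest-neighbour identification on
the K2P matrix: each ingroup individual is queried against all others;
*success* if every nearest neighbour (exact distance ties included) is
conspecific, *ambiguous* if ties span species, *failure* otherwise.
`best_close_match()` additionally marks queries *unidentified* when the
nearest distance exceeds a threshold; `intraspecific_threshold()` sets it
as a quantile (default 0.95) of all intraspecific distances, interpolated
between order statistics exactly as `stats::quantile(type = 7)`. With an
infinite threshold best close match reduces to best match — an identity
the tests enforce.

`top_hit_discrimination()` is the similarity-scored variant: leave-one-out
percent identity over mutually unambiguous columns, a species succeeding
only if every member's top hits are exclusively conspecific. The scorer is
pluggable, so BLAST-style scores can be substituted without changing the
success logic.

## 5. The simulator

`build_dataset()` generates multi-locus datasets with known truth so every
criterion above can be validated against its generating parameters:

* **Species tree.** A random coalescent topology (`ape::rcoal`) whose node
  heights are re-spaced evenly over `[min_split_frac, 1] × inter_depth`
  (default `min_split_frac = 0.15`). Raw coalescent heights can place two
  species arbitrarily close together, which would break the simulator's
  contract that distinct species are separated by at least a known
  divergence; the floor makes "well-separated at these settings" a design
  guarantee instead of a per-seed accident.
* **Sequences.** Root sequences drawn at the locus `gc_target`; evolution
  along each branch under Kimura's two-parameter substitution model with
  transition/transversion parameter `kappa` (default 4), using exact branch
  transition probabilities rather than small-step approximation.
* **Individuals.** Each species' individuals hang from a star with arm
  length `intra_depth`, so the *expected pairwise* intraspecific divergence
  is `2 × intra_depth` — the quantity `partition_distances()` estimates.
* **Twins.** `twin_pairs` copies one species' rows verbatim onto another,
  reproducing the shared-haplotype species pairs that defeat every
  barcoding method; downstream failure of exactly those pairs is an
  acceptance property.
* **Indels** appear as species-shared gap column blocks (non-coding-spacer
  style); **missing loci** remove whole species from a locus, shrinking
  concatenated denominators; **outgroups** attach at three times the
  ingroup depth.

All stages draw from seeds derived deterministically from the single
`seed` via `derive_seed()`, so datasets are byte-reproducible.

## 6. Orchestration

`run_evaluation()` applies the selected methods to every single locus and
every requested combination (`"all"` = all subsets of size ≥ 2; four loci
give 11). Concatenation keeps only samples present in every member locus,
so combination denominators legitimately shrink when loci have missing
species. Marker sets with fewer than three ingroup samples are skipped
with a logged reason. `render_reports()` writes survey-style tables
(rates formatted `"84.85% (28/33)"`), per-marker-set gap histograms,
newick trees, per-query tables and a deterministic `summary.json`:
re-running with the same seed reproduces it byte for byte.

## Scope and limitations

The simulator is a calibration instrument, not a model of any real genus:
it uses a single substitution regime per locus (no rate heterogeneity
across sites, no recombination or hybridization), star-shaped
intraspecific structure, and species-level missingness. Problem sizes in
the documentation and tests (tens of species, hundreds of base pairs,
bootstrap in the hundreds to low thousands) are the package's own choices
for desk-scale validation. The NJ implementation targets correctness and
determinism over asymptotic speed; for thousands of tips a specialized
implementation would be preferable.
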