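# barcodegap

Four-criteria evaluation of DNA barcoding loci for species identification.

DNA barcoding surveys ask a deceptively simple question: given aligned
sequences of a few candidate loci (for plants typically ITS, matK, rbcL,
psbA-trnH) from many individuals of many species, which locus — or
combination of loci — actually tells the species apart? The field answers
with a standard battery, and `barcodegap` implements all of it:

1. **Sequence characterization** — length, GC content, variable and
   parsimony-informative sites per locus (`locus_stats()`).
2. **Barcoding-gap analysis** — Kimura 2-parameter (K2P) distances with
   pairwise deletion,
   `d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)` for transition/transversion
   proportions `P` and `Q`; intraspecific vs interspecific distributions,
   gap and overlap statistics (`k2p_distance_matrix()`,
   `partition_distances()`, `gap_statistics()`).
3. **Tree-based discrimination** — from-scratch neighbour joining with
   deterministic tie-breaking, column-bootstrap support (partition-aware
   for concatenated alignments), and species monophyly scored against a
   support threshold (`nj_tree()`, `bootstrap_support()`,
   `species_discrimination()`).
4. **Distance-based identification** — leave-one-out best match, best
   close match with a threshold set from the intraspecific distance
   quantile, and similarity-scored top-hit discrimination
   (`best_match()`, `best_close_match()`, `top_hit_discrimination()`).

A calibrated multi-locus simulator (`build_dataset()`) generates datasets
with known species trees, divergences, identical-sequence "twin" species
pairs, indels, missing loci and outgroups, so every criterion can be
validated against ground truth. `run_evaluation()` orchestrates all four
criteria over every single locus and every concatenated combination and
renders survey-style reports.

## Worked example

Simulate 10 species (one pair sharing identical sequences — the classic
barcoding failure mode), evaluate two loci and their combination:

```r
library(barcodegap)

p <- sim_params(10, c(2, 4),
                list(locus_spec("ITS", 619, gc_target = 57),
                     locus_spec("rbcL", 705, gc_target = 43)),
                intra_depth = 0.004, inter_depth = 0.08,
                twin_pairs = 1, n_outgroups = 1, seed = 11)
sim <- build_dataset(p)
ds  <- sim$dataset
ds
#> <barcode_dataset> 33 samples, 10 species (1 outgroup), 2 loci
#>   ITS: 33 sequences x 619 bp
#>   rbcL: 33 sequences x 705 bp

locus_stats(ds$loci$ITS)
#> <locus_stats> ITS: n=33, aligned 619 bp (ungapped 619-619), GC 52.0-56.4%,
#>   385 variable / 246 parsimony-informative sites

dm <- k2p_distance_matrix(ds$loci$ITS)
gp <- partition_distances(dm, ds$samples)
gap_statistics(gp)[c("intra_mean", "inter_mean", "gap", "overlap_fraction")]
#> $intra_mean
#> [1] 0.7407424
#> $inter_mean
#> [1] 14.66622
#> $gap
#> [1] -1.473298
#> $overlap_fraction
#> [1] 1
```

Mean intraspecific divergence is ~0.74% against ~14.7% interspecific, yet
the gap is *negative* and the overlap total: the twin pair's between-species
distances are exactly zero, which is precisely how shared haplotypes destroy
threshold-based identification. The discrimination battery localizes the
damage:

```r
summ <- run_evaluation(ds, eval_config(bootstrap_B = 200, seed = 11))
summ
#> <evaluation_summary> 3 marker set(s), seed 11
#>   ITS: NJ 80.00% (8/10), BM 78.12% (25/32), BCM 71.88% (23/32), TopHit 80.00% (8/10)
#>   rbcL: NJ 80.00% (8/10), BM 78.12% (25/32), BCM 78.12% (25/32), TopHit 80.00% (8/10)
#>   ITS+rbcL: NJ 80.00% (8/10), BM 78.12% (25/32), BCM 78.12% (25/32), TopHit 80.00% (8/10)

render_reports(summ, "reports")   # tables, trees, histograms, summary.json
```

Exactly the two twin species fail every method (8/10 discriminated), no
amount of locus concatenation rescues them, and re-running with the same
seed reproduces `summary.json` byte for byte.

Real data enters through `read_barcode_dataset()` — one aligned FASTA per
locus with headers `Species_binomial|sample_id` and an optional
`|outgroup` flag — or via the thin command-line wrapper in
`inst/cli/barcode-eval` (`simulate` and `run` subcommands).

See the vignette `vignettes/barcode-evaluation-methods.Rmd` for the full
methods description: distance and tree algorithms, tie-breaking and
clamping rules, bootstrap and threshold conventions, simulator design and
its limitations.

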