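# morphoevo

Macroevolutionary analysis of discrete morphological character matrices on
dated phylogenies: time-binned morphospace occupation, bootstrapped and
rarefied disparity curves, and maximum-likelihood rates of discrete character
evolution — the standard paleobiological pipeline for asking *when* a clade's
morphological variety was assembled and *when* its anatomy evolved fastest.

It is written for paleobiologists and comparative morphologists who have (a)
a taxa × characters matrix of discrete skeletal characters in NEXUS format,
(b) one or more undated cladograms, and (c) first/last appearance dates (FADs
and LADs, in Ma) for the sampled taxa.

## What it computes

**Distances.** Inter-taxon dissimilarity uses the maximum observable rescaled
distance (MORD). For taxa *i*, *j* and the set *K(i,j)* of characters scored
in both:

    D_ij = sum over k in K(i,j) of w_k d_ijk  /  sum over k in K(i,j) of w_k m_k

where `d_ijk` is the per-character distance (0/1 for unordered characters,
the minimum absolute state difference for ordered ones, minimised over
polymorphic state sets) and `m_k` its maximum attainable value (the observed
state range for ordered characters). Missing (`?`) and inapplicable (`-`)
cells are both non-comparable. Pairs with no comparable characters are
undefined and an iterative trimmer (`trim_incalculable()`) removes the fewest
taxa needed to make the matrix complete.

**Morphospace.** Principal coordinates (PCO) of the MORD matrix, retaining
positive-eigenvalue axes; per-time-bin occupancy, convex-hull areas, and
Brownian (maximum-likelihood) ancestral coordinates for phylomorphospace and
chronophylomorphospace plots.

**Disparity.** The sum of variances (SoV) of the ordination scores over all
retained axes, per time bin, with bootstrap percentile intervals and
rarefaction to the smallest usable bin size. Pre-ordination disparity is
available as the weighted mean pairwise distance (WMPD).

**Time-scaling.** Three a-posteriori calibrations of a cladogram from tip
ages drawn within stratigraphic ranges: the *equal* method (zero-length
branches share the duration of the closest positive ancestral branch), the
*minimum branch length* method (every branch at least `mbl` Myr), and a
whole-tree *Hedman* method (Bayesian node ages from successive outgroup
first appearances, computed by discretised uniform-prior integration and
propagated root-to-tips).

**Rates.** Ancestral states per character under a single-rate Mk model
(marginal ML via the pruning algorithm), modal-state change counts per
branch, Poisson exposures weighted by character completeness, and two-rate
vs one-rate likelihood-ratio tests (compared to chi-squared, 1 df) per
branch and per time bin, with Benjamini-Hochberg correction. The replicated
design of the field — *n* trees × *n* dating replicates, averaged "spaghetti"
curves — is provided by `rates_replicated()`.

**Clusters and character profiles.** PAM clustering of morphospace with
silhouette-selected *k*, and per-character Cramér's V profiles against
discretised PCO axes.

**Synthetic data.** A birth–death simulator with fossil sampling and
stratigraphic ranges plus an exact (Gillespie) Mk character simulator with
per-bin rate multipliers. Built-in scenarios: `null`, `burst` (3× rate in
the 150–100 Ma bin) and `expansion` (half the characters activate at
150 Ma). Every stage of the pipeline is verified against these known truths.

## Worked example

Simulate a "burst" dataset (a clade of ~50 lepidosaur-like taxa scored for
200 characters, with a planted 3× rate pulse at 150–100 Ma), then run the
full pipeline on the emitted files:

```r
library(morphoevo)

cfg   <- make_scenario("burst", seed = 42)
files <- simulate_scenario_files(cfg, "demo-input")

pc <- pipeline_config(
  matrix = files$paths$matrix, trees = files$paths$trees,
  ranges = files$paths$ranges,
  bins = list(kind = "equal", span = c(250, 0), width = 50),
  dating_methods = "hedman", dating_args = list(t0 = 260, resolution = 300),
  n_trees = 2, n_datings = 2, bootstrap_reps = 200,
  seed = 7, outdir = "demo-out")
res <- run_pipeline(pc)

res$distances
#> MORD distances: 50 taxa; 0 undefined pair(s); mean defined distance 0.227
res$ordination
#> PCO ordination: 50 taxa, 25 positive axes (correction: none)
#>   variance explained PCO1-3: 57, 9.8, 4.9 %
res$disparity[, c("bin", "n", "sov", "lo", "hi")]
#>       bin  n    sov      lo     hi
#> 1 250-200  0     NA      NA     NA
#> 2 200-150  5 0.0173 0.00853 0.0186
#> 3 150-100  7 0.0183 0.00979 0.0206
#> 4  100-50  4 0.0484 0.00637 0.0584
#> 5    50-0 38 0.0484 0.03955 0.0531
res$rates$mean_curve
#>   method     bin mean_rate
#> 1 hedman 250-200     0.295
#> 2 hedman 200-150     0.215
#> 3 hedman 150-100     0.389
#> 4 hedman  100-50     0.146
#> 5 hedman    50-0     0.226
```

Reading the output: the oldest bin holds no sampled taxa, disparity (SoV)
steps up after the planted event, and the mean rate curve — averaged over
2 trees × 2 dating replicates — peaks in the planted 150–100 Ma bin at
0.389 changes per character-weighted Myr, roughly 2–3× the background, as
planted. `demo-out/` also receives the distance CSV, ordination scores,
per-bin occupancy and hull areas, per-branch and per-bin LRT tables, the
iteration-level rate curves, cluster assignments, Cramér profiles, and a
run manifest; re-running with the same seed reproduces every table
byte-for-byte.

A thin command-line wrapper is installed at
`inst/scripts/run-pipeline.R` (`run -c config.yaml`, or
`simulate --scenario burst -o dir`).

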