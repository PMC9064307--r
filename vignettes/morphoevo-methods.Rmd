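---
title: "Disparity and evolutionary rates from discrete characters: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disparity and evolutionary rates from discrete characters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoevo)
```

This vignette is the package's own account of its methods: the models it
fits, the numerical choices it makes, what its synthetic-data generator does
and does not emulate, and where the approach is known to be fragile. The
README shows the workflow; here we explain why each stage is built the way
it is.

## The data model

A discrete morphological matrix is taxa × characters, each cell a single
state, a polymorphic state set, missing (`?`), or inapplicable (`-`).
Characters carry an ordering flag (unordered or ordered) and a non-negative
weight. State codes are integers 0–31 written with the symbol alphabet 0–9,
A–V, which covers published matrices. Ordering and weights are read from a
NEXUS ASSUMPTIONS block when present, default to unordered/1 otherwise, and
can be overridden by a sidecar CSV (`index,ordering,weight`) because
assumptions blocks vary across programs. Missing and inapplicable are kept
distinct in the data model — they mean different things biologically (not
observed vs not meaningful, e.g. limb characters in limbless taxa) — but
both are treated as non-comparable in distance calculations, which is
standard practice; no coherent alternative for inapplicables exists in a
distance framework.

## Distances: MORD

For each taxon pair the raw distance is summed over comparable characters
and divided by the summed maximum attainable distance of those characters
("maximum observable" rescaling). Choices worth stating:

* **Polymorphism** contributes the *minimum* distance over cross-pairs of
  the two state sets — a polymorphic taxon is compatible with the states it
  exhibits.
* **Ordered maxima** use the state range observed anywhere in the matrix
  for that character, not just in the pair, matching the definition of the
  maximum *observable* distance.
* Pairs with no comparable characters (or only zero-range ones) are
  *undefined*, not zero. Ordination needs a complete matrix, so
  `trim_incalculable()` removes, iteratively, the taxon involved in the most
  undefined entries (ties broken alphabetically) and returns the removal
  log, making the choice auditable — published studies rarely state whether
  and how they trimmed.

## Ordination

PCO is the metric eigendecomposition of the double-centred squared-distance
matrix. MORD matrices are generally non-Euclidean, so negative eigenvalues
appear; the default retains the positive-eigenvalue axes and reports
variance explained relative to the positive sum (recorded in the output),
with the Cailliez correction available when a fully Euclidean embedding is
preferred. Axis signs are fixed by making each axis's first nonzero loading
positive, so plots reproduce across platforms. Two internal identities are
enforced by tests: the retained eigenvalue sum equals the sum of squared
centroid distances of the embedded points, and the full-sample sum of
variances equals the eigenvalue sum over n−1.

Ancestral coordinates for phylomorphospaces are per-axis maximum-likelihood
Brownian estimates on the dated tree (equivalent to weighted squared-change
parsimony), computed with phytools and verified in tests against the normal
equations solved directly.

## Time bins and membership

Bins are half-open `[older, younger)`: an age exactly on a boundary belongs
to the younger bin, so nothing is double-counted; the youngest bin is closed
at 0 so extant taxa belong somewhere. The bundled stage chart supports
geological-stage bins; equal-width bins are built from the younger end so
only the oldest bin is ever truncated. Bin membership uses the full
stratigraphic range by default (a taxon occupies every bin its range
touches), with a point-age rule available for dated-tip workflows.

## Time-scaling

Tip ages are drawn uniformly within each taxon's stratigraphic range
(extant taxa fixed at 0), and dating is repeated across draws so downstream
conclusions can be checked for robustness to range uncertainty.

* **equal** — node ages initialise at the oldest descendant tip age, the
  root is pushed back by `root_extension` (default 10 Myr, conventional in
  this literature), and each run of zero-length edges shares the duration of
  the closest positive ancestral branch equally along the path. With all
  tips at one age this spaces internal nodes evenly along the extension —
  a useful hand-checkable case.
* **mbl** — a tips-to-root pass sets each node to
  `max(oldest descendant tip age, oldest child age + mbl)` (default 1 Myr),
  so every branch meets the floor. As `mbl` goes to 0 this reproduces the
  first-appearance initialisation exactly.
* **hedman** — Bayesian node ages from successive outgroup first
  appearances. Time is discretised into `resolution` cells on (0, t0); the
  root posterior is built by the recursive integration over the outgroup-age
  chain (each divergence uniform between its constraint and the previous
  divergence), and every other node, visited root-to-tips, takes its
  parent's posterior as the distribution of its older bound with a uniform
  prior above its own oldest descendant tip age. Point estimates are
  posterior means, which strictly decrease toward the tips, so all branch
  durations are positive. The discretisation converges quickly: doubling
  the resolution moves node means by well under 0.5% at the default
  settings, and the two-constraint case is tested against direct
  quadrature. The outgroup ages and the upper bound t0 are user inputs —
  they are properties of the empirical dataset, not of the method.

All three methods guarantee strictly positive branch durations, which the
rate machinery requires.

## Rates

Per character, a single-rate Mk model is fitted on the dated tree and
marginal ancestral state probabilities are computed by the pruning
algorithm; each internal node takes its maximum-marginal state, ties broken
toward the lower state code for reproducibility. The per-character ML rate
is maximised over a fixed log-spaced grid (25 points across
10⁻³·⁵–10⁰·⁵ changes per character-Myr). The grid makes the likelihood
pass vectorise across all characters sharing a state count and ordering
type — partial likelihoods are k × characters matrices transformed in the
shared eigenbasis of the unit-rate generator — and a ~20% rate
discretisation has negligible effect on modal states, which is all the
change counting consumes. A fixed-rate entry point bypasses the grid and is
what the oracle tests use.

Changes are counted between modal states (deterministic, reproducible),
summed over characters with weights; a branch is scorable for a character
only when both ends carry information (scored tip; internal node with at
least one scored descendant). The Poisson exposure of a branch is its
duration times its weighted fraction of scorable characters — this is how
missing data enters the model. Expected (marginal-probability-weighted)
change counts are a recognised alternative; modal counting was chosen for
reproducibility and because the tests calibrate it directly.

Branch and bin tests compare a two-rate Poisson model (focal unit vs the
rest) to a one-rate model by a likelihood-ratio statistic against χ²(1),
with Benjamini–Hochberg correction at α = 0.05 by default. Branches
spanning several bins allocate duration and changes proportionally to
temporal overlap. Two properties of this scheme matter for interpretation:

* Under honest homogeneous Poisson data the test is well calibrated
  (empirical type-I error ≈ 5% at α = 0.05 in the acceptance suite).
* The allocation smears changes of boundary-spanning branches into
  neighbouring bins, so a planted rate pulse is recovered *attenuated* in
  adjacent bins; rate ratios should be read against non-adjacent baseline
  bins.

The replicated design (`rates_replicated()`) draws trees at random, dates
each several times per method, and returns all iteration curves plus their
pointwise mean — the "spaghetti plot" table. The default 5 × 5 = 25
iterations per method mirrors common practice.

## Disparity

SoV uses the n−1 variance over all retained axes. Bootstrap intervals are
2.5/97.5 percentiles over taxon resampling (500 replicates by default —
unstated in most applied work, so it is config-exposed); rarefaction
subsamples without replacement to the smallest bin size with at least two
taxa, reported in the output metadata. Bins with fewer than two ordinated
taxa are returned as NA rather than silently dropped.

## The synthetic-data generator

The generator is first-class, tested code: it produces a birth–death tree
(via `ape::rlineage`, i.e. two founder lineages diverging at the root age),
samples extant tips with a fixed probability and extinct tips with
probability `1 − exp(−ψ · terminal branch duration)`, brackets each fossil's
true age with a symmetric stratigraphic range (half-width 5 Myr by
default), and evolves characters root-to-tips by exact exponential waiting
times under Mk, with the instantaneous rate multiplied per time bin.
Ordered characters step between neighbouring states at half the base rate
per direction. Missing and inapplicable masks are i.i.d.

Default study conditions (chosen once, on scientific grounds, and then
frozen): ~40 sampled tips on a 250 Myr clade with high turnover
(birth 0.08, death 0.07 per lineage-Myr), fossil-dominated sampling whose
record reaches at least 60% of the root age — emulating a clade whose
fossil record spans its history — 200 characters at a base rate of 0.001
changes per character-Myr (about one change per character over the clade's
history, typical of conservative skeletal matrices), 25% missing and 5%
inapplicable cells, and 50 Myr analysis bins. The `burst` scenario plants a
3× multiplier in the 150–100 Ma bin; `expansion` freezes half the
characters until 150 Ma.

What the generator does *not* emulate — and therefore what green tests do
not establish about real data: characters are independent (no correlated
character suites), masking is unstructured (real inapplicability is
clade-structured, e.g. limb characters in limbless clades), there are no
polymorphic cells, rates are homogeneous across characters apart from the
bin multipliers, and cladogram error is only mimicked by local
rearrangement variants. Real matrices can violate any of these.

## Known limitations

The central caveat is inherited from the method itself: per-bin rate tests
condition on an *estimated* time-tree. A-posteriori dating from first
appearances mis-allocates exposure by tens of percent at realistic sampling
densities, and with enough characters the Poisson LRT will detect that
distortion rather than genuine rate variation — in development this showed
up as a high false-positive fraction whenever the per-bin change counts
were large. At the default study conditions (sparse changes, Hedman
dating) the planted burst is recovered in ≈95% of runs with a bin-level
false-positive fraction of ≈9% after correction — close to, not far below,
the nominal level. Applied conclusions should therefore rest on signals
that persist across dating methods, replicates and bin schemes, never on a
single dated tree; rate results on matrices with many fast characters
deserve particular caution.

Smaller notes: the root region is a boundary for ancestral-state inference
(changes near the root cannot always be polarised and edge bins are
estimated with the least exposure); the Hedman propagation treats the
parent posterior as the only older constraint for nodes without outgroup
information, which is diffuse where subtrees are all-extant; and PAM
cluster labels are arbitrary integers — only the partition is meaningful.

## Problem sizes used by the checks

The test suite and acceptance script run at fixture scale: 8–14 taxa for
the exact oracles, 40 tips × 200 characters for scenario recovery (20–100
seeded runs per property), 2000 replicates for LRT calibration, and a
15-tip × 40-character fixture for the 25-iteration replication design.
These sizes make every check exact or tightly converged while keeping the
whole suite runnable in minutes on one CPU.
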