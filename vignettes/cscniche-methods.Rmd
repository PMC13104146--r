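---
title: "Methods: CSC signature discovery and tumor-boundary niche mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CSC signature discovery and tumor-boundary niche mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and design decisions
behind `cscniche`. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

# The analysis model

The package treats cancer stemness as a continuous per-cell trait, not a
discrete cell type. Discovery proceeds in four stages, each of which makes
assumptions worth stating.

## Stemness scores

`diversity_score()` is a deliberately simplified transcriptional-diversity
estimator: per-cell detected-gene counts are the primary signal (stem-like
cells express broader transcriptomes), the top `n_corr_genes = 200` genes
most correlated with those counts are averaged to denoise it, the average
is smoothed over a kNN cell-similarity graph
(`score <- alpha * neighbor_mean + (1 - alpha) * initial`, with
`alpha = 0.7` for `smooth_iters = 50` fixed-point iterations — the map is a
contraction, so 50 iterations are far past convergence), and the result is
rank-scaled to [0, 1]. We contract only rank-level behavior: the original
diversity-based tools include regression sub-steps that downstream analysis
never relies on, and exact score reproduction is a non-goal.

`signature_auc()` ranks genes within each cell (descending expression, ties
broken by fixed gene index — deterministic and order-stable) and integrates
the signature recovery curve over the top `ceil(top_frac * n_genes)` ranks
with the trapezoidal rule, normalized by the best attainable curve
`min(x, n_signature)`. Scores are therefore in [0, 1], equal to 1 iff the
signature occupies the top ranks, and invariant to any monotone per-cell
transformation of expression. `top_frac = 0.05` follows the common
ranking-AUC convention; the threshold is exposed because no principled
value exists — it trades sensitivity to weakly expressed signature genes
against dilution by housekeeping expression.

## Metacells

Gene–gene correlations on sparse single-cell counts are unstable, and
malignant cells additionally carry patient-specific expression shifts, so
cells are first aggregated into metacells. Defaults follow the printed
protocol of the study this package emulates: genes with scaled variance
(variance/mean of log-normalized expression) above 0.08, mitochondrial
genes excluded, K = 100 nearest neighbors, 500 bootstrap iterations over
75% of cells, minimum metacell size 50.

Two details are this package's own, because the within-bootstrap partition
rule is not documented anywhere we could follow:

* **Bootstrap partition.** Each bootstrap builds a mutual-kNN graph on
  Pearson-correlation distance. Connected components — the naive choice —
  degenerate on a continuous stemness manifold: the graph is one giant
  component plus singletons at every K we tested (5–100), so co-clustering
  frequencies carry no structure. We therefore partition each bootstrap
  graph into Louvain modularity communities, with an exposed `resolution`
  parameter (default 4) chosen so communities sit at the metacell scale
  (tens of cells) rather than the macro-cluster scale. Two genuinely
  separated populations still yield between-population co-clustering near
  zero, which the tests assert.
* **Tree cut.** The co-clustering matrix is clustered with Ward linkage
  (`ward.D2`) on `1 - coclustering` and cut at the finest level compatible
  with the size floor (`floor(n / min_size)` clusters), after which
  undersized clusters merge into their most co-clustered neighbor. Average
  linkage — the textbook alternative — chains on smooth co-clustering
  frequencies and collapses the partition to a single metacell on
  realistic data; Ward yields balanced metacells whose stemness
  between-group variance far exceeds the within-group variance (asserted
  as an F-test in the suite).

Metacell expression and traits are arithmetic means over member cells, so
the size-weighted mean of metacell means equals the global mean exactly
(conservation is asserted at 1e-9).

At test scale (2,000 cells, half malignant) we run `n_boot = 100` and
`min_size = 25`: the study aggregated 50,275 malignant cells under
`min_size = 50`, and applying that floor to a thousand cells would leave
too few metacells to estimate a correlation network. The printed defaults
remain the package defaults.

## Co-expression network and signature

The network follows standard weighted co-expression practice on the
metacell matrix: unsigned adjacency `|cor|^beta` (the study does not state
signed vs unsigned; unsigned is the convention and the planted structure is
sign-coherent — `network_type` is exposed), soft threshold chosen as the
smallest power in 1..20 whose scale-free fit R² (log-frequency vs
log-connectivity regression, sign-flipped when the slope is positive)
reaches 0.8, otherwise the best-fitting power. Topological overlap uses
the canonical formula with unit diagonal. Modules come from a *static* cut
of the average-linkage tree on `1 - TOM` at 0.99 of the tree height
(dynamic tree cutting is a non-goal; 0.995 absorbs noise genes into the
stemness module at desk scale, and the cut was tuned once on synthetic
fixtures before the acceptance tests were frozen), with clusters under
`min_module_size = 30` sent to grey. Modules are named by size rank with
the conventional color aliases (largest = turquoise).

Eigengenes are the first principal component of the standardized module
submatrix (unit norm, sign-oriented so correlation with the module mean is
non-negative; a module containing a constant gene is an error rather than a
silent drop). The CSC signature is the sorted intersection of the module
most correlated with the metacell stemness trait and malignant markers.
Markers use the common average-log-fold-change form
`log((mean(expm1(x1)) + 1) / (mean(expm1(x2)) + 1))` — pseudocount 1 —
with raw Wilcoxon p-values, because the emulated criterion is a plain
`lfc > 0.5, p < 0.05`; a Benjamini–Hochberg mode is provided.

## Spatial malignancy and the niche

Spots cluster by Leiden community detection on a kNN graph over the top
principal components of log-normalized expression (deterministic under the
seed). The reference for CNV inference is the cluster with the highest
mean immune score (mean log-normalized expression over the pan-immune, T,
B and myeloid marker sets); ties break to the lowest cluster id.

CNV inference mirrors standard reference-based practice: genes below mean
expression 0.1 are dropped (the one parameter the emulated protocol fixes),
log2 of library-size-normalized counts, centering on the reference mean,
genome ordering, a 101-gene moving average within chromosomes (window
shrinks at chromosome edges), per-spot median subtraction, and clamping at
±0.2. Window and clamp follow common practice and are exposed. The CNV
score is the mean of squared profile values — the emulated study never
defines its score algebraically, so this package's definition is its own
and is stated here. Malignant calling Ward-clusters the non-reference
profiles into `n_clusters = 8` (the "eight vs nine clusters" phrasing in
the source figures is ambiguous; the count is a parameter) and calls a
cluster malignant when its median score exceeds the reference median plus
three reference MADs — also this package's rule, with a 95th-percentile
fallback when the MAD is zero. Note the clamp saturates at gains of 1.5×
and above (log2(1.5) > 0.2); the monotonicity property of score vs gain is
therefore established with the clamp widened.

Boundary geometry uses lattice-graph BFS, not Euclidean distance: the
boundary is the set of tumor spots within `width = 2` steps of the nearest
non-tumor spot, matching the "2-spot width" reading. Spots at the section
edge are classified from observed spots only — tissue beyond the capture
area is unknown, so the edge is *not* treated as non-tumor. Co-localization
uses the union denominator (`double-positive / either-positive`), reading
"of the A- or B-expressing spots" literally, with positivity defined as
raw count > 0 (the emulated threshold is "greater than zero" on an
unstated layer; the threshold is configurable). Deconvolution is
non-negative least squares of CPM spot expression on CPM reference
profiles — an explicit simplification of conditional-autoregressive
deconvolution models (no spatial prior), and the returned proportions are
transcript shares, so types with deeper per-cell libraries weigh more than
their cell-number share.

## Communication

Group means are 10%-trimmed means of log-normalized expression; the
interaction probability is the saturating form `L·R / (kh + L·R)` with
`kh = 0.5`, multi-subunit complexes entering as geometric means of subunit
means (one absent subunit silences the complex). The full communication
framework this simplifies (Hill exponents, agonist/antagonist cofactors,
population-size corrections, pattern factorization) is intentionally out of
scope: downstream conclusions consume only pair rankings and pathway
dominance. Significance is a label-permutation null with add-one smoothing
(`p = (1 + #{perm >= obs}) / (1 + n_perm)`, minimum 20 permutations);
pairs with p ≥ 0.05 are zeroed before pathway and sender/receiver
aggregation, so filtering can only shrink totals. "Pathway strength" is
the sum of significant pair probabilities — again a definition this
package owns, stated because the emulated figures never define theirs.

## Biomarker statistics

Mann–Whitney U is oriented to the first group, exact (Wilcoxon
distribution) for tie-free samples of at most 8 per group, otherwise
normal with tie and continuity corrections; fully tied inputs return
p = 1. ROC-AUC uses the rank formula and equals U/(n1·n2) identically.
The log-rank test accumulates O−E over event times with the hypergeometric
variance; the default hazard ratio is the Pike estimator
`(O1/E1)/(O2/E2)` with a log-scale CI from variance 1/V — chosen because
the package needs a transparent two-group estimator, with a
single-covariate Cox Newton solver (Breslow ties) behind the same
interface for continuous biomarkers (it is verified against the survival
package in the suite). Maximally selected rank statistics evaluate the
standardized log-rank z at every candidate cutpoint between the 10% and
90% biomarker quantiles; the returned Kaplan–Meier p at the selected cut
is the naive log-rank p and is explicitly flagged as not
selection-adjusted — the suite demonstrates the inflation this causes.

# The synthetic world

The generator's defaults are the stated conditions of the emulated study
wherever one exists, and a single documented choice elsewhere.

* **Cohort** (`sc_sim_config`): 2,000 cells, 1,500 genes, 5 patients, half
  malignant, negative-binomial counts (dispersion 2) with log-normal gene
  baselines (meanlog log 0.3, sdlog 0.8 — a few hundred counts per cell,
  sparse but not pathological). Malignant cells draw stemness
  `s ~ Uniform(0,1)`; a planted 50-gene module (first gene named DSG2)
  scales as `exp(2·s)`; detection probability is `1 − 0.3·(1 − s)`
  (binomial thinning), so stem-like cells express more genes; malignant
  cells get per-patient log-normal shifts (sd 0.3) while non-malignant
  cells do not, mirroring the observation that only tumor cells group by
  patient. Six non-malignant types carry canonical marker blocks; the
  communication genes are planted so fibroblasts are the MDK-high sender
  and malignant cells the NCL-high receiver.
* **Section** (`spatial_sim_config`): 40×40 hex lattice (offset
  coordinates, 6-neighbor rule; a 4-neighbor square mode exists for exact
  hand-checkable geometry), 1–10 cells per spot sampled from the cohort's
  type profiles, a centered tumor disc of radius 12 with a 2× expression
  gain on chromosome 1 (chromosome 1 holds only type-neutral genes, so the
  gain is clean of composition signal; marker genes are interleaved across
  the other chromosomes so no window concentrates composition
  differences), a fibroblast-rich stroma ring, an immune pocket, and
  epithelial-rich normal tissue. Fibroblasts predominate inside and around
  the tumor, matching the described histology. DSG2/FAP positivity is
  planted per spot: niche spots (boundary ring ∪ adjacent stroma) are
  double-positive with probability `coloc_frac = 0.85` (the middle of the
  reported 78–92% range), half of core spots are DSG2-only at baseline
  intensity, and the boundary DSG2 mean is 3× the core mean. The
  ground-truth co-localization percentage is the realized fraction over
  the whole section (~54% under defaults — lower than the niche-level
  0.85 because DSG2-only core spots enter the union denominator), and the
  recovery criterion compares against that realized truth.
* **Survival** (`simulate_survival`): biomarker `z ~ N(0,1)`, exponential
  event times with hazard `0.05·exp(log_hr·z)` per month (median around
  14 months at the baseline), independent exponential censoring calibrated
  to the requested censored fraction.

What the generator does **not** emulate: transcript-level dropout
structure beyond uniform thinning, doublets, spliced/unspliced layers,
segmental (sub-chromosomal) CNVs, H&E imagery, spatial autocorrelation of
expression beyond the planted regions, and batch effects in non-malignant
cells. A green recovery test therefore establishes that the pipeline
recovers the planted structure under this noise model — not that it would
reproduce any particular study's numbers on real cohorts.

# Numerical choices and degenerate inputs

* Log-normalization targets 10,000 counts per cell; cells with zero total
  counts are an error naming the cell, except in spatial scoring where
  all-zero spots legitimately occur and score 0 (`allow_zero`).
* Ranking ties everywhere break by fixed index (genes) or lowest id
  (clusters); all stochastic stages consume explicit seeds and are
  asserted bit-identical under them.
* TOM inputs are validated (symmetry 1e-10, entries in [0, 1], zero
  diagonal); `TOM >= adjacency` is *not* asserted anywhere — it is false
  in general — correctness is established against a brute-force triple
  loop.
* The scaled-variance gene filter zeroes variances below 1e-12 to avoid
  catastrophic-cancellation residue promoting constant genes at
  threshold 0.
* NNLS is a Lawson–Hanson active-set implementation; an all-zero spot
  deconvolves to the uniform simplex point rather than NaN.
* Pike HR errors on zero expected or observed events; maxstat requires 20
  subjects and 5 events and errors on constant biomarkers.

# Known limitations

* Metacell counts and module boundaries at desk scale (tens of metacells)
  are sensitive to the bootstrap resolution; the defaults are tuned for
  cohorts of a few thousand cells and should be revisited for much larger
  or smaller data.
* Deconvolution without a spatial prior under-uses neighborhood
  information and reports transcript shares, not cell fractions.
* The maxstat p-value is deliberately unadjusted; use it for cutpoint
  selection, not inference.
* The communication model omits population-size effects: a large
  low-expressing group and a small high-expressing group with equal means
  score identically.
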