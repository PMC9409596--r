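---
title: "How fdsweep quantifies trait-choice sensitivity of functional diversity metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How fdsweep quantifies trait-choice sensitivity of functional diversity metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdsweep)
```

## The question

Functional diversity (FD) metrics compress a community's trait composition
into single numbers, but their values depend on analyst choices that are
rarely standardised: how many traits enter the calculation, and how
correlated those traits are. `fdsweep` provides the machinery to measure
that dependence in grassland-like plant communities: it computes eight FD
metrics over *every* subset of the available traits, then models each
metric as a function of trait number and of the correlation structure among
traits.

## Data model and filtering

Two tables drive everything: a plot-by-species abundance matrix
(`CommunityMatrix`, percent cover or any non-negative abundance, with a
study label per plot) and a species-mean trait table (`TraitTable`, mixed
continuous and categorical traits, missing values allowed). Replicate trait
measurements are averaged into species means (`speciesMeanTraits()`);
categorical traits must be constant within a species.

Before metrics are computed for a trait subset, two rules are applied
(`filterTraitCoverage()`):

1. **100% trait coverage** — species missing any trait of the subset are
   removed everywhere. Rare species are the usual casualties, which mirrors
   field practice where trait campaigns cannot cover every rarity.
2. **80% abundance representation** — a plot must retain at least 80% of
   its original abundance after the removal; otherwise all of its records
   for that subset are marked missing. We apply this rule *per plot*: the
   alternative (dropping a whole study when any plot fails) discards far
   more data, and the plot is the unit at which metrics are computed.

Abundances are renormalised to relative abundances only *after* filtering,
per subset: each subset defines its own retained community. Undefined
metric values always propagate as `NA`, never as zero — a zero would be
read as "no diversity" by the downstream regressions.

## Distances and ordination

Gower dissimilarity (`gowerDistance()`) handles mixed trait types:
range-normalised absolute differences for continuous traits (ranges taken
globally over the filtered species pool, so distances are comparable across
plots), 0/1 mismatch for categoricals, averaged with equal weight. A
zero-range trait contributes zero, with a warning. Euclidean distance
(`euclideanDistance()`) is available for all-continuous subsets and
z-scores each trait by default, since trait units are incommensurate
(plant height in cm versus leaf nitrogen in %); the standardisation is a
config switch because practice varies.

Principal coordinates analysis (`pcoa()`) eigendecomposes the
double-centred Gram matrix. Axes with non-positive eigenvalues are dropped.
Gower matrices are generally not Euclidean-embeddable and can produce
negative eigenvalues; we deliberately apply no Cailliez or Lingoes
correction — the constants inflate every distance and distort hull volumes
— and instead record the dropped negative inertia on the result object so
the user can judge the distortion. Dissimilarity-based metrics are computed
on the distance matrix directly wherever possible; only functional richness
requires the ordination.

## The eight metrics

* **FRich** (`functionalRichness()`): convex hull volume of the present
  species in the first `dims` PCoA axes, conventionally `dims = 2`. The
  hull volume is computed exactly: shoelace formula in 2-D; in higher
  dimensions by enumerating supporting facets (all point subsets whose
  hyperplane leaves every other point on one side, coplanar groups merged)
  and summing centroid pyramids. Cost grows as C(S, d), which is immaterial
  at community sizes (tens of species, d ≤ 6). Degenerate configurations
  (too few species, collinear points, fewer positive axes than `dims`) are
  undefined, not zero.
* **FEve** (`functionalEvenness()`): branch-length/abundance regularity of
  the minimum spanning tree. For branch *l* joining species *i*, *j*:
  EW~l~ = dist(i, j)/(w~i~ + w~j~), PEW~l~ = EW~l~/ΣEW, and
  FEve = (Σ min(PEW~l~, 1/(S−1)) − 1/(S−1)) / (1 − 1/(S−1)). Requires
  S ≥ 3. The MST is built by Kruskal's algorithm with ties broken by
  (length, species index), so equal-length configurations are reproducible.
* **FDis** (`functionalDispersion()`): abundance-weighted mean distance to
  the abundance-weighted centroid, Σa~j~z~j~/Σa~j~. Centroids need
  coordinates, so distance-matrix input is embedded internally on all
  positive PCoA axes (exactly equivalent for Euclidean-embeddable input).
* **FDiv** (`functionalDivergence()`): (Δd + d̄~G~)/(Δ|d| + d̄~G~) with
  Δd = Σa~j~(z~j~ − d̄~G~), Δ|d| = Σa~j~|z~j~ − d̄~G~|, where d̄~G~ is the
  unweighted mean distance to the reference centroid. With explicit
  coordinates the reference centroid is the mean of the convex-hull vertex
  species (the metric's standard construction); in distance-only mode it
  falls back to the all-species mean, which stays defined without hulls.
* **Rao's Q** (`raosQ()`): Σ~i<j~ d~ij~p~i~p~j~, the expected trait
  distance between two random draws. (Some renderings of the formula show
  a single abundance factor; the standard quadratic form is used here.)
* **KDE richness / evenness / dispersion** (`buildHypervolume()` and
  friends): a Gaussian kernel mixture over species coordinates in z-scored
  continuous trait space, bounded at the density quantile enclosing 95% of
  probability mass, with volume estimated by importance sampling from the
  mixture itself (Vol = E[1{f ≥ t}/f]). Richness is the volume of the
  uniform-weight hypervolume; evenness the Jaccard overlap between the
  abundance-weighted hypervolume and the uniform-weight reference on the
  same coordinates (the closest constructible reading of "evenly
  distributed traits and abundances"); dispersion the mean distance of the
  retained random points to their centroid. Categorical traits are excluded
  — Gaussian kernels are undefined on unordered categories.

### KDE numerical choices

Bandwidths follow a per-dimension Silverman rule on the weighted sample,
with the sample size taken as the number of *distinct* species coordinates;
combined with inverse-CDF component sampling this makes hypervolumes
exactly invariant to splitting a species into duplicates with divided
weights, and bit-identical under a fixed seed. The boundary mass (0.95),
Monte-Carlo sample size (10 000 for standalone builds, 2000 default in
sweep configurations, 200 in the package's own end-to-end demonstrations)
and seed are all explicit configuration. Smaller sample sizes trade volume
precision (a few percent relative error) for speed; they do not bias the
trait-number trends, which aggregate over hundreds of subsets.

## The sweep

`enumerateSubsets()` generates every trait combination from pairs up to the
full set — for 10 traits: 45 pairs, 120 triples, 210 quadruples, and so on
to the single 10-trait set. `runSweep()` computes, for each subset: the
coverage filter, both distance types (Euclidean only for all-continuous
subsets), and all eight metrics per plot, emitting one long-format record
per (plot, metric, distance, subset, dims). KDE records are labelled with
the `"euclidean"` distance type, since they live in Euclidean trait space
rather than on a distance matrix. Per-cell failures are caught, logged and
recorded as missing; a sweep never aborts.

`correlationSummary()` attaches the trait-correlation side of the design:
for 4-trait all-continuous subsets, the minimum, maximum and mean of the
six pairwise Pearson correlations on species means. We summarise
*absolute* correlations by default — the redundancy hypothesis concerns
correlation strength, not sign — and expose the convention as an argument,
since a signed reading is also defensible.

## Inference

`fitMetricVsTraitNumber()` and `fitMetricVsCorrelation()` fit each metric
against trait number (or a correlation summary at fixed k = 4) as
polynomials of degree 1–4 with a per-plot random intercept, by maximum
likelihood — ML rather than REML because AIC comparisons across
fixed-effect structures require it. The minimum-AIC degree is selected,
ties resolved toward the lower degree. Repeated measures within a plot are
controlled by the random intercept alone; an AR(1) residual structure is
deliberately omitted because trait subsets have no natural ordering along
which serial correlation could be defined. With a single plot the machinery
degrades to ordinary least squares.

Each test's p-value is the likelihood-ratio test of the selected model
against the intercept-only model (coefficient-level Satterthwaite p-values
are also reported). `runInference()` collects all tests of a run — every
metric × predictor combination fitted — and applies Benjamini–Hochberg
adjustment across that whole family, the widest defensible choice given
that the family is otherwise unspecified.

## The synthetic generator

No site data ship with the package; `makeBenchmarkSuite()` builds three
study-like datasets whose shapes mirror the grassland settings the
pipeline targets:

* a planted biodiversity experiment: 16-species pool, 48 plots, 10
  continuous traits, per-plot richness 8–16, lognormal abundances;
* a tallgrass watershed survey: 60 species, 4 transects, 12 traits of
  which 2 categorical (photosynthetic pathway, growth form), richness
  25–40;
* a desert grassland: 40 species, 60 quadrats, 10 traits (1 categorical),
  richness 4–12, geometric rank-abundances with ratio 0.2 so the top
  species holds roughly 80% of cover, as desert grasslands dominated by a
  single grama grass do.

Continuous traits come from a Gaussian copula: a multivariate normal with a
block-structured target correlation (a "leaf-economics-like" correlated
block of four traits at ρ = 0.7 over a 0.05 background), pushed through
mild monotone marginal transforms — lognormal for size-like traits,
logit-normal for fraction-like ones. The transforms are kept mild
(log-scale SD 0.25) so Pearson correlations of the emitted values track the
latent targets; strongly skewed marginals would attenuate them. Categorical
traits are independent multinomials by default, as no cross-type dependence
is specified for the target systems. Missingness is applied preferentially
to rare species (the rarest get about twice the nominal rate, the
commonest almost none), reproducing the field reality that trait campaigns
under-sample rarities — this is what makes the coverage filter and the 80%
rule bind.

What the generator does *not* emulate: intraspecific trait variation,
spatial structure among plots, environmental filtering linking trait
values to abundances, and trait–category dependence. Passing tests on
synthetic data therefore demonstrate the correctness and stability of the
machinery under realistic marginal structure, not ecological conclusions
about any real site.

## Problem sizes and determinism

The package's own end-to-end demonstration runs the three synthetic studies
through every subset (1013, 4083 and 1013 subsets respectively), both
distance types, all eight metrics and the full inference stage — about
1.4 million metric records — using 200-point Monte-Carlo hypervolumes;
that scale keeps a complete run in the minutes range on a single core
while leaving all trends measurable. Every stochastic component (trait
generation, community assembly, hypervolume sampling) is seeded explicitly
and restores the caller's RNG state, so identical configurations reproduce
byte-identical outputs.

## Known limitations

* Gower negative-eigenvalue inertia is reported, not corrected; hull-based
  richness on strongly non-Euclidean Gower spaces inherits that
  approximation.
* The exact hull algorithm is exponential in the dimension and intended
  for `dims` ≤ ~6; the conventional analysis uses 2.
* KDE metrics silently skip categorical traits; a subset with a single
  continuous trait yields 1-D hypervolumes.
* The 80% representation rule is evaluated per plot; per-study evaluation
  is a defensible alternative the package does not implement.
* Correlation summaries use absolute Pearson correlations on species
  means; rank-based alternatives are not provided.

## A minimal run

```{r example, eval = FALSE}
suite <- makeBenchmarkSuite(seed = 1)
st <- suite$biocon
subsets <- enumerateSubsets(traitIds(st$traits))
sw <- runSweep(st$community, st$traits, subsets,
               sweepConfig(kdeSamples = 200))
corr <- correlationTable(st$traits, subsets)
inf <- runInference(sw, corr)
inf$table
```
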