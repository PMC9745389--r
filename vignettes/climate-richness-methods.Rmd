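---
title: "Methods: colonization time, diversification rate, and climate-richness relationships"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colonization time, diversification rate, and climate-richness relationships}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(climrich)
```

# The question

Species richness is almost always correlated with climate, but a correlation
with climate is not an explanation: richness in a climatic zone can only
change through speciation, extinction, and dispersal. Two process-level
hypotheses can connect climate to richness through those mechanisms:

* **Diversification rate** — some climates sustain faster net
  diversification (speciation minus extinction), so the clades occupying
  them proliferate more;
* **Time for speciation** — high-richness climates were colonized earlier,
  so lineages there simply had longer to accumulate species. This hypothesis
  presupposes climatic niche conservatism: lineages tend to stay near the
  climate of their ancestors, so colonization of a new climatic zone is a
  datable, relatively rare event.

`climrich` implements the full analysis chain needed to confront the two
hypotheses with data: a time-calibrated phylogeny, a grid-cell climate table
(mean annual precipitation, MAP, mm/yr; mean annual temperature, MAT, °C),
and a species-by-cell occurrence table.

# The pipeline

## Climatic bins and richness

Each species' climatic distribution is summarized over the grid cells it
occupies (min/mean/max per variable). The observed range of cell values is
divided into half-open bins `[lower, upper)` (top bin closed); the
conventional defaults are 17 MAP bins and 14 MAT bins, both configurable. A
species joins every bin its min–max envelope intersects — a species spanning
250–350 mm of MAP under 100-mm bins joins both the 200–300 and the 300–400
bin. Per bin we report:

* **regional richness** — the number of species whose envelopes intersect
  the bin;
* **area** — the number of grid cells whose climate value lies in the bin;
* **local richness** — the mean number of resident species per cell among
  those cells (cells with no residents count 0; a bin with no cells has no
  local richness). Averaging per cell corrects for the very different areas
  occupied by different climates.

Boundary ownership (half-open intervals) is a convention; the qualitative
results never depend on it, but it guarantees each cell value falls in
exactly one bin.

## Diversification rates

Two standard estimator families are provided.

**Clade-level (method of moments, stem age).** For a clade with `n` extant
species and stem age `t` (the age of the node where the clade attaches to
the rest of the tree),

$$\hat r = \frac{\log[n(1-\epsilon)+\epsilon]}{t},$$

where `epsilon` is the assumed extinction fraction (extinction/speciation;
0, 0.5 and 0.9 are the conventional settings). A monotypic clade always gets
rate 0. Each member species inherits its clade's rate, using either regional
(`richness_region`) or global (`richness_global`) clade richness; clades can
be filtered to those predominantly occupying the focal region (fraction of
species ≥ 0.60 by default, boundary inclusive). Crown-age variants are
deliberately not implemented: the workflow is built around stem ages, which
exist for every clade including monotypic ones.

**Species-level (DR statistic).** The equal-splits measure of tip `i` sums
the branch lengths on its root path with weights halved at each successive
split away from the tip (the root's own subtending edge is excluded, the
usual convention); DR is its inverse. High DR marks tips embedded in dense,
recent splitting. An optional exclusion threshold drops the highest-DR
species before bins are aggregated — the published sensitivity analyses drop
DR > 1.5/Myr, about the top 5% on the empirical tree — because a small
fraction of very young species can otherwise dominate bin means.

Per-bin rate summaries report both the species-weighted mean and the median,
plus counts of unrated and excluded species.

## Trait models, signal, ancestral states

Species mean climate values are modeled on the tree under four Gaussian
models: Brownian motion (BM), Pagel's lambda (LA; BM with off-diagonal
covariance shrunk by `lambda`), single-peak stationary Ornstein–Uhlenbeck
(OU; covariance `(sigma2/2*alpha) exp(-alpha d)` in patristic distance `d`),
and white noise (WN). All likelihoods are exact maximum likelihood computed
by Felsenstein pruning on a transformed tree (lambda transform for LA;
node-height transform plus root edge for OU), in linear time per evaluation;
the test suite verifies them against dense multivariate-normal algebra. The
root state is the GLS mean and `sigma2` its profiled ML value; `lambda` and
`alpha` use bounded one-dimensional optimization (tolerance 1e-8; `lambda`
in [0,1], `alpha` in [1e-8, 50/tree height]). Models are compared by AIC
(`2k - 2 lnL`; k = 2 for BM/WN, 3 for LA/OU), ties going to the simpler
model. AICc is not used, matching the cited workflow's explicit choice.

Phylogenetic signal is `lambda` itself, with a likelihood-ratio test of
`lambda = 0` against a one-degree chi-squared — the working test of niche
conservatism. Note this is conservative: an OU process can conserve niches
while depressing measured lambda.

Ancestral climatic values are conditional expectations under BM or under LA
at the fitted lambda, computed by a two-pass message-passing algorithm
(tip-to-root peeling, then root-to-tip distribution of the complementary
information). At `lambda = 1` this is exactly BM; at `lambda = 0` every
internal node collapses to the GLS grand mean. Rate-heterogeneous (multiple
variance) Brownian reconstruction is out of scope; the lambda model is the
supported route, which published robustness checks report as giving similar
downstream results.

For trees too large to reconstruct at once, the two-stage workflow
reconstructs within each genus (BM), takes each genus' crown estimate as a
single tip datum placed at the genus crown age (terminal branch = stem age −
crown age), and reconstructs again on that genus-level tree. Genera must be
monophyletic; violations are reported by name rather than silently resolved.
The within-genus model is BM (genera are small and young, so lambda is
poorly identified inside them); the genus-level stage defaults to LA.

## Colonization times

The first colonization of a bin is dated by the oldest lineage reconstructed
inside it: candidates are internal nodes whose reconstructed value falls in
the bin (at their node age) and extant tips whose observed climatic range
intersects the bin, dated at half their terminal branch length (the
half-age rule; "species age" is read as the terminal branch length). The
recorded time is the maximum over all candidates and is a minimum age for
the colonization. When both node and tip candidates exist the overall
maximum is used; ties are kept in the record. Tip ranges (not just means)
intersect bins by default, mirroring the data available at tips versus
nodes; a mean-only mode is provided.

## Regressions and the hypothesis tally

Bin-level relationships (climate~richness, rate~richness, time~richness) use
ordinary least squares — there is no phylogeny among bins — with the overall
F-test p-value, r², and AIC from the profiled Gaussian likelihood so linear
and quadratic fits are comparable. Across clades (rate~climate), phylogenetic
generalized least squares with the lambda-scaled Brownian covariance is
provided, with `lambda` fixed at 1 by default or estimated by ML; weighting
bins in the bin-level regressions was considered and rejected in favor of the
plain unweighted fits the published workflow reports.

Within-clade replication reruns the chain inside each named clade and
tallies, at p < .05, whether richness is explained by time and not rate,
rate and not time, both, or neither. The default tally follows the raw
p-value rule (sign-agnostic, as in the published tables); a companion tally
requiring a positive slope is always reported, since "support" for either
hypothesis is directional.

# The synthetic generator

Because the full empirical data set (a flora-scale phylogeny with gridded
ranges) is not shippable, every stage is validated against a generator with
known ground truth:

* **Trees** — constant-rate birth–death conditioned on the number of tips,
  or trait-dependent branching (below).
* **Niches** — exact forward simulation under BM/LA/OU/WN, with true
  internal-node values retained for scoring reconstructions.
* **Landscape** — a 1-D climate gradient of grid cells (default spacing: 50
  mm MAP, 0.5 °C MAT); a species occupies every cell within `halfwidth` of
  its niche value (defaults 150 mm and 1.5 °C, so an envelope spans roughly
  two bins, matching the scale of the worked binning example). MAP and MAT
  are generated independently; the analyses treat them separately throughout.
* **Taxonomy** — genera are random monophyletic clusters with varying stem
  ages (stochastic preorder stopping, mean cut 0.35 × tree height, ~7–8
  species per genus), emulating real taxonomies in which genus ages vary
  widely.

Three scenarios fix the causal structure:

* **time** — homogeneous birth–death (0.1/0.02 per Myr), fully conserved
  Brownian niche whose standard deviation at the present is calibrated to
  600 mm (6 °C) regardless of tree height. Zones near the root niche are
  colonized earlier and accumulate more species; true rates are constant.
* **rate** — speciation rises linearly with the niche value (0.05 to 0.5
  per Myr across the gradient) in a discrete-time forward simulation
  (step 0.2 Myr, niche Brownian rate 30000 mm²/Myr, reflecting bounds,
  no extinction); richness tracks the niche–rate ramp, and the generator
  stores each tip's true birth rate.
* **null** — homogeneous tree with a signal-free (white-noise) niche; no
  engineered relation between richness, time, or rate.

The generator is bit-reproducible per seed and echoes its configuration in
the bundle.

## What the scenarios do and do not establish

Two findings from calibrating the scenarios deserve emphasis, because they
delimit what a passing end-to-end run demonstrates about real data.

**Estimated rates inherit a positive richness bias in small time-driven
worlds.** In the time scenario the true rate is constant, yet the bin-level
regression of estimated rate on richness comes out significantly positive
in roughly a third of 200-tip replicates — under every estimator variant we
tried (DR or stem method-of-moments at any `epsilon`, mean or median
aggregation, with or without high-DR exclusion, 8–17 bins, up to 500 tips).
The mechanism is order statistics under niche conservatism: the species that
reach climatically extreme, species-poor zones are disproportionately
lineages with long independent histories, and every lineage-density-based
estimator scores exactly those lineages as slow. The published analyses the
package follows report the same phenomenon on real data as spuriously
positive DR–richness relationships driven by a few percent of species. At
flora scale (tens of thousands of species) the clade-level route escapes it;
at a few hundred tips it does not. Consequently the end-to-end expectation
we can honestly certify is asymmetric: the time signal is essentially always
detected in time-driven worlds, and the rate signal is detected in most
rate-driven worlds, but the *absence* of a positive rate–richness relation
in a time-driven world cannot be guaranteed at these sizes, and the
corresponding check is expected to fail until much larger problem sizes are
feasible. Users comparing the two regressions on modest trees should weigh
the rate result accordingly.

**Colonization times need phylogenetic signal.** When the niche carries no
signal (the null scenario), reconstruction collapses to the grand mean and
bin dating falls back to the half-tip-age rule; the maximum over more tip
candidates in richer bins is then mechanically older, producing a spurious
positive time–richness association in most replicates. The method is
explicitly premised on high signal — the empirical analyses it mirrors
report lambda near 1 — so colonization-time results should only be
interpreted after confirming significant signal, which the pipeline reports
alongside every run. The null scenario therefore validates the generator's
lack of structure (constant true rates, lambda estimates near 0), not a 5%
false-positive rate for the time regression.

# Numerical choices and degenerate inputs

* Non-ultrametric trees are tolerated (warning when tip-depth spread exceeds
  1e-6 × height); node ages are max-descendant-depth based. OU fitting
  requires ultrametry and refuses otherwise.
* Zero-length terminal branches are allowed (a tip-dated colonization then
  gets time 0); zero-length *sister* pairs with distinct values make the
  covariance singular and are reported as errors rather than silently
  regularized.
* Constant tip values short-circuit every fit to `sigma2 = 0` with a
  `degenerate` flag instead of failing inside the optimizer; lambda on a
  star tree is flagged `unidentifiable`.
* Optimizer estimates within 1e-6 of a bound are flagged `at_bound`.
* AIC ties (exact) go to the model with fewer parameters; the comparison is
  order-invariant.
* All randomness in the generator flows from a single integer seed.

# Problem sizes used in validation

The shipped validation suite runs parameter recovery at 200–300 tips with 50
replicates, regression calibration with 300–500 replicates, and scenario
discrimination with 50 time-driven and 25 rate-driven 200-tip replicates —
sizes chosen so the whole suite completes on a laptop in a few minutes while
keeping Monte-Carlo error on the reported proportions a few percentage
points.

# Known limitations

* Rate-heterogeneous Brownian reconstruction (multiple-variance models) is
  not implemented; LA is the supported reconstruction model.
* No spatial structure beyond the climate gradient: no adjacency, dispersal
  kernels, or paleoclimate change through time.
* PGLS supports a single predictor (the rate~climate use case), not general
  model formulas.
* The colonization estimator returns point times; uncertainty in the
  reconstructions is not propagated.
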