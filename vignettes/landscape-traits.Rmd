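---
title: "Patch-level landscape metrics as plant traits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-level landscape metrics as plant traits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchtraits)
```

`patchtraits` analyses centimetre-resolution maps of plant patches on small
vegetation plots and asks whether the geometry of a species' patches — how
large, how numerous, how ragged — behaves like a functional trait: a
species-level attribute that covaries with classical traits such as canopy
height or leaf economics. This vignette documents the models, conventions
and numerical choices behind the package, in the spirit of the methods
vignettes of ordination and differential-analysis packages: it explains what
is computed and why, and what the accompanying tests do and do not
establish. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The raster model of a plot

A plot is a regular grid (by convention 100 × 100 cells of 1 cm) whose cells
hold one integer species code each, 0 for bare substrate; mixed occupancy
within a cell is not representable. Coordinates are 0-based `(row, col)`
with row 0 at the top. Two occupied cells belong to the same *patch* when
they share an edge and a species code (the four-neighbour or rook rule);
diagonal contact separates patches. This raster is taken as the
authoritative representation of the mapped vegetation — the analysis never
refers back to vector outlines.

Perimeter counts every unit edge between a patch cell and anything outside
the patch: bare substrate, another species, *or the plot boundary*. Plots
are windows into a larger mosaic, but treating the boundary as edge keeps
every patch's perimeter well defined without torus artefacts; since all
plots share the same extent, the convention affects all of them alike.

## Patch and plot metrics

Per patch the package reports area `A` (cells × cell-size²), perimeter `P`,
and the square-normalised raster shape index `P/(4√A)`. The square
normalisation (rather than the circle-based vector form, which scores a
square ≈ 1.128) is chosen so that the index is exactly 1 for every n × n
square and grows without bound with irregularity; on integer geometry small
non-square patches can only exceed 1.

Seven plot-level metrics summarise each mosaic: MPS (mean patch area, cm²),
PSCV (100 × population sd of areas / MPS; the population sd makes PSCV = 0
exact for a single patch), TE (sum of per-patch perimeters, cm), NP, MSI
(mean shape index), PR (number of species present) and SHDI
(−∑ pᵢ log pᵢ in nats). Two conventions deserve emphasis:

* **TE counts shared boundaries twice.** An edge between two patches of
  different species contributes to both patches' perimeters and hence twice
  to TE. This keeps TE consistent with MSI (both derive from the same
  per-patch perimeters); the alternative single-count reading of "total
  edge" would decouple them.
* **SHDI proportions are over vegetated area only**, excluding bare
  substrate. This is required for the defining identity SHDI = 0 whenever
  PR = 1, regardless of how much of the plot is bare, and gives the upper
  bound SHDI ≤ log PR with equality at equal species areas.

Species-level aggregates (frequency of occurrence, MPS ± sd, total cover,
MSI ± sd, NP, TE) use the sample standard deviation, as they describe a
sample of patches per species. Distribution summaries report moment-based
skewness g₁ = m₃/m₂^1.5 and type-7 (linear-interpolation) quartiles.

## Community structure

Relevés are compared with Bray–Curtis dissimilarity on cell-count
abundances and clustered by Ward linkage. The default variant is the
classic `ward.D` criterion applied to the unsquared dissimilarities —
matching the era's default behaviour of standard hierarchical-clustering
software — with `ward.D2` available as an option; with the survey data this
package is modelled on, the cluster-wise ANOVA F statistics would arbitrate
between the two, and the default is the variant to try first. Cluster
labels are canonicalised (each cluster is keyed by its *characteristic
species*, the species whose mean abundance inside most exceeds that
outside; clusters are ordered by that species' within-cluster abundance) so
that assignments are reproducible across input orderings. The number of
clusters is a parameter, default `k = 3`; no optimal-k machinery is
included. Landscape metrics are screened across groupings by classical
one-way fixed-effects ANOVA with t-based 95% intervals per group; only the
omnibus F is reported, no post-hoc tests.

## The coupled ordination

Let `L` (plots × species) hold nonnegative abundances, `R` (plots ×
metrics) and `Q` (species × traits) quantitative variables. With
`P = L / sum(L)`, row margins `r` and column margins `c` of `P` supply the
correspondence-analysis weights. `R` is centred and normed column-wise
under `r`, `Q` under `c` ("centred normed" analyses; population-style
weighted variance). The cross table

&nbsp;&nbsp;&nbsp;&nbsp;`X = t(R̃) P Q̃` (metrics × traits)

is decomposed by SVD; the squared singular values λₐ are the RLQ
eigenvalues, ∑λ is the total co-inertia, and
`∑λ = ∑ X²` links the ordination to the fourth-corner statistics exactly
(the tests assert this identity to 1e-10). Plot scores are `R̃ U`, species
scores `Q̃ V`; variable–axis associations are weighted Pearson correlations
of the raw columns with these scores under `r` (metrics) and `c` (traits).
Per-axis inertia contributions are the squared loadings × 100, so each axis
sums to 100% and the conventional two-axis summary sums to 200%.

Numerical choices: the SVD is taken of `X` directly rather than an eigen
decomposition of `XᵀX` (better conditioned); eigenvalues below 1e-12 of the
largest are treated as zero and their axes dropped; and because singular
vector signs are arbitrary, each axis is oriented so that the metric with
the largest |loading| loads positive, making outputs deterministic (tests
that compare associations use absolute values anyway). Ordinal traits
(e.g. a 1–6 lateral-spread score) are treated as quantitative; no
Hill–Smith mixed coding is provided.

## Partial RLQ

To ask whether a categorical plot covariate (terrain-age class ta1–ta3 or
cobble-cover class ts1–ts3) structures the trait–metric coupling, the
metric table is conditioned on the partition: the *normed* metrics are
centred within each covariate class (using the row weights restricted to
the class) and the decomposition is rerun. The ordering — norm globally,
then centre within classes, with no second norming — is deliberate: it
reduces exactly to the basic analysis when the partition has one class, and
a metric fully determined by the classes is annihilated rather than being
re-inflated to unit variance. `Q` is left untouched, since the covariate
partitions samples, not species. The diagnostic is comparative: a
substantially *higher* leading-axis share after conditioning would indicate
that the covariate matters. Conditioning the correspondence analysis of `L`
on the same partition is a documented alternative scheme that this package
does not implement.

## Fourth-corner permutation tests

Each entry of `X` is a weighted correlation between one trait and one
metric through the abundances, tested against two distinct nulls:

* **Model 2** permutes whole plot rows of `L`, destroying any link between
  abundances and the plot metrics while preserving the trait structure —
  it tests L↔R.
* **Model 4** permutes species columns of `L` (equivalently rows of `Q`) —
  it tests L↔Q.

Per-cell tests are two-sided on |X[j,k]|; the global statistic is ∑X² = ∑λ.
All p-values use the add-one estimator `(b + 1)/(B + 1)`, which never
returns zero, with `B = 49999` as the conventional default. Weights are
recomputed under every permutation (they travel with the rows/columns of
`L`). A trait–metric pair is declared significant only when *both* nulls
are rejected — the cell-wise max-p rule — and flags are reported under two
conventions, α = √0.05 and α = 0.05. The √0.05 convention assumes the two
component p-values are independent and uniform so that the combined level
is ≈ 0.05; when one of the links genuinely holds, that assumption fails and
only the α = 0.05 flags control the trait-link error at the nominal level
(conservatively). Both are emitted precisely because the conventions
disagree in that regime. Raw combined p-values are reported by default; an
optional Benjamini–Hochberg adjustment across cells is available behind the
`fdr` flag but off by default. Variable–axis associations are tested the
same way, recomputing the ordination under each permutation and comparing
|correlation|.

One practical note on discreteness: with `B` permutations, p-values are
multiples of `1/(B+1)`, so the exact-level rejection rule for a calibration
study is `p ≤ α` (the strict `<` rule rejects slightly below nominal). The
per-cell significance *flags* keep the strict `<` convention.

## The synthetic-study generator

`simulation_config()` describes a simulated campaign shaped like the field
design the package is modelled on: 46 plots of 100 × 100 cells, 16 species,
9 traits (one ordinal 1–6 column), and three-level terrain-age and
cobble-cover classes assigned independently of everything else — the
covariate-null scenario, with an optional effect size for conditioning
studies. Species patches are grown as Eden blobs: from a uniformly random
free seed cell, uniformly random frontier cells accrete until a lognormal
target area (default meanlog `log(28)`, sdlog 0.9 in cells — mean ≈ 43 cm²
and strongly right-skewed, matching the patch-size regime such surveys
report) is reached or the patch is boxed in; overlaps resolve first-come in
randomised patch order. This yields shape indices mostly in the 1.0–1.7
range observed for cushion/tussock vegetation. Occupancy (default 0.35 per
species × plot) and patches-per-occupied-species (default 5) give per-plot
richness near 6 and a few dozen patches per plot, comparable to the
motivating survey.

A single coupling parameter β ≥ 0 ties a latent species axis `z` to the
mosaic through two channels: species sorting (the occupancy logit gains
`β·z·u` for a plot gradient `u`) and patch size (log target area gains
`0.35·β·z`). Traits load on `z` with fixed loadings. At β = 0 the traits
are independent of everything — the trait-link null is exactly true — while
β ≈ 2 produces strong coupling. Every plot is guaranteed at least one patch
(metrics are undefined on empty plots). Given a seed the study is bit
reproducible, and the emitted `R` and `L` tables are recomputed from the
emitted rasters, so tables and rasters are exactly self-consistent.

**What the generator does not emulate** — and hence what passing tests do
not show about field data: spatial autocorrelation between plots, species
interactions (competition, facilitation) beyond first-come crowding,
observation error in the mapping, non-lognormal patch-size mixtures, and
covariates that act on patch geometry rather than on the gradient.
Crucially, because the metric table is *computed from the same rasters* as
the abundance table, the L↔R link is structurally real even at β = 0; only
the trait side is a true null there. Calibration claims are therefore made
for the trait-link (model 4) test, and the √0.05 flags are expected to be
anticonservative in exactly the way described above.

## Simulation sizes used by the tests

The package's own validation runs use deliberately chosen problem sizes:
property tests and oracles run on 12 × 12 rasters and tables of 6–12 plots;
the type-I calibration draws 1,200 replicates of a 24-plot, 40 × 40-cell,
8-species, 4-trait design at β = 0 with 199 permutations; power and
monotonicity use the full 46-plot design with up to 399 permutations; and
the acceptance script uses the full design with 49,999 permutations. These
sizes give Monte-Carlo standard errors comfortably inside the asserted
tolerances.

## Interfaces and limitations

The package is organised tibble-first: every analysis function accepts data
frames (identifier in the first column) or labelled matrices and returns
tibbles or fitted objects with `tidy()`, `glance()` and `autoplot()`
methods; `run_study()` drives the full chain and writes stable CSVs plus a
run manifest. The functions themselves are the intended interface — the
expected user is an R analyst, so no shell entry point is shipped.

Known limitations: only permutation models 2 and 4 of the general
fourth-corner framework are implemented (models 1, 3, 5, 6 are not);
categorical traits are coded numerically rather than by chi-square
fourth-corner variants; partial RLQ conditions `R` only; vector (GIS) patch
input is out of scope — rasters are the native representation; and the
deposited plot-level tables of the motivating survey are not redistributed,
so the tests that compare against its published values run only when those
files are installed locally (see `?nardis_deposited_tables`).
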