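---
title: "Quantifying spatially structured phylogenetic congruence between symbiont lineages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatially structured phylogenetic congruence between symbiont lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cophylospace)
```

## The problem

In obligate symbioses such as lichens, the evolutionary history of one
partner (the fungal mycobiont) may track the history of the other (the
green-algal photobiont). When it does, the pairwise genetic distances of
the two partners are correlated across specimens — *phylogenetic
congruence*. But both partners also live in space: dispersal limitation,
habitat structure and partner availability can make genetic variation
spatially autocorrelated, and a naive congruence estimate then conflates
"partners track each other" with "both partners track geography".

`cophylospace` separates these signals. Its inputs are two paired
genetic distance matrices (one per partner, specimens matched by
identifier) and, optionally, specimen coordinates. Its outputs are

* a **variance partition** of one partner's genetic variation into four
  adjusted-R² fractions — partner alone `[a]`, spatially structured
  partner variation `[b]` ("shared"), purely spatial `[c]`, and
  unexplained `[d]` — computed in both dependent-matrix directions, and
* a **Procrustes congruence test** (the tree-free "Procrustes approach
  to co-phylogeny") with a permutation p-value and per-specimen
  residual diagnostics.

Everything is distance-based: no phylogenetic trees are estimated, which
avoids committing to a single topology at the cost of not being able to
reconstruct individual events such as algal switches.

## The procedure, stage by stage

### Genetic and geographic distances

From aligned sequences the package computes uncorrected *p*-distances
(the proportion of differing sites among pairwise-comparable sites) or
Tamura–Nei (TN93) model-corrected distances. Sites where either sequence
of a pair carries a gap, `N` or an IUPAC ambiguity code are excluded
pair by pair (*pairwise deletion*, the default) rather than removing
whole columns; complete deletion is available. Ambiguity codes are
treated as missing, not partially matched — the simplest defensible
rule, and it is recorded in the output attributes.

TN93 estimates base frequencies from the two sequences of each pair at
their compared sites (per-pair, the common default; a global option uses
the whole alignment and then matches `ape::dist.dna` exactly). A
saturated pair — any logarithm argument non-positive — is flagged
`inestimable` and propagated as `NA`, never as a silent `NaN`. Where
both are defined, the TN93 distance dominates the *p*-distance.

Geographic distances are haversine great-circle distances on a sphere of
radius 6,371,000 m. At the spatial extents this analysis targets (meters
to ~1,300 km) the sphere/ellipsoid discrepancy (< 0.5%) is far below
anything the spatial eigenfunctions can resolve.

### Principal coordinates (PCoA)

All ordinations share one implementation: Gower double-centering of
\(-\tfrac12 d_{ij}^2\), symmetric eigendecomposition, axes scaled by
\(\sqrt{\lambda}\). Genetic distance matrices are frequently
non-Euclidean; by default the negative-eigenvalue axes are counted and
excluded from coordinates (common db-RDA practice), with the Lingoes and
Cailliez additive corrections available by configuration. Eigenvalues
are called positive above a relative tolerance of \(10^{-10}\lambda_1\),
so rounding-level eigenvalues of degenerate inputs do not produce
phantom axes.

### Moran's eigenvector maps (MEMs)

Spatial predictors are the classic distance-based spatial
eigenfunctions (PCNM): geographic distances above a truncation
threshold *t* are replaced by 4*t*, the modified matrix is put through
PCoA, and positive-eigenvalue axes are retained — at most *n* − 1 of
them. `MEM1` is the broadest spatial scale; higher indices are finer.
When *t* is not supplied it is the largest edge of a minimum spanning
tree over the locations (the smallest threshold keeping the points
connected); ties among candidate edges are resolved by lexicographic
node order, so the rule is deterministic given input order. On regular
transects the eigenvectors' Moran's I (binary neighbour weights at
d ≤ *t*) decreases with the index, which is what "broad to fine scale"
means operationally.

### db-RDA, forward selection, variance partitioning

Distance-based redundancy analysis projects the response PCoA
coordinates onto the column space of centered predictors;
\(R^2\) is the constrained fraction of total inertia, adjusted by the
Ezekiel formula \(1-(1-R^2)(n-1)/(n-m-1)\) with *m* the predictor rank.
Significance is by permutation of response rows with the convention
\(p = (\#\{F_{perm} \ge F_{obs}\}+1)/(n_{perm}+1)\), which cannot
return zero.

Spatial predictors enter by greedy forward selection: at each step every
remaining eigenvector is tested by a permutation test of its partial
pseudo-F given the already-selected set (999 permutations and entry
threshold α = 0.05 by default; both configurable and logged). Ties on
the p-value lattice are broken by larger added R², then lower index.
Only the α stopping rule is applied; an adjusted-R²-based double
stopping criterion is a documented possible extension, not the default,
because the selected-set sizes reported for this analysis style come
from the plain α rule.

With partner predictors `P` and selected spatial predictors `S`, the
partition uses three fits, `A = adjR²(P)`, `B = adjR²(S)`,
`AB = adjR²([P S])`:

    a = AB − B,  b = A + B − AB,  c = AB − A,  d = 1 − AB.

The fractions sum to one; `a`, `b`, `c` can be slightly negative (an
adjusted-R² artifact) and are reported raw, with a clamped-at-zero
display column in `tidy()` — raw values are authoritative in machine
output. Without spatial input the partition reduces to
`a = A, b = c = 0, d = 1 − A`.

**Converting an explanatory distance matrix into predictors** is the one
genuinely open convention in this analysis style. The default retains
all positive-eigenvalue PCoA axes; `first_k` and a cumulative-95%
rule are alternatives. A full-rank genetic matrix has *n* − 1 positive
axes, which saturates the constrained model, so the pipeline caps the
partner block (largest eigenvalues first) at
*n* − 3 − *m*<sub>space</sub> columns, keeping at least two residual
degrees of freedom in the combined fit. The cap only binds for
high-rank partner matrices; results for low-rank partners are
unaffected. This choice materially affects the partner fraction for
small *n*, which is why it is stated here rather than hidden.

### The Procrustes congruence test

Both partners' matrices are embedded by PCoA (positive axes, zero-padded
to a common width), and the second configuration is superimposed on the
first by least-squares Procrustes: centering, scaling and a rotation
from the SVD of \(Y^{\top}X\). Two conventions matter and are fixed as
follows:

* **Reflections are allowed** (full orthogonal group). PCoA axis signs
  are arbitrary, so excluding reflections would make the statistic
  depend on sign conventions.
* **The superimposition is asymmetric**: the second partner (by
  convention the fungal configuration) is scaled and rotated onto the
  first. The direction is configurable by swapping the arguments, and
  the pipeline reports both directions.

The global statistic \(m^2\) is the residual sum of squares; each
specimen's squared residual measures its personal lack of fit to the
co-diversification pattern (large residual = discordant pairing).
Significance comes from randomising the row-to-row pairing of the
second configuration (uniform Fisher–Yates permutations, seeded; the
observed pairing is not excluded from the null draws) and counting
\(p = (\#\{m^2_{perm} \le m^2_{obs}\}+1)/(n_{perm}+1)\) — one-sided,
small \(m^2\) as evidence of congruence. The default 10,000
randomisations put the smallest attainable p-value near \(10^{-4}\).
`residuals_by_trait()` summarises residuals by a categorical specimen
trait (growth form, apothecia presence) with the overall median as the
reference line, mirroring the standard bar-chart diagnostic
(`autoplot()` draws it).

## The synthetic-data generator

Because deposited specimen data cannot ship with the package, every
statistical property is validated against a generator with known ground
truth (`cophylo_scenario()` / `generate_dataset()`):

* **Fungal tree**: pure birth (Yule), unit rate, grown to
  `n_specimens` tips. The simplest process with adjustable depth; the
  pipeline is agnostic to the tree generator.
* **Algal lineage history**: at each fungal speciation the algal
  lineage co-speciates with probability `p_cospeciation`; otherwise the
  new fungal daughter attaches to an existing algal lineage chosen
  uniformly. Independently, after each speciation every fungal lineage
  switches its algal association with probability `switch_rate`.
  Lineages never go extinct. Note a structural consequence: with
  `p_cospeciation = 0` no algal split ever occurs, all specimens share
  one algal lineage and the algal distance matrix is identically zero —
  the fully degenerate "no co-diversification" corner, where the
  partner fraction is zero by definition.
* **Sequences**: Jukes–Cantor simulation (uniform root, site
  independence) on each tree, depth rescaled to `subst_rate` expected
  substitutions per site. JC is deliberately simpler than the TN93
  estimator the package offers — the estimation-model mismatch is
  intentional and harmless at these divergences. The default
  `subst_rate = 0.05` over 600 ITS-like sites yields mean pairwise
  *p*-distances around 0.05–0.10 with maxima below 0.2, the range
  typical of intrageneric ITS comparisons.
* **Locations**: a convex blend of 2-D Brownian motion along the fungal
  tree (rescaled to the bounding box) and uniform scatter, weighted by
  `spatial_signal` σ ∈ [0, 1]. σ = 1 makes close relatives spatial
  neighbours (strong co-dispersal geography), σ = 0 removes all spatial
  signal. The default 100 km box represents a regional sample; meters
  are converted to decimal degrees at the equator so haversine distances
  reproduce the box extents.

Everything is a pure function of the scenario, including its seed;
component seeds are derived from the scenario seed by fixed offsets, so
written datasets are byte-identical across runs.

What the generator does **not** emulate: indel evolution and alignment
error (alignments are simulated gap-free), rate variation across sites
and lineages, recombination, intra-thallus photobiont mixtures,
tripartite symbioses, and non-uniform sampling designs. A pipeline
validated on these simulations is therefore validated for its
*statistical machinery* — calibration, power, monotone response to
co-speciation and spatial signal — not for robustness to alignment
artefacts in real ITS data.

## Numerical choices and degenerate inputs

* Distance matrices are validated (symmetry, zero diagonal,
  non-negativity, label integrity) at every module boundary; joins are
  always by specimen label, never position, and a label mismatch is an
  error naming the offending specimens.
* Permutation p-values use the +1 convention throughout and are exactly
  reproducible from seeds; the pipeline derives per-stage seeds from the
  master seed by fixed offsets so stages can be re-run independently.
* An all-zero response distance matrix is an error in `dbrda()` (there
  is nothing to explain); an all-zero *predictor* side yields the empty
  model with R² = 0. In the Procrustes test a zero-variance second
  configuration maps to the centroid (scale 0) and returns the maximal
  residual sum of squares.
* Collinear predictor columns are dropped (with a warning) via a
  rank-revealing QR; reported *m* is always the rank actually used.
* Human-readable reports print fractions to two decimals and render
  p-values below 10/(n_perm+1) as "<" bounds; the TSV output keeps full
  precision.

## Problem sizes used in validation

The shipped test suite validates calibration with 1000 independent
db-RDA null replicates (n = 30) and 500 Procrustes null replicates
(n = 20, 99 randomisations each); power with 50 fully co-speciating,
co-dispersing datasets (n = 40, 199 randomisations, rejection at
p ≤ 0.01 required in ≥ 90%); and parameter recovery with paired-seed
sweeps over co-speciation probability {0, 0.5, 1} and spatial signal
{0, 1} (n = 30, 10 seeds per level). These sizes give stable Monte
Carlo estimates while keeping the whole suite under a few minutes on a
single CPU; all thresholds were fixed before the runs.

## Known limitations

* Exact reproduction of published two-decimal fractions for real
  datasets depends on the explanatory-axis convention discussed above;
  when comparing against other software, state the axis-retention rule
  and the forward-selection parameters.
* Adjusted R² is unstable when the predictor rank approaches *n*; the
  pipeline's cap keeps the model estimable but cannot make a
  30-predictor fit on 33 specimens informative. Prefer larger *n* or a
  stricter axis rule in that regime.
* The spatial basis uses a single truncation rule (largest MST edge);
  spatial-weighting-matrix optimisation and asymmetric eigenvector maps
  are out of scope.
* Procrustes residuals are comparable within a dataset, not across
  datasets.

## A minimal session

```{r example, eval = FALSE}
library(cophylospace)

ds <- generate_dataset(cophylo_scenario(n_specimens = 40, seed = 1))
report <- run_congruence_analysis(
  ds$algal, ds$fungal, coords = ds$coords,
  config = run_config(seed = 1))
print(report)
tidy(report)
autoplot(report)

paco <- report$results$algae$paco
residuals_by_trait(paco)
autoplot(paco)
```
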