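---
title: "Methods: compartments, cell types and synaptic selectivity in a cortical column"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartments, cell types and synaptic selectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and numerical
choices: what each stage assumes, which parameters matter and why their
defaults are what they are, what the synthetic column does and does not
emulate, and where the design was genuinely open.

## Skeleton processing

**Soma collapse.** Skeletons arrive rooted at the soma centroid with the
cell body represented by ordinary vertices. All vertices within Euclidean
radius `1.25 * (3 V / 4 pi)^(1/3)` of the centroid (the radius of a
sphere with the nucleus volume `V`, padded by 1.25 for lopsided cell
bodies) *and* reachable from the root through in-radius vertices are
merged into the root; synapses on merged vertices re-attach to the root.
The connectivity constraint matters: a distal branch that loops back near
the soma must not be swallowed.

**Axon identification.** Synapse flow centrality counts, per vertex, the
(input, output) synapse pairs whose unique tree path crosses it; for a
cell with one axon it peaks where the axon leaves the
input-bearing arbor. We compute it in O(n) from subtree input/output
counts (a pair avoids vertex v only if both synapses fall in one
component of the tree minus v) and verify it against brute-force path
enumeration in the tests. The root is not an admissible split — its
"subtree" is the whole arbor — and ties are broken toward the soma. The
split quality is scored by the segregation index: with `n_i` synapses and
input fraction `p_i` in part i, `H_i` the binary entropy (0·ln 0 = 0),

```
index = 1 - sum_i n_i H_i / (N H_total),  clipped to [0, 1],
```

1 for perfectly segregated inputs/outputs, about 0 under uniform mixing.
Inhibitory cells always take the flow-centrality split (a cell with no
outputs is flagged and gets an empty axon). Excitatory cells accept it
only when the index is at least 0.7; below that, every branch downstream
of the 30 μm perisomatic region (path distance; the alternative Euclidean
reading of "within 30 μm of the cell body" changes little because the
region is small) with path length > 20 μm and input density
< 0.1 synapses/μm is labeled axonal.

**False-merge pruning.** Terminal dendritic segments (between a branch
point and an end point) with input density < 0.1 synapses/μm are removed
iteratively until every terminal segment passes; removal can expose a new
bare terminal, hence the fixed-point iteration. Pruning is idempotent and
pruned synapses are excluded from all downstream statistics. One
consequence worth knowing: pruning is survivorship-biased — segments that
happen to receive inhibitory synapses gain input density and survive more
often, which slightly distorts a low-density population's share of the
baseline (see Selectivity below).

**Apical scoring.** A random forest predicts per-vertex apical membership
from eleven geometric features (depths, path and Euclidean distances,
tortuosity, branch count to root, radial offset, angle to the vertical;
conventions at the root: tortuosity 1, angle 0). The forest uses
balanced per-tree stratified sampling because apical vertices are a small
minority and an unbalanced forest biases probabilities — and therefore
the aggregated branch log-odds — low. The aggregation is the
contribution here, not the weights: per soma-child branch,
`R = clip(sum log odds, ±200)`, branches with maximum tip length under
50 μm are dropped from the soft-max denominator,
`S_i = exp(R_i/50)/sum_j exp(R_j/50)`, and a branch qualifies when its
tip reaches 50 μm, `R > 0` and `S > 0.25` (strict, so four equally
weighted branches yield none). The model is retrainable on any labeled
set and any externally supplied per-vertex probability can be used
instead. On synthetic columns the planted apical branch is recovered for
more than 90 % of cells.

**Compartments.** Soma = root; proximal = dendritic vertices within
50 μm path distance of the root (ties at exactly 50 μm are proximal —
logged as configurable, since the boundary is a convention); apical =
beyond-proximal vertices on qualifying apical branches; distal basal =
the rest. Synapses inherit their postsynaptic vertex's compartment;
synapses onto inhibitory cells are pooled as a fifth target compartment.

## Inhibitory subclasses

Six features describe an interneuron's output: the fraction onto
inhibitory neurons; fractions of excitatory-target synapses onto soma,
proximal and apical compartments (distal basal is the complement, so it
is measured but not a feature); the fraction of synapses in multisynaptic
connections (≥ 2 synapses onto one target); and the fraction of those
within 15 μm presynaptic path distance of a sibling synapse of the same
connection ("clumped"). The 15 μm threshold is roughly a quarter of a
soma circumference; the clumped fraction is non-decreasing in the
threshold by construction and results are qualitatively stable from 5 to
100 μm. Path distances use the presynaptic axon skeleton; when it is
missing the code falls back to Euclidean distance with a warning.

A linear discriminant (MASS::lda) is trained on the expert-labeled subset
and applied to all inhibitory cells; disagreements with the expert labels
are retained as the data-driven view. Compartment fractions here are
normalized over excitatory-target synapses (a flag can switch to
all-column-target normalization, an open reading of the feature
definition). InhTCs are subtyped by the larger of their DistTC vs PeriTC
output share — for well-separated cells this equals 2-means on the
1-simplex, and it is deterministic; ties go to the DistTC subtype with a
warning. Group comparisons of synapse size and synapses-per-connection
use medians with percentile-bootstrap CIs (n = 1000) and Welch t-tests
(classical Student's t by flag; Welch is the robust default when group
variances differ), Holm–Šidák corrected.

## Excitatory M-types

The 29 features are listed in `?excitatory_mtypes`. Sparse principal
components come from `mixOmics::spca`, which parameterizes sparsity as
the number of nonzero loadings per component (defaults: 10 of 50 depth
bins, 5 of 13 soma-centered bins); components are sign-fixed so the
largest-magnitude loading is positive, and the loading matrices are
persisted with the run for reproducibility. Missing scalars (e.g. vertex
radius when no vertex lies beyond 30 μm) are median-imputed before
z-scoring. The feature pipeline is invariant to vertex re-indexing and to
rigid translation within the pia plane (tested).

Consensus clustering runs Leiden (modularity objective, resolution 1.3)
on a k-nearest-neighbour graph (k = 10, Euclidean metric on z-scored
features) of a fresh 95 % subsample, 500 times by default. Edges carry
Jaccard weights (the overlap of the endpoints' neighbour sets): with
unweighted edges, every cell of a tight group whose size is near k is
forced to spend edges outside the group, those edges funnel onto the
single nearest "bridge" cell, and modularity then misassigns it — the
Jaccard weighting suppresses exactly those bridges. Co-clustering counts
are normalized by co-sampling counts (cells absent from ~5 % of runs
would otherwise be biased), the consensus dendrogram is complete linkage
on 1 − co-clustering with an infinitesimal feature-distance term that
orders otherwise-tied merges (pairs never co-clustered all sit at
distance 1), and the cluster number is scanned over 2–30.

Choosing the cluster number was the one place where the obvious rule
failed. Minimum Davies–Bouldin, the natural first choice, has two failure
modes on this problem: singleton clusters have zero within-scatter and
trivially minimize it (so cuts with singletons are inadmissible), and
when one cell type is a feature-space outlier, the 2-cluster cut
"outlier type vs everything else" minimizes DB while lumping cells the
base clusterer never co-clusters. The final rule therefore restricts the
scan to *consensus-consistent* cuts — every cluster's mean within-cluster
co-clustering at least 0.4, i.e. members really do co-cluster in a
substantial share of runs — and picks the maximum mean Silhouette among
them, with DB breaking near-ties (within 1 %); both traces are persisted
with the run. On planted columns this recovers the archetype partition
(ARI ≥ 0.92 across seeds) while still merging the spurious sub-splits
that Leiden imposes on small homogeneous groups.

Clusters are named by their modal expert label with letter suffixes in
order of ascending median soma depth; label ties resolve alphabetically
with a warning, unlabeled clusters are `unlabeled_<k>`. Per-M-type
feature importances come from one-vs-rest random forests after SMOTE
oversampling of the minority class (implemented in-package: interpolation
between minority nearest neighbours), using normalized
Mean-Decrease-in-Impurity.

## Connectivity statistics

Net input matrices average synapse counts over *all* cells of the target
M-type, including those with zero input. Connection density is the
fraction of an M-type's cells receiving at least one synapse from a given
interneuron (multisynaptic connections count once); Pearson correlations
of density profiles are computed across interneurons of one subclass,
with zero-variance M-types reported as missing rather than propagated as
NaN. The perisomatic/distal balance is a per-M-type Spearman correlation
of PeriTC vs DistTC synapse counts per cell, with percentile-bootstrap
CIs (n = 2000 cell resamples), bootstrap two-sided p-values and
Holm–Šidák correction across M-types. Output budgets are normalized over
excitatory targets only, so they are insensitive to how much of an axon
targets inhibitory cells or leaves the column. Motif groups reuse the
consensus engine on budget vectors (k clamped to at most half the
interneuron count for small populations) and are ordered by
synapse-weighted mean target depth, superficial first.

## Selectivity Index

The baseline bins every somatic/dendritic input synapse of every column
cell by (depth bin, compartment, target class); depth bins are 20 μm,
half-open, pia to white matter. For each interneuron, every observed
output synapse independently redraws its target class from the baseline
conditional of its (depth bin, compartment) stratum — multinomial, i.e.
with replacement; a without-replacement mode exists but the strata are
large enough that it matters little. One thousand shuffles per
interneuron is the default (configurable; an order of magnitude more
changes p-value granularity, not the medians). SI = observed count /
median shuffled count; two-sided p = 2·min(P̂(X ≤ obs), P̂(X ≥ obs)) with
add-one smoothing, capped at 1; Holm–Šidák within interneuron over
classes with nonzero potential connectivity (baseline mass in at least
one observed stratum). A zero shuffle median with a positive observation
yields an infinite SI sentinel (capped at 10 for display, excluded from
group medians). The compartment-preference variant swaps the roles of
compartment and target class. Group-level selectivity takes the median
SI per (motif group, class) with non-significant entries set to 1 first;
an entry is annotated non-significant when fewer than half the group's
members are individually significant.

Two finite-size facts shape how SI behaves and how we validate it. First,
with a fixed output budget, favoring a class compresses the measured SI:
if the favored class has baseline share `b` in the relevant strata and
the true preference is a multiplier `m`, the expected SI is
`m / (1 + (m - 1) b)`, and stratum-to-stratum heterogeneity of `b`
compresses further (the within-stratum odds transform is concave).
Second, in a small column the assayed interneurons' own outputs are a
non-negligible part of the baseline and drag SI toward 1;
`build_baseline()` therefore takes an `exclude_pre` argument for a
leave-out baseline. At biological scale inhibitory outputs are under 2 %
of all inputs and both effects are immaterial; at desk scale the
validation design keeps `b` near 2 % and excludes the assayed cells.

## The synthetic column

`generate_column()` emulates the statistical structure every stage
consumes: layered soma placement; dendritic trees grown as recursive
branching processes (5 μm vertex step, Gaussian segment lengths,
direction jitter setting tortuosity, reflection at the pia and white
matter); type-specific linear input densities and log-normal synapse
sizes; an optional apical trunk toward the pia with a tuft fan;
inhibitory cells with multipolar dendrites and an output axon that
places connections with `1 + Poisson(lambda)` synapses spaced
exponentially (the clump scale) along the axon path, and waypoint gaps
between connections. Axon polylines materialize vertices at synapse
anchors and waypoints with true path-length edges rather than a uniform
~2 μm spacing; the clumped statistic only needs path distances, which are
identical. Target choice is two-stage: the (depth bin, compartment)
stratum follows the unweighted baseline restricted to the cell's axial
span (where the axon is), and the per-M-type selectivity multiplier acts
on the class choice *within* the stratum — so a multiplier expresses
pure selectivity, not a change of the axon's spatial footprint.
Inhibitory-target draws pick the target subclass first (so planted
inhibition-of-inhibition shares are realized exactly) and a cell within
it by baseline share. Every cell draws from its own RNG substream, so
adding a cell does not perturb the others. Background inputs carry
`pre_cell = NA` — unidentified partners outside the modeled population,
as in real EM synapse tables.

Default study conditions, chosen once:

* the default column has 8 M-types × 28 cells plus 40 interneurons
  (12 PeriTC / 14 DistTC / 8 SparTC / 6 InhTC) with disjoint
  compartment-preference vectors, ~150k synapses, a few seconds to
  generate;
* planted M-types are depth-compact (10 μm soma bands) and strongly
  separated in density, size, cable, radius and apical geometry. That
  compactness is deliberate: the feature suite contains nine
  depth-loaded features, and a type whose somata spread over many depth
  bins presents a stable internal depth gradient that any
  resolution-1.3 clusterer will split — the planted-recovery test is
  about archetype recovery, not about how much within-type depth spread
  survives;
* the calibration column (`calibration_spec`) uses multipliers ≡ 1 and
  synapses-per-connection fixed at 1, which is the permutation null's own
  generative model. Multisynaptic connections overdisperse per-class
  counts relative to a per-synapse shuffle, so on real data the SI
  p-values are anti-conservative for strongly multisynaptic cells — a
  caveat of the method itself, not of the implementation;
* the recovery column (`recovery_spec`) plants multipliers {0.5, 2, 4}
  on a rare reference type ("Lsp", ~2 % of baseline synapses) spread
  evenly over depth with distal-dominated arbors and an input density
  well above the pruning threshold. Each of those qualifiers removes a
  measured bias: local-share heterogeneity, proximal-compartment
  dominance in sparsely occupied bins, and pruning survivorship;
* the motif column (`motif_spec`) plants four laminar targeting
  archetypes (tight soma bands, 200 μm spans, within-stratum boost 15 on
  disjoint M-type pairs).

What passing these tests shows — and what it does not. Recovery of
planted structure demonstrates that the machinery measures what it
claims under its own assumptions: tree-shaped neurites, honest synapse
assignment, compartment rules matching the generator's, and targeting
that factorizes into (spatial footprint) × (class selectivity). Real EM
data violate several of these gracefully (truncated arbors, detached
spines, synapse-detection errors, proofreading gaps) and the tests say
nothing about robustness to those; analyses of real columns also rest on
expert labels and proofreading quality that no synthetic column can
emulate.

## Numerical conventions and degenerate inputs

Half-open depth bins `[lo, hi)`, clamped at the column bounds. Autapses
are kept in tables, counted and logged, excluded from all connectivity
statistics. Holm–Šidák is implemented step-down
(`1 - (1-p)^(m-i+1)` with a cumulative maximum). Bootstrap CIs are
percentile CIs; a constant sample gives a zero-width CI. LDA on
degenerate (constant) features raises an informative error, as do empty
strata in the shuffle, cells with no outputs in the feature extractor,
and non-tree SWC input. The pipeline writes plain-text artifacts with a
checksum manifest, and two runs with one seed are byte-identical; tests
and the acceptance script use reduced problem sizes (50-run consensus,
1000 shuffles, desk-scale columns) — stated here as the package's chosen
validation scale.

## Known limitations

Single-axon assumption by default (a two-axon mode reruns the split with
the first axon masked); no spine-detachment repair; no lateral-distance
term in the selectivity null (depth is the only spatial covariate); the
synthetic column is straight (no slanted deep-layer streamlines), its
morphologies are minimal branching processes rather than biophysically
realistic arbors, and its M-type archetypes are cleaner than any real
cell-type landscape.
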