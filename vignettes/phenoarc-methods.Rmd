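---
title: "Mapping time-resolved phenotype connections with phenoarc"
author: "phenoarc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping time-resolved phenotype connections with phenoarc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoarc)
```

## The model

`phenoarc` operates on a gene × phenotype × time score tensor
`v[g, p, t]`, parsed from a whitespace-delimited table with one row per
(gene, phenotype) pair and one column per time point. Time points are
**1-based everywhere** in this package — file columns, function
arguments, TSV outputs and axis labels all agree. A configurable token
(default `"NA"`) marks missing scores; a missing score never passes any
gate, never becomes a prominent phenotype and breaks line-plot polylines
and transition chains. Pairs absent from the file are treated as missing
at every time point.

Two derived structures carry the analysis:

* the **event mask** `M[g, p, t]`, true iff the score is observed and
  falls in the phenotype's threshold interval, and
* **connection sets**: records `(source, target, t_source, t_target,
  gene set)` whose weight is always the size of the gene set. Records
  with empty gene sets are never stored, so weights are at least 1.

## Gating

Threshold intervals are **inclusive at both ends**. This is a modeling
choice (interval endpoints are typically quoted thresholds such as
published score cut-offs or quartile values, and a gene *at* the cut-off
should count); nothing downstream depends on the strictness for
continuous scores, where boundary ties have measure zero.

Quartile gates pool each phenotype's observed scores **across all genes
and time points** and keep the lower (`v ≤ Q1`) or upper (`v ≥ Q3`)
quartile. One gate per phenotype/condition mirrors how per-treatment
quartile thresholds are tabulated in drug-response studies. Quartiles use
the linear-interpolation definition (the value at rank `0.25 (n - 1)`
between order statistics, `stats::quantile` type 7), the convention
shared by R's default and NumPy's `linear` method. By construction the
fraction of pooled observations passing the lower gate is at least 0.25
and minimal among cuts at observed values; the test suite asserts this
against a sort-based oracle.

## Connections

Two connection semantics are provided, matching the two ways a screen
analyst links phenotypes:

**Lagged co-occurrence.** For each exact lag `x` in a user-chosen set,
gene `g` joins `(p, q, t, t+x)` iff `M[g, p, t]` and `M[g, q, t+x]`.
Lag-0 records are undirected and stored with endpoints in dataset
phenotype order, each unordered pair counted once; positive lags give
directed records. We expose *sets of exact lags* rather than a lag range
because the two compose: a range is just `lags = 0:k`, while a range-only
interface cannot express "exactly 2 apart". The view-level "time
interval" control maps to `max_lag` filtering instead.

**Prominence transitions.** Each gene's *prominence profile* is its
arg-max phenotype per time point, optionally restricted to scores passing
thresholds; ties break deterministically toward the earlier phenotype in
input order, and a time point with no passing score yields a gap. A
transition arc `(p_t, p_{t+1}, t, t+1)` is emitted whenever consecutive
entries are both present and differ. Gaps break chains — we do not emit
arcs across unobserved stretches, because "the population transitioned
from A to B" is not supported when the intervening state is unknown.
Self-transitions (unchanged phenotype) are omitted by default and
available via `include_self = TRUE`. Whether thresholds should apply
before the arg-max is left to the caller (`derive_prominence(d,
thresholds)`), since both regimes are defensible; the default applies
none.

Weights are aggregated **per (pair, t, lag) record**; cross-time
aggregation (e.g. `lane_weights()`) is always an explicit, separate step
so that no information is lost before filtering.

## Lane ordering

Arc views are most readable when heavily connected phenotypes sit on
adjacent lanes. The objective is the sum of pairwise connection weights
between consecutive lanes of the ordering (`adjacent_score()`), a linear
arrangement problem that is NP-hard in general. `order_lanes()` uses an
agglomerative chain-merging heuristic: every lane starts as a singleton
chain; repeatedly the two chains with the greatest total between-chain
weight merge, concatenated in whichever of the four end-to-end
orientations places the most weight across the new junction. The final
chain is then polished by a deterministic 2-opt pass (reverse any
contiguous segment that raises the score, first-improvement sweeps until
a fixed point). The greedy merge alone occasionally lands near 75% of the
exhaustive optimum on adversarial random matrices; with the 2-opt polish
the package holds an asserted floor of 80% of optimum on random 6-lane
instances and recovers path-structured instances exactly (both are
checked against full enumeration of the 720 permutations in the test
suite). If the heuristic ever scored below the input order, the input
order is returned — reordering is a viewing aid and must never make the
display worse. Ties are broken lexicographically by chain label, so the
result is deterministic; a `tie_seed` argument is accepted for interface
stability but has no effect. The ordering is computed once over the whole
view window, not per time point, so lanes stay fixed as one steps through
time.

## Gene networks

`cophenotype_network()` links two genes at time `t` iff they share at
least one passing phenotype, with the number of shared passing
phenotypes as the edge weight (for condition-style data: the number of
conditions both genes respond to). Networks of 500+ nodes raise a
capacity error: the cap reflects layout/readability practice rather than
correctness, so `force_large = TRUE` bypasses it.

`synchronous_network()` links genes whose **entire** prominence profiles
are identical, including agreeing on gap positions. The stricter
whole-profile rule is chosen over requiring synchrony only at transition
moments because "exact same succession" is only well defined when the
whole timeline matches; the looser alternative would also link genes that
dwell in different phenotypes between shared transitions. Since profile
identity is an equivalence relation, every connected component is a
clique — an invariant the tests check on random data.

`core_variable_split()` classifies genes across a series of per-time
networks: `core` iff present in every network, else `variable`.

`force_layout()` wraps a seeded Fruchterman–Reingold layout (all-pairs
repulsion, spring attraction along edges; start coordinates drawn from a
seeded RNG, fixed iteration count, default 200) and rescales to the unit
square; a single node sits at (0.5, 0.5). Identical inputs and seed give
identical coordinates.

## Profile analytics

Succession profiles are encoded **one-hot**: per time point a block of
`P` indicators with a single 1 at the prominent phenotype, all zeros at a
gap. Integer phenotype codes would impose a spurious metric (phenotype 1
is not "closer" to phenotype 2 than to phenotype 7); with one-hot blocks
the squared Euclidean distance between two fully defined profiles is
exactly twice their Hamming distance, which is the natural dissimilarity
for categorical successions.

Hierarchical clustering (`hier_cluster()`, used for heat-map row/column
arrangement) supports single, average and complete linkage under
Euclidean or Manhattan distance, and is validated against a naive
pairwise reference implementation on small inputs. Heat maps are
clustered independently per time point. K-means (`kmeans_profiles()`)
runs Lloyd iteration from `restarts` seeded random initializations (k
distinct encoded profiles each) and keeps the lowest within-cluster sum
of squares; `k` defaults to 4, a typical class count for first-phenotype
groupings, but is a free parameter. `pca2()` projects centered encodings
onto the first two principal axes with the sign convention that each
axis's first nonzero loading is positive, making coordinates reproducible
across platforms.

## Rendering

All renderers emit SVG **text** with fixed-format numbers, so identical
inputs give byte-identical files — the property golden-file tests and
cross-artifact audits rely on. The drawing contracts are:

* one drawable element (`path.arc`, `polyline.arc` or `path.chord`) per
  connection record in view;
* stroke width (2D) and apex height (3D, recorded in `data-apex`)
  exactly proportional to weight (`base_size` / `unit_height` per weight
  unit);
* directed arcs take the palette color of their **target** phenotype —
  the phenotype transitioned into — while undirected records use the
  single connection color;
* opacity is `1 - transparency`, default transparency 0.20;
* circular views draw `P` equal segments whose spans sum to 360°
  (`data-span` attributes, closure asserted to 1e-6).

Arcs are symmetric quadratic curves; the curve family is an aesthetic
choice with no semantic content. Lane colors are assigned by
post-ordering phenotype index so they are stable across views of one
dataset. Interactivity of the original display idiom (hover, rotate,
single-vs-cumulative toggle) is replaced by explicit parameters:
`timepoint`, the `cumulative` style flag, and `camera = c(azimuth,
elevation)` for the 3D projection (rotation plus tilt, fixed canvas
fit). Qualitative palettes come from ColorBrewer (including the
colorblind-safe `Dark2`/`Paired`) with a `single` scheme for
direction-free displays; requesting more colors than a scheme holds is an
error that suggests `single`. Raster (PNG) export is not provided — every
testable contract lives in the SVG, and a second raster geometry path
would be untestable weight; SVG converts losslessly downstream.

## Synthetic fixtures

`generate_fixture()` emulates the two study shapes the package targets,
structurally but not statistically:

* **screen** mode: 7 morphology categories (mitotic_delay, binuclear,
  polylobed, grape, large, dynamic, apoptosis), default 60 genes × 20
  time points — a desk-scale stand-in for a time-lapse knockdown screen.
  Planted transition motifs hold the source phenotype prominent up to the
  motif time and the target afterwards, so each motif gene contributes
  exactly one transition. Planted synchronous groups share a full profile
  template.
* **drug** mode: 6 conditions (nicotine, ethanol, cocaine,
  methamphetamine, heroin, morphine) × 4 time points (1, 2, 4, 8 h),
  default 42 genes, baseline expression N(7, 1) on a log2-like scale.
  Planted sets are shifted 5 units below/above baseline at chosen
  condition/time coordinates, far past the pooled quartiles.

Prominent scores are fixed at 0.9 against backgrounds drawn below 0.5,
so at zero noise the arg-max is unambiguous and every planted structure
is recovered *exactly* by the corresponding operation — the manifest the
generator returns is checkable ground truth. Ties are deliberately
impossible in fixtures; tie-break behavior is exercised by hand-built
micro-inputs instead, because a fixture that depends on the tie rule
would couple the generator to the implementation detail it is supposed
to test. Background genes take constant profiles (transition-free),
except when synchronous groups are planted, where backgrounds get
pairwise-distinct profiles via base-P integer coding so the synchronous
network contains exactly the planted cliques. Gaussian `noise > 0`
perturbs all scores; recovery then degrades gracefully and is asserted
only at documented levels (e.g. k-means class recovery with ARI ≥ 0.9 at
10% label flips). What passing these tests shows is that the *mechanics*
are correct; it says nothing about signal-to-noise in real screens,
where score distributions are heavy-tailed and phenotype calls are
correlated.

## Numerical and interface choices

* Dataset files split fields on any run of spaces/tabs; network files
  are strictly single-tab-separated, with the enrichment table carrying
  (term id, description, p-value, `|`-joined members) and interactions
  one pair per line. Interaction rows naming unknown terms are dropped
  with a logged warning rather than an error, so one enrichment file can
  serve several interaction files.
* `write_dataset()` prints 15 significant digits, which round-trips the
  doubles the generator produces; the parse→write→parse identity is
  property-tested on random datasets.
* Degenerate inputs are defined, not rejected: constant score vectors
  give `Q1 = Q3`, so both quartile gates admit every observation; a
  single-row matrix clusters trivially with empty merge history; an
  all-zero bar series draws zero-height columns; an empty connection set
  renders lanes and axes with zero arcs.
* The CLI surfaces every module under subcommands (`gate`, `connect`,
  `transitions`, `order`, `network`, `sync-network`, `cluster`,
  `kmeans`, `render`, `fixtures`), reads flat `key = value` config files
  with CLI flags taking precedence, logs record/connection counts and
  applied gates, warns (without failing) when a dataset exceeds a few
  thousand genes × 50 phenotypes × 100 time points, and maps the
  package's classed errors (format, value, key, duplicate, capacity) to
  categorized messages and a nonzero exit.

## Problem sizes in the test suite

The suite validates conservation on random 20-gene × 5-phenotype ×
10-time masks against a brute-force triple loop, lane ordering against
full enumeration on 6 lanes (all 720 path labelings plus 200 random
matrices), hierarchical clustering against the pairwise reference on ≤ 6
rows for all linkage × metric combinations, and k-means recovery on 60
genes × 4 planted classes. These sizes were chosen so each oracle is
exhaustively checkable while the code paths exercised are exactly those
used at screen scale.

## Known limitations

* No normalization is performed or offered; heterogeneous inputs must be
  normalized upstream, and the quartile gates inherit whatever scale the
  input uses.
* Annotation networks are loaded from files only; there is no live
  database retrieval, and enrichment itself is out of scope (the package
  consumes enrichment output).
* The lane-ordering heuristic is not an exact minimum-linear-arrangement
  solver; only the adjacency objective is optimized, not arc crossings.
* The 3D view is a fixed orthographic-style projection; it trades the
  original idiom's interactive depth cues for reproducibility.
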