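# phenoarc

Time-resolved phenotype connection mapping and arc visualization for
genetic screens.

## The problem

Large perturbation screens — RNAi knockdown studies scored for
morphological defects over a time-lapse, or drug-response expression time
courses — produce a gene × phenotype × time tensor of scores. The
questions a screen analyst asks of such data are relational and temporal:
which phenotypes are linked by the same genes at the same moment, which
phenotype does a cell population transition into next, when do two
treatments start regulating the same genes, and which genes behave
synchronously throughout?

`phenoarc` answers these by turning gated score events into **timed,
weighted phenotype-to-phenotype connections** ("arcs") and the gene
networks behind them, with deterministic SVG renderings in place of an
interactive display. It is aimed at computational biologists who want the
analysis scriptable, testable and reproducible.

## The method

Let `v[g, p, t]` be the score of gene `g` for phenotype `p` at time point
`t ∈ {1..n}` (1-based throughout). The pipeline is:

1. **Gating.** An event mask `M[g, p, t]` is true iff the score is
   observed and lies in the phenotype's inclusive interval
   `[lo_p, hi_p]`. Intervals can be set manually or derived from the
   pooled per-phenotype score distribution as quartile gates: the lower
   gate keeps `v ≤ Q1`, the upper keeps `v ≥ Q3` (linear-interpolation
   percentiles). Without thresholds every observed score passes — and all
   phenotypes come out interconnected, so gating for outstanding behavior
   is the analyst's first decision.
2. **Connections.** For a lag `x`, gene `g` joins the connection
   `(p, q, t, t + x)` iff `M[g, p, t]` and `M[g, q, t + x]`. The arc
   weight `w_pq(t, x)` is the number of such genes. Lag-0 arcs are
   undirected; positive lags are directed. Alternatively, **transitions**
   follow each gene's *most prominent* phenotype (the arg-max over
   phenotypes per time point) and connect consecutive time points where
   the prominent phenotype changes.
3. **Lane ordering.** For the arc views, phenotype lanes are permuted to
   maximize `Σ_i W(o_i, o_i+1)`, the total connection weight between
   adjacent lanes, by agglomerative chain merging with a 2-opt polish
   (never worse than the input order).
4. **Networks.** Per time point, genes sharing a passing phenotype are
   linked (`weight` = number of shared phenotypes/conditions); genes with
   identical full succession profiles form cliques in the synchronous
   network; genes present at every time point are `core`, the rest
   `variable`.
5. **Profile analytics.** Succession profiles are one-hot encoded
   (`n × P` indicators) for hierarchical clustering, k-means classing
   (default k = 4) and a 2-component principal projection.
6. **Rendering.** Linear, circular and 3D-perspective arc views, heat
   maps and line plots as deterministic SVG text: stroke width / apex
   height ∝ weight, directed arcs colored by their *target* phenotype,
   default arc transparency 20%.

## Worked example

```r
library(phenoarc)

# synthetic screen: 30 genes, 7 morphology phenotypes, 8 time points,
# with two planted transition motifs
fx <- generate_fixture(fixture_spec(
  "screen", genes = 30, n_timepoints = 8,
  motifs = data.frame(source = c("mitotic_delay", "binuclear"),
                      target = c("polylobed", "apoptosis"),
                      time = c(3, 5), count = c(5, 3)),
  seed = 42))
dataset <- fx$dataset
#> pheno_dataset: 30 genes x 7 phenotypes x 8 time points (210 records)

profile <- derive_prominence(dataset)
arcs <- derive_transitions(profile)
as.data.frame(arcs[, c("source", "target", "t_source", "t_target", "weight")])
#>          source    target t_source t_target weight
#> 1 mitotic_delay polylobed        3        4      5
#> 2     binuclear apoptosis        5        6      3
```

Both planted motifs are recovered: five genes switch their prominent
phenotype from `mitotic_delay` to `polylobed` between time points 3 and 4
(an arc of weight 5), three more from `binuclear` to `apoptosis` between
5 and 6.

```r
W <- lane_weights(arcs, dataset$phenotypes)
ordering <- order_lanes(W)
as.character(ordering)
#> [1] "apoptosis"  "binuclear"  "dynamic"  "grape"  "large"
#> [6] "mitotic_delay"  "polylobed"
adjacent_score(ordering, W)
#> [1] 8
```

The lane ordering puts both connected pairs on adjacent lanes, so the
full connection weight (5 + 3 = 8) sits between neighbors.

```r
svg <- render_linear(arcs, ordering, n_timepoints = dataset$n_timepoints)
count_arc_elements(svg)   # one drawable arc per connection record
#> [1] 2
render_save(svg, "transitions.svg")

synchronous_network(profile)
#> gene_network: 30 nodes, 37 edges
```

The synchronous network links every pair of genes with an identical
succession profile — here the two motif groups plus the constant-profile
background genes, each group forming a clique.

The same pipeline is available from a shell:

```sh
Rscript inst/exec/phenoarc fixtures --mode screen --genes 30 --timepoints 8 \
    --motifs "mitotic_delay>polylobed@3x5" --seed 42 --out screen.txt
Rscript inst/exec/phenoarc render --input screen.txt --view linear \
    --mode transitions --out arcs.svg --tsv-out arcs.tsv
```

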