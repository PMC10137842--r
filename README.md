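# spreadrank

Identifying **influential spreaders** in contact networks — the few nodes
that, when seeded, push information or infection through the whole network
fastest, and when immunized, block it best.

Classic centralities (degree, betweenness, k-shell, eigenvector, VoteRank)
score nodes one at a time, so a top-k set often wastes its budget on nodes
whose influence regions overlap. This package implements a path-reachability
alternative with an explicit set-selection stage:

1. **Local vital nodes.** Only nodes whose degree exceeds the network mean
   ⟨k⟩ = 2E/N are scored — in scale-free networks these few hubs dominate
   local spreading.
2. **Spread centrality.** For every ordered pair of vital nodes *i*, *j*,
   all *valid spread paths* (simple paths of at most 6 edges, the
   six-degrees horizon) are enumerated. Three indices summarise them:
   the path count PN<sub>ij</sub>; the mean path length PL; and the
   *path diversity*

   PD<sub>ij</sub> = mean over path pairs of ( 1 − 2·w / (d₁ + d₂) ),

   where d₁, d₂ are the interior-node counts of the two paths and w the
   number of interior nodes they share (1 = fully disjoint routes,
   0 = identical routes). Per node,
   **SC<sub>i</sub> = [ norm(PD<sub>i</sub>) + norm(PN<sub>i</sub>) +
   norm(1/PL<sub>i</sub>) ] / 3**, with min–max normalisation across the
   vital-node population.
3. **Dynamic set selection.** Nodes are picked by maximal working SC; after
   each pick, neighbours retain 1/2 and second-order neighbours 3/4 of
   their working value (overlap attenuation, compounding across picks).
   Picking stops when the residual giant component drops below q < μ
   (default μ = 0.01) of the original N; a greedy deletion pass then prunes
   picks whose restoration keeps q < μ. The result is a compact set that
   simultaneously spreads widely and, as an immunization target,
   fragments the network.
4. **SIR harness.** A discrete-time synchronous SIR Monte-Carlo engine
   (per-contact infection probability β, per-step recovery probability γ;
   a susceptible with m infected neighbours is infected with probability
   1 − (1−β)^m) evaluates any node set as initial infected (spreading) or
   initial recovered (targeted immunization), reporting the final recovered
   fraction P<sub>r</sub> over 100-run ensembles.

Everything is deterministic for a fixed seed, igraph-backed, and returns
tidy tibbles that pipe straight into dplyr/ggplot2.

## Worked example

```r
library(spreadrank)

g <- ba_graph(60, 2, seed = 11)      # scale-free test network
head(spread_centrality(g))
#> # A tibble: 6 × 7
#>   node  degree vital    pd    pn    pl    sc
#>   <chr>  <dbl> <lgl> <dbl> <dbl> <dbl> <dbl>
#> 1 2         19 TRUE  0.699  426.  5.53 0.883
#> 2 5         20 TRUE  0.672  509.  5.56 0.835
#> 3 7         18 TRUE  0.660  507.  5.56 0.802
#> 4 1         10 TRUE  0.652  518.  5.60 0.701
#> 5 3         11 TRUE  0.642  505.  5.62 0.596
#> 6 21         7 TRUE  0.635  432.  5.62 0.488

s <- spreadrank_select(g, mu = 0.1)
s
#> <spreadrank_set> 11 node(s) selected of 60 (preselected 14)
#>   residual giant component q = 0.0667 < mu = 0.1
#>   selected: 2, 5, 3, 7, 13, 25, 9, 21, 12, 16, 1
```

Node `2` tops the table: among the 60-node network's 15 hubs it reaches the
others through the most numerous (`pn`), shortest (`pl`) and most mutually
disjoint (`pd` near 0.7) routes. The selection keeps 11 of 14 preselected
nodes; removing them shatters the giant component to 6.7% of the network
(4 of 60 nodes), below the μ = 0.1 threshold.

```r
sir_ensemble(g, beta = 0.1, gamma = 0.05, infected = s$selected,
             runs = 20, seed = 1)
#> <sir_ensemble> 20 run(s), N = 60, beta = 0.1, gamma = 0.05: Pr = 0.9142 (sd 0.0484)
```

Seeding the selected set infects 91% of the network on average. The same
set used as `recovered` in `immunization_experiment()` confines the
epidemic to the small residual components instead.

`run_experiment()` drives the full comparison protocol (selection, equal
top-|S| budgets for all baseline rankings, spreading and immunization
sweeps over a β grid, trajectory at a pinned β) and writes per-method CSV
curves plus a JSON manifest. A command-line front-end lives in
`inst/scripts/spreadrank` (subcommands `select`, `rank`, `sir`,
`experiment`).

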