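# netcurve

Large networks are hard to *look at*: beyond a few hundred vertices a
drawing is hairball, and practice falls back on bags of summary statistics
(degree distributions, clustering coefficients, motif counts) that each see
the structure from one angle. `netcurve` implements a mesoscopic
alternative: a breadth-first search with two queues maps any network onto a
planar point cloud whose staircase — the **characteristic curve** — carries
local linking structure and global connectivity in a single nondecreasing
function, comparable across networks by simple area.

For whom: network scientists and systems biologists who want to compare
large graphs wholesale, test how well growth models reproduce a real
network (the motivating case is a confidence-scored protein–protein
interaction map), or study what BFS/traceroute-style sampling does to
degree distributions.

## The objects and the theory

A FIFO BFS explores vertices in first-touched, first-explored order.
*QueueT* collects newly touched vertices; vertex at position *i* with
parent at position *j* becomes the point (i/N, j/N) — the **BFS-tree**.
*QueueG* starts with the root's copy and receives one copy per incident
edge endpoint of every explored vertex, so all M edges survive; copies are
placed at (own QueueG position / N, position of the parent's reference
copy / N) — the **BFS-graph**, ending at exactly (2M+1)/N on a connected
multigraph.

For configuration-model graphs with degree distribution P(k) (generating
function g0, mean z, excess function g1 = g0′/z) the curves have exact
mean-field forms, parametrised by the stub-survival probability ψ:

* tree curve: ( 1 − g0(g1(ψ)), 1 − g0(ψ) )
* graph curve: ( z(1 − ψ g1(ψ)), z(1 − ψ g1⁻¹(ψ)) )

terminating at the giant component S = 1 − g0(u\*), u\* the smallest root
of g1(u) = u (the Molloy–Reed size). Closed forms: random regular
f_G(x) = k(1 − (1 − x/k)^{1/(k−1)}); Poisson via the principal Lambert-W
branch; lattice-embedded random regular graphs via the slope parameter λ,
the largest real root of (λ−1)^d = r(λ+1)^{d−1}. The same machinery yields
the traceroute result: homogeneous networks show an apparent power-law
tree-degree density ∝ (t−1)^{−(λ−2)/(λ−1)} with cutoff 1+λ.

On top sit a curve-area **graph distance** (axes aligned by each graph's
giant-component average degree, padding at S), a search-efficiency
**clustering measure** Λ against degree-matched random counterparts, a
**median-distance classifier** over model classes (DMC, DMR, LPA, Poisson),
and an end-to-end pipeline that filters a confidence-scored edge list and
ranks growth models against it.

## Worked example

```r
library(netcurve)

# a random 3-regular graph lands on its analytic curve
g   <- sample_rrg(10000, 3, seed = 1)
cur <- map_curve(g, seed = 2)
cur
#> <bfs_curve: graph, empirical-run>  S = 1.0000  z_gc = 3.000  x_end = 3.0001  (1000 samples)
curve_deviation(cur, rrg_curves(3)$graph)
#> [1] 0.01153327

# giant component of a sparse Poisson graph, closed form vs simulation
giant_component_size(poisson_dist(2))
#> [1] 0.7968121
giant_component(sample_poisson_rg(100000, 2, seed = 3))$fraction
#> [1] 0.79875

# model evaluation on a synthetic interaction-style data set (DMR-grown)
path <- make_fixture("ppi-like", n = 1500, seed = 7)
el   <- read_weighted_edgelist(path)
net  <- filter_network(el, 0.65)
evaluate_models(net, models = c("DMC", "DMR", "LPA"),
                n_instances = 15, seed = 3)
#> <evaluation_report> target: 1018 vertices, 1071 edges, S = 0.771
#> # A tibble: 3 × 5
#>   model median_distance n_flagged mean_s  rank
#>   <chr>           <dbl>     <int>  <dbl> <dbl>
#> 1 DMR            0.0275         0  0.685     1
#> 2 LPA            0.0803         0  1         2
#> 3 DMC            0.128          0  0.208     3
```

The report reads: among the three growth models, duplication–mutation with
random rewiring (DMR) sits closest to the target's characteristic curve
(median distance 0.028 over 15 size-matched instances) and wins the
ranking — correctly, since the fixture was DMR-grown; the DMC instances
fragment (mean giant component 21% of vertices) and land far away.

`autoplot()` methods draw curves, BFS point clouds, efficiency profiles,
accuracy matrices and evaluation reports; `tidy()`/`glance()` return the
tabular cores. A thin command-line front end lives at
`inst/cli/netcurve.R` (subcommands `generate`, `map`, `theory`,
`distance`, `evaluate`).

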