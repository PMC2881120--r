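# netgrow

Biological, technological and social networks are usually studied
through observed instances whose wiring reflects both function and
history — which makes proper null models hard to come by. netgrow
grows *surrogate* networks by a purely stochastic event process, with
no functional constraint, so that hypotheses of the form "property X
requires constraint Y" can be tested against graphs that acquired X by
growth alone. It targets systems biologists and network scientists who
need controls with a prescribed degree distribution, modularity, or
mixing pattern — and who want to ask what growth process could have
produced an observed network.

## The model

A graph is grown (or shrunk) from a seed by iterating three
independent stochastic sub-events, handled in a fixed order:

| event       | probability | on success                                                        |
|-------------|-------------|-------------------------------------------------------------------|
| node        | P_N         | add a degree-0 node (prob. p) or delete a random node (1 − p)     |
| edge        | P_E         | connect a random unconnected pair (q) or disconnect a pair (1 − q)|
| duplication | P_D         | duplicate a random node (r) or fuse two random nodes (1 − r)      |

Only the ratios of (pP_N, qP_E, rP_D) matter for the grown structure;
the ratio η = P_E/P_N sets the asymptotic mean degree ⟨k⟩ = 2qη. With
no duplication the degree distribution is the exponential law of grown
random graphs, p(k) = (2η)^k/(1+2η)^(k+1); duplication fattens it
toward scale-free, and small P_N yields Poisson-like graphs.

Each node carries a module tag ("color"). An assortativity matrix e
gates edge placement by the colors of the drawn pair, which generates
modular, bipartite/k-partite, or lattice-constrained graphs. Given a
labeled graph, the package measures its mixing matrix, Newman's
modularity Q_N and assortativity r, and the functional modularity
Q_H = (N_c·Tr e − 1)/(N_c − 1), which is 1 for perfectly modular, ~0
for randomly colored, and −1 for bipartite (*anti-modular*) graphs.
Small-world-ness is quantified as S^Δ = (C/C_random)/(L/L_random)
against Erdős–Rényi G(n,m) baselines, and the percolation transition is
tracked through the relative giant-component size S. A Monte-Carlo
search (`monte_carlo_fit()`) reverse-engineers growth parameters from
an observed degree distribution via threshold-binned RMS fitting and a
Wilcoxon rank-sum comparison.

## Worked example

Grow a 1,000-node network with five modules, strong intra-module
preference (π = 0.8) and some duplication, then measure it:

```r
library(netgrow)
pars <- growth_params(p_n = 0.5, p_e = 1, p_d = 0.2, n_colors = 5,
                      e_matrix = equal_opportunity(5, 0.8))
g <- grow_network(pars, max_nodes = 1000, initial = "one_per_module",
                  seed = 42)
graph_metrics(g)
#> # A tibble: 8 × 2
#>   measure          value
#>   <chr>            <dbl>
#> 1 n           1000
#> 2 m           3162
#> 3 mean_degree    6.32
#> 4 density        0.00633
#> 5 giant          0.776
#> 6 qn             0.546
#> 7 qh             0.707
#> 8 r              0.700
```

The mean degree sits near its asymptote 2η = 4 scaled up by
duplication; 77.6% of nodes are in the giant component; the functional
modularity (0.707) exceeds Newman's topological measure (0.546), as
expected for a strongly modular labeling, and matches the assortativity
r because the generator is the equal-opportunity model. A small-world
summary against matched G(n, m) baselines:

```r
small_world_stats(g, replicates = 20, seed = 1)
#> <small_world_stats>
#>   L_g = 4.059  (L_random = 3.95)  lambda_g = 1.028
#>   C_g = 0.1064  (C_random = 0.006651)  gamma_g  = 15.99
#>   S_delta = 15.56   xi = 0.00633
```

Sweep functions (`small_world_sweep()`, `percolation_sweep()`,
`modularity_pi_curve()`) return tibbles with `autoplot()` methods;
fitted `monte_carlo_fit()` objects have `tidy()`, `glance()` and
`autoplot()` methods. A thin command-line front end
(`inst/scripts/netgrow`) exposes `grow`, `randomize`, `metrics`,
`sweep`, `fit` and `fixtures` subcommands over JSON/YAML configs.

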