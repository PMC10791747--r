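# triguild

Simulation toolkit for **three-guild multiplex ecological networks**: a
plant guild that simultaneously anchors a mutualistic sub-network with
pollinators and an antagonistic sub-network with herbivores, while species
compete within each guild. The package is for theoretical and community
ecologists studying how **adaptive interaction rewiring** — animals
switching plant partners when the switch pays off — reshapes network
structure (nestedness, modularity) and stability (resilience).

## The model in brief

Species carry Gaussian niche profiles on a one-dimensional axis; the
interaction coefficient between species *i* and *j* is the overlap ratio

&nbsp;&nbsp;&nbsp;&nbsp;α<sub>ij</sub> = exp( −(s̄<sub>i</sub> − s̄<sub>j</sub>)² / 4σ² ),

scaled by one strength scalar per interaction type: competition
β<sub>ij</sub> = Ω<sub>c</sub>α<sub>ij</sub> (β<sub>ii</sub> = 1), mutualism
γ<sub>ij</sub> = Ω<sub>m</sub>θ<sub>ij</sub>α<sub>ij</sub>, antagonism
τ<sub>ij</sub> = Ω<sub>p</sub>θ<sub>ij</sub>α<sub>ij</sub>, with binary
incidence matrices θ drawn Bernoulli at a target connectance. Biomasses
follow a Lotka–Volterra system with type II (saturating) functional
responses; for plant *i*,

&nbsp;&nbsp;&nbsp;&nbsp;dP<sub>i</sub>/dt = P<sub>i</sub> ( r − Σ<sub>j</sub> β<sub>ij</sub>P<sub>j</sub> + Σ<sub>j</sub> γ<sub>ij</sub>M<sub>j</sub> / (1 + h Σ<sub>k∈mut(P<sub>i</sub>)</sub> M<sub>k</sub>) − Σ<sub>j</sub> τ<sub>ij</sub>H<sub>j</sub> / (1 + h Σ<sub>k∈ant(H<sub>j</sub>)</sub> P<sub>k</sub>) ),

with mirrored gain terms for pollinators and (ε-discounted) herbivores.
Rewiring repeats a propose/accept cycle: a random animal detaches from
partner plant *j* with probability 1 − ψ<sub>j</sub><sup>−1</sup>
(ψ<sub>j</sub> = plant *j*'s partner count in that guild), attaches to a
random unlinked plant, the community is re-equilibrated, and the switch is
kept only if the animal's equilibrium biomass strictly increased. Stability
is resilience |max Re λ| of the analytic Jacobian at a locally stable
equilibrium; structure is NODF nestedness and Barber bipartite modularity
with null-model z-scores (one-tailed, threshold 1.645).

See `vignettes/adaptive-multiplex-networks.Rmd` for the full account of the
model, the numerical choices, and the design decisions.

## Worked example

```r
library(triguild)

params <- model_params(omega_c = 0.1, omega_m = 0.1, omega_p = 0.1)
net <- generate_network(15, 15, 15, params, seed = 2027)
net
#> <interaction_matrices> 15/15/15 species; 36 mutualistic, 35 antagonistic links

eq <- integrate_to_equilibrium(NULL, net)
eq
#> <equilibrium_result> converged: TRUE; locally stable: TRUE
#>   resilience: 0.506309
#>   min biomass: 0.5257; t = 50

traj <- run_rewiring(net, n_attempts = 4000, seed = 31, metrics_window = 0)
traj
#> <rewiring_trajectory> 4000 attempts, 2257 proposals, 124 accepted
#>   final resilience: 0.525962 (locally stable: TRUE)

report <- structure_report(traj$mats, n_null = 200, seed = 5)
report$table
#> # A tibble: 4 × 8
#>   subnetwork   metric     observed null_mean null_sd      z significant relative
#>   <chr>        <chr>         <dbl>     <dbl>   <dbl>  <dbl> <lgl>          <dbl>
#> 1 mutualistic  nodf         17.5      15.6    4.01    0.492 FALSE         0.127
#> 2 mutualistic  modularity    0.656     0.503  0.0499  3.06  TRUE          0.303
#> 3 antagonistic nodf         12.9      15.2    3.97   -0.595 FALSE        -0.155
#> 4 antagonistic modularity    0.548     0.518  0.0574  0.513 FALSE         0.0568

stats <- plant_stats(traj$mats, traj$eq)
correlation_suite(stats)
#> # A tibble: 1 × 5
#>   spearman_dd r2_dd slope_db r2_db spearman_db
#>         <dbl> <dbl>    <dbl> <dbl>       <dbl>
#> 1       0.735 0.457    0.817 0.654       0.846
```

Reading the output: after 4000 rewiring attempts (124 accepted switches,
each of which strictly raised the focal animal's equilibrium biomass), the
mutualistic sub-network has become significantly more compartmentalized
than the equiprobable null expectation (modularity 0.656 vs 0.503, z =
3.06 > 1.645), link counts have stayed exactly at 36/35, and the plants'
degree centralities in the two sub-networks — independent by construction in
the random starting network — are now strongly positively correlated
(Spearman ρ = 0.74), with the per-plant energy-budget difference tracking
the degree-centrality difference (r² = 0.65). Longer runs at 30 species per
guild sharpen all of these signatures.

Other entry points: `enumerate_strength_grid()` + `run_sweep()` for the
55-point interaction-strength design, `asymmetric_scenarios()` for unequal
sub-network complexity, `lhs_sensitivity()` for ±30% Latin hypercube
designs, `autoplot()` / `tidy()` / `glance()` methods for the result
objects, and a thin command-line front end in `inst/cli/triguild`
(`generate`, `equilibrate`, `rewire`, `metrics`, `sweep`, `lhs`).

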