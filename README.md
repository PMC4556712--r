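# ggmbench

Benchmarking large-scale network recovery from short, autocorrelated
Gaussian time series.

## The problem

Functional networks (e.g. resting-state fMRI networks with hundreds to
thousands of ROIs) are often estimated by thresholding pairwise
correlations. For jointly Gaussian node signals the marginal correlation
between two nodes is a function of the *products of partial correlations
along the paths* connecting them, so indirect connections masquerade as
direct ones: thresholded correlation networks acquire spurious triangles,
fragment into components, and can look like small worlds when the true
network is not. Partial correlations — zero exactly when no direct edge
exists in a Gaussian graphical model (GGM) — fix this in principle, but for
`n < p` the sample covariance is singular and regularized estimators are
needed.

`ggmbench` turns this into a reproducible simulation benchmark. Ground
truth is a graph `G` carrying a partial-correlation matrix `R` with
`support(R) = G`, regularized to positive definiteness; data are `p × T`
Gaussian series with covariance `Σ = 2C` (where `C` is the correlation
matrix implied by `R`) and AR(1) temporal structure `ρ^|lag|`, so `n`
observations are worth only `n' = n(1−ρ)/(1+ρ)` independent ones. Four
estimators are compared after pruning each to the same edge count k (the
truth, ±20%, or a fixed 3% density):

- **pairwise** — Pearson correlations;
- **shrinkage** — partial correlations from `Σ̂ = (1−λ_s)S + λ_s diag(S)`
  with the analytic optimal λ_s;
- **pseudoinverse** — partial correlations from the Moore–Penrose inverse
  `S⁺` via `r_ij = −γ_ij / √(γ_ii γ_jj)`;
- **glasso** — L1-penalized inverse covariance (own Rcpp implementation),
  with the penalty λ_l searched to hit a target support size.

Recovery is scored by TPR/FPR (overall and per degree-bin pairing) and by
discrepancies in network metrics: average path length, transitivity,
Humphries–Gurney small-worldness `(C/C_rand)/(L/L_rand)`, components,
betweenness, degree and strength.

## Worked example

```r
library(ggmbench)

topo <- finalize_connected(generate_random(200, count = 300, seed = 1))
topo
#> <network_topology> 193 nodes, 299 edges (density 0.01614)

ggm <- build_ggm(topo, seed = 2)          # R, C, Sigma on that topology
ts  <- simulate_ar1_gaussian(ggm$sigma, T_len = 1000, rho = 0.5, seed = 3)
ts
#> <time_series_matrix> 193 nodes x 1000 time points (rho = 0.5)

k <- n_edges(topo)
for (m in c("pairwise", "shrinkage", "pseudoinverse", "glasso")) {
  w   <- estimate_weights(ts, m,
                          target_edges = glasso_support_target(k, topo$n_nodes))
  net <- select_top_k(w, k)               # same density for every method
  r   <- tpr_fpr(net, topo)
  cat(sprintf("%-13s TPR = %.2f  FPR = %.4f  components = %d\n",
              m, r$tpr, r$fpr, components_summary(net)$n_components))
}
#> pairwise      TPR = 0.12  FPR = 0.0144  components = 161
#> shrinkage     TPR = 0.69  FPR = 0.0051  components = 8
#> pseudoinverse TPR = 0.70  FPR = 0.0049  components = 9
#> glasso        TPR = 0.72  FPR = 0.0046  components = 10

effective_sample_size(1000, 0.5)
#> [1] 333.3333
```

At matched density the pairwise network recovers only 12% of true edges and
shatters into 161 components (the truth is one component of 193 nodes),
while the partial-correlation estimators recover ~70% — even though the
1000 autocorrelated time points carry only ~333 effective observations for
a 193-node graph.

`run_study()` runs the full factorial design (topologies × series lengths ×
estimators × selection densities × seeds) and returns a tidy summary;
`generate_roi_fixture()` + `consistency_analysis()` reproduce the
application-style analyses on synthetic hierarchically parcellated ROI
series. A CLI wrapper for every stage is in `inst/cli/ggmbench.R`.

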