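---
title: "Benchmarking network recovery from short, autocorrelated Gaussian time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking network recovery from short, autocorrelated Gaussian time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Large functional networks — in particular resting-state fMRI networks with
hundreds to thousands of regions of interest (ROIs) — are routinely estimated
by thresholding pairwise correlations between node time series. A marginal
correlation, however, cannot distinguish a direct connection from an indirect
one: in a Gaussian system, the correlation between two nodes is a function of
the product of partial correlations along the paths connecting them, so every
chain of direct links induces marginal correlation between its endpoints. A
thresholded correlation network therefore acquires spurious triangles,
fragments into components, and misrepresents degree and betweenness — it can
look like a small world when the true network is not.

`ggmbench` rebuilds this problem as a controlled benchmark:

1. **Topology** — generate a known ground-truth graph (Erdős–Rényi, an
   acquaintance-model small world with or without hubs, or preferential
   attachment), restricted to its largest connected component.
2. **Weights** — place a valid Gaussian graphical model (GGM) on the graph:
   a partial-correlation matrix `R` whose support equals the topology,
   regularized to positive definiteness, then converted to a correlation
   matrix `C` and covariance `Σ = 2C`.
3. **Data** — simulate `p × T` Gaussian series with cross-sectional
   covariance `Σ` and AR(1) temporal correlation `ρ^|lag|` (default
   `ρ = 0.5`), so that `n` observations carry only
   `n' = n(1−ρ)/(1+ρ)` observations' worth of information.
4. **Recovery** — estimate edge weights with four estimators: pairwise
   Pearson correlation, and partial correlations via the Schäfer–Strimmer
   shrinkage covariance, the Moore–Penrose pseudoinverse, and the graphical
   lasso (our own block-coordinate-descent implementation; none of the
   environment's packages provide it).
5. **Selection and scoring** — binarize each weight matrix by keeping the
   `k` largest |weights| (the true count, ±20%, or a fixed 3% density),
   then score TPR/FPR overall and by degree-bin pairing, plus discrepancies
   in path length, clustering, small-worldness, components, betweenness,
   degree and strength.

`run_study()` executes the full factorial design; `generate_roi_fixture()`
and `consistency_analysis()` reproduce the application-style analyses
(hierarchically nested parcellations, shrinking time series) on synthetic
ROI data.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `rho` | 0.5 | AR(1) autocorrelation; halves the effective sample size at 0.5 (`n' = n/3`) |
| `variance` | 2 | common node variance of the generating covariance |
| edge weights | U([−1, −.01] ∪ [.01, 1]) | partial correlations on the support, signs equiprobable, magnitudes bounded away from 0 |
| `eig_floor` | 1e-3 | minimum eigenvalue of the implied concentration matrix after regularization (below) |
| selection densities | k, round(0.8k), round(1.2k) | fixed-density pruning so method comparisons are not confounded by thresholding |
| degree bins | 5 equal bins + 50 top-degree nodes | hub-resolved TPR/FPR |
| `fixed_density_k` | 3% (floor) | parcellation-style selection; gives 68/193/716/3003/14985 edges for 68/114/219/448/1000 ROIs |

## Numerical and design choices

**PD regularization (`regularize_to_pd`).** How the raw weight matrix is
made positive definite is genuinely open: we multiply all off-diagonal
entries by a common factor `c ∈ (0, 1]`, found by bisection (tolerance 1e-4)
as the largest factor for which the implied concentration matrix has minimum
eigenvalue ≥ `eig_floor`. Uniform scaling preserves the support and the sign
pattern exactly, so re-zeroing non-edges afterwards is a no-op, and
termination is guaranteed (`c → 0` gives the identity).

**The eigenvalue floor.** A floor that is essentially machine precision
(1e-6) makes the implied correlation matrix numerically degenerate at
p = 200–2000: the largest |correlation| exceeds 0.999, the graphical lasso
can diverge for `n < p` inputs, and all estimators collapse onto
pairwise-correlation behavior, destroying the very contrasts the benchmark
studies. The default floor of 1e-3 is the package's own choice: it stays
close to the "just barely positive definite" construction — indirect
correlations remain strong enough that the population-level pairwise
network is badly wrong (its top-k edge set plateaus at a low TPR no matter
how long the series) — while keeping `Σ` invertible in double precision so
the partial-correlation estimators behave regularly. `eig_floor` is an
exported argument; users can study the degenerate regime explicitly.

**Acquaintance model.** The small-world-with-tunable-hubs generator is
reconstructed from its published description rather than copied from a
library (none provides it): starting from an Erdős–Rényi seed graph with
mean degree 2, each iteration a uniformly chosen node introduces two of its
neighbors (or, with fewer than two neighbors, links itself to a random
node); with probability `p_d` a random node is then replaced by a newcomer
with one random link. The initial condition is not fixed by the
description; the ER seed is our choice and is irrelevant after the ~625
iterations per node used in practice.

**Graphical lasso.** Implemented as Friedman-style block coordinate descent
(Rcpp/Armadillo), solving each column's lasso subproblem by cyclic
coordinate descent; correctness is verified in the tests against the KKT
conditions of the penalized likelihood and against the closed-form limits
λ → 0 (matrix inverse) and λ → ∞ (diagonal). Density targeting searches λ
on a warm-started descending geometric path until the support brackets the
target, then bisects (≤ 40 steps) to within ±2% of the requested edge
count, ties resolved toward the sparser solution. A pure bisection from a
near-zero λ is not used: for `n < p` the unpenalized problem is ill-posed
and the solver can diverge there.

**Glasso in the study pipeline.** When the generating GGM is nearly
singular, the λ that forces the glasso support down to the selection
density itself (3% and below) is enormous on the correlation scale, and the
L1 bias then reduces the estimate to thresholded marginal correlations. The
study harness (`run_study`) therefore fits the glasso at a support ten
times the densest selection criterion (`glasso_support_target()`) and lets
the shared top-|weight| pruning step set the final density — the same
pruning all four estimators pass through. `glasso_pcor()` itself still
targets any exact support size on request.

**Shrinkage intensity.** The analytic optimal intensity for shrinking
off-diagonal correlations toward zero: the ratio of the summed estimated
variances of the sample correlations to their summed squares, clipped to
[0, 1]. Because the target keeps the sample variances, shrinking the
covariance and shrinking the correlation matrix coincide here. Partial
correlations are computed from the inverse of the shrunk covariance, which
is positive definite for any λ > 0, hence defined for `n < p`.

**Pseudoinverse.** SVD-based, singular values below
`max(dim) · ε · σ_max` treated as zero — the standard tolerance; for a
positive-definite sample covariance this is the plain inverse.

**Path length on fragmented graphs.** Average geodesic distance is taken
over reachable pairs only; unreachable pairs are excluded rather than given
an infinite or imputed distance. This matters because pairwise-correlation
networks fragment; excluding unreachable pairs makes their path lengths
look *shorter*, which is part of the small-worldness inflation the
benchmark demonstrates.

**Small-worldness.** Humphries–Gurney index `(C/C_rand)/(L/L_rand)` with
the reference values estimated as means over an ensemble of ER graphs with
matched node and edge count (default 10 seeded replicates); a closed-form
reference (`C_rand = k̄/(n−1)`, `L_rand = ln n / ln k̄`) is provided for
speed and cross-checked in the tests.

**Strength.** Sum of |weights| over a node's selected edges: partial
correlations carry signs, and the sign convention for strength is not fixed
by common usage; absolute values keep strength monotone in connectivity.

**Degree bins.** Top-degree bin of exactly `top_n` nodes (ties broken by
node index), remaining nodes sorted by degree and split into 5 bins whose
sizes differ by at most 1, remainders assigned to the lowest bins.
Undefined bin-pair rates (no true edges / no non-edges in a pairing) are
reported as missing rather than 0, so averages are not biased.

**Rounding.** The ±20% selection counts round half away from zero (the
reference cases are exact multiples, so this is unconstrained); the 3% rule
floors.

**Representative topology selection.** Candidates are compared on
transitivity, average path length, average degree, degree variance, average
betweenness and small-worldness; each metric is z-scored across candidates
("normalized") and the candidate closest to the group mean in Euclidean
distance wins, ties to the lowest index.

**Prefix lengths for the consistency analysis.** The shrinking-series
analysis uses a near-geometric grid of 16 lengths from the full series down
to 15 time points (the source design names only the endpoints).

## What the synthetic data do and do not emulate

The generator produces exactly the stated world: known topology, exact-zero
partial correlations off the support, uniform variance, Gaussian
innovations, stationary AR(1) temporal structure, and (for the ROI fixture)
coarser parcellations formed as exact means of their constituent fine ROIs.
It does **not** emulate hemodynamic response convolution, scanner noise,
motion artifacts, non-stationarity, negative-definite preprocessing
artifacts, or spatial autocorrelation between neighboring ROIs beyond what
the GGM implies. A green test therefore establishes that an estimator
recovers a sparse GGM from short AR(1) Gaussian series at matched density —
not that it recovers networks from real BOLD data.

## Scaled acceptance testing

The headline comparative results at p = 2000 with full replication are not
desk-reproducible; the acceptance suite asserts the method *orderings* at
p = 200 (a sparse ER truth with mean degree 3, series lengths 50–1000, five
replicate seeds): pairwise networks are small-world-inflated and fragmented
at every length; shrinkage and glasso TPR rise with series length while
pairwise TPR stays flat; the pseudoinverse FPR is worst when `n < p`; and
acquaintance-model graphs score far above 1 in small-worldness while ER
graphs sit near 1. Exact reference values (the analytic identities, the
9-node tree's 84 implied triangles, and the dense/sparse random-network
table rows) are recomputed at full scale in `scripts/acceptance.R`.

## Known limitations

- The PD regularization (hence the weight magnitudes and the implied
  correlation scale) is one of several defensible constructions; recovery
  rates depend on it quantitatively, though the qualitative orderings are
  stable across the floors we examined.
- The graphical lasso solver is tuned for the sparse-target regime used
  here; for dense targets at `n ≪ p` it refuses rather than diverges.
- `small_worldness` with simulated references is stochastic; use enough
  reference seeds (or the analytic mode) when comparing close values.
- The acquaintance generator is a reconstruction; its hub regime (`p_d`
  small) matches the described qualitative behavior but individual runs are
  not comparable to any published instance.
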