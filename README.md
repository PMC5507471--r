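# connectoscope

Network analysis of directed, spatially embedded brain connectomes at the
region (areal) scale — the resolution at which a rat cerebral connectome
has ~125 regions, ~2,900 directed interareal projections (density
ρ = M/N(N−1) ≈ 0.19), several hundred reciprocal pairs, and a partial
neurochemical annotation. The package is for systems neuroscientists and
network scientists who have a region table (with stereotaxic coordinates)
and a directed edge list, and want the standard structural battery plus
the generative and inferential models that go with it:

* **Directed graph statistics** — density, reciprocity (M = M₁ + 2M₂),
  degree/betweenness ranking tables, clustering, directed path lengths,
  the eigenspectrum of the co-occurrence matrix AAᵀ, the 16-class triad
  (3-motif) census and the directed-clique census.
* **Core–periphery inference** — a two-block stochastic block model fitted
  by EM: edge i→j is Bernoulli with probability p(gᵢ, gⱼ) given latent
  classes g ∈ {core, periphery}; the likelihood
  P(A | p, γ) = Σ_g Π_{i≠j} p(gᵢgⱼ)^Aᵢⱼ (1−p(gᵢgⱼ))^(1−Aᵢⱼ) Π γ(gᵢ)
  is maximized over soft memberships. Plus a clique-based core detector
  and the analytic Erdős–Rényi specificity bound
  C(N,K)·C(L,qL)·p^{qL}(1−p)^{(1−q)L}, L = K(K−1), evaluated in log space.
* **Onion dendrograms** — Girvan–Newman edge-betweenness deletion with
  strongly-connected-component tracking, per-node onion depth, Newick
  export, and the depth-vs-core association profile.
* **Structural controllability** — driver nodes via maximum matching,
  degree-preserving rewiring nulls, and the driver-count curve under
  longest-edge removal.
* **EDR generative model** — random networks whose connection lengths obey
  the exponential distance rule p(l) ∝ e^(−λl) on a given geometry, and
  decay-rate estimation by ensemble property matching over M₁/M₂, motifs,
  cliques, eigenspectra and clustering, with a per-property λ_P and a
  consensus band.
* **Recursive coarsening** — minimum-weight spanning tree with binary
  intra/inter-region weights, fundamental-cut conductance ratings, and
  contraction to a macro-region quotient network.
* **Synthetic data** — geometry, EDR networks, planted core–periphery
  graphs and chemical layers with truth records, emulating the areal-scale
  statistics above.

Everything takes and returns tibbles; fitted objects have `tidy()`,
`glance()` and `autoplot()` methods.

## Worked example

```r
library(connectoscope)

# a synthetic 125-area connectome: EDR wiring (lambda = 0.6 /mm) on a
# rat-scale geometry at density 0.19, 25% chemical coverage
syn <- generate_synthetic_connectome(N = 125, M = 2906, lambda = 0.6, seed = 1)
graph_summary(syn$connectome)
#> # A tibble: 1 × 9
#>   n_regions     M density    M1    M2 loops mean_clustering mean_path diameter
#> 1       125  2906   0.187  1234   836     0           0.472      1.96        4

# recover the decay rate by ensemble property matching
fit <- match_lambda(syn$connectome, syn$D, grid = seq(0, 1.5, 0.1),
                    n_rep = 30, seed = 2)
fit
#> <edr_fit> grid [ 0 , 1.5 ] 1/mm, 30 replicates per point
#>   lambda_M1          = 0.6
#>   ...
#>   consensus band: 0.6 - 0.6 1/mm
```

All six matched properties independently select the generating decay rate;
a tight consensus band is the signature that a single-λ EDR describes the
network. On a planted two-block graph at the empirically observed affinity
scale the SBM recovers structure and parameters:

```r
gen <- generate_planted_core_periphery(N = 125, K = 69, p_cc = 0.41,
                                       p_pp = 0.03, p_cp = 0.12, seed = 1)
fit <- fit_core_periphery(gen$connectome, n_restarts = 10, seed = 1)
fit
#> <core_periphery_fit> core: 69 nodes, periphery: 56 nodes
#>   affinity p_cc = 0.417  p_cp/pc = 0.125 / 0.116  p_pp = 0.0312
#>   block densities rho_cc = 0.42, rho_pp = 0.03, rho_cp = 0.12
mean(tidy(fit)$core == gen$truth$assignment)
#> [1] 1

# how specific is such a core in a random graph of the same density?
attr(er_core_bound(125, 69, 0.19, 0.41), "log10")
#> [1] -227.3     # i.e. ~4.9e-228 — essentially impossible by chance
```

The 69-node core is recovered exactly, the affinities land within
sampling error of the generating values, and the analytic bound says a
core that dense cannot arise in an Erdős–Rényi graph — observing one is
structurally meaningful.

A whole analysis battery (metrics tables, core–periphery JSON, Newick
dendrogram, controllability report, EDR fit) runs from one config:

```r
run_analysis(list(edge_file = "edges.tsv", region_file = "regions.tsv",
                  stages = c("metrics", "core", "gn", "control", "edr"),
                  seed = 42, out_dir = "out"))
```

`inst/cli/connectoscope-run.R` wraps this for the shell.

## Acceptance script

`scripts/acceptance.R` re-runs the package end to end on the synthetic
stated world — it generates the 125-area EDR connectome with its chemical
layer, executes the full pipeline (metrics, SBM core–periphery,
Girvan–Newman dendrogram, controllability with rewiring null and removal
curve, EDR property matching) plus the macro-region coarsening path, and
writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness derives from `--seed`.

## File formats

Edge table: TSV `source  target  chemicals` (chemicals optional,
`;`-separated; rows with source == target become self-loops). Region
table: TSV `id  name  macro_region  x  y  z  bregma`. Interchange:
GraphML (lossless), edge-list TSV, adjacency CSV (drops the chemical
layer). Dendrograms export as Newick.
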