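---
title: "Network analysis of directed brain connectomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network analysis of directed brain connectomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectoscope)
```

# The object of study

An areal-scale connectome is a directed binary graph: nodes are named brain
regions with stereotaxic centre coordinates (mm), and an edge $i \to j$
records an axonal projection from region $i$ to region $j$. At this scale a
rat cerebral connectome has on the order of $N = 125$ regions,
$M \approx 2{,}900$ directed interareal links (density
$\rho = M/N(N-1) \approx 0.19$), several hundred reciprocally connected
pairs, a small set of intraregional (self) connections, and a partial
neurochemical annotation — roughly a quarter of the edges carry one or more
of ~25 transmitter labels, the rest are plain binary links.

The `connectome` container mirrors this: an $N \times N$ zero-diagonal
binary adjacency matrix ordered like the region table, a separate
self-loop set (so every graph statistic operates on the loop-free
interareal network), and an optional edge-to-label map restricted to a
declared vocabulary.

# Graph statistics

Density, in/out-degrees, reciprocity ($M = M_1 + 2M_2$ with $M_1$
unidirectional and $M_2$ bidirectional pairs), local clustering on the
undirected support, directed shortest paths, betweenness, the triad census
and the directed-clique census follow their textbook definitions; igraph
provides the algorithmic core and every result returns as a tibble.
Conventions that the definitions leave open are fixed as follows and used
consistently:

* **Betweenness normalization.** Node betweenness is the sum over ordered
  pairs $s \ne t$ of $\sigma_{st}(v)/\sigma_{st}$ divided by
  $(N-1)(N-2)$; edge betweenness divides by $N(N-1)$. Only "fraction of
  shortest paths" is inherent to the quantity; the constants make values
  comparable across graphs and leave rankings and Girvan–Newman deletions
  unchanged.
* **Unreachable pairs** are excluded from path averages (the alternative —
  infinite distances — makes every non-strongly-connected graph
  degenerate).
* **Ranking ties** break by region id ascending, so published-style degree
  and betweenness tables are reproducible.
* **Clique counting.** A directed $k$-clique is a vertex set carrying all
  $k(k-1)$ links, i.e. a complete subgraph of the reciprocal (mutual-link)
  graph. The census counts *all* complete subsets per size, not only
  maximal ones: overlapping same-size cliques are biologically meaningful
  (a dense core typically contains many interlocking maximum cliques) and
  this is the reading under which published clique-count figures are
  internally consistent.
* **Spectra.** Directed adjacency matrices have complex eigenvalues, so the
  spectrum reported is that of the symmetric co-occurrence matrix $AA^T$;
  for binary $A$ its trace — hence the eigenvalue sum — equals $M$, which
  the tests assert as a conservation law.

# Core–periphery inference

The two-block stochastic block model treats each node's class
$g_i \in \{c, p\}$ as latent with prior $\gamma$, and each directed edge as
an independent Bernoulli draw with probability $p_{g_i g_j}$ from a
$2 \times 2$ affinity matrix. The fit maximizes the marginal likelihood

$$P(A \mid p, \gamma) = \sum_{g} \prod_{i \ne j}
  p_{g_i g_j}^{A_{ij}} (1 - p_{g_i g_j})^{1 - A_{ij}} \prod_i \gamma_{g_i}$$

via mean-field EM. Design choices, made where the method description is
open:

* **Sequential membership updates.** The E-step updates the soft
  memberships one node at a time (coordinate ascent on the evidence lower
  bound). Parallel mean-field updates can oscillate on dense graphs;
  sequential updates make the lower bound provably non-decreasing, which
  the tests assert per iteration.
* **Restarts and convergence.** 20 random initializations by default,
  relative lower-bound change below $10^{-8}$ or 500 iterations. The
  label-switching symmetry is resolved by calling the class with the
  larger internal connection probability the core; assignment thresholds
  the posterior core probability at $\gamma_c > 0.5$.
* **Unweighted model.** The weighted variational-Bayes extension of this
  model is out of scope; on unweighted networks the plain EM is the
  appropriate special case, and near-boundary affinities are clamped to
  $[10^{-10}, 1 - 10^{-10}]$ so ideal planted graphs (complete core, empty
  periphery) remain well-defined.

On dense coarse-scale networks an assumption-free alternative is the
clique-based core: the union of all vertices in maximum-size cliques
(`clique_based_core()`), inapplicable when the largest clique has fewer
than three nodes.

**Specificity bound.** How surprising is a dense core in a random graph?
For a directed Erdős–Rényi graph on $N$ nodes with density $p$, the
probability of some $K$-subset having internal density $q$ is at most
$\binom{N}{K} \binom{L}{qL} p^{qL} (1-p)^{(1-q)L}$ with $L = K(K-1)$.
`er_core_bound()` evaluates this in log space. Because $q$ is in practice
a *rounded printed density*, $qL$ is generally non-integer; the binomial
is therefore evaluated with the continuous log-gamma extension — the only
choice well-defined for such inputs. For $N=125, K=69, p=0.19, q=0.41$
this yields $10^{-227.3} \approx 4.9 \times 10^{-228}$: a 69-node core of
density 0.41 in a 0.19-dense random graph is essentially impossible, so an
observed one is highly specific. Note the convention: plugging exact edge
fractions instead of 2-d.p. densities shifts such bounds by an order or
two (e.g. $q = 287/380$ vs $q = 0.76$ for a 20-node clique core gives
$10^{-102.1}$ vs $10^{-104.2}$); the package follows the printed-density
convention in its worked examples and documents the sensitivity here.

# Onion dendrograms

The Girvan–Newman procedure recomputes directed edge betweenness, deletes
the single highest-betweenness edge (ties: lexicographically smallest
(source, target) pair, for exact reproducibility), and records strongly
connected components after every deletion until no edges remain. Edge
deletion can only refine an SCC partition, so splits nest into a
dendrogram. Dense connectomes do not break into balanced communities;
instead single areas peel off a persisting big component — an onion. A
node's depth is the number of splits of its own component it survived
(still in a component of $\ge 2$ nodes) before isolation;
`onion_profile()` reports the Spearman correlation between depth and the
SBM core probability, which is positive when core areas sit at the heart
of the onion, and is flagged `degenerate` (association 0) when either
variable is constant, as on a complete digraph.

# Recursive coarsening

To collapse a fine-grained connectome onto macro-regions, edges of the
undirected support are weighted 0 (intraregional) or 1 (interregional) —
the only reading under which a *minimum*-weight spanning tree prefers
intraregional edges and contraction can respect region boundaries. Each
tree edge is rated by the conductance of its fundamental cut (cut edges
over the smaller side's volume; the source names the quantity without a
formula). Intraregional tree edges are contracted in decreasing rating
order — a high-conductance cut is a poor separator, so such edges merge
first — until each macro-region is a single node; if a macro-region cannot
be contracted to one node through intraregional edges the labels are
inconsistent with the wiring and the call errors rather than guessing.
The final quotient has an edge $r \to s$ iff any member edge crossed from
$r$ to $s$; intraregional links collapse away and are reported as counts.
The quotient itself is invariant to the contraction order; the plan
(tree, ratings, order) is attached for inspection because the *ratings*
are the scientifically interesting part at intermediate scales.

# Structural controllability

A directed network is structurally controllable from its unmatched nodes:
a matching is a set of edges sharing no tails and no heads, and nodes that
head no matched edge must receive independent driving signals. Maximum
matching (computed on the bipartite out-copy/in-copy representation)
minimizes this driver set; only the driver *count* is stable across the
generally non-unique optima, so the reported set is one realization. A
perfect matching yields zero drivers and is flagged rather than bumped to
the one-driver convention.

Two perturbation analyses accompany the matching: degree-preserving
double-edge swaps (rejecting loops and duplicates; 20M attempted swaps
by default, one derived RNG stream per replicate) give the null
distribution of the driver count at fixed in/out-degree sequences, and
`edge_removal_curve()` removes the longest connections first (Euclidean
inter-centre distance, lexicographic tie-break) to show how wiring economy
degrades controllability as long-range links disappear.

# The EDR generative model

The exponential distance rule says projection lengths are distributed as
$p(l) \sim e^{-\lambda l}$. Given only the geometry (distance matrix), the
number of nodes and the edge count, the EDR network model is the
maximum-entropy construction honouring that rule: draw $l$ from the
exponential, pick uniformly among region pairs in the same distance bin,
orient at random, skip existing edges, stop at the target edge count.
$\lambda = 0$ is the constant distance rule (CDR), the geometry-blind
uniform baseline.

Numerical choices:

* **Binning.** Fixed-width bins, default (max pairwise distance)/50; the
  width is a reported knob since the source does not state one. Draws in
  empty bins are rejected and redrawn — snapping to the nearest occupied
  bin would bias $p(l)$.
* **Sampling.** The literal loop is exactly weighted sampling without
  replacement over directed pairs with fixed weights (bin probability over
  bin occupancy), so the default sampler implements it as an exponential
  race in log space: simulate one exponential key per directed pair,
  take the `target_M` smallest. Identical distribution, no rejection
  stalls at extreme $\lambda$, and numerically safe for any decay rate.
  The literal loop is retained (`method = "sequential"`) and the suite
  checks distributional agreement.

**Decay-rate estimation** is by ensemble property matching: for each
$\lambda$ on a grid (default $0$–$2\ \mathrm{mm}^{-1}$ in steps of 0.05),
average $M_1$, $M_2$, the 16 triad counts, clique counts by size, the
sorted $AA^T$ spectrum and mean clustering over an ensemble (1,000
replicates in a full analysis; 100 is the documented desk-scale
reduction), and let each property pick its own $\lambda_P$ minimizing the
deviation from the data (absolute differences for scalars, RMS for
vectors; triad deviations on raw counts at coarse scale or on model/data
ratios at fine scale, selectable). The *consensus interval* — the range of
the $\lambda_P$ — is the result: a tight band says a single decay rate
explains many independent properties at once; per-property optima that
disagree say a one-parameter EDR is the wrong model at that resolution,
which is itself the scientifically expected outcome when gray-matter and
white-matter connections mix at fine parcellations.

# The synthetic world

The generators produce fixtures with the statistical structure the
analyses assume, each carrying a truth record for recovery tests:

* `generate_geometry()`: uniform centres in a 15 × 10 × 12 mm box
  (diagonal 21.7 mm, so max distances ≈ 20 mm and
  $\lambda = 0.6\ \mathrm{mm}^{-1}$ is meaningfully selective —
  configurable).
* EDR networks at the data scale ($N = 125$, $M = 2{,}906$, density 0.19,
  $M_2$ in the several-hundreds at $\lambda \approx 0.6$).
* Planted two-block graphs at the fitted affinity scale
  ($\rho_{cc}/\rho_{cp}/\rho_{pp} = 0.41/0.12/0.03$).
* Chemical layers at 25.08% coverage with the observed label mix (GABA
  18.36%, dopamine 15.37%, serotonin 13.47%, glutamate 10.75%, enkephalin
  7.76%, remainder spread over 20 further labels).

What the generators deliberately do **not** emulate: spatially organized
macro-region structure (labels are exchangeable), literature-mining
provenance, weighted or cell-type-resolved connectivity, and the
two-decay-rate (gray + white matter) EDR. A green recovery test therefore
establishes that the estimators work on networks *generated by the model
they assume* at realistic size and density — not that any particular real
connectome satisfies those assumptions.

# Degenerate inputs and edge cases

Empty graphs are legal everywhere they can be (censuses, dendrograms,
driver analysis); density needs $N \ge 2$, the triad census $N \ge 3$, the
SBM $N \ge 4$. Graphs with no reachable pairs error in path statistics
rather than returning NaN. The EDR sampler refuses a target edge count
above the number of available directed pairs. Coarsening refuses label
maps inconsistent with connectivity. The rewiring null warns and returns
the input when no swap is feasible (e.g. a directed 3-cycle).

# Known limitations

* The EM fit returns a local optimum; restarts mitigate but do not
  guarantee the global one, and on real data core membership can move by
  a node between equally good optima.
* Property-matching deviation curves depend mildly on bin width, grid and
  ensemble size; consensus bands should be read at grid resolution.
* Girvan–Newman recomputes full edge betweenness per deletion
  ($O(M \cdot NM)$ overall), fine for areal-scale networks, not for
  thousands of nodes.
* The clique census is exponential in the worst case; the EDR matching
  path bounds enumerated clique size (default 12) and reports counts, not
  the cliques themselves.
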