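#' Synthetic region geometry
#'
#' Uniform region centres inside a rat-brain-scale box. The default
#' 15 x 10 x 12 mm extent gives a maximal pairwise distance near 20 mm
#' (the box diagonal is 21.7 mm), so that an EDR decay rate of
#' 0.6 1/mm is meaningfully selective on this geometry.
#'
#' @param N Number of regions (>= 2).
#' @param extent Length-3 numeric box extent in mm.
#' @param seed Integer seed.
#' @return List with `regions` (tibble `id`, `name`, `macro_region`,
#'   `x`, `y`, `z`) and `D` (distance matrix from
#'   [euclidean_distances()]).
#' @export
generate_geometry <- function(N, extent = c(15, 10, 12), seed = 1) {
  stopifnot(N >= 2, length(extent) == 3)
  if (any(extent <= 0)) stop("degenerate box extent")
  set.seed(seed)
  regions <- tibble::tibble(
    id = sprintf("R%03d", seq_len(N)),
    name = sprintf("region %d", seq_len(N)),
    macro_region = "synthetic",
    x = stats::runif(N, 0, extent[1]),
    y = stats::runif(N, 0, extent[2]),
    z = stats::runif(N, 0, extent[3])
  )
  list(regions = regions, D = euclidean_distances(regions))
}

#' Planted two-block core-periphery graph
#'
#' Directed Bernoulli edges: the first K regions form the core, the rest
#' the periphery, and an edge i -> j appears independently with
#' probability `p_cc`, `p_pp` or `p_cp` according to the endpoint blocks
#' (both core-to-periphery directions use `p_cp`). The returned truth
#' record carries the planted assignment and parameters so recovery can
#' be tested downstream.
#'
#' @param N Number of regions.
#' @param K Core size, 0 < K < N.
#' @param p_cc,p_pp,p_cp Block connection probabilities. The defaults are
#'   the fitted block densities of the 125-area rat connectome
#'   (0.41 / 0.03 / 0.12) at its core fraction.
#' @param seed Integer seed.
#' @param regions Optional region table (defaults to synthetic ids).
#' @return List with `connectome` and `truth` (list: `core_ids`,
#'   `assignment`, `p`, `seed`).
#' @export
generate_planted_core_periphery <- function(N = 125, K = 69, p_cc = 0.41,
                                            p_pp = 0.03, p_cp = 0.12,
                                            seed = 1, regions = NULL) {
  if (K <= 0 || K >= N) stop("need 0 < K < N")
  for (p in c(p_cc, p_pp, p_cp)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  set.seed(seed)
  if (is.null(regions)) {
    regions <- tibble::tibble(id = sprintf("R%03d", seq_len(N)))
  }
  core <- seq_len(N) <= K
  P <- matrix(p_cp, N, N)
  P[core, core] <- p_cc
  P[!core, !core] <- p_pp
  A <- matrix(as.integer(stats::runif(N * N) < P), N, N)
  diag(A) <- 0L
  C <- connectome(regions, A)
  truth <- list(core_ids = regions$id[core],
                assignment = stats::setNames(core, regions$id),
                p = c(p_cc = p_cc, p_pp = p_pp, p_cp = p_cp),
                K = K, seed = seed)
  list(connectome = C, truth = truth)
}

#' Default chemical label proportions
#'
#' Label frequencies among the chemically annotated edges of the rat
#' connectome: GABA 18.36%, dopamine 15.37%, serotonin 13.47%, glutamate
#' 10.75%, enkephalin 7.76%; the remaining mass is spread evenly over the
#' other 20 vocabulary labels.
#'
#' @return Named numeric vector over [default_chemical_vocabulary()],
#'   summing to 1.
#' @export
default_chemical_proportions <- function() {
  vocab <- default_chemical_vocabulary()
  big5 <- c(GABA = 0.1836, dopamine = 0.1537, serotonin = 0.1347,
            glutamate = 0.1075, enkephalin = 0.0776)
  rest <- setdiff(vocab, names(big5))
  p <- c(big5, stats::setNames(rep((1 - sum(big5)) / length(rest),
                                   length(rest)), rest))
  p[vocab]
}

#' Overlay a synthetic chemical layer on a connectome
#'
#' Labels a `coverage` fraction of the directed edges (default 25.08%,
#' the chemical coverage of the rat connectome); each labelled edge gets
#' one label drawn from `proportions`. Unlabelled edges remain plain
#' binary links.
#'
#' @param C A [connectome].
#' @param proportions Named label frequencies over the vocabulary
#'   (renormalized if needed); default
#'   [default_chemical_proportions()].
#' @param coverage Fraction of edges to label, in \[0, 1\].
#' @param seed Integer seed.
#' @return List with `connectome` (labelled copy) and `truth`
#'   (`proportions`, `coverage`, `seed`).
#' @export
generate_chemical_layers <- function(C, proportions = default_chemical_proportions(),
                                     coverage = 0.2508, seed = 1) {
  if (coverage < 0 || coverage > 1) stop("coverage must lie in [0, 1]")
  set.seed(seed)
  et <- edge_tibble(C)[, c("source", "target")]
  m <- nrow(et)
  n_lab <- round(coverage * m)
  chemical <- NULL
  if (n_lab > 0) {
    pick <- sample.int(m, n_lab)
    prop <- proportions / sum(proportions)
    chemical <- tibble::tibble(
      source = et$source[pick], target = et$target[pick],
      label = sample(names(prop), n_lab, replace = TRUE, prob = prop)
    )
  }
  out <- connectome(C$regions, C$A, self_loops = C$self_loops,
                    chemical = chemical,
                    vocabulary = unique(c(C$vocabulary, names(proportions))))
  list(connectome = out,
       truth = list(proportions = proportions, coverage = coverage,
                    seed = seed))
}

#' A complete synthetic connectome fixture
#'
#' Bundles the generators into one call that emulates the statistical
#' structure of the 125-area rat connectome: uniform geometry in a
#' rat-scale box, an EDR network at the data density (about 0.19, i.e.
#' 2,906 directed links at N = 125) with decay rate `lambda`, and a
#' 25-label chemical layer covering about a quarter of the edges.
#'
#' @param N Number of regions.
#' @param M Number of directed links.
#' @param lambda EDR decay rate (1/mm).
#' @param coverage Chemical coverage fraction.
#' @param seed Master seed (fans out to geometry, network and labels).
#' @return List with `connectome`, `D`, `regions` and `truth`.
#' @export
generate_synthetic_connectome <- function(N = 125, M = 2906, lambda = 0.6,
                                          coverage = 0.2508, seed = 1) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 3)
  geo <- generate_geometry(N, seed = seeds[1])
  C <- sample_edr_network(geo$D, edr_spec(lambda, M, seed = seeds[2]),
                          regions = geo$regions)
  chem <- generate_chemical_layers(C, coverage = coverage, seed = seeds[3])
  list(connectome = chem$connectome, D = geo$D, regions = geo$regions,
       truth = list(lambda = lambda, M = M, coverage = coverage,
                    seed = seed, seeds = seeds))
}
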