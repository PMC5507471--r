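#' Graph density of a directed connectome
#'
#' Ratio of existing directed links to all possible ordered pairs,
#' `M / (N (N - 1))`. Self-loops are excluded by construction.
#'
#' @param C A [connectome].
#' @return A fraction in `[0, 1]`.
#' @export
graph_density <- function(C) {
  n <- n_regions(C)
  if (n < 2) stop("density needs at least 2 regions")
  n_edges(C) / (n * (n - 1))
}

#' Reciprocity counts
#'
#' Classifies every unordered region pair as unconnected, unidirectional
#' (M1) or bidirectional (M2), so that `M = M1 + 2 M2`. Self-loops are
#' counted separately.
#'
#' @param C A [connectome].
#' @return Tibble with one row: `M1`, `M2`, `loops`, `M`.
#' @export
reciprocity_counts <- function(C) {
  A <- C$A
  both <- sum(A & t(A)) / 2
  M <- sum(A)
  tibble::tibble(M1 = as.integer(M - 2 * both), M2 = as.integer(both),
                 loops = length(C$self_loops), M = as.integer(M))
}

#' Degree table with deterministic rankings
#'
#' In-, out- and total degree per region, excluding self-loops. Rankings
#' are 1-based, degree descending, ties broken by region id ascending.
#'
#' @param C A [connectome].
#' @return Tibble with columns `id`, `k_in`, `k_out`, `k_total`,
#'   `rank_in`, `rank_out`.
#' @export
degree_table <- function(C) {
  A <- C$A
  ids <- C$regions$id
  k_in <- colSums(A)
  k_out <- rowSums(A)
  rank_of <- function(k) {
    ord <- order(-k, ids)
    r <- integer(length(k)); r[ord] <- seq_along(k); r
  }
  tibble::tibble(id = ids,
                 k_in = as.integer(k_in), k_out = as.integer(k_out),
                 k_total = as.integer(k_in + k_out),
                 rank_in = rank_of(k_in), rank_out = rank_of(k_out))
}

#' Node and edge betweenness centrality
#'
#' Fraction of shortest directed paths running through each node (endpoints
#' excluded) or edge, counting all geodesics between every ordered pair
#' with equal weight; unreachable pairs contribute nothing. Node values are
#' normalized by `(N-1)(N-2)`, edge values by `N(N-1)`, so both are
#' fractions. Rankings and Girvan-Newman deletions are invariant to these
#' constants.
#'
#' @param C A [connectome].
#' @return List with tibbles `nodes` (`id`, `bc`, `rank`) and `edges`
#'   (`source`, `target`, `bc`).
#' @export
betweenness_table <- function(C) {
  g <- as_igraph(C, "directed")
  n <- n_regions(C)
  ids <- C$regions$id
  nb <- igraph::betweenness(g, directed = TRUE) / max(1, (n - 1) * (n - 2))
  eb <- igraph::edge_betweenness(g, directed = TRUE) / max(1, n * (n - 1))
  el <- igraph::as_edgelist(g)
  ord <- order(-nb, ids)
  rank <- integer(n); rank[ord] <- seq_len(n)
  list(
    nodes = tibble::tibble(id = ids, bc = unname(nb), rank = rank),
    edges = tibble::tibble(source = el[, 1], target = el[, 2], bc = unname(eb))
  )
}

#' Local clustering coefficients
#'
#' Computed on the undirected simple support of the digraph (directions
#' discarded, double links collapsed): for each node, the fraction of
#' pairs of its neighbours that are themselves connected. Nodes with fewer
#' than two neighbours get 0. The global coefficient is the arithmetic
#' mean over all nodes.
#'
#' @param C A [connectome].
#' @return List with tibble `nodes` (`id`, `clustering`) and scalar `mean`.
#' @export
clustering_local <- function(C) {
  g <- as_igraph(C, "undirected")
  cc <- unname(igraph::transitivity(g, type = "local", isolates = "zero"))
  cc[is.nan(cc)] <- 0
  list(nodes = tibble::tibble(id = C$regions$id, clustering = cc),
       mean = mean(cc))
}

#' Eigenvalue spectrum of the co-occurrence matrix
#'
#' The directed adjacency matrix is non-symmetric, so the spectrum of
#' `A A^T` (symmetric, real, nonnegative) is used instead. For a binary
#' `A`, the eigenvalues sum to `M` (trace identity).
#'
#' @param C A [connectome].
#' @return Numeric vector of N eigenvalues, descending.
#' @export
cooccurrence_spectrum <- function(C) {
  AAt <- tcrossprod(C$A)
  ev <- eigen(AAt, symmetric = TRUE, only.values = TRUE)$values
  sort(ev, decreasing = TRUE)
}

#' Directed shortest-path statistics
#'
#' Average directed shortest path length over reachable ordered pairs and
#' the diameter (the largest of these path lengths). Unreachable pairs are
#' excluded rather than set to infinity, so the average stays finite on
#' non-strongly-connected graphs.
#'
#' @param C A [connectome].
#' @return Tibble with one row: `mean_path`, `diameter`,
#'   `reachable_pairs`.
#' @export
path_stats <- function(C) {
  g <- as_igraph(C, "directed")
  d <- igraph::distances(g, mode = "out")
  diag(d) <- NA
  d <- d[is.finite(d) & !is.na(d)]
  if (length(d) == 0) stop("no reachable ordered pairs")
  tibble::tibble(mean_path = mean(d), diameter = max(d),
                 reachable_pairs = length(d))
}

#' One-call summary of directed-graph statistics
#'
#' @param C A [connectome].
#' @return One-row tibble: `n_regions`, `M`, `density`, `M1`, `M2`,
#'   `loops`, `mean_clustering`, `mean_path`, `diameter`.
#' @export
graph_summary <- function(C) {
  rc <- reciprocity_counts(C)
  ps <- path_stats(C)
  tibble::tibble(
    n_regions = n_regions(C), M = rc$M, density = graph_density(C),
    M1 = rc$M1, M2 = rc$M2, loops = rc$loops,
    mean_clustering = clustering_local(C)$mean,
    mean_path = ps$mean_path, diameter = ps$diameter
  )
}

#' Summed degrees over a group of subregions
#'
#' Convenience for questions like "how many in/out links does a composite
#' structure collect across its constituent areas": sums the subregions'
#' in- and out-degrees and counts their distinct outside partners. Note
#' that summing double-counts projections shared by several subregions
#' and ignores links internal to the group for the partner count; this is
#' a reporting convenience, not a validated aggregate of the network.
#'
#' @param C A [connectome].
#' @param ids Character vector of member region ids.
#' @return One-row tibble: `n_members`, `k_in_sum`, `k_out_sum`,
#'   `n_partners` (distinct non-member regions linked in either
#'   direction).
#' @export
aggregate_degrees <- function(C, ids) {
  bad <- setdiff(ids, C$regions$id)
  if (length(bad)) stop("unknown regions: ", paste(bad, collapse = ", "))
  member <- C$regions$id %in% ids
  A <- C$A
  partners <- which(colSums(A[member, , drop = FALSE]) > 0 |
                      rowSums(A[, member, drop = FALSE]) > 0)
  tibble::tibble(
    n_members = sum(member),
    k_in_sum = sum(A[, member]),
    k_out_sum = sum(A[member, ]),
    n_partners = length(setdiff(C$regions$id[partners], ids))
  )
}
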