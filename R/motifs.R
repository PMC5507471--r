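#' Census of 3-node directed motifs
#'
#' Assigns every unordered node triple to one of the 16 isomorphism
#' classes of directed graphs on three nodes (including the empty triad),
#' using the standard triad taxonomy. Class labels follow the usual
#' MAN (mutual/asymmetric/null) naming:
#' `003, 012, 102, 021D, 021U, 021C, 111D, 111U, 030T, 030C, 201,
#' 120D, 120U, 120C, 210, 300`. Counts sum to `choose(N, 3)`.
#'
#' @param C A [connectome] with at least 3 regions.
#' @return Tibble with columns `motif` (ordered factor) and `count`.
#' @export
motif_census <- function(C) {
  if (n_regions(C) < 3) stop("motif census needs at least 3 regions")
  g <- as_igraph(C, "directed")
  counts <- igraph::triad_census(g)
  tibble::tibble(motif = factor(triad_classes(), levels = triad_classes()),
                 count = as.numeric(counts))
}

#' The 16 triad class labels, in igraph's census order
#' @return Character vector of length 16.
#' @export
triad_classes <- function() {
  c("003", "012", "102", "021D", "021U", "021C", "111D", "111U",
    "030T", "030C", "201", "120D", "120U", "120C", "210", "300")
}

#' Census of directed cliques by size
#'
#' A directed k-clique is a vertex subset carrying all `k (k - 1)`
#' directed links, i.e. a complete subgraph of the reciprocal
#' (mutual-link) undirected graph. All complete vertex subsets are
#' counted per size — not only maximal ones — so overlapping same-size
#' cliques each count.
#'
#' @param C A [connectome].
#' @param max_k Optional upper bound on clique size to enumerate
#'   (`Inf` = unbounded).
#' @return List with `counts_by_size` (tibble `size`, `count`; size 1 is
#'   N), `max_size`, and `max_cliques` (list of region-id vectors at
#'   `max_size`).
#' @export
clique_census <- function(C, max_k = Inf) {
  gr <- as_igraph(C, "reciprocal")
  up <- if (is.finite(max_k)) max_k else 0   # igraph: 0 means no limit
  cnt <- igraph::clique_size_counts(gr, min = 1, max = up)
  counts <- tibble::tibble(size = seq_along(cnt), count = cnt) |>
    dplyr::filter(.data$count > 0)
  max_size <- max(counts$size)
  mc <- igraph::cliques(gr, min = max_size, max = max_size)
  max_cliques <- unique(purrr::map(mc, \(v) sort(igraph::V(gr)$name[v])))
  list(counts_by_size = counts, max_size = max_size,
       max_cliques = max_cliques)
}

#' Directed edge support of a set of cliques
#'
#' For a collection of vertex subsets (typically the maximum cliques),
#' returns the union of their vertices and the number of directed edges
#' the union induces in the connectome.
#'
#' @param C A [connectome].
#' @param vertex_subsets List of character vectors of region ids.
#' @return List with `vertices` (sorted union) and `n_edges` (induced
#'   directed edge count).
#' @export
clique_edge_support <- function(C, vertex_subsets) {
  verts <- sort(unique(unlist(vertex_subsets)))
  bad <- setdiff(verts, C$regions$id)
  if (length(bad)) stop("unknown vertices: ", paste(bad, collapse = ", "))
  idx <- match(verts, C$regions$id)
  list(vertices = verts, n_edges = sum(C$A[idx, idx]))
}
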