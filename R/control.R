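#' Driver nodes via maximum matching
#'
#' Structural controllability of a directed network reduces to maximum
#' matching: a matching is a set of directed edges sharing no common
#' start vertices and no common end vertices; nodes that are not the end
#' (head) of any matched edge are unmatched and must be driven by
#' independent input signals. A maximum matching minimizes the number of
#' these driver nodes. The matching is computed on the bipartite
#' representation (one out-copy and one in-copy per node).
#'
#' The driver set is one realization of a possibly non-unique optimum;
#' only its size is contract-stable. A graph with a perfect matching has
#' zero drivers, reported as-is with `perfect_matching = TRUE`.
#'
#' @param C A [connectome].
#' @return An object of class `matching_result`: list with
#'   `matched_edges` (tibble `source`, `target`), `driver_nodes`
#'   (character), `n_drivers`, `perfect_matching`.
#' @export
find_driver_nodes <- function(C) {
  ids <- C$regions$id
  n <- length(ids)
  et <- edge_tibble(C)
  if (nrow(et) == 0) {
    return(structure(list(matched_edges = tibble::tibble(source = character(),
                                                         target = character()),
                          driver_nodes = ids, n_drivers = n,
                          perfect_matching = n == 0),
                     class = "matching_result"))
  }
  # bipartite graph: out-copies (type FALSE) vs in-copies (type TRUE)
  from <- match(et$source, ids)
  to <- match(et$target, ids) + n
  bg <- igraph::make_empty_graph(2 * n, directed = FALSE)
  bg <- igraph::add_edges(bg, rbind(from, to))
  igraph::V(bg)$type <- rep(c(FALSE, TRUE), each = n)
  mm <- igraph::max_bipartite_match(bg)
  mate <- mm$matching[seq_len(n)]            # out-copy i -> matched in-copy
  matched_from <- which(!is.na(mate))
  matched_to <- mate[matched_from] - n
  matched_heads <- unique(matched_to)
  drivers <- ids[!seq_len(n) %in% matched_heads]
  structure(
    list(matched_edges = tibble::tibble(source = ids[matched_from],
                                        target = ids[matched_to]),
         driver_nodes = drivers,
         n_drivers = length(drivers),
         perfect_matching = length(drivers) == 0),
    class = "matching_result"
  )
}

#' @export
print.matching_result <- function(x, ...) {
  cat("<matching_result>", nrow(x$matched_edges), "matched edges,",
      x$n_drivers, "driver node(s)\n")
  if (x$n_drivers > 0 && x$n_drivers <= 10) {
    cat("  drivers:", paste(x$driver_nodes, collapse = ", "), "\n")
  }
  if (x$perfect_matching) cat("  perfect matching (0 drivers)\n")
  invisible(x)
}

#' Degree-preserving rewiring (double-edge swaps)
#'
#' Repeatedly picks two directed edges (a -> b, c -> d) and swaps their
#' heads to (a -> d, c -> b), rejecting swaps that would create a
#' self-loop or a duplicate edge. Every node's in- and out-degree is
#' preserved exactly. Deterministic under `seed`. Chemical labels are
#' dropped (they are tied to specific projections); self-loops are kept
#' untouched.
#'
#' @param C A [connectome].
#' @param n_swaps Number of attempted swaps; at least 10 M (M = number of
#'   edges) is recommended for thorough mixing, 20 M is the usual default.
#' @param seed Integer seed.
#' @return A rewired [connectome]. If no swap could be performed, the
#'   input connectome (minus labels) is returned with a warning.
#' @export
rewire_preserving_degrees <- function(C, n_swaps = 20 * n_edges(C), seed = 1) {
  ids <- C$regions$id
  n <- length(ids)
  A <- C$A
  idx <- which(A == 1L, arr.ind = TRUE)
  m <- nrow(idx)
  if (m < 2) {
    warning("graph too small to swap; returning input")
    return(connectome(C$regions, A, self_loops = C$self_loops))
  }
  set.seed(seed)
  src <- idx[, 1]; tgt <- idx[, 2]
  accepted <- 0L
  pairs <- matrix(sample.int(m, 2 * n_swaps, replace = TRUE), ncol = 2)
  for (k in seq_len(n_swaps)) {
    e1 <- pairs[k, 1]; e2 <- pairs[k, 2]
    if (e1 == e2) next
    a <- src[e1]; b <- tgt[e1]; c_ <- src[e2]; d <- tgt[e2]
    if (a == d || c_ == b) next                      # would create loops
    if (A[a, d] == 1L || A[c_, b] == 1L) next        # would duplicate
    A[a, b] <- 0L; A[c_, d] <- 0L
    A[a, d] <- 1L; A[c_, b] <- 1L
    tgt[e1] <- d; tgt[e2] <- b
    accepted <- accepted + 1L
  }
  if (accepted == 0L) {
    warning("no degree-preserving swap possible; returning input unchanged")
  }
  connectome(C$regions, A, self_loops = C$self_loops)
}

#' Null distribution of the driver count under degree-preserving rewiring
#'
#' @param C A [connectome].
#' @param n_rep Number of randomized replicates (500 in a full analysis).
#' @param n_swaps Attempted swaps per replicate (default 20 M).
#' @param seed Master seed; each replicate gets its own derived stream.
#' @return Tibble with one row per replicate: `replicate`, `n_drivers`.
#' @export
driver_null_distribution <- function(C, n_rep = 500,
                                     n_swaps = 20 * n_edges(C), seed = 1) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_rep)
  purrr::map_dfr(seq_len(n_rep), function(r) {
    Cr <- rewire_preserving_degrees(C, n_swaps = n_swaps, seed = rep_seeds[r])
    tibble::tibble(replicate = r, n_drivers = find_driver_nodes(Cr)$n_drivers)
  })
}

#' Driver count while removing the longest connections
#'
#' Repeatedly removes the currently longest remaining edge (length =
#' Euclidean distance between the endpoints' centres; ties broken by
#' lexicographically smallest (source, target)), recording the graph
#' density and the driver-node count every `step` removals, down to the
#' edgeless graph.
#'
#' @param C A [connectome].
#' @param D Distance matrix from [euclidean_distances()], covering all
#'   edges.
#' @param step Record every `step` removals (the intact network and the
#'   final edgeless state are always recorded).
#' @return Tibble with columns `n_removed`, `density`, `n_drivers`.
#' @export
edge_removal_curve <- function(C, D, step = 1) {
  ids <- C$regions$id
  if (!all(ids %in% rownames(D))) stop("distance matrix missing regions")
  et <- edge_tibble(C)[, c("source", "target")]
  et$length <- D[cbind(et$source, et$target)]
  if (anyNA(et$length)) stop("missing distances for some edges")
  ord <- order(-et$length, et$source, et$target)
  et <- et[ord, ]
  n <- length(ids)
  m <- nrow(et)
  record_at <- unique(c(0L, seq_len(m)[seq_len(m) %% step == 0], m))
  A <- C$A
  out <- vector("list", length(record_at))
  j <- 1L
  for (r in record_at) {
    if (r > 0) {
      rng <- (max(record_at[record_at < r]) + 1L):r
      A[cbind(match(et$source[rng], ids), match(et$target[rng], ids))] <- 0L
    }
    Cr <- connectome(C$regions, A)
    out[[j]] <- tibble::tibble(n_removed = r,
                               density = sum(A) / (n * (n - 1)),
                               n_drivers = find_driver_nodes(Cr)$n_drivers)
    j <- j + 1L
  }
  dplyr::bind_rows(out)
}

#' Plot a driver-count versus density removal curve
#'
#' @param curve Tibble from [edge_removal_curve()], optionally with a
#'   `group` column to overlay several curves (e.g. data versus null).
#' @return A ggplot object.
#' @export
plot_removal_curve <- function(curve) {
  aes <- if ("group" %in% names(curve)) {
    ggplot2::aes(.data$density, .data$n_drivers, colour = .data$group)
  } else {
    ggplot2::aes(.data$density, .data$n_drivers)
  }
  ggplot2::ggplot(curve, aes) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "graph density (longest edges removed first)",
                  y = "number of driver nodes") +
    ggplot2::theme_minimal()
}
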