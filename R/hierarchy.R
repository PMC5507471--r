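#' Girvan-Newman onion dendrogram with SCC tracking
#'
#' Iteratively recomputes the directed edge betweenness, deletes the
#' single highest-betweenness edge (ties broken by lexicographically
#' smallest (source, target) pair, for reproducibility), and records the
#' strongly connected components after each deletion, until no edges
#' remain. Because edge deletion can only refine the SCC partition, the
#' split events are strictly nested and form a dendrogram. In dense
#' brain networks the splits typically peel single areas off a persisting
#' big component — an onion rather than a balanced community hierarchy.
#'
#' A node's depth is the number of split events of its own component that
#' it survived (i.e. after which it still sat in a component of at least
#' two nodes) before becoming isolated.
#'
#' @param C A [connectome].
#' @return An object of class `gn_dendrogram`: list with `deletions`
#'   (tibble `step`, `source`, `target`, `bc`, `n_components`), `splits`
#'   (list of events with `step`, `parent`, `children` vertex sets),
#'   `depth` (tibble `id`, `depth`), and `initial_components`.
#' @export
girvan_newman <- function(C) {
  g <- as_igraph(C, "directed")
  ids <- C$regions$id
  n <- length(ids)
  comp_sets <- function(g) {
    m <- igraph::components(g, mode = "strong")$membership
    unname(split(names(m), m))
  }
  current <- comp_sets(g)
  initial <- current
  splits <- list()
  depth <- stats::setNames(integer(n), ids)
  del <- vector("list", igraph::ecount(g))
  step <- 0L
  while (igraph::ecount(g) > 0) {
    step <- step + 1L
    eb <- igraph::edge_betweenness(g, directed = TRUE)
    el <- igraph::as_edgelist(g)
    pick <- order(-eb, el[, 1], el[, 2])[1]
    del[[step]] <- tibble::tibble(step = step, source = el[pick, 1],
                                  target = el[pick, 2], bc = eb[pick])
    g <- igraph::delete_edges(g, pick)
    newc <- comp_sets(g)
    if (length(newc) > length(current)) {
      # map each old component to the new components its vertices fall in
      idx <- stats::setNames(rep(seq_along(newc), lengths(newc)),
                             unlist(newc))
      for (old in current) {
        kids <- unique(idx[old])
        if (length(kids) > 1) {
          children <- newc[kids]
          splits[[length(splits) + 1]] <-
            list(step = step, parent = sort(old),
                 children = lapply(children, sort))
          for (ch in children) {
            if (length(ch) >= 2) depth[ch] <- depth[ch] + 1L
          }
        }
      }
    }
    del[[step]]$n_components <- length(newc)
    current <- newc
  }
  structure(
    list(deletions = dplyr::bind_rows(del), splits = splits,
         depth = tibble::tibble(id = ids, depth = unname(depth[ids])),
         initial_components = initial),
    class = "gn_dendrogram"
  )
}

#' @export
print.gn_dendrogram <- function(x, ...) {
  cat("<gn_dendrogram>", nrow(x$deletions), "edge deletions,",
      length(x$splits), "split events, max depth",
      max(x$depth$depth), "\n")
  invisible(x)
}

#' Onion profile: dendrogram depth versus core membership
#'
#' Joins the Girvan-Newman depth of every node with its posterior core
#' probability and reports their Spearman rank correlation. In an
#' onion-organized network, core nodes concentrate towards the inside
#' (greater depth), so the association is positive. When either variable
#' is constant the association is undefined and reported as 0 with
#' `degenerate = TRUE`.
#'
#' @param d A `gn_dendrogram`.
#' @param fit A `core_periphery_fit` on the same node set.
#' @return List with `nodes` (tibble `id`, `depth`, `gamma_core`, `core`),
#'   `association` (Spearman rho), `degenerate`.
#' @export
onion_profile <- function(d, fit) {
  nodes <- dplyr::inner_join(d$depth, fit$membership, by = "id")
  if (nrow(nodes) != nrow(d$depth) || nrow(nodes) != nrow(fit$membership)) {
    stop("dendrogram and fit cover different node sets")
  }
  degenerate <- stats::sd(nodes$depth) == 0 || stats::sd(nodes$gamma_core) == 0
  rho <- if (degenerate) 0 else
    stats::cor(nodes$depth, nodes$gamma_core, method = "spearman")
  list(nodes = nodes, association = rho, degenerate = degenerate)
}

#' Export a Girvan-Newman dendrogram as Newick
#'
#' Internal nodes are annotated with the deletion step at which the
#' component split; leaves are region ids. Multiple initial strongly
#' connected components are joined under an artificial root (step 0).
#'
#' @param d A `gn_dendrogram`.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @return Newick string (invisibly when written to `path`).
#' @export
gn_newick <- function(d, path = NULL) {
  key <- function(set) paste(sort(set), collapse = "\r")
  split_at <- new.env(parent = emptyenv())
  for (s in d$splits) assign(key(s$parent), s, envir = split_at)
  build <- function(set) {
    if (length(set) == 1) return(gsub("[ (),:;]", "_", set))
    s <- get0(key(set), envir = split_at)
    if (is.null(s)) {
      # component never split (can only be edge deletions inside it)
      return(paste0("(", paste(vapply(set, build, ""), collapse = ","), ")"))
    }
    kids <- vapply(s$children, build, "")
    paste0("(", paste(kids, collapse = ","), ")s", s$step)
  }
  roots <- d$initial_components
  nwk <- if (length(roots) == 1) {
    paste0(build(roots[[1]]), ";")
  } else {
    paste0("(", paste(vapply(roots, build, ""), collapse = ","), ")s0;")
  }
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Recursive coarsening of a connectome to its macro-region quotient
#'
#' Edges of the undirected support get binary weights — 0 for
#' intraregional (same macro-region label) and 1 for interregional — so
#' that a minimum-weight spanning tree prefers intraregional edges. Every
#' tree edge is rated by the conductance of the fundamental cut it
#' induces (cut edges over the smaller side's volume); intraregional tree
#' edges are then contracted in decreasing rating order (a high-conductance
#' cut is a poor separator, so such edges are merged first) until each
#' macro-region has collapsed to a single node. The quotient network has
#' a directed edge r -> s iff any member edge i -> j existed with
#' label(i) = r != s = label(j); intraregional links collapse away and are
#' recorded as quotient self-loops with counts in the plan.
#'
#' @param C A [connectome].
#' @param region_labels Named character vector mapping region id to
#'   macro-region; default taken from the `macro_region` column.
#' @return The quotient [connectome]; attribute `"plan"` carries the
#'   spanning tree, per-tree-edge conductance ratings, contraction order
#'   and intraregional link counts.
#' @export
coarsen <- function(C, region_labels = NULL) {
  ids <- C$regions$id
  if (is.null(region_labels)) {
    if (!"macro_region" %in% names(C$regions)) {
      stop("no `region_labels` given and no `macro_region` column present")
    }
    region_labels <- stats::setNames(C$regions$macro_region, ids)
  }
  if (!all(ids %in% names(region_labels))) {
    stop("every region needs a label")
  }
  lab <- region_labels[ids]

  g <- as_igraph(C, "undirected")
  el <- igraph::as_edgelist(g)
  w <- as.integer(lab[el[, 1]] != lab[el[, 2]])
  igraph::E(g)$weight <- w
  tree <- igraph::mst(g, weights = w)

  # conductance of the fundamental cut of each tree edge (on the support)
  deg <- igraph::degree(g)
  tel <- igraph::as_edgelist(tree)
  rating <- vapply(seq_len(nrow(tel)), function(k) {
    t2 <- igraph::delete_edges(tree, k)
    m <- igraph::components(t2)$membership
    side <- names(m)[m == m[tel[k, 1]]]
    cross <- sum(xor(el[, 1] %in% side, el[, 2] %in% side))
    vols <- c(sum(deg[side]), sum(deg) - sum(deg[side]))
    cross / max(1, min(vols))
  }, numeric(1))
  plan_edges <- tibble::tibble(
    u = tel[, 1], v = tel[, 2],
    intra = lab[tel[, 1]] == lab[tel[, 2]],
    conductance = rating
  )

  # contract intraregional tree edges, highest conductance first
  contraction <- dplyr::arrange(dplyr::filter(plan_edges, .data$intra),
                                dplyr::desc(.data$conductance))
  group <- stats::setNames(ids, ids)     # union-find over region ids
  find <- function(x) { while (group[[x]] != x) x <- group[[x]]; x }
  for (k in seq_len(nrow(contraction))) {
    ru <- find(contraction$u[k]); rv <- find(contraction$v[k])
    if (lab[ru] != lab[rv]) {
      stop("contraction forced across different labels: ", ru, " / ", rv)
    }
    if (ru != rv) group[[rv]] <- ru
  }
  roots <- vapply(ids, find, "")
  per_label <- tapply(roots, lab, function(x) length(unique(x)))
  if (any(per_label > 1)) {
    stop("labels inconsistent with connectivity: macro-region(s) ",
         paste(names(per_label)[per_label > 1], collapse = ", "),
         " did not contract to a single node")
  }

  labels_ord <- unique(unname(lab))
  nq <- length(labels_ord)
  Aq <- matrix(0L, nq, nq, dimnames = list(labels_ord, labels_ord))
  et <- edge_tibble(C)
  ls <- unname(lab[et$source]); lt <- unname(lab[et$target])
  inter <- ls != lt
  Aq[cbind(match(ls[inter], labels_ord), match(lt[inter], labels_ord))] <- 1L
  intra_counts <- table(factor(ls[!inter], levels = labels_ord)) +
    table(factor(unname(lab[C$self_loops]), levels = labels_ord))
  quotient <- connectome(
    tibble::tibble(id = labels_ord, name = labels_ord,
                   macro_region = labels_ord),
    Aq,
    self_loops = labels_ord[intra_counts > 0]
  )
  attr(quotient, "plan") <- list(
    tree_edges = plan_edges,
    contraction_order = contraction,
    intra_counts = tibble::tibble(macro_region = labels_ord,
                                  n_internal_links = as.integer(intra_counts))
  )
  quotient
}
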