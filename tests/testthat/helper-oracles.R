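# Independent brute-force oracles and fixture builders used across the suite.
# These deliberately avoid the package's own code paths (and igraph) for the
# quantities they check.

# random directed binary graph as a connectome, optional loops/labels
random_connectome <- function(n, p = 0.3, seed = 1, loops = 0, labels = FALSE) {
  set.seed(seed)
  ids <- sprintf("v%02d", seq_len(n))
  A <- matrix(as.integer(stats::runif(n * n) < p), n, n)
  diag(A) <- 0L
  dimnames(A) <- list(ids, ids)
  self_loops <- if (loops > 0) sample(ids, loops) else character()
  chemical <- NULL
  if (labels && sum(A) > 0) {
    idx <- which(A == 1L, arr.ind = TRUE)
    pick <- sample(nrow(idx), max(1, round(0.25 * nrow(idx))))
    chemical <- tibble::tibble(
      source = ids[idx[pick, 1]], target = ids[idx[pick, 2]],
      label = sample(default_chemical_vocabulary(), length(pick),
                     replace = TRUE))
  }
  connectome(tibble::tibble(id = ids, name = ids, macro_region = "x"),
             A, self_loops = self_loops, chemical = chemical)
}

# all shortest directed paths between an ordered pair, by exhaustive DFS
# returns list of vertex index paths (including endpoints)
all_geodesics <- function(A, s, t) {
  n <- nrow(A)
  # BFS distances from s
  dist <- rep(Inf, n); dist[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      for (v in which(A[u, ] == 1L)) {
        if (dist[v] > dist[u] + 1) { dist[v] <- dist[u] + 1; nxt <- c(nxt, v) }
      }
    }
    frontier <- unique(nxt)
  }
  if (!is.finite(dist[t])) return(list())
  paths <- list()
  walk <- function(path) {
    u <- path[length(path)]
    if (u == t) { paths[[length(paths) + 1]] <<- path; return() }
    for (v in which(A[u, ] == 1L)) {
      if (dist[v] == dist[u] + 1 && dist[v] <= dist[t]) walk(c(path, v))
    }
  }
  walk(s)
  paths[vapply(paths, length, 1L) == dist[t] + 1]
}

# brute-force node and edge betweenness (unnormalized sums of
# sigma_st(.)/sigma_st over ordered pairs)
brute_betweenness <- function(A) {
  n <- nrow(A)
  node <- numeric(n)
  edge <- matrix(0, n, n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    paths <- all_geodesics(A, s, t)
    np <- length(paths)
    if (np == 0) next
    for (p in paths) {
      if (length(p) > 2) {
        interior <- p[-c(1, length(p))]
        node[interior] <- node[interior] + 1 / np
      }
      for (k in seq_len(length(p) - 1)) {
        edge[p[k], p[k + 1]] <- edge[p[k], p[k + 1]] + 1 / np
      }
    }
  }
  list(node = node, edge = edge)
}

# canonical code of a 3-node directed subgraph under vertex permutations
triad_canonical <- function(sub) {
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  codes <- vapply(perms, function(pm) {
    m <- sub[pm, pm]
    sum(c(m[1,2], m[1,3], m[2,1], m[2,3], m[3,1], m[3,2]) * 2^(0:5))
  }, numeric(1))
  min(codes)
}

# archetype adjacency of each of the 16 triad classes (A=1, B=2, C=3)
triad_archetypes <- function() {
  e <- function(...) {
    m <- matrix(0L, 3, 3)
    for (p in list(...)) m[p[1], p[2]] <- 1L
    m
  }
  list(
    `003`  = e(),
    `012`  = e(c(1,2)),
    `102`  = e(c(1,2), c(2,1)),
    `021D` = e(c(2,1), c(2,3)),
    `021U` = e(c(1,2), c(3,2)),
    `021C` = e(c(1,2), c(2,3)),
    `111D` = e(c(1,2), c(2,1), c(3,1)),
    `111U` = e(c(1,2), c(2,1), c(1,3)),
    `030T` = e(c(1,2), c(3,2), c(1,3)),
    `030C` = e(c(2,1), c(3,2), c(1,3)),
    `201`  = e(c(1,2), c(2,1), c(2,3), c(3,2)),
    `120D` = e(c(2,1), c(2,3), c(1,3), c(3,1)),
    `120U` = e(c(1,2), c(3,2), c(1,3), c(3,1)),
    `120C` = e(c(1,2), c(2,3), c(1,3), c(3,1)),
    `210`  = e(c(1,2), c(2,3), c(3,2), c(1,3), c(3,1)),
    `300`  = e(c(1,2), c(2,1), c(2,3), c(3,2), c(1,3), c(3,1))
  )
}

# brute-force triad census: classify every unordered triple
brute_motif_census <- function(A) {
  arch <- triad_archetypes()
  code2class <- stats::setNames(names(arch),
                                vapply(arch, triad_canonical, numeric(1)))
  counts <- stats::setNames(numeric(16), names(arch))
  n <- nrow(A)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    idx <- c(i, j, k)
    cls <- code2class[[as.character(triad_canonical(A[idx, idx]))]]
    counts[cls] <- counts[cls] + 1
  }
  counts
}

# exhaustive clique census on the reciprocal graph (all complete subsets)
brute_clique_census <- function(A) {
  R <- (A == 1L) & (t(A) == 1L)
  n <- nrow(A)
  counts <- numeric(n)
  for (mask in 1:(2^n - 1)) {
    v <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    k <- length(v)
    ok <- k == 1 || all(R[v, v][upper.tri(matrix(0, k, k))])
    if (ok) counts[k] <- counts[k] + 1
  }
  counts
}

# brute-force maximum matching size by recursion over the edge list
brute_max_matching <- function(A) {
  idx <- which(A == 1L, arr.ind = TRUE)
  m <- nrow(idx)
  best <- 0
  rec <- function(k, used_tail, used_head, size) {
    if (size + (m - k + 1) <= best) return()   # bound
    if (k > m) { best <<- max(best, size); return() }
    s <- idx[k, 1]; t <- idx[k, 2]
    if (!used_tail[s] && !used_head[t]) {
      ut <- used_tail; uh <- used_head; ut[s] <- TRUE; uh[t] <- TRUE
      rec(k + 1, ut, uh, size + 1)
    }
    rec(k + 1, used_tail, used_head, size)
  }
  if (m > 0) rec(1, rep(FALSE, nrow(A)), rep(FALSE, nrow(A)), 0)
  best
}

# reachability-closure SCC partition (no igraph)
brute_scc <- function(A) {
  n <- nrow(A)
  Rch <- diag(n) > 0
  B <- A == 1L
  repeat {
    new <- Rch | (Rch %*% B > 0)
    if (identical(new, Rch)) break
    Rch <- new
  }
  comp <- integer(n)
  cid <- 0
  for (i in seq_len(n)) {
    if (comp[i] == 0) {
      cid <- cid + 1
      comp[Rch[i, ] & Rch[, i]] <- cid
    }
  }
  comp
}

# from-scratch Girvan-Newman deletion/split sequence using the brute
# betweenness and SCC oracles
brute_girvan_newman <- function(A, ids = rownames(A)) {
  deletions <- list()
  split_steps <- integer(0)
  ncomp_prev <- max(brute_scc(A))
  step <- 0
  while (sum(A) > 0) {
    step <- step + 1
    eb <- brute_betweenness(A)$edge
    eb[A == 0L] <- -Inf
    cand <- which(eb == max(eb), arr.ind = TRUE)
    ord <- order(ids[cand[, 1]], ids[cand[, 2]])
    pick <- cand[ord[1], , drop = FALSE]
    deletions[[step]] <- c(ids[pick[1]], ids[pick[2]])
    A[pick] <- 0L
    ncomp <- max(brute_scc(A))
    if (ncomp > ncomp_prev) split_steps <- c(split_steps, step)
    ncomp_prev <- ncomp
  }
  list(deletions = do.call(rbind, deletions), split_steps = split_steps)
}
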