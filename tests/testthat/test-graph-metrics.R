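test_that("density follows M / N(N-1) and handles the complete digraph", {
  n <- 6
  A <- matrix(1L, n, n); diag(A) <- 0L
  C <- connectome(tibble::tibble(id = letters[1:n]), A)
  expect_equal(graph_density(C), 1)
  expect_error(graph_density(connectome(tibble::tibble(id = "a"))), "2 regions")
})

test_that("reciprocity counts match pair-by-pair classification", {
  two <- tibble::tibble(id = c("a", "b"))
  both <- connectome(two, matrix(c(0L, 1L, 1L, 0L), 2))
  expect_equal(reciprocity_counts(both)$M2, 1L)
  expect_equal(reciprocity_counts(both)$M1, 0L)
  one <- connectome(two, matrix(c(0L, 0L, 1L, 0L), 2))
  expect_equal(reciprocity_counts(one)$M1, 1L)
  expect_equal(reciprocity_counts(one)$M2, 0L)

  C <- random_connectome(30, p = 0.25, seed = 7, loops = 4)
  rc <- reciprocity_counts(C)
  # brute force over unordered pairs
  m1 <- 0; m2 <- 0
  for (i in 1:29) for (j in (i + 1):30) {
    s <- C$A[i, j] + C$A[j, i]
    if (s == 1) m1 <- m1 + 1
    if (s == 2) m2 <- m2 + 1
  }
  expect_equal(rc$M1, m1)
  expect_equal(rc$M2, m2)
  expect_equal(rc$loops, 4L)
  expect_equal(rc$M, rc$M1 + 2L * rc$M2)
})

test_that("degree table equals row/column sums with deterministic ranks", {
  # out-star on 6 nodes
  A <- matrix(0L, 6, 6); A[1, 2:6] <- 1L
  C <- connectome(tibble::tibble(id = letters[1:6]), A)
  dt <- degree_table(C)
  expect_equal(dt$k_out, c(5L, rep(0L, 5)))
  expect_equal(dt$rank_out, c(1L, 2:6))       # ties broken by id ascending

  C2 <- random_connectome(15, p = 0.3, seed = 2)
  dt2 <- degree_table(C2)
  expect_equal(dt2$k_in, unname(colSums(C2$A)))
  expect_equal(dt2$k_out, unname(rowSums(C2$A)))
  expect_equal(dt2$k_total, dt2$k_in + dt2$k_out)
  expect_equal(sum(dt2$k_in), sum(dt2$k_out))
  expect_equal(sum(dt2$k_in), n_edges(C2))
})

test_that("betweenness matches exhaustive geodesic enumeration", {
  # directed path a -> b -> c
  A <- matrix(0L, 3, 3); A[1, 2] <- 1L; A[2, 3] <- 1L
  C <- connectome(tibble::tibble(id = c("a", "b", "c")), A)
  bt <- betweenness_table(C)
  expect_gt(bt$nodes$bc[2], 0)
  expect_equal(bt$nodes$bc[c(1, 3)], c(0, 0))

  # complete digraph: all geodesics are single edges
  A4 <- matrix(1L, 4, 4); diag(A4) <- 0L
  C4 <- connectome(tibble::tibble(id = letters[1:4]), A4)
  expect_true(all(betweenness_table(C4)$nodes$bc == 0))

  for (seed in 1:4) {
    C8 <- random_connectome(8, p = 0.3, seed = seed)
    bt8 <- betweenness_table(C8)
    oracle <- brute_betweenness(C8$A)
    expect_equal(bt8$nodes$bc, oracle$node / (7 * 6), tolerance = 1e-10)
    eb <- oracle$edge / (8 * 7)
    got <- stats::setNames(bt8$edges$bc,
                           paste(bt8$edges$source, bt8$edges$target))
    idx <- which(C8$A == 1L, arr.ind = TRUE)
    want <- stats::setNames(eb[idx],
                            paste(rownames(C8$A)[idx[, 1]],
                                  colnames(C8$A)[idx[, 2]]))
    expect_equal(got[names(want)], want, tolerance = 1e-10)
  }
})

test_that("clustering is computed on the undirected support", {
  # bidirectional triangle
  A <- matrix(1L, 3, 3); diag(A) <- 0L
  C <- connectome(tibble::tibble(id = letters[1:3]), A)
  expect_equal(clustering_local(C)$nodes$clustering, rep(1, 3))

  # star: no neighbour pairs connected
  A2 <- matrix(0L, 5, 5); A2[1, 2:5] <- 1L
  C2 <- connectome(tibble::tibble(id = letters[1:5]), A2)
  expect_equal(clustering_local(C2)$mean, 0)

  C3 <- random_connectome(12, p = 0.3, seed = 9)
  U <- (C3$A | t(C3$A)) * 1L
  want <- vapply(1:12, function(i) {
    nb <- which(U[i, ] == 1L)
    if (length(nb) < 2) return(0)
    pairs <- utils::combn(nb, 2)
    mean(U[cbind(pairs[1, ], pairs[2, ])])
  }, numeric(1))
  expect_equal(clustering_local(C3)$nodes$clustering, want, tolerance = 1e-12)
})

test_that("co-occurrence spectrum is real, nonnegative, and sums to M", {
  Ce <- connectome(tibble::tibble(id = letters[1:4]))
  expect_equal(cooccurrence_spectrum(Ce), rep(0, 4))

  # directed 3-cycle: A A^T is the identity
  A <- matrix(0L, 3, 3); A[1, 2] <- A[2, 3] <- A[3, 1] <- 1L
  C3 <- connectome(tibble::tibble(id = letters[1:3]), A)
  expect_equal(cooccurrence_spectrum(C3), rep(1, 3))

  for (seed in 1:5) {
    C <- random_connectome(20, p = 0.3, seed = seed)
    ev <- cooccurrence_spectrum(C)
    expect_true(all(ev >= -1e-9))
    expect_equal(sum(ev), n_edges(C), tolerance = 1e-9)
    expect_false(is.unsorted(rev(ev)))
  }
})

test_that("path statistics exclude unreachable pairs", {
  # directed path on 5 nodes: diameter 4
  A <- matrix(0L, 5, 5); A[cbind(1:4, 2:5)] <- 1L
  C <- connectome(tibble::tibble(id = letters[1:5]), A)
  ps <- path_stats(C)
  expect_equal(ps$diameter, 4)
  expect_equal(ps$reachable_pairs, 10)          # forward pairs only

  A4 <- matrix(1L, 4, 4); diag(A4) <- 0L
  C4 <- connectome(tibble::tibble(id = letters[1:4]), A4)
  expect_equal(path_stats(C4)$mean_path, 1)
  expect_equal(path_stats(C4)$diameter, 1)

  C10 <- random_connectome(10, p = 0.25, seed = 3)
  ps10 <- path_stats(C10)
  # BFS oracle
  d <- matrix(Inf, 10, 10)
  for (s in 1:10) for (t in 1:10) {
    if (s != t) {
      paths <- all_geodesics(C10$A, s, t)
      if (length(paths)) d[s, t] <- length(paths[[1]]) - 1
    }
  }
  fin <- d[is.finite(d)]
  expect_equal(ps10$mean_path, mean(fin))
  expect_equal(ps10$diameter, max(fin))

  expect_error(path_stats(connectome(tibble::tibble(id = c("a", "b")))),
               "reachable")
})

test_that("aggregate degrees sum subregion links and count outside partners", {
  C <- random_connectome(12, p = 0.3, seed = 31)
  ids <- C$regions$id[1:3]
  agg <- aggregate_degrees(C, ids)
  member <- C$regions$id %in% ids
  expect_equal(agg$k_in_sum, sum(degree_table(C)$k_in[member]))
  expect_equal(agg$k_out_sum, sum(degree_table(C)$k_out[member]))
  et <- edge_tibble(C)
  touching <- union(et$target[et$source %in% ids], et$source[et$target %in% ids])
  expect_equal(agg$n_partners, length(setdiff(touching, ids)))
  expect_error(aggregate_degrees(C, "zz"), "zz")
})
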