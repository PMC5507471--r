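test_that("driver sets on canonical graphs", {
  # directed path: a single driver (the source)
  n <- 6
  A <- matrix(0L, n, n); A[cbind(1:(n - 1), 2:n)] <- 1L
  C <- connectome(tibble::tibble(id = letters[1:n]), A)
  mr <- find_driver_nodes(C)
  expect_equal(mr$n_drivers, 1)
  expect_equal(mr$driver_nodes, "a")

  # edgeless graph: every node is a driver
  Ce <- connectome(tibble::tibble(id = letters[1:5]))
  expect_equal(find_driver_nodes(Ce)$n_drivers, 5)

  # directed cycle: perfect matching, zero drivers, flagged
  Ac <- matrix(0L, 4, 4); Ac[cbind(1:4, c(2, 3, 4, 1))] <- 1L
  Cc <- connectome(tibble::tibble(id = letters[1:4]), Ac)
  mrc <- find_driver_nodes(Cc)
  expect_equal(mrc$n_drivers, 0)
  expect_true(mrc$perfect_matching)
})

test_that("matching size equals brute-force search and the driver identity holds", {
  for (seed in 1:6) {
    C <- random_connectome(7, p = 0.25, seed = seed)
    mr <- find_driver_nodes(C)
    best <- brute_max_matching(C$A)
    expect_equal(nrow(mr$matched_edges), best)
    expect_equal(mr$n_drivers, 7 - best)
    # matching validity: no shared tails or heads
    expect_false(any(duplicated(mr$matched_edges$source)))
    expect_false(any(duplicated(mr$matched_edges$target)))
    # every matched edge is a real edge
    expect_true(all(C$A[cbind(mr$matched_edges$source,
                              mr$matched_edges$target)] == 1L))
    # drivers are exactly the nodes that head no matched edge
    expect_setequal(mr$driver_nodes,
                    setdiff(C$regions$id, mr$matched_edges$target))
  }
})

test_that("rewiring preserves in/out degrees, edge count and simplicity", {
  C <- random_connectome(25, p = 0.2, seed = 2, loops = 3)
  Cr <- rewire_preserving_degrees(C, n_swaps = 20 * n_edges(C), seed = 5)
  expect_equal(rowSums(Cr$A), rowSums(C$A))
  expect_equal(colSums(Cr$A), colSums(C$A))
  expect_equal(n_edges(Cr), n_edges(C))
  expect_true(all(diag(Cr$A) == 0L))
  expect_true(all(Cr$A %in% c(0L, 1L)))
  expect_setequal(Cr$self_loops, C$self_loops)
  # it actually mixed
  expect_gt(sum(Cr$A != C$A), 0)
  # determinism under seed
  Cr2 <- rewire_preserving_degrees(C, n_swaps = 20 * n_edges(C), seed = 5)
  expect_identical(Cr2$A, Cr$A)

  # directed 3-cycle admits no valid swap
  Ac <- matrix(0L, 3, 3); Ac[cbind(1:3, c(2, 3, 1))] <- 1L
  Cc <- connectome(tibble::tibble(id = letters[1:3]), Ac)
  expect_warning(Cs <- rewire_preserving_degrees(Cc, n_swaps = 200, seed = 1),
                 "no degree-preserving swap")
  expect_identical(Cs$A, Cc$A)
})

test_that("edge removal curve matches a sort-and-truncate oracle", {
  set.seed(8)
  geo <- generate_geometry(12, seed = 8)
  C <- sample_edr_network(geo$D, edr_spec(0.4, 40, seed = 9))
  curve <- edge_removal_curve(C, geo$D, step = 5)
  # final point: edgeless graph
  last <- curve[nrow(curve), ]
  expect_equal(last$density, 0)
  expect_equal(last$n_drivers, 12)
  # oracle: sort edges by length descending and recount after truncation
  et <- edge_tibble(C)
  et$len <- geo$D[cbind(et$source, et$target)]
  et <- et[order(-et$len, et$source, et$target), ]
  for (r in curve$n_removed) {
    keep <- et[-seq_len(r), , drop = FALSE]
    if (r == 0) keep <- et
    A <- matrix(0L, 12, 12, dimnames = dimnames(C$A))
    A[cbind(keep$source, keep$target)] <- 1L
    Ck <- connectome(C$regions, A)
    row <- curve[curve$n_removed == r, ]
    expect_equal(row$density, sum(A) / (12 * 11))
    expect_equal(row$n_drivers, find_driver_nodes(Ck)$n_drivers)
  }
  # driver count at reduced density is at least the intact count
  intact <- curve$n_drivers[curve$n_removed == 0]
  expect_true(all(curve$n_drivers[curve$density < curve$density[1]] >= intact))
})

test_that("equal distances fall back to deterministic lexicographic removal", {
  n <- 6
  reg <- tibble::tibble(id = letters[1:n], x = 0, y = 0, z = 0)
  # distances all equal (coincident points are disallowed by the EDR
  # sampler but fine here: build D manually)
  D <- matrix(1, n, n, dimnames = list(reg$id, reg$id)); diag(D) <- 0
  C <- random_connectome(n, p = 0.5, seed = 10)
  dimnames(D) <- dimnames(C$A)
  c1 <- edge_removal_curve(C, D, step = 2)
  c2 <- edge_removal_curve(C, D, step = 2)
  expect_identical(c1, c2)
})

test_that("the degree-preserving null distribution is reproducible", {
  C <- random_connectome(15, p = 0.25, seed = 3)
  null1 <- driver_null_distribution(C, n_rep = 5, n_swaps = 200, seed = 4)
  null2 <- driver_null_distribution(C, n_rep = 5, n_swaps = 200, seed = 4)
  expect_identical(null1, null2)
  expect_true(all(null1$n_drivers >= 1 | null1$n_drivers == 0))
})
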