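test_that("the first split severs the bridge between two dense blocks", {
  # two reciprocal K4s joined by one bidirectional bridge
  A <- matrix(0L, 8, 8)
  A[1:4, 1:4] <- 1L; A[5:8, 5:8] <- 1L; diag(A) <- 0L
  A[4, 5] <- A[5, 4] <- 1L
  C <- connectome(tibble::tibble(id = letters[1:8]), A)
  d <- girvan_newman(C)
  first <- d$splits[[1]]
  expect_setequal(purrr::map_int(first$children, length), c(4L, 4L))
  # the deletion causing it is one bridge direction
  del <- d$deletions[first$step, ]
  expect_true(paste(del$source, del$target) %in% c("d e", "e d"))
})

test_that("deletion count equals M and components never merge", {
  C <- random_connectome(10, p = 0.25, seed = 12)
  d <- girvan_newman(C)
  expect_equal(nrow(d$deletions), n_edges(C))
  expect_false(is.unsorted(d$deletions$n_components))
  expect_equal(d$deletions$n_components[nrow(d$deletions)], 10)

  # edgeless graph: empty log, N singletons at step 0
  Ce <- connectome(tibble::tibble(id = letters[1:5]))
  de <- girvan_newman(Ce)
  expect_equal(nrow(de$deletions), 0)
  expect_length(de$initial_components, 5)
})

test_that("split sequence equals a from-scratch reimplementation", {
  for (seed in c(3, 5)) {
    C <- random_connectome(8, p = 0.25, seed = seed)
    d <- girvan_newman(C)
    oracle <- brute_girvan_newman(C$A)
    got <- as.matrix(d$deletions[, c("source", "target")])
    dimnames(got) <- NULL
    dimnames(oracle$deletions) <- NULL
    expect_equal(got, oracle$deletions)
    expect_equal(purrr::map_int(d$splits, "step"), oracle$split_steps)
  }
})

test_that("dendrogram depth is invariant under node relabelling", {
  C <- random_connectome(9, p = 0.3, seed = 21)
  d1 <- girvan_newman(C)
  # permuted copy: same graph, ids renamed in a way that preserves
  # lexicographic order (so tie-breaking is isomorphic)
  ids <- C$regions$id
  new_ids <- stats::setNames(sprintf("w%02d", seq_along(ids)), ids)
  A2 <- C$A
  dimnames(A2) <- list(unname(new_ids[rownames(C$A)]),
                       unname(new_ids[colnames(C$A)]))
  C2 <- connectome(tibble::tibble(id = unname(new_ids)), A2)
  d2 <- girvan_newman(C2)
  expect_equal(d2$depth$depth,
               d1$depth$depth[match(names(new_ids), d1$depth$id)])
})

test_that("onion profile links depth and core membership", {
  # planted ideal core-periphery graphs: core nodes sit deeper
  assoc <- numeric(5)
  for (s in 1:5) {
    gen <- generate_planted_core_periphery(N = 24, K = 8, p_cc = 0.95,
                                           p_pp = 0.04, p_cp = 0.25, seed = s)
    fit <- fit_core_periphery(gen$connectome, n_restarts = 3, seed = s)
    d <- girvan_newman(gen$connectome)
    prof <- onion_profile(d, fit)
    assoc[s] <- prof$association
    core_depth <- prof$nodes$depth[prof$nodes$id %in% gen$truth$core_ids]
    peri_depth <- prof$nodes$depth[!prof$nodes$id %in% gen$truth$core_ids]
    expect_gt(stats::median(core_depth), stats::median(peri_depth))
  }
  expect_true(all(assoc > 0))

  # complete digraph: no variation in gamma or depth -> degenerate
  A <- matrix(1L, 5, 5); diag(A) <- 0L
  Ck <- connectome(tibble::tibble(id = letters[1:5]), A)
  fitk <- fit_core_periphery(Ck, n_restarts = 2, seed = 1)
  profk <- onion_profile(girvan_newman(Ck), fitk)
  expect_true(profk$degenerate)
  expect_equal(profk$association, 0)
})

test_that("newick export round-trips through ape", {
  C <- random_connectome(12, p = 0.3, seed = 14)
  d <- girvan_newman(C)
  nwk <- gn_newick(d)
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, C$regions$id)
})

test_that("coarsening yields the label quotient network", {
  # planted 3-block graph with dense intra-block connectivity
  set.seed(31)
  reg <- tibble::tibble(id = sprintf("n%02d", 1:15),
                        macro_region = rep(c("A", "B", "C"), each = 5))
  A <- matrix(0L, 15, 15)
  for (b in 0:2) {
    idx <- b * 5 + (1:5)
    A[idx, idx] <- 1L
  }
  diag(A) <- 0L
  A[2, 7] <- 1L; A[8, 12] <- 1L       # A->B, B->C only
  C <- connectome(reg, A)
  q <- coarsen(C)
  expect_equal(q$regions$id, c("A", "B", "C"))
  et <- edge_tibble(q)
  expect_equal(nrow(et), 2)
  expect_setequal(paste(et$source, et$target), c("A B", "B C"))
  expect_setequal(q$self_loops, c("A", "B", "C"))  # internal links collapse

  plan <- attr(q, "plan")
  expect_equal(sum(plan$intra_counts$n_internal_links), 3 * 20)
})

test_that("quotient edges equal an independent group-by reduction", {
  set.seed(17)
  n <- 20
  reg <- tibble::tibble(id = sprintf("m%02d", 1:n),
                        macro_region = sample(c("X", "Y", "Z", "W"), n,
                                              replace = TRUE, prob = c(.3, .3, .2, .2)))
  # dense intra-label connectivity so contraction is feasible
  A <- matrix(0L, n, n)
  for (lab in unique(reg$macro_region)) {
    idx <- which(reg$macro_region == lab)
    A[idx, idx] <- 1L
  }
  diag(A) <- 0L
  extra <- matrix(as.integer(runif(n * n) < 0.1), n, n); diag(extra) <- 0L
  A <- pmax(A, extra)
  C <- connectome(reg, A)
  q <- coarsen(C)
  expect_equal(sort(q$regions$id), sort(unique(reg$macro_region)))

  et <- edge_tibble(C)
  lab <- stats::setNames(reg$macro_region, reg$id)
  want <- unique(tibble::tibble(source = unname(lab[et$source]),
                                target = unname(lab[et$target]))) |>
    dplyr::filter(source != target) |>
    dplyr::arrange(source, target)
  got <- dplyr::arrange(edge_tibble(q), source, target)
  expect_equal(got, want)
  expect_true(all(diag(q$A) == 0L))

  # inconsistent labels: a macro-region whose nodes cannot be joined
  reg_bad <- tibble::tibble(id = c("a", "b", "c", "d"),
                            macro_region = c("P", "Q", "P", "Q"))
  Ab <- matrix(0L, 4, 4)
  Ab[1, 2] <- Ab[2, 1] <- 1L; Ab[3, 4] <- Ab[4, 3] <- 1L
  expect_error(coarsen(connectome(reg_bad, Ab)), "labels inconsistent")
})
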