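#' Specification of an EDR random-network draw
#'
#' The exponential distance rule (EDR) states that projection lengths l
#' are distributed as p(l) ~ exp(-lambda l). The EDR network model draws
#' directed edges between region pairs so that realized connection
#' lengths follow this law on the given geometry, at a fixed total edge
#' count. `lambda = 0` is the constant distance rule (CDR): every pair is
#' equally likely.
#'
#' @param lambda Decay rate, 1/mm (>= 0; 0 = CDR).
#' @param target_M Number of directed edges to place.
#' @param bin_width Distance bin width in mm; `NULL` = (max distance)/50.
#' @param seed Optional integer seed (used when the sampler is called with
#'   `use_spec_seed = TRUE`).
#' @return An `edr_spec` list.
#' @export
edr_spec <- function(lambda, target_M, bin_width = NULL, seed = NULL) {
  stopifnot(lambda >= 0, target_M >= 0, is.null(bin_width) || bin_width > 0)
  structure(list(lambda = lambda, target_M = as.integer(target_M),
                 bin_width = bin_width, seed = seed),
            class = "edr_spec")
}

# precompute pair distances and distance-bin assignment for a geometry
edr_context <- function(D, bin_width = NULL) {
  ids <- rownames(D)
  n <- nrow(D)
  ut <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[ut]
  if (any(d <= 0)) stop("distance matrix must be positive off-diagonal")
  dmax <- max(d)
  if (is.null(bin_width)) bin_width <- dmax / 50
  bin <- pmin(floor(d / bin_width) + 1L, as.integer(ceiling(dmax / bin_width)))
  bin_n <- tabulate(bin)
  list(ids = ids, n = n, i = ut[, 1], j = ut[, 2], d = d, bin = bin,
       bin_n = bin_n, bin_width = bin_width, n_bins = length(bin_n))
}

# log probability mass of each distance bin under Exp(lambda), lambda > 0
edr_bin_logprob <- function(ctx, lambda) {
  a <- (seq_len(ctx$n_bins) - 1) * ctx$bin_width
  -lambda * a + log1p(-exp(-lambda * ctx$bin_width))
}

#' Sample a directed network under the exponential distance rule
#'
#' Repeats until exactly `target_M` directed edges are placed: draw a
#' length l from Exp(lambda) (for lambda = 0, a uniformly random pair),
#' find the set of unordered region pairs whose distance falls in the
#' same distance bin as l (redrawing when the bin is empty), choose one
#' pair uniformly, orient it at random, and skip the draw when that
#' directed edge already exists. No self-loops are produced.
#'
#' The default `method = "race"` implements this process as exact
#' weighted sampling without replacement over the directed pairs (each
#' with weight bin-probability / bin-occupancy), via exponential race
#' keys in log space — distributionally identical to the literal
#' rejection loop (`method = "sequential"`, kept for small-scale
#' cross-checks) but orders of magnitude faster.
#'
#' @param D Distance matrix (mm) with region ids as dimnames.
#' @param spec An [edr_spec()].
#' @param regions Optional region table; default is minimal (ids only).
#' @param method `"race"` (fast, default) or `"sequential"` (literal loop).
#' @return A [connectome] with attribute `"edr_spec"`.
#' @export
sample_edr_network <- function(D, spec, regions = NULL,
                               method = c("race", "sequential")) {
  method <- match.arg(method)
  ctx <- edr_context(D, spec$bin_width)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  if (spec$target_M > 2 * length(ctx$d)) {
    stop("target_M exceeds the number of available directed pairs; graph saturates")
  }
  if (method == "race") {
    picked <- edr_sample_race(ctx, spec$lambda, spec$target_M)
  } else {
    picked <- edr_sample_sequential(ctx, spec$lambda, spec$target_M)
  }
  A <- matrix(0L, ctx$n, ctx$n, dimnames = list(ctx$ids, ctx$ids))
  A[picked] <- 1L
  if (is.null(regions)) regions <- tibble::tibble(id = ctx$ids)
  out <- connectome(regions, A)
  attr(out, "edr_spec") <- spec
  out
}

# exact weighted sampling without replacement by exponential race
edr_sample_race <- function(ctx, lambda, target_M) {
  P <- length(ctx$d)
  if (lambda == 0) {
    logw <- rep(0, P)
  } else {
    lbp <- edr_bin_logprob(ctx, lambda)
    logw <- lbp[ctx$bin] - log(ctx$bin_n[ctx$bin])
  }
  keys <- log(stats::rexp(2 * P)) - c(logw, logw)   # first P: i->j, rest: j->i
  take <- order(keys)[seq_len(target_M)]
  fwd <- take <= P
  p <- ifelse(fwd, take, take - P)
  cbind(ifelse(fwd, ctx$i[p], ctx$j[p]),
        ifelse(fwd, ctx$j[p], ctx$i[p]))
}

# literal draw-bin-pair-orient-reject loop (reference implementation)
edr_sample_sequential <- function(ctx, lambda, target_M) {
  pairs_by_bin <- split(seq_along(ctx$d), ctx$bin)
  have <- new.env(parent = emptyenv())
  out <- matrix(0L, target_M, 2)
  placed <- 0L
  dmax_bin <- ctx$n_bins
  while (placed < target_M) {
    if (lambda == 0) {
      p <- sample.int(length(ctx$d), 1)
    } else {
      l <- stats::rexp(1, rate = lambda)
      b <- floor(l / ctx$bin_width) + 1
      if (b > dmax_bin || ctx$bin_n[b] == 0) next     # empty bin: redraw
      cand <- pairs_by_bin[[as.character(b)]]
      p <- cand[sample.int(length(cand), 1)]
    }
    fwd <- stats::runif(1) < 0.5
    key <- paste0(p, if (fwd) "f" else "r")
    if (!is.null(have[[key]])) next                   # edge exists: skip
    have[[key]] <- TRUE
    placed <- placed + 1L
    out[placed, ] <- if (fwd) c(ctx$i[p], ctx$j[p]) else c(ctx$j[p], ctx$i[p])
  }
  out
}

# fast property vector from a binary adjacency matrix
# returns list(M1, M2, motifs[16], cliques (counts by size, index = size),
#              eigenvalues (desc), clustering)
adjacency_properties <- function(A, max_clique_k = 12) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  M <- sum(A)
  M2 <- sum(A & t(A)) / 2
  motifs <- as.numeric(igraph::triad_census(g))
  R <- (A & t(A)) * 1L
  gr <- igraph::graph_from_adjacency_matrix(R, mode = "undirected")
  cnt <- igraph::clique_size_counts(gr, min = 1, max = max_clique_k)
  sizes <- c(cnt, numeric(max_clique_k - length(cnt)))
  und <- igraph::graph_from_adjacency_matrix((A | t(A)) * 1L, mode = "undirected")
  cc <- igraph::transitivity(und, type = "local", isolates = "zero")
  cc[is.nan(cc)] <- 0
  ev <- sort(eigen(tcrossprod(A), symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  list(M1 = M - 2 * M2, M2 = M2, motifs = motifs, cliques = sizes,
       eigenvalues = ev, clustering = mean(cc))
}

#' Ensemble-averaged properties of the EDR model
#'
#' Draws `n_rep` EDR networks on the geometry `D` and averages the graph
#' properties used for property matching: number of uni- and
#' bidirectional links (M1, M2), the 16 triad-census counts, the clique
#' counts by size, the sorted eigenvalues of the co-occurrence matrix
#' A A^T, and the mean local clustering coefficient.
#'
#' @param D Distance matrix with region ids as dimnames.
#' @param spec An [edr_spec()].
#' @param n_rep Ensemble size (1,000 in a full analysis; 100 is the usual
#'   desk-scale reduction).
#' @param max_clique_k Clique sizes are enumerated up to this bound.
#' @return List of ensemble means, same shape as the per-network
#'   property list, plus `n_rep`.
#' @export
ensemble_properties <- function(D, spec, n_rep, max_clique_k = 12) {
  stopifnot(n_rep >= 1)
  ctx <- edr_context(D, spec$bin_width)
  if (spec$target_M > 2 * length(ctx$d)) {
    stop("target_M exceeds the number of available directed pairs")
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  acc <- NULL
  for (r in seq_len(n_rep)) {
    picked <- edr_sample_race(ctx, spec$lambda, spec$target_M)
    A <- matrix(0L, ctx$n, ctx$n)
    A[picked] <- 1L
    pr <- adjacency_properties(A, max_clique_k)
    if (is.null(acc)) {
      acc <- pr
    } else {
      acc <- purrr::map2(acc, pr, `+`)
    }
  }
  out <- purrr::map(acc, \(x) x / n_rep)
  out$n_rep <- n_rep
  out
}

#' Estimate the EDR decay rate by ensemble property matching
#'
#' For every lambda on the grid, draws an ensemble of EDR networks with
#' the data network's edge count on the data geometry and measures how
#' far the ensemble-averaged properties sit from the data's: absolute
#' deviations for M1, M2 and mean clustering; root-mean-square deviations
#' over the 16 triad counts (raw counts, or count ratios model/data for
#' the fine scale), over the clique counts by size (aligned, missing
#' sizes = 0) and over the sorted co-occurrence eigenvalues. Each
#' property P selects its own best-matching `lambda_P` (argmin of the
#' deviation curve); the consensus interval is the range of the
#' `lambda_P`. Tight consensus across properties indicates that a single
#' decay rate describes the network.
#'
#' @param C_data A [connectome] (the data network; its edge count fixes
#'   `target_M`).
#' @param D Distance matrix on the same regions.
#' @param grid Numeric vector of lambda values (1/mm); default
#'   `seq(0, 2, by = 0.05)`.
#' @param n_rep Ensemble size per grid point.
#' @param seed Integer seed for the whole scan.
#' @param bin_width Distance bin width (mm); `NULL` = (max distance)/50.
#' @param motif_mode `"counts"` (RMS on raw triad counts, coarse scale) or
#'   `"ratios"` (RMS on model/data count ratios, fine scale).
#' @param max_clique_k Clique sizes enumerated up to this bound.
#' @return An object of class `edr_fit`: list with `deviations` (long
#'   tibble `lambda`, `property`, `deviation`), `lambda_hat` (tibble
#'   `property`, `lambda`), `consensus` (length-2 numeric), `data_properties`,
#'   and the scan settings.
#' @export
match_lambda <- function(C_data, D, grid = seq(0, 2, by = 0.05),
                         n_rep = 100, seed = 1, bin_width = NULL,
                         motif_mode = c("counts", "ratios"),
                         max_clique_k = 12) {
  motif_mode <- match.arg(motif_mode)
  if (length(grid) == 0) stop("empty lambda grid")
  ctx <- edr_context(D, bin_width)
  stopifnot(all(C_data$regions$id %in% rownames(D)))
  data_pr <- adjacency_properties(C_data$A, max_clique_k)
  target_M <- n_edges(C_data)
  set.seed(seed)
  rows <- vector("list", length(grid))
  for (gi in seq_along(grid)) {
    lam <- grid[gi]
    acc <- NULL
    for (r in seq_len(n_rep)) {
      picked <- edr_sample_race(ctx, lam, target_M)
      A <- matrix(0L, ctx$n, ctx$n)
      A[picked] <- 1L
      pr <- adjacency_properties(A, max_clique_k)
      acc <- if (is.null(acc)) pr else purrr::map2(acc, pr, `+`)
    }
    mp <- purrr::map(acc, \(x) x / n_rep)
    motif_dev <- if (motif_mode == "counts") {
      sqrt(mean((mp$motifs - data_pr$motifs)^2))
    } else {
      keep <- data_pr$motifs > 0
      sqrt(mean((mp$motifs[keep] / data_pr$motifs[keep] - 1)^2))
    }
    rows[[gi]] <- tibble::tibble(
      lambda = lam,
      property = c("M1", "M2", "motif_RMS", "clique_RMS", "eig_RMS",
                   "clustering"),
      deviation = c(abs(mp$M1 - data_pr$M1),
                    abs(mp$M2 - data_pr$M2),
                    motif_dev,
                    sqrt(mean((mp$cliques - data_pr$cliques)^2)),
                    sqrt(mean((mp$eigenvalues - data_pr$eigenvalues)^2)),
                    abs(mp$clustering - data_pr$clustering))
    )
  }
  deviations <- dplyr::bind_rows(rows)
  lambda_hat <- deviations |>
    dplyr::group_by(.data$property) |>
    dplyr::slice_min(.data$deviation, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("property", lambda = "lambda")
  structure(
    list(deviations = deviations, lambda_hat = lambda_hat,
         consensus = range(lambda_hat$lambda),
         data_properties = data_pr,
         grid = grid, n_rep = n_rep, seed = seed,
         bin_width = ctx$bin_width, motif_mode = motif_mode),
    class = "edr_fit"
  )
}

#' @export
print.edr_fit <- function(x, ...) {
  cat("<edr_fit> grid [", min(x$grid), ",", max(x$grid), "] 1/mm,",
      x$n_rep, "replicates per point\n")
  for (k in seq_len(nrow(x$lambda_hat))) {
    cat(sprintf("  lambda_%-11s = %.3g\n", x$lambda_hat$property[k],
                x$lambda_hat$lambda[k]))
  }
  cat(sprintf("  consensus band: %.3g - %.3g 1/mm\n",
              x$consensus[1], x$consensus[2]))
  invisible(x)
}

#' Deviation curves of an EDR fit
#'
#' @param x An `edr_fit`.
#' @param ... Unused.
#' @return Long tibble `lambda`, `property`, `deviation`.
#' @method tidy edr_fit
#' @export
tidy.edr_fit <- function(x, ...) x$deviations

#' One-row summary of an EDR fit
#'
#' @param x An `edr_fit`.
#' @param ... Unused.
#' @return Tibble with one column `lambda_<P>` per property plus the
#'   consensus band and scan settings.
#' @method glance edr_fit
#' @export
glance.edr_fit <- function(x, ...) {
  wide <- stats::setNames(as.list(x$lambda_hat$lambda),
                          paste0("lambda_", x$lambda_hat$property))
  tibble::as_tibble(c(wide, list(consensus_lo = x$consensus[1],
                                 consensus_hi = x$consensus[2],
                                 n_rep = x$n_rep,
                                 bin_width = x$bin_width)))
}

#' Plot EDR property-matching deviation curves
#'
#' One facet per matched property; the vertical band is the consensus
#' interval spanned by the per-property optima.
#'
#' @param object An `edr_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot edr_fit
#' @export
autoplot.edr_fit <- function(object, ...) {
  ggplot2::ggplot(object$deviations,
                  ggplot2::aes(.data$lambda, .data$deviation)) +
    ggplot2::annotate("rect", xmin = object$consensus[1],
                      xmax = object$consensus[2], ymin = -Inf, ymax = Inf,
                      alpha = 0.2, fill = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = dplyr::inner_join(
      object$deviations, object$lambda_hat, by = c("property", "lambda")),
      colour = "#c0392b") +
    ggplot2::facet_wrap(~property, scales = "free_y") +
    ggplot2::labs(x = expression(lambda ~ (mm^-1)), y = "deviation from data",
                  title = "EDR property matching") +
    ggplot2::theme_minimal()
}
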