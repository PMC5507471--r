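#' Two-block core-periphery fit by expectation-maximization
#'
#' Fits the two-block stochastic block model to the directed binary
#' adjacency matrix: each node belongs to the core (c) or periphery (p)
#' class, and an edge i -> j is present independently with probability
#' `p[g_i, g_j]` given the memberships. The likelihood
#' \deqn{P(A \mid p, \gamma) = \sum_g \prod_{i \ne j}
#'   p_{g_i g_j}^{A_{ij}} (1 - p_{g_i g_j})^{1 - A_{ij}} \prod_i \gamma_{g_i}}
#' is maximized with a mean-field EM algorithm: soft memberships are
#' updated node by node (coordinate ascent, so the evidence lower bound
#' never decreases), then the class proportions and the 2 x 2 affinity
#' matrix are re-estimated. The class with the higher internal connection
#' probability is labelled core; a node is assigned to the core iff its
#' posterior core probability exceeds 0.5.
#'
#' @param C A [connectome] with at least 4 regions.
#' @param n_restarts Number of random initializations; the best fit (by
#'   lower bound) is returned.
#' @param seed Integer seed controlling the initializations.
#' @param max_iter Iteration cap per restart.
#' @param tol Relative lower-bound change declaring convergence.
#' @return An object of class `core_periphery_fit`: a list with
#'   `membership` (tibble `id`, `gamma_core`, `core`), `affinity`
#'   (2 x 2, rows/cols `c`, `p`), `proportions`, `log_likelihood`
#'   (the lower bound at the optimum), `block_densities`,
#'   `elbo_trace`, `converged`.
#' @export
fit_core_periphery <- function(C, n_restarts = 20, seed = 1,
                               max_iter = 500, tol = 1e-8) {
  if (n_regions(C) < 4) stop("core-periphery fit needs at least 4 regions")
  A <- C$A
  storage.mode(A) <- "double"
  n <- nrow(A)
  best <- NULL
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_restarts)
  any_converged <- FALSE
  for (r in seq_len(n_restarts)) {
    set.seed(seeds[r])
    fit <- em_two_block(A, max_iter = max_iter, tol = tol)
    any_converged <- any_converged || fit$converged
    if (is.null(best) || fit$elbo > best$elbo) best <- fit
  }
  out <- finish_cp_fit(C, best, n_restarts, seed)
  if (!any_converged) {
    rlang::abort("EM did not converge within the iteration cap in any restart",
                 class = "connectoscope_em_no_convergence", fit = out)
  }
  out
}

# one EM run from a random soft initialization; A: double matrix, zero diag
em_two_block <- function(A, max_iter, tol) {
  n <- nrow(A)
  eps <- 1e-10
  Q <- matrix(stats::runif(2 * n, 0.25, 0.75), n, 2)
  Q <- Q / rowSums(Q)
  elbo_trace <- numeric(0)
  elbo_old <- -Inf
  converged <- FALSE
  pi_k <- colMeans(Q)
  P <- m_step_affinity(A, Q, eps)
  for (it in seq_len(max_iter)) {
    lp <- log(P); l1p <- log1p(-P)
    lpi <- log(pmax(pi_k, eps))
    colQ <- colSums(Q)
    # sequential (coordinate-ascent) membership updates
    for (i in seq_len(n)) {
      a <- A[i, ]; b <- A[, i]
      s1 <- c(sum(a * Q[, 1]), sum(a * Q[, 2]))
      t1 <- c(sum(b * Q[, 1]), sum(b * Q[, 2]))
      s0 <- (colQ - Q[i, ]) - s1
      t0 <- (colQ - Q[i, ]) - t1
      f <- lpi +
        lp %*% s1 + l1p %*% s0 +        # out-links: lp[c, d] s1[d]
        crossprod(lp, t1) + crossprod(l1p, t0)  # in-links: lp[d, c] t1[d]
      f <- as.numeric(f)
      qi <- exp(f - max(f)); qi <- qi / sum(qi)
      colQ <- colQ - Q[i, ] + qi
      Q[i, ] <- qi
    }
    pi_k <- colMeans(Q)
    P <- m_step_affinity(A, Q, eps)
    elbo <- two_block_elbo(A, Q, P, pi_k, eps)
    elbo_trace <- c(elbo_trace, elbo)
    if (is.finite(elbo_old) &&
        abs(elbo - elbo_old) <= tol * (abs(elbo_old) + eps)) {
      converged <- TRUE
      break
    }
    elbo_old <- elbo
  }
  list(Q = Q, P = P, pi = pi_k, elbo = elbo, elbo_trace = elbo_trace,
       converged = converged)
}

m_step_affinity <- function(A, Q, eps) {
  num <- crossprod(Q, A %*% Q)                    # diag(A) = 0
  S <- colSums(Q)
  den <- outer(S, S) - crossprod(Q)               # sum_{i != j} q_ic q_jd
  P <- num / pmax(den, eps)
  pmin(pmax(P, eps), 1 - eps)
}

two_block_elbo <- function(A, Q, P, pi_k, eps) {
  lp <- log(P); l1p <- log1p(-P)
  S <- colSums(Q)
  E1 <- crossprod(Q, A %*% Q)                     # expected edge counts
  Epairs <- outer(S, S) - crossprod(Q)
  E0 <- Epairs - E1
  ll_edges <- sum(E1 * lp) + sum(E0 * l1p)
  ll_prior <- sum(Q %*% log(pmax(pi_k, eps)))
  entropy <- -sum(Q * log(pmax(Q, eps)))
  ll_edges + ll_prior + entropy
}

finish_cp_fit <- function(C, best, n_restarts, seed) {
  # label-switching: class with larger internal probability is the core
  ord <- order(-diag(best$P))
  Q <- best$Q[, ord, drop = FALSE]
  P <- best$P[ord, ord]
  dimnames(P) <- list(c("c", "p"), c("c", "p"))
  gamma_core <- Q[, 1]
  core <- gamma_core > 0.5
  membership <- tibble::tibble(id = C$regions$id, gamma_core = gamma_core,
                               core = core)
  bd <- if (any(core) && any(!core)) {
    block_densities(C, C$regions$id[core])
  } else NULL
  structure(
    list(membership = membership, affinity = P,
         proportions = stats::setNames(best$pi[ord], c("c", "p")),
         log_likelihood = best$elbo, block_densities = bd,
         elbo_trace = best$elbo_trace, converged = best$converged,
         n_restarts = n_restarts, seed = seed),
    class = "core_periphery_fit"
  )
}

#' @export
print.core_periphery_fit <- function(x, ...) {
  k <- sum(x$membership$core)
  cat("<core_periphery_fit> core:", k, "nodes, periphery:",
      nrow(x$membership) - k, "nodes\n")
  cat("  affinity p_cc =", signif(x$affinity["c", "c"], 3),
      " p_cp/pc =", signif(x$affinity["c", "p"], 3), "/",
      signif(x$affinity["p", "c"], 3),
      " p_pp =", signif(x$affinity["p", "p"], 3), "\n")
  if (!is.null(x$block_densities)) {
    bd <- x$block_densities
    cat(sprintf("  block densities rho_cc = %.2f, rho_pp = %.2f, rho_cp = %.2f\n",
                bd$rho_cc, bd$rho_pp, bd$rho_cp))
  }
  invisible(x)
}

#' Realized block densities of a core/periphery split
#'
#' With K core nodes, the core-core density is the number of realized
#' directed core-core edges over `K (K - 1)`, the periphery-periphery
#' density over `(N - K)(N - K - 1)`, and the core-periphery density
#' (both directions pooled) over `2 K (N - K)`.
#'
#' @param C A [connectome].
#' @param core_ids Character vector of region ids forming the core.
#' @return One-row tibble: `K`, `rho_cc`, `rho_pp`, `rho_cp`.
#' @export
block_densities <- function(C, core_ids) {
  ids <- C$regions$id
  bad <- setdiff(core_ids, ids)
  if (length(bad)) stop("unknown core ids: ", paste(bad, collapse = ", "))
  core <- ids %in% core_ids
  K <- sum(core); n <- length(ids)
  if (K == 0 || K == n) stop("core and periphery must both be non-empty")
  A <- C$A
  tibble::tibble(
    K = K,
    rho_cc = sum(A[core, core]) / (K * (K - 1)),
    rho_pp = sum(A[!core, !core]) / ((n - K) * (n - K - 1)),
    rho_cp = (sum(A[core, !core]) + sum(A[!core, core])) / (2 * K * (n - K))
  )
}

#' Clique-based core detection
#'
#' For dense (coarse-scale) networks the core can be read off the clique
#' distribution: the union of all vertices participating in maximum-size
#' directed cliques. Inapplicable when the largest clique has fewer than
#' 3 nodes.
#'
#' @param C A [connectome].
#' @return Sorted character vector of core region ids.
#' @export
clique_based_core <- function(C) {
  cc <- clique_census(C)
  if (cc$max_size < 3) {
    stop("clique-based core detection inapplicable: largest clique has size ",
         cc$max_size)
  }
  sort(unique(unlist(cc$max_cliques)))
}

#' Analytic Erdos-Renyi specificity bound for a dense core
#'
#' Upper bound on the probability that a directed Erdos-Renyi graph on N
#' nodes with link density p contains a K-node subgraph of internal
#' density q: with `L = K (K - 1)`,
#' \deqn{C(N, K)\, C(L, qL)\, p^{qL} (1 - p)^{(1 - q) L}.}
#' Binomial coefficients are evaluated with the continuous log-gamma
#' extension (q L need not be an integer when q is a rounded density) and
#' the whole expression in log space; the result is capped at 1.
#'
#' @param N,K Node counts (0 < K <= N).
#' @param p Ambient density, in (0, 1).
#' @param q Core internal density, in (0, 1].
#' @return The bound as a probability; attribute `"log10"` carries its
#'   uncapped base-10 logarithm.
#' @export
er_core_bound <- function(N, K, p, q) {
  if (K <= 0 || K > N) stop("need 0 < K <= N")
  if (p <= 0 || p >= 1) stop("need 0 < p < 1")
  if (q <= 0 || q > 1) stop("need 0 < q <= 1")
  L <- K * (K - 1)
  qL <- q * L
  lchoose_cont <- function(n, k) lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)
  lb <- lchoose_cont(N, K) + lchoose_cont(L, qL) +
    qL * log(p) + (1 - q) * L * log1p(-p)
  out <- min(exp(lb), 1)
  attr(out, "log10") <- lb / log(10)
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-node tidy view of a core-periphery fit
#'
#' @param x A `core_periphery_fit`.
#' @param ... Unused.
#' @return Tibble with `id`, `gamma_core`, `core`.
#' @method tidy core_periphery_fit
#' @export
tidy.core_periphery_fit <- function(x, ...) x$membership

#' One-row summary of a core-periphery fit
#'
#' @param x A `core_periphery_fit`.
#' @param ... Unused.
#' @return Tibble with core size, affinities, block densities,
#'   log-likelihood bound and convergence flag.
#' @method glance core_periphery_fit
#' @export
glance.core_periphery_fit <- function(x, ...) {
  bd <- x$block_densities
  tibble::tibble(
    n_core = sum(x$membership$core),
    n_periphery = sum(!x$membership$core),
    p_cc = x$affinity["c", "c"], p_pp = x$affinity["p", "p"],
    rho_cc = if (is.null(bd)) NA_real_ else bd$rho_cc,
    rho_pp = if (is.null(bd)) NA_real_ else bd$rho_pp,
    rho_cp = if (is.null(bd)) NA_real_ else bd$rho_cp,
    log_likelihood = x$log_likelihood,
    converged = x$converged
  )
}

#' Plot core probabilities of a fitted core-periphery model
#'
#' Nodes ordered by their posterior core probability, colored by the
#' resulting assignment (threshold 0.5, dashed line).
#'
#' @param object A `core_periphery_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot core_periphery_fit
#' @export
autoplot.core_periphery_fit <- function(object, ...) {
  df <- dplyr::arrange(object$membership, dplyr::desc(.data$gamma_core))
  df$ord <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(.data$ord, .data$gamma_core,
                                   colour = .data$core)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b",
                                            `FALSE` = "#2980b9"),
                                 labels = c(`TRUE` = "core",
                                            `FALSE` = "periphery"),
                                 name = NULL) +
    ggplot2::labs(x = "node rank", y = expression(gamma[c]),
                  title = "Core membership probabilities") +
    ggplot2::theme_minimal()
}
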