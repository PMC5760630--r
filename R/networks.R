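# Directed-network ensembles and network-inferability theory.
#
# A link j -> i can be recovered from steady-state knockout data only when no
# alternative route can fully explain the target's response.  For randomly
# perturbed node sets this reduces to a motif-counting problem on the directed
# topology, giving the expected inferable fraction F(q) and the inferability
# measures I_F (area under F) and I_F* (its out-degree-only approximation).

#' Construct a directed network
#'
#' @param n_nodes number of nodes; nodes are labelled `1:n_nodes`.
#' @param edges two-column integer matrix of directed links
#'   (column 1 = source, column 2 = target).
#' @param weights optional numeric vector of link strengths, parallel to the
#'   rows of `edges`; `weights[e]` is the direct effect of `edges[e, 1]` on
#'   `edges[e, 2]`.
#' @return an object of class `directed_network`.
#' @details Self-loops and bidirectional pairs are disallowed: reciprocal
#'   links are excluded from the inferability analysis, because an existing
#'   link from the current target excludes the reverse link from transmitting
#'   information back.
#' @export
directed_network <- function(n_nodes, edges, weights = NULL) {
  stopifnot(n_nodes >= 1)
  edges <- matrix(as.integer(edges), ncol = 2,
                  dimnames = list(NULL, c("source", "target")))
  if (nrow(edges) > 0) {
    if (any(edges < 1L) || any(edges > n_nodes)) {
      stop("edge endpoints must be node indices in 1..n_nodes")
    }
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    key <- paste(edges[, 1], edges[, 2])
    if (anyDuplicated(key)) stop("duplicate edges are not allowed")
    rev_key <- paste(edges[, 2], edges[, 1])
    if (any(rev_key %in% key)) {
      stop("bidirectional pairs are not allowed")
    }
  }
  if (!is.null(weights)) {
    stopifnot(length(weights) == nrow(edges))
    weights <- as.numeric(weights)
  }
  structure(list(n_nodes = as.integer(n_nodes), edges = edges,
                 weights = weights),
            class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("directed_network: %d nodes, %d links (mean out-degree %.2f)%s\n",
              x$n_nodes, nrow(x$edges), nrow(x$edges) / x$n_nodes,
              if (is.null(x$weights)) "" else ", weighted"))
  invisible(x)
}

#' Out-degree of every node
#' @param net a `directed_network`.
#' @return integer vector of out-degrees, one per node.
#' @export
out_degree <- function(net) {
  tabulate(net$edges[, 1], nbins = net$n_nodes)
}

# Adjacency list of out-neighbours.
out_neighbours <- function(net) {
  nb <- vector("list", net$n_nodes)
  if (nrow(net$edges) > 0) {
    sp <- split(net$edges[, 2], factor(net$edges[, 1], levels = 1:net$n_nodes))
    nb <- lapply(sp, as.integer)
  }
  nb
}

# Sample E unordered pairs (i < j) without replacement, with probability
# proportional to prob (one entry per pair, in the column-major order of
# combn(n, 2)). Returns a 2-column matrix.
sample_pairs <- function(n, n_edges, prob = NULL) {
  all_pairs <- t(utils::combn(n, 2))
  if (n_edges > nrow(all_pairs)) {
    stop(sprintf("infeasible degree sequence: %d links requested but only %d node pairs exist",
                 n_edges, nrow(all_pairs)))
  }
  idx <- sample.int(nrow(all_pairs), n_edges, replace = FALSE, prob = prob)
  all_pairs[idx, , drop = FALSE]
}

#' Generate a scale-free directed network
#'
#' Node degree propensities are drawn from a power law with exponent `gamma`
#' (Pareto tail, truncated at `n - 1`) and rescaled so that the realized mean
#' out-degree equals `mean_degree`.  Links are placed between node pairs with
#' probability proportional to the product of their propensities and oriented
#' from the endpoint of higher total degree to the lower one, so that
#' high-degree nodes act as regulatory hubs with many outgoing links
#' (`hub_mode = "outgoing"`).  `hub_mode = "incoming"` returns the same graph
#' with all link directions inverted.
#'
#' @param n number of nodes (>= 3).
#' @param gamma power-law exponent (> 1).
#' @param mean_degree target mean out-degree, `E/n` with `E` the number of
#'   links; must satisfy `0 < mean_degree < (n - 1) / 2`.
#' @param hub_mode `"outgoing"` or `"incoming"`.
#' @param seed integer seed; the same seed reproduces the same edge set.
#' @return a `directed_network`.
#' @export
generate_scale_free_network <- function(n, gamma = 2.5, mean_degree = 2,
                                        hub_mode = c("outgoing", "incoming"),
                                        seed = NULL) {
  hub_mode <- match.arg(hub_mode)
  stopifnot(n >= 3, gamma > 1, mean_degree > 0)
  n_edges <- round(n * mean_degree)
  if (n_edges > n * (n - 1) / 2) {
    stop(sprintf("infeasible degree sequence: mean degree %.2f needs %d links but at most %d pairs exist",
                 mean_degree, n_edges, n * (n - 1) %/% 2))
  }
  if (!is.null(seed)) set.seed(seed)
  # Pareto draws with unit scale, truncated at n - 1; the absolute scale
  # cancels in the pair-sampling probabilities.
  w <- (1 - stats::runif(n))^(-1 / (gamma - 1))
  w <- pmin(w, n - 1)
  pairs <- t(utils::combn(n, 2))
  prob <- w[pairs[, 1]] * w[pairs[, 2]]
  if (n_edges > nrow(pairs)) stop("infeasible degree sequence")
  idx <- sample.int(nrow(pairs), n_edges, replace = FALSE, prob = prob)
  und <- pairs[idx, , drop = FALSE]
  # orient from high to low total degree, ties broken at random
  deg <- tabulate(c(und[, 1], und[, 2]), nbins = n)
  key <- deg + stats::runif(n) # random, consistent tie-break per node
  flip <- key[und[, 1]] < key[und[, 2]]
  edges <- cbind(ifelse(flip, und[, 2], und[, 1]),
                 ifelse(flip, und[, 1], und[, 2]))
  if (hub_mode == "incoming") edges <- edges[, 2:1, drop = FALSE]
  directed_network(n, edges)
}

#' Generate a directed network by random link insertion
#'
#' Uniformly random node pairs receive a link with a uniformly random
#' direction; out-degrees are then approximately Poisson with mean
#' `mean_degree`.
#'
#' @inheritParams generate_scale_free_network
#' @return a `directed_network`.
#' @export
generate_random_network <- function(n, mean_degree, seed = NULL) {
  stopifnot(n >= 2, mean_degree > 0)
  n_edges <- round(n * mean_degree)
  if (n_edges > n * (n - 1) / 2) {
    stop(sprintf("infeasible mean degree %.2f for %d nodes", mean_degree, n))
  }
  if (!is.null(seed)) set.seed(seed)
  und <- sample_pairs(n, n_edges)
  flip <- stats::runif(nrow(und)) < 0.5
  edges <- cbind(ifelse(flip, und[, 2], und[, 1]),
                 ifelse(flip, und[, 1], und[, 2]))
  directed_network(n, edges)
}

#' Draw a random perturbed node set
#'
#' By default each node is perturbed independently with probability `q`
#' (matching the independence assumption behind the closed-form F(q)); with
#' `fixed_size = TRUE` exactly `round(q * n)` nodes are drawn, for
#' reproducing fraction-of-perturbed-nodes plots.
#'
#' @param net a `directed_network`.
#' @param q fraction (or per-node probability) of perturbed nodes, in [0, 1].
#' @param fixed_size draw exactly `round(q * n)` nodes instead of Bernoulli.
#' @param seed optional integer seed.
#' @return integer vector of perturbed node indices.
#' @export
perturbed_set <- function(net, q, fixed_size = FALSE, seed = NULL) {
  stopifnot(q >= 0, q <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- net$n_nodes
  if (fixed_size) {
    sort(sample.int(n, round(q * n)))
  } else {
    which(stats::runif(n) < q)
  }
}

#' Count inferable links for a given perturbed node set
#'
#' A directed link s -> t is inferable from steady-state perturbation data if
#' the activity of s cannot be fully reconstructed from the remaining
#' network.  In `motif` mode the edge is flagged inferable iff s is perturbed
#' and either (a) t and every out-neighbour of s are perturbed, or (b) t is
#' not perturbed, every out-neighbour of s except t is perturbed, and every
#' out-neighbour of t is perturbed.  In `refined` mode, nodes already
#' identified as targets of the current target node are deleted from the
#' graph before testing each edge (a link out of t excludes the reverse link,
#' since bidirectional pairs are excluded), and the flags are iterated to a
#' fixed point.
#'
#' @param net a `directed_network`.
#' @param perturbed integer vector of perturbed node indices.
#' @param mode `"motif"` or `"refined"`.
#' @return a list with `count` (number of inferable links), `flags` (logical
#'   vector parallel to the edge rows) and `fraction`.
#' @export
count_inferable_links <- function(net, perturbed, mode = c("motif", "refined")) {
  mode <- match.arg(mode)
  n <- net$n_nodes
  if (length(perturbed) > 0 &&
      (any(perturbed < 1) || any(perturbed > n))) {
    stop("perturbed set must be a subset of the nodes")
  }
  edges <- net$edges
  if (nrow(edges) == 0) {
    return(list(count = 0L, flags = logical(0), fraction = NaN))
  }
  p <- logical(n)
  p[perturbed] <- TRUE
  s <- edges[, 1]; t <- edges[, 2]
  # unperturbed out-neighbour counts, vectorised over edges
  cnt <- tabulate(s[!p[t]], nbins = n)
  flags <- p[s] & ((p[t] & cnt[s] == 0L) |
                   (!p[t] & cnt[s] == 1L & cnt[t] == 0L))
  if (mode == "refined") {
    nb <- out_neighbours(net)
    repeat {
      changed <- FALSE
      for (e in seq_len(nrow(edges))) {
        if (flags[e]) next
        se <- s[e]; te <- t[e]
        if (!p[se]) next
        # targets of t with an already-inferable incoming link from t are
        # removed from the graph prior to testing this edge
        removed <- t[flags & s == te]
        out_s <- setdiff(nb[[se]], removed)
        out_t <- setdiff(nb[[te]], removed)
        ok <- if (p[te]) {
          all(p[out_s])
        } else {
          all(p[setdiff(out_s, te)]) && all(p[out_t])
        }
        if (ok) {
          flags[e] <- TRUE
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  list(count = sum(flags), flags = flags, fraction = mean(flags))
}

#' Expected fraction of inferable links at perturbed fraction q
#'
#' Averages `count_inferable_links` over random perturbed sets in which each
#' node is perturbed independently with probability `q`.  With
#' `exhaustive = TRUE` the exact expectation is computed by enumerating all
#' 2^n perturbed sets (small networks only).
#'
#' @param net a `directed_network` with at least one link.
#' @param q perturbation probability in [0, 1].
#' @param n_draws number of Monte Carlo draws.
#' @param mode counting mode, see [count_inferable_links()].
#' @param exhaustive enumerate all perturbed sets exactly.
#' @param seed optional integer seed for the Monte Carlo draws.
#' @return the expected inferable fraction (scalar).
#' @export
expected_inferable_fraction <- function(net, q, n_draws = 1000,
                                        mode = "motif", exhaustive = FALSE,
                                        seed = NULL) {
  stopifnot(q >= 0, q <= 1)
  if (nrow(net$edges) == 0) stop("network has no links")
  n <- net$n_nodes
  if (exhaustive) {
    if (n > 20) stop("exhaustive enumeration limited to n <= 20")
    total <- 0
    for (mask in 0:(2^n - 1)) {
      pert <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) != 0)
      wgt <- q^length(pert) * (1 - q)^(n - length(pert))
      if (wgt == 0) next
      total <- total + wgt * count_inferable_links(net, pert, mode)$fraction
    }
    return(total)
  }
  if (!is.null(seed)) set.seed(seed)
  mean(vapply(seq_len(n_draws), function(d) {
    pert <- which(stats::runif(n) < q)
    count_inferable_links(net, pert, mode)$fraction
  }, numeric(1)))
}

# Per-edge motif statistics: out-degree of source (k), of target (l), and
# number of shared targets (m).
edge_motif_stats <- function(net) {
  if (nrow(net$edges) == 0) stop("network has no links")
  k_out <- out_degree(net)
  nb <- out_neighbours(net)
  s <- net$edges[, 1]; t <- net$edges[, 2]
  m <- vapply(seq_along(s), function(e) {
    length(intersect(nb[[s[e]]], nb[[t[e]]]))
  }, integer(1))
  data.frame(k = k_out[s], l = k_out[t], m = m)
}

#' Closed-form expected fraction of inferable links F(q)
#'
#' Evaluates
#' \deqn{F(q) = \sum_{k,l} \sum_{m=0}^{\min(k-1,l)}
#'   [q^{k+1} + (1-q) q^{k+l-m}] P(k, l, m | k \to l)}
#' where `P(k, l, m | k -> l)` is the conditional probability that an edge
#' connects a source of out-degree `k` to a target of out-degree `l` sharing
#' `m` common targets, estimated empirically over the edges of `net`.  The
#' exponent `z = k + l - m` counts the distinct nodes that must be perturbed
#' when the target is not: the target itself enters the first factor, the
#' remaining `k - 1` source targets and the `l - m` non-shared target targets
#' the second.  Under independent Bernoulli(q) perturbations this equals the
#' exact per-edge motif probability, so it matches
#' [expected_inferable_fraction()] in exhaustive motif mode.
#'
#' @param net a `directed_network` with at least one link.
#' @param q perturbation probability, may be a vector.
#' @return F(q), same length as `q`.
#' @export
F_closed_form <- function(net, q) {
  st <- edge_motif_stats(net)
  vapply(q, function(qq) {
    mean(qq^(st$k + 1) + (1 - qq) * qq^(st$k + st$l - st$m))
  }, numeric(1))
}

#' Network inferability I_F: the area under the F(q) curve
#'
#' @param net a `directed_network` with at least one link.
#' @param q_grid ascending grid covering [0, 1] (trapezoid integration).
#' @param estimator `"closed_form"` (exact under Bernoulli perturbations) or
#'   `"monte_carlo"` (random perturbed sets per grid point).
#' @param n_draws Monte Carlo draws per grid point.
#' @param mode counting mode for the Monte Carlo estimator.
#' @param seed optional integer seed.
#' @return an object of class `inferability_curve`: list with `q_grid`,
#'   `F_values`, `I_F` and `I_F_star`.
#' @export
inferability_IF <- function(net, q_grid = seq(0, 1, length.out = 101),
                            estimator = c("closed_form", "monte_carlo"),
                            n_draws = 200, mode = "motif", seed = NULL) {
  estimator <- match.arg(estimator)
  if (is.unsorted(q_grid, strictly = TRUE) ||
      min(q_grid) < 0 || max(q_grid) > 1) {
    stop("q_grid must be strictly ascending within [0, 1]")
  }
  if (estimator == "closed_form") {
    Fv <- F_closed_form(net, q_grid)
  } else {
    if (!is.null(seed)) set.seed(seed)
    Fv <- vapply(q_grid, function(qq) {
      expected_inferable_fraction(net, qq, n_draws = n_draws, mode = mode)
    }, numeric(1))
  }
  structure(list(q_grid = q_grid, F_values = Fv,
                 I_F = trapz(q_grid, Fv),
                 I_F_star = inferability_IF_star(net, q_grid)),
            class = "inferability_curve")
}

#' @export
print.inferability_curve <- function(x, ...) {
  cat(sprintf("inferability_curve: I_F = %.4f, I_F* = %.4f (%d q points)\n",
              x$I_F, x$I_F_star, length(x$q_grid)))
  invisible(x)
}

#' Out-degree-only inferability measure I_F*
#'
#' Replaces the joint edge statistics `P(k, l, m | k -> l)` in F(q) by the
#' product of the edge-end out-degree marginals, with the shared-target count
#' `m` following the hypergeometric distribution implied by independent
#' target placement (source draws its other `k - 1` targets among the
#' `n - 2` nodes of which `l` are targets of the target node).  I_F* is a
#' function of the out-degree distributions alone.
#'
#' @inheritParams inferability_IF
#' @return scalar I_F*.
#' @export
inferability_IF_star <- function(net, q_grid = seq(0, 1, length.out = 101)) {
  st <- edge_motif_stats(net)
  n <- net$n_nodes
  pk <- table(st$k) / nrow(st) # source out-degree marginal over edges
  pl <- table(st$l) / nrow(st) # target out-degree marginal over edges
  ks <- as.integer(names(pk)); ls <- as.integer(names(pl))
  Fq <- numeric(length(q_grid))
  for (a in seq_along(ks)) {
    k <- ks[a]
    for (b in seq_along(ls)) {
      l <- ls[b]
      mmax <- min(k - 1, l)
      m <- 0:mmax
      pm <- stats::dhyper(m, l, n - 2 - l, k - 1)
      pm <- pm / sum(pm)
      w <- as.numeric(pk[a] * pl[b])
      for (i in seq_along(q_grid)) {
        qq <- q_grid[i]
        Fq[i] <- Fq[i] + w * sum(pm * (qq^(k + 1) + (1 - qq) * qq^(k + l - m)))
      }
    }
  }
  trapz(q_grid, Fq)
}
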