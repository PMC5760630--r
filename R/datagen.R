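# Synthetic knockout-screen generators: a linear steady-state model (the
# inference model's own generative form) and a nonlinear ODE steady-state
# model with Hill-type regulation, both on generated topologies.

#' Build a perturbation design for a knockout screen
#'
#' Every experiment perturbs exactly one node (single-gene screens); the
#' perturbation force of a knockout is shared across its replicates
#' (replicates differ by noise only, as in repeated deletion-strain
#' measurements) and is drawn from a standard normal distribution by
#' default, or fixed to a strong negative force with
#' `strength_mode = "knockout"`.
#'
#' @param net a `directed_network` (defines the node set).
#' @param perturbed integer vector of perturbable/perturbed node indices.
#' @param n_replicates experimental replicates per knockout.
#' @param n_wt number of wild-type replicate samples.
#' @param strength_mode `"gaussian"` (standard-normal forces, the model's
#'   identifiability assumption) or `"knockout"` (fixed force of -5 on the
#'   log2 scale).
#' @param seed optional integer seed for the force draws.
#' @return object of class `perturbation_design`: `experiments` data frame
#'   (node, replicate, strength), `n_wt`, `q` (fraction of perturbed
#'   nodes) and `n_nodes`.
#' @export
perturbation_design <- function(net, perturbed, n_replicates = 2, n_wt = 20,
                                strength_mode = c("gaussian", "knockout"),
                                seed = NULL) {
  strength_mode <- match.arg(strength_mode)
  n <- net$n_nodes
  perturbed <- sort(unique(as.integer(perturbed)))
  stopifnot(all(perturbed >= 1), all(perturbed <= n))
  if (!is.null(seed)) set.seed(seed)
  strength <- switch(strength_mode,
                     gaussian = stats::rnorm(length(perturbed)),
                     knockout = rep(-5, length(perturbed)))
  experiments <- data.frame(
    node = rep(perturbed, each = n_replicates),
    replicate = rep(seq_len(n_replicates), times = length(perturbed)),
    strength = rep(strength, each = n_replicates))
  structure(list(experiments = experiments, n_wt = as.integer(n_wt),
                 q = length(perturbed) / n, n_nodes = n,
                 perturbable = perturbed),
            class = "perturbation_design")
}

#' Draw link weights for a generated topology
#'
#' Off-diagonal interaction strengths are drawn uniformly from
#' `[-1.5, -0.5] U [0.5, 1.5]` and, if necessary, scaled down by a common
#' factor until the interaction matrix `A` (diagonal -1) is stable with a
#' margin (all eigenvalue real parts below `-margin`) and the steady-state
#' gain is bounded (no off-diagonal entry of `A^-1` exceeds `gain_cap` in
#' magnitude).  The gain cap bounds the amplification of perturbations
#' along long paths and feedback cycles, keeping simulated responses on a
#' realistic log2 scale; cascades in real transcriptional networks are
#' strongly damped.
#'
#' @param net a `directed_network`.
#' @param seed optional integer seed.
#' @param range absolute weight range.
#' @param unit set all weights to exactly 1 instead (linear links of slope
#'   one, the regime in which F(q) is derived); the gain cap is then
#'   disabled so that link functions keep slope one.
#' @param margin stability margin (default 0.5).
#' @param gain_cap bound on the total steady-state gain between any node
#'   pair (default 3).
#' @return the network with a `weights` field.
#' @export
assign_link_weights <- function(net, seed = NULL, range = c(0.5, 1.5),
                                unit = FALSE, margin = 0.5, gain_cap = 3) {
  if (!is.null(seed)) set.seed(seed)
  ne <- nrow(net$edges)
  w <- if (unit) {
    rep(1, ne)
  } else {
    stats::runif(ne, range[1], range[2]) * sample(c(-1, 1), ne, replace = TRUE)
  }
  for (iter in 1:80) {
    A <- interaction_matrix(directed_network(net$n_nodes, net$edges, w))
    stable <- max(Re(eigen(A, only.values = TRUE)$values)) < -margin
    gain_ok <- unit || {
      Ai <- tryCatch(solve(A), error = function(e) NULL)
      !is.null(Ai) && max(abs(Ai - diag(diag(Ai)))) <= gain_cap
    }
    if (stable && gain_ok) break
    w <- w * 0.9
  }
  directed_network(net$n_nodes, net$edges, w)
}

#' Interaction matrix of a weighted network
#'
#' `A[i, j]` is the direct effect of node `j` on node `i`; the diagonal is
#' the restoring force, fixed to -1.
#'
#' @param net a weighted `directed_network`.
#' @return the N x N interaction matrix.
#' @export
interaction_matrix <- function(net) {
  if (is.null(net$weights)) stop("network has no link weights")
  A <- diag(-1, net$n_nodes)
  A[cbind(net$edges[, 2], net$edges[, 1])] <- net$weights
  A
}

# Measurement-noise standard deviations for a log2 fold-change matrix.
noise_sd_matrix <- function(y, sigma, noise_mode) {
  switch(noise_mode,
         none = array(0, dim(y)),
         constant = array(sigma, dim(y)),
         # sigma = relative error on the expression level; on the log2 scale
         # this is a constant standard deviation sigma * log2(e)
         expr_fraction = array(sigma * log2(exp(1)), dim(y)),
         # sigma = fraction of the log2 fold change itself, floored
         fc_fraction = pmax(sigma * abs(y), 0.01),
         stop(sprintf("unknown noise_mode '%s'", noise_mode)))
}

#' Simulate a knockout screen from the linear steady-state model
#'
#' Solves `0 = A (y - y_ref) + B u` per experiment (so
#' `y = y_ref - A^{-1} B u`, with `y_ref = 0` on the log2 fold-change
#' scale) and adds Gaussian measurement noise.  Perturbation forces are
#' taken from the design; because the downstream estimators re-centre the
#' data at the sample mean, the model's requirement that the forces average
#' to zero over the experiment set is met automatically.
#'
#' @param net a weighted `directed_network` whose interaction matrix is
#'   stable (use [assign_link_weights()]).
#' @param design a [perturbation_design()].
#' @param sigma noise scale; its meaning depends on `noise_mode`.
#' @param noise_mode `"expr_fraction"` (default: `sigma` is the relative
#'   error of the expression level, a constant sd of `sigma * log2(e)` on
#'   the log2 scale), `"fc_fraction"` (sd is `sigma` times the absolute
#'   log2 fold change, floored at 0.01), `"constant"` (sd = `sigma`) or
#'   `"none"`.
#' @param seed optional integer seed for the noise draws.
#' @return an [expression_dataset()] with attribute `"noiseless"` holding
#'   the noise-free matrix.
#' @export
simulate_linear_knockouts <- function(net, design, sigma = 0.1,
                                      noise_mode = c("expr_fraction",
                                                     "fc_fraction",
                                                     "constant", "none"),
                                      seed = NULL) {
  noise_mode <- match.arg(noise_mode)
  stopifnot(inherits(design, "perturbation_design"))
  A <- interaction_matrix(net)
  sp <- eigen(A, only.values = TRUE)$values
  if (max(Re(sp)) >= 0) {
    stop(sprintf("unstable interaction matrix: max Re(eigenvalue) = %.3f (spectrum: %s)",
                 max(Re(sp)), paste(sprintf("%.2f", Re(sp)), collapse = ", ")))
  }
  n <- net$n_nodes
  Ainv <- solve(A)
  ex <- design$experiments
  P <- nrow(ex) + design$n_wt
  y <- matrix(0, n, P)
  for (k in seq_len(nrow(ex))) {
    f <- numeric(n)
    f[ex$node[k]] <- ex$strength[k]
    y[, k] <- -Ainv %*% f
  }
  genes <- paste0("G", seq_len(n))
  pert <- c(genes[ex$node], rep(NA_character_, design$n_wt))
  repl <- c(ex$replicate, seq_len(design$n_wt))
  cn <- c(sprintf("ko_%s_r%d", genes[ex$node], ex$replicate),
          if (design$n_wt > 0) sprintf("wt_r%d", seq_len(design$n_wt)))
  dimnames(y) <- list(genes, cn)
  y_clean <- y
  if (noise_mode != "none") {
    if (!is.null(seed)) set.seed(seed)
    sd <- noise_sd_matrix(y, sigma, noise_mode)
    y <- y + stats::rnorm(length(y)) * sd
  }
  out <- expression_dataset(y, pert, repl)
  attr(out, "noiseless") <- y_clean
  out
}

# Hill regulation term for one parent.
hill_term <- function(x, K, h, activating) {
  xh <- pmax(x, 0)^h
  if (activating) xh / (K^h + xh) else K^h / (K^h + xh)
}

#' Simulate a knockout screen from a nonlinear ODE steady-state model
#'
#' Node activities follow `dx_i/dt = b_i * prod_j reg_ij(x_j) - x_i` with
#' Hill-type activation `x^h / (K^h + x^h)` or repression
#' `K^h / (K^h + x^h)` for each parent (sign of the link weight), Hill
#' coefficients in {1, 2} and `K` and maximal rates drawn log-uniformly.  A
#' knockout sets the perturbed gene's production to a small basal leak, so
#' its own log2 fold change is strongly negative but bounded by the
#' expression floor.  Steady states are found by relaxation with
#' \pkg{deSolve}; non-convergent experiments are flagged and excluded.
#' Output is `log2(x_perturbed / x_wildtype)` plus Gaussian noise.
#'
#' @param net a `directed_network` (weights only contribute their signs;
#'   unweighted links are treated as activating).
#' @param design a [perturbation_design()] (strengths are ignored: knockout
#'   semantics).
#' @param noise_sd_fraction noise scale passed to the chosen `noise_mode`.
#' @param noise_mode as in [simulate_linear_knockouts()].
#' @param seed integer seed for the kinetic parameters.
#' @param noise_seed separate seed for the noise draws (defaults to a
#'   stream derived from `seed`), so that datasets differing only in noise
#'   share the same noiseless core.
#' @param t_max relaxation horizon; convergence requires
#'   `max |dx/dt| < 1e-6` at `t_max`.
#' @return an [expression_dataset()] with attributes `"noiseless"` and
#'   `"excluded_experiments"`.
#' @export
simulate_nonlinear_knockouts <- function(net, design, noise_sd_fraction = 0.1,
                                         noise_mode = c("expr_fraction",
                                                        "fc_fraction",
                                                        "constant", "none"),
                                         seed = 1, noise_seed = NULL,
                                         t_max = 200) {
  noise_mode <- match.arg(noise_mode)
  stopifnot(inherits(design, "perturbation_design"))
  n <- net$n_nodes
  set.seed(derive_seed(seed, "kinetics"))
  parents <- vector("list", n)
  signs <- vector("list", n)
  for (e in seq_len(nrow(net$edges))) {
    t <- net$edges[e, 2]
    parents[[t]] <- c(parents[[t]], net$edges[e, 1])
    w <- if (is.null(net$weights)) 1 else net$weights[e]
    signs[[t]] <- c(signs[[t]], sign(w))
  }
  b <- exp(stats::runif(n, log(0.5), log(2)))
  K <- exp(stats::runif(n, log(0.5), log(2)))
  h <- sample(1:2, n, replace = TRUE)
  leak <- 1e-3

  deriv <- function(t, x, parms) {
    prod_on <- parms$prod_on
    p <- b
    for (i in seq_len(n)) {
      if (length(parents[[i]]) > 0) {
        for (a in seq_along(parents[[i]])) {
          p[i] <- p[i] * hill_term(x[parents[[i]][a]], K[i], h[i],
                                   signs[[i]][a] > 0)
        }
      }
    }
    list(p * prod_on + leak - x)
  }
  steady <- function(prod_on, x0) {
    sol <- deSolve::ode(y = x0, times = c(0, t_max / 2, t_max), func = deriv,
                        parms = list(prod_on = prod_on))
    xT <- sol[nrow(sol), -1]
    dx <- unlist(deriv(0, xT, list(prod_on = prod_on)))
    list(x = pmax(xT, 1e-9), converged = max(abs(dx)) < 1e-6)
  }

  wt <- steady(rep(1, n), rep(1, n))
  if (!wt$converged) stop("wild-type steady state did not converge")
  ex <- design$experiments
  genes <- paste0("G", seq_len(n))
  cols <- list(); pert <- character(0); repl <- integer(0); nm <- character(0)
  excluded <- integer(0)
  cache <- list()
  for (k in seq_len(nrow(ex))) {
    g <- ex$node[k]
    key <- as.character(g)
    if (is.null(cache[[key]])) {
      prod_on <- rep(1, n); prod_on[g] <- 0
      st <- steady(prod_on, wt$x)
      cache[[key]] <- st
    }
    st <- cache[[key]]
    if (!st$converged) {
      excluded <- c(excluded, k)
      next
    }
    cols[[length(cols) + 1]] <- log2(st$x / wt$x)
    pert <- c(pert, genes[g])
    repl <- c(repl, ex$replicate[k])
    nm <- c(nm, sprintf("ko_%s_r%d", genes[g], ex$replicate[k]))
  }
  if (design$n_wt > 0) {
    for (k in seq_len(design$n_wt)) {
      cols[[length(cols) + 1]] <- rep(0, n)
      pert <- c(pert, NA_character_)
      repl <- c(repl, k)
      nm <- c(nm, sprintf("wt_r%d", k))
    }
  }
  y <- do.call(cbind, cols)
  dimnames(y) <- list(genes, nm)
  y_clean <- y
  if (noise_mode != "none") {
    set.seed(noise_seed %||% derive_seed(seed, "noise"))
    sd <- noise_sd_matrix(y, noise_sd_fraction, noise_mode)
    y <- y + stats::rnorm(length(y)) * sd
  }
  out <- expression_dataset(y, pert, repl)
  attr(out, "noiseless") <- y_clean
  attr(out, "excluded_experiments") <- excluded
  out
}

#' Three-node chain demonstration datasets
#'
#' The canonical noise-induced false-positive setting: a chain
#' `1 -> 2 -> 3` (two links, unit strengths) with independent perturbations
#' applied to nodes 1 and 2.  One dataset is generated per measurement-noise
#' level; with rising noise on the intermediate node, partial correlations
#' report a spurious direct link `1 -> 3`, while the PRC minimum strength
#' stays near zero.
#'
#' @param noise_grid numeric vector of constant noise standard deviations.
#' @param n_experiments independently perturbed experiments per perturbed
#'   node.
#' @param n_wt wild-type replicates appended to each dataset.
#' @param seed integer seed (forces are shared across noise levels; noise
#'   draws use a derived stream per level).
#' @return list of [expression_dataset()]s, one per noise level, each with
#'   attribute `"noise_sd"`.
#' @export
make_three_node_demo <- function(noise_grid, n_experiments = 100, n_wt = 30,
                                 seed = 1) {
  net <- directed_network(3, rbind(c(1, 2), c(2, 3)), weights = c(1, 1))
  A <- interaction_matrix(net)
  Ainv <- solve(A)
  set.seed(derive_seed(seed, "forces"))
  u1 <- stats::rnorm(n_experiments)
  u2 <- stats::rnorm(n_experiments)
  y <- matrix(0, 3, 2 * n_experiments + n_wt)
  for (k in seq_len(n_experiments)) {
    y[, k] <- -Ainv %*% c(u1[k], 0, 0)
    y[, n_experiments + k] <- -Ainv %*% c(0, u2[k], 0)
  }
  genes <- paste0("G", 1:3)
  pert <- c(rep("G1", n_experiments), rep("G2", n_experiments),
            rep(NA_character_, n_wt))
  repl <- c(seq_len(n_experiments), seq_len(n_experiments), seq_len(n_wt))
  dimnames(y) <- list(genes, sprintf("s%03d", seq_len(ncol(y))))
  # every experiment has its own force, so each is its own condition
  cond <- c(sprintf("e%03d", seq_len(2 * n_experiments)),
            rep(".wt", n_wt))
  lapply(noise_grid, function(s) {
    set.seed(derive_seed(seed, paste0("noise", s)))
    d <- expression_dataset(y + stats::rnorm(length(y)) * s, pert, repl,
                            cond)
    attr(d, "noise_sd") <- s
    d
  })
}
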