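# Partial response coefficients (PRC).
#
# Model: steady-state log-scale activities obey 0 = A (y - y_ref) + B u with
# A negative definite (A_ij = direct effect of j on i) and observations
# y_obs = y + eps, eps ~ N(0, sigma^2 D).  The covariance of y_obs is then
# C = A^-1 B B^T A^-T + sigma^2 D, and the maximum-likelihood decomposition
# of the sample covariance (probabilistic PCA) yields eigenvectors whose
# null-space components give link strengths that do not depend on sigma^2:
# the estimators below are asymptotically unbiased with respect to additive
# measurement noise.

#' Unbiased sample covariance with optional shrinkage regularisation
#'
#' The reference state is the sample mean, and the maximum-likelihood
#' covariance is rescaled by `P/(P-1)` to the unbiased estimate.  When the
#' covariance is rank deficient (fewer independent samples than observables,
#' or degenerate data) it is regularised as `(1 - epsilon) S + epsilon I`, so
#' that the noise floor remains estimable; the return value records whether
#' regularisation fired.
#'
#' @param x numeric matrix, observables (genes) in rows, samples in columns.
#' @param epsilon shrinkage weight used when the covariance is rank
#'   deficient (default 0.05).
#' @return list with `S` (possibly regularised covariance), `S_raw`
#'   (unregularised), `regularized` flag, `epsilon`, `n_samples` and
#'   `y_ref` (the sample mean).
#' @export
sample_covariance <- function(x, epsilon = 0.05) {
  x <- as.matrix(x)
  P <- ncol(x)
  if (P < 2) stop("at least 2 samples are required for a sample covariance")
  y_ref <- rowMeans(x)
  xc <- x - y_ref
  S <- tcrossprod(xc) / (P - 1)
  rk <- qr(S, tol = 1e-10)$rank
  regularized <- rk < nrow(S)
  out <- list(S = S, S_raw = S, regularized = regularized,
              epsilon = epsilon, n_samples = P, y_ref = y_ref)
  if (regularized && epsilon > 0) {
    out$S <- (1 - epsilon) * S + epsilon * diag(nrow(S))
  }
  out
}

#' Maximum-likelihood covariance decomposition (probabilistic PCA)
#'
#' Eigendecomposition of the noise-whitened covariance
#' `D^(-1/2) S D^(-1/2)` with `D = diag(r)`.  The `N0` smallest eigenvalues
#' correspond to the observables that receive no perturbation in the current
#' data subset (the left null space of `A^-1 B`); their mean estimates the
#' measurement-noise level `sigma^2`, and the remaining signal singular
#' values are `sqrt(Lambda_k - sigma^2)` (clipped at zero when sampling
#' fluctuations push an eigenvalue below the noise floor).
#'
#' @param S symmetric covariance matrix (or the result of
#'   [sample_covariance()]).
#' @param N0 number of unperturbed observables in the data subset (set from
#'   the experimental design, not estimated from the spectrum).
#' @param r optional vector of scaled noise variances `r_i = sigma_i^2 /
#'   sigma^2` (default isotropic, all 1).
#' @return object of class `ppca_decomposition`: `values` (ascending
#'   eigenvalues of the whitened covariance), `vectors` (orthonormal
#'   eigenvectors, columns matching `values`), `sigma2`, `Sigma` (signal
#'   singular values), `N0`, `r`, `n_clipped`, and `degenerate` (TRUE when
#'   the split between null and signal eigenvalues is a numerical tie, in
#'   which case the null-space orientation is determined by sampling noise).
#' @export
ppca_decompose <- function(S, N0, r = NULL) {
  if (is.list(S) && !is.null(S$S)) S <- S$S
  S <- as.matrix(S)
  N <- nrow(S)
  stopifnot(N0 >= 1)
  if (N0 >= N) stop("N0 must be smaller than the number of observables (no signal subspace)")
  if (is.null(r)) r <- rep(1, N)
  stopifnot(length(r) == N, all(r > 0))
  iw <- 1 / sqrt(r)
  Sw <- S * tcrossprod(iw)
  eg <- eigen(Sw, symmetric = TRUE)
  ord <- order(eg$values) # ascending
  values <- eg$values[ord]
  vectors <- eg$vectors[, ord, drop = FALSE]
  # deterministic sign: largest-magnitude component positive
  for (k in seq_len(ncol(vectors))) {
    pk <- which.max(abs(vectors[, k]))
    if (vectors[pk, k] < 0) vectors[, k] <- -vectors[, k]
  }
  sigma2 <- mean(values[seq_len(N0)])
  Sigma <- numeric(N)
  excess <- values - sigma2
  idx <- seq.int(N0 + 1, N)
  Sigma[idx] <- sqrt(pmax(excess[idx], 0))
  structure(list(values = values, vectors = vectors, sigma2 = sigma2,
                 Sigma = Sigma, N0 = as.integer(N0), r = r,
                 S_whitened = Sw,
                 n_clipped = sum(excess[idx] < 0),
                 degenerate = N0 < N &&
                   (values[N0 + 1] - values[N0]) < 1e-12),
            class = "ppca_decomposition")
}

#' @export
print.ppca_decomposition <- function(x, ...) {
  cat(sprintf("ppca_decomposition: N = %d, N0 = %d, sigma2_hat = %.4g%s\n",
              length(x$values), x$N0, x$sigma2,
              if (x$degenerate) " (degenerate null space)" else ""))
  invisible(x)
}

#' PRC row estimate when a single observable is unperturbed
#'
#' With node `i` the only unperturbed observable (`N0 = 1`), the i-th row of
#' the interaction matrix is proportional to the smallest-eigenvalue
#' eigenvector of the whitened covariance, un-whitened by `D^(-1/2)`:
#' `A_ij / A_ii = (U_j1 / sqrt(r_j)) / (U_i1 / sqrt(r_i))`.  The measurement
#' noise `sigma^2` shifts eigenvalues but not eigenvectors, so the estimate
#' is invariant to the noise level.  The row is returned on the conventional
#' `A_ii := -1` scale, so that entry `j` is directly comparable to the
#' planted regulatory gain of link `j -> i`.
#'
#' @param decomp a `ppca_decomposition` with `N0 = 1`.
#' @param i index of the unperturbed target observable.
#' @param tol identifiability tolerance on the target's component in the
#'   null direction.
#' @return numeric vector: the i-th row of A with `A_ii = -1`.
#' @export
prc_row_single_unperturbed <- function(decomp, i, tol = 1e-8) {
  stopifnot(inherits(decomp, "ppca_decomposition"))
  if (decomp$N0 != 1) {
    stop("prc_row_single_unperturbed requires N0 = 1 (a single unperturbed observable)")
  }
  u <- decomp$vectors[, 1]
  a <- u / sqrt(decomp$r) # un-whitened row direction
  if (abs(a[i]) < tol * max(abs(a))) {
    stop(sprintf("row not identifiable: target %d carries no weight in the null direction", i))
  }
  ratio <- a / a[i] # A_ij / A_ii
  row <- -ratio     # A_ii := -1
  row[i] <- -1
  row
}

# Internal single-pair PRC engine.
#
# Y          genes x samples matrix (already replicate-averaged or not)
# pert       per-sample perturbed gene NAME (NA = wild type); knockouts
#            of genes outside the observable set still count as
#            perturbation directions
# i, j       target and source row indices
# r          scaled noise variances per gene
# type       "min" (alternative routes subtracted via the null-space
#            projection of the j-removed covariance) or "max" (off-diagonal
#            A' set to zero: the plain two-node errors-in-variables problem)
#
# The null-space dimension of the reduced system counts one signal
# direction per distinct knockout in the kept samples (including knockouts
# of the unobserved source j, whose perturbative effect stays in the data):
# observables reached by those perturbations are treated as perturbed.
# When the target carries no weight in that null space, no combination of
# the other observables explains its variation - there are no alternative
# routes and the minimum falls back to the plain two-node problem.
#
# Returns list(strength, coeffs, D2, n_samples).
prc_pair_engine <- function(Y, pert, i, j, r, type = c("min", "max"),
                            epsilon = 0.05, tol = 1e-10) {
  type <- match.arg(type)
  gn <- rownames(Y) %||% paste0("G", seq_len(nrow(Y)))
  keep <- is.na(pert) | pert != gn[i]
  if (!any(!is.na(pert[keep]) & pert[keep] == gn[j])) {
    stop("source node has no perturbation experiments once the target's are removed")
  }
  Y <- Y[, keep, drop = FALSE]
  pert <- pert[keep]
  P <- ncol(Y)
  if (P < 3) stop("too few samples after removing the target's perturbation experiments")
  N <- nrow(Y)

  coeffs <- NULL
  if (type == "min" && N > 2) {
    red <- setdiff(seq_len(N), j)
    Yr <- Y[red, , drop = FALSE]
    rr <- r[red]
    n_ko <- length(unique(pert[!is.na(pert)]))
    N0r <- max(1L, (N - 1L) - n_ko)
    if (N0r < length(red)) {
      Sr <- sample_covariance(Yr, epsilon = epsilon)$S_raw
      iw <- 1 / sqrt(rr)
      Sw <- Sr * tcrossprod(iw)
      eg <- eigen(Sw, symmetric = TRUE)
      ord <- order(eg$values)
      U0 <- eg$vectors[, ord[seq_len(N0r)], drop = FALSE]
      ii <- match(i, red)
      proj <- U0 %*% U0[ii, ] # null-space projector row of the target
      a <- as.numeric(proj) * iw # un-whitened A' row direction
      if (abs(a[ii]) >= tol * max(abs(a), tol)) {
        coeffs <- a / a[ii] # A'_il / A'_ii, with coeffs[ii] = 1
      }
    }
  }

  if (is.null(coeffs)) {
    # plain two-node problem (max strength, or min with nothing to subtract)
    y2 <- Y[i, ]
    D2 <- r[i]
  } else {
    red <- setdiff(seq_len(N), j)
    cfull <- numeric(N)
    cfull[red] <- coeffs
    y2 <- as.numeric(crossprod(cfull, Y))
    D2 <- sum(coeffs^2 * r[red])
  }
  strength <- two_node_strengths(matrix(Y[j, ], ncol = 1),
                                 matrix(y2, ncol = 1), r[j], D2, tol)
  list(strength = strength, coeffs = coeffs, D2 = D2, n_samples = P)
}

# Resolve gene identifiers (names or indices) against a dataset.
resolve_gene <- function(data, g) {
  if (is.character(g)) {
    idx <- match(g, data$genes)
    if (is.na(idx)) stop(sprintf("unknown gene '%s'", g))
    idx
  } else {
    as.integer(g)
  }
}

# Shared front-end for the exported min/max strength estimators.
prc_strength <- function(data, i, j, noise = NULL, type, epsilon = 0.05) {
  stopifnot(inherits(data, "expression_dataset"))
  i <- resolve_gene(data, i)
  j <- resolve_gene(data, j)
  if (i == j) stop("source and target must differ")
  r <- noise_ratios_for(data, noise)
  res <- prc_pair_engine(data$values, data$perturbed, i, j, r, type = type,
                         epsilon = epsilon)
  res$strength
}

#' Minimum relative link strength (alternative routes subtracted)
#'
#' Estimates a lower bound for the strength of the directed link `j -> i`.
#' Experiments perturbing `i` are removed; node `j` is removed from the
#' observables while keeping its perturbative effect in the data; the
#' remaining network's link strengths `A'` onto `i` are read off the null
#' space of the reduced whitened covariance; and the two-node residual
#' problem between `y_j` and `y_i + sum_l (A'_il / A'_ii) y_l` is solved by
#' the noise-whitened smallest-eigenvector (errors-in-variables) estimator.
#' The result is reported on the `A_ii := -1` scale.  Variation of the
#' target that any other observable can explain is credited to the
#' alternative routes, so the estimate is conservative: it approaches the
#' true strength when the source is uncorrelated with the remaining
#' observables and approaches zero when the link is absent, independently of
#' the measurement-noise level.
#'
#' @param data an [expression_dataset()].
#' @param i target gene (name or index).
#' @param j source gene (name or index); must be perturbed in the data.
#' @param noise optional [replicate_residuals()] noise model supplying the
#'   scaled variances `r`; defaults to isotropic noise.
#' @param epsilon covariance regularisation weight.
#' @return scalar strength estimate (NA when not identifiable).
#' @export
prc_min_strength <- function(data, i, j, noise = NULL, epsilon = 0.05) {
  prc_strength(data, i, j, noise, type = "min", epsilon = epsilon)
}

#' Maximum relative link strength (total effect)
#'
#' As [prc_min_strength()] but with the off-diagonal elements of `A'` set to
#' zero: the residual pair is `(y_j, y_i)` and the estimate captures the
#' total (direct plus indirect) effect of `j` on `i` as a two-node
#' errors-in-variables slope.
#'
#' @inheritParams prc_min_strength
#' @return scalar strength estimate (NA when not identifiable).
#' @export
prc_max_strength <- function(data, i, j, noise = NULL, epsilon = 0.05) {
  prc_strength(data, i, j, noise, type = "max", epsilon = epsilon)
}

#' Classify a link as inferable or non-inferable from bootstrap samples
#'
#' A link is non-inferable when (i) the bootstrap interval of the difference
#' between maximum and minimum strength magnitudes excludes zero — the two
#' estimates disagree, so alternative routes carry part of the effect — and
#' (ii) the bootstrap interval of the minimum strength includes zero — no
#' variation of the target is attributable to the source alone.  Otherwise
#' the link is inferable.
#'
#' @param min_samples,max_samples paired bootstrap samples of the minimum
#'   and maximum strengths (same replicates, same length).
#' @param alpha interval level (default 0.05: 95% intervals).
#' @param zero_tol numerical tolerance around zero, for degenerate
#'   (noise-free) bootstrap distributions.
#' @return TRUE if the link is inferable.
#' @export
classify_link_inferability <- function(min_samples, max_samples,
                                       alpha = 0.05, zero_tol = 1e-8) {
  min_samples <- min_samples[is.finite(min_samples)]
  max_samples <- max_samples[is.finite(max_samples)]
  if (length(min_samples) == 0 || length(max_samples) == 0) {
    stop("empty bootstrap distributions")
  }
  n <- min(length(min_samples), length(max_samples))
  dif <- abs(max_samples[seq_len(n)]) - abs(min_samples[seq_len(n)])
  ci_d <- stats::quantile(dif, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  ci_m <- stats::quantile(min_samples, c(alpha / 2, 1 - alpha / 2),
                          names = FALSE)
  diff_sig <- ci_d[1] > zero_tol || ci_d[2] < -zero_tol
  min_zero <- ci_m[1] <= zero_tol && ci_m[2] >= -zero_tol
  !(diff_sig && min_zero)
}
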