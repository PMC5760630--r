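# Covariance decomposition and the PRC estimators.

test_that("sample covariance is unbiased and regularises rank-deficient input", {
  x <- cbind(c(0, 0), c(2, 2))
  sc <- sample_covariance(x)
  expect_equal(sc$S_raw, matrix(2, 2, 2))
  expect_true(sc$regularized) # rank 1 < 2
  # constant data collapses to epsilon * I
  sc0 <- sample_covariance(matrix(1, 3, 5), epsilon = 0.05)
  expect_equal(sc0$S, 0.05 * diag(3))
  # full-rank data with P > N stays untouched
  set.seed(1)
  scf <- sample_covariance(matrix(rnorm(3 * 50), 3, 50))
  expect_false(scf$regularized)
  expect_identical(scf$S, scf$S_raw)
  expect_error(sample_covariance(matrix(1, 3, 1)), "2 samples")
})

test_that("ppca decomposition recovers the hand-computed spectrum", {
  d <- ppca_decompose(diag(c(4, 1)), N0 = 1)
  expect_equal(d$values, c(1, 4))
  expect_equal(d$sigma2, 1)
  expect_equal(d$Sigma, c(0, sqrt(3)))
  # pure noise: N0 = N - 1
  dn <- ppca_decompose(2 * diag(4), N0 = 3)
  expect_equal(dn$sigma2, 2)
  expect_equal(dn$Sigma[4], 0)
  expect_error(ppca_decompose(diag(3), N0 = 3), "signal subspace")
})

test_that("forward-constructed covariances are recovered to machine precision", {
  set.seed(7)
  for (rep in 1:5) {
    N <- 6
    U <- qr.Q(qr(matrix(rnorm(N * N), N)))
    Sig <- c(0, 0, sort(runif(N - 2, 0.5, 3)))
    s2 <- 0.3
    S <- U %*% diag(Sig^2 + s2) %*% t(U)
    d <- ppca_decompose(S, N0 = 2)
    expect_equal(d$sigma2, s2, tolerance = 1e-10)
    expect_equal(sort(d$Sigma[3:N]), sort(Sig[3:N]), tolerance = 1e-8)
    # reconstruction identity on the whitened covariance
    rec <- d$vectors %*% diag(d$Sigma^2 + d$sigma2) %*% t(d$vectors)
    expect_lt(max(abs(rec - d$S_whitened)), 1e-8)
  }
})

test_that("single-unperturbed-row estimate is exact and noise invariant", {
  a <- 2
  base <- matrix(c(1, a, a, a^2), 2, 2)
  rows <- lapply(c(0, 0.5, 10), function(s2) {
    prc_row_single_unperturbed(ppca_decompose(base + s2 * diag(2), N0 = 1), 2)
  })
  for (row in rows) {
    expect_equal(unname(row[1] / row[2]), -a, tolerance = 1e-10)
    expect_equal(unname(row[2]), -1)
  }
  # sigma-invariance to tight tolerance across the noise grid
  expect_lt(max(abs(rows[[1]] - rows[[3]])), 1e-10)
  # anisotropic noise: whitening must cancel out of the ratio
  r <- c(4, 0.25)
  Sw_input <- base + 0.2 * diag(r)
  row_an <- prc_row_single_unperturbed(ppca_decompose(Sw_input, N0 = 1, r = r), 2)
  expect_equal(unname(row_an[1]), a, tolerance = 1e-10)
  # target orthogonal to the null direction is not identifiable
  expect_error(prc_row_single_unperturbed(ppca_decompose(diag(c(0.1, 2)), 1), 2),
               "not identifiable")
})

test_that("full interaction matrix is recovered from a complete noise-free screen", {
  sc <- make_screen(n = 8, q = 1, n_rep = 2, n_wt = 10, noise_mode = "none",
                    strength_mode = "gaussian", seed = 3)
  A <- interaction_matrix(sc$net)
  err <- 0
  for (i in 1:8) {
    keep <- is.na(sc$data$perturbed) | sc$data$perturbed != paste0("G", i)
    sub <- subset_dataset(sc$data, samples = keep)
    S <- sample_covariance(sub$values, epsilon = 0)$S_raw
    row <- prc_row_single_unperturbed(ppca_decompose(S, N0 = 1), i)
    err <- max(err, max(abs(row - A[i, ])))
  }
  expect_lt(err, 1e-6)
})

test_that("chain strengths behave as derived: false link null, true link bounded", {
  # chain 1 -> 2 -> 3 with unit weights, nodes 1 and 2 perturbed
  sets <- make_three_node_demo(c(0, 0.2), n_experiments = 4000, seed = 11)
  for (d in sets) {
    min13 <- prc_min_strength(d, "G3", "G1")
    max13 <- prc_max_strength(d, "G3", "G1")
    min23 <- prc_min_strength(d, "G3", "G2")
    max23 <- prc_max_strength(d, "G3", "G2")
    # false direct link: minimum stays at zero regardless of noise
    expect_lt(abs(min13), 0.05)
    # ... while the total (maximum) effect through node 2 is material
    expect_gt(abs(max13), 0.5)
    # true link: the maximum is the exact two-node slope (w = 1)
    expect_equal(max23, 1, tolerance = 0.05)
    # the minimum is a conservative positive lower bound
    expect_gt(min23, 0.1)
    expect_lte(abs(min23), abs(max23) + 0.05)
  }
  # derived population value of the lower bound for unit weights and unit
  # forces split over two perturbed nodes: 0.2325 (two-step total
  # least-squares computation on the population covariance)
  expect_equal(prc_min_strength(sets[[1]], "G3", "G2"), 0.2325,
               tolerance = 0.05)
})

test_that("direct-only pairs give min = max when the source is uncorrelated", {
  # j -> i plus an isolated perturbed bystander: no correlated covariates
  net <- directed_network(3, rbind(c(1, 2)), weights = 0.8)
  des <- perturbation_design(net, c(1, 3), n_replicates = 2, n_wt = 10,
                             strength_mode = "gaussian", seed = 5)
  dat <- simulate_linear_knockouts(net, des, noise_mode = "none")
  mn <- prc_min_strength(dat, "G2", "G1")
  mx <- prc_max_strength(dat, "G2", "G1")
  # up to the finite-sample correlation between the two perturbation
  # profiles (shared forces across replicates), min and max coincide
  expect_equal(mn, mx, tolerance = 0.05)
  expect_equal(mx, 0.8, tolerance = 1e-8)
  # absent link between independent perturbed nodes: max ~ 0
  expect_lt(abs(prc_max_strength(dat, "G3", "G1")), 1e-8)
})

test_that("inferability classification follows the two bootstrap conditions", {
  # degenerate equal distributions: inferable
  expect_true(classify_link_inferability(rep(0.8, 50), rep(0.8, 50)))
  # minimum at zero, maximum clearly away: non-inferable
  set.seed(2)
  expect_false(classify_link_inferability(rnorm(200, 0, 0.01),
                                          rnorm(200, 0.6, 0.01)))
  # minimum away from zero: inferable even if max differs
  expect_true(classify_link_inferability(rnorm(200, 0.4, 0.01),
                                         rnorm(200, 0.9, 0.01)))
  expect_error(classify_link_inferability(numeric(0), numeric(0)), "empty")
})
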