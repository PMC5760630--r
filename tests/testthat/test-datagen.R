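# Synthetic knockout-screen generators.

test_that("linear simulator satisfies its defining steady-state equation", {
  sc <- make_screen(n = 10, q = 0.6, n_rep = 2, n_wt = 5,
                    noise_mode = "none", strength_mode = "gaussian", seed = 7)
  A <- interaction_matrix(sc$net)
  y <- attr(sc$data, "noiseless")
  ex <- sc$design$experiments
  for (k in seq_len(nrow(ex))) {
    f <- numeric(10); f[ex$node[k]] <- ex$strength[k]
    expect_lt(max(abs(A %*% y[, k] + f)), 1e-10)
  }
  # wild-type block is the reference state
  expect_equal(max(abs(y[, sc$data$perturbed %in% NA])), 0)
  # zero perturbations leave every sample at the reference
  des0 <- perturbation_design(sc$net, integer(0), n_wt = 4)
  d0 <- simulate_linear_knockouts(sc$net, des0, noise_mode = "none")
  expect_equal(max(abs(d0$values)), 0)
})

test_that("fold changes propagate as products of link weights along a chain", {
  net <- net_chain3(weights = c(0.7, -1.2))
  des <- perturbation_design(net, 1, n_replicates = 1, n_wt = 0,
                             strength_mode = "gaussian", seed = 2)
  d <- simulate_linear_knockouts(net, des, noise_mode = "none")
  u <- des$experiments$strength[1]
  expect_equal(unname(d$values[, 1]), c(u, 0.7 * u, -1.2 * 0.7 * u),
               tolerance = 1e-12)
})

test_that("unstable interaction matrices are rejected with a spectrum report", {
  bad <- directed_network(3, rbind(c(1, 2), c(2, 3), c(3, 1)),
                          weights = c(2, 2, 2)) # cycle gain 8 > 1
  des <- perturbation_design(bad, 1:3)
  expect_error(simulate_linear_knockouts(bad, des), "unstable")
})

test_that("noise modes scale as declared", {
  net <- net_chain3(weights = c(1, 1))
  des <- perturbation_design(net, 1:2, n_replicates = 200, n_wt = 0,
                             strength_mode = "knockout", seed = 3)
  d_const <- simulate_linear_knockouts(net, des, sigma = 0.2,
                                       noise_mode = "constant", seed = 4)
  resid <- d_const$values - attr(d_const, "noiseless")
  expect_equal(sd(resid), 0.2, tolerance = 0.05)
  d_expr <- simulate_linear_knockouts(net, des, sigma = 0.1,
                                      noise_mode = "expr_fraction", seed = 5)
  expect_equal(sd(d_expr$values - attr(d_expr, "noiseless")),
               0.1 * log2(exp(1)), tolerance = 0.05)
  # fc_fraction: noise proportional to the signal, floored for null entries
  d_fc <- simulate_linear_knockouts(net, des, sigma = 0.1,
                                    noise_mode = "fc_fraction", seed = 6)
  rs <- d_fc$values - attr(d_fc, "noiseless")
  big <- abs(attr(d_fc, "noiseless")) > 3
  expect_gt(sd(rs[big]), 2 * sd(rs[abs(attr(d_fc, "noiseless")) < 1e-9]))
})

test_that("noiseless covariance converges to the model covariance", {
  # chain with independent standard-normal forces on nodes 1 and 2: the
  # model covariance is the mixture (C1 + C2)/2 with Ck = A^-1 e_k e_k' A^-T
  d <- make_three_node_demo(0, n_experiments = 5000, n_wt = 0, seed = 17)[[1]]
  A <- interaction_matrix(net_chain3(weights = c(1, 1)))
  Ainv <- solve(A)
  Cmodel <- (tcrossprod(Ainv[, 1]) + tcrossprod(Ainv[, 2])) / 2
  S <- sample_covariance(d$values)$S_raw
  expect_equal(unname(S), Cmodel, tolerance = 0.1)
})

test_that("nonlinear knockouts are floored, reachability-consistent and seed-separable", {
  net <- assign_link_weights(generate_scale_free_network(20, 2.5, 2, seed = 5),
                             seed = 6)
  des <- perturbation_design(net, 1:20, n_replicates = 2, n_wt = 10,
                             strength_mode = "knockout", seed = 7)
  dat <- simulate_nonlinear_knockouts(net, des, 0.1, seed = 8)
  nl <- attr(dat, "noiseless")
  own <- vapply(1:20, function(g) {
    nl[g, which(dat$perturbed == paste0("G", g))[1]]
  }, numeric(1))
  expect_true(all(own < -1))   # knocked-out gene strongly down ...
  expect_true(all(own > -20))  # ... but bounded by the expression floor
  # genes unreachable from the knockout do not move (before noise)
  ed <- net$edges
  reach <- function(s) {
    r <- s
    repeat {
      nw <- unique(c(r, ed[ed[, 1] %in% r, 2]))
      if (length(nw) == length(r)) break
      r <- nw
    }
    r
  }
  off <- setdiff(1:20, reach(1))
  expect_lt(max(abs(nl[off, which(dat$perturbed == "G1")])), 1e-8)
  # same core with a different noise stream
  dat2 <- simulate_nonlinear_knockouts(net, des, 0.1, seed = 8,
                                       noise_seed = 123)
  expect_identical(attr(dat2, "noiseless"), nl)
  expect_false(identical(dat2$values, dat$values))
})

test_that("three-node demo exposes the noise-induced false-positive mechanism", {
  sets <- make_three_node_demo(c(0.05, 0.2, 0.6), n_experiments = 2500,
                               seed = 13)
  ratios <- vapply(sets, function(d) {
    pc <- partial_correlation_matrix(d)
    abs(pc[1, 3] / pc[2, 3])
  }, numeric(1))
  expect_true(all(diff(ratios) > 0)) # partial correlation grows with noise
  prc13 <- vapply(sets, function(d) abs(prc_min_strength(d, "G3", "G1")),
                  numeric(1))
  expect_lt(max(prc13), 0.06) # PRC stays near zero throughout
})
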