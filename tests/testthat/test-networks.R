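# Directed-network generation and the inferability theory.

test_that("network constructor enforces the structural invariants", {
  expect_error(directed_network(3, rbind(c(1, 1))), "self-loop")
  expect_error(directed_network(3, rbind(c(1, 2), c(2, 1))), "bidirectional")
  expect_error(directed_network(3, rbind(c(1, 2), c(1, 2))), "duplicate")
  expect_error(directed_network(3, rbind(c(1, 4))), "node indices")
  net <- net_chain3()
  expect_equal(out_degree(net), c(1L, 1L, 0L))
})

test_that("scale-free generator hits the requested mean degree and is reproducible", {
  net <- generate_scale_free_network(300, 2.5, 2, seed = 11)
  expect_equal(nrow(net$edges) / net$n_nodes, 2, tolerance = 0.01)
  net2 <- generate_scale_free_network(300, 2.5, 2, seed = 11)
  expect_identical(net$edges, net2$edges)
  # outgoing hubs: out-degree distribution much more skewed than in-degree
  expect_gt(max(out_degree(net)), max(tabulate(net$edges[, 2], 300)))
  # inverted direction gives the same undirected graph
  inc <- generate_scale_free_network(300, 2.5, 2, hub_mode = "incoming",
                                     seed = 11)
  expect_equal(unname(inc$edges[, c(2, 1)]), unname(net$edges))
  # tiny network: the edge count is fixed by the mean degree
  tiny <- generate_scale_free_network(3, 2.5, 0.67, seed = 1)
  expect_lte(nrow(tiny$edges), 2)
  expect_error(generate_scale_free_network(10, 2.5, 8, seed = 1),
               "infeasible")
})

test_that("random generator gives Poisson-like out-degrees at the requested mean", {
  net <- generate_random_network(100, 3, seed = 5)
  expect_equal(nrow(net$edges), 300)
  kd <- out_degree(net)
  expect_equal(mean(kd), 3, tolerance = 1e-9)
  # Poisson-like: variance close to the mean (hub-free)
  expect_lt(var(kd), 2 * mean(kd))
  small <- generate_random_network(2, 0.5, seed = 2)
  expect_lte(nrow(small$edges), 1)
  expect_error(generate_random_network(10, 6), "infeasible")
})

test_that("motif counting reproduces the canonical illustrative networks", {
  # two of three nodes perturbed: refined counting makes the network fully
  # inferable, motif counting flags the two links into the unperturbed sink
  res_m <- count_inferable_links(net_ffl(), c(1, 2), "motif")
  expect_equal(res_m$fraction, 2 / 3)
  res_r <- count_inferable_links(net_ffl(), c(1, 2), "refined")
  expect_equal(res_r$fraction, 1.0)
  # perturbed out-hub with unperturbed leaves: nothing is inferable
  hub <- net_out_hub(3)
  expect_equal(count_inferable_links(hub, 1, "motif")$count, 0L)
  expect_equal(count_inferable_links(hub, 1, "refined")$count, 0L)
  # all nodes perturbed: every link inferable
  net <- generate_random_network(12, 1.5, seed = 3)
  expect_true(all(count_inferable_links(net, 1:12, "motif")$flags))
  expect_error(count_inferable_links(net, 99), "subset")
})

test_that("refined counting dominates motif counting and is idempotent", {
  set.seed(42)
  for (rep in 1:20) {
    net <- generate_random_network(8, 1.5, seed = 100 + rep)
    pert <- which(runif(8) < 0.5)
    m <- count_inferable_links(net, pert, "motif")
    r <- count_inferable_links(net, pert, "refined")
    expect_gte(r$count, m$count)
    expect_true(all(r$flags | !m$flags)) # refined keeps every motif flag
    r2 <- count_inferable_links(net, pert, "refined")
    expect_identical(r$flags, r2$flags)
  }
})

test_that("closed-form F(q) equals the exhaustive motif expectation", {
  expect_equal(F_closed_form(net_single_edge(), 0.5), 0.5)
  expect_equal(expected_inferable_fraction(net_single_edge(), 0.5,
                                           exhaustive = TRUE), 0.5)
  expect_equal(F_closed_form(net_chain3(), 0.5), 0.4375)
  expect_equal(expected_inferable_fraction(net_chain3(), 0.5,
                                           exhaustive = TRUE), 0.4375)
  # per-edge probabilities are exact under Bernoulli perturbations, so the
  # identity holds on arbitrary small networks
  for (s in 1:5) {
    net <- generate_random_network(6, 1.2, seed = s)
    if (nrow(net$edges) == 0) next
    for (q in c(0.3, 0.7)) {
      expect_equal(F_closed_form(net, q),
                   expected_inferable_fraction(net, q, exhaustive = TRUE),
                   tolerance = 1e-12)
    }
  }
  expect_equal(F_closed_form(net_chain3(), 1), 1)
  expect_equal(F_closed_form(net_chain3(), 0), 0)
})

test_that("F(q) is monotone with F(0)=0 and F(1)=1", {
  for (s in 1:5) {
    net <- generate_scale_free_network(40, 2.5, 2, seed = s)
    Fv <- F_closed_form(net, seq(0, 1, 0.1))
    expect_true(all(diff(Fv) >= -1e-12))
    expect_equal(Fv[1], 0)
    expect_equal(Fv[11], 1)
  }
})

test_that("Monte Carlo estimate matches the exhaustive expectation", {
  net <- generate_random_network(7, 1.3, seed = 9)
  q <- 0.4
  exact <- expected_inferable_fraction(net, q, exhaustive = TRUE)
  set.seed(1)
  draws <- replicate(2000, count_inferable_links(
    net, which(runif(7) < q), "motif")$fraction)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - exact), 3 * se + 1e-12)
})

test_that("inferability measures reduce to closed forms on canonical graphs", {
  cs <- inferability_IF(net_single_edge())
  expect_equal(cs$I_F, 0.5, tolerance = 1e-4)
  expect_equal(cs$I_F_star, 0.5, tolerance = 1e-4)
  # ring (identical out-degree 1): I_F = I_F* = integral of q^2(2-q) = 5/12
  for (n in c(4, 9)) {
    rg <- inferability_IF(net_ring(n))
    expect_equal(rg$I_F, 5 / 12, tolerance = 1e-4)
    expect_equal(rg$I_F_star, 5 / 12, tolerance = 1e-4)
  }
  expect_error(inferability_IF(net_ring(4), q_grid = c(0.5, 0.2, 1)),
               "ascending")
})

test_that("Monte Carlo and closed-form inferability curves agree", {
  net <- generate_scale_free_network(60, 2.5, 2, seed = 4)
  cf <- inferability_IF(net, q_grid = seq(0, 1, 0.1))
  mc <- inferability_IF(net, q_grid = seq(0, 1, 0.1),
                        estimator = "monte_carlo", n_draws = 300, seed = 8)
  expect_equal(mc$I_F, cf$I_F, tolerance = 0.02)
})
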