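# Small canonical networks and datasets used across tests.

net_single_edge <- function() directed_network(2, rbind(c(1, 2)))

net_chain3 <- function(weights = NULL) {
  directed_network(3, rbind(c(1, 2), c(2, 3)), weights = weights)
}

# Fully inferable 3-node example: two perturbed nodes, one unperturbed sink.
net_ffl <- function() directed_network(3, rbind(c(1, 2), c(1, 3), c(2, 3)))

# Out-hub: one perturbed centre targeting unperturbed leaves.
net_out_hub <- function(leaves = 3) {
  directed_network(leaves + 1, cbind(1, 1 + seq_len(leaves)))
}

# Directed ring: every node has out-degree exactly 1.
net_ring <- function(n = 5) directed_network(n, cbind(1:n, c(2:n, 1)))

# Planted weighted network + linear knockout screen in one call.
make_screen <- function(n = 30, mean_degree = 2, q = 0.5, n_rep = 2,
                        n_wt = 30, sigma = 0.1, noise_mode = "expr_fraction",
                        strength_mode = "knockout", seed = 1,
                        gamma = 2.5) {
  net <- assign_link_weights(
    generate_scale_free_network(n, gamma, mean_degree,
                                seed = derive_seed_t(seed, "net")),
    seed = derive_seed_t(seed, "w"))
  pert <- perturbed_set(net, q, fixed_size = TRUE,
                        seed = derive_seed_t(seed, "pert"))
  des <- perturbation_design(net, pert, n_replicates = n_rep, n_wt = n_wt,
                             strength_mode = strength_mode,
                             seed = derive_seed_t(seed, "des"))
  dat <- simulate_linear_knockouts(net, des, sigma = sigma,
                                   noise_mode = noise_mode,
                                   seed = derive_seed_t(seed, "noise"))
  list(net = net, pert = pert, design = des, data = dat,
       truth_key = paste0("G", net$edges[, 1], "->G", net$edges[, 2]))
}

# local copy so helpers do not reach into internals
derive_seed_t <- function(master, key) {
  h <- 0
  for (cc in utf8ToInt(as.character(key))) h <- (h * 31 + cc) %% 2147483647
  as.integer((as.numeric(master) * 1000003 + h) %% 2147483629 + 1)
}

edge_keys <- function(el) paste0(el$source, "->", el$target)
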