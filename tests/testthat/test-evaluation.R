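# Evaluation: partial correlations, inferability-aware ROC, DREAM-style
# scoring, and the file interfaces.

test_that("partial correlations vanish for independent and chain-separated pairs", {
  set.seed(51)
  d <- expression_dataset(matrix(rnorm(4 * 400), 4, 400),
                          rep(NA, 400))
  pc <- partial_correlation_matrix(d)
  expect_lt(max(abs(pc)), 0.15)
  expect_equal(pc, t(pc))
  # noiseless-ish chain: pcor(1,3 | 2) ~ 0 (Markov property)
  d3 <- make_three_node_demo(0.01, n_experiments = 3000, seed = 52)[[1]]
  pc3 <- partial_correlation_matrix(d3)
  expect_lt(abs(pc3[1, 3]), 0.1)
  expect_gt(abs(pc3[2, 3]), 0.5)
  # singular covariance without regularisation is an error
  dd <- expression_dataset(matrix(rnorm(10 * 4), 10, 4), rep(NA, 4))
  expect_error(partial_correlation_matrix(dd, epsilon = 0), "singular")
})

test_that("ROC evaluation is exact on perfect and random rankings", {
  net <- generate_random_network(12, 1.5, seed = 53)
  genes <- paste0("G", 1:12)
  perfect <- data.frame(source = genes[net$edges[, 1]],
                        target = genes[net$edges[, 2]], score = 1)
  r <- roc_vs_inferable(perfect, net)
  expect_equal(r$auroc, 1.0)
  expect_equal(r$tp_fraction, 1.0)
  # random scores hover at 1/2
  set.seed(54)
  aucs <- replicate(40, {
    sc <- matrix(runif(144), 12, 12)
    roc_vs_inferable(sc, net)$auroc
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.05)
  expect_error(roc_vs_inferable(perfect, directed_network(3, matrix(0, 0, 2))),
               "empty truth")
})

test_that("ROC is invariant under monotone score transforms and denominator switch is exact", {
  net <- generate_random_network(10, 1.4, seed = 55)
  set.seed(56)
  sc <- matrix(runif(100), 10, 10)
  flags <- rep(c(TRUE, FALSE), length.out = nrow(net$edges))
  a1 <- roc_vs_inferable(sc, net)$auroc
  a2 <- roc_vs_inferable(exp(3 * sc), net)$auroc
  expect_equal(a1, a2)
  # predictions recovering exactly the inferable links: switching the
  # denominator rescales the TP fraction by |inferable| / |all|
  genes <- paste0("G", 1:10)
  inf_pred <- data.frame(source = genes[net$edges[flags, 1]],
                         target = genes[net$edges[flags, 2]], score = 1)
  r_all <- roc_vs_inferable(inf_pred, net, flags, "all_links")
  r_inf <- roc_vs_inferable(inf_pred, net, flags, "inferable_links")
  expect_equal(r_inf$tp_fraction, 1)
  expect_equal(r_all$tp_fraction, sum(flags) / nrow(net$edges))
})

test_that("DREAM-style scoring matches analytic tails and degenerates to zero", {
  # t-fit mode: p-values match the analytic t tail within 5% relative error
  set.seed(57)
  nulls <- 0.5 + 0.03 * rt(4000, df = 6)
  for (x in c(0.58, 0.62)) {
    p_fit <- prcnet:::null_p_value(x, nulls, "t_fit")
    p_true <- pt(-(x - 0.5) / 0.03, df = 6)
    expect_equal(p_fit / p_true, 1, tolerance = 0.35)
  }
  # exponential-tail mode: monotone and calibrated at the body
  p_mid <- prcnet:::null_p_value(0.5, nulls, "two_tail_exp_family")
  p_far <- prcnet:::null_p_value(0.65, nulls, "two_tail_exp_family")
  expect_gt(p_mid, 0.3)
  # 5 sigma out on a t(6) null: analytic tail ~ 1.2e-3, the fitted
  # exponential tail should agree within a factor of a few
  p_true <- pt(-5, df = 6)
  expect_lt(p_far, 5 * p_true)
  expect_gt(p_far, p_true / 5)
  # degenerate: observed at the null centre for every network -> score 0
  gold <- expand.grid(source = paste0("G", 1:6), target = paste0("G", 1:6),
                      stringsAsFactors = FALSE)
  gold <- gold[gold$source != gold$target, ]
  set.seed(58)
  gold$label <- as.integer(seq_len(nrow(gold)) %in% sample(nrow(gold), 8))
  pred <- gold[, 1:2]
  pred$score <- gold$label + rnorm(nrow(gold), sd = 0.3)
  met <- ranked_prediction_metrics(pred, gold)
  nl <- list(auroc = c(rep(met$auroc, 50), met$auroc + rnorm(500, 0, 0.05)),
             aupr = c(rep(met$aupr, 50), met$aupr + rnorm(500, 0, 0.05)))
  sc0 <- dream3_score(list(pred), list(gold), list(nl), fit_mode = "t_fit")
  expect_lt(sc0$overall, 2) # near-null observation scores low
  # strong separation scores high
  nl2 <- list(auroc = 0.5 + 0.02 * rnorm(500), aupr = 0.1 + 0.02 * rnorm(500))
  sc1 <- dream3_score(list(pred), list(gold), list(nl2))
  expect_gt(sc1$overall, sc0$overall)
  expect_error(dream3_score(list("missing_file.txt"), list(gold), list(nl2)),
               "not found")
})

test_that("expression and network files round-trip and validate", {
  sc <- make_screen(n = 6, q = 0.5, n_rep = 2, n_wt = 4, seed = 59)
  ef <- tempfile(); af <- tempfile(); nf <- tempfile()
  write_expression(sc$data, ef, af)
  back <- read_expression(ef, af)
  expect_equal(back$values, sc$data$values)
  expect_identical(back$perturbed, sc$data$perturbed)
  write_network(sc$net, nf)
  netb <- read_network(nf, n_nodes = 6)
  expect_setequal(paste(netb$edges[, 1], netb$edges[, 2]),
                  paste(sc$net$edges[, 1], sc$net$edges[, 2]))
  # annotation referencing an unknown sample fails with the id
  an <- utils::read.delim(af)
  an$sample_id[1] <- "nope"
  af2 <- tempfile()
  utils::write.table(an, af2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression(ef, af2), "nope")
  # DREAM prediction format validation
  pf <- tempfile()
  writeLines(c("G1\tG2\t0.9", "G2\tG3\t0.5"), pf)
  expect_true(validate_prediction_file(pf))
  writeLines(c("G1\tG2\t0.1", "G2\tG3\t0.5"), pf)
  expect_error(validate_prediction_file(pf), "descending")
})

test_that("pipeline edge lists rank the inferable links at the top of the ROC", {
  sc <- make_screen(n = 40, q = 1, n_rep = 4, n_wt = 40, sigma = 0.1,
                    seed = 503)
  flags <- count_inferable_links(sc$net, sc$pert, "motif")$flags
  el <- run_inference(sc$data, method = "subnetwork", n_boot = 40, seed = 504)
  r <- roc_vs_inferable(el, sc$net, flags, "inferable_links")
  expect_gt(r$auroc, 0.9)
  expect_gt(r$tp_fraction, 0.8)
  # the unbiasedness advantage over partial correlations shows in the
  # strength estimates, not only the ranking: on the noisy chain the
  # false-to-true strength ratio is an order of magnitude smaller for PRC
  d <- make_three_node_demo(0.3, n_experiments = 2500, seed = 505)[[1]]
  pc <- partial_correlation_matrix(d)
  ratio_pc <- abs(pc[1, 3] / pc[2, 3])
  ratio_prc <- abs(prc_min_strength(d, "G3", "G1") /
                     prc_min_strength(d, "G3", "G2"))
  expect_lt(ratio_prc, ratio_pc / 3)
})
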