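# The five-step inference pipeline: (1) cluster co-expressed genes, (2) find
# significantly responding nodes per knocked-out source (the noise cutoff),
# (3) infer PRC link strengths within each subnetwork with residual
# bootstrapping, (4) test directed links inside two-gene clusters with one
# perturbed member, (5) assemble the significant links into an edge list.
# Restricting inference to significant responders imposes a sparsity
# constraint without a regularisation parameter.

# Vectorised two-node whitened smallest-eigenvector strengths.
# y1, y2: samples x replicates matrices (columns are bootstrap replicates).
two_node_strengths <- function(y1, y2, D1, D2, tol = 1e-10) {
  y1 <- as.matrix(y1); y2 <- as.matrix(y2)
  P <- nrow(y1)
  m1 <- colMeans(y1); m2 <- colMeans(y2)
  c11 <- (colSums(y1 * y1) - P * m1^2) / (P - 1)
  c22 <- (colSums(y2 * y2) - P * m2^2) / (P - 1)
  c12 <- (colSums(y1 * y2) - P * m1 * m2) / (P - 1)
  ev <- eig2_smallest(c11 / D1, c12 / sqrt(D1 * D2), c22 / D2)
  num <- ev$v1 / sqrt(D1)
  den <- ev$v2 / sqrt(D2)
  s <- -num / den
  s[abs(den) < tol] <- NA_real_
  s
}

# Minimum/maximum strengths plus bootstrap distributions for one candidate
# link j -> i.  Yk/pk: raw (unaveraged) data with the target's perturbation
# experiments already removed (pk = per-sample perturbed row index, NA for
# wild type); stack: horizontally stacked bootstrap matrices built from the
# replicate-averaged data (target's columns already removed), Pb columns
# per block, B blocks.  The residual coefficients A' are estimated once
# from the raw data and held fixed across bootstrap replicates.
#
# When the target carries (numerically) no weight in the null space of the
# reduced covariance, no combination of the other observables explains any
# of its variation: there are no alternative routes and the minimum
# coincides with the maximum.
link_stats <- function(Yk, n_ko, i, j, r, stack = NULL, B = 0, Pb = 0,
                       epsilon = 0.05, tol = 1e-10) {
  N <- nrow(Yk)
  P <- ncol(Yk)
  cfull <- NULL
  D2min <- r[i]
  if (N > 2) {
    red <- setdiff(seq_len(N), j)
    # null-space dimension of the reduced system: every distinct knockout
    # (including knockouts of the unobserved source j) contributes one
    # perturbation direction
    N0r <- max(1L, (N - 1L) - n_ko)
    if (N0r < length(red)) {
      Yr <- Yk[red, , drop = FALSE]
      m <- rowMeans(Yr)
      Sr <- tcrossprod(Yr - m) / (P - 1)
      iw <- 1 / sqrt(r[red])
      Sw <- Sr * tcrossprod(iw)
      eg <- eigen(Sw, symmetric = TRUE)
      ord <- order(eg$values)
      U0 <- eg$vectors[, ord[seq_len(N0r)], drop = FALSE]
      ii <- match(i, red)
      a <- as.numeric(U0 %*% U0[ii, ]) * iw
      if (abs(a[ii]) >= tol * max(abs(a), tol)) {
        coeffs <- a / a[ii]
        cfull <- numeric(N)
        cfull[red] <- coeffs
        D2min <- sum(coeffs^2 * r[red])
      }
    }
  }
  yj <- Yk[j, ]
  res_max <- Yk[i, ]
  res_min <- if (is.null(cfull)) res_max else as.numeric(crossprod(cfull, Yk))
  smax <- two_node_strengths(matrix(yj, ncol = 1), matrix(res_max, ncol = 1),
                             r[j], r[i], tol)
  smin <- if (is.null(cfull)) smax else {
    two_node_strengths(matrix(yj, ncol = 1), matrix(res_min, ncol = 1),
                       r[j], D2min, tol)
  }
  boot_min <- boot_max <- numeric(0)
  if (B > 0 && !is.null(stack)) {
    yj_b <- matrix(stack[j, ], Pb, B)
    rmax_b <- matrix(stack[i, ], Pb, B)
    boot_max <- two_node_strengths(yj_b, rmax_b, r[j], r[i], tol)
    boot_min <- if (is.null(cfull)) boot_max else {
      rmin_b <- matrix(crossprod(cfull, stack), Pb, B)
      two_node_strengths(yj_b, rmin_b, r[j], D2min, tol)
    }
  }
  list(min = smin, max = smax, boot_min = boot_min, boot_max = boot_max,
       min_is_max = is.null(cfull))
}

# PRC row of target i when it is the only unperturbed observable in the
# kept samples (N0 = 1): the full i-th row of A (A_ii = -1) from the
# smallest eigenvector, plus bootstrap rows from the averaged+delta data.
# Returns NULL when the row is not identifiable.
row_stats <- function(Yk, i, r, stack = NULL, B = 0, Pb = 0, tol = 1e-8) {
  row_of <- function(M) {
    m <- rowMeans(M)
    S <- tcrossprod(M - m) / (ncol(M) - 1)
    dec <- ppca_decompose(S, N0 = 1, r = r)
    tryCatch(prc_row_single_unperturbed(dec, i, tol = tol),
             error = function(e) rep(NA_real_, nrow(M)))
  }
  point <- row_of(Yk)
  if (all(is.na(point))) return(NULL)
  boot_rows <- NULL
  if (B > 0 && !is.null(stack)) {
    boot_rows <- matrix(NA_real_, nrow(Yk), B)
    for (b in seq_len(B)) {
      boot_rows[, b] <- row_of(stack[, (b - 1) * Pb + seq_len(Pb),
                                     drop = FALSE])
    }
  }
  list(row = point, boot_rows = boot_rows)
}

# Two-sided bootstrap p-value for the minimum strength against zero: the
# fraction of bootstrap minimum strengths crossing zero (doubled for the
# two-sided test).
p_from_boot <- function(b, tol = 1e-9) {
  b <- b[is.finite(b)]
  if (length(b) == 0) return(NA_real_)
  min(1, 2 * min(mean(b <= tol), mean(b >= -tol)))
}

# Stacked bootstrap matrices for the residual bootstrap: every sample is
# replaced by a pseudo-replicate, the mean log2 fold change of its group
# (its knockout's replicates, or the wild-type block) plus one fresh
# replicate-noise draw delta per gene.  The pseudo-datasets have the same
# layout and noise level as the observed data, so bootstrap estimates share
# the sampling distribution of the point estimates — in particular their
# spread shrinks with the replicate count.  Returns an N x (P * B) matrix,
# or NULL when B = 0.
make_boot_stack <- function(data, noise, B, seed) {
  if (B <= 0) return(NULL)
  delta <- noise$delta[data$genes, , drop = FALSE]
  if (any(is.na(delta))) stop("noise model does not cover all genes of the dataset")
  G <- nrow(data$values)
  P <- ncol(data$values)
  grp <- data$condition
  means <- vapply(unique(grp), function(g) {
    rowMeans(data$values[, grp == g, drop = FALSE])
  }, numeric(G))
  template <- means[, match(grp, unique(grp)), drop = FALSE]
  nd <- ncol(delta)
  set.seed(seed)
  idx <- sample.int(nd, G * P * B, replace = TRUE)
  noise_draws <- matrix(delta[cbind(rep(seq_len(G), P * B), idx)], G, P * B)
  matrix(rep(template, B), G, P * B) + noise_draws
}

#' Cluster co-expressed genes
#'
#' Genes whose profiles are strongly correlated across all perturbations
#' (and the wild-type reference block, which anchors the unperturbed state)
#' carry no independent information and are merged into single network
#' nodes.  Average-linkage hierarchical clustering on the distance
#' `1 - |Pearson correlation|`, cut at height `1 - threshold`, so that
#' within-cluster co-expression is at least `threshold` on average.
#'
#' @param data an [expression_dataset()] with at least 2 samples.
#' @param threshold absolute-correlation threshold in (0, 1].
#' @return object of class `cluster_set`: `assignment` (named integer
#'   vector gene -> cluster id), `sizes`, `members` (list), `threshold`.
#' @export
cluster_coexpressed <- function(data, threshold = 0.9) {
  stopifnot(inherits(data, "expression_dataset"))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  v <- data$values
  if (sum(!is.na(data$perturbed)) < 2) {
    stop("at least 2 perturbation samples are required")
  }
  cc <- suppressWarnings(stats::cor(t(v)))
  cc[!is.finite(cc)] <- 0 # constant genes correlate with nothing
  d <- stats::as.dist(1 - abs(cc))
  hc <- stats::hclust(d, method = "average")
  assignment <- stats::cutree(hc, h = 1 - threshold)
  names(assignment) <- data$genes
  members <- split(names(assignment), assignment)
  structure(list(assignment = assignment,
                 sizes = vapply(members, length, integer(1)),
                 members = members, threshold = threshold),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d genes in %d clusters (%d non-singleton), threshold %.2f\n",
              length(x$assignment), length(x$members),
              sum(x$sizes > 1), x$threshold))
  invisible(x)
}

#' Build the subnetwork of a knocked-out source gene
#'
#' The subnetwork nodes are the genes responding significantly to the
#' source knockout ([significant_responders()]); the subnetwork samples are
#' all experiments perturbing any subnetwork node, plus the wild-type
#' replicates.
#'
#' @inheritParams significant_responders
#' @return an [expression_dataset()] restricted to the subnetwork, with
#'   attributes `"source"` and `"empty"` (TRUE when nothing but the source
#'   responded, in which case no links are emitted).
#' @export
build_subnetwork <- function(source, data, noise, fdr = 0.05,
                             mt = "BH", ref = "normal") {
  responders <- significant_responders(source, data, noise, fdr = fdr,
                                       mt = mt, ref = ref)
  src <- data$genes[resolve_gene(data, source)]
  keep_samples <- is.na(data$perturbed) | data$perturbed %in% responders
  sub <- subset_dataset(data, genes = responders, samples = keep_samples)
  attr(sub, "source") <- src
  attr(sub, "empty") <- length(responders) <= 1
  sub
}

empty_links <- function() {
  data.frame(source = character(0), target = character(0),
             strength_min = numeric(0), strength_max = numeric(0),
             p_value = numeric(0), inferable = logical(0))
}

# Core link-inference loop over candidate (source, target) pairs on a fixed
# observable set, grouped by target: point estimates and the A' residual
# coefficients come from the raw replicate samples (covariances of full
# rank), bootstrap distributions from pseudo-datasets in which every sample
# is its group mean plus a fresh resampled residual-noise draw.  When the
# target is the only unperturbed observable of the kept samples, the full
# PRC row (N0 = 1) serves all its sources at once and min = max by
# construction.
infer_links <- function(data, candidates, noise, n_boot, seed,
                        alpha = 0.05, epsilon = 0.05, zero_tol = 1e-6) {
  if (nrow(candidates) == 0) return(empty_links())
  Y <- data$values
  pn <- data$perturbed
  r <- noise_ratios_for(data, noise)
  stack <- if (n_boot > 0) make_boot_stack(data, noise, n_boot, seed) else NULL
  N <- nrow(Y)
  rows <- list()
  for (tg in unique(candidates$target)) {
    i <- match(tg, data$genes)
    keep <- is.na(pn) | pn != tg
    if (sum(keep) < 3) next
    Yk <- Y[, keep, drop = FALSE]
    pk <- pn[keep]
    Pb <- sum(keep)
    stk <- if (!is.null(stack)) {
      stack[, rep(keep, n_boot), drop = FALSE]
    } else NULL
    srcs <- candidates$source[candidates$target == tg]
    src_idx <- match(srcs, data$genes)
    ok <- vapply(srcs, function(j) {
      any(!is.na(pk) & pk == j)
    }, logical(1))
    srcs <- srcs[ok]; src_idx <- src_idx[ok]
    if (length(srcs) == 0) next
    # distinct knockouts among the kept samples, including knockouts of
    # genes outside the observable set: each is one perturbation direction
    n_ko <- length(unique(pk[!is.na(pk)]))
    if (N - n_ko == 1 && N > 2) {
      # target is the only unperturbed observable: direct row estimate
      rs <- row_stats(Yk, i, r, stk, n_boot, Pb)
      if (is.null(rs)) next
      for (k in seq_along(srcs)) {
        j <- src_idx[k]
        s <- rs$row[j]
        if (!is.finite(s)) next
        bs <- if (!is.null(rs$boot_rows)) rs$boot_rows[j, ] else numeric(0)
        p <- if (n_boot > 0) p_from_boot(bs) else NA_real_
        rows[[length(rows) + 1]] <- data.frame(
          source = srcs[k], target = tg, strength_min = s,
          strength_max = s, p_value = p, inferable = TRUE,
          stringsAsFactors = FALSE)
      }
      next
    }
    for (k in seq_along(srcs)) {
      j <- src_idx[k]
      st <- tryCatch(
        link_stats(Yk, n_ko, i, j, r, stk, n_boot, Pb, epsilon = epsilon),
        error = function(e) NULL)
      if (is.null(st) || !is.finite(st$min) || !is.finite(st$max)) next
      p <- if (n_boot > 0) p_from_boot(st$boot_min) else NA_real_
      inf <- if (n_boot > 0 && sum(is.finite(st$boot_min)) > 1) {
        classify_link_inferability(st$boot_min, st$boot_max,
                                   alpha = alpha, zero_tol = zero_tol)
      } else {
        # degenerate (no bootstrap): point-value version of the same rule
        !((abs(st$max) - abs(st$min)) > zero_tol && abs(st$min) <= zero_tol)
      }
      rows[[length(rows) + 1]] <- data.frame(
        source = srcs[k], target = tg,
        strength_min = st$min, strength_max = st$max,
        p_value = p, inferable = inf, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty_links())
  do.call(rbind, rows)
}

# Single-source convenience wrapper around infer_links.
infer_links_for_source <- function(data, source, targets, noise, n_boot,
                                   seed, alpha = 0.05, epsilon = 0.05,
                                   zero_tol = 1e-6) {
  targets <- setdiff(targets, source)
  if (length(targets) == 0) return(empty_links())
  infer_links(data,
              data.frame(source = source, target = targets,
                         stringsAsFactors = FALSE),
              noise, n_boot, seed, alpha = alpha, epsilon = epsilon,
              zero_tol = zero_tol)
}

#' Infer directed links within a subnetwork
#'
#' For every candidate target in the subnetwork, all experiments perturbing
#' the target are removed, the PRC minimum and maximum strengths of the
#' link source -> target are estimated, and their significance is assessed
#' by residual bootstrapping: replicate-noise draws `delta` are added to the
#' replicate-averaged knockout fold changes, the strengths are recomputed
#' for every bootstrap replicate, and the two-sided p-value is the fraction
#' of bootstrap minimum strengths crossing zero.
#'
#' @param subnet subnetwork dataset from [build_subnetwork()] (or any
#'   [expression_dataset()] if `source` is given).
#' @param noise a [replicate_residuals()] noise model on the subnetwork's
#'   genes.
#' @param n_boot number of bootstrap replicates (the delta-draw count).
#' @param seed integer seed for the bootstrap draws.
#' @param source source gene (defaults to the subnetwork's `"source"`
#'   attribute).
#' @param alpha interval level for the inferability classification.
#' @param zero_tol numerical zero tolerance for degenerate bootstrap
#'   distributions.
#' @param epsilon covariance regularisation weight.
#' @return data.frame of link records: source, target, strength_min,
#'   strength_max, p_value, inferable.
#' @export
infer_subnetwork_links <- function(subnet, noise, n_boot = 200, seed = 1,
                                   source = NULL, alpha = 0.05,
                                   zero_tol = 1e-6, epsilon = 0.05) {
  source <- source %||% attr(subnet, "source")
  if (is.null(source)) stop("no source gene given or attached to the subnetwork")
  if (isTRUE(attr(subnet, "empty"))) {
    return(infer_links_for_source(subnet, source, character(0), noise, 0, seed))
  }
  targets <- setdiff(subnet$genes, source)
  infer_links_for_source(subnet, source, targets, noise, n_boot, seed,
                         alpha = alpha, epsilon = epsilon,
                         zero_tol = zero_tol)
}

#' Directed links inside two-gene clusters with one perturbed member
#'
#' Co-expressed pairs collapse to a single node in the clustered network,
#' so the within-pair link is tested separately: for every two-gene cluster
#' with exactly one perturbed member, the directed link perturbed ->
#' unperturbed is estimated by the two-node errors-in-variables PRC and
#' bootstrapped as in [infer_subnetwork_links()].
#'
#' @param clusters a [cluster_coexpressed()] result.
#' @param data the gene-level [expression_dataset()].
#' @param noise gene-level [replicate_residuals()].
#' @param n_boot,seed,zero_tol as in [infer_subnetwork_links()].
#' @return data.frame of link records (possibly empty).
#' @export
two_node_cluster_links <- function(clusters, data, noise, n_boot = 200,
                                   seed = 1, zero_tol = 1e-6) {
  perturbed_genes <- unique(stats::na.omit(data$perturbed))
  rows <- list()
  for (mem in clusters$members) {
    if (length(mem) != 2) next
    is_p <- mem %in% perturbed_genes
    if (sum(is_p) != 1) next
    src <- mem[is_p]; tgt <- mem[!is_p]
    pair <- subset_dataset(data, genes = mem)
    rec <- infer_links_for_source(pair, src, tgt, noise, n_boot,
                                  derive_seed(seed, paste0("pair_", src)),
                                  zero_tol = zero_tol)
    if (nrow(rec) > 0) rows[[length(rows) + 1]] <- rec
  }
  if (length(rows) == 0) {
    return(data.frame(source = character(0), target = character(0),
                      strength_min = numeric(0), strength_max = numeric(0),
                      p_value = numeric(0), inferable = logical(0)))
  }
  do.call(rbind, rows)
}

#' Assemble link records into the final edge list
#'
#' Combines subnetwork-level and two-node-cluster link records, removes
#' duplicates (keeping the most significant record), applies
#' Benjamini-Hochberg correction across all links, and sorts by
#' significance.  The `subnetwork` method additionally removes every link
#' with more than one gene in its source or target cluster, leaving links
#' between single genes — the edge list that would arise by skipping the
#' clustering step.
#'
#' @param cluster_links,subnet_links data.frames of link records (either may
#'   be empty); records may carry `source_size`/`target_size` columns for
#'   cluster-level links (missing sizes are taken as 1).
#' @param method `"clustering"` or `"subnetwork"`.
#' @param fdr link-level false discovery rate for the `significant` flag.
#' @return object of class `edge_list`: a data.frame sorted by adjusted
#'   significance with attribute `"method"`.
#' @export
assemble_edge_list <- function(cluster_links, subnet_links,
                               method = c("clustering", "subnetwork"),
                               fdr = 0.05) {
  method <- match.arg(method)
  el <- rbind(fill_sizes(subnet_links), fill_sizes(cluster_links))
  if (method == "subnetwork" && nrow(el) > 0) {
    el <- el[el$source_size == 1 & el$target_size == 1, , drop = FALSE]
  }
  if (nrow(el) > 0) {
    el <- el[order(el$p_value, -abs(el$strength_min)), , drop = FALSE]
    dup <- duplicated(paste(el$source, el$target))
    el <- el[!dup, , drop = FALSE]
    el$significance <- stats::p.adjust(el$p_value, method = "BH")
    el$significant <- !is.na(el$significance) & el$significance <= fdr
    el <- el[order(el$significance), , drop = FALSE]
    rownames(el) <- NULL
  } else {
    el$significance <- numeric(0)
    el$significant <- logical(0)
  }
  structure(el, method = method, class = c("edge_list", "data.frame"))
}

fill_sizes <- function(el) {
  if (is.null(el) || nrow(el) == 0) {
    el <- data.frame(source = character(0), target = character(0),
                     strength_min = numeric(0), strength_max = numeric(0),
                     p_value = numeric(0), inferable = logical(0))
  }
  if (is.null(el$source_size)) el$source_size <- rep(1L, nrow(el))
  if (is.null(el$target_size)) el$target_size <- rep(1L, nrow(el))
  el
}

#' Run the full network-inference pipeline
#'
#' Orchestrates noise estimation, optional clustering, subnetwork
#' construction, PRC link inference with residual bootstrapping, and edge
#' list assembly.  Three variants are provided: `"prc"` (no sparsity
#' constraint: every gene is a candidate target of every perturbed gene),
#' `"subnetwork"` (targets restricted to significant responders of each
#' source) and `"clustering"` (co-expressed genes merged into single nodes
#' before the subnetwork step, plus the two-gene-cluster link test).
#'
#' @param data an [expression_dataset()] with perturbation annotations and
#'   (unless `noise` is supplied) a wild-type replicate block.
#' @param method `"subnetwork"`, `"clustering"` or `"prc"`.
#' @param fdr_nodes significance level for the responding-node test.
#' @param fdr_links false discovery rate for link significance.
#' @param n_boot bootstrap replicates per link.
#' @param seed master seed; per-source streams are derived from it, so
#'   results do not depend on iteration order.
#' @param threshold co-expression threshold for the clustering variant.
#' @param noise optional precomputed [replicate_residuals()].
#' @param alpha interval level for the inferability classification.
#' @param mt,ref responder-test options, see [significant_responders()].
#' @param refine_passes maximum number of refinement passes: identified
#'   targets of a target node are removed from the observables and the
#'   remaining non-significant links re-tested (0 disables refinement).
#' @param out_dir optional directory: writes `edges.tsv`, `noise.tsv` and
#'   `run_log.json`.
#' @return an `edge_list` (see [assemble_edge_list()]) with attributes
#'   `"clusters"` (clustering method) and `"run_log"`.
#' @export
run_inference <- function(data, method = c("subnetwork", "clustering", "prc"),
                          fdr_nodes = 0.05, fdr_links = 0.05, n_boot = 200,
                          seed = 1, threshold = 0.9, noise = NULL,
                          alpha = 0.05, mt = "BH", ref = "normal",
                          refine_passes = 2, out_dir = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(data, "expression_dataset"))
  perturbed_genes <- unique(stats::na.omit(data$perturbed))
  if (length(perturbed_genes) == 0) {
    stop("dataset contains no perturbation annotations; nothing to infer from")
  }
  if (is.null(noise)) {
    if (sum(is.na(data$perturbed)) < 2) {
      stop("noise estimation requires at least 2 wild-type replicates (or pass 'noise')")
    }
    noise <- replicate_residuals(wt_matrix(data))
  }
  clusters <- NULL
  cl_links <- NULL
  if (method == "clustering") {
    clusters <- cluster_coexpressed(data, threshold)
    cdata <- cluster_dataset(data, clusters)
    cnoise <- replicate_residuals(wt_matrix(cdata))
    links <- subnetwork_flow(cdata, cnoise, fdr_nodes, n_boot, seed,
                             alpha, mt, ref, restrict = TRUE)
    sz <- clusters$sizes[sub("^C", "", links$source)]
    tz <- clusters$sizes[sub("^C", "", links$target)]
    links$source_size <- as.integer(sz)
    links$target_size <- as.integer(tz)
    cl_links <- two_node_cluster_links(clusters, data, noise,
                                       n_boot = n_boot, seed = seed)
  } else {
    links <- subnetwork_flow(data, noise, fdr_nodes, n_boot, seed,
                             alpha, mt, ref, restrict = method == "subnetwork")
  }
  asm <- function(l) {
    assemble_edge_list(cl_links, l,
                       method = if (method == "clustering") "clustering" else "subnetwork",
                       fdr = fdr_links)
  }
  el <- asm(links)
  # Refinement: nodes already identified as targets of the current target
  # cannot transmit information back to it (bidirectional links are
  # excluded), so they are removed from the observables and the remaining
  # non-significant links re-tested, iterating to a fixed point.
  if (refine_passes > 0) {
    rdata <- if (method == "clustering") cluster_dataset(data, clusters) else data
    rnoise <- if (method == "clustering") replicate_residuals(wt_matrix(rdata)) else noise
    for (pass in seq_len(refine_passes)) {
      refined <- refine_links(el, rdata, rnoise, n_boot,
                              derive_seed(seed, paste0("refine", pass)),
                              alpha = alpha, fdr = fdr_links)
      if (is.null(refined)) break
      links <- merge_link_records(links, refined)
      el <- asm(links)
    }
  }
  attr(el, "method") <- method
  attr(el, "clusters") <- clusters
  attr(el, "noise") <- noise
  attr(el, "run_log") <- list(
    method = method, seed = seed, n_boot = n_boot,
    fdr_nodes = fdr_nodes, fdr_links = fdr_links,
    n_sources = length(perturbed_genes),
    n_links_tested = nrow(links) + if (is.null(cl_links)) 0 else nrow(cl_links),
    n_significant = sum(el$significant))
  if (!is.null(out_dir)) write_run_outputs(el, noise, out_dir)
  el
}

# Subnetwork (or unconstrained) link inference over all perturbed sources.
subnetwork_flow <- function(data, noise, fdr_nodes, n_boot, seed,
                            alpha, mt, ref, restrict = TRUE) {
  sources <- unique(stats::na.omit(data$perturbed))
  if (!restrict) {
    cand <- do.call(rbind, lapply(sources, function(src) {
      data.frame(source = src, target = setdiff(data$genes, src),
                 stringsAsFactors = FALSE)
    }))
    return(infer_links(data, cand, noise, n_boot,
                       derive_seed(seed, "prc_all"), alpha = alpha))
  }
  out <- list()
  for (src in sources) {
    s_seed <- derive_seed(seed, paste0("src_", src))
    subnet <- build_subnetwork(src, data, noise, fdr = fdr_nodes,
                               mt = mt, ref = ref)
    if (isTRUE(attr(subnet, "empty"))) next
    rec <- infer_subnetwork_links(subnet, noise, n_boot = n_boot,
                                  seed = s_seed, source = src,
                                  alpha = alpha)
    if (nrow(rec) > 0) out[[length(out) + 1]] <- rec
  }
  if (length(out) == 0) return(empty_links())
  do.call(rbind, out)
}

# Re-test non-significant links after deleting, for each target node, the
# nodes already identified as its targets (significant inferable outgoing
# links) from the observables.  Returns refined link records, or NULL when
# nothing qualifies for re-testing.
refine_links <- function(el, data, noise, n_boot, seed, alpha = 0.05,
                         fdr = 0.05) {
  if (nrow(el) == 0) return(NULL)
  sig <- el[el$significant & el$inferable, , drop = FALSE]
  if (nrow(sig) == 0) return(NULL)
  out_map <- split(sig$target, sig$source)
  pending <- el[!el$significant, , drop = FALSE]
  if (nrow(pending) == 0) return(NULL)
  out <- list()
  for (tg in unique(pending$target)) {
    drop <- setdiff(out_map[[tg]], tg)
    drop <- intersect(drop, data$genes)
    if (length(drop) == 0) next
    srcs <- setdiff(pending$source[pending$target == tg], drop)
    srcs <- intersect(srcs, setdiff(data$genes, tg))
    if (length(srcs) == 0) next
    sub <- subset_dataset(data, genes = setdiff(data$genes, drop))
    rec <- tryCatch(
      infer_links(sub,
                  data.frame(source = srcs, target = tg,
                             stringsAsFactors = FALSE),
                  noise, n_boot, derive_seed(seed, tg), alpha = alpha),
      error = function(e) NULL)
    if (!is.null(rec) && nrow(rec) > 0) out[[length(out) + 1]] <- rec
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

# Replace link records by their refined version when the refinement gives a
# smaller p-value (node removal can only sharpen the test).
merge_link_records <- function(links, refined) {
  key <- paste(links$source, links$target)
  rkey <- paste(refined$source, refined$target)
  m <- match(rkey, key)
  for (k in seq_along(m)) {
    if (is.na(m[k])) next
    old_p <- links$p_value[m[k]]
    new_p <- refined$p_value[k]
    if (is.na(old_p) || (!is.na(new_p) && new_p < old_p)) {
      for (cl in c("strength_min", "strength_max", "p_value", "inferable")) {
        links[[cl]][m[k]] <- refined[[cl]][k]
      }
    }
  }
  links
}

# Collapse a dataset to cluster-level nodes (mean member profiles); a
# sample perturbs a cluster when it perturbs any member.
cluster_dataset <- function(data, clusters) {
  ids <- sort(unique(clusters$assignment))
  v <- do.call(rbind, lapply(ids, function(cid) {
    colMeans(data$values[clusters$members[[as.character(cid)]], ,
                         drop = FALSE])
  }))
  rownames(v) <- paste0("C", ids)
  colnames(v) <- data$samples
  pert <- ifelse(is.na(data$perturbed), NA_character_,
                 paste0("C", clusters$assignment[data$perturbed]))
  expression_dataset(v, pert, data$replicate, data$condition)
}

#' Expand cluster-level links to gene-level pairs
#'
#' Every cluster-level link is expanded to all member-gene pairs
#' (inheriting strength and significance), and the two-node within-cluster
#' links are kept as is.  Used to evaluate the clustering method against a
#' gene-level ground truth.
#'
#' @param el an `edge_list` from the clustering method.
#' @param clusters the matching `cluster_set`.
#' @return a data.frame of gene-level link records.
#' @export
expand_cluster_links <- function(el, clusters) {
  if (nrow(el) == 0) return(el)
  rows <- lapply(seq_len(nrow(el)), function(k) {
    src <- el$source[k]; tgt <- el$target[k]
    sg <- if (grepl("^C", src)) clusters$members[[sub("^C", "", src)]] else src
    tg <- if (grepl("^C", tgt)) clusters$members[[sub("^C", "", tgt)]] else tgt
    expand.grid(source = sg, target = tg, stringsAsFactors = FALSE,
                KEEP.OUT.ATTRS = FALSE) |>
      cbind(el[k, setdiff(names(el), c("source", "target")), drop = FALSE],
            row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out <- out[out$source != out$target, , drop = FALSE]
  dup <- duplicated(paste(out$source, out$target))
  out[!dup, , drop = FALSE]
}

write_run_outputs <- function(el, noise, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_list(el, file.path(out_dir, "edges.tsv"))
  utils::write.table(
    data.frame(gene = names(noise$sigma_i),
               sigma_i = unname(noise$sigma_i),
               r_i = unname(noise$r)),
    file.path(out_dir, "noise.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_report(attr(el, "run_log"), file.path(out_dir, "run_log.json"))
}
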