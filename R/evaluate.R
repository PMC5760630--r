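# Inferability-aware evaluation: partial-correlation baseline, ROC curves
# whose true-positive rate can be computed with respect to the inferable
# links only, and DREAM3-style significance scoring against sampled null
# distributions.

#' Partial-correlation score matrix
#'
#' Partial correlations from the inverse of the (regularised) sample
#' covariance: `pc_ij = -Omega_ij / sqrt(Omega_ii Omega_jj)`.  The standard
#' undirected baseline; sensitive to measurement noise on intermediate
#' nodes, which induces false-positive links.
#'
#' @param data an [expression_dataset()] (or plain genes x samples matrix).
#' @param epsilon shrinkage weight used when the covariance is rank
#'   deficient; with `epsilon = 0` a singular covariance is an error.
#' @return symmetric genes x genes matrix of partial correlations (zero
#'   diagonal).
#' @export
partial_correlation_matrix <- function(data, epsilon = 0.05) {
  x <- if (inherits(data, "expression_dataset")) data$values else as.matrix(data)
  sc <- sample_covariance(x, epsilon = epsilon)
  if (sc$regularized && epsilon <= 0) {
    stop("singular covariance; supply a positive regularisation epsilon")
  }
  om <- solve(sc$S)
  d <- 1 / sqrt(diag(om))
  pc <- -om * tcrossprod(d)
  diag(pc) <- 0
  dimnames(pc) <- list(rownames(x), rownames(x))
  pc
}

# Normalise predictions to a data.frame(source, target, score).
as_score_frame <- function(scores, genes) {
  if (is.matrix(scores)) {
    # scores[i, j] scores the link j -> i (row = target), as in the
    # interaction-matrix convention; symmetric matrices score both
    # directions equally.
    idx <- which(row(scores) != col(scores), arr.ind = TRUE)
    data.frame(source = genes[idx[, 2]], target = genes[idx[, 1]],
               score = abs(scores[idx]), stringsAsFactors = FALSE)
  } else if (inherits(scores, "data.frame")) {
    df <- data.frame(source = as.character(scores$source),
                     target = as.character(scores$target),
                     stringsAsFactors = FALSE)
    df$score <- if (!is.null(scores$score)) {
      scores$score
    } else if (!is.null(scores$significance)) {
      1 - scores$significance # smaller adjusted p = stronger link
    } else if (!is.null(scores$p_value)) {
      1 - scores$p_value
    } else {
      abs(scores$strength_min)
    }
    df
  } else {
    stop("scores must be a matrix or a data.frame")
  }
}

#' ROC evaluation against a ground-truth network
#'
#' Ranks candidate links by score and sweeps a threshold.  With
#' `denominator = "inferable_links"` the true-positive rate is computed
#' with respect to the inferable links only: non-inferable true links are
#' excluded from both positives and negatives, since no method can recover
#' them from the available perturbations.
#'
#' @param scores matrix (entry `[i, j]` scores link j -> i; symmetric
#'   matrices are scored in both directions) or a data.frame with columns
#'   source, target and one of score / significance / p_value /
#'   strength_min (an `edge_list` works directly); links absent from a
#'   data.frame are treated as score 0.
#' @param truth a `directed_network` (the planted topology); gene names
#'   `G<i>` map to node indices.
#' @param inferable_flags optional logical vector parallel to the edges of
#'   `truth` (e.g. from [count_inferable_links()]).
#' @param denominator `"all_links"` or `"inferable_links"`.
#' @return object of class `evaluation_report`: `roc_points` (fpr, tpr),
#'   `auroc`, `tp_fraction` (TPR at full prediction list, or at the
#'   significance calls when `scores` is an edge list with a `significant`
#'   column), `denominator_mode`, `n_positive`, `n_negative`.
#' @export
roc_vs_inferable <- function(scores, truth,
                             inferable_flags = NULL,
                             denominator = c("all_links", "inferable_links")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(truth, "directed_network"))
  if (nrow(truth$edges) == 0) stop("empty truth network")
  n <- truth$n_nodes
  genes <- paste0("G", seq_len(n))
  true_key <- paste(truth$edges[, 1], truth$edges[, 2])
  pos_key <- true_key
  if (denominator == "inferable_links") {
    if (is.null(inferable_flags)) stop("inferable_flags required for the inferable-link denominator")
    stopifnot(length(inferable_flags) == nrow(truth$edges))
    pos_key <- true_key[inferable_flags]
  }
  sf <- as_score_frame(scores, genes)
  si <- match(sf$source, genes)
  ti <- match(sf$target, genes)
  ok <- !is.na(si) & !is.na(ti) & si != ti
  sf <- sf[ok, , drop = FALSE]
  key <- paste(si[ok], ti[ok])
  all_pairs <- paste(rep(seq_len(n), each = n - 1),
                     unlist(lapply(seq_len(n), function(i) setdiff(seq_len(n), i))))
  score <- numeric(length(all_pairs))
  names(score) <- all_pairs
  score[key] <- sf$score
  is_pos <- all_pairs %in% pos_key
  is_true <- all_pairs %in% true_key
  cand <- is_pos | !is_true # drop excluded non-inferable true links
  sc <- score[cand]; lab <- is_pos[cand]
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (n_pos == 0 || n_neg == 0) stop("degenerate evaluation: need both positives and negatives")
  # rank-based AUROC with tie averaging
  rk <- rank(sc)
  auroc <- (sum(rk[lab]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(sc), decreasing = TRUE)
  roc <- t(vapply(thr, function(th) {
    c(fpr = sum(sc[!lab] >= th) / n_neg, tpr = sum(sc[lab] >= th) / n_pos)
  }, numeric(2)))
  roc <- rbind(c(0, 0), roc, c(1, 1))
  tp_fraction <- if (inherits(scores, "data.frame") &&
                     !is.null(scores$significant)) {
    hit <- paste(match(scores$source, genes),
                 match(scores$target, genes))[scores$significant]
    sum(pos_key %in% hit) / length(pos_key)
  } else {
    sum(sc[lab] > 0) / n_pos
  }
  structure(list(roc_points = as.data.frame(roc), auroc = unname(auroc),
                 tp_fraction = tp_fraction, denominator_mode = denominator,
                 n_positive = n_pos, n_negative = n_neg),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: AUROC = %.3f, TP fraction = %.3f (%s denominator, %d positives)\n",
              x$auroc, x$tp_fraction, x$denominator_mode, x$n_positive))
  invisible(x)
}

# Area under the precision-recall curve (average precision over the
# recall increments at the positive positions).
aupr_from_ranking <- function(score, label) {
  ord <- order(score, decreasing = TRUE)
  lab <- label[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  rec <- tp / sum(lab)
  dr <- diff(c(0, rec[lab]))
  sum(dr * prec[lab])
}

#' AUROC and AUPR of a ranked prediction list against a gold standard
#'
#' @param pred data.frame with columns source, target, score (descending
#'   ranking).
#' @param gold data.frame with columns source, target, label (1 = true
#'   link, 0 = absent); only pairs present in the gold standard are scored,
#'   as in the DREAM evaluation.
#' @return list with `auroc` and `aupr`.
#' @export
ranked_prediction_metrics <- function(pred, gold) {
  gkey <- paste(gold$source, gold$target)
  score <- numeric(nrow(gold))
  names(score) <- gkey
  pkey <- paste(pred$source, pred$target)
  keep <- pkey %in% gkey
  score[pkey[keep]] <- pred$score[keep]
  lab <- gold$label == 1
  if (!any(lab) || all(lab)) stop("gold standard needs both classes")
  rk <- rank(score)
  n_pos <- sum(lab); n_neg <- sum(!lab)
  list(auroc = (sum(rk[lab]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg),
       aupr = aupr_from_ranking(score, lab))
}

# p-value of an observed metric against null samples, by curve fitting.
null_p_value <- function(x, null_samples,
                         fit_mode = c("two_tail_exp_family", "t_fit")) {
  fit_mode <- match.arg(fit_mode)
  null_samples <- null_samples[is.finite(null_samples)]
  if (length(null_samples) < 20) stop("too few null samples for curve fitting")
  if (fit_mode == "t_fit") {
    m <- mean(null_samples)
    s <- stats::sd(null_samples)
    dens <- function(v, sc, df) stats::dt((v - m) / sc, df) / sc
    fit <- tryCatch(
      MASS::fitdistr(null_samples, dens,
                     start = list(sc = s, df = 10),
                     lower = c(1e-6, 0.5)),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(max(stats::pt(-(x - m) / s, df = 10), .Machine$double.xmin))
    }
    sc <- fit$estimate["sc"]; df <- fit$estimate["df"]
    return(max(stats::pt(-(x - m) / sc, df = df), .Machine$double.xmin))
  }
  # exponential-family tail fit: empirical body, maximum-likelihood
  # exponential decay beyond the 80th percentile of each tail
  upper <- x >= stats::median(null_samples)
  v <- if (upper) null_samples else -null_samples
  xx <- if (upper) x else -x
  q0 <- stats::quantile(v, 0.8, names = FALSE)
  tail_frac <- mean(v > q0)
  exceed <- v[v > q0] - q0
  if (xx <= q0 || length(exceed) < 5) {
    p <- mean(v >= xx)
    return(max(p, 1 / (length(v) + 1)))
  }
  rate <- 1 / mean(exceed)
  max(tail_frac * exp(-rate * (xx - q0)), .Machine$double.xmin)
}

#' DREAM3-style overall score for a set of network predictions
#'
#' For each network, AUROC and AUPR are computed against the gold standard
#' and converted to p-values against organiser-sampled null distributions
#' by curve fitting — either exponential-family tails (the original scoring
#' method) or a single location-scale t fit.  The per-metric score is the
#' mean of `-log10 p` over the networks, and the overall score is the mean
#' of the AUROC and AUPR scores; all p-values equal to 1 give a score of 0.
#'
#' @param predictions list of prediction data.frames (source, target,
#'   score) or file paths in the challenge format
#'   (`G1<TAB>G2<TAB>weight`, descending).
#' @param golds list of gold-standard data.frames (source, target, label)
#'   or file paths (`G1<TAB>G2<TAB>0/1`).
#' @param nulls list (one per network) of lists with numeric vectors
#'   `auroc` and `aupr`: the sampled null distributions.
#' @param fit_mode `"two_tail_exp_family"` or `"t_fit"`.
#' @return list with `overall` score, `auroc_score`, `aupr_score`, and a
#'   per-network data.frame `networks` (auroc, aupr, p_auroc, p_aupr).
#' @export
dream3_score <- function(predictions, golds, nulls,
                         fit_mode = c("two_tail_exp_family", "t_fit")) {
  fit_mode <- match.arg(fit_mode)
  stopifnot(length(predictions) == length(golds),
            length(golds) == length(nulls))
  rows <- lapply(seq_along(predictions), function(k) {
    pred <- read_prediction_if_path(predictions[[k]])
    gold <- read_gold_if_path(golds[[k]])
    met <- ranked_prediction_metrics(pred, gold)
    nl <- nulls[[k]]
    if (is.null(nl$auroc) || is.null(nl$aupr)) {
      stop(sprintf("null distributions for network %d must contain 'auroc' and 'aupr' samples", k))
    }
    data.frame(auroc = met$auroc, aupr = met$aupr,
               p_auroc = null_p_value(met$auroc, nl$auroc, fit_mode),
               p_aupr = null_p_value(met$aupr, nl$aupr, fit_mode))
  })
  networks <- do.call(rbind, rows)
  auroc_score <- mean(-log10(networks$p_auroc))
  aupr_score <- mean(-log10(networks$p_aupr))
  list(overall = (auroc_score + aupr_score) / 2,
       auroc_score = auroc_score, aupr_score = aupr_score,
       networks = networks)
}

read_prediction_if_path <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) stop(sprintf("prediction file not found: %s", x))
    df <- utils::read.delim(x, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 3) stop(sprintf("malformed prediction file (need 3 columns): %s", x))
    names(df)[1:3] <- c("source", "target", "score")
    df
  } else {
    x
  }
}

read_gold_if_path <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) stop(sprintf("gold-standard file not found: %s", x))
    df <- utils::read.delim(x, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 3) stop(sprintf("malformed gold-standard file (need 3 columns): %s", x))
    names(df)[1:3] <- c("source", "target", "label")
    df
  } else {
    x
  }
}
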