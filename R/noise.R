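# Gene-specific biological variability from wild-type replicates, and the
# significance test behind the noise cutoff: a node enters a subnetwork only
# when its knockout response exceeds its own replicate variability.

#' Replicate residuals and gene-specific noise levels
#'
#' Centres every gene's wild-type replicate profile,
#' `delta_in = log2(r_in) - <log2(r_in)>_n`, and summarises the natural
#' variation among biological replicates: per-gene standard deviations
#' `sigma_i`, the pooled variance `sigma^2` (mean of the per-gene
#' variances), and the scaled ratios `r_i = sigma_i^2 / sigma^2` that form
#' the diagonal noise matrix `D` used for whitening.
#'
#' @param wt numeric matrix of wild-type log2 ratios, genes in rows and
#'   replicates in columns (at least 2 columns).
#' @param fit_df also fit the t degrees of freedom of the pooled
#'   standardized residuals (requires >= 100 values).
#' @return object of class `replicate_residuals` with fields `delta`
#'   (centred residual matrix), `sigma_i` (named), `pooled_sigma2`, `r`
#'   (named scaled variances), `excluded` (genes with zero replicate
#'   variance, assigned the pooled level), and `t_df` (NA unless `fit_df`).
#' @export
replicate_residuals <- function(wt, fit_df = FALSE) {
  wt <- as.matrix(wt)
  if (ncol(wt) < 2) stop("at least 2 wild-type replicates per gene are required")
  if (is.null(rownames(wt))) rownames(wt) <- paste0("G", seq_len(nrow(wt)))
  delta <- wt - rowMeans(wt)
  sigma_i <- apply(delta, 1, stats::sd)
  ok <- sigma_i > 0
  if (!any(ok)) stop("all genes have constant replicates; no variability to estimate")
  pooled <- mean(sigma_i[ok]^2)
  excluded <- rownames(wt)[!ok]
  sigma_i[!ok] <- sqrt(pooled) # constant-replicate genes get the pooled level
  r <- sigma_i^2 / pooled
  t_df <- NA_real_
  obj <- structure(list(delta = delta, sigma_i = sigma_i,
                        pooled_sigma2 = pooled, r = r,
                        excluded = excluded, t_df = t_df),
                   class = "replicate_residuals")
  if (fit_df) obj$t_df <- fit_t_df(pooled_z_scores(obj))
  obj
}

#' @export
print.replicate_residuals <- function(x, ...) {
  cat(sprintf("replicate_residuals: %d genes x %d replicates, pooled sigma = %.4g%s\n",
              nrow(x$delta), ncol(x$delta), sqrt(x$pooled_sigma2),
              if (is.na(x$t_df)) "" else sprintf(", t df = %.1f", x$t_df)))
  invisible(x)
}

# Pooled per-gene-standardized residuals (z-scores).
pooled_z_scores <- function(noise) {
  z <- noise$delta / noise$sigma_i
  as.numeric(z[noise$sigma_i > 0 | TRUE, ])
}

#' Fit the degrees of freedom of a central t distribution
#'
#' Maximum-likelihood fit of a location-0, free-scale t distribution to
#' pooled standardized replicate residuals.  Wild-type variability in large
#' replicate compendia is close to normal but heavier tailed; the fitted
#' degrees of freedom quantify the excess.
#'
#' @param z numeric vector of standardized residuals (>= 100 values).
#' @return fitted degrees of freedom (scalar).
#' @export
fit_t_df <- function(z) {
  z <- z[is.finite(z)]
  if (length(z) < 100) stop("at least 100 values are required for a stable t fit")
  dens <- function(x, s, df) stats::dt(x / s, df) / s
  fit <- MASS::fitdistr(z, dens, start = list(s = stats::sd(z), df = 10),
                        lower = c(1e-3, 0.5))
  unname(fit$estimate["df"])
}

#' Genes responding significantly to a single-gene knockout
#'
#' Restricts the data to samples in which only `source` is perturbed, tests
#' every gene's mean log2 fold change against its own replicate-variability
#' null (sigma_i from the wild-type replicates), and applies multiple
#' testing correction.  The significantly responding genes — always
#' including the source — define the subnetwork of the source node.
#'
#' @param source gene name or index of the knocked-out gene.
#' @param data an [expression_dataset()].
#' @param noise a [replicate_residuals()] noise model.
#' @param fdr significance level (Benjamini-Hochberg false discovery rate,
#'   or the familywise level for `mt = "bonferroni"` where the threshold is
#'   `fdr / N`).
#' @param mt multiple-testing mode: `"BH"` (default) or `"bonferroni"`.
#' @param ref reference distribution for the test statistic: `"normal"`
#'   (default) or `"t"` (uses the fitted `t_df` of the noise model).
#' @return character vector of responding gene names.
#' @export
significant_responders <- function(source, data, noise, fdr = 0.05,
                                   mt = c("BH", "bonferroni"),
                                   ref = c("normal", "t")) {
  mt <- match.arg(mt)
  ref <- match.arg(ref)
  stopifnot(inherits(data, "expression_dataset"))
  src_idx <- resolve_gene(data, source)
  source <- data$genes[src_idx]
  sel <- which(!is.na(data$perturbed) & data$perturbed == source)
  if (length(sel) == 0) {
    stop(sprintf("source gene '%s' has no single-perturbation samples", source))
  }
  m <- rowMeans(data$values[, sel, drop = FALSE])
  sig <- noise$sigma_i[data$genes]
  sig[is.na(sig) | sig == 0] <- sqrt(noise$pooled_sigma2)
  stat <- m / (sig / sqrt(length(sel)))
  p <- if (ref == "t" && is.finite(noise$t_df)) {
    2 * stats::pt(-abs(stat), df = noise$t_df)
  } else {
    2 * stats::pnorm(-abs(stat))
  }
  hit <- if (mt == "BH") {
    stats::p.adjust(p, method = "BH") <= fdr
  } else {
    p <= fdr / length(p)
  }
  union(source, data$genes[which(hit)])
}
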