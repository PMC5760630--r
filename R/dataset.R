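# Expression dataset container: log2 fold-change matrices from single-gene
# knockout screens, with per-sample perturbation annotations.

#' Construct an expression dataset
#'
#' @param values numeric matrix of log2 fold changes versus the pooled
#'   reference (M-values), genes in rows, samples in columns.  Row names are
#'   gene identifiers; column names are sample identifiers (generated when
#'   absent).
#' @param perturbed character vector, one entry per sample: the identifier
#'   of the knocked-out gene, or `NA` for wild-type replicates.
#' @param replicate integer vector of replicate indices per sample.
#' @param condition optional character vector naming the experimental
#'   condition of each sample; samples sharing a condition are biological
#'   replicates (averaged together and resampled as a group by the residual
#'   bootstrap).  Defaults to the perturbed gene (all knockouts of a gene
#'   are replicates of one condition) with one common wild-type condition.
#' @return object of class `expression_dataset` with fields `values`,
#'   `genes`, `samples`, `perturbed`, `replicate`, `condition` and
#'   `unmeasured` (perturbed genes that are not among the measured genes).
#' @export
expression_dataset <- function(values, perturbed, replicate = NULL,
                               condition = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("G", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  }
  if (length(perturbed) != ncol(values)) {
    stop("'perturbed' must have one entry per sample")
  }
  perturbed <- as.character(perturbed)
  perturbed[perturbed %in% c("WT", "wt", "")] <- NA_character_
  if (is.null(replicate)) replicate <- rep(1L, ncol(values))
  if (is.null(condition)) {
    condition <- ifelse(is.na(perturbed), ".wt", perturbed)
  }
  stopifnot(length(condition) == ncol(values))
  unmeasured <- setdiff(unique(perturbed[!is.na(perturbed)]),
                        rownames(values))
  structure(list(values = values,
                 genes = rownames(values),
                 samples = colnames(values),
                 perturbed = perturbed,
                 replicate = as.integer(replicate),
                 condition = as.character(condition),
                 unmeasured = unmeasured),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples (%d knockouts, %d wild-type)\n",
              nrow(x$values), ncol(x$values),
              length(unique(stats::na.omit(x$perturbed))),
              sum(is.na(x$perturbed))))
  invisible(x)
}

#' Subset an expression dataset by genes and/or samples
#' @param data an `expression_dataset`.
#' @param genes gene names or indices to keep (default all).
#' @param samples sample names or logical/integer index to keep.
#' @return the restricted `expression_dataset`.
#' @export
subset_dataset <- function(data, genes = NULL, samples = NULL) {
  stopifnot(inherits(data, "expression_dataset"))
  v <- data$values
  pert <- data$perturbed
  repl <- data$replicate
  cond <- data$condition
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, data$samples)
    v <- v[, samples, drop = FALSE]
    pert <- pert[samples]
    repl <- repl[samples]
    cond <- cond[samples]
  }
  if (!is.null(genes)) {
    if (is.numeric(genes)) genes <- data$genes[genes]
    v <- v[genes, , drop = FALSE]
  }
  expression_dataset(v, pert, repl, cond)
}

#' Wild-type replicate matrix of a dataset
#' @param data an `expression_dataset`.
#' @return genes x replicates matrix of the wild-type samples.
#' @export
wt_matrix <- function(data) {
  stopifnot(inherits(data, "expression_dataset"))
  data$values[, is.na(data$perturbed), drop = FALSE]
}

#' Average the replicates of each experimental condition
#'
#' Collapses the samples of every condition (by default, every distinct
#' knocked-out gene, plus one wild-type block) to their mean profile.  This
#' is the representation to which bootstrap residuals are added.
#'
#' @param data an `expression_dataset`.
#' @param keep_wt keep the averaged wild-type column(s) (default TRUE).
#' @return an `expression_dataset` with one column per condition.
#' @export
average_knockouts <- function(data, keep_wt = TRUE) {
  stopifnot(inherits(data, "expression_dataset"))
  conds <- unique(data$condition)
  pert_of <- data$perturbed[match(conds, data$condition)]
  if (!keep_wt) {
    conds <- conds[!is.na(pert_of)]
    pert_of <- pert_of[!is.na(pert_of)]
  }
  cols <- lapply(conds, function(cc) {
    rowMeans(data$values[, data$condition == cc, drop = FALSE])
  })
  v <- do.call(cbind, cols)
  dimnames(v) <- list(data$genes, paste0("avg_", conds))
  expression_dataset(v, pert_of, rep(1L, ncol(v)), conds)
}

# Scaled noise-variance vector aligned with the dataset's genes.
noise_ratios_for <- function(data, noise = NULL) {
  if (is.null(noise)) return(rep(1, length(data$genes)))
  stopifnot(inherits(noise, "replicate_residuals"))
  r <- noise$r[data$genes]
  r[is.na(r)] <- 1
  unname(r)
}
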