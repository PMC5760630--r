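# TSV/JSON file interfaces.  Gene identifiers are opaque strings; all
# files are UTF-8 tab-separated with round-trip identity.

#' Read an expression dataset from TSV files
#'
#' @param expr_file genes x samples TSV with a header row of sample ids and
#'   gene ids in the first column.
#' @param annot_file sample-annotation TSV with columns `sample_id`,
#'   `perturbed` (gene id, or `WT` for wild-type replicates) and optionally
#'   `replicate`.
#' @return an [expression_dataset()].
#' @export
read_expression <- function(expr_file, annot_file) {
  if (!file.exists(expr_file)) stop(sprintf("expression file not found: %s", expr_file))
  if (!file.exists(annot_file)) stop(sprintf("annotation file not found: %s", annot_file))
  ex <- utils::read.delim(expr_file, check.names = FALSE,
                          stringsAsFactors = FALSE)
  genes <- as.character(ex[[1]])
  v <- as.matrix(ex[, -1, drop = FALSE])
  if (!is.numeric(v)) {
    bad <- which(!vapply(ex[-1], is.numeric, logical(1)))[1] + 1
    stop(sprintf("malformed expression file %s: non-numeric column %d", expr_file, bad))
  }
  rownames(v) <- genes
  an <- utils::read.delim(annot_file, stringsAsFactors = FALSE)
  need <- c("sample_id", "perturbed")
  if (!all(need %in% names(an))) {
    stop(sprintf("annotation file %s must contain columns: %s",
                 annot_file, paste(need, collapse = ", ")))
  }
  bad <- which(!an$sample_id %in% colnames(v))
  if (length(bad) > 0) {
    stop(sprintf("annotation line %d references unknown sample '%s'",
                 bad[1] + 1, an$sample_id[bad[1]]))
  }
  an <- an[match(colnames(v), an$sample_id), ]
  if (anyNA(an$sample_id)) {
    miss <- setdiff(colnames(v), an$sample_id)
    stop(sprintf("samples missing from annotation: %s",
                 paste(utils::head(miss, 5), collapse = ", ")))
  }
  expression_dataset(v, an$perturbed,
                     if (!is.null(an$replicate)) an$replicate else NULL,
                     if (!is.null(an$condition)) an$condition else NULL)
}

#' Write an expression dataset to TSV files
#' @param data an [expression_dataset()].
#' @param expr_file,annot_file output paths.
#' @export
write_expression <- function(data, expr_file, annot_file) {
  stopifnot(inherits(data, "expression_dataset"))
  df <- data.frame(gene = data$genes, data$values, check.names = FALSE)
  utils::write.table(df, expr_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  an <- data.frame(sample_id = data$samples,
                   perturbed = ifelse(is.na(data$perturbed), "WT",
                                      data$perturbed),
                   replicate = data$replicate,
                   condition = data$condition)
  utils::write.table(an, annot_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(data)
}

#' Read a directed network from an edge-list TSV
#'
#' Format: `source<TAB>target[<TAB>weight]`, node ids as strings, no
#' header (a `source...` header line is tolerated and skipped).
#'
#' @param file path.
#' @param n_nodes optional total node count (defaults to the number of
#'   distinct endpoint ids).
#' @return a `directed_network`; node names are kept in the attribute
#'   `"node_names"`.
#' @export
read_network <- function(file, n_nodes = NULL) {
  if (!file.exists(file)) stop(sprintf("network file not found: %s", file))
  df <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE)
  if (identical(tolower(as.character(df[1, 1])), "source")) {
    df <- df[-1, , drop = FALSE]
  }
  if (ncol(df) < 2) stop(sprintf("malformed network file (need >= 2 columns): %s", file))
  ids <- sort(unique(c(df[[1]], df[[2]])))
  n <- n_nodes %||% length(ids)
  edges <- cbind(match(df[[1]], ids), match(df[[2]], ids))
  w <- if (ncol(df) >= 3) as.numeric(df[[3]]) else NULL
  net <- directed_network(n, edges, w)
  attr(net, "node_names") <- ids
  net
}

#' Write a directed network as an edge-list TSV
#' @param net a `directed_network`.
#' @param file output path.
#' @param node_names optional id strings (default `G<i>`).
#' @export
write_network <- function(net, file, node_names = NULL) {
  node_names <- node_names %||% paste0("G", seq_len(net$n_nodes))
  df <- data.frame(source = node_names[net$edges[, 1]],
                   target = node_names[net$edges[, 2]])
  if (!is.null(net$weights)) df$weight <- net$weights
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(net)
}

#' Write an inferred edge list to TSV
#' @param el an `edge_list` (or compatible data.frame).
#' @param file output path.
#' @export
write_edge_list <- function(el, file) {
  utils::write.table(as.data.frame(el), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(el)
}

#' Read an edge list written by [write_edge_list()]
#' @param file path.
#' @return a data.frame of link records.
#' @export
read_edge_list <- function(file) {
  if (!file.exists(file)) stop(sprintf("edge list not found: %s", file))
  utils::read.delim(file, stringsAsFactors = FALSE)
}

#' Write a JSON report
#' @param x a named list of results.
#' @param file output path.
#' @export
write_report <- function(x, file) {
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(x)
}

#' Validate a DREAM-format prediction file
#'
#' Checks the `G1<TAB>G2<TAB>weight` layout with numeric, descending
#' weights.
#'
#' @param file path.
#' @return TRUE invisibly; errors with the offending line number otherwise.
#' @export
validate_prediction_file <- function(file) {
  df <- read_prediction_if_path(file)
  if (!is.numeric(df$score)) {
    stop(sprintf("non-numeric weight in prediction file %s", file))
  }
  if (is.unsorted(rev(df$score))) {
    bad <- which(diff(df$score) > 0)[1]
    stop(sprintf("prediction file %s not in descending order at line %d",
                 file, bad + 1))
  }
  invisible(TRUE)
}
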