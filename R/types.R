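#' Construct a gene expression matrix object
#'
#' The basic expression container: a numeric matrix with genes as rows and
#' samples (cells) as columns, plus an optional per-sample task label used to
#' partition samples into learning tasks (e.g. cell types or batches).
#'
#' @param values numeric matrix, genes x samples.
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param sample_ids character vector of unique sample identifiers (columns).
#' @param task_labels optional character/factor vector, one label per sample;
#'   defaults to a single task `"task1"`.
#' @param is_counts logical; `TRUE` when `values` are untransformed counts
#'   (nonnegative integers).
#' @return an object of class `grn_expression`.
#' @export
grn_expression <- function(values, gene_ids = rownames(values),
                           sample_ids = colnames(values),
                           task_labels = NULL, is_counts = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (is.null(task_labels)) task_labels <- rep("task1", length(sample_ids))
  task_labels <- as.character(task_labels)
  obj <- structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         task_labels = task_labels, is_counts = isTRUE(is_counts)),
    class = "grn_expression")
  validate_grn_expression(obj)
}

validate_grn_expression <- function(x) {
  stopifnot(inherits(x, "grn_expression"))
  if (nrow(x$values) != length(x$gene_ids))
    stop("expression: row count does not match number of gene ids")
  if (ncol(x$values) != length(x$sample_ids))
    stop("expression: column count does not match number of sample ids")
  if (anyDuplicated(x$gene_ids))
    stop("expression: duplicate gene ids: ",
         paste(unique(x$gene_ids[duplicated(x$gene_ids)]), collapse = ", "))
  if (anyDuplicated(x$sample_ids))
    stop("expression: duplicate sample ids")
  if (length(x$task_labels) != length(x$sample_ids))
    stop("expression: task_labels length does not match sample count")
  if (anyNA(x$values)) stop("expression: NA values not allowed")
  if (x$is_counts) {
    if (any(x$values < 0))
      stop("expression: negative values not allowed when is_counts")
    if (any(abs(x$values - round(x$values)) > 1e-8))
      stop("expression: non-integral values not allowed when is_counts")
  }
  rownames(x$values) <- x$gene_ids
  colnames(x$values) <- x$sample_ids
  x
}

#' @exportS3Method print grn_expression
print.grn_expression <- function(x, ...) {
  cat(sprintf("Gene expression matrix: %d genes x %d samples (%s)\n",
              length(x$gene_ids), length(x$sample_ids),
              if (x$is_counts) "counts" else "transformed"))
  tl <- table(x$task_labels)
  cat(sprintf("Tasks: %d (%s)\n", length(tl),
              paste(sprintf("%s=%d", names(tl), tl), collapse = ", ")))
  invisible(x)
}

#' Construct a TF-by-gene adjacency network (prior or gold standard)
#'
#' @param values numeric matrix, TFs x genes; entries in `{-1,0,1}` or real.
#' @param tf_ids,gene_ids unique identifiers for rows/columns.
#' @param role `"prior"` or `"gold_standard"`.
#' @return an object of class `grn_adjacency`.
#' @export
grn_adjacency <- function(values, tf_ids = rownames(values),
                          gene_ids = colnames(values),
                          role = c("prior", "gold_standard")) {
  role <- match.arg(role)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  obj <- structure(
    list(values = values, tf_ids = as.character(tf_ids),
         gene_ids = as.character(gene_ids), role = role),
    class = "grn_adjacency")
  validate_grn_adjacency(obj)
}

validate_grn_adjacency <- function(x) {
  stopifnot(inherits(x, "grn_adjacency"))
  if (nrow(x$values) != length(x$tf_ids) ||
      ncol(x$values) != length(x$gene_ids))
    stop("adjacency: dimensions do not match identifier lists")
  if (anyDuplicated(x$tf_ids)) stop("adjacency: duplicate TF ids")
  if (anyDuplicated(x$gene_ids)) stop("adjacency: duplicate gene ids")
  if (all(x$values == 0)) stop("adjacency: network has no edges")
  self <- intersect(x$tf_ids, x$gene_ids)
  n_self <- sum(vapply(self, function(s)
    x$values[match(s, x$tf_ids), match(s, x$gene_ids)] != 0, logical(1)))
  if (n_self > 0)
    message(sprintf("adjacency: %d self-edge(s) present (TF regulating itself)",
                    n_self))
  rownames(x$values) <- x$tf_ids
  colnames(x$values) <- x$gene_ids
  x
}

#' @exportS3Method print grn_adjacency
print.grn_adjacency <- function(x, ...) {
  cat(sprintf("%s network: %d TFs x %d genes, %d edges\n",
              if (x$role == "prior") "Prior" else "Gold-standard",
              length(x$tf_ids), length(x$gene_ids), sum(x$values != 0)))
  invisible(x)
}

n_edges <- function(adj) sum(adj$values != 0)

#' Construct a TF activity matrix
#'
#' @param values numeric matrix, TFs x samples.
#' @param tf_ids,sample_ids identifiers.
#' @param provenance per-TF tag, `"estimated"` or `"expression_fallback"`.
#' @return an object of class `grn_activities`.
#' @export
grn_activities <- function(values, tf_ids = rownames(values),
                           sample_ids = colnames(values), provenance) {
  values <- as.matrix(values)
  tf_ids <- as.character(tf_ids)
  stopifnot(nrow(values) == length(tf_ids),
            ncol(values) == length(sample_ids),
            length(provenance) == length(tf_ids),
            all(provenance %in% c("estimated", "expression_fallback")))
  rownames(values) <- tf_ids
  colnames(values) <- sample_ids
  structure(list(values = values, tf_ids = tf_ids,
                 sample_ids = as.character(sample_ids),
                 provenance = stats::setNames(provenance, tf_ids)),
            class = "grn_activities")
}

#' @exportS3Method print grn_activities
print.grn_activities <- function(x, ...) {
  cat(sprintf("TF activity matrix: %d TFs x %d samples (%d estimated, %d expression fallback)\n",
              length(x$tf_ids), length(x$sample_ids),
              sum(x$provenance == "estimated"),
              sum(x$provenance == "expression_fallback")))
  invisible(x)
}

#' Construct a scored edge set (one bootstrap/task worth of model output)
#'
#' @param tf,gene,score,beta_sign parallel vectors describing edges; scores
#'   are nonnegative explained-variance scores, signs in `{-1,0,1}`.
#' @param universe list with `tfs` and `genes`: the TF x gene space over
#'   which the scores are defined.
#' @param origin free-form label (task id, bootstrap index).
#' @return an object of class `grn_edge_set`.
#' @export
grn_edge_set <- function(tf, gene, score, beta_sign, universe,
                         origin = "task1/b1") {
  edges <- data.frame(tf = as.character(tf), gene = as.character(gene),
                      score = as.numeric(score),
                      beta_sign = as.integer(beta_sign),
                      stringsAsFactors = FALSE)
  stopifnot(is.list(universe), !is.null(universe$tfs), !is.null(universe$genes))
  if (nrow(edges)) {
    if (any(!is.finite(edges$score)) || any(edges$score < 0))
      stop("edge set: scores must be finite and nonnegative")
    if (anyDuplicated(edges[, c("tf", "gene")]))
      stop("edge set: duplicate (tf, gene) pairs")
    if (!all(edges$tf %in% universe$tfs) || !all(edges$gene %in% universe$genes))
      stop("edge set: edge outside universe")
  }
  structure(list(edges = edges,
                 universe = list(tfs = as.character(universe$tfs),
                                 genes = as.character(universe$genes)),
                 origin = origin),
            class = "grn_edge_set")
}

#' Construct a ranked (rank-combined) network
#'
#' Normally produced by [rank_combine()]; the constructor validates the
#' confidence/rank-sum relationship.
#'
#' @param edges data.frame with columns tf, gene, confidence, rank_sum,
#'   mean_sign.
#' @param universe list with `tfs`, `genes`.
#' @param n_combined number of edge sets combined.
#' @return an object of class `grn_ranked_network`.
#' @export
grn_ranked_network <- function(edges, universe, n_combined) {
  stopifnot(all(c("tf", "gene", "confidence", "rank_sum", "mean_sign")
                %in% names(edges)))
  if (nrow(edges)) {
    if (any(edges$confidence < -1e-12) || any(edges$confidence > 1 + 1e-12))
      stop("ranked network: confidence outside [0,1]")
    if (anyDuplicated(edges[, c("tf", "gene")]))
      stop("ranked network: duplicate edges")
    o <- order(edges$rank_sum)
    if (is.unsorted(-edges$confidence[o]))
      stop("ranked network: confidence must be decreasing in rank_sum")
  }
  edges$confidence <- pmin(1, pmax(0, edges$confidence))
  structure(list(edges = edges,
                 universe = list(tfs = as.character(universe$tfs),
                                 genes = as.character(universe$genes)),
                 n_combined = as.integer(n_combined)),
            class = "grn_ranked_network")
}

#' @exportS3Method print grn_ranked_network
print.grn_ranked_network <- function(x, ...) {
  cat(sprintf("Ranked network: %d scored edges over a %d TF x %d gene universe (%d edge sets combined)\n",
              nrow(x$edges), length(x$universe$tfs), length(x$universe$genes),
              x$n_combined))
  if (nrow(x$edges)) {
    top <- utils::head(x$edges[order(-x$edges$confidence, x$edges$tf,
                                     x$edges$gene), ], 5)
    cat("Top edges:\n")
    print(top, row.names = FALSE)
  }
  invisible(x)
}

universe_size <- function(universe)
  length(universe$tfs) * length(universe$genes)

same_universe <- function(a, b)
  identical(sort(a$tfs), sort(b$tfs)) && identical(sort(a$genes), sort(b$genes))

# Deterministic 32-bit seed derived from a base seed and a string key; used to
# give every (gene, bootstrap, replicate) its own reproducible stream without
# depending on evaluation order.
seed_from_key <- function(base_seed, key) {
  h <- 0
  for (b in utf8ToInt(as.character(key))) h <- (h * 31 + b) %% 2147483647
  as.integer((as.numeric(base_seed) %% 2147483647 + h) %% 2147483647)
}
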