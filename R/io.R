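#' Read a gene expression matrix from disk
#'
#' Two on-disk layouts are supported: a dense TSV (rows = genes, first column
#' = gene id, header = sample ids) and a sparse triplet layout (Matrix-Market
#' coordinate file plus one-identifier-per-line gene and sample files).
#'
#' @param path path to the dense TSV, or to the Matrix-Market file for
#'   `format = "sparse_triplet"`.
#' @param format `"dense_tsv"` or `"sparse_triplet"`.
#' @param gene_file,sample_file identifier lists for the sparse layout;
#'   default `<path>.genes` / `<path>.samples`.
#' @param task_labels optional per-sample task labels.
#' @param is_counts whether values are raw counts (validated as such).
#' @return a [grn_expression] object.
#' @export
read_expression <- function(path, format = c("dense_tsv", "sparse_triplet"),
                            gene_file = paste0(path, ".genes"),
                            sample_file = paste0(path, ".samples"),
                            task_labels = NULL, is_counts = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (format == "dense_tsv") {
    tab <- tryCatch(
      utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                        colClasses = "character", quote = ""),
      error = function(e) stop("parse error reading ", path, ": ",
                               conditionMessage(e)))
    if (ncol(tab) < 2) stop("parse error: dense expression TSV needs a gene id column and >=1 sample column")
    gene_ids <- tab[[1]]
    vals <- suppressWarnings(
      vapply(tab[-1], as.numeric, numeric(nrow(tab))))
    vals <- matrix(vals, nrow = nrow(tab),
                   dimnames = list(NULL, colnames(tab)[-1]))
    bad <- which(apply(is.na(vals), 1, any))
    if (length(bad))
      stop("parse error: non-numeric expression value at data line ", bad[1])
    grn_expression(vals, gene_ids = gene_ids, sample_ids = colnames(tab)[-1],
                   task_labels = task_labels, is_counts = is_counts)
  } else {
    if (!file.exists(gene_file)) stop("gene id file not found: ", gene_file)
    if (!file.exists(sample_file)) stop("sample id file not found: ", sample_file)
    m <- tryCatch(as.matrix(Matrix::readMM(path)),
                  error = function(e) stop("parse error reading ", path, ": ",
                                           conditionMessage(e)))
    gene_ids <- readLines(gene_file)
    sample_ids <- readLines(sample_file)
    if (nrow(m) != length(gene_ids))
      stop("sparse expression: row count ", nrow(m),
           " does not match gene id file (", length(gene_ids), ")")
    if (ncol(m) != length(sample_ids))
      stop("sparse expression: column count does not match sample id file")
    grn_expression(m, gene_ids = gene_ids, sample_ids = sample_ids,
                   task_labels = task_labels, is_counts = is_counts)
  }
}

#' Write a gene expression matrix as dense TSV
#'
#' @param expr a [grn_expression].
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = expr$gene_ids,
                   format(expr$values, digits = 12, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene", expr$sample_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a prior-knowledge or gold-standard network
#'
#' Accepts a 3-column edge list (TF, gene, value; with or without header) or
#' a dense labeled table (rows = TFs, first column = TF id, header = gene
#' ids). With `format = "auto"` a 3-column file is treated as an edge list.
#'
#' @param path file path.
#' @param role `"prior"` or `"gold_standard"`. Gold-standard values are
#'   coerced to sign unless `signed = FALSE` is overridden.
#' @param format `"auto"`, `"edge_list"` or `"dense"`.
#' @param coerce_sign coerce values to `{-1,0,1}`; default `TRUE` for
#'   gold standards.
#' @return a [grn_adjacency] object.
#' @export
read_adjacency <- function(path, role = c("prior", "gold_standard"),
                           format = c("auto", "edge_list", "dense"),
                           coerce_sign = NULL) {
  role <- match.arg(role)
  format <- match.arg(format)
  if (is.null(coerce_sign)) coerce_sign <- role == "gold_standard"
  if (!file.exists(path)) stop("network file not found: ", path)
  first <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (format == "auto") format <- if (length(first) == 3) "edge_list" else "dense"
  if (format == "edge_list") {
    has_header <- is.na(suppressWarnings(as.numeric(first[3])))
    tab <- utils::read.table(path, header = has_header, sep = "\t",
                             colClasses = c("character", "character", "character"),
                             quote = "")
    if (ncol(tab) != 3) stop("parse error: edge list must have 3 columns")
    val <- suppressWarnings(as.numeric(tab[[3]]))
    if (anyNA(val))
      stop("parse error: non-numeric edge value at data line ",
           which(is.na(val))[1])
    key <- paste(tab[[1]], tab[[2]], sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate edge in network file: ",
           gsub("\r", " -> ", key[duplicated(key)][1]))
    tfs <- sort(unique(tab[[1]]))
    genes <- sort(unique(tab[[2]]))
    m <- matrix(0, length(tfs), length(genes), dimnames = list(tfs, genes))
    m[cbind(match(tab[[1]], tfs), match(tab[[2]], genes))] <- val
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, quote = "",
                             colClasses = "character")
    tfs <- tab[[1]]
    m <- vapply(tab[-1], function(col) suppressWarnings(as.numeric(col)),
                numeric(nrow(tab)))
    m <- matrix(m, nrow = nrow(tab), dimnames = list(tfs, colnames(tab)[-1]))
    if (anyNA(m)) stop("parse error: non-numeric value in dense network table")
  }
  if (coerce_sign) m <- sign(m)
  grn_adjacency(m, tf_ids = rownames(m), gene_ids = colnames(m), role = role)
}

#' Write a network as a 3-column edge list TSV
#'
#' @param adj a [grn_adjacency].
#' @param path output path.
#' @export
write_adjacency <- function(adj, path) {
  idx <- which(adj$values != 0, arr.ind = TRUE)
  df <- data.frame(tf = adj$tf_ids[idx[, 1]], gene = adj$gene_ids[idx[, 2]],
                   value = adj$values[idx], stringsAsFactors = FALSE)
  df <- df[order(df$tf, df$gene), ]
  df$value <- sprintf("%.10g", df$value)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align expression, prior and gold-standard namespaces
#'
#' Restricts network gene axes to genes measured in the expression matrix and
#' canonicalizes ordering (lexicographic). TFs are kept even when their own
#' expression is not measured: their activity can still be estimated from
#' their prior targets. The expression object itself is returned unchanged
#' apart from validation.
#'
#' @param expr a [grn_expression].
#' @param prior a [grn_adjacency] with role prior.
#' @param gold optional [grn_adjacency] with role gold_standard.
#' @return list with elements `expression`, `prior`, `gold` (or NULL), and
#'   `dropped` (counts of discarded identifiers).
#' @export
align_namespaces <- function(expr, prior, gold = NULL) {
  keep_genes <- sort(intersect(prior$gene_ids, expr$gene_ids))
  if (!length(keep_genes))
    stop("no genes shared between expression matrix and prior network")
  dropped_genes <- setdiff(prior$gene_ids, keep_genes)
  tf_order <- sort(prior$tf_ids)
  pv <- prior$values[match(tf_order, prior$tf_ids),
                     match(keep_genes, prior$gene_ids), drop = FALSE]
  prior2 <- grn_adjacency(pv, tf_order, keep_genes, role = prior$role)
  tf_unmeasured <- setdiff(tf_order, expr$gene_ids)
  if (length(dropped_genes) || length(tf_unmeasured))
    message(sprintf("align: dropped %d prior gene(s) absent from expression; %d TF(s) have no measured expression",
                    length(dropped_genes), length(tf_unmeasured)))
  gold2 <- NULL
  dropped_gold <- 0L
  if (!is.null(gold)) {
    gg <- sort(intersect(gold$gene_ids, expr$gene_ids))
    if (!length(gg))
      stop("no genes shared between expression matrix and gold standard")
    dropped_gold <- length(setdiff(gold$gene_ids, gg))
    gt <- sort(gold$tf_ids)
    gold2 <- grn_adjacency(gold$values[match(gt, gold$tf_ids),
                                       match(gg, gold$gene_ids), drop = FALSE],
                           gt, gg, role = gold$role)
  }
  list(expression = validate_grn_expression(expr), prior = prior2,
       gold = gold2,
       dropped = list(prior_genes = length(dropped_genes),
                      unmeasured_tfs = length(tf_unmeasured),
                      gold_genes = dropped_gold))
}

#' Write a ranked network to TSV
#'
#' Tab-separated with header `tf target confidence rank_sum sign`, sorted by
#' confidence descending with lexicographic (tf, target) tie-break. Numeric
#' columns round-trip at 10 significant digits via [read_ranked_network()].
#'
#' @param net a [grn_ranked_network].
#' @param path output path.
#' @export
write_ranked_network <- function(net, path) {
  e <- net$edges[order(-net$edges$confidence, net$edges$tf, net$edges$gene), ]
  df <- data.frame(tf = e$tf, target = e$gene,
                   confidence = sprintf("%.10g", e$confidence),
                   rank_sum = sprintf("%.10g", e$rank_sum),
                   sign = e$mean_sign, stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok) stop("cannot write ranked network to ", path)
  # universe + combination count ride along so the file round-trips
  meta <- file.path(dirname(path), paste0(basename(path), ".meta.json"))
  jsonlite::write_json(list(tfs = net$universe$tfs, genes = net$universe$genes,
                            n_combined = net$n_combined),
                       meta, auto_unbox = TRUE)
  invisible(path)
}

#' Read a ranked network written by [write_ranked_network()]
#'
#' @param path path to the TSV.
#' @return a [grn_ranked_network].
#' @export
read_ranked_network <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "character", "numeric",
                                          "numeric", "integer"), quote = "")
  meta_path <- file.path(dirname(path), paste0(basename(path), ".meta.json"))
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    uni <- list(tfs = meta$tfs, genes = meta$genes)
    ncomb <- meta$n_combined
  } else {
    uni <- list(tfs = sort(unique(tab$tf)), genes = sort(unique(tab$target)))
    ncomb <- 1L
  }
  grn_ranked_network(
    data.frame(tf = tab$tf, gene = tab$target, confidence = tab$confidence,
               rank_sum = tab$rank_sum, mean_sign = tab$sign,
               stringsAsFactors = FALSE),
    universe = uni, n_combined = ncomb)
}
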