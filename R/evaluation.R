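#' Hold genes out of a prior network for cross-validation
#'
#' Selects `round(fraction * n)` of the `n` genes that have at least one
#' prior edge, uniformly without replacement, and zeroes their columns in the
#' training prior. Networks learned from the training prior are then scored
#' on the held-out genes only.
#'
#' @param prior a [grn_adjacency].
#' @param fraction fraction in `[0, 1)` of prior genes to hold out.
#' @param seed integer seed.
#' @return list with `training_prior`, `holdout_genes`, `fraction`, `seed`.
#' @export
split_prior_holdout <- function(prior, fraction = 0.2, seed = 42) {
  if (fraction >= 1) stop("holdout fraction must be < 1")
  with_edges <- prior$gene_ids[colSums(prior$values != 0) > 0]
  if (fraction > 0 && length(with_edges) < 5)
    stop("prior has fewer than 5 genes with edges; cannot hold out")
  n_hold <- round(fraction * length(with_edges))
  set.seed(seed)
  holdout <- sort(sample(with_edges, n_hold))
  v <- prior$values
  v[, match(holdout, prior$gene_ids)] <- 0
  training <- if (n_hold < length(with_edges))
    grn_adjacency(v, prior$tf_ids, prior$gene_ids, role = prior$role)
  else stop("holdout removed every prior edge")
  list(training_prior = training, holdout_genes = holdout,
       fraction = fraction, seed = seed)
}

#' Score a ranked network against a gold standard
#'
#' The scoring universe is (TFs in the gold standard) x (genes in the gold
#' standard, optionally restricted to e.g. held-out genes), intersected with
#' the network's universe. Edges are walked in confidence order with
#' equal-confidence edges treated as one block (block-averaged precision);
#' universe edges missing from the network are appended as a final all-tied
#' block so recall always reaches 1. AUPR is average precision over the
#' positives; the random baseline is `P / U`. MCC and F1 are evaluated at
#' every block boundary.
#'
#' @param net a [grn_ranked_network].
#' @param gold a [grn_adjacency] (role gold_standard or prior).
#' @param restrict_to_genes optional character vector restricting the scored
#'   gene set (e.g. holdout genes).
#' @return an object of class `grn_score`: list with `aupr`,
#'   `random_baseline`, `max_mcc`, `max_f1`, `n_positives`, `universe_size`,
#'   and a `curve` data.frame (recall, precision, mcc, f1 per block).
#' @export
score_network <- function(net, gold, restrict_to_genes = NULL) {
  tfs <- intersect(net$universe$tfs, gold$tf_ids)
  genes <- intersect(net$universe$genes, gold$gene_ids)
  if (!is.null(restrict_to_genes)) genes <- intersect(genes, restrict_to_genes)
  if (!length(tfs) || !length(genes))
    stop("score_network: empty scoring universe")
  U <- length(tfs) * length(genes)
  gv <- gold$values[match(tfs, gold$tf_ids), match(genes, gold$gene_ids),
                    drop = FALSE]
  pos_keys <- paste(tfs[which(gv != 0, arr.ind = TRUE)[, 1]],
                    genes[which(gv != 0, arr.ind = TRUE)[, 2]], sep = "\r")
  P <- length(pos_keys)
  if (P == 0) stop("score_network: no gold positives in scoring universe")
  e <- net$edges[net$edges$tf %in% tfs & net$edges$gene %in% genes, ,
                 drop = FALSE]
  e <- e[order(-e$confidence, e$tf, e$gene), , drop = FALSE]
  conf <- e$confidence
  is_pos <- paste(e$tf, e$gene, sep = "\r") %in% pos_keys
  # final block: universe pairs the network never scored
  n_missing <- U - nrow(e)
  pos_missing <- P - sum(is_pos)
  block_id <- c(if (nrow(e)) cumsum(!duplicated(conf)) else integer(0))
  nb <- if (length(block_id)) max(block_id) else 0L
  size <- tabulate(block_id, nb)
  pos_in <- vapply(seq_len(nb), function(b) sum(is_pos[block_id == b]),
                   numeric(1))
  bconf <- conf[!duplicated(conf)]
  if (n_missing > 0) {
    size <- c(size, n_missing)
    pos_in <- c(pos_in, pos_missing)
    bconf <- c(bconf, -Inf)
    nb <- nb + 1L
  }
  cum_n <- cumsum(size)
  cum_tp <- cumsum(pos_in)
  precision <- cum_tp / cum_n
  recall <- cum_tp / P
  aupr <- sum(pos_in * precision) / P
  tp <- cum_tp; fpv <- cum_n - cum_tp; fnv <- P - tp; tnv <- U - cum_n - fnv
  mcc <- mcc_from_counts(tp, fpv, fnv, tnv)
  f1 <- f1_from_counts(tp, fpv, fnv)
  structure(list(aupr = aupr, random_baseline = P / U,
                 max_mcc = max(mcc), max_f1 = max(f1),
                 n_positives = P, universe_size = U,
                 curve = data.frame(confidence = bconf, recall = recall,
                                    precision = precision, mcc = mcc,
                                    f1 = f1)),
            class = "grn_score")
}

#' @exportS3Method print grn_score
print.grn_score <- function(x, ...) {
  cat(sprintf("Network score: AUPR %.4f (random baseline %.4f, %.1fx)\n",
              x$aupr, x$random_baseline, x$aupr / x$random_baseline))
  cat(sprintf("  %d positives over universe of %d; max MCC %.3f, max F1 %.3f\n",
              x$n_positives, x$universe_size, x$max_mcc, x$max_f1))
  invisible(x)
}
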