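#' Rank-combine scored edge sets into a confidence-ranked network
#'
#' Within each edge set, edges are ranked by score descending (rank 1 best,
#' ties get the average rank); edges of the universe absent from a set get
#' the worst possible rank (the universe size `U`). Rank sums over the `M`
#' sets map affinely to a confidence in `[0, 1]`:
#' `confidence = 1 - (rank_sum - M) / (M * (U - 1))`, so an edge ranked first
#' everywhere has confidence 1 and one absent everywhere has confidence 0.
#' The combined sign is the sign of the mean of the per-set coefficient signs.
#'
#' @param edge_sets list of [grn_edge_set] sharing one universe.
#' @return a [grn_ranked_network] holding every edge scored in at least one
#'   set.
#' @export
rank_combine <- function(edge_sets) {
  stopifnot(length(edge_sets) >= 1)
  uni <- edge_sets[[1]]$universe
  for (es in edge_sets)
    if (!same_universe(uni, es$universe))
      stop("rank_combine: edge sets have mismatched universes")
  U <- universe_size(uni)
  M <- length(edge_sets)
  key_of <- function(tf, gene) paste(tf, gene, sep = "\r")
  rank_sum <- list(); sign_sum <- list(); seen <- list()
  acc <- new.env(parent = emptyenv())
  for (es in edge_sets) {
    e <- es$edges
    if (!nrow(e)) next
    r <- rank(-e$score, ties.method = "average")
    for (i in seq_len(nrow(e))) {
      k <- key_of(e$tf[i], e$gene[i])
      prev <- acc[[k]]
      if (is.null(prev)) prev <- c(0, 0, 0)  # rank_sum_present, n_present, sign
      acc[[k]] <- prev + c(r[i], 1, e$beta_sign[i])
    }
  }
  keys <- ls(acc)
  if (!length(keys)) {
    return(grn_ranked_network(
      data.frame(tf = character(0), gene = character(0),
                 confidence = numeric(0), rank_sum = numeric(0),
                 mean_sign = integer(0)), uni, M))
  }
  vals <- vapply(keys, function(k) acc[[k]], numeric(3))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  rank_sum <- vals[1, ] + (M - vals[2, ]) * U  # absent sets contribute rank U
  confidence <- 1 - (rank_sum - M) / (M * (U - 1))
  edges <- data.frame(tf = vapply(parts, `[[`, "", 1),
                      gene = vapply(parts, `[[`, "", 2),
                      confidence = confidence, rank_sum = rank_sum,
                      mean_sign = as.integer(sign(vals[3, ])),
                      stringsAsFactors = FALSE)
  edges <- edges[order(-edges$confidence, edges$tf, edges$gene), ]
  rownames(edges) <- NULL
  grn_ranked_network(edges, uni, M)
}

# Confusion counts swept over the distinct confidence thresholds of a ranked
# network against a reference adjacency, counted over the full universe.
confusion_sweep <- function(net, reference) {
  uni <- net$universe
  ref_keys <- adjacency_edge_keys(reference)
  ref_keys <- ref_keys[ref_keys %in% universe_keys(uni)]
  P <- length(ref_keys)
  U <- universe_size(uni)
  if (P == 0) stop("reference network empty over the ranked-network universe")
  e <- net$edges[order(-net$edges$confidence, net$edges$tf, net$edges$gene), ]
  is_pos <- paste(e$tf, e$gene, sep = "\r") %in% ref_keys
  thresholds <- unique(e$confidence)
  tp <- fp <- integer(length(thresholds))
  cum_tp <- cumsum(is_pos)
  cum_n <- seq_len(nrow(e))
  last_of_block <- !duplicated(e$confidence, fromLast = TRUE)
  tp <- cum_tp[last_of_block]
  nn <- cum_n[last_of_block]
  fp <- nn - tp
  fn <- P - tp
  tn <- U - nn - fn
  list(thresholds = thresholds, tp = tp, fp = fp, fn = fn, tn = tn,
       P = P, U = U)
}

mcc_from_counts <- function(tp, fp, fn, tn) {
  den <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tn + fn))
  ifelse(den == 0, 0, (tp * tn - fp * fn) / den)
}

f1_from_counts <- function(tp, fp, fn) {
  den <- 2 * tp + fp + fn
  ifelse(den == 0, 0, 2 * tp / den)
}

#' Size a ranked network by maximizing MCC (or F1) against a reference
#'
#' Sweeps every distinct confidence threshold; at threshold `t` the predicted
#' positives are the edges with confidence >= t, and the Matthews correlation
#' coefficient is computed over the full TF x gene universe (MCC is 0
#' whenever a marginal is empty). Returns the largest threshold achieving the
#' maximum, the retained edges, and the full sweep curve. Maximum F1 gives a
#' less conservative network (true negatives do not enter F1).
#'
#' @param net a [grn_ranked_network].
#' @param reference a [grn_adjacency] (e.g. the prior or its union across
#'   tasks) defining positives.
#' @param metric `"mcc"` or `"f1"`.
#' @return list with `threshold`, `network` (filtered [grn_ranked_network]),
#'   `curve` (data.frame threshold/tp/fp/fn/tn/mcc/f1), `max_metric`.
#' @export
threshold_max_mcc <- function(net, reference, metric = c("mcc", "f1")) {
  metric <- match.arg(metric)
  if (!nrow(net$edges)) stop("threshold_max_mcc: ranked network has no edges")
  sw <- confusion_sweep(net, reference)
  mcc <- mcc_from_counts(sw$tp, sw$fp, sw$fn, sw$tn)
  f1 <- f1_from_counts(sw$tp, sw$fp, sw$fn)
  vals <- if (metric == "mcc") mcc else f1
  best <- which(vals == max(vals))[1]  # thresholds descend: first = largest t
  thr <- sw$thresholds[best]
  keep <- net$edges[net$edges$confidence >= thr, , drop = FALSE]
  rownames(keep) <- NULL
  list(threshold = thr,
       network = grn_ranked_network(keep, net$universe, net$n_combined),
       curve = data.frame(threshold = sw$thresholds, tp = sw$tp, fp = sw$fp,
                          fn = sw$fn, tn = sw$tn, mcc = mcc, f1 = f1),
       max_metric = vals[best], metric = metric)
}

adjacency_edge_keys <- function(adj) {
  idx <- which(adj$values != 0, arr.ind = TRUE)
  paste(adj$tf_ids[idx[, 1]], adj$gene_ids[idx[, 2]], sep = "\r")
}

universe_keys <- function(uni)
  as.vector(outer(uni$tfs, uni$genes, paste, sep = "\r"))
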