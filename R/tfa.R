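#' Estimate transcription factor activities
#'
#' Estimates a latent per-sample activity for each TF from the prior network
#' by least squares: with `P` the genes x TFs prior connectivity (self-edges
#' zeroed) and `X` the genes x samples expression, the activity matrix is
#' `A_hat = pinv(P) %*% X`. A TF whose prior column is empty after alignment
#' falls back to its own expression row when the TF is a measured gene
#' (provenance `"expression_fallback"`); otherwise it is dropped with a
#' warning.
#'
#' @param expr a [grn_expression] (normally transformed, not raw counts).
#' @param prior a [grn_adjacency] aligned to the expression gene space.
#' @param svd_tol relative singular-value cutoff for the pseudoinverse;
#'   singular values below `svd_tol * max(sv)` are treated as zero.
#' @return a [grn_activities] object (TFs x samples with provenance tags).
#' @export
estimate_tfa <- function(expr, prior, svd_tol = 1e-10) {
  genes <- intersect(prior$gene_ids, expr$gene_ids)
  if (!length(genes)) stop("estimate_tfa: prior and expression share no genes")
  P <- t(prior$values[, match(genes, prior$gene_ids), drop = FALSE])
  rownames(P) <- genes
  # a TF trivially "explains" its own transcript; remove self-edges
  self <- intersect(colnames(P), genes)
  if (length(self)) P[cbind(match(self, genes), match(self, colnames(P)))] <- 0
  has_targets <- colSums(P != 0) > 0
  if (!any(has_targets) && !any(prior$tf_ids %in% expr$gene_ids))
    stop("estimate_tfa: prior empty after alignment and no TF is measured")
  tfs <- colnames(P)
  X <- expr$values[match(genes, expr$gene_ids), , drop = FALSE]
  act <- matrix(0, length(tfs), ncol(X), dimnames = list(tfs, expr$sample_ids))
  if (any(has_targets)) {
    Pt <- P[, has_targets, drop = FALSE]
    act[has_targets, ] <- pseudoinverse(Pt, tol = svd_tol) %*% X
  }
  provenance <- ifelse(has_targets, "estimated", "expression_fallback")
  fallback <- !has_targets
  measured <- tfs %in% expr$gene_ids
  drop_tf <- fallback & !measured
  if (any(fallback & measured)) {
    idx <- which(fallback & measured)
    act[idx, ] <- expr$values[match(tfs[idx], expr$gene_ids), , drop = FALSE]
  }
  if (any(drop_tf)) {
    warning("estimate_tfa: dropped ", sum(drop_tf),
            " TF(s) with no prior targets and no measured expression: ",
            paste(utils::head(tfs[drop_tf], 5), collapse = ", "))
    act <- act[!drop_tf, , drop = FALSE]
    provenance <- provenance[!drop_tf]
    tfs <- tfs[!drop_tf]
  }
  grn_activities(act, tf_ids = tfs, sample_ids = expr$sample_ids,
                 provenance = provenance)
}

#' Moore-Penrose pseudoinverse via singular value decomposition
#'
#' @param A numeric matrix.
#' @param tol singular values below `tol * max(singular values)` are zeroed.
#' @return the pseudoinverse of `A`.
#' @export
pseudoinverse <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
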