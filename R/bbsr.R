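#' Mutual information and context likelihood of relatedness (CLR)
#'
#' Computes pairwise mutual information between every regressor (TF activity)
#' and every target gene by equal-width binning of each variable over its
#' observed range, then background-corrects it: `CLR_ij =
#' sqrt(max(0, z_row)^2 + max(0, z_col)^2)` where the z-scores standardize
#' `MI_ij` against its row and column MI distributions. Constant variables
#' have MI 0 by convention.
#'
#' @param targets numeric matrix, genes x samples.
#' @param regressors numeric matrix, TFs x samples.
#' @param n_bins number of equal-width bins per variable (>= 2).
#' @return list with `mi` and `clr`, both TFs x genes and nonnegative.
#' @export
compute_mi_clr <- function(targets, regressors, n_bins = 10) {
  stopifnot(ncol(targets) == ncol(regressors), ncol(targets) >= 2, n_bins >= 2)
  n <- ncol(targets)
  bin <- function(m) {
    t(apply(m, 1, function(v) {
      r <- range(v)
      if (r[2] <= r[1]) return(rep(NA_integer_, n))  # constant: MI 0
      pmin(n_bins, 1L + as.integer(floor((v - r[1]) / (r[2] - r[1]) * n_bins)))
    }))
  }
  bt <- bin(targets)
  br <- bin(regressors)
  bt[is.na(bt)] <- 0L
  br[is.na(br)] <- 0L
  storage.mode(bt) <- storage.mode(br) <- "integer"
  mi <- .mi_matrix(br, bt, as.integer(n_bins))
  dimnames(mi) <- list(rownames(regressors), rownames(targets))
  zr <- (mi - rowMeans(mi)) / apply(mi, 1, function(v) {
    s <- stats::sd(v); if (is.na(s) || s == 0) Inf else s
  })
  zc <- t((t(mi) - colMeans(mi)) / apply(mi, 2, function(v) {
    s <- stats::sd(v); if (is.na(s) || s == 0) Inf else s
  }))
  clr <- sqrt(pmax(zr, 0)^2 + pmax(zc, 0)^2)
  list(mi = mi, clr = clr)
}

#' Select candidate regulators for one gene
#'
#' Prior regulators of the gene come first, ordered by CLR descending, and
#' are truncated at `nK`; if fewer than `nK` prior regulators exist, the list
#' is filled with the highest-CLR non-prior TFs. The gene's own TF (when the
#' gene is itself a TF) is never a candidate. Ties break lexicographically.
#'
#' @param gene_id gene identifier.
#' @param prior a [grn_adjacency].
#' @param clr CLR matrix (TFs x genes) from [compute_mi_clr()].
#' @param nK maximum number of candidates.
#' @return character vector of candidate TF ids (possibly empty).
#' @export
select_candidates <- function(gene_id, prior, clr, nK = 10) {
  stopifnot(nK >= 1)
  tfs <- setdiff(rownames(clr), gene_id)
  if (!length(tfs)) return(character(0))
  cl <- if (gene_id %in% colnames(clr)) clr[tfs, gene_id] else
    stats::setNames(rep(0, length(tfs)), tfs)
  in_prior <- if (gene_id %in% prior$gene_ids) {
    pt <- prior$tf_ids[prior$values[, match(gene_id, prior$gene_ids)] != 0]
    tfs %in% pt
  } else rep(FALSE, length(tfs))
  ord <- order(!in_prior, -cl, tfs)
  pri <- tfs[ord][in_prior[ord]]
  oth <- tfs[ord][!in_prior[ord]]
  utils::head(c(utils::head(pri, nK), oth), nK)
}

# OLS residual sum of squares (and coefficients) for a column subset via a
# precomputed Gram system; returns NULL when the subset design is singular.
ols_subset <- function(G, Xy, yy, idx) {
  if (!length(idx)) return(list(rss = yy, beta = numeric(0)))
  Gm <- G[idx, idx, drop = FALSE]
  beta <- tryCatch(solve(Gm, Xy[idx]), error = function(e) NULL)
  if (is.null(beta) || any(!is.finite(beta))) return(NULL)
  list(rss = max(yy - sum(beta * Xy[idx]), 0), beta = beta)
}

#' Best-subset regression with BIC selection
#'
#' Enumerates all subsets of the candidate predictors, scores each by
#' `BIC = n * ln(max(RSS, eps)/n) + ln(n) * sum(w_j)` over its predictors,
#' and returns the minimizer (ties: fewer predictors, then lexicographically
#' smaller predictor set). Per-predictor penalty weights `w_j < 1` favor
#' inclusion (used to encode prior support). Each selected predictor gets an
#' explained-variance score `d_j = max(0, 1 - RSS_full / RSS_without_j)`.
#'
#' @param y centered response vector.
#' @param X predictor matrix (columns = candidates, normally standardized).
#' @param penalty_weights per-candidate BIC weights (default all 1).
#' @param eps RSS floor guarding `log(0)`.
#' @return list with `selected` (column names or indices), `coefficients`,
#'   `scores` (d_j), `bic`, `n`.
#' @export
best_subset_regression <- function(y, X, penalty_weights = rep(1, ncol(X)),
                                   eps = 1e-10) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  stopifnot(nrow(X) == n, length(penalty_weights) == p, n > p + 1)
  cn <- colnames(X)
  if (is.null(cn)) cn <- as.character(seq_len(p))
  G <- crossprod(X)
  Xy <- drop(crossprod(X, y))
  yy <- sum(y^2)
  bics <- .subset_bics(G, Xy, yy, as.integer(n), penalty_weights, eps)
  if (all(!is.finite(bics))) stop("best_subset_regression: all subsets singular")
  masks <- which(bics == min(bics)) - 1L  # ties resolved below
  if (length(masks) > 1) {
    subsets <- lapply(masks, function(m)
      which(bitwAnd(m, bitwShiftL(1L, seq_len(p) - 1L)) != 0L))
    sizes <- lengths(subsets)
    subsets <- subsets[sizes == min(sizes)]
    keys <- vapply(subsets, function(s) paste(cn[s], collapse = "\r"), "")
    idx <- subsets[[order(keys)[1]]]
  } else {
    idx <- which(bitwAnd(masks, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
  }
  best <- list(idx = idx, bic = min(bics), fit = ols_subset(G, Xy, yy, idx))
  scores <- numeric(length(idx))
  if (length(idx)) {
    rss_full <- best$fit$rss
    for (k in seq_along(idx)) {
      f <- ols_subset(G, Xy, yy, idx[-k])
      rss_mj <- if (is.null(f)) NA_real_ else f$rss
      scores[k] <- if (is.na(rss_mj)) 0 else
        max(0, 1 - rss_full / max(rss_mj, eps))
    }
  }
  list(selected = cn[idx],
       coefficients = stats::setNames(as.numeric(best$fit$beta), cn[idx]),
       scores = stats::setNames(scores, cn[idx]),
       bic = best$bic, n = n)
}

# Bootstrap column indices: draws are indexed against the canonical
# (sorted-sample-id) order so permuting input columns cannot change the
# resampled dataset.
bootstrap_columns <- function(sample_ids, seed) {
  ord <- order(sample_ids)
  set.seed(seed)
  ord[sample.int(length(sample_ids), length(sample_ids), replace = TRUE)]
}

# Shared per-gene model loop for the single-task engines. `fit_gene` maps
# (y, X, candidates) to a list(selected, coefficients, scores).
engine_edges <- function(expr_vals, act_vals, genes, fit_gene) {
  out_tf <- character(0); out_gene <- character(0)
  out_score <- numeric(0); out_sign <- integer(0)
  tf_ids <- rownames(act_vals)
  Xall <- t(act_vals)
  sds <- col_pop_sd(Xall)
  for (g in genes) {
    y <- expr_vals[g, ]
    y <- y - mean(y)
    if (all(y == 0)) next
    keep_tf <- setdiff(tf_ids[sds > 0], g)
    if (!length(keep_tf)) next
    Xs <- scale_pop(Xall[, keep_tf, drop = FALSE])
    fit <- tryCatch(fit_gene(y, Xs, g),
                    error = function(e) { message("gene ", g, " skipped: ",
                                                  conditionMessage(e)); NULL })
    if (is.null(fit) || !length(fit$selected)) next
    out_tf <- c(out_tf, fit$selected)
    out_gene <- c(out_gene, rep(g, length(fit$selected)))
    out_score <- c(out_score, fit$scores[fit$selected])
    out_sign <- c(out_sign, as.integer(sign(fit$coefficients[fit$selected])))
  }
  list(tf = out_tf, gene = out_gene, score = out_score, sign = out_sign)
}

pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

col_pop_sd <- function(M) {
  mu <- colMeans(M)
  sqrt(pmax(colMeans(M * M) - mu * mu, 0))
}

scale_pop <- function(M) {
  mu <- colMeans(M)
  sd <- col_pop_sd(M)
  sd[sd == 0] <- 1
  sweep(sweep(M, 2, mu), 2, sd, `/`)
}

#' Run the BBSR engine over bootstraps
#'
#' For each bootstrap (samples drawn with replacement), candidate regulators
#' per gene are preselected by prior membership and CLR, the best subset is
#' chosen by BIC, and each selected edge is scored by its explained-variance
#' contribution `d_j` with the sign of its coefficient.
#'
#' @param expr a [grn_expression] (transformed values; regression targets are
#'   its genes).
#' @param activities a [grn_activities] for the same samples.
#' @param prior a [grn_adjacency] (drives candidate preselection and penalty
#'   weights).
#' @param n_bootstraps number of bootstrap resamples.
#' @param seed base seed; bootstrap `b` uses `seed + b`.
#' @param nK candidate cap per gene.
#' @param prior_penalty_weight BIC weight for prior-supported candidates
#'   (1 = no reweighting; < 1 favors prior edges).
#' @param n_bins MI bins.
#' @return list of [grn_edge_set], one per bootstrap.
#' @export
run_bbsr <- function(expr, activities, prior, n_bootstraps = 5, seed = 42,
                     nK = 10, prior_penalty_weight = 1, n_bins = 10) {
  stopifnot(identical(expr$sample_ids, activities$sample_ids))
  universe <- list(tfs = activities$tf_ids, genes = expr$gene_ids)
  lapply(seq_len(n_bootstraps), function(b) {
    cols <- bootstrap_columns(expr$sample_ids, seed + b)
    ev <- expr$values[, cols, drop = FALSE]
    av <- activities$values[, cols, drop = FALSE]
    clr <- compute_mi_clr(ev, av, n_bins = n_bins)$clr
    res <- engine_edges(ev, av, expr$gene_ids, function(y, Xs, g) {
      cand <- intersect(select_candidates(g, prior, clr, nK), colnames(Xs))
      if (!length(cand)) return(list(selected = character(0)))
      w <- rep(1, length(cand))
      if (g %in% prior$gene_ids) {
        pt <- prior$tf_ids[prior$values[, match(g, prior$gene_ids)] != 0]
        w[cand %in% pt] <- prior_penalty_weight
      }
      best_subset_regression(y, Xs[, cand, drop = FALSE], penalty_weights = w)
    })
    grn_edge_set(res$tf, res$gene, res$score, res$sign, universe,
                 origin = sprintf("bootstrap%d", b))
  })
}
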