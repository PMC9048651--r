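#' Lasso (L1-penalized least squares) by coordinate descent
#'
#' Minimizes `(1/(2n)) ||y - X b||^2 + lam * sum_j w_j |b_j|`. At `lam = 0`
#' the ordinary least-squares solution is returned directly.
#'
#' @param y centered response.
#' @param X predictor matrix (normally standardized columns).
#' @param lam nonnegative penalty.
#' @param weights optional per-predictor penalty multipliers (default 1).
#' @param tol,maxit coordinate-descent stopping controls.
#' @return numeric coefficient vector (named after `X` columns).
#' @export
solve_l1_least_squares <- function(y, X, lam, weights = rep(1, ncol(X)),
                                   tol = 1e-10, maxit = 1e5) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), lam >= 0, length(weights) == ncol(X))
  if (lam == 0) {
    b <- stats::lm.fit(X, y)$coefficients
    b[is.na(b)] <- 0
  } else {
    b <- .cd_lasso(X, y, lam, weights, numeric(ncol(X)), tol, as.integer(maxit))
    b[abs(b) < 1e-12] <- 0
  }
  stats::setNames(as.numeric(b), colnames(X))
}

#' Smallest penalty that zeroes every lasso coefficient
#'
#' @param y centered response; @param X predictor matrix.
#' @return `max_j |x_j' y| / n`.
#' @export
lasso_lambda_max <- function(y, X) max(abs(crossprod(X, y))) / length(y)

#' StARS: choose the lasso penalty by stability selection
#'
#' Fits the lasso path on `n_subsamples` subsamples (without replacement, of
#' size `ceil(subsample_fraction * n)`) over a log-spaced grid from
#' `lambda_max` down to `0.01 * lambda_max`. For each penalty, the selection
#' frequency `theta_j` of every predictor yields the mean edge instability
#' `D = mean_j 2 theta_j (1 - theta_j)`, which is monotonized from the
#' largest penalty downward. The selected penalty is the smallest grid value
#' whose monotonized instability is at most `threshold` (least regularization
#' that is still stable); if none qualifies, `lambda_max` is returned.
#'
#' @param y centered response.
#' @param X standardized predictor matrix.
#' @param grid_size,n_subsamples,subsample_fraction,threshold StARS controls.
#' @param seed integer seed for the subsample draws.
#' @return list with `lambda` (the selection) and `path` (a `grn_stars_path`:
#'   lambdas, theta matrix, instability `D`, monotonized `D_bar`).
#' @export
stars_select_lambda <- function(y, X, grid_size = 20, n_subsamples = 20,
                                subsample_fraction = 0.63, threshold = 0.05,
                                seed = 42) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(n >= 10, nrow(X) == n)
  if (pop_sd(y) == 0)
    return(list(lambda = NA_real_, path = NULL, degenerate = TRUE))
  lmax <- lasso_lambda_max(y, X)
  if (lmax <= 0) return(list(lambda = NA_real_, path = NULL, degenerate = TRUE))
  lambdas <- exp(seq(log(lmax), log(0.01 * lmax), length.out = grid_size))
  m <- as.integer(ceiling(subsample_fraction * n))
  p <- ncol(X)
  sel <- matrix(0, p, grid_size)
  set.seed(seed)
  w <- rep(1, p)
  for (s in seq_len(n_subsamples)) {
    idx <- sample.int(n, m)
    ys <- y[idx] - mean(y[idx])
    Xs <- scale_pop(X[idx, , drop = FALSE])
    beta <- .cd_lasso_path_gram(crossprod(Xs) / m, drop(crossprod(Xs, ys)) / m,
                                lambdas, w, 1e-8, 10000L)
    sel <- sel + (beta != 0)
  }
  theta <- sel / n_subsamples
  D <- colMeans(2 * theta * (1 - theta))
  D_bar <- cummax(D)
  ok <- which(D_bar <= threshold)
  lambda <- if (length(ok)) lambdas[max(ok)] else lmax
  path <- structure(list(lambdas = lambdas, theta = theta, D = D,
                         D_bar = D_bar, threshold = threshold),
                    class = "grn_stars_path")
  list(lambda = lambda, path = path, degenerate = FALSE)
}

#' Run the StARS-LASSO engine over bootstraps
#'
#' Per bootstrap and per gene: the penalty is chosen by [stars_select_lambda()],
#' the lasso is fit on the full bootstrap at that penalty, and the selected
#' support is refit by OLS to compute the same explained-variance scores
#' `d_j` as the best-subset engine. All TF activities are candidate
#' predictors; the prior influences this engine only through the activity
#' estimates.
#'
#' @inheritParams run_bbsr
#' @param grid_size,n_subsamples,subsample_fraction,threshold StARS controls.
#' @return list of [grn_edge_set], one per bootstrap.
#' @export
run_stars_lasso <- function(expr, activities, prior = NULL, n_bootstraps = 5,
                            seed = 42, grid_size = 20, n_subsamples = 20,
                            subsample_fraction = 0.63, threshold = 0.05) {
  stopifnot(identical(expr$sample_ids, activities$sample_ids))
  universe <- list(tfs = activities$tf_ids, genes = expr$gene_ids)
  lapply(seq_len(n_bootstraps), function(b) {
    cols <- bootstrap_columns(expr$sample_ids, seed + b)
    ev <- expr$values[, cols, drop = FALSE]
    av <- activities$values[, cols, drop = FALSE]
    res <- engine_edges(ev, av, expr$gene_ids, function(y, Xs, g) {
      st <- stars_select_lambda(y, Xs, grid_size, n_subsamples,
                                subsample_fraction, threshold,
                                seed = seed_from_key(seed + b, g))
      if (isTRUE(st$degenerate)) return(list(selected = character(0)))
      beta <- solve_l1_least_squares(y, Xs, st$lambda)
      sel <- names(beta)[beta != 0]
      if (!length(sel)) return(list(selected = character(0)))
      refit_scores(y, Xs, sel)
    })
    grn_edge_set(res$tf, res$gene, res$score, res$sign, universe,
                 origin = sprintf("bootstrap%d", b))
  })
}

# OLS refit of a selected support; explained-variance edge scores d_j defined
# as in the best-subset engine.
refit_scores <- function(y, X, selected, eps = 1e-10) {
  Xm <- X[, selected, drop = FALSE]
  G <- crossprod(Xm)
  Xy <- drop(crossprod(Xm, y))
  yy <- sum(y^2)
  full <- ols_subset(G, Xy, yy, seq_along(selected))
  if (is.null(full)) return(list(selected = character(0)))
  scores <- vapply(seq_along(selected), function(k) {
    f <- ols_subset(G, Xy, yy, seq_along(selected)[-k])
    if (is.null(f)) 0 else max(0, 1 - full$rss / max(f$rss, eps))
  }, numeric(1))
  list(selected = selected,
       coefficients = stats::setNames(full$beta, selected),
       scores = stats::setNames(scores, selected))
}
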