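#' Dirty-model multi-task objective
#'
#' The penalized objective decomposing per-task coefficients `w_k = b_k + s_k`
#' into a block-shared component `B` (row-wise l-infinity penalty, so a
#' predictor is either shared across tasks or not) and a task-specific sparse
#' component `S` (weighted l1 penalty):
#' `sum_k (1/(2 n_k)) ||y_k - X_k (b_k + s_k)||^2 +
#'  lamB * sum_j max_k |B_jk| + lamS * sum_jk w_jk |S_jk|`.
#'
#' @param B,S predictors x tasks coefficient matrices.
#' @param tasks list of per-task data, each a list with `y` (centered
#'   response) and `X` (standardized predictor matrix).
#' @param lamB,lamS nonnegative penalties.
#' @param edge_weights predictors x tasks positive weight matrix on the l1
#'   term (default all ones).
#' @return the scalar objective value.
#' @export
amusr_objective <- function(B, S, tasks, lamB, lamS,
                            edge_weights = matrix(1, nrow(B), ncol(B))) {
  stopifnot(lamB >= 0, lamS >= 0, all(edge_weights > 0),
            nrow(B) == nrow(S), ncol(B) == length(tasks))
  val <- 0
  for (k in seq_along(tasks)) {
    nk <- length(tasks[[k]]$y)
    r <- tasks[[k]]$y - tasks[[k]]$X %*% (B[, k] + S[, k])
    val <- val + sum(r^2) / (2 * nk)
  }
  val + lamB * sum(apply(abs(B), 1, max)) + lamS * sum(edge_weights * abs(S))
}

#' Fit the dirty multi-task model at fixed penalties
#'
#' Alternating exact block-coordinate minimization: per-entry soft
#' thresholding for `S`, and a per-row l-infinity proximal update for `B`
#' (computed by projection onto the l1 ball). The objective is monotonically
#' nonincreasing; iteration stops when the relative objective decrease falls
#' below `tol`.
#'
#' @inheritParams amusr_objective
#' @param tol relative objective-decrease tolerance.
#' @param max_iter iteration cap; non-convergence returns the best iterate
#'   with `converged = FALSE`.
#' @return list with `B`, `S`, `W = B + S`, `objective`, `trace` (objective
#'   per iteration), `converged`.
#' @export
fit_dirty_model <- function(tasks, lamB, lamS,
                            edge_weights = NULL, tol = 1e-4, max_iter = 200) {
  K <- length(tasks)
  p <- ncol(tasks[[1]]$X)
  if (is.null(edge_weights)) edge_weights <- matrix(1, p, K)
  Xs <- lapply(tasks, function(t) as.matrix(t$X))
  ys <- lapply(tasks, function(t) as.numeric(t$y))
  fit <- .dirty_fit(Xs, ys, lamB, lamS, edge_weights, tol, as.integer(max_iter))
  if (!fit$converged)
    warning("fit_dirty_model: not converged in ", max_iter, " iterations")
  # clear floating-point dust at penalty boundaries so supports are exact
  fit$B[abs(fit$B) < 1e-8] <- 0
  fit$S[abs(fit$S) < 1e-8] <- 0
  pn <- colnames(tasks[[1]]$X)
  dimnames(fit$B) <- dimnames(fit$S) <- list(pn, names(tasks))
  fit$W <- fit$B + fit$S
  fit
}

#' Per-task l1 penalty weights from prior networks
#'
#' Predictor/task pairs supported by that task's prior receive weight `rho`
#' (in (0, 1]; values below 1 make prior-supported edges cheaper to select);
#' all other pairs get weight 1. `rho = 1` disables the adaptation.
#'
#' @param priors list of [grn_adjacency], one per task (recycled if length 1).
#' @param gene_id target gene.
#' @param tf_ids predictor (TF) identifiers, in design-matrix column order.
#' @param rho prior weight in (0, 1].
#' @return `length(tf_ids)` x `length(priors)` weight matrix.
#' @export
make_prior_edge_weights <- function(priors, gene_id, tf_ids, rho = 1) {
  stopifnot(rho > 0, rho <= 1)
  W <- matrix(1, length(tf_ids), length(priors))
  for (k in seq_along(priors)) {
    pk <- priors[[k]]
    if (!(gene_id %in% pk$gene_ids)) next
    col <- pk$values[, match(gene_id, pk$gene_ids)]
    supported <- tf_ids %in% pk$tf_ids[col != 0]
    W[supported, k] <- rho
  }
  W
}

# Smallest lamB (with lamS = lamB / sqrt(K)) at which B = S = 0 is optimal.
amusr_lambda_max <- function(tasks, edge_weights) {
  K <- length(tasks)
  C <- vapply(tasks, function(t)
    drop(crossprod(t$X, t$y)) / length(t$y), numeric(ncol(tasks[[1]]$X)))
  C <- matrix(C, ncol = K)
  max(sqrt(K) * max(abs(C) / edge_weights), max(rowSums(abs(C))))
}

#' Choose dirty-model penalties by EBIC
#'
#' Sweeps a log-spaced grid of `grid_size` values of `lamB` from the smallest
#' all-zero penalty down to 1% of it, with `lamS = lamB / sqrt(K)` coupled,
#' and picks the fit minimizing the extended BIC
#' `sum_k [n_k ln(max(RSS_k, eps)/n_k) + df_k ln(n_k) + 2 gamma df_k ln(p)]`
#' with `df_k` the number of nonzero per-task coefficients. Ties go to the
#' larger penalty.
#'
#' @inheritParams fit_dirty_model
#' @param grid_size number of grid points (>= 2).
#' @param gamma EBIC weight on the `ln(p)` term.
#' @param eps RSS floor.
#' @return list with `lambda_B`, `lambda_S`, `fit`, `ebic`, and the full
#'   `grid`/`ebic_path`.
#' @export
select_lambda_ebic <- function(tasks, grid_size = 20, gamma = 1,
                               edge_weights = NULL, tol = 1e-4,
                               max_iter = 200, eps = 1e-10) {
  stopifnot(grid_size >= 2)
  K <- length(tasks)
  p <- ncol(tasks[[1]]$X)
  if (is.null(edge_weights)) edge_weights <- matrix(1, p, K)
  lmax <- amusr_lambda_max(tasks, edge_weights)
  if (lmax <= 0) lmax <- 1e-8
  grid <- exp(seq(log(lmax), log(0.01 * lmax), length.out = grid_size))
  best <- NULL
  ebics <- numeric(grid_size)
  for (i in seq_along(grid)) {
    lamB <- grid[i]
    fit <- suppressWarnings(
      fit_dirty_model(tasks, lamB, lamB / sqrt(K), edge_weights, tol, max_iter))
    ebic <- 0
    for (k in seq_len(K)) {
      nk <- length(tasks[[k]]$y)
      r <- tasks[[k]]$y - tasks[[k]]$X %*% fit$W[, k]
      rss <- sum(r^2)
      df <- sum(fit$W[, k] != 0)
      ebic <- ebic + nk * log(max(rss, eps) / nk) + df * log(nk) +
        2 * gamma * df * log(p)
    }
    ebics[i] <- ebic
    if (is.null(best) || ebic < best$ebic)
      best <- list(lambda_B = lamB, lambda_S = lamB / sqrt(K), fit = fit,
                   ebic = ebic)
  }
  c(best, list(grid = grid, ebic_path = ebics))
}

#' Run the AMuSR multi-task engine
#'
#' For each gene, a dirty-model fit is run jointly over every task in which
#' the gene is measured; per-task edges are the nonzero combined coefficients,
#' scored by per-task OLS-refit explained variance. Prior networks enter both
#' through the task activity estimates and (optionally, `rho < 1`) as reduced
#' l1 weights on prior-supported edges.
#'
#' @param expr_list list of [grn_expression], one per task.
#' @param act_list list of [grn_activities], one per task, sharing a common
#'   TF list.
#' @param priors list of [grn_adjacency] per task (or a single one, recycled).
#' @param n_bootstraps bootstraps (resampled within each task).
#' @param seed base seed.
#' @param gamma EBIC gamma.
#' @param rho prior weight in (0, 1]; 1 disables prior adaptation.
#' @param grid_size penalty grid size.
#' @return list of [grn_edge_set] of length `n_bootstraps * n_tasks`, with
#'   origins `"<task>/bootstrap<b>"`; all share the union-gene universe.
#' @export
run_amusr <- function(expr_list, act_list, priors, n_bootstraps = 1,
                      seed = 42, gamma = 1, rho = 1, grid_size = 20) {
  K <- length(expr_list)
  stopifnot(K == length(act_list))
  if (inherits(priors, "grn_adjacency")) priors <- list(priors)
  if (length(priors) == 1) priors <- rep(priors, K)
  stopifnot(length(priors) == K)
  tf_ids <- act_list[[1]]$tf_ids
  for (k in seq_len(K)) stopifnot(identical(act_list[[k]]$tf_ids, tf_ids))
  task_names <- names(expr_list)
  if (is.null(task_names)) task_names <- sprintf("task%d", seq_len(K))
  all_genes <- sort(unique(unlist(lapply(expr_list, `[[`, "gene_ids"))))
  universe <- list(tfs = tf_ids, genes = all_genes)
  out <- list()
  for (b in seq_len(n_bootstraps)) {
    evs <- vector("list", K); avs <- vector("list", K)
    for (k in seq_len(K)) {
      cols <- bootstrap_columns(expr_list[[k]]$sample_ids, seed + b)
      evs[[k]] <- expr_list[[k]]$values[, cols, drop = FALSE]
      avs[[k]] <- scale_pop(t(act_list[[k]]$values[, cols, drop = FALSE]))
    }
    acc <- lapply(seq_len(K), function(k)
      list(tf = character(0), gene = character(0), score = numeric(0),
           sign = integer(0)))
    for (g in all_genes) {
      in_task <- vapply(expr_list, function(e) g %in% e$gene_ids, logical(1))
      pred <- setdiff(tf_ids, g)
      tasks <- list(); tidx <- integer(0)
      for (k in which(in_task)) {
        y <- evs[[k]][match(g, expr_list[[k]]$gene_ids), ]
        y <- y - mean(y)
        if (all(y == 0)) next
        tasks[[length(tasks) + 1]] <- list(y = y,
                                           X = avs[[k]][, pred, drop = FALSE])
        tidx <- c(tidx, k)
      }
      if (!length(tasks)) next
      ew <- make_prior_edge_weights(priors[tidx], g, pred, rho)
      sel <- tryCatch(
        select_lambda_ebic(tasks, grid_size = grid_size, gamma = gamma,
                           edge_weights = ew),
        error = function(e) { message("gene ", g, " skipped: ",
                                      conditionMessage(e)); NULL })
      if (is.null(sel)) next
      W <- sel$fit$W
      for (t in seq_along(tidx)) {
        k <- tidx[t]
        selected <- pred[W[, t] != 0]
        if (!length(selected)) next
        rf <- refit_scores(tasks[[t]]$y, tasks[[t]]$X, selected)
        if (!length(rf$selected)) next
        acc[[k]]$tf <- c(acc[[k]]$tf, rf$selected)
        acc[[k]]$gene <- c(acc[[k]]$gene, rep(g, length(rf$selected)))
        acc[[k]]$score <- c(acc[[k]]$score, rf$scores[rf$selected])
        acc[[k]]$sign <- c(acc[[k]]$sign,
                           as.integer(sign(rf$coefficients[rf$selected])))
      }
    }
    for (k in seq_len(K))
      out[[length(out) + 1]] <-
        grn_edge_set(acc[[k]]$tf, acc[[k]]$gene, acc[[k]]$score, acc[[k]]$sign,
                     universe,
                     origin = sprintf("%s/bootstrap%d", task_names[k], b))
  }
  out
}
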