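#' Generate a ground-truth regulatory network
#'
#' Each (TF, gene) edge is present independently with probability `sparsity`;
#' nonzero coefficients are drawn as `+/- Uniform(0.5, 2)`. TFs are the first
#' `n_tfs` genes, so every TF's own transcript is part of the gene space. TF
#' transcripts carry no regulatory inputs in the truth: their expression rows
#' are generated directly from their own activity (see [simulate_dataset()]),
#' so edges are placed only into the remaining genes.
#'
#' @param n_genes,n_tfs dimensions (`n_tfs <= n_genes`).
#' @param sparsity edge probability in (0, 1).
#' @param seed integer seed.
#' @return an object of class `grn_truth`: list with `coefficients`
#'   (TF x gene signed matrix), `tf_ids`, `gene_ids`, `sparsity`,
#'   `count_scale`, `seed`.
#' @export
generate_truth <- function(n_genes, n_tfs, sparsity, seed = 42) {
  stopifnot(sparsity > 0, sparsity < 1, n_tfs <= n_genes)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  tf_ids <- gene_ids[seq_len(n_tfs)]
  set.seed(seed)
  present <- matrix(stats::runif(n_tfs * n_genes) < sparsity, n_tfs, n_genes)
  present[, seq_len(n_tfs)] <- FALSE  # TF transcripts have no regulators
  mag <- matrix(stats::runif(n_tfs * n_genes, 0.5, 2), n_tfs, n_genes)
  sgn <- matrix(sample(c(-1, 1), n_tfs * n_genes, replace = TRUE),
                n_tfs, n_genes)
  W <- present * mag * sgn
  dimnames(W) <- list(tf_ids, gene_ids)
  structure(list(coefficients = W, tf_ids = tf_ids, gene_ids = gene_ids,
                 sparsity = sparsity, count_scale = 0.3, seed = seed),
            class = "grn_truth")
}

#' Truth support as an adjacency network
#'
#' @param truth a `grn_truth`.
#' @param role adjacency role.
#' @param signed keep coefficient signs (default) or return unsigned support.
#' @return a [grn_adjacency].
#' @export
truth_adjacency <- function(truth, role = "gold_standard", signed = TRUE) {
  v <- if (signed) sign(truth$coefficients) else
    (truth$coefficients != 0) * 1
  grn_adjacency(v, truth$tf_ids, truth$gene_ids, role = role)
}

#' Simulate an expression dataset from a ground truth
#'
#' Activities are i.i.d. standard normal per TF and sample. In continuous
#' mode, `X = t(W) %*% A + Normal(0, sigma)`. In counts mode, Poisson counts
#' are drawn with rates `exp(count_scale * linear_predictor)` scaled to a
#' mean depth of 2000 counts per sample, emulating sparse scRNAseq counts.
#' TF genes' own rows carry their activity (plus noise) rather than the
#' regulatory signal, so expression-fallback TF activity estimation is
#' exercised by construction.
#'
#' @param truth a `grn_truth`.
#' @param n_samples number of samples (>= 2).
#' @param sigma Gaussian noise standard deviation.
#' @param mode `"continuous"` or `"counts"`.
#' @param seed integer seed.
#' @param mean_depth target mean counts per sample in counts mode.
#' @param task_label task label to assign to all samples.
#' @return list with `expression` ([grn_expression]) and `activities`
#'   ([grn_activities], the true latent activities).
#' @export
simulate_dataset <- function(truth, n_samples, sigma = 0.5,
                             mode = c("continuous", "counts"), seed = 42,
                             mean_depth = 2000, task_label = "task1") {
  mode <- match.arg(mode)
  stopifnot(n_samples >= 2)
  n_tfs <- length(truth$tf_ids)
  n_genes <- length(truth$gene_ids)
  set.seed(seed)
  A <- matrix(stats::rnorm(n_tfs * n_samples), n_tfs, n_samples,
              dimnames = list(truth$tf_ids, NULL))
  lin <- t(truth$coefficients) %*% A
  # TF transcripts track their own activity, not their regulatory inputs
  lin[seq_len(n_tfs), ] <- A
  sample_ids <- sprintf("s%05d", seq_len(n_samples))
  if (mode == "continuous") {
    X <- lin + matrix(stats::rnorm(n_genes * n_samples, sd = sigma),
                      n_genes, n_samples)
    expr <- grn_expression(X, truth$gene_ids, sample_ids,
                           task_labels = rep(task_label, n_samples),
                           is_counts = FALSE)
  } else {
    rate <- exp(truth$count_scale * lin)
    rate <- rate * mean_depth / mean(colSums(rate))
    X <- matrix(stats::rpois(length(rate), rate), n_genes, n_samples)
    expr <- grn_expression(X, truth$gene_ids, sample_ids,
                           task_labels = rep(task_label, n_samples),
                           is_counts = TRUE)
  }
  acts <- grn_activities(A, truth$tf_ids, sample_ids,
                         provenance = rep("estimated", n_tfs))
  list(expression = expr, activities = acts)
}

#' Generate multi-task ground truths and datasets
#'
#' A shared core of `round(shared_fraction * n_edges)` edges is common to all
#' tasks; each task replaces the remaining edges with its own uniformly
#' resampled edges (same per-task edge count as the source truth).
#'
#' @param truth a `grn_truth` providing the edge budget and dimensions.
#' @param n_tasks number of tasks.
#' @param shared_fraction fraction in `[0, 1]` of edges shared by all tasks.
#' @param n_samples per-task sample count (scalar or vector).
#' @param sigma noise level passed to [simulate_dataset()].
#' @param mode simulation mode.
#' @param seed integer seed.
#' @return list with `truths` (per-task `grn_truth`) and `datasets` (per-task
#'   output of [simulate_dataset()]).
#' @export
make_multitask <- function(truth, n_tasks, shared_fraction, n_samples,
                           sigma = 0.5, mode = "continuous", seed = 42) {
  stopifnot(shared_fraction >= 0, shared_fraction <= 1, n_tasks >= 1)
  n_samples <- rep(n_samples, length.out = n_tasks)
  W <- truth$coefficients
  edge_idx <- which(W != 0)
  n_edges <- length(edge_idx)
  n_core <- round(shared_fraction * n_edges)
  allowed <- which(allowed_cells(W))
  set.seed(seed)
  core <- sample(edge_idx, n_core)
  truths <- vector("list", n_tasks)
  datasets <- vector("list", n_tasks)
  for (k in seq_len(n_tasks)) {
    Wk <- matrix(0, nrow(W), ncol(W), dimnames = dimnames(W))
    Wk[core] <- W[core]
    n_extra <- n_edges - n_core
    pool <- setdiff(allowed, core)
    extra <- sample(pool, n_extra)
    Wk[extra] <- sample(c(-1, 1), n_extra, replace = TRUE) *
      stats::runif(n_extra, 0.5, 2)
    tk <- truth
    tk$coefficients <- Wk
    tk$seed <- seed + k
    truths[[k]] <- tk
    ds <- simulate_dataset(tk, n_samples[k], sigma = sigma,
                           mode = mode, seed = seed + 1000 * k,
                           task_label = sprintf("task%d", k))
    # sample ids unique across tasks so task datasets can be concatenated
    new_ids <- sprintf("task%d_%s", k, ds$expression$sample_ids)
    ds$expression$sample_ids <- new_ids
    colnames(ds$expression$values) <- new_ids
    ds$activities$sample_ids <- new_ids
    colnames(ds$activities$values) <- new_ids
    datasets[[k]] <- ds
  }
  names(truths) <- names(datasets) <- sprintf("task%d", seq_len(n_tasks))
  list(truths = truths, datasets = datasets)
}

# cells where truth/prior edges may live: targets that are not TF transcripts
allowed_cells <- function(W) {
  ok <- matrix(TRUE, nrow(W), ncol(W))
  ok[, seq_len(nrow(W))] <- FALSE
  ok
}

#' Degrade a truth network into an imperfect prior
#'
#' Keeps `round(keep_fraction * n_edges)` true edges uniformly at random and
#' adds `round(add_fraction * n_kept)` false edges at uniformly sampled empty
#' cells. The output is unsigned (all retained/added edges are 1).
#'
#' @param truth a `grn_truth`.
#' @param keep_fraction fraction of true edges retained (in `[0, 1]`).
#' @param add_fraction false edges added, as a fraction of the kept edges.
#' @param seed integer seed.
#' @return a [grn_adjacency] with role `"prior"`.
#' @export
corrupt_prior <- function(truth, keep_fraction = 1, add_fraction = 0,
                          seed = 42) {
  stopifnot(keep_fraction >= 0, keep_fraction <= 1, add_fraction >= 0)
  W <- truth$coefficients
  edge_idx <- which(W != 0)
  n_keep <- round(keep_fraction * length(edge_idx))
  set.seed(seed)
  kept <- sample(edge_idx, n_keep)
  v <- matrix(0, nrow(W), ncol(W), dimnames = dimnames(W))
  v[kept] <- 1
  n_add <- round(add_fraction * n_keep)
  if (n_add > 0) {
    empty <- setdiff(which(v == 0 & allowed_cells(W)), edge_idx)
    v[sample(empty, n_add)] <- 1
  }
  grn_adjacency(v, truth$tf_ids, truth$gene_ids, role = "prior")
}
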