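#' Filter genes by total count across all samples
#'
#' Implements the "1 count per N cells" rule: a gene is kept when its total
#' count over all samples is at least `floor(n_samples / per_cells)` (clamped
#' to a minimum of 1). With 44,343 cells and `per_cells = 20` the threshold is
#' 2217 counts.
#'
#' @param expr a [grn_expression] with `is_counts = TRUE`.
#' @param per_cells integer >= 1; one count required per this many cells.
#' @return the filtered [grn_expression]; the threshold used is attached as
#'   attribute `"threshold"` and reported via message.
#' @export
filter_genes_by_total_count <- function(expr, per_cells = 20) {
  stopifnot(expr$is_counts, per_cells >= 1)
  n <- length(expr$sample_ids)
  threshold <- max(1L, floor(n / per_cells))
  totals <- rowSums(expr$values)
  keep <- totals >= threshold
  if (!any(keep)) stop("gene filter removed all genes (threshold ", threshold, ")")
  message(sprintf("gene filter: threshold %d counts; kept %d/%d genes",
                  threshold, sum(keep), length(keep)))
  out <- grn_expression(expr$values[keep, , drop = FALSE],
                        gene_ids = expr$gene_ids[keep],
                        sample_ids = expr$sample_ids,
                        task_labels = expr$task_labels,
                        is_counts = TRUE)
  attr(out, "threshold") <- threshold
  out
}

#' Count-filter threshold for a given number of samples
#'
#' @param n_samples number of samples (cells).
#' @param per_cells one count required per this many cells.
#' @return integer threshold, `max(1, floor(n_samples / per_cells))`.
#' @export
count_filter_threshold <- function(n_samples, per_cells = 20)
  max(1L, as.integer(floor(n_samples / per_cells)))

#' Transform a count matrix
#'
#' `"ftt"` is the Freeman-Tukey variance-stabilizing transform
#' `sqrt(x + 1) + sqrt(x) - 1` (zero-preserving), `"log2"` is the pseudocount
#' transform `log2(x + 1)`, `"raw"` is the identity.
#'
#' @param expr a [grn_expression] with nonnegative values.
#' @param method one of `"raw"`, `"ftt"`, `"log2"`.
#' @return transformed [grn_expression]; `is_counts` is `FALSE` after a
#'   non-identity transform.
#' @export
transform_counts <- function(expr, method = c("raw", "ftt", "log2")) {
  method <- match.arg(method)
  if (any(expr$values < 0)) stop("transform: negative values in input")
  if (method == "raw") return(expr)
  v <- switch(method,
              ftt = sqrt(expr$values + 1) + sqrt(expr$values) - 1,
              log2 = log2(expr$values + 1))
  grn_expression(v, expr$gene_ids, expr$sample_ids, expr$task_labels,
                 is_counts = FALSE)
}

#' Depth-normalize counts to the median cell total
#'
#' Each column (cell) is scaled so its total equals the median of all column
#' totals. Columns with zero total are left unchanged with a warning.
#'
#' @param expr a [grn_expression] with `is_counts = TRUE`.
#' @return normalized [grn_expression] (no longer integral counts).
#' @export
depth_normalize <- function(expr) {
  stopifnot(expr$is_counts)
  totals <- colSums(expr$values)
  med <- stats::median(totals)
  factors <- ifelse(totals > 0, med / totals, 1)
  if (any(totals == 0))
    warning(sum(totals == 0), " sample(s) with zero total left unnormalized")
  v <- sweep(expr$values, 2, factors, `*`)
  grn_expression(v, expr$gene_ids, expr$sample_ids, expr$task_labels,
                 is_counts = FALSE)
}

#' Noise-only negative control
#'
#' Replaces the data with per-gene Gaussian noise matched to each gene's
#' observed mean and standard deviation, `x_i ~ N(mu_i, sigma_i)`, with each
#' cell rescaled so its total count equals the observed cell total. Negative
#' draws are clipped to zero before rescaling.
#'
#' @param expr a [grn_expression] with `is_counts = TRUE`.
#' @param seed integer seed; output is deterministic given the seed.
#' @param rescale rescale columns to the observed totals (the control used in
#'   benchmarking); set `FALSE` to expose the raw clipped draws.
#' @return a [grn_expression] with `is_counts = FALSE` (values are real).
#' @export
make_noise_control <- function(expr, seed, rescale = TRUE) {
  stopifnot(expr$is_counts)
  mu <- rowMeans(expr$values)
  sigma <- apply(expr$values, 1, stats::sd)
  sigma[is.na(sigma)] <- 0
  n <- length(expr$sample_ids)
  set.seed(seed)
  draws <- matrix(stats::rnorm(length(mu) * n, mean = mu, sd = sigma),
                  nrow = length(mu), ncol = n)
  draws[draws < 0] <- 0
  if (rescale) {
    target <- colSums(expr$values)
    got <- colSums(draws)
    fac <- ifelse(got > 0, target / got, 0)
    draws <- sweep(draws, 2, fac, `*`)
  }
  grn_expression(draws, expr$gene_ids, expr$sample_ids, expr$task_labels,
                 is_counts = FALSE)
}

#' Shuffled-prior negative control
#'
#' Randomly permutes the gene labels of the prior network: column `j` of the
#' output holds the prior targets of a uniformly chosen other gene slot.
#' Edge count and per-TF out-degrees are preserved exactly.
#'
#' @param prior a [grn_adjacency].
#' @param seed integer seed.
#' @return shuffled [grn_adjacency].
#' @export
shuffle_prior <- function(prior, seed) {
  set.seed(seed)
  perm <- sample.int(length(prior$gene_ids))
  grn_adjacency(prior$values[, perm, drop = FALSE], prior$tf_ids,
                prior$gene_ids, role = prior$role)
}

#' Add random false edges to a prior network
#'
#' Adds `round(fraction * n_true_edges)` edges of weight +1 at uniformly
#' sampled empty (TF, gene) cells, leaving original edges untouched. Used to
#' probe robustness to prior corruption.
#'
#' @param prior a [grn_adjacency].
#' @param fraction nonnegative fraction of the existing edge count to add.
#' @param seed integer seed.
#' @return corrupted [grn_adjacency].
#' @export
add_random_prior_edges <- function(prior, fraction, seed) {
  stopifnot(fraction >= 0)
  n_true <- sum(prior$values != 0)
  n_add <- round(fraction * n_true)
  if (n_add == 0) return(prior)
  empty <- which(prior$values == 0)
  if (length(empty) < n_add)
    stop("not enough empty cells to add ", n_add, " edges")
  set.seed(seed)
  pick <- sample(empty, n_add)
  v <- prior$values
  v[pick] <- 1
  grn_adjacency(v, prior$tf_ids, prior$gene_ids, role = prior$role)
}
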