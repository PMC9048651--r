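# Small fixtures built in code; all randomness is seeded by the caller.

tiny_expression <- function() {
  grn_expression(matrix(c(1, 0, 2, 3, 0, 5), nrow = 3, byrow = TRUE,
                        dimnames = list(c("g1", "g2", "g3"), c("s1", "s2"))),
                 is_counts = TRUE)
}

tiny_prior <- function() {
  grn_adjacency(matrix(c(1, 0, 0, -1), 2, 2, byrow = TRUE,
                       dimnames = list(c("A", "B"), c("g1", "g2"))),
                role = "prior")
}

random_expression <- function(n_genes, n_samples, seed, counts = TRUE) {
  set.seed(seed)
  v <- if (counts) matrix(rpois(n_genes * n_samples, 5), n_genes) else
    matrix(rnorm(n_genes * n_samples), n_genes)
  grn_expression(v, gene_ids = sprintf("g%03d", seq_len(n_genes)),
                 sample_ids = sprintf("s%03d", seq_len(n_samples)),
                 is_counts = counts)
}

random_prior <- function(n_tfs, n_genes, density, seed) {
  set.seed(seed)
  v <- matrix(rbinom(n_tfs * n_genes, 1, density) *
                sample(c(-1, 1), n_tfs * n_genes, replace = TRUE),
              n_tfs, n_genes)
  if (all(v == 0)) v[1, 1] <- 1
  grn_adjacency(v, tf_ids = sprintf("tf%02d", seq_len(n_tfs)),
                gene_ids = sprintf("g%03d", seq_len(n_genes)), role = "prior")
}

# standard small simulated instance shared by several engine tests
small_instance <- function(seed = 7, n_genes = 60, n_tfs = 10,
                           n_samples = 200, sigma = 0.5) {
  truth <- generate_truth(n_genes, n_tfs, 0.1, seed = seed)
  sim <- simulate_dataset(truth, n_samples, sigma = sigma, seed = seed)
  list(truth = truth, sim = sim,
       prior = corrupt_prior(truth, keep_fraction = 0.8, seed = seed),
       gold = truth_adjacency(truth))
}

# population-sd standardization used across engine tests
scale_pop_test <- function(M) {
  mu <- colMeans(M)
  s <- apply(M, 2, function(v) sqrt(mean((v - mean(v))^2)))
  s[s == 0] <- 1
  sweep(sweep(M, 2, mu), 2, s, "/")
}

# independent best-subset oracle: enumerate subsets with lm(); shares no code
# with best_subset_regression
bbsr_oracle <- function(y, X, w) {
  p <- ncol(X); n <- length(y)
  best_bic <- Inf; best <- integer(0)
  for (size in 0:p) for (subset in if (size == 0) list(integer(0)) else
    utils::combn(p, size, simplify = FALSE)) {
    rss <- if (length(subset) == 0) sum(y^2) else {
      fit <- lm(y ~ 0 + X[, subset, drop = FALSE])
      if (anyNA(coef(fit))) next
      sum(resid(fit)^2)
    }
    bic <- n * log(max(rss, 1e-10) / n) + log(n) * sum(w[subset])
    if (bic < best_bic - 1e-12) { best_bic <- bic; best <- subset }
  }
  sort(best)
}

# fraction of random instances where best_subset_regression agrees with the
# lm()-based exhaustive oracle
bbsr_oracle_agreement <- function(n_instances, seed) {
  set.seed(seed)
  agree <- 0L
  for (i in seq_len(n_instances)) {
    n <- sample(30:80, 1)
    p <- sample(2:8, 1)
    X <- scale(matrix(rnorm(n * p), n, p))
    attributes(X)[c("scaled:center", "scaled:scale")] <- NULL
    colnames(X) <- sprintf("x%d", 1:p)
    k_true <- sample(0:min(3, p), 1)
    beta <- numeric(p)
    if (k_true > 0) beta[sample(p, k_true)] <- runif(k_true, 0.5, 2)
    y <- drop(X %*% beta + rnorm(n)); y <- y - mean(y)
    w <- rep(1, p)
    fit <- best_subset_regression(y, X, penalty_weights = w)
    if (identical(sort(match(fit$selected, colnames(X))), bbsr_oracle(y, X, w)))
      agree <- agree + 1L
  }
  agree / n_instances
}

# criterion-7-style comparison: mean per-task held-out AUPR of joint
# multi-task AMuSR vs independently run BBSR on the same tasks
multitask_comparison <- function(seed, n_genes = 200, n_tfs = 20,
                                 n_samples = 150, n_boot = 2) {
  base <- generate_truth(n_genes, n_tfs, 0.05, seed = seed)
  mt <- make_multitask(base, 3, shared_fraction = 0.8, n_samples = n_samples,
                       sigma = 0.5, seed = seed)
  prior <- corrupt_prior(base, keep_fraction = 0.8, seed = seed)
  sp <- split_prior_holdout(prior, 0.2, seed = seed)
  exprs <- lapply(mt$datasets, function(d) d$expression)
  acts <- lapply(exprs, function(e)
    suppressWarnings(estimate_tfa(e, sp$training_prior)))
  golds <- lapply(mt$truths, truth_adjacency)
  task_names <- names(exprs)
  am_sets <- run_amusr(exprs, acts, sp$training_prior, n_bootstraps = n_boot,
                       seed = seed)
  am <- vapply(seq_along(task_names), function(k) {
    sets_k <- Filter(function(s)
      startsWith(s$origin, paste0(task_names[k], "/")), am_sets)
    score_network(rank_combine(sets_k), golds[[k]],
                  restrict_to_genes = sp$holdout_genes)$aupr
  }, numeric(1))
  bb <- vapply(seq_along(task_names), function(k) {
    sets_k <- run_bbsr(exprs[[k]], acts[[k]], sp$training_prior,
                       n_bootstraps = n_boot, seed = seed)
    score_network(rank_combine(sets_k), golds[[k]],
                  restrict_to_genes = sp$holdout_genes)$aupr
  }, numeric(1))
  c(amusr = mean(am), bbsr = mean(bb))
}
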