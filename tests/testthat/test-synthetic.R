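test_that("truth generation hits the requested sparsity and is reproducible", {
  truth <- generate_truth(200, 20, 0.05, seed = 1)
  n_edges <- sum(truth$coefficients != 0)
  # binomial over the 20 x 180 allowed cells: mean 180, sd ~13.1
  n_cells <- 20 * (200 - 20)
  expect_lt(abs(n_edges - 0.05 * n_cells), 3 * sqrt(n_cells * 0.05 * 0.95))
  expect_identical(generate_truth(200, 20, 0.05, seed = 1)$coefficients,
                   truth$coefficients)
  expect_false(identical(generate_truth(200, 20, 0.05, seed = 2)$coefficients,
                         truth$coefficients))
  # coefficients are signed with magnitudes in [0.5, 2]
  mags <- abs(truth$coefficients[truth$coefficients != 0])
  expect_true(all(mags >= 0.5 & mags <= 2))
  expect_true(any(truth$coefficients > 0) && any(truth$coefficients < 0))
  # TF transcripts carry no regulatory inputs in the truth
  expect_true(all(truth$coefficients[, 1:20] == 0))
})

test_that("noiseless continuous data let TFA recover the true activities", {
  truth <- generate_truth(50, 8, 0.15, seed = 2)
  sim <- simulate_dataset(truth, 100, sigma = 0, seed = 2)
  prior <- grn_adjacency(truth$coefficients, truth$tf_ids, truth$gene_ids,
                         role = "prior")
  act <- suppressWarnings(suppressMessages(estimate_tfa(sim$expression, prior)))
  expect_lt(max(abs(act$values[truth$tf_ids, ] -
                      sim$activities$values[truth$tf_ids, ])), 1e-8)
})

test_that("count mode gives nonnegative integers at the requested depth", {
  truth <- generate_truth(100, 10, 0.08, seed = 3)
  sim <- simulate_dataset(truth, 200, sigma = 0.5, mode = "counts", seed = 3)
  v <- sim$expression$values
  expect_true(all(v >= 0) && all(v == round(v)))
  expect_true(sim$expression$is_counts)
  expect_lt(abs(mean(colSums(v)) - 2000) / 2000, 0.1)
})

test_that("held-out recovery degrades monotonically-in-median as noise grows", {
  # held-out scoring: training-prior edges can be rediscovered from shared
  # noise (activities are estimated from the same matrix), so only holdout
  # genes measure real signal
  med <- sapply(c(0.5, 2, 8), function(sig) {
    auprs <- sapply(1:3, function(seed) {
      truth <- generate_truth(100, 12, 0.08, seed = seed)
      sim <- simulate_dataset(truth, 300, sigma = sig, seed = seed)
      prior <- corrupt_prior(truth, 0.8, 0, seed = seed)
      fit <- suppressMessages(grn_infer(sim$expression, prior,
                                        gold = truth_adjacency(truth),
                                        method = "bbsr",
                                        holdout_fraction = 0.2,
                                        n_bootstraps = 2, seed = 50 + seed))
      fit$score$aupr
    })
    median(auprs)
  })
  expect_true(all(diff(med) < 0))
})

test_that("multi-task truths share exactly the requested core", {
  truth <- generate_truth(80, 10, 0.1, seed = 4)
  mt <- make_multitask(truth, 3, shared_fraction = 0.8, n_samples = 50,
                       seed = 4)
  supports <- lapply(mt$truths, function(t) which(t$coefficients != 0))
  core <- Reduce(intersect, supports)
  n_edges <- sum(truth$coefficients != 0)
  expect_gte(length(core), round(0.8 * n_edges))
  # per-task edge counts match the source budget
  for (s in supports) expect_equal(length(s), n_edges)
  # pairwise Jaccard at least core/union
  for (a in 1:2) for (b in (a + 1):3) {
    j <- length(intersect(supports[[a]], supports[[b]])) /
      length(union(supports[[a]], supports[[b]]))
    expect_gte(j, round(0.8 * n_edges) / (2 * n_edges - round(0.8 * n_edges)))
  }
  # shared_fraction 1: identical truths
  mt1 <- make_multitask(truth, 3, 1, 30, seed = 5)
  expect_identical(mt1$truths[[1]]$coefficients, mt1$truths[[3]]$coefficients)
  # shared_fraction 0: overlap near chance (hypergeometric mean)
  mt0 <- make_multitask(truth, 2, 0, 30, seed = 6)
  s0 <- lapply(mt0$truths, function(t) which(t$coefficients != 0))
  n_cells <- 10 * (80 - 10)
  expected_overlap <- length(s0[[1]]) * length(s0[[2]]) / n_cells
  expect_lt(length(intersect(s0[[1]], s0[[2]])),
            expected_overlap + 3 * sqrt(expected_overlap))
})

test_that("prior corruption keeps and adds the exact edge counts without collisions", {
  truth <- generate_truth(100, 10, 0.1, seed = 7)
  true_support <- which(truth$coefficients != 0)
  pr <- corrupt_prior(truth, 1, 0, seed = 1)
  expect_equal(sort(which(pr$values != 0)), sort(true_support))
  pr2 <- corrupt_prior(truth, 0.8, 0.5, seed = 1)
  n_keep <- round(0.8 * length(true_support))
  expect_equal(sum(pr2$values != 0), n_keep + round(0.5 * n_keep))
  added <- setdiff(which(pr2$values != 0), true_support)
  expect_length(added, round(0.5 * n_keep))
  expect_true(all(pr2$values %in% c(0, 1)))  # unsigned
})

test_that("a truth-derived prior beats a shuffled prior on held-out genes", {
  folds <- sapply(1:3, function(seed) {
    truth <- generate_truth(200, 20, 0.05, seed = seed)
    sim <- simulate_dataset(truth, 500, sigma = 0.5, seed = seed)
    prior <- corrupt_prior(truth, 0.8, 0, seed = seed)
    gold <- truth_adjacency(truth)
    f_true <- suppressMessages(grn_infer(sim$expression, prior, gold = gold,
                                         holdout_fraction = 0.2,
                                         n_bootstraps = 2, seed = seed))
    f_shuf <- suppressMessages(grn_infer(sim$expression, prior, gold = gold,
                                         holdout_fraction = 0.2,
                                         n_bootstraps = 2, seed = seed,
                                         control = "shuffle_prior"))
    c(true = f_true$score$aupr / f_true$score$random_baseline,
      shuf = f_shuf$score$aupr / f_shuf$score$random_baseline)
  })
  expect_gt(mean(folds["true", ]), 2 * mean(folds["shuf", ]))
})
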