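test_that("count filter threshold follows the 1-per-N-cells rule", {
  expect_equal(count_filter_threshold(44343, 20), 2217L)
  # totals {0, 5, 100} at n = 40, per_cells = 20 -> threshold 2, keep 2 genes
  set.seed(1)
  v <- rbind(rep(0, 40),
             c(rep(1, 5), rep(0, 35)),
             c(rep(5, 20), rep(0, 20)))
  expr <- grn_expression(v, gene_ids = c("a", "b", "c"),
                         sample_ids = sprintf("s%02d", 1:40))
  out <- suppressMessages(filter_genes_by_total_count(expr, 20))
  expect_equal(attr(out, "threshold"), 2L)
  expect_equal(out$gene_ids, c("b", "c"))
  # per_cells > n clamps the threshold to 1: only all-zero genes removed
  out2 <- suppressMessages(filter_genes_by_total_count(expr, 1000))
  expect_equal(attr(out2, "threshold"), 1L)
  expect_equal(out2$gene_ids, c("b", "c"))
})

test_that("filter threshold is invariant to sample order and commutes with transform", {
  expr <- random_expression(30, 50, seed = 4)
  perm <- sample(seq_along(expr$sample_ids))
  expr_p <- grn_expression(expr$values[, perm], expr$gene_ids,
                           expr$sample_ids[perm])
  f1 <- suppressMessages(filter_genes_by_total_count(expr, 7))
  f2 <- suppressMessages(filter_genes_by_total_count(expr_p, 7))
  expect_equal(sort(f1$gene_ids), sort(f2$gene_ids))
  # filter-then-transform == transform-then-subset on survivors
  a <- transform_counts(f1, "ftt")
  b <- transform_counts(expr, "ftt")
  expect_equal(a$values, b$values[a$gene_ids, ])
})

test_that("transforms match their closed forms and preserve zero", {
  expr <- grn_expression(matrix(c(0, 3, 1, 8), 2,
                                dimnames = list(c("g1", "g2"), c("s1", "s2"))))
  ftt <- transform_counts(expr, "ftt")
  expect_equal(ftt$values["g1", "s1"], 0)
  expect_equal(ftt$values["g2", "s1"], sqrt(4) + sqrt(3) - 1)
  lg <- transform_counts(expr, "log2")
  expect_equal(lg$values["g1", "s1"], 0)
  expect_equal(lg$values["g2", "s1"], 2)  # log2(3+1)
  expect_false(ftt$is_counts)
  # monotone nondecreasing elementwise
  x <- 0:50
  expect_true(all(diff(sqrt(x + 1) + sqrt(x) - 1) > 0))
  neg <- grn_expression(matrix(-1, 1, 1, dimnames = list("g", "s")),
                        is_counts = FALSE)
  expect_error(transform_counts(neg, "ftt"), "negative")
})

test_that("depth normalization scales every cell to the median total", {
  v <- matrix(c(4, 6, 10, 20), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  out <- depth_normalize(grn_expression(v))
  expect_equal(unname(colSums(out$values)), c(20, 20))
  expect_equal(out$values[, "s1"], c(g1 = 8, g2 = 12))
  # equal totals: identity
  v2 <- matrix(c(1, 3, 2, 2), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(depth_normalize(grn_expression(v2))$values, v2)
  # zero-total column untouched, others scaled to the median over all columns
  v3 <- matrix(c(0, 0, 2, 2, 6, 2), 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  expect_warning(depth_normalize(grn_expression(v3)), "zero total")
  out3 <- suppressWarnings(depth_normalize(grn_expression(v3)))
  expect_equal(unname(colSums(out3$values)), c(0, 4, 4))
})

test_that("noise control preserves cell totals and per-gene means", {
  expr <- random_expression(40, 80, seed = 9)
  noise <- make_noise_control(expr, seed = 21)
  expect_equal(colSums(noise$values), colSums(expr$values), tolerance = 1e-12)
  expect_equal(dim(noise$values), dim(expr$values))
  expect_identical(make_noise_control(expr, seed = 21)$values, noise$values)
  # constant gene (sigma = 0) gives a constant row before rescaling
  cexpr <- grn_expression(rbind(g1 = rep(4, 30), g2 = rpois(30, 8)),
                          sample_ids = sprintf("s%02d", 1:30))
  raw <- make_noise_control(cexpr, seed = 3, rescale = FALSE)
  expect_true(all(raw$values["g1", ] == 4))
  # raw draw means track mu_i within 3 standard errors over many samples
  # (means well above zero so clipping bias is negligible)
  wide <- grn_expression(matrix(rpois(5 * 10000, c(10, 15, 20, 26, 33)), 5,
                                dimnames = list(sprintf("g%d", 1:5),
                                                sprintf("s%05d", 1:10000))))
  mu <- rowMeans(wide$values)
  sds <- apply(wide$values, 1, sd)
  raw2 <- make_noise_control(wide, seed = 5, rescale = FALSE)
  se <- sds / sqrt(10000)
  expect_true(all(abs(rowMeans(raw2$values) - mu) < 3 * se + 0.01))
})

test_that("prior shuffle preserves edge count, out-degrees and determinism", {
  prior <- random_prior(6, 40, 0.15, seed = 11)
  sh <- shuffle_prior(prior, seed = 2)
  expect_equal(sum(sh$values != 0), sum(prior$values != 0))
  expect_equal(rowSums(sh$values != 0), rowSums(prior$values != 0))
  expect_equal(unname(sort(colSums(sh$values != 0))),
               unname(sort(colSums(prior$values != 0))))
  expect_identical(shuffle_prior(prior, seed = 2)$values, sh$values)
  expect_false(identical(sh$values, prior$values))
})

test_that("random prior edges are added in the exact count and never collide", {
  prior <- random_prior(5, 50, 0.4, seed = 13)
  prior$values <- abs(prior$values)
  n0 <- sum(prior$values != 0)
  out <- add_random_prior_edges(prior, 0.5, seed = 1)
  expect_equal(sum(out$values != 0), n0 + round(0.5 * n0))
  expect_true(all(out$values[prior$values != 0] == prior$values[prior$values != 0]))
  expect_identical(add_random_prior_edges(prior, 0, seed = 1)$values,
                   prior$values)
  full <- grn_adjacency(matrix(1, 2, 2, dimnames = list(c("A", "B"),
                                                        c("x", "y"))))
  expect_error(add_random_prior_edges(full, 0.5, seed = 1), "empty cells")
})
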