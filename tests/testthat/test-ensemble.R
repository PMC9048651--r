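uni3 <- list(tfs = "A", genes = c("g1", "g2", "g3"))

es <- function(scores, uni = uni3, origin = "t", signs = NULL) {
  genes <- names(scores)
  if (is.null(signs)) signs <- rep(1L, length(scores))
  grn_edge_set(rep("A", length(scores)), genes, unname(scores), signs, uni,
               origin = origin)
}

test_that("a single edge set maps ranks affinely onto [0, 1]", {
  net <- rank_combine(list(es(c(g1 = 5, g2 = 3, g3 = 1))))
  e <- net$edges[order(net$edges$gene), ]
  U <- 3
  expect_equal(e$rank_sum, c(1, 2, 3))
  expect_equal(e$confidence, 1 - (c(1, 2, 3) - 1) / (U - 1))
  expect_equal(max(net$edges$confidence), 1)
})

test_that("identical rankings are idempotent and reversed rankings cancel", {
  s1 <- es(c(g1 = 5, g2 = 3, g3 = 1))
  same <- rank_combine(list(s1, es(c(g1 = 50, g2 = 30, g3 = 10))))
  e <- same$edges[order(same$edges$gene), ]
  expect_equal(order(-e$confidence), 1:3)
  rev <- rank_combine(list(s1, es(c(g1 = 1, g2 = 3, g3 = 5))))
  expect_equal(length(unique(rev$edges$confidence)), 1L)  # (1+3)=(2+2)=(3+1)
})

test_that("rank combination is commutative and invariant to monotone score transforms", {
  set.seed(70)
  uni <- list(tfs = c("A", "B"), genes = sprintf("g%d", 1:6))
  mk <- function(seed, f = identity) {
    set.seed(seed)
    n <- 8
    tf <- sample(uni$tfs, n, TRUE)
    gene <- sample(uni$genes, n, TRUE)
    k <- !duplicated(paste(tf, gene))
    grn_edge_set(tf[k], gene[k], f(runif(sum(k))),
                 sample(c(-1L, 1L), sum(k), TRUE), uni)
  }
  a <- rank_combine(list(mk(1), mk(2), mk(3)))
  b <- rank_combine(list(mk(3), mk(1), mk(2)))
  expect_equal(a$edges, b$edges)
  # strictly monotone transform of within-set scores changes nothing
  c2 <- rank_combine(list(mk(1, f = function(x) exp(5 * x)), mk(2), mk(3)))
  expect_equal(a$edges, c2$edges)
})

test_that("absent edges take the worst rank in the universe", {
  uni <- list(tfs = "A", genes = c("g1", "g2", "g3", "g4"))
  two_sets <- list(es(c(g1 = 2, g2 = 1), uni), es(c(g1 = 9), uni))
  net <- rank_combine(two_sets)
  e <- net$edges
  expect_equal(e$rank_sum[e$gene == "g1"], 2)          # rank 1 + rank 1
  expect_equal(e$rank_sum[e$gene == "g2"], 2 + 4)      # rank 2 + absent (U=4)
  expect_false("g3" %in% e$gene)
})

test_that("mismatched universes are rejected", {
  s1 <- es(c(g1 = 1), uni3)
  s2 <- es(c(g1 = 1), list(tfs = "A", genes = c("g1", "gX", "g3")))
  expect_error(rank_combine(list(s1, s2)), "universe")
})

# independent brute-force sweep for the MCC threshold
mcc_brute <- function(net, ref) {
  keys_ref <- paste(ref$tf_ids[which(ref$values != 0, arr.ind = TRUE)[, 1]],
                    ref$gene_ids[which(ref$values != 0, arr.ind = TRUE)[, 2]])
  U <- length(net$universe$tfs) * length(net$universe$genes)
  best <- -Inf; best_t <- NA
  for (t in sort(unique(net$edges$confidence), decreasing = TRUE)) {
    pred <- net$edges[net$edges$confidence >= t, ]
    keys_pred <- paste(pred$tf, pred$gene)
    tp <- sum(keys_pred %in% keys_ref)
    fp <- length(keys_pred) - tp
    fn <- length(keys_ref) - tp
    tn <- U - tp - fp - fn
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
    if (mcc > best) { best <- mcc; best_t <- t }
  }
  list(mcc = best, threshold = best_t)
}

test_that("max-MCC thresholding equals an independent brute-force sweep", {
  set.seed(71)
  for (i in 1:20) {
    uni <- list(tfs = sprintf("t%d", 1:3), genes = sprintf("g%d", 1:8))
    n <- 15
    tf <- sample(uni$tfs, n, TRUE); gene <- sample(uni$genes, n, TRUE)
    k <- !duplicated(paste(tf, gene))
    set <- grn_edge_set(tf[k], gene[k], runif(sum(k)),
                        rep(1L, sum(k)), uni)
    net <- rank_combine(list(set))
    ref <- random_prior(3, 8, 0.25, seed = i)
    ref$tf_ids <- uni$tfs; ref$gene_ids <- uni$genes
    dimnames(ref$values) <- list(uni$tfs, uni$genes)
    got <- threshold_max_mcc(net, ref)
    oracle <- mcc_brute(net, ref)
    expect_equal(got$max_metric, oracle$mcc, tolerance = 1e-12)
    expect_equal(got$threshold, oracle$threshold)
    expect_true(all(got$curve$mcc >= -1 & got$curve$mcc <= 1))
  }
})

test_that("a network that ranks the reference first reaches MCC 1", {
  uni <- list(tfs = "A", genes = c("g1", "g2", "g3", "g4"))
  ref <- grn_adjacency(matrix(c(1, 1, 0, 0), 1, 4,
                              dimnames = list("A", uni$genes)), role = "prior")
  set <- es(c(g1 = 4, g2 = 3, g3 = 2, g4 = 1), uni)
  out <- threshold_max_mcc(rank_combine(list(set)), ref)
  expect_equal(out$max_metric, 1)
  expect_equal(sort(out$network$edges$gene), c("g1", "g2"))
  # disjoint reference: MCC <= 0 everywhere, largest threshold returned
  ref2 <- grn_adjacency(matrix(c(0, 0, 0, 1), 1, 4,
                               dimnames = list("A", uni$genes)), role = "prior")
  set2 <- es(c(g1 = 4, g2 = 3), uni)
  out2 <- threshold_max_mcc(rank_combine(list(set2)), ref2)
  expect_true(all(out2$curve$mcc <= 0))
  expect_equal(out2$threshold, max(out2$curve$threshold))
})

test_that("max-F1 sizing is no more conservative than max-MCC", {
  set.seed(72)
  uni <- list(tfs = sprintf("t%d", 1:3), genes = sprintf("g%d", 1:10))
  n <- 24
  tf <- sample(uni$tfs, n, TRUE); gene <- sample(uni$genes, n, TRUE)
  k <- !duplicated(paste(tf, gene))
  net <- rank_combine(list(grn_edge_set(tf[k], gene[k], runif(sum(k)),
                                        rep(1L, sum(k)), uni)))
  ref <- random_prior(3, 10, 0.3, seed = 5)
  dimnames(ref$values) <- list(uni$tfs, uni$genes)
  ref$tf_ids <- uni$tfs; ref$gene_ids <- uni$genes
  mcc <- threshold_max_mcc(net, ref, metric = "mcc")
  f1 <- threshold_max_mcc(net, ref, metric = "f1")
  expect_gte(nrow(f1$network$edges), nrow(mcc$network$edges))
})
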