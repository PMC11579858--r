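test_that("binary F-score matches the hand-worked example", {
  # positive class values [1, 3], negative [-1, -3]:
  # F = ((2-0)^2 + (-2-0)^2) / (var(pos) + var(neg)) = 8 / 4 = 2
  # shifted by +10 so counts stay non-negative (F is shift-invariant)
  m <- sc_matrix(matrix(c(1, 3, -1, -3) + 10, 4, 1),
                 gene_ids = "g1", labels = c("pos", "pos", "neg", "neg"))
  rk <- fscore_rank(m)
  expect_equal(unname(rk$scores["g1"]), 2, tolerance = 1e-10)
})

test_that("genes identical across classes score 0 and are excluded", {
  x <- cbind(g1 = c(1, 3, 11, 13), g2 = c(7, 7, 7, 7))
  m <- sc_matrix(x, labels = c("a", "a", "b", "b"))
  rk <- fscore_rank(m)
  expect_equal(unname(rk$scores["g2"]), 0)
  expect_false("g2" %in% rk$ranked_gene_ids)
  expect_equal(rk$n_excluded, 1L)
})

test_that("multiclass F-score equals the one-vs-rest brute-force oracle", {
  for (seed in 1:5) {
    m <- random_toy(4, 6, 3, seed = seed)
    rk <- fscore_rank(m)
    expect_equal(unname(rk$scores), oracle_fscore(as_dense(m), m$labels),
                 tolerance = 1e-10)
  }
  # and the "max" aggregation stays >= the mean one
  m <- random_toy(4, 6, 3, seed = 9)
  expect_true(all(fscore_rank(m, aggregate = "max")$scores >=
                    fscore_rank(m)$scores - 1e-12))
})

test_that("F-score is shift-invariant and scale-invariant", {
  m <- random_toy(5, 8, 2, seed = 31)
  base <- fscore_rank(m)$scores
  shifted <- m; shifted$counts <- m$counts + 7
  scaled <- m; scaled$counts <- m$counts * 3.5
  expect_equal(fscore_rank(shifted)$scores, base, tolerance = 1e-8)
  expect_equal(fscore_rank(scaled)$scores, base, tolerance = 1e-8)
})

test_that("F-score validates its inputs", {
  m1 <- sc_matrix(matrix(1:4, 2, 2), labels = c("a", "a"))
  expect_error(fscore_rank(m1), ">= 2 classes")
  m2 <- sc_matrix(matrix(1:6, 3, 2), labels = c("a", "a", "b"))
  expect_error(fscore_rank(m2), ">= 2 cells")
})

test_that("CV2 fit solves the 2-gene system exactly", {
  # two cells per value pair give exact sample moments:
  # gene A: mu 1, CV2 1.1; gene B: mu 10, CV2 0.2
  # solving CV2 = a1/mu + a0 through both points: a1 = 1, a0 = 0.1
  a <- 1 + c(-1, 1) * sqrt(1.1 / 2)
  b <- 10 + c(-1, 1) * sqrt(20 / 2)
  m <- sc_matrix(cbind(gA = a, gB = b))
  rk <- cv2_rank(m)
  expect_equal(rk$fit$a1, 1, tolerance = 1e-6)
  expect_equal(rk$fit$a0, 0.1, tolerance = 1e-6)
  expect_equal(unname(rk$fit$cv2), c(1.1, 0.2), tolerance = 1e-10)
})

test_that("CV2 moments agree with a two-pass brute force and handle degeneracy", {
  set.seed(41)
  x <- matrix(rpois(200, 5), 20, 10,
              dimnames = list(NULL, paste0("g", 1:10)))
  m <- sc_matrix(x)
  rk <- cv2_rank(m)
  mu_bf <- apply(x, 2, mean)
  cv2_bf <- apply(x, 2, function(v) stats::var(v) / mean(v)^2)
  expect_equal(unname(rk$fit$mu), unname(mu_bf), tolerance = 1e-10)
  expect_equal(unname(rk$fit$cv2), unname(cv2_bf), tolerance = 1e-10)

  const <- sc_matrix(cbind(gA = c(1, 2, 3), gB = c(5, 5, 5),
                           gC = c(2, 8, 14)))
  rk2 <- cv2_rank(const)   # constant gene: CV2 = 0, undefined score
  expect_false("gB" %in% rk2$ranked_gene_ids)

  same_mean <- sc_matrix(cbind(gA = c(1, 3), gB = c(0, 4)))
  expect_error(cv2_rank(same_mean), "degenerate")

  zero <- sc_matrix(cbind(gA = c(0, 0), gB = c(1, 3), gC = c(2, 10)))
  expect_warning(cv2_rank(zero), "zero-mean")
})

test_that("PCA importance matches the eigendecomposition oracle", {
  set.seed(51)
  x <- matrix(rnorm(30 * 8, 10, 2), 30, 8,
              dimnames = list(NULL, paste0("g", 1:8)))
  m <- sc_matrix(abs(x))
  for (k in c(2, 5)) {
    rk <- pca_rank(m, n_components = k)
    expect_equal(unname(rk$scores), oracle_pca_importance(as_dense(m), k),
                 tolerance = 1e-8)
  }
})

test_that("PCA ranking: constant genes drop, dominant axes lead, duplication is neutral", {
  set.seed(52)
  n <- 40
  s <- rnorm(n)                      # shared latent axis
  g1 <- s + 0.05 * rnorm(n)          # tracks the axis almost perfectly
  rest <- sapply(1:4, function(i) 0.5 * s + rnorm(n))
  x <- cbind(g1, rest, const = 7) + 50
  colnames(x) <- paste0("g", 1:6)
  m <- sc_matrix(x)
  rk <- pca_rank(m, n_components = 1)   # the leading axis is g1's
  expect_equal(rk$ranked_gene_ids[1], "g1")
  expect_false("g6" %in% rk$ranked_gene_ids)
  expect_equal(unname(rk$scores["g6"]), 0)

  dup <- sc_matrix(rbind(x, x), cell_ids = paste0("c", 1:(2 * n)))
  expect_equal(pca_rank(dup, n_components = 1)$ranked_gene_ids,
               rk$ranked_gene_ids)

  expect_error(pca_rank(m, n_components = 0), "n_components")
})

test_that("rankings are descending with no non-positive scores, ties stable", {
  for (seed in 1:5) {
    m <- random_toy(5, 12, 2, seed = 100 + seed)
    for (method in c("fscore", "cv2", "pca")) {
      rk <- rank_genes(m, method)
      s <- rk$scores[rk$ranked_gene_ids]
      expect_true(all(s > 0), label = paste(method, "positivity"))
      expect_true(all(diff(s) <= 1e-15), label = paste(method, "descending"))
    }
  }
  # tie-break: equal scores keep input gene order
  tied <- sc_matrix(cbind(gB2 = c(1, 3, 11, 13), gA1 = c(1, 3, 11, 13)),
                    labels = c("a", "a", "b", "b"))
  expect_equal(fscore_rank(tied)$ranked_gene_ids, c("gB2", "gA1"))
})

test_that("planted discriminative genes dominate the F-score ranking", {
  # effect of 2 within-class SDs on 5 planted genes among 200 nulls
  m <- random_toy(30, 200, 2, seed = 77, shift_gene = 1:5, shift = 4)
  rk <- fscore_rank(m)
  planted_ranks <- match(paste0("g", 1:5), rk$ranked_gene_ids)
  null_scores <- rk$scores[paste0("g", 6:200)]
  cutoff <- stats::quantile(null_scores, 0.95)
  expect_true(all(rk$scores[paste0("g", 1:5)] > cutoff))
  expect_true(all(planted_ranks <= 15))
})

test_that("top-k overlap counts match set intersections", {
  ids <- paste0("g", 1:1000)
  set.seed(61)
  rks <- lapply(c("fscore", "cv2", "pca"), function(meth) {
    sc <- stats::setNames(sample(seq_len(1000)), ids)
    structure(list(method = meth, scores = sc,
                   ranked_gene_ids = names(sort(-sc)), n_excluded = 0L),
              class = "feature_ranking")
  })
  ov <- topk_overlap(rks, k = 100)
  tops <- lapply(rks, function(r) r$ranked_gene_ids[1:100])
  for (i in 1:3) for (j in 1:3)
    expect_equal(ov$pairwise[i, j], length(intersect(tops[[i]], tops[[j]])))
  expect_setequal(ov$common_genes, Reduce(intersect, tops))

  same <- topk_overlap(rks[c(1, 1)], k = 10)
  expect_equal(unname(same$pairwise[1, 2]), 10L)
  disjoint <- list(rks[[1]], rks[[2]])
  disjoint[[2]]$ranked_gene_ids <- rev(disjoint[[1]]$ranked_gene_ids)
  expect_equal(unname(topk_overlap(disjoint, k = 100)$pairwise[1, 2]), 0L)

  expect_error(topk_overlap(rks[1], k = 10), ">= 2")
  expect_error(topk_overlap(rks, k = 2000), "exceeds")
})

test_that("rankings export as tidy TSV", {
  m <- random_toy(4, 6, 2, seed = 71)
  rk <- fscore_rank(m)
  f <- tempfile(fileext = ".tsv")
  write_ranking(rk, f)
  df <- read.delim(f)
  expect_equal(names(df), c("gene_id", "score", "rank", "method"))
  expect_equal(df$gene_id, rk$ranked_gene_ids)
  expect_equal(df$rank, seq_along(rk$ranked_gene_ids))
})
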