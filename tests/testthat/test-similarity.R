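test_that("interval Jaccard similarity has the stated endpoints and
          symmetry", {
  expect_equal(jaccard_interval(c(0.1, 0.3), c(0.1, 0.3)), 1)
  expect_equal(jaccard_interval(c(0.1, 0.2), c(0.3, 0.4)), 0)
  expect_equal(jaccard_interval(c(0, 2), c(1, 3)), 1 / 3)
  expect_equal(jaccard_interval(c(1, 3), c(0, 2)), 1 / 3)
  # touching intervals share no length
  expect_equal(jaccard_interval(c(0, 1), c(1, 2)), 0)
  # identical degenerate bars are identical
  expect_equal(jaccard_interval(c(0.5, 0.5), c(0.5, 0.5)), 1)
  expect_error(jaccard_interval(c(0, Inf), c(0, 1)), "finite")

  # bounded in [0, 1] and symmetric on random intervals
  for (s in 1:20) {
    iv <- withr::with_seed(s, sort(runif(4)))
    a <- iv[c(1, 3)]; b <- iv[c(2, 4)]
    j <- jaccard_interval(a, b)
    expect_gte(j, 0); expect_lte(j, 1)
    expect_equal(j, jaccard_interval(b, a))
  }
})

test_that("barcode similarity: identity, emptiness and optimal matching", {
  xy <- withr::with_seed(4, matrix(runif(30, 0, 500), ncol = 2))
  bc <- persistence_barcode(xy)
  expect_equal(barcode_similarity(bc, bc, 0L), 1)
  expect_equal(overall_similarity(bc, bc), 1)

  empty <- manual_barcode(data.frame(dimension = integer(),
                                     birth = numeric(), death = numeric()))
  expect_equal(barcode_similarity(bc, empty, 0L), 0)
  expect_message(s <- barcode_similarity(empty, empty, 1L), "empty")
  expect_equal(s, 1)

  # invariant under permutation of the bar order
  bars <- data.frame(dimension = 0L, birth = c(0, 0, 0.1, 0.3),
                     death = c(0.2, 0.5, 0.4, 0.9))
  b1 <- manual_barcode(bars)
  b2 <- manual_barcode(bars[c(3, 1, 4, 2), ])
  expect_equal(barcode_similarity(b1, b2, 0L, normalize = FALSE), 1)
})

test_that("assignment matching equals a brute-force permutation oracle", {
  score <- function(a, b) {
    # exhaustive maximum over one-to-one matchings (n <= 4)
    na <- nrow(a); nb <- nrow(b)
    n <- max(na, nb)
    w <- matrix(0, n, n)          # zero-padded square weight matrix
    for (i in seq_len(na)) for (j in seq_len(nb))
      w[i, j] <- jaccard_interval(a[i, ], b[j, ])
    best <- 0
    for (p in asplit(all_permutations(n), 1))
      best <- max(best, sum(w[cbind(seq_len(n), p)]))
    best / n
  }
  for (s in 1:10) {
    ab <- withr::with_seed(s, list(
      a = t(apply(matrix(runif(8), ncol = 2), 1, sort)),
      b = t(apply(matrix(runif(6), ncol = 2), 1, sort))))
    bca <- manual_barcode(data.frame(dimension = 1L, birth = ab$a[, 1],
                                     death = ab$a[, 2]))
    bcb <- manual_barcode(data.frame(dimension = 1L, birth = ab$b[, 1],
                                     death = ab$b[, 2]))
    got <- barcode_similarity(bca, bcb, 1L, normalize = FALSE)
    expect_equal(got, score(ab$a, ab$b), tolerance = 1e-9)
    # best-match variant stays in [0, 1]
    bm <- barcode_similarity(bca, bcb, 1L, normalize = FALSE,
                             method = "best_match")
    expect_gte(bm, 0); expect_lte(bm, 1)
  }
})

test_that("scale normalization makes comparisons scale-free", {
  xy <- withr::with_seed(11, matrix(runif(28, 0, 300), ncol = 2))
  bc1 <- persistence_barcode(xy)
  bc2 <- persistence_barcode(xy * 4.2)
  expect_equal(overall_similarity(bc1, bc2), 1, tolerance = 1e-9)
  expect_lt(barcode_similarity(bc1, bc2, 0L, normalize = FALSE), 1)
})

test_that("overall similarity is the mean of the per-dimension values", {
  same0 <- data.frame(dimension = 0L, birth = 0, death = 1)
  a <- manual_barcode(rbind(same0,
                            data.frame(dimension = 1L, birth = 0.1,
                                       death = 0.2)))
  b <- manual_barcode(rbind(same0,
                            data.frame(dimension = 1L, birth = 0.7,
                                       death = 0.8)))
  # dim0 identical (1), dim1 disjoint (0) -> overall 0.5
  expect_equal(overall_similarity(a, b, normalize = FALSE), 0.5)
})

test_that("similarity heatmaps are symmetric, unit-diagonal and
          HC-block-ordered", {
  mk <- function(b, d) manual_barcode(
    data.frame(dimension = c(0L, 1L), birth = c(0, b), death = c(d, d)))
  barcodes <- list(mk(0.1, 0.5), mk(0.4, 0.9), mk(0.1, 0.5), mk(0.12, 0.52))
  labels <- c("nHC", "HC", "nHC", "HC")
  hm <- similarity_heatmap(barcodes, labels, measure = "overall",
                           normalize = FALSE)
  expect_equal(hm$values, t(hm$values))
  expect_equal(diag(hm$values), rep(1, 4))
  expect_equal(hm$labels$hc_label, c("HC", "HC", "nHC", "nHC"))
  expect_equal(hm$labels$id, c(2L, 4L, 1L, 3L))
  expect_true(all(hm$values >= 0 & hm$values <= 1))

  # two internally homogeneous groups: within-block beats cross-block
  g1 <- replicate(4, mk(0.1, 0.3), simplify = FALSE)
  g2 <- replicate(4, mk(0.6, 0.9), simplify = FALSE)
  hm2 <- similarity_heatmap(c(g1, g2), rep(c("HC", "nHC"), each = 4),
                            normalize = FALSE)
  bs <- block_summary(hm2)
  expect_gt(bs["hc_hc"], bs["hc_nhc"])
  expect_gt(bs["nhc_nhc"], bs["hc_nhc"])

  # size measure: absolute differences, zero diagonal, unbounded
  hs <- similarity_heatmap(list(), hc_labels = c("HC", "nHC", "nHC"),
                           measure = "size", sizes = c(100, 250, 400))
  expect_equal(diag(hs$values), rep(0, 3))
  expect_equal(hs$values[1, 3], 300)
  expect_equal(hs$values, t(hs$values))

  expect_equal(dim(similarity_heatmap(list(), character())$values), c(0, 0))
})

test_that("second-generation heatmaps average block summaries by
          condition", {
  mk <- function(b, d) manual_barcode(
    data.frame(dimension = c(0L, 1L), birth = c(0, b), death = c(d, d)))
  hom <- similarity_heatmap(
    c(replicate(3, mk(0.1, 0.3), simplify = FALSE),
      replicate(3, mk(0.5, 0.8), simplify = FALSE)),
    rep(c("HC", "nHC"), each = 3), normalize = FALSE)
  # single matrix: equals its own block summary
  g1 <- second_generation_heatmap(list(hom))
  expect_equal(unlist(g1[c("hc_hc", "nhc_nhc", "hc_nhc")],
                      use.names = FALSE),
               unname(block_summary(hom)))
  # averaging identical matrices changes nothing
  g3 <- second_generation_heatmap(list(hom, hom, hom))
  expect_equal(g3$hc_hc, g1$hc_hc)
  expect_equal(g3$n_matrices, 3L)

  # degraded HC homogeneity lowers the HC-HC block mean
  mixed <- similarity_heatmap(
    c(list(mk(0.1, 0.3), mk(0.3, 0.6), mk(0.05, 0.5)),
      replicate(3, mk(0.5, 0.8), simplify = FALSE)),
    rep(c("HC", "nHC"), each = 3), normalize = FALSE)
  g2 <- second_generation_heatmap(list(hom, mixed), c("ctrl", "treated"))
  expect_lt(g2$hc_hc[g2$condition == "treated"],
            g2$hc_hc[g2$condition == "ctrl"])
  expect_error(second_generation_heatmap(list(hom), c("a", "b")),
               "one condition per matrix")
})
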