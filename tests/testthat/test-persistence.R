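test_that("the filtration follows the sphere-contact rule", {
  # two points at distance d: edge when the growing spheres touch, d/2
  filt <- build_filtration(rbind(c(0, 0), c(100, 0)))
  expect_equal(filt$edges$alpha, 50)

  # equilateral triangle of side s: three edges and the face at s/2
  s <- 80
  tri <- rbind(c(0, 0), c(s, 0), c(s / 2, s * sqrt(3) / 2))
  ft <- build_filtration(tri)
  expect_equal(ft$edges$alpha, rep(s / 2, 3))
  expect_equal(ft$triangles$alpha, s / 2)

  # square of side s: four sides at s/2, diagonals at s * sqrt(2) / 2
  fs <- build_filtration(unit_square(200))
  expect_equal(sort(fs$edges$alpha), c(rep(100, 4), rep(100 * sqrt(2), 2)))

  # duplicates merged with a warning
  expect_warning(build_filtration(rbind(c(0, 0), c(0, 0), c(50, 0))),
                 "duplicated")
  expect_error(build_filtration(matrix(numeric(), 0, 2)), "at least one")
})

test_that("barcodes match the brute-force boundary-matrix oracle on all
          small point sets", {
  # the unit square: one hole [0.5, sqrt(2)/2]
  bc <- persistence_barcode(unit_square())
  hole <- bc[bc$dimension == 1, ]
  expect_equal(nrow(hole), 1)
  expect_equal(c(hole$birth, hole$death), c(0.5, sqrt(2) / 2))
  expect_same_bars(bc, oracle_barcode(unit_square()))

  # random point sets with 3 to 8 points
  for (n in 3:8) {
    for (s in 1:5) {
      xy <- withr::with_seed(100 * n + s, matrix(runif(2 * n, 0, 10),
                                                 ncol = 2))
      expect_same_bars(persistence_barcode(xy), oracle_barcode(xy))
      expect_same_bars(persistence_barcode(xy, keep_zero = TRUE),
                       oracle_barcode(xy, keep_zero = TRUE))
    }
  }
})

test_that("component structure: one essential bar, n bars at alpha 0,
          monotone B0", {
  xy <- withr::with_seed(5, matrix(runif(30, 0, 1000), ncol = 2))
  bc <- persistence_barcode(xy, keep_zero = TRUE)
  expect_equal(sum(bc$dimension == 0 & is.infinite(bc$death)), 1)
  expect_equal(sum(bc$dimension == 0), nrow(xy))
  expect_true(all(bc$death >= bc$birth))

  # beyond half the maximum pairwise distance a single component remains
  expect_equal(unname(betti_numbers(bc, max(dist(xy)) / 2)["B0"]), 1L)

  # B0 non-increasing in alpha; B0(0) = n
  alphas <- seq(0, max(dist(xy)) / 2, length.out = 25)
  b0 <- vapply(alphas, function(a) betti_numbers(bc, a)["B0"], integer(1))
  expect_equal(b0[1], nrow(xy))
  expect_true(all(diff(b0) <= 0))

  # isolated points below half the minimum distance: (n, 0)
  far <- rbind(c(0, 0), c(1000, 0), c(0, 1000), c(1500, 1500))
  expect_equal(unname(betti_numbers(persistence_barcode(far), 10)),
               c(4L, 0L))
})

test_that("barcodes are invariant under rigid motions and scale linearly", {
  xy <- withr::with_seed(9, matrix(runif(24, 0, 500), ncol = 2))
  bc <- persistence_barcode(xy)
  moved <- rigid_transform(xy, angle = 1.1, shift = c(-300, 800))
  expect_same_bars(persistence_barcode(moved), bc, tol = 1e-8)

  k <- 3.7
  bck <- persistence_barcode(xy * k)
  expect_equal(bck$birth, bc$birth * k, tolerance = 1e-12)
  expect_equal(bck$death, bc$death * k, tolerance = 1e-12)
})

test_that("an alpha cap leaves essential features open", {
  # square capped between the side and diagonal scales: the hole persists
  bc <- persistence_barcode(unit_square(200), alpha_max_nm = 120)
  hole <- bc[bc$dimension == 1, ]
  expect_equal(hole$birth, 100)
  expect_true(is.infinite(hole$death))
})

test_that("rounding and pruning follow the two-decimal micrometre rule", {
  bars <- data.frame(dimension = c(0L, 0L, 1L),
                     birth = c(0, 1, 100),        # nm
                     death = c(4, Inf, 250))      # nm
  bc <- manual_barcode(bars, n_points = 5L, unit = "nm")
  pruned <- round_and_prune(bc, decimals = 2, unit = "um")
  # (0.001, 0.004) um rounds to (0, 0): excluded; (0.10, 0.25) um: kept
  expect_equal(nrow(pruned), 2)
  expect_equal(pruned$birth, c(0, 0.1))
  expect_equal(pruned$death, c(Inf, 0.25))
  expect_equal(attr(pruned, "unit"), "um")

  # pruning never increases the bar count
  for (s in 1:5) {
    xy <- withr::with_seed(s, matrix(runif(20, 0, 300), ncol = 2))
    full <- persistence_barcode(xy)
    expect_lte(nrow(round_and_prune(full)), nrow(full))
  }
})

test_that("endpoint histograms normalize per dimension and average across
          nuclei", {
  f <- field_spec(6000, 6000)
  mk <- function(seed, radius) {
    sim <- simulate_clustered(cluster_pattern_spec(4, 20, radius,
                                                   min_separation_nm = 1500),
                              f, seed = seed)
    round_and_prune(persistence_barcode(sim$events))
  }
  bcs <- lapply(1:3, mk, radius = 150)
  eh <- endpoint_histogram(bcs, bin_width = 0.05)
  expect_equal(sum(eh$freq_dim0), 1, tolerance = 1e-9)
  expect_equal(sum(eh$freq_dim1), 1, tolerance = 1e-9)

  # a single nucleus averages to its own histogram
  eh1 <- endpoint_histogram(bcs[1], bin_edges = eh$bin_edges)
  deaths <- bcs[[1]]$death[bcs[[1]]$dimension == 0 &
                             is.finite(bcs[[1]]$death)]
  h <- tabulate(findInterval(deaths, eh$bin_edges, rightmost.closed = TRUE),
                length(eh$bin_edges) - 1)
  expect_equal(eh1$freq_dim0, h / sum(h))

  # inflating the domain radius shifts the dimension-1 endpoint mass to
  # larger alpha (chromatin decondensation direction check)
  ctrl <- lapply(1:3, mk, radius = 100)
  dec <- lapply(4:6, mk, radius = 150)
  edges <- seq(0, 1, by = 0.05)
  mean_endpoint <- function(ehist) {
    ctr <- (edges[-1] + edges[-length(edges)]) / 2
    sum(ctr * ehist$freq_dim1)
  }
  eh_ctrl <- endpoint_histogram(ctrl, bin_edges = edges)
  eh_dec <- endpoint_histogram(dec, bin_edges = edges)
  expect_gt(mean_endpoint(eh_dec), mean_endpoint(eh_ctrl))
})
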