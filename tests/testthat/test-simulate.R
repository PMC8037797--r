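test_that("homogeneous patterns have the requested size, support and seed
          reproducibility", {
  f <- field_spec(24000, 24000)
  tb <- simulate_homogeneous(2000, f, seed = 11)
  expect_s3_class(tb, "localization_table")
  expect_equal(nrow(tb), 2000)
  expect_true(all(in_field <- tb$x_nm >= 0 & tb$x_nm <= 24000 &
                    tb$y_nm >= 0 & tb$y_nm <= 24000))
  expect_true(all(tb$precision_nm == 10))

  expect_identical(as.data.frame(simulate_homogeneous(500, f, seed = 3)),
                   as.data.frame(simulate_homogeneous(500, f, seed = 3)))
  expect_false(identical(
    as.data.frame(simulate_homogeneous(500, f, seed = 3)),
    as.data.frame(simulate_homogeneous(500, f, seed = 4))))

  expect_equal(nrow(simulate_homogeneous(0, f, seed = 1)), 0)
  expect_error(simulate_homogeneous(-1, f, seed = 1), "must be >= 0")
})

test_that("simulation does not disturb the global RNG state", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_homogeneous(10, field_spec(1000), seed = 1))
  expect_identical(before, .Random.seed)
})

test_that("clustered patterns respect counts, containment and the 2R
          diameter bound", {
  f <- field_spec(24000, 24000)
  spec <- cluster_pattern_spec(10, 100, 50)
  sim <- simulate_clustered(spec, f, seed = 5)
  expect_equal(nrow(sim$events), 1000)
  expect_equal(sim$labels, rep(1:10, each = 100))
  xy <- cbind(sim$events$x_nm, sim$events$y_nm)
  d_own <- sqrt(rowSums((xy - sim$centers[sim$labels, ])^2))
  expect_true(all(d_own <= 50))
  for (k in 1:10) {
    pts <- xy[sim$labels == k, ]
    expect_lte(max(dist(pts)), 2 * 50)
  }
  expect_true(all(xy >= 0 & xy <= 24000))

  # disc that cannot fit
  expect_error(simulate_clustered(cluster_pattern_spec(1, 10, 600),
                                  field_spec(1000), seed = 1),
               "does not fit")
})

test_that("intra-cluster distance support scales with the cluster radius", {
  f <- field_spec(24000, 24000)
  max_intra <- function(radius, seed) {
    sim <- simulate_clustered(cluster_pattern_spec(10, 100, radius), f, seed)
    xy <- cbind(sim$events$x_nm, sim$events$y_nm)
    max(vapply(1:10, function(k) max(dist(xy[sim$labels == k, ])),
               numeric(1)))
  }
  # brute-force max pairwise distances approach the diameters 100 and 160
  m50 <- max_intra(50, seed = 7)
  m80 <- max_intra(80, seed = 7)
  expect_lt(abs(m50 - 100), 10)
  expect_lt(abs(m80 - 160), 10)
  expect_lt(abs(m80 / m50 - 160 / 100), 0.1)
})

test_that("mixtures reduce to the pure cases and label background as 0", {
  f <- field_spec(24000, 24000)
  spec <- cluster_pattern_spec(5, 50, 50)
  mix <- simulate_mixture(spec, 300, f, seed = 9)
  expect_equal(nrow(mix$events), 5 * 50 + 300)
  expect_equal(sum(mix$labels == 0), 300)

  # no background: same draw as simulate_clustered
  expect_identical(
    as.data.frame(simulate_mixture(spec, 0, f, seed = 2)$events),
    as.data.frame(simulate_clustered(spec, f, seed = 2)$events))
  # no clusters: same draw as simulate_homogeneous
  empty <- cluster_pattern_spec(0, 1, 50)
  expect_identical(
    as.data.frame(simulate_mixture(empty, 400, f, seed = 2)$events)[
      c("x_nm", "y_nm")],
    as.data.frame(simulate_homogeneous(400, f, seed = 2))[
      c("x_nm", "y_nm")])
})

test_that("minimum cluster separation is honoured", {
  f <- field_spec(10000, 10000)
  sim <- simulate_clustered(
    cluster_pattern_spec(8, 10, 50, min_separation_nm = 2000), f, seed = 13)
  expect_gte(min(dist(sim$centers)), 2000)
  expect_error(
    simulate_clustered(
      cluster_pattern_spec(100, 5, 50, min_separation_nm = 5000), f,
      seed = 1),
    "separation")
})

test_that("two-channel specs validate HC flags and carry ground truth", {
  f <- field_spec(10000, 10000)
  domains <- data.frame(x_nm = 3000, y_nm = 3000, radius_nm = 800,
                        n_points = 500)
  foci_in <- data.frame(x_nm = 3100, y_nm = 2900, radius_nm = 150,
                        n_points = 40, hc_associated = TRUE)
  foci_out <- data.frame(x_nm = 8000, y_nm = 8000, radius_nm = 150,
                         n_points = 40, hc_associated = FALSE)

  spec <- two_channel_spec(f, domains, rbind(foci_in, foci_out),
                           background_a = 50, background_b = 500, seed = 4)
  sim <- simulate_two_channel(spec)
  expect_equal(nrow(sim$channel_a), 80 + 50)
  expect_equal(nrow(sim$channel_b), 500 + 500)
  expect_equal(sim$labels_a, c(rep(1L, 40), rep(2L, 40), rep(0L, 50)))
  expect_equal(sim$foci$hc_associated, c(TRUE, FALSE))

  # inconsistent flag rejected
  bad <- foci_in; bad$hc_associated <- FALSE
  expect_error(two_channel_spec(f, domains, bad), "inconsistent")

  # all foci inside domains -> all HC ground truth
  all_in <- random_two_channel_spec(hc_fraction = 1, n_foci = 6, seed = 8)
  expect_true(all(all_in$foci$hc_associated))
  # determinism
  s1 <- simulate_two_channel(random_two_channel_spec(seed = 21))
  s2 <- simulate_two_channel(random_two_channel_spec(seed = 21))
  expect_identical(as.data.frame(s1$channel_a), as.data.frame(s2$channel_a))
  expect_identical(as.data.frame(s1$channel_b), as.data.frame(s2$channel_b))
})

test_that("generated coordinates always lie inside the field", {
  f <- field_spec(5000, 8000, origin = c(-1000, 200))
  for (s in 1:5) {
    mix <- simulate_mixture(cluster_pattern_spec(4, 30, 100), 200, f,
                            seed = s)
    expect_true(all(mix$events$x_nm >= -1000 & mix$events$x_nm <= 4000))
    expect_true(all(mix$events$y_nm >= 200 & mix$events$y_nm <= 8200))
  }
})
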