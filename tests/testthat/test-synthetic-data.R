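test_that("zero-noise generators satisfy their geometric equations exactly", {
  moons <- make_two_moons(3000, noise_sd = 0, seed = 0)
  first <- moons$points[moons$labels == 1L, , drop = FALSE]
  expect_equal(sqrt(rowSums(first^2)), rep(1, nrow(first)))
  second <- moons$points[moons$labels == 2L, , drop = FALSE]
  expect_equal(sqrt((second[, 1] - 1)^2 + (second[, 2] - 0.5)^2),
               rep(1, nrow(second)))

  rings <- make_concentric_rings(4600, radii = c(1, 3), noise_sd = 0, seed = 0)
  r <- sqrt(rowSums(rings$points^2))
  expect_equal(r, c(1, 3)[rings$labels])

  mix <- make_gaussian_mixture(30, means = rbind(c(0, 0), c(5, 5)), sds = 0, seed = 0)
  expect_true(all(mix$points[mix$labels == 2L, 1] == 5))
  expect_true(all(mix$points[mix$labels == 1L, ] == 0))
})

test_that("generators are bit-identical under a fixed seed", {
  for (gen in list(function(s) make_two_moons(10, noise_sd = 0.2, seed = s),
                   function(s) make_concentric_rings(11, noise_sd = 0.1, seed = s),
                   function(s) make_gaussian_mixture(12, seed = s))) {
    a <- gen(7)
    b <- gen(7)
    expect_identical(a$points, b$points)
    expect_identical(a$labels, b$labels)
    expect_false(identical(a$points, gen(8)$points))
  }
})

test_that("every generated point carries a label and counts are exact", {
  mix <- make_gaussian_mixture(1500, seed = 3)
  expect_length(mix$labels, 1500)
  expect_setequal(unique(mix$labels), 1:3)

  # largest-remainder apportionment: counts sum exactly to n
  w <- c(0.5, 0.3, 0.2)
  mix2 <- make_gaussian_mixture(1001, weights = w, seed = 3)
  counts <- as.integer(table(mix2$labels))
  expect_equal(sum(counts), 1001L)
  expect_true(all(abs(counts - 1001 * w) <= 1))

  moons <- make_two_moons(9, seed = 1)
  expect_equal(as.integer(table(moons$labels)), c(5L, 4L))
})

test_that("mixture component sample means obey the law of large numbers", {
  mix <- make_gaussian_mixture(300, means = rbind(c(0, 0), c(10, 0), c(0, 10)),
                               sds = 0.1, seed = 5)
  means <- rbind(c(0, 0), c(10, 0), c(0, 10))
  for (i in 1:3) {
    pts <- mix$points[mix$labels == i, , drop = FALSE]
    tol <- 3 * 0.1 / sqrt(nrow(pts))
    expect_true(all(abs(colMeans(pts) - means[i, ]) < tol))
  }
})

test_that("noisy rings remain radially disjoint at the default noise level", {
  rings <- make_concentric_rings(4600, radii = c(1, 3), noise_sd = 0.05, seed = 0)
  r <- sqrt(rowSums(rings$points^2))
  expect_lt(max(r[rings$labels == 1L]), min(r[rings$labels == 2L]))
})

test_that("generator argument validation rejects degenerate inputs", {
  expect_error(make_two_moons(1), "n")
  expect_error(make_two_moons(10, noise_sd = -0.1), "noise_sd")
  expect_error(make_concentric_rings(10, radii = 2), "radii")
  expect_error(make_concentric_rings(10, radii = c(1, 1)), "radii")
  expect_warning(make_concentric_rings(100, radii = c(1, 1.1), noise_sd = 0.1),
                 "overlap")
  expect_error(make_gaussian_mixture(10, means = rbind(c(0, 0)), sds = c(1, 2)),
               "component")
  expect_error(make_gaussian_mixture(10, weights = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(make_gaussian_mixture(10, means = list(c(0, 0), c(1, 1, 1))),
               "equal length")
})
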