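dg <- seq(5, 150, by = 1)

test_that("peak finding handles single, double and flat distributions", {
  g1 <- distance_distribution(dg, dnorm(dg, 54, 5))
  pk <- find_peaks(g1)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$area, 1, tolerance = 1e-9)
  expect_equal(pk$mode, 54)
  expect_true(pk$left < pk$mode && pk$mode < pk$right)

  w2 <- 0.84 * dnorm(dg, 54, 2.5) + 0.16 * dnorm(dg, 89, 2.5)
  pk2 <- find_peaks(distance_distribution(dg, w2))
  expect_equal(nrow(pk2), 2L)
  expect_equal(pk2$area, c(0.84, 0.16), tolerance = 1e-9)
  expect_equal(pk2$mode, c(54, 89))

  flat <- distance_distribution(dg, rep(1, length(dg)))
  pkf <- find_peaks(flat)
  expect_equal(nrow(pkf), 1L)
  expect_equal(c(pkf$left, pkf$right), range(dg))
})

test_that("sub-threshold peaks merge into the nearest retained peak", {
  w <- 0.90 * dnorm(dg, 60, 4) + 0.01 * dnorm(dg, 100, 2) +
    0.09 * dnorm(dg, 120, 3)
  pk <- find_peaks(distance_distribution(dg, w), min_area = 0.02)
  expect_equal(nrow(pk), 2L)
  # the 1% ripple at 100 joins the 120 peak (its nearest neighbor)
  expect_equal(sort(pk$mode), c(60, 120))
  expect_equal(sum(pk$area), 1, tolerance = 1e-9)
  expect_equal(min(pk$area), 0.10, tolerance = 1e-3)
})

test_that("baseline exclusion drops evidence-free plateau peaks", {
  n <- length(dg)
  w <- 0.8 * dnorm(dg, 54, 4) + 0.15 * dnorm(dg, 89, 4)
  w <- w / sum(w)
  w[dg >= 120] <- 0.3 / n       # entropy plateau below the uniform level
  pk <- find_peaks(distance_distribution(dg, w), min_height = 0.5)
  expect_equal(nrow(pk), 2L)
  expect_equal(sort(pk$mode), c(54, 89))
  # without exclusion the plateau segment is retained
  pk0 <- find_peaks(distance_distribution(dg, w))
  expect_gt(nrow(pk0), 2L)
})

test_that("population fractions renormalize over retained peaks", {
  pk <- data.frame(area = c(0.6, 0.3))
  expect_equal(population_fractions(pk), c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(population_fractions(data.frame(area = 0.7)), 1)
  expect_equal(population_fractions(data.frame(area = c(0.84, 0.16))),
               c(0.84, 0.16))
})

test_that("free-energy differences follow RT log-ratio", {
  expect_equal(delta_g(0.5, 0.5), 0)
  expect_equal(delta_g(0.85, 0.15, 298.15), 1.028, tolerance = 1e-3)
  expect_equal(delta_g(0.84, 0.16, 298.15), 0.982, tolerance = 1e-3)
  # antisymmetric under swapping major/minor
  expect_equal(delta_g(0.85, 0.15), -delta_g(0.15, 0.85))
  expect_error(delta_g(0, 1), "positive")
})

test_that("fractions are invariant under rescaling of the weights", {
  w <- 0.7 * dnorm(dg, 50, 5) + 0.3 * dnorm(dg, 100, 5)
  f1 <- population_fractions(find_peaks(distance_distribution(dg, w)))
  f2 <- population_fractions(find_peaks(distance_distribution(dg, 37 * w)))
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("resolution smoothing preserves modes and kills ripple", {
  # symmetric peak with band-edge ripple of ~9 A period riding on it
  w <- dnorm(dg, 54, 6) * (1 + 0.4 * cos(2 * pi * (dg - 49) / 9))
  d0 <- distance_distribution(dg, w)
  expect_gt(nrow(find_peaks(d0)), 1L)          # ripple splits the peak
  ds <- resolution_smooth(d0, q_max = 0.35)
  pk <- find_peaks(ds)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$mode, 54, tolerance = 2)
  expect_equal(sum(ds$weights), 1, tolerance = 1e-9)
})

test_that("ensemble summary reports fractions and free energy together", {
  w <- 0.84 * dnorm(dg, 54, 2.5) + 0.16 * dnorm(dg, 89, 2.5)
  s <- ensemble_summary(distance_distribution(dg, w), label_pair = "BH")
  expect_equal(s$fractions, c(0.84, 0.16), tolerance = 1e-6)
  expect_equal(s$delta_g, delta_g(s$fractions[1], s$fractions[2]),
               tolerance = 1e-9)
  expect_output(print(s), "BH")
})
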