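test_that("scenario construction validates weights and presets exist", {
  expect_error(xsi_scenario("BH", list()), "at least one state")
  expect_error(xsi_scenario("BH", list(list(distance = 54, weight = 0.5))),
               "sum to 1")
  expect_error(xsi_scenario("BH", list(list(distance = 54, weight = 1)),
                            jitter = -1), "non-negative")
  expect_error(scenario_preset("no_such"), "unknown")
  for (nm in c("high_Mg_BH", "high_Mg_HR", "high_Mg_BR",
               "intermediate_Mg_BH", "low_salt_BR", "low_salt_HR",
               "low_salt_RX")) {
    sc <- scenario_preset(nm)
    expect_s3_class(sc, "xsi_scenario")
    expect_equal(sum(vapply(sc$states, `[[`, numeric(1), "weight")), 1)
  }
})

test_that("bundle generation is deterministic given a seed", {
  b1 <- small_bundle("high_Mg_BH", seed = 9, n_conformers = 5L)
  b2 <- small_bundle("high_Mg_BH", seed = 9, n_conformers = 5L)
  expect_identical(b1$profiles$AB$intensity, b2$profiles$AB$intensity)
  b3 <- small_bundle("high_Mg_BH", seed = 10, n_conformers = 5L)
  expect_false(identical(b1$profiles$AB$intensity,
                         b3$profiles$AB$intensity))
})

test_that("splitting one state into two identical halves changes nothing", {
  s1 <- xsi_scenario("BH", list(list(distance = 60, weight = 1)),
                     jitter = 0, noise = 0)
  s2 <- xsi_scenario("BH", list(list(distance = 60, weight = 0.5),
                                list(distance = 60, weight = 0.5)),
                     jitter = 0, noise = 0)
  b1 <- small_bundle(s1, n_conformers = 4L)
  b2 <- small_bundle(s2, n_conformers = 4L)
  for (role in c("AB", "A", "B", "U", "Au", "Buf"))
    expect_equal(b1$profiles[[role]]$intensity,
                 b2$profiles[[role]]$intensity, tolerance = 1e-12)
})

test_that("noisy profiles scatter around the noiseless curve", {
  sc0 <- xsi_scenario("BH", list(list(distance = 54, weight = 1)),
                      jitter = 0, noise = 0)
  clean <- small_bundle(sc0, n_conformers = 3L)$profiles$AB
  sc <- xsi_scenario("BH", list(list(distance = 54, weight = 1)),
                     jitter = 0, noise = 0.01)
  n_rep <- 40L
  devs <- sapply(seq_len(n_rep), function(s) {
    b <- small_bundle(sc, seed = 100 + s, n_conformers = 3L)
    b$profiles$AB$intensity - clean$intensity
  })
  sig <- small_bundle(sc, seed = 1, n_conformers = 3L)$profiles$AB$sigma
  # mean over replicates converges to 0 within 3 standard errors, pointwise
  z <- abs(rowMeans(devs)) / (sig / sqrt(n_rep))
  expect_lt(mean(z > 3), 0.05)
  # two seeds differ
  expect_gt(max(abs(devs[, 1] - devs[, 2])), 0)
})

test_that("FRET traces respect the two-state stationary distribution", {
  m <- fret_state_model(k12 = 20, k21 = 20)
  tr <- generate_fret_trace(m, duration = 60, seed = 4)
  frac2 <- mean(tr$true_states == 2L)
  # symmetric rates: occupancy 1/2 within ~3 s.e. of the dwell count
  n_dwell <- 60 * 20
  expect_lt(abs(frac2 - 0.5), 3 / sqrt(n_dwell))
  # frozen limit: negligible rates, no noise -> constant trace
  frozen <- generate_fret_trace(fret_state_model(k12 = 1e-9, k21 = 1e-9),
                                duration = 1, noise_sd = 0, seed = 5)
  e <- fret_efficiency(frozen)
  expect_equal(length(unique(round(e, 12))), 1L)
  expect_true(unique(round(e, 2)) %in% c(0.14, 0.58))
})

test_that("mean dwell in the low-FRET state matches the forward rate", {
  m <- fret_state_model()  # 45.6 / 7.9 1/s
  set.seed(8)
  dwells <- unlist(lapply(1:10, function(i) {
    p <- generate_fret_trace(m, duration = 10)$true_path
    # drop the censored first and last dwells of each trace
    keep <- p$state == 1L & seq_len(nrow(p)) > 1 & seq_len(nrow(p)) < nrow(p)
    (p$end - p$start)[keep]
  }))
  expect_gt(length(dwells), 200)
  expect_lt(abs(mean(dwells) - 1 / 45.6) / (1 / 45.6), 0.10)
})

test_that("FRET traces round trip through CSV", {
  tr <- generate_fret_trace(fret_state_model(), 0.5, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_fret_trace(tr, f)
  tr2 <- read_fret_trace(f)
  expect_equal(tr2$fps, tr$fps, tolerance = 1e-6)
  expect_equal(tr2$donor, tr$donor, tolerance = 1e-6)
})
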