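test_that("chi-squared and its analytic amplitude minimizer agree", {
  q <- q_small
  model <- interference_basis(q, 60)
  pat <- make_pattern(q, 3.5 * model, rep(0.2, 60))
  expect_equal(chi_squared(pat, model, 3.5), 0)
  # adding k*sigma to one point adds k^2
  pat2 <- pat
  pat2$values[10] <- pat2$values[10] + 3 * pat2$sigma[10]
  expect_equal(chi_squared(pat2, model, 3.5), 9, tolerance = 1e-9)
  # closed-form amplitude equals the numeric minimizer
  set.seed(2)
  patn <- make_pattern(q, 3.5 * model + rnorm(60, 0, 0.2),
                       runif(60, 0.1, 0.3))
  a_hat <- fit_amplitude(patn, model)
  a_num <- optimize(function(a) chi_squared(patn, model, a),
                    c(0, 10), tol = 1e-10)$minimum
  expect_equal(a_hat, a_num, tolerance = 1e-6)
})

test_that("a noiseless single-distance pattern inverts to its distance", {
  q <- default_q_grid(n = 120L)
  bas <- build_basis_matrix(q, default_d_grid())
  truth <- 93
  vals <- 1250 * interference_basis(q, truth)
  pat <- make_pattern(q, vals, rep(1e-4 * max(abs(vals)), 120))
  d <- fit_distribution(pat, bas)
  expect_equal(d$d_grid[which.max(d$weights)], truth, tolerance = 1)
  expect_true(all(d$weights >= 0))
  expect_equal(sum(d$weights), 1, tolerance = 1e-9)
})

test_that("uninformative data return the prior", {
  q <- q_small
  bas <- build_basis_matrix(q, seq(20, 120, by = 5))
  pat <- make_pattern(q, interference_basis(q, 54), rep(1e9, 60))
  d <- fit_distribution(pat, bas)
  expect_lt(max(abs(d$weights - 1 / length(bas$d_grid))), 1e-6)
  prior <- dnorm(bas$d_grid, 70, 30); prior <- prior / sum(prior)
  d2 <- fit_distribution(pat, bas, prior = prior)
  expect_lt(max(abs(d2$weights - prior)), 1e-6)
})

test_that("a two-component pattern is recovered in modes and weights", {
  set.seed(7)
  q <- default_q_grid()
  bas <- build_basis_matrix(q, default_d_grid())
  truth <- 1250 * (0.84 * interference_basis(q, 54) +
                     0.16 * interference_basis(q, 89))
  sigma <- 0.01 * max(abs(truth)) * sqrt(pmax(abs(truth) / max(abs(truth)),
                                              0.05))
  pat <- make_pattern(q, truth + rnorm(length(q), 0, sigma), sigma)
  d <- fit_distribution(pat, bas)
  pk <- find_peaks(d, min_height = 0.5)
  expect_gte(nrow(pk), 2)
  expect_equal(pk$mode[1], 54, tolerance = 2)
  expect_equal(pk$mode[2], 89, tolerance = 2)
  fr <- population_fractions(pk[1:2, ])
  expect_equal(fr[1], 0.84, tolerance = 0.05)
})

test_that("solver matches a brute-force constrained optimizer on small grids", {
  dg <- seq(20, 125, by = 15)  # 8 well-separated bins
  q <- default_q_grid(n = 60L)
  bas <- build_basis_matrix(q, dg)
  p_true <- c(0, 0, 0, 0.8, 0, 0, 0.2, 0)
  y <- 1000 * drop(p_true %*% bas$values)

  # feasible case: stated sigma above the injected noise, so the chi2
  # constraint is reachable and active at the target
  set.seed(42)
  pat_f <- make_pattern(q, y + rnorm(60, 0, 5), rep(8, 60))
  fit_f <- fit_distribution(pat_f, bas)
  expect_false(fit_f$diagnostics$infeasible)
  p_or <- maxent_oracle(pat_f, bas, fit_f$diagnostics$chi2_per_point)
  expect_lt(max(abs(fit_f$weights - p_or)), 1e-4)

  # infeasible case: tiny stated sigma, least-chi2 solution returned
  set.seed(43)
  pat_i <- make_pattern(q, y + rnorm(60, 0, 2), rep(0.5, 60))
  fit_i <- fit_distribution(pat_i, bas)
  expect_true(fit_i$diagnostics$infeasible)
  expect_gt(fit_i$diagnostics$chi2_per_point, 1)
  p_or_i <- maxent_oracle(pat_i, bas, fit_i$diagnostics$chi2_per_point)
  expect_lt(max(abs(fit_i$weights - p_or_i)), 1e-4)
})

test_that("infeasibility flag tracks whether the target is reachable", {
  dg <- seq(30, 110, by = 10)
  q <- q_small
  bas <- build_basis_matrix(q, dg)
  y <- 800 * interference_basis(q, 60)
  pat_ok <- make_pattern(q, y, rep(1, 60))
  expect_false(fit_distribution(pat_ok, bas)$diagnostics$infeasible)
  # a pattern no basis mixture can reach (wrong q-dependence), tiny sigma
  pat_bad <- make_pattern(q, 100 * exp(-10 * q), rep(0.01, 60))
  expect_true(fit_distribution(pat_bad, bas)$diagnostics$infeasible)
})

test_that("recovered mode is stable under q-grid refinement", {
  mk <- function(n) {
    q <- default_q_grid(n = n)
    bas <- build_basis_matrix(q, default_d_grid())
    set.seed(13)
    truth <- 1250 * interference_basis(q, 72)
    sig <- rep(0.01 * max(abs(truth)), n)
    pat <- make_pattern(q, truth + rnorm(n, 0, sig), sig)
    d <- fit_distribution(pat, bas)
    d$d_grid[which.max(d$weights)]
  }
  expect_equal(mk(128L), mk(256L), tolerance = 1)
})

test_that("fitted distributions are normalized and non-negative by construction", {
  q <- q_small
  bas <- build_basis_matrix(q, seq(20, 120, by = 4))
  for (s in 1:5) {
    set.seed(s)
    d0 <- sample(30:100, 1)
    truth <- 1000 * interference_basis(q, d0)
    sig <- rep(runif(1, 0.005, 0.05) * max(abs(truth)), 60)
    pat <- make_pattern(q, truth + rnorm(60, 0, sig), sig)
    d <- fit_distribution(pat, bas)
    expect_true(all(d$weights >= 0))
    expect_equal(sum(d$weights), 1, tolerance = 1e-9)
    expect_equal(d$d_grid[which.max(d$weights)], d0, tolerance = 4)
  }
})
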