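test_that("sphere form amplitude matches the closed form and its limits", {
  expect_identical(sphere_form_amplitude(0, 7), 1)
  # direct evaluation of 3[sin(qR) - qR cos(qR)]/(qR)^3 at qR = 0.7
  x <- 0.7
  expect_equal(sphere_form_amplitude(0.1, 7),
               3 * (sin(x) - x * cos(x)) / x^3, tolerance = 1e-12)
  expect_equal(sphere_form_amplitude(0.1, 7), 0.9519, tolerance = 1e-4)
  expect_error(sphere_form_amplitude(0.1, -1), "positive")
  expect_error(sphere_form_amplitude(-0.1, 7), "non-negative")
})

test_that("first form-factor zero sits at the root of tan x = x", {
  # independent root bracketing of tan x = x on (pi, 3pi/2)
  root <- uniroot(function(x) sin(x) - x * cos(x), c(pi + 0.1, 4.6),
                  tol = 1e-12)$root
  expect_equal(root, 4.4934, tolerance = 1e-4)
  q0 <- root / 7
  expect_equal(q0, 0.6419, tolerance = 1e-3)
  expect_lt(abs(sphere_form_amplitude(q0, 7)), 1e-10)
  eps <- 1e-3
  expect_true(sphere_form_amplitude(q0 - eps, 7) *
                sphere_form_amplitude(q0 + eps, 7) < 0)
})

test_that("interference basis is F^2 at d = 0 and oscillates as sinc", {
  q <- default_q_grid(n = 50L)
  expect_equal(interference_basis(q, 0), sphere_form_amplitude(q)^2)
  # sinc factor at q = 0.05, d = 54
  expect_equal(interference_basis(0.05, 54) / sphere_form_amplitude(0.05)^2,
               0.15829, tolerance = 1e-5)
  # zeros wherever qd = k*pi
  d <- 54
  qz <- (1:3) * pi / d
  expect_equal(interference_basis(qz, d), rep(0, 3), tolerance = 1e-12)
  expect_error(interference_basis(q, -1), "non-negative")
})

test_that("basis matrix rows equal the basis function and stay bounded", {
  q <- default_q_grid(n = 40L)
  dg <- c(30, 54, 93)
  bm <- build_basis_matrix(q, dg)
  expect_equal(dim(bm$values), c(3L, 40L))
  for (i in 1:3)
    expect_equal(bm$values[i, ], interference_basis(q, dg[i]))
  f2 <- sphere_form_amplitude(q)^2
  expect_true(all(abs(bm$values) <= rep(f2, each = 3) + 1e-12))
  # distinct distances spanning >= 1 oscillation give distinct rows
  expect_gt(max(abs(bm$values[1, ] - bm$values[3, ])), 0.01)
  one <- build_basis_matrix(q, 54)
  expect_equal(drop(one$values), interference_basis(q, 54))
})

test_that("Debye intensity reproduces closed forms and invariances", {
  q <- default_q_grid(n = 40L)
  # one bead of weight f -> constant f^2
  m1 <- bead_model(matrix(0, 1, 3), weights = 5)
  expect_equal(debye_intensity(m1, q)$intensity, rep(25, 40))
  # two gold beads at distance d, no DNA
  d <- 54
  m2 <- bead_model(rbind(c(0, 0, 0), c(d, 0, 0)), weights = c(25, 25),
                   is_gold = c(TRUE, TRUE))
  f2 <- (25 * sphere_form_amplitude(q))^2
  expect_equal(debye_intensity(m2, q)$intensity,
               2 * f2 * (1 + sin(q * d) / (q * d)), tolerance = 1e-12)
  # rigid rotation leaves I(q) unchanged
  set.seed(3)
  xyz <- matrix(rnorm(30, sd = 20), 10, 3)
  w <- runif(10, 0.5, 2)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  i1 <- debye_intensity(bead_model(xyz, w), q)$intensity
  i2 <- debye_intensity(bead_model(xyz %*% R + 5, w), q)$intensity
  expect_equal(i2, i1, tolerance = 1e-10)
  # coincident beads: handled by the r -> 0 limit
  m3 <- bead_model(rbind(c(0, 0, 0), c(0, 0, 0)), weights = c(1, 1))
  expect_equal(debye_intensity(m3, q)$intensity, rep(4, 40))
})

test_that("Debye sum decomposes into parts plus cross term", {
  q <- default_q_grid(n = 30L)
  set.seed(11)
  a_xyz <- matrix(rnorm(18, sd = 15), 6, 3)
  b_xyz <- matrix(rnorm(24, sd = 15) + 30, 8, 3)
  wa <- runif(6, 0.5, 2); wb <- runif(8, 0.5, 2)
  I_union <- debye_intensity(bead_model(rbind(a_xyz, b_xyz), c(wa, wb)),
                             q)$intensity
  I_a <- debye_intensity(bead_model(a_xyz, wa), q)$intensity
  I_b <- debye_intensity(bead_model(b_xyz, wb), q)$intensity
  # brute-force cross term over all pairs
  cross <- sapply(q, function(qq) {
    s <- 0
    for (i in 1:6) for (j in 1:8) {
      r <- sqrt(sum((a_xyz[i, ] - b_xyz[j, ])^2))
      s <- s + wa[i] * wb[j] * sin(qq * r) / (qq * r)
    }
    s
  })
  expect_equal(I_union, I_a + I_b + 2 * cross, tolerance = 1e-10)
})
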