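# shared fixtures: small grids and generators keep unit tests fast; the
# acceptance tests use the package defaults.

q_small <- default_q_grid(n = 60L)

# quick bundle: few conformers, small grid
small_bundle <- function(preset_or_scenario, seed = 1, n_conformers = 25L,
                         q_grid = q_small) {
  sc <- if (is.character(preset_or_scenario))
    scenario_preset(preset_or_scenario) else preset_or_scenario
  generate_xsi_bundle(sc, q_grid = q_grid, n_conformers = n_conformers,
                      seed = seed)
}

extract_from_bundle <- function(bundle) {
  sub <- lapply(bundle$profiles[c("AB", "A", "B", "U")],
                subtract_buffer, buffer = bundle$profiles$Buf)
  extract_interference(sub$AB, sub$A, sub$B, sub$U)
}

make_pattern <- function(q_grid, values, sigma) {
  structure(list(q_grid = q_grid, values = values, sigma = sigma),
            class = "interference_pattern")
}

# Brute-force constrained optimizer for the maximum-entropy problem:
# maximize -sum p log(p/m) subject to chi2/N <= target, amplitude refit in
# closed form. Penalty method with escalating multiplier on softmax
# coordinates, solved by Nelder-Mead. Independent of the package's solver.
maxent_oracle <- function(pattern, basis, target, m = NULL,
                          mus = 10^(2:9)) {
  B <- basis$values
  nd <- nrow(B)
  N <- length(pattern$q_grid)
  if (is.null(m)) m <- rep(1 / nd, nd)
  s2 <- pattern$sigma^2
  I <- pattern$values
  chi2_of <- function(p) {
    y <- drop(p %*% B)
    a <- sum(I * y / s2) / sum(y^2 / s2)
    sum((I - a * y)^2 / s2)
  }
  ent <- function(p) {
    nz <- p > 0
    -sum(p[nz] * log(p[nz] / m[nz]))
  }
  obj <- function(z, mu) {
    p <- exp(z - max(z)); p <- p / sum(p)
    -ent(p) + mu * max(0, chi2_of(p) / N - target)^2
  }
  z <- log(m)
  for (mu in mus)
    z <- stats::optim(z, obj, mu = mu, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-15))$par
  # final refinement with a quasi-Newton pass at the stiffest penalty
  z <- stats::optim(z, obj, mu = mus[length(mus)], method = "BFGS",
                    control = list(maxit = 5000, reltol = 1e-15))$par
  p <- exp(z - max(z))
  p / sum(p)
}
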