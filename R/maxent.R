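#' Chi-squared misfit between an interference pattern and a model curve
#'
#' \deqn{\chi^2 = \sum_j [(I_{obs}(q_j) - a\,M(q_j))/\sigma_j]^2}
#'
#' @param pattern An `interference_pattern` (see [extract_interference()]) or
#'   any list with `q_grid`, `values`/`intensity` and `sigma`.
#' @param model_curve Numeric vector on the same grid.
#' @param amplitude Overall scale `a` applied to the model.
#' @return Chi-squared (dimensionless).
#' @export
chi_squared <- function(pattern, model_curve, amplitude = 1) {
  obs <- pattern_values(pattern)
  if (length(model_curve) != length(obs$values))
    stop("model curve length does not match pattern grid")
  if (any(obs$sigma <= 0)) stop("sigma must be positive")
  sum(((obs$values - amplitude * model_curve) / obs$sigma)^2)
}

pattern_values <- function(pattern) {
  vals <- if (!is.null(pattern$values)) pattern$values else pattern$intensity
  list(q_grid = pattern$q_grid, values = vals, sigma = pattern$sigma)
}

#' Closed-form amplitude minimizing chi-squared
#'
#' Weighted least-squares scale \eqn{a = \sum I M/\sigma^2 / \sum M^2/\sigma^2}.
#'
#' @inheritParams chi_squared
#' @return The optimal amplitude.
#' @export
fit_amplitude <- function(pattern, model_curve) {
  obs <- pattern_values(pattern)
  denom <- sum(model_curve^2 / obs$sigma^2)
  if (denom <= 0) return(0)
  sum(obs$values * model_curve / obs$sigma^2) / denom
}

new_distance_distribution <- function(d_grid, weights, amplitude = NA_real_,
                                      diagnostics = list()) {
  structure(list(d_grid = d_grid, weights = weights, amplitude = amplitude,
                 diagnostics = diagnostics),
            class = "distance_distribution")
}

#' Construct a distance distribution from explicit weights
#'
#' Normalizes non-negative weights on a uniform distance grid; used for
#' priors and for tests.
#'
#' @param d_grid Uniform ascending distance grid (Angstrom).
#' @param weights Non-negative weights (normalized to sum 1).
#' @return A `distance_distribution`.
#' @export
distance_distribution <- function(d_grid, weights) {
  if (length(d_grid) != length(weights)) stop("length mismatch")
  if (length(d_grid) > 1) {
    steps <- diff(d_grid)
    if (any(steps <= 0) ||
        max(abs(steps - steps[1])) > 1e-9 * steps[1])
      stop("d_grid must be uniform and ascending")
  }
  if (any(weights < 0)) stop("weights must be non-negative")
  s <- sum(weights)
  if (s <= 0) stop("weights sum to zero")
  new_distance_distribution(d_grid, weights / s)
}

#' @export
print.distance_distribution <- function(x, ...) {
  mode_d <- x$d_grid[which.max(x$weights)]
  cat(sprintf("<distance_distribution> %d points, step %g A, mode %g A\n",
              length(x$d_grid), x$d_grid[2] - x$d_grid[1], mode_d))
  if (length(x$diagnostics))
    cat(sprintf("  chi2/N = %.4g, entropy = %.4g, iterations = %s%s\n",
                x$diagnostics$chi2_per_point, x$diagnostics$entropy,
                x$diagnostics$iterations,
                if (isTRUE(x$diagnostics$infeasible))
                  " [chi2 target unreachable]" else ""))
  invisible(x)
}

# entropy relative to prior m: S = -sum p log(p/m); terms with p = 0 vanish
relative_entropy <- function(p, m) {
  nz <- p > 0
  -sum(p[nz] * log(p[nz] / m[nz]))
}

# Minimize lambda * chi2(p) + sum p log(p/m) over the simplex for a fixed
# trade-off multiplier. Weights are parameterized multiplicatively as
# p = exp(z)/sum(exp(z)), which keeps them positive without explicit bounds;
# the unconstrained z problem is solved by BFGS with the analytic gradient.
# chi2 refits the overall amplitude in closed form at every evaluation; by
# the envelope theorem its gradient can treat the amplitude as fixed.
maxent_inner <- function(p, lambda, B, obs, m, max_iter = 2000L) {
  s2 <- obs$sigma^2
  I <- obs$values
  eval_p <- function(p) {
    y <- drop(p %*% B)
    den <- sum(y^2 / s2)
    a <- if (is.finite(den) && den > 0) sum(I * y / s2) / den else 0
    chi2 <- sum((I - a * y)^2 / s2)
    list(chi2 = chi2, amplitude = a, y = y)
  }
  softmax <- function(z) {
    z <- z - max(z)
    e <- exp(z)
    e / sum(e)
  }
  fn <- function(z) {
    p <- softmax(z)
    ev <- eval_p(p)
    v <- lambda * ev$chi2 - relative_entropy(p, m)
    if (!is.finite(v)) 1e300 else v
  }
  gr <- function(z) {
    p <- softmax(z)
    ev <- eval_p(p)
    grad_chi2 <- drop(B %*% ((-2 * ev$amplitude) *
                               (I - ev$amplitude * ev$y) / s2))
    g <- lambda * grad_chi2 + log(pmax(p, 1e-300) / m) + 1
    p * (g - sum(p * g))
  }
  z0 <- log(pmax(p, 1e-12))
  fit <- stats::optim(z0, fn, gr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-14))
  p_fin <- softmax(fit$par)
  ev <- eval_p(p_fin)
  list(p = p_fin, chi2 = ev$chi2, amplitude = ev$amplitude,
       iterations = as.integer(fit$counts[["function"]]))
}

#' Maximum-entropy inversion of an interference pattern
#'
#' Recovers the distance distribution `P(d)` that maximizes the entropy
#' \eqn{S = -\sum_i p_i \ln(p_i/m_i)} relative to the prior `m`, subject to
#' the fit constraint \eqn{\chi^2/N \le} `chi2_target`, where the model is
#' the basis-matrix combination \eqn{a \sum_i p_i B(q, d_i)} with the overall
#' amplitude `a` refit in closed form at every step. The constraint is
#' enforced by bisection on the entropy/chi-squared trade-off multiplier;
#' weights are updated multiplicatively (exponentiated gradient), which keeps
#' them positive without explicit bounds.
#'
#' If even the unconstrained least-chi-squared solution cannot reach the
#' target, that solution is returned with `diagnostics$infeasible = TRUE`.
#' If the prior itself already satisfies the constraint (e.g. uninformative
#' data with huge sigma), the prior is returned unchanged.
#'
#' @param pattern An `interference_pattern` (from [extract_interference()]).
#' @param basis A [build_basis_matrix()] whose q grid matches the pattern.
#' @param prior Prior weights on the basis distance grid (default uniform);
#'   normalized internally.
#' @param chi2_target Target reduced chi-squared per point (default 1.0,
#'   matched within +/- 0.05).
#' @param max_iter Iteration cap for each inner solve.
#' @return A `distance_distribution` with fitted `amplitude` and
#'   `diagnostics` (`chi2`, `chi2_per_point`, `entropy`, `iterations`,
#'   `lambda`, `infeasible`). Weights below 1e-12 are reported as 0.
#' @export
fit_distribution <- function(pattern, basis, prior = NULL,
                             chi2_target = 1.0, max_iter = 10000L) {
  stopifnot(inherits(basis, "basis_matrix"))
  obs <- pattern_values(pattern)
  if (length(obs$q_grid) != length(basis$q_grid) ||
      max(abs(obs$q_grid - basis$q_grid)) > 1e-9 * max(basis$q_grid))
    stop("pattern and basis q grids do not overlap")
  if (any(obs$sigma <= 0)) stop("sigma must be positive")
  B <- basis$values
  nd <- length(basis$d_grid)
  N <- length(obs$q_grid)
  m <- if (is.null(prior)) rep(1 / nd, nd) else {
    if (length(prior) != nd) stop("prior length does not match d grid")
    if (any(prior < 0)) stop("prior must be non-negative")
    prior / sum(prior)
  }
  if (any(m == 0)) {
    # zero-prior bins are excluded from the support; keep them at zero
    m <- pmax(m, 1e-300)
  }
  tol_band <- 0.05

  chi2_of <- function(p) {
    y <- drop(p %*% B)
    a <- fit_amplitude(pattern, y)
    sum((obs$values - a * y)^2 / obs$sigma^2)
  }

  finish <- function(p, chi2, amplitude, iters, lambda, infeasible) {
    p[p < 1e-12] <- 0
    p <- p / sum(p)
    y <- drop(p %*% B)
    a <- fit_amplitude(pattern, y)
    chi2 <- sum((obs$values - a * y)^2 / obs$sigma^2)
    new_distance_distribution(
      basis$d_grid, p, amplitude = a,
      diagnostics = list(chi2 = chi2, chi2_per_point = chi2 / N,
                         entropy = relative_entropy(p, m),
                         iterations = iters, lambda = lambda,
                         infeasible = infeasible))
  }

  # constraint already inactive at the entropy maximum (the prior)?
  if (chi2_of(m) / N <= chi2_target)
    return(finish(m, NA, NA, 0L, 0, FALSE))

  # feasibility: exact least-chi2 over non-negative weights (the amplitude
  # is absorbed into the unnormalized weights, making chi2 quadratic)
  A <- t(B) / obs$sigma
  nnls <- pracma::lsqnonneg(A, obs$values / obs$sigma)
  chi2_min <- sum(nnls$resid.norm)
  if (chi2_min / N > chi2_target) {
    u <- nnls$x
    if (sum(u) <= 0) u <- m
    return(finish(u / sum(u), NA, NA, 0L, Inf, TRUE))
  }

  total_iters <- 0L
  run <- function(p0, lambda, iters = 2000L) {
    r <- maxent_inner(p0, lambda, B, obs, m, max_iter = iters)
    total_iters <<- total_iters + r$iterations
    r
  }

  # bracket: grow lambda until chi2/N drops below the target band
  lam_lo <- 1e-10
  lam_hi <- 1e-6
  p_warm <- m
  repeat {
    r_hi <- run(p_warm, lam_hi)
    p_warm <- r_hi$p
    if (r_hi$chi2 / N <= chi2_target) break
    lam_lo <- lam_hi
    lam_hi <- lam_hi * 10
    if (lam_hi > 1e16) break  # NNLS said feasible; accept closest
  }

  # bisect on log(lambda) to land chi2/N within the tolerance band
  r_mid <- r_hi
  lam_mid <- lam_hi
  for (i in 1:60) {
    if (abs(r_mid$chi2 / N - chi2_target) <= tol_band) break
    lam_mid <- sqrt(lam_lo * lam_hi)
    r_mid <- run(p_warm, lam_mid)
    p_warm <- r_mid$p
    if (r_mid$chi2 / N > chi2_target) lam_lo <- lam_mid else lam_hi <- lam_mid
  }
  # final polish at the selected multiplier with the full iteration budget
  r_fin <- run(r_mid$p, lam_mid, iters = max_iter)
  finish(r_fin$p, r_fin$chi2, r_fin$amplitude, total_iters, lam_mid, FALSE)
}
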