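#' Default momentum-transfer grid
#'
#' 256 linearly spaced points on 0.01-0.35 1/Angstrom, covering the q range
#' over which a 7 Angstrom gold label produces usable interference signal at
#' typical small-angle beamline geometries.
#'
#' @param n Number of points.
#' @param q_min,q_max Range (1/Angstrom).
#' @return Numeric vector.
#' @export
default_q_grid <- function(n = 256L, q_min = 0.01, q_max = 0.35) {
  seq(q_min, q_max, length.out = n)
}

#' Default distance grid for inversions
#'
#' 5-150 Angstrom in 1 Angstrom steps, spanning all gold-gold distances a
#' four-way junction with 11 bp arms can produce, with margin.
#'
#' @param d_min,d_max,step Grid range and step (Angstrom).
#' @return Numeric vector.
#' @export
default_d_grid <- function(d_min = 5, d_max = 150, step = 1) {
  seq(d_min, d_max, by = step)
}

# numerically safe sinc(x) = sin(x)/x with sinc(0) = 1
sinc <- function(x) {
  out <- rep(1, length(x))
  nz <- abs(x) > 1e-12
  out[nz] <- sin(x[nz]) / x[nz]
  out
}

#' Sphere form-factor amplitude
#'
#' Normalized scattering amplitude of a homogeneous sphere of radius `radius`:
#' \deqn{F(q) = 3\,[\sin(qR) - qR\cos(qR)]/(qR)^3,\qquad F(0)=1,}
#' the standard small-angle form factor used here for the 7 Angstrom gold
#' nanocrystal labels.
#'
#' @param q Momentum transfer (1/Angstrom), `q >= 0` (vectorized).
#' @param radius Sphere radius (Angstrom), positive.
#' @return Dimensionless amplitude, same length as `q`.
#' @export
sphere_form_amplitude <- function(q, radius = 7) {
  if (radius <= 0) stop("radius must be positive")
  if (any(q < 0)) stop("q must be non-negative")
  x <- q * radius
  out <- rep(1, length(x))
  nz <- x > 1e-6
  xz <- x[nz]
  out[nz] <- 3 * (sin(xz) - xz * cos(xz)) / xz^3
  out
}

#' Gold-gold interference basis function
#'
#' The scattering interference between two gold labels separated by a fixed
#' distance `d`:
#' \deqn{B(q, d) = F(q, R)^2 \, \mathrm{sinc}(qd),}
#' where `F` is the sphere form amplitude. A measured interference pattern is
#' modeled as a non-negative weighted combination of these curves over a
#' distance grid, which is what the maximum-entropy inversion fits.
#'
#' @param q_grid Momentum transfer values (1/Angstrom).
#' @param d Label-label distance (Angstrom), `d >= 0`.
#' @param radius Gold label radius (Angstrom).
#' @return Numeric vector of basis values on `q_grid`.
#' @export
interference_basis <- function(q_grid, d, radius = 7) {
  if (d < 0) stop("distance must be non-negative")
  sphere_form_amplitude(q_grid, radius)^2 * sinc(q_grid * d)
}

#' Basis matrix of interference curves
#'
#' @param q_grid Momentum transfer values (1/Angstrom).
#' @param d_grid Distance centers (Angstrom).
#' @param radius Gold label radius (Angstrom).
#' @return Object of class `basis_matrix`: list with `d_grid`, `q_grid`,
#'   `radius` and `values`, a `length(d_grid) x length(q_grid)` matrix whose
#'   row i is [interference_basis()] at `d_grid[i]`.
#' @export
build_basis_matrix <- function(q_grid, d_grid = default_d_grid(), radius = 7) {
  if (length(q_grid) == 0L || length(d_grid) == 0L)
    stop("empty grid")
  f2 <- sphere_form_amplitude(q_grid, radius)^2
  values <- sinc(outer(d_grid, q_grid)) *
    matrix(f2, nrow = length(d_grid), ncol = length(q_grid), byrow = TRUE)
  structure(list(d_grid = d_grid, q_grid = q_grid, radius = radius,
                 values = values),
            class = "basis_matrix")
}

#' Coarse bead model of a labeled construct
#'
#' Beads are point scatterers (one per base pair on the helix axis) with
#' unit weight; gold labels are spheres whose weight is multiplied by the
#' sphere form amplitude at radius `gold_radius`. The default weight contrast
#' (gold 25 : DNA 1) makes the gold-gold term dominate, as XSI requires.
#'
#' @param coordinates Numeric matrix (n x 3) of bead positions (Angstrom).
#' @param weights Numeric scattering weights per bead.
#' @param is_gold Logical vector flagging gold beads (0, 1 or 2 of them).
#' @param gold_radius Gold sphere radius (Angstrom).
#' @return Object of class `bead_model`.
#' @export
bead_model <- function(coordinates, weights = NULL, is_gold = NULL,
                       gold_radius = 7) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3L) stop("coordinates must be n x 3")
  n <- nrow(coordinates)
  if (n < 1L) stop("need at least one bead")
  if (any(!is.finite(coordinates))) stop("non-finite coordinates")
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(is_gold)) is_gold <- rep(FALSE, n)
  if (length(weights) != n || length(is_gold) != n)
    stop("weights/is_gold length mismatch")
  if (sum(is_gold) > 2L) stop("at most two gold labels supported")
  structure(list(coordinates = coordinates, weights = as.numeric(weights),
                 is_gold = as.logical(is_gold), gold_radius = gold_radius),
            class = "bead_model")
}

#' Debye scattering intensity of a bead model
#'
#' Orientation-averaged intensity
#' \deqn{I(q) = \sum_i \sum_j f_i(q) f_j(q)\, \mathrm{sinc}(q r_{ij}),}
#' with \eqn{f_i(q)} the bead weight, multiplied by the sphere form amplitude
#' for gold beads, and the diagonal term equal to \eqn{f_i^2}. Coincident
#' beads are handled by the \eqn{r \to 0} limit of the sinc. The result is
#' invariant under rigid rotation and translation of the coordinates.
#'
#' @param model A [bead_model()].
#' @param q_grid Momentum transfer values (1/Angstrom).
#' @return A [scattering_profile()] with role `"derived"` and a nominal
#'   (positive, negligible) sigma; callers attach real uncertainties.
#' @export
debye_intensity <- function(model, q_grid = default_q_grid()) {
  stopifnot(inherits(model, "bead_model"))
  xyz <- model$coordinates
  n <- nrow(xyz)
  ff <- sphere_form_amplitude(q_grid, model$gold_radius)   # nq
  # f matrix: nq x n, q-dependent only for gold beads
  fmat <- matrix(model$weights, nrow = length(q_grid), ncol = n, byrow = TRUE)
  if (any(model$is_gold))
    fmat[, model$is_gold] <- fmat[, model$is_gold, drop = FALSE] * ff
  diag_term <- rowSums(fmat^2)                             # nq
  if (n == 1L) {
    inten <- diag_term
  } else {
    ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    d <- sqrt(rowSums((xyz[ij[, 1], , drop = FALSE] -
                         xyz[ij[, 2], , drop = FALSE])^2))  # npairs
    sincs <- sinc(outer(q_grid, d))                         # nq x npairs
    wpair <- fmat[, ij[, 1], drop = FALSE] * fmat[, ij[, 2], drop = FALSE]
    inten <- diag_term + 2 * rowSums(wpair * sincs)
  }
  scattering_profile(q_grid, inten,
                     sigma = rep(1e-12 * max(1, abs(inten)), length(q_grid)),
                     label = "derived")
}
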