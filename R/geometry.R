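#' Parametric four-way junction geometry
#'
#' Describes a junction conformer by the directions of its four helical arms
#' (named X, B, H, R in cyclic order, so X-H and B-R are opposite pairs) and
#' the axial dimensions that set where a 3'-terminal gold label sits: base
#' pairs per arm, helical rise, a central gap (open conformations only) and
#' an effective axial gold offset beyond the terminal base pair. The default
#' axial offset of 10.2 Angstrom is calibrated so that a continuous B-form
#' helix of 22 bp with terminal labels predicts a 93 Angstrom gold-gold
#' distance; a small salt-dependent shift (about +2 Angstrom at intermediate
#' salt) can be added via `salt_offset_shift`.
#'
#' @param arm_directions 4 x 3 numeric matrix of unit vectors with rownames
#'   `X, B, H, R` (normalized on input).
#' @param bp_per_arm Base pairs per arm (default 11: four 22-mer strands).
#' @param rise Helical rise per bp (Angstrom, default 3.3).
#' @param center_gap Central gap between opposing arm ends (Angstrom;
#'   16.3 for open conformations, 0 for stacked).
#' @param axial_offset Effective axial gold offset per label (Angstrom).
#' @param salt_offset_shift Additional offset at elevated salt (Angstrom).
#' @return Object of class `junction_geometry`.
#' @export
junction_geometry <- function(arm_directions,
                              bp_per_arm = 11, rise = 3.3,
                              center_gap = 0, axial_offset = 10.2,
                              salt_offset_shift = 0) {
  arm_directions <- as.matrix(arm_directions)
  if (!identical(dim(arm_directions), c(4L, 3L)))
    stop("arm_directions must be a 4 x 3 matrix")
  if (is.null(rownames(arm_directions)))
    rownames(arm_directions) <- c("X", "B", "H", "R")
  if (!setequal(rownames(arm_directions), c("X", "B", "H", "R")))
    stop("arm names must be X, B, H, R")
  nrm <- sqrt(rowSums(arm_directions^2))
  if (any(nrm <= 0)) stop("zero arm direction")
  arm_directions <- arm_directions / nrm
  if (bp_per_arm < 1) stop("bp_per_arm must be >= 1")
  if (rise <= 0) stop("rise must be positive")
  structure(list(arm_directions = arm_directions, bp_per_arm = bp_per_arm,
                 rise = rise, center_gap = center_gap,
                 axial_offset = axial_offset,
                 salt_offset_shift = salt_offset_shift),
            class = "junction_geometry")
}

#' Junction geometry presets
#'
#' * `planar`: square-planar open cross (arms at 90 deg in a plane,
#'   16.3 Angstrom central gap taken from a protein-bound planar crystal
#'   structure).
#' * `pyramid`: square pyramid; four arms on a cone of apex half-angle
#'   `half_angle` (degrees) about the +z axis, 90 deg apart in azimuth;
#'   `half_angle = 90` reduces to `planar`.
#' * `tetrahedral`: arms along regular tetrahedron vertices (pairwise
#'   cos = -1/3), 16.3 Angstrom gap.
#' * `stacked`: coaxially stacked X-structure, zero gap; the X-H pair is
#'   drawn collinear and the B-R pair collinear along a second axis tilted
#'   by the inter-duplex angle `ida` (degrees, default 60).
#'
#' @param name One of `"planar"`, `"pyramid"`, `"tetrahedral"`, `"stacked"`.
#' @param half_angle Apex half-angle in degrees (pyramid only).
#' @param ida Inter-duplex angle in degrees (stacked only).
#' @param ... Passed to [junction_geometry()] (e.g. `salt_offset_shift`).
#' @return A `junction_geometry`.
#' @export
junction_preset <- function(name = c("planar", "pyramid", "tetrahedral",
                                     "stacked"),
                            half_angle = 70, ida = 60, ...) {
  name <- match.arg(name)
  dirs <- switch(name,
    planar = pyramid_directions(90),
    pyramid = pyramid_directions(half_angle),
    tetrahedral = {
      m <- rbind(X = c(1, 1, 1), B = c(1, -1, -1),
                 H = c(-1, 1, -1), R = c(-1, -1, 1)) / sqrt(3)
      m
    },
    stacked = {
      a <- ida * pi / 180
      # helix 1: X and H collinear along z; helix 2: B and R along an axis
      # at angle `ida` from helix 1
      rbind(X = c(0, 0, 1), H = c(0, 0, -1),
            B = c(sin(a), 0, cos(a)), R = -c(sin(a), 0, cos(a)))
    })
  gap <- if (name == "stacked") 0 else 16.3
  junction_geometry(dirs, center_gap = gap, ...)
}

pyramid_directions <- function(half_angle) {
  a <- half_angle * pi / 180
  phi <- c(X = 0, B = pi / 2, H = pi, R = 3 * pi / 2)
  m <- cbind(sin(a) * cos(phi), sin(a) * sin(phi), rep(cos(a), 4))
  rownames(m) <- names(phi)
  m
}

arm_reach <- function(geom) {
  geom$center_gap / 2 + geom$bp_per_arm * geom$rise +
    geom$axial_offset + geom$salt_offset_shift
}

#' Gold label positions of a junction geometry
#'
#' Each label sits at distance
#' `center_gap/2 + bp_per_arm * rise + axial_offset + salt_offset_shift`
#' from the junction center along its arm direction.
#'
#' @param geom A [junction_geometry()].
#' @return 4 x 3 matrix of positions (Angstrom), rownames `X, B, H, R`.
#' @export
label_positions <- function(geom) {
  stopifnot(inherits(geom, "junction_geometry"))
  geom$arm_directions * arm_reach(geom)
}

#' Predicted gold-gold distance for a label pair
#'
#' @param geom A [junction_geometry()].
#' @param pair Two arm names, as a length-2 vector (`c("B", "R")`) or a
#'   2-character string (`"BR"`).
#' @return Euclidean distance (Angstrom) between the two label positions.
#' @export
pair_distance <- function(geom, pair) {
  pos <- label_positions(geom)
  pair <- parse_pair(pair)
  if (!all(pair %in% rownames(pos)))
    stop("unknown arm name in pair: ", paste(pair, collapse = ""))
  sqrt(sum((pos[pair[1], ] - pos[pair[2], ])^2))
}

parse_pair <- function(pair) {
  if (length(pair) == 1L) pair <- strsplit(pair, "")[[1]]
  if (length(pair) != 2L) stop("a pair is two arm names")
  pair
}

#' Predicted distances for all six label pairs
#'
#' @param geom A [junction_geometry()].
#' @return Named numeric vector over pairs `XB, XH, XR, BH, BR, HR`.
#' @export
predict_distances <- function(geom) {
  pairs <- c("XB", "XH", "XR", "BH", "BR", "HR")
  vapply(pairs, function(p) pair_distance(geom, p), numeric(1))
}

#' End-to-end distance of a continuous stacked helix
#'
#' For a coaxially stacked pair of arms with no central gap the two terminal
#' labels are `2 * bp_per_arm * rise + 2 * (axial_offset + salt_offset_shift)`
#' apart; with the defaults this is 93.0 Angstrom, the continuous B-form
#' prediction for a 22 bp helix with terminal gold labels.
#'
#' @param geom A [junction_geometry()].
#' @return Distance (Angstrom).
#' @export
stacked_helix_distance <- function(geom = junction_preset("stacked")) {
  2 * geom$bp_per_arm * geom$rise +
    2 * (geom$axial_offset + geom$salt_offset_shift)
}

#' Inter-duplex angle implied by the short-pair distance of a stacked X
#'
#' Inverts `d = 2 L' sin(IDA/2)` with `L' = bp_per_arm * rise + axial_offset
#' (+ salt shift)`, the label reach of a stacked arm with no central gap.
#'
#' @param d_short Measured short-pair gold-gold distance (Angstrom).
#' @param geom A [junction_geometry()] supplying the arm dimensions.
#' @return Inter-duplex angle in degrees.
#' @export
ida_from_short_distance <- function(d_short,
                                    geom = junction_preset("stacked")) {
  L <- geom$bp_per_arm * geom$rise + geom$axial_offset +
    geom$salt_offset_shift
  if (d_short <= 0 || d_short > 2 * L)
    stop(sprintf("distance %g outside invertible range (0, %g]", d_short,
                 2 * L))
  2 * asin(d_short / (2 * L)) * 180 / pi
}

#' Fit arm directions of a model family to measured pair distances
#'
#' Least-squares fit of predicted gold-gold distances to measured ones over
#' the free parameters of a geometric family:
#' * `planar` - no free parameters (square-planar cross);
#' * `pyramid` - apex half-angle of a regular square pyramid;
#' * `tetrahedral` - no free parameters;
#' * `free` - all four arm directions (8 spherical angles; distances are
#'   rotation-invariant, so the global orientation is irrelevant).
#'
#' The `free` fit uses deterministic multi-start local optimization (fixed
#' internal seed) seeded from the structured presets plus random directions.
#' Families are nested (planar is a pyramid at 90 deg; any pyramid is a
#' special free geometry), so RMSD is non-increasing from `planar` through
#' `pyramid` to `free`.
#'
#' @param measured Named numeric vector of measured distances (Angstrom),
#'   names being pairs such as `"BR"`. At least two pairs.
#' @param geom Base [junction_geometry()] supplying arm dimensions
#'   (bp, rise, gap, offsets).
#' @param model_family One of `"planar"`, `"pyramid"`, `"tetrahedral"`,
#'   `"free"`.
#' @param n_starts Random multi-starts for the `free` family.
#' @return List with `family`, fitted `geometry`, `rmsd` (Angstrom),
#'   `predicted` (named vector over the measured pairs), `parameters`
#'   (fitted family parameters) and `overparameterized` (flag set when the
#'   `free` family is fitted to fewer than 3 distances).
#' @export
fit_arm_directions <- function(measured, geom = junction_preset("planar"),
                               model_family = c("planar", "pyramid",
                                                "tetrahedral", "free"),
                               n_starts = 24L) {
  model_family <- match.arg(model_family)
  if (length(measured) < 2L) stop("need at least two measured pairs")
  if (is.null(names(measured))) stop("measured distances must be named")
  pairs <- lapply(names(measured), parse_pair)
  meas <- as.numeric(measured)

  rmsd_for <- function(g) {
    pred <- vapply(pairs, function(p)
      sqrt(sum((label_positions(g)[p[1], ] - label_positions(g)[p[2], ])^2)),
      numeric(1))
    sqrt(mean((pred - meas)^2))
  }
  geom_with_dirs <- function(dirs)
    junction_geometry(dirs, bp_per_arm = geom$bp_per_arm, rise = geom$rise,
                      center_gap = geom$center_gap,
                      axial_offset = geom$axial_offset,
                      salt_offset_shift = geom$salt_offset_shift)

  overpar <- FALSE
  if (model_family == "planar") {
    g <- geom_with_dirs(pyramid_directions(90))
    pars <- list(half_angle = 90)
  } else if (model_family == "tetrahedral") {
    g <- geom_with_dirs(junction_preset("tetrahedral")$arm_directions)
    pars <- list()
  } else if (model_family == "pyramid") {
    obj <- function(a) rmsd_for(geom_with_dirs(pyramid_directions(a)))
    opt <- stats::optimize(obj, interval = c(1, 90))
    # the planar end point is a valid pyramid; keep whichever is better
    a <- if (obj(90) < opt$objective) 90 else opt$minimum
    g <- geom_with_dirs(pyramid_directions(a))
    pars <- list(half_angle = a)
  } else { # free
    overpar <- length(measured) < 3L
    dirs_from_par <- function(th) {
      m <- cbind(sin(th[1:4]) * cos(th[5:8]), sin(th[1:4]) * sin(th[5:8]),
                 cos(th[1:4]))
      rownames(m) <- c("X", "B", "H", "R")
      m
    }
    obj <- function(th) rmsd_for(geom_with_dirs(dirs_from_par(th)))
    par_from_dirs <- function(m) {
      m <- m / sqrt(rowSums(m^2))
      c(acos(pmin(1, pmax(-1, m[, 3]))), atan2(m[, 2], m[, 1]))
    }
    # seed from the structured families (incl. the fitted pyramid) so the
    # enlarged family can never fit worse than the nested ones
    a_best <- stats::optimize(function(a)
      rmsd_for(geom_with_dirs(pyramid_directions(a))), c(1, 90))$minimum
    starts <- list(par_from_dirs(junction_preset("tetrahedral")$arm_directions),
                   par_from_dirs(pyramid_directions(90)),
                   par_from_dirs(pyramid_directions(a_best)))
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(20L)
    for (i in seq_len(n_starts))
      starts[[length(starts) + 1L]] <- c(stats::runif(4, 0, pi),
                                         stats::runif(4, -pi, pi))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    best <- NULL
    for (s in starts) {
      fit <- stats::optim(s, obj, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    g <- geom_with_dirs(dirs_from_par(best$par))
    pars <- list(angles = best$par)
    if (overpar)
      warning("free-direction fit to fewer than 3 distances is ",
              "over-parameterized; RMSD near 0 is not informative")
  }
  pred <- vapply(pairs, function(p)
    sqrt(sum((label_positions(g)[p[1], ] - label_positions(g)[p[2], ])^2)),
    numeric(1))
  names(pred) <- names(measured)
  list(family = model_family, geometry = g, rmsd = rmsd_for(g),
       predicted = pred, parameters = pars, overparameterized = overpar)
}

#' Compare all geometry families against measured distances
#'
#' @inheritParams fit_arm_directions
#' @return data.frame with one row per family (`planar`, `pyramid`,
#'   `tetrahedral`, `free`) and its fit RMSD (Angstrom).
#' @export
compare_geometry_models <- function(measured,
                                    geom = junction_preset("planar")) {
  fams <- c("planar", "pyramid", "tetrahedral", "free")
  fits <- lapply(fams, function(f)
    suppressWarnings(fit_arm_directions(measured, geom, f)))
  data.frame(family = fams,
             rmsd = vapply(fits, `[[`, numeric(1), "rmsd"),
             overparameterized = vapply(fits, `[[`, logical(1),
                                        "overparameterized"))
}
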