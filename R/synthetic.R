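#' XSI simulation scenario
#'
#' Describes the conformational ensemble and noise model from which a full
#' six-profile bundle is generated: a mixture of junction states, each with a
#' characteristic gold-gold distance and population weight, plus distance
#' jitter (conformational breathing), counting-noise level and exposure
#' count.
#'
#' @param label_pair Label-pair name (`"BH"`, `"HR"`, `"BR"`, `"RX"`).
#' @param states List of states, each a list with `distance` (Angstrom),
#'   `weight` (probability) and optionally `center_gap` (Angstrom; 0 for
#'   stacked conformers, 16.3 for open ones).
#' @param jitter Distance jitter s.d. per conformer (Angstrom, default 5).
#' @param noise Relative noise level at the low-q anchor (default 0.01).
#' @param exposures Number of averaged exposures (default 10, mirroring the
#'   10 x 3 s exposure protocol).
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @param condition Free-text salt description.
#' @return Object of class `xsi_scenario`.
#' @export
xsi_scenario <- function(label_pair, states, jitter = 5, noise = 0.01,
                         exposures = 10L, seed = NULL, condition = "") {
  if (length(states) == 0L) stop("scenario needs at least one state")
  w <- vapply(states, function(s) s$weight, numeric(1))
  if (any(w < 0)) stop("state weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9) stop("state weights must sum to 1")
  if (jitter < 0) stop("jitter must be non-negative")
  if (noise < 0) stop("noise must be non-negative")
  if (exposures < 1) stop("need at least one exposure")
  states <- lapply(states, function(s) {
    if (is.null(s$center_gap)) s$center_gap <- 0
    s
  })
  structure(list(label_pair = label_pair, states = states, jitter = jitter,
                 noise = noise, exposures = as.integer(exposures),
                 seed = seed, condition = condition),
            class = "xsi_scenario")
}

#' Named scenario presets
#'
#' Ensembles parameterized from the measured junction distance
#' distributions: at high divalent salt the junction interconverts between
#' the stacked conformers isoII (84%) and isoI (16%); at low ionic strength
#' it sits in a single open state. Peak positions (Angstrom):
#'
#' | preset | states (distance, weight) | condition |
#' |---|---|---|
#' | `high_Mg_BH` | 54 (0.84), 89 (0.16) | 10 mM MgCl2 |
#' | `high_Mg_HR` | 89 (0.84), 57 (0.16) | 10 mM MgCl2 |
#' | `high_Mg_BR` | 86 (0.84), 90 (0.16) | 10 mM MgCl2 |
#' | `intermediate_Mg_BH` | 61 (0.84), 84 (0.16) | 150 uM MgCl2 |
#' | `low_salt_BR` | 93 (1.0), open | 30 mM Tris only |
#' | `low_salt_HR` | 90 (1.0), open | 30 mM Tris only |
#' | `low_salt_RX` | 87 (1.0), open | 30 mM Tris only |
#'
#' The two BR peaks at high salt overlap by construction (their separation
#' is below the 5 Angstrom ensemble width); the measurement resolves them
#' only as a broadened single feature, which is the behavior the preset
#' encodes.
#'
#' @param name Preset name.
#' @param seed Seed stored on the scenario.
#' @param ... Overrides passed to [xsi_scenario()] (`jitter`, `noise`,
#'   `exposures`).
#' @return An `xsi_scenario`.
#' @export
scenario_preset <- function(name, seed = NULL, ...) {
  tab <- list(
    high_Mg_BH = list(pair = "BH", d = c(54, 89), w = c(0.84, 0.16),
                      gap = c(0, 0), cond = "10 mM MgCl2"),
    high_Mg_HR = list(pair = "HR", d = c(89, 57), w = c(0.84, 0.16),
                      gap = c(0, 0), cond = "10 mM MgCl2"),
    high_Mg_BR = list(pair = "BR", d = c(86, 90), w = c(0.84, 0.16),
                      gap = c(0, 0), cond = "10 mM MgCl2"),
    intermediate_Mg_BH = list(pair = "BH", d = c(61, 84), w = c(0.84, 0.16),
                              gap = c(0, 0), cond = "150 uM MgCl2"),
    low_salt_BR = list(pair = "BR", d = 93, w = 1, gap = 16.3,
                       cond = "30 mM Tris only"),
    low_salt_HR = list(pair = "HR", d = 90, w = 1, gap = 16.3,
                       cond = "30 mM Tris only"),
    low_salt_RX = list(pair = "RX", d = 87, w = 1, gap = 16.3,
                       cond = "30 mM Tris only"))
  if (!name %in% names(tab))
    stop("unknown scenario preset: ", name, " (available: ",
         paste(names(tab), collapse = ", "), ")")
  p <- tab[[name]]
  states <- mapply(function(d, w, g) list(distance = d, weight = w,
                                          center_gap = g),
                   p$d, p$w, p$gap, SIMPLIFY = FALSE)
  xsi_scenario(p$pair, states, seed = seed, condition = p$cond, ...)
}

# Bead coordinates of one junction conformer with the two labeled arms
# opened to the target gold-gold distance. The two labeled arms lie in the
# xy-plane at +/- theta/2 about x; the unlabeled arms point along +/- z.
# If the target exceeds the collinear reach, the labeled arms are stretched
# axially (breathing) instead.
conformer_beads <- function(d_label, bp_per_arm = 11, rise = 3.3,
                            center_gap = 0, axial_offset = 10.2) {
  reach <- center_gap / 2 + bp_per_arm * rise + axial_offset
  stretch <- 1
  if (d_label >= 2 * reach) {
    stretch <- d_label / (2 * reach)
    theta <- pi
  } else {
    theta <- 2 * asin(d_label / (2 * reach))
  }
  u1 <- c(cos(theta / 2), sin(theta / 2), 0)
  u2 <- c(cos(theta / 2), -sin(theta / 2), 0)
  u3 <- c(0, 0, 1)
  u4 <- c(0, 0, -1)
  radii <- center_gap / 2 + (seq_len(bp_per_arm) - 0.5) * rise
  dna <- rbind(outer(radii, u1), outer(radii, u2),
               outer(radii, u3), outer(radii, u4))
  gold <- rbind(reach * u1, reach * u2)
  list(dna = dna * stretch, gold = gold * stretch)
}

construct_model <- function(beads, golds, gold_weight = 25,
                            gold_radius = 7) {
  g <- beads$gold[golds, , drop = FALSE]
  coords <- rbind(beads$dna, g)
  n_dna <- nrow(beads$dna)
  bead_model(coords,
             weights = c(rep(1, n_dna), rep(gold_weight, nrow(g))),
             is_gold = c(rep(FALSE, n_dna), rep(TRUE, nrow(g))),
             gold_radius = gold_radius)
}

#' Generate a synthetic six-profile XSI bundle
#'
#' Samples `n_conformers` junction conformers per state (the scenario's
#' distance jitter is split evenly, in variance, between an angular jitter
#' of the labeled-arm opening angle and axial breathing of the arms), builds
#' coarse bead models for the four constructs AB (both golds), A and B (one
#' gold each) and U (no gold) from the *same* conformer sample, and averages
#' their Debye intensities. The free-gold profile Au is two uncorrelated
#' 7 Angstrom spheres; the buffer Buf is a flat baseline, which is also
#' added to the five sample profiles. Gaussian counting noise with
#' `sigma(q) = noise * sqrt(I(q) I(q_1))` is added per exposure and the
#' exposures averaged, so the reported uncertainty is
#' `sigma(q) / sqrt(exposures)`.
#'
#' Because all four constructs share one conformer ensemble, the molecule
#' and molecule-gold cross terms cancel exactly in the interference
#' combination `AB + U - A - B` of the noiseless bundle.
#'
#' @param scenario An [xsi_scenario()] or preset name.
#' @param q_grid Momentum-transfer grid (1/Angstrom).
#' @param n_conformers Conformers sampled per state (default 200).
#' @param gold_weight Gold:DNA scattering weight contrast (default 25).
#' @param bp_per_arm,rise,axial_offset Junction arm dimensions (Angstrom).
#' @param buffer_level Flat buffer intensity; default 10% of the unlabeled
#'   construct's intensity at the first q point.
#' @param seed Overrides the scenario's seed.
#' @return A [profile_bundle()].
#' @export
generate_xsi_bundle <- function(scenario, q_grid = default_q_grid(),
                                n_conformers = 200L, gold_weight = 25,
                                bp_per_arm = 11, rise = 3.3,
                                axial_offset = 10.2,
                                buffer_level = NULL, seed = NULL) {
  if (is.character(scenario)) scenario <- scenario_preset(scenario)
  stopifnot(inherits(scenario, "xsi_scenario"))
  seed <- if (!is.null(seed)) seed else scenario$seed
  if (!is.null(seed)) set.seed(seed)
  nq <- length(q_grid)
  roles4 <- c("AB", "A", "B", "U")
  acc <- stats::setNames(rep(list(rep(0, nq)), 4), roles4)
  sd_component <- scenario$jitter / sqrt(2)
  for (s in scenario$states) {
    state_acc <- stats::setNames(rep(list(rep(0, nq)), 4), roles4)
    for (i in seq_len(n_conformers)) {
      d_ang <- if (scenario$jitter > 0) stats::rnorm(1, 0, sd_component) else 0
      ax <- if (scenario$jitter > 0)
        stats::rnorm(1, 0, sd_component / s$distance) else 0
      d_geom <- max(2, s$distance + d_ang)
      beads <- conformer_beads(d_geom, bp_per_arm = bp_per_arm, rise = rise,
                               center_gap = s$center_gap,
                               axial_offset = axial_offset)
      beads$dna <- beads$dna * (1 + ax)
      beads$gold <- beads$gold * (1 + ax)
      models <- list(AB = construct_model(beads, c(1, 2), gold_weight),
                     A = construct_model(beads, 1, gold_weight),
                     B = construct_model(beads, 2, gold_weight),
                     U = construct_model(beads, integer(0), gold_weight))
      for (role in roles4)
        state_acc[[role]] <- state_acc[[role]] +
          debye_intensity(models[[role]], q_grid)$intensity
    }
    for (role in roles4)
      acc[[role]] <- acc[[role]] + s$weight * state_acc[[role]] / n_conformers
  }
  # free gold: two uncorrelated spheres of the same weight
  f2 <- (gold_weight * sphere_form_amplitude(q_grid))^2
  acc$Au <- 2 * f2
  if (is.null(buffer_level)) buffer_level <- 0.1 * acc$U[1]
  acc$Buf <- rep(buffer_level, nq)
  noiseless <- lapply(acc[c("AB", "A", "B", "U", "Au")],
                      function(I) I + buffer_level)
  noiseless$Buf <- acc$Buf

  profiles <- lapply(names(noiseless), function(role) {
    I <- noiseless[[role]]
    if (scenario$noise > 0) {
      sig_exp <- scenario$noise * sqrt(pmax(I * I[1], 0))
      sig_exp <- pmax(sig_exp, 1e-12 * max(abs(I)))
      meas <- rowMeans(vapply(seq_len(scenario$exposures), function(e)
        I + stats::rnorm(nq, 0, sig_exp), numeric(nq)))
      scattering_profile(q_grid, meas, sig_exp / sqrt(scenario$exposures),
                         label = role)
    } else {
      scattering_profile(q_grid, I, rep(1e-6 * max(abs(I)), nq),
                         label = role)
    }
  })
  names(profiles) <- names(noiseless)
  profile_bundle(profiles, condition = scenario$condition,
                 label_pair = scenario$label_pair)
}

#' Two-state FRET kinetic model
#'
#' @param E_low,E_high FRET efficiencies of the two states (isoI is the
#'   low-FRET state, isoII the high-FRET state).
#' @param k12 Rate constant isoI -> isoII (1/s).
#' @param k21 Rate constant isoII -> isoI (1/s).
#' @return Object of class `fret_state_model`.
#' @export
fret_state_model <- function(E_low = 0.14, E_high = 0.58,
                             k12 = 45.6, k21 = 7.9) {
  if (E_low < 0 || E_low > 1 || E_high < 0 || E_high > 1)
    stop("FRET efficiencies must lie in [0, 1]")
  if (k12 <= 0 || k21 <= 0) stop("rates must be positive")
  structure(list(E_low = E_low, E_high = E_high, k12 = k12, k21 = k21),
            class = "fret_state_model")
}

#' Simulate a two-state smFRET intensity trace
#'
#' Simulates a continuous-time telegraph path with exponential dwell times
#' at the model rates (initial state drawn from the stationary
#' distribution), integrates the state occupancy over each camera frame, and
#' emits donor/acceptor intensities with fixed total intensity and
#' independent Gaussian noise per channel. The latent path is returned for
#' validation of idealization methods.
#'
#' @param model A [fret_state_model()].
#' @param duration Trace length (s).
#' @param fps Frame rate (frames/s, default 306).
#' @param total_intensity Donor + acceptor signal per frame (a.u.).
#' @param noise_sd Per-channel Gaussian noise s.d. (a.u.).
#' @param seed Optional integer seed.
#' @return Object of class `fret_trace`: list with `time`, `donor`,
#'   `acceptor`, `fps`, `true_states` (1 = isoI/low, 2 = isoII/high, frame
#'   majority), `true_occupancy` (fraction of each frame in state 2),
#'   `true_path` (the continuous telegraph path as start/end/state, the last
#'   dwell truncated at `duration`) and the generating `model`.
#' @export
generate_fret_trace <- function(model, duration, fps = 306,
                                total_intensity = 1000, noise_sd = 80,
                                seed = NULL) {
  stopifnot(inherits(model, "fret_state_model"))
  if (duration <= 0) stop("duration must be positive")
  if (fps <= 0) stop("fps must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  p2 <- model$k12 / (model$k12 + model$k21)
  state <- if (stats::runif(1) < p2) 2L else 1L
  t0 <- 0
  starts <- numeric(0); ends <- numeric(0); st <- integer(0)
  while (t0 < duration) {
    rate <- if (state == 1L) model$k12 else model$k21
    dwell <- stats::rexp(1, rate)
    starts <- c(starts, t0); ends <- c(ends, min(t0 + dwell, duration))
    st <- c(st, state)
    t0 <- t0 + dwell
    state <- 3L - state
  }
  n_frames <- floor(duration * fps)
  edges <- seq_len(n_frames + 1) / fps - 1 / fps
  occ2 <- rep(0, n_frames)
  for (k in which(st == 2L)) {
    lo <- pmin(pmax(starts[k], edges[-length(edges)]), edges[-1])
    hi <- pmin(pmax(ends[k], edges[-length(edges)]), edges[-1])
    occ2 <- occ2 + (hi - lo) * fps
  }
  E_frame <- model$E_low + occ2 * (model$E_high - model$E_low)
  acceptor <- total_intensity * E_frame
  donor <- total_intensity * (1 - E_frame)
  if (noise_sd > 0) {
    acceptor <- acceptor + stats::rnorm(n_frames, 0, noise_sd)
    donor <- donor + stats::rnorm(n_frames, 0, noise_sd)
  }
  structure(list(time = (seq_len(n_frames) - 0.5) / fps,
                 donor = donor, acceptor = acceptor, fps = fps,
                 true_states = ifelse(occ2 > 0.5, 2L, 1L),
                 true_occupancy = occ2,
                 true_path = data.frame(start = starts, end = ends,
                                        state = st),
                 model = model),
            class = "fret_trace")
}

#' @export
print.fret_trace <- function(x, ...) {
  cat(sprintf("<fret_trace> %d frames at %g fps (%.3g s)\n",
              length(x$time), x$fps, length(x$time) / x$fps))
  invisible(x)
}

#' Write a FRET trace as CSV (time, donor, acceptor)
#'
#' @param trace A [generate_fret_trace()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fret_trace <- function(trace, path) {
  utils::write.csv(data.frame(time = trace$time, donor = trace$donor,
                              acceptor = trace$acceptor),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a FRET trace CSV written by [write_fret_trace()]
#'
#' @param path CSV with columns time, donor, acceptor (uniform sampling).
#' @return A `fret_trace` (without latent path).
#' @export
read_fret_trace <- function(path) {
  df <- utils::read.csv(path)
  dt <- diff(df$time)
  if (any(abs(dt - dt[1]) > 1e-9 * dt[1]))
    stop("non-uniform frame times")
  structure(list(time = df$time, donor = df$donor, acceptor = df$acceptor,
                 fps = 1 / dt[1], true_states = NULL, true_occupancy = NULL,
                 model = NULL),
            class = "fret_trace")
}
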