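#' Scattering profile
#'
#' A one-dimensional small-angle scattering curve: intensity \eqn{I(q)} with
#' per-point uncertainties on an ascending momentum-transfer grid. This is the
#' container for each of the six measured samples of an XSI experiment
#' (doubly labeled AB, singly labeled A and B, unlabeled U, free gold Au,
#' buffer Buf) and for derived curves such as the gold-gold interference
#' pattern.
#'
#' @param q_grid Numeric vector of momentum-transfer values (1/Angstrom),
#'   strictly increasing and positive.
#' @param intensity Numeric vector of intensities (arbitrary units), same
#'   length as `q_grid`. May be negative for derived interference curves.
#' @param sigma Numeric vector of per-point uncertainties, all positive.
#' @param label Role tag: one of `"AB"`, `"A"`, `"B"`, `"U"`, `"Au"`,
#'   `"Buf"`, `"derived"`.
#'
#' @return An object of class `scattering_profile`: a list with elements
#'   `q_grid`, `intensity`, `sigma`, `label`.
#' @export
scattering_profile <- function(q_grid, intensity, sigma,
                               label = "derived") {
  q_grid <- as.numeric(q_grid)
  intensity <- as.numeric(intensity)
  sigma <- as.numeric(sigma)
  if (length(q_grid) == 0L)
    stop("empty q grid")
  if (length(intensity) != length(q_grid) || length(sigma) != length(q_grid))
    stop("q_grid, intensity and sigma must have equal length")
  if (any(!is.finite(q_grid)) || any(!is.finite(intensity)) ||
      any(!is.finite(sigma)))
    stop("non-finite values in profile")
  if (any(q_grid <= 0))
    stop("all q values must be positive")
  if (any(diff(q_grid) <= 0))
    stop("q grid must be strictly increasing")
  if (any(sigma <= 0))
    stop("all sigma values must be positive")
  label <- match.arg(label, c("AB", "A", "B", "U", "Au", "Buf", "derived"))
  structure(list(q_grid = q_grid, intensity = intensity, sigma = sigma,
                 label = label),
            class = "scattering_profile")
}

#' @export
print.scattering_profile <- function(x, ...) {
  cat(sprintf("<scattering_profile> role %s, %d points, q = [%.4g, %.4g] 1/A\n",
              x$label, length(x$q_grid), min(x$q_grid), max(x$q_grid)))
  invisible(x)
}

#' Read a scattering profile from a whitespace-separated text file
#'
#' Parses the common beamline `.dat` dialect: three (or more) whitespace
#' separated numeric columns `q  I  sigma`; lines starting with `#` are
#' comments; columns beyond the third are ignored. Rows containing non-finite
#' values are dropped with a message reporting the count.
#'
#' @param path Path to an existing file.
#' @param label Role tag recorded on the returned profile (default
#'   `"derived"`; bundle loading assigns proper roles).
#'
#' @return A [scattering_profile()].
#' @export
read_profile <- function(path, label = "derived") {
  if (!file.exists(path))
    stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  body <- lines[keep]
  lineno <- which(keep)
  if (length(body) == 0L)
    stop("no data lines in ", path)
  fields <- strsplit(trimws(body), "\\s+")
  ncol <- vapply(fields, length, integer(1))
  bad <- which(ncol < 3L)
  if (length(bad) > 0L)
    stop(sprintf("parse error at line %d of %s: expected >= 3 columns, got %d",
                 lineno[bad[1]], path, ncol[bad[1]]))
  num <- lapply(fields, function(f) suppressWarnings(as.numeric(f[1:3])))
  # a token that fails numeric conversion is NA-but-not-NaN; "nan"/"inf"
  # convert cleanly and are handled below as non-finite rows
  conv <- vapply(num, function(v) any(is.na(v) & !is.nan(v)), logical(1))
  if (any(conv)) {
    i <- which(conv)[1]
    stop(sprintf("parse error at line %d of %s: non-numeric field",
                 lineno[i], path))
  }
  m <- do.call(rbind, num)
  finite <- apply(is.finite(m), 1, all)
  if (any(!finite))
    message(sum(!finite), " rows with non-finite values dropped from ", path)
  m <- m[finite, , drop = FALSE]
  scattering_profile(m[, 1], m[, 2], m[, 3], label = label)
}

#' Write a scattering profile to a `.dat` text file
#'
#' Three whitespace-separated columns (`q`, `I`, `sigma`) at 15 significant
#' digits, preceded by `#` comment headers. Values survive a
#' write/read round trip to at least 12 significant digits.
#'
#' @param profile A [scattering_profile()].
#' @param path Output path.
#' @param header Optional character vector of extra header lines (written as
#'   `#` comments).
#' @return Invisibly, `path`.
#' @export
write_profile <- function(profile, path, header = character()) {
  stopifnot(inherits(profile, "scattering_profile"))
  hdr <- c(sprintf("# xsijunction scattering profile, role=%s", profile$label),
           "# q(1/A)  intensity(a.u.)  sigma",
           if (length(header)) paste("#", header))
  rows <- sprintf("%.15g %.15g %.15g",
                  profile$q_grid, profile$intensity, profile$sigma)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

bundle_roles <- c("AB", "A", "B", "U", "Au", "Buf")

#' Six-profile XSI measurement bundle
#'
#' One complete XSI data set for a single label pair and salt condition:
#' the doubly labeled sample (AB), the two singly labeled samples (A, B),
#' the unlabeled macromolecule (U), the free gold nanocrystals (Au) and the
#' buffer (Buf), all recorded on the same q grid.
#'
#' @param profiles Named list of six [scattering_profile()]s with names
#'   `AB, A, B, U, Au, Buf`.
#' @param condition Free-text salt-condition description.
#' @param label_pair Label-pair name (e.g. `"BH"`).
#'
#' @return An object of class `profile_bundle`.
#' @export
profile_bundle <- function(profiles, condition = "", label_pair = "") {
  missing <- setdiff(bundle_roles, names(profiles))
  if (length(missing) > 0L)
    stop("bundle is missing role(s): ", paste(missing, collapse = ", "))
  profiles <- profiles[bundle_roles]
  q0 <- profiles[["AB"]]$q_grid
  for (role in bundle_roles) {
    p <- profiles[[role]]
    stopifnot(inherits(p, "scattering_profile"))
    if (length(p$q_grid) != length(q0) ||
        max(abs(p$q_grid - q0) / pmax(abs(q0), 1e-300)) > 1e-9)
      stop("q-grid mismatch between roles AB and ", role,
           " (profiles must share one grid; no interpolation is performed)")
  }
  structure(list(profiles = profiles, condition = condition,
                 label_pair = label_pair, q_grid = q0),
            class = "profile_bundle")
}

#' @export
print.profile_bundle <- function(x, ...) {
  cat(sprintf("<profile_bundle> pair %s, condition '%s', %d q points\n",
              x$label_pair, x$condition, length(x$q_grid)))
  invisible(x)
}

#' Load a six-profile bundle from a role-to-path manifest
#'
#' @param manifest Named character vector or list mapping each of the six
#'   roles `AB, A, B, U, Au, Buf` to a `.dat` file path.
#' @param condition,label_pair Metadata stored on the bundle.
#'
#' @return A [profile_bundle()]. Grids must agree within 1e-9 relative;
#'   mismatches are an error, never silently interpolated.
#' @export
load_bundle <- function(manifest, condition = "", label_pair = "") {
  manifest <- unlist(manifest)
  missing <- setdiff(bundle_roles, names(manifest))
  if (length(missing) > 0L)
    stop("manifest is missing role(s): ", paste(missing, collapse = ", "))
  profiles <- lapply(bundle_roles, function(role)
    read_profile(manifest[[role]], label = role))
  names(profiles) <- bundle_roles
  profile_bundle(profiles, condition = condition, label_pair = label_pair)
}

#' Write a bundle to a directory of `.dat` files plus a manifest
#'
#' @param bundle A [profile_bundle()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest (named vector role -> path).
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "profile_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(bundle_roles, function(role) {
    p <- file.path(dir, paste0(role, ".dat"))
    write_profile(bundle$profiles[[role]], p,
                  header = c(paste("condition:", bundle$condition),
                             paste("label_pair:", bundle$label_pair)))
    p
  }, character(1))
  manifest <- data.frame(role = bundle_roles, path = basename(paths))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(stats::setNames(paths, bundle_roles))
}

#' Write a distance distribution to CSV
#'
#' Two columns (`distance_A`, `probability`) with `#` comment headers
#' recording the grid step and fit diagnostics. Probabilities round-trip
#' exactly through [read_distribution()].
#'
#' @param dist A `distance_distribution` (see [fit_distribution()]).
#' @param path Output path.
#' @param header Optional extra header lines.
#' @return Invisibly, `path`.
#' @export
write_distribution <- function(dist, path, header = character()) {
  stopifnot(inherits(dist, "distance_distribution"))
  dg <- dist$diagnostics
  num <- function(x) if (is.null(x)) "NA" else sprintf("%.15g", x)
  hdr <- c("# xsijunction distance distribution",
           sprintf("# grid_step_A: %g", dist$d_grid[2] - dist$d_grid[1]),
           sprintf("# amplitude: %s", num(dist$amplitude)),
           sprintf("# chi2_per_point: %s", num(dg$chi2_per_point)),
           sprintf("# entropy: %s", num(dg$entropy)),
           sprintf("# iterations: %s",
                   if (is.null(dg$iterations)) "NA" else dg$iterations),
           sprintf("# infeasible: %s",
                   if (is.null(dg$infeasible)) "NA" else dg$infeasible),
           if (length(header)) paste("#", header),
           "distance_A,probability")
  rows <- sprintf("%.15g,%.15g", dist$d_grid, dist$weights)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a distance distribution written by [write_distribution()]
#'
#' @param path CSV path.
#' @return A `distance_distribution` with diagnostics recovered from the
#'   header.
#' @export
read_distribution <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[grepl("^#", lines)]
  body <- lines[!grepl("^(#|distance_A)", lines) & nzchar(lines)]
  m <- do.call(rbind, lapply(strsplit(body, ","), as.numeric))
  grab <- function(key, cast = as.numeric) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(ln) == 0L) return(NA)
    val <- trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
    if (val == "NA") return(NA)
    cast(val)
  }
  new_distance_distribution(
    d_grid = m[, 1], weights = m[, 2],
    amplitude = grab("amplitude"),
    diagnostics = list(chi2_per_point = grab("chi2_per_point"),
                       entropy = grab("entropy"),
                       iterations = grab("iterations", as.integer),
                       infeasible = grab("infeasible",
                                         function(x) as.logical(x)),
                       chi2 = NA_real_))
}
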