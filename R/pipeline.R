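# 31-bit polynomial rolling hash of a config's deparsed form; used to stamp
# outputs so any result file can be traced to the exact configuration.
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Read a pipeline run configuration
#'
#' A single declarative YAML file with the layout
#' ```yaml
#' conditions:
#'   - name: high_Mg_BH
#'     preset: high_Mg_BH       # or: manifest: {AB: ab.dat, A: ...}
#' inversion: {chi2_target: 1.0, d_min: 5, d_max: 150, d_step: 1}
#' analysis:  {min_area: 0.02, temperature: 298.15}
#' seed: 1
#' ```
#' All fields except `conditions` are optional; defaults are the package
#' defaults.
#'
#' @param path YAML file, or a list with the same structure (returned
#'   as-is after validation).
#' @return A validated config list.
#' @export
read_run_config <- function(path) {
  config <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(config$conditions) || length(config$conditions) == 0L)
    stop("config must list at least one condition")
  for (cond in config$conditions) {
    if (is.null(cond$name)) stop("every condition needs a name")
    if (is.null(cond$preset) && is.null(cond$manifest))
      stop("condition '", cond$name, "' needs a preset or a manifest")
  }
  config
}

#' Run the XSI analysis pipeline over configured conditions
#'
#' For each condition: obtain the six-profile bundle (generated from a
#' scenario preset or loaded from a manifest), buffer-subtract the four
#' macromolecule profiles, extract the gold-gold interference pattern,
#' invert it by maximum entropy, and summarize the resulting distance
#' distribution. All intermediates are written under
#' `outdir/<condition name>/`; each output carries the config hash in its
#' header. An error in one condition is logged and the remaining conditions
#' proceed. Identical config and seed give identical outputs.
#'
#' @param config Path to a YAML config or an equivalent list (see
#'   [read_run_config()]).
#' @param outdir Output directory.
#' @param seed Overrides the config's seed.
#' @param quiet Suppress progress messages.
#' @return Named list per condition: `distribution`, `summary`,
#'   `interference`, or a `condition_error` on failure. Invisible.
#' @export
run_pipeline <- function(config, outdir = "xsi_run", seed = NULL,
                         quiet = FALSE) {
  config <- read_run_config(config)
  if (!is.null(seed)) config$seed <- seed
  base_seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  hash <- config_hash(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  inv <- config$inversion
  d_grid <- default_d_grid(d_min = inv$d_min %||% 5,
                           d_max = inv$d_max %||% 150,
                           step = inv$d_step %||% 1)
  chi2_target <- inv$chi2_target %||% 1.0
  ana <- config$analysis
  min_area <- ana$min_area %||% 0.02
  temperature <- ana$temperature %||% 298.15
  min_height <- ana$min_height %||% 0.5
  n_conformers <- config$simulate$n_conformers %||% 200L

  results <- list()
  for (i in seq_along(config$conditions)) {
    cond <- config$conditions[[i]]
    t0 <- proc.time()[["elapsed"]]
    cond_dir <- file.path(outdir, cond$name)
    dir.create(cond_dir, showWarnings = FALSE, recursive = TRUE)
    results[[cond$name]] <- tryCatch({
      cond_seed <- (base_seed + 7919L * i) %% .Machine$integer.max
      bundle <- if (!is.null(cond$preset)) {
        say("[%s] generating bundle from preset '%s' (seed %d)",
            cond$name, cond$preset, cond_seed)
        generate_xsi_bundle(scenario_preset(cond$preset), seed = cond_seed,
                            n_conformers = n_conformers)
      } else {
        say("[%s] loading bundle from manifest", cond$name)
        load_bundle(cond$manifest, label_pair = cond$pair %||% "")
      }
      sub <- lapply(bundle$profiles[c("AB", "A", "B", "U")],
                    subtract_buffer, buffer = bundle$profiles$Buf)
      pattern <- extract_interference(sub$AB, sub$A, sub$B, sub$U)
      write_profile(as_profile(pattern),
                    file.path(cond_dir, "interference.dat"),
                    header = paste("config_hash:", hash))
      basis <- build_basis_matrix(pattern$q_grid, d_grid)
      dist <- fit_distribution(pattern, basis, chi2_target = chi2_target)
      write_distribution(dist, file.path(cond_dir, "distribution.csv"),
                         header = paste("config_hash:", hash))
      summ <- ensemble_summary(dist, min_area = min_area,
                               temperature = temperature,
                               q_max = max(pattern$q_grid),
                               min_height = min_height,
                               condition = bundle$condition,
                               label_pair = bundle$label_pair)
      utils::write.csv(cbind(summ$peaks,
                             fraction = population_fractions(summ$peaks)),
                       file.path(cond_dir, "peaks.csv"), row.names = FALSE)
      say("[%s] done in %.1f s: %d peak(s), major mode %.1f A",
          cond$name, proc.time()[["elapsed"]] - t0, nrow(summ$peaks),
          summ$peaks$mode[1])
      list(distribution = dist, summary = summ, interference = pattern)
    }, error = function(e) {
      say("[%s] FAILED: %s", cond$name, conditionMessage(e))
      structure(list(message = conditionMessage(e)),
                class = "condition_error")
    })
  }
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
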