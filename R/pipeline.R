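#' Read and validate a pipeline configuration
#'
#' The whole experiment — chamber scenario, puff schedule, per-puff source,
#' simulation settings — lives in a single YAML document. Schema violations
#' are reported with the path of the offending field.
#'
#' Expected structure:
#' ```yaml
#' seed: 1
#' scenario: {volume_m3: 6, ach: 0, label: static,
#'            dilution_flow_eags_lpm: 2, dilution_flow_chamber_lpm: 2}
#' schedule: {n_puffs: 20, interval_s: 300, start_s: 0,
#'            profile: {volume_mL: 55, duration_s: 3}}
#' source:   {number_per_puff: 3.0e10,
#'            modes: [{weight: 1, gmd_nm: 100, gsd: 1.7}]}
#' simulate: {beta_dep_per_s: 1.34e-4, dt_s: 10, horizon_s: 10000,
#'            ceiling: 3000, noise: {gsd: 1.0}}
#' density_g_cm3: 1
#' ```
#' An `input_csv` key (path to a [write_conc_csv()] file) may replace the
#' `simulate`/`source` blocks to analyze measured data.
#'
#' @param path Path to the YAML file, or an already-parsed list.
#' @return A validated config list of class `chamber_config`.
#' @export
read_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  need <- function(keys, where, what) {
    for (k in keys) {
      if (is.null(where[[k]])) {
        stop(sprintf("config field `%s%s` is missing", what, k), call. = FALSE)
      }
    }
  }
  need("scenario", cfg, "")
  need(c("volume_m3", "ach", "label"), cfg$scenario, "scenario.")
  need("schedule", cfg, "")
  need(c("n_puffs", "interval_s"), cfg$schedule, "schedule.")
  if (is.null(cfg$input_csv)) {
    need("source", cfg, "")
    need(c("number_per_puff", "modes"), cfg$source, "source.")
    for (i in seq_along(cfg$source$modes)) {
      need(c("weight", "gmd_nm", "gsd"), cfg$source$modes[[i]],
           sprintf("source.modes[%d].", i))
    }
    need("seed", cfg, "")
  }
  structure(cfg, class = c("chamber_config", "list"))
}

# YAML 1.1 reads unsuffixed exponents like 1.0e9 as strings; coerce
num <- function(x) if (is.null(x)) x else as.numeric(x)

config_scenario <- function(cfg) {
  s <- cfg$scenario
  chamber_scenario(num(s$volume_m3), num(s$ach), s$label,
                   dilution_flow_eags_lpm = num(s$dilution_flow_eags_lpm) %||% NA_real_,
                   dilution_flow_chamber_lpm = num(s$dilution_flow_chamber_lpm) %||% NA_real_)
}

config_schedule <- function(cfg) {
  s <- cfg$schedule
  prof <- if (!is.null(s$profile)) {
    puff_profile(num(s$profile$volume_mL) %||% 55, num(s$profile$duration_s) %||% 3)
  } else puff_profile()
  regular_schedule(num(s$n_puffs), num(s$interval_s), num(s$start_s) %||% 60, prof)
}

config_source <- function(cfg) {
  modes <- lapply(cfg$source$modes, function(m) {
    lognormal_mode(num(m$weight), num(m$gmd_nm), num(m$gsd))
  })
  source_spec(modes, num(cfg$source$number_per_puff))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full emission-characterization pipeline
#'
#' Executes simulate (or load) -> instrument ceiling -> decay fit -> total
#' emission and emission factors (number and mass) -> size-mode fit, and
#' writes every artifact to `out_dir`: the concentration series (plus
#' saturation sidecar), the decay fit, the emission results, the normalized
#' average distribution and fitted modes, and a JSON run manifest recording
#' the seed, the config, and the package version. A failed run leaves no
#' partial artifact directory. Reruns with the same seed are byte-identical.
#'
#' @param config Path to a YAML config, or a list ([read_config()] schema).
#' @param out_dir Artifact directory, created (must not already contain a
#'   manifest unless `overwrite = TRUE`).
#' @param seed Overrides the config seed.
#' @param overwrite Allow writing into an existing artifact directory.
#' @return Invisibly, a list with the in-memory objects: `series`, `decay`,
#'   `emissions`, `distribution`, `modes`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, overwrite = FALSE) {
  cfg <- read_config(config)
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  if (dir.exists(out_dir) && file.exists(file.path(out_dir, "manifest.json")) &&
      !overwrite) {
    stop(sprintf("artifact directory `%s` already holds a run; set overwrite = TRUE",
                 out_dir), call. = FALSE)
  }
  scenario <- config_scenario(cfg)
  schedule <- config_schedule(cfg)

  # compute everything before writing anything, so failures leave no partial
  # artifact directory
  if (!is.null(cfg$input_csv)) {
    series <- read_conc_csv(cfg$input_csv)
  } else {
    sim <- cfg$simulate %||% list()
    noise <- NULL
    if (!is.null(sim$noise) && (num(sim$noise$gsd) %||% 1) > 1) {
      noise <- noise_spec(num(sim$noise$gsd),
                          poisson = isTRUE(sim$noise$poisson),
                          sample_volume_cm3 = num(sim$noise$sample_volume_cm3) %||% 16.7)
    }
    series <- simulate_chamber(
      scenario, schedule, config_source(cfg),
      beta_dep = num(sim$beta_dep_per_s) %||% 1.34e-4,
      dt_s = num(sim$dt_s) %||% 10,
      horizon_s = num(sim$horizon_s),
      noise = noise, seed = seed
    )
    if (!is.null(sim$ceiling)) series <- apply_instrument(series, num(sim$ceiling))
  }

  emis <- estimate_emissions(series, scenario, schedule,
                             density_g_cm3 = cfg$density_g_cm3 %||% 1)
  decay <- attr(emis, "decay_fit")
  dist <- normalize_distribution(series)
  modes <- tryCatch(fit_modes(dist, "auto"), error = function(e) NULL)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_conc_csv(series, file.path(out_dir, "conc_series.csv"),
                 flags_path = file.path(out_dir, "conc_series_flags.csv"))
  write_decay_csv(decay, file.path(out_dir, "decay_fit.csv"))
  write_emission_csv(emis, file.path(out_dir, "emissions.csv"))
  write_distribution_csv(dist, file.path(out_dir, "distribution.csv"))
  if (!is.null(modes)) write_modes_csv(modes, file.path(out_dir, "modes.csv"))

  manifest <- list(
    package = "chamberEF",
    version = as.character(utils::packageVersion("chamberEF")),
    seed = seed,
    n_puffs = length(schedule$puff_times_s),
    scenario = scenario$label,
    config = unclass(cfg),
    artifacts = list.files(out_dir),
    mode_fit_converged = !is.null(modes)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(series = series, decay = decay, emissions = emis,
                 distribution = dist, modes = modes, manifest = manifest))
}
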