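#' Chamber scenarios
#'
#' Describes the exposure chamber an experiment runs in: its volume, air
#' exchange rate, and the dilution flows used to convert chamber measurements
#' back to generator output. The two study scenarios are `static` (unventilated,
#' 0 ACH) and `dynamic` (ventilated, 3 changes per hour) in a 6 m^3 chamber.
#'
#' @param volume_m3 Chamber volume in cubic metres, positive.
#' @param ach Air exchange rate in changes per hour; 0 for the static scenario.
#' @param label `"static"` or `"dynamic"`. Static requires `ach == 0`, dynamic
#'   `ach > 0`.
#' @param dilution_flow_eags_lpm Flow into the aerosol generation system, LPM.
#' @param dilution_flow_chamber_lpm Flow into the exposure chamber, LPM.
#' @return An object of class `chamber_scenario`.
#' @examples
#' static_chamber <- chamber_scenario(6, ach = 0, label = "static")
#' dynamic_chamber <- chamber_scenario(6, ach = 3, label = "dynamic")
#' @export
chamber_scenario <- function(volume_m3 = 6, ach = 0,
                             label = c("static", "dynamic"),
                             dilution_flow_eags_lpm = NA_real_,
                             dilution_flow_chamber_lpm = NA_real_) {
  label <- match.arg(label)
  if (!is.numeric(volume_m3) || volume_m3 <= 0) {
    stop("`volume_m3` must be positive", call. = FALSE)
  }
  if (!is.numeric(ach) || ach < 0) stop("`ach` must be >= 0", call. = FALSE)
  if (label == "static" && ach != 0) {
    stop("static scenario requires `ach = 0`", call. = FALSE)
  }
  if (label == "dynamic" && ach <= 0) {
    stop("dynamic scenario requires `ach > 0`", call. = FALSE)
  }
  structure(
    list(volume_m3 = volume_m3, ach = ach, label = label,
         dilution_flow_eags_lpm = dilution_flow_eags_lpm,
         dilution_flow_chamber_lpm = dilution_flow_chamber_lpm),
    class = "chamber_scenario"
  )
}

#' Dilution factor of a scenario
#'
#' The ratio of the flow into the aerosol generation system over the flow into
#' the exposure chamber, used to rescale chamber-derived emissions to generator
#' output when part of the generator flow is diverted to other sampling. For a
#' static chamber with no diverted flow the factor is 1.
#'
#' @param scenario A [chamber_scenario()].
#' @return Dimensionless dilution factor.
#' @export
dilution_factor <- function(scenario) {
  stopifnot(inherits(scenario, "chamber_scenario"))
  fe <- scenario$dilution_flow_eags_lpm
  fc <- scenario$dilution_flow_chamber_lpm
  if (is.na(fe) || is.na(fc)) {
    if (scenario$label == "static") return(1)
    stop("dilution flows must be set to compute a dilution factor", call. = FALSE)
  }
  if (fe <= 0 || fc <= 0) stop("dilution flows must be positive", call. = FALSE)
  fe / fc
}

#' Lognormal source modes and per-puff source specifications
#'
#' A `lognormal_mode` is one mode of a particle number size distribution with
#' a geometric mean diameter (GMD, nm) and geometric standard deviation (GSD).
#' A `source_spec` combines one or more weighted modes with the total number of
#' particles emitted per puff. Typical defaults: pod-type devices emit a single
#' mode near 100 nm; mod-type devices are bimodal with an Aitken mode at
#' 58.2 nm and an accumulation mode at 794 nm.
#'
#' @param n_total Mode amplitude (number concentration or count), >= 0. In a
#'   `source_spec` the mode amplitudes are interpreted as weights and must sum
#'   to 1.
#' @param gmd_nm Geometric mean diameter in nm, positive.
#' @param gsd Geometric standard deviation, >= 1.
#' @return `lognormal_mode` returns an object of class `lognormal_mode`.
#' @export
lognormal_mode <- function(n_total, gmd_nm, gsd) {
  if (!is.numeric(n_total) || n_total < 0) stop("`n_total` must be >= 0", call. = FALSE)
  if (!is.numeric(gmd_nm) || gmd_nm <= 0) stop("`gmd_nm` must be positive", call. = FALSE)
  if (!is.numeric(gsd) || gsd < 1) stop("`gsd` must be >= 1", call. = FALSE)
  structure(list(n_total = n_total, gmd_nm = gmd_nm, gsd = gsd),
            class = "lognormal_mode")
}

#' @rdname lognormal_mode
#' @param modes List of [lognormal_mode()]s; their `n_total` weights must sum
#'   to 1.
#' @param number_per_puff Total particles emitted per puff, positive.
#' @export
source_spec <- function(modes, number_per_puff) {
  if (inherits(modes, "lognormal_mode")) modes <- list(modes)
  stopifnot(all(vapply(modes, inherits, logical(1), "lognormal_mode")))
  w <- vapply(modes, `[[`, numeric(1), "n_total")
  if (abs(sum(w) - 1) > 1e-8) {
    stop("mode weights (`n_total`) must sum to 1", call. = FALSE)
  }
  if (!is.numeric(number_per_puff) || number_per_puff <= 0) {
    stop("`number_per_puff` must be positive", call. = FALSE)
  }
  structure(list(modes = modes, number_per_puff = number_per_puff),
            class = "source_spec")
}

#' @rdname lognormal_mode
#' @export
pod_source <- function(number_per_puff = 3e10) {
  source_spec(list(lognormal_mode(1, 100, 1.7)), number_per_puff)
}

#' @rdname lognormal_mode
#' @export
mod_source <- function(number_per_puff = 1e10) {
  source_spec(list(lognormal_mode(0.5, 58.2, 1.6),
                   lognormal_mode(0.5, 794, 1.6)), number_per_puff)
}

# per-puff particle count allocated to each bin of `grid`; particles outside
# the grid range are dropped (capture fraction attached as an attribute)
allocate_source <- function(source, grid) {
  le <- log(grid$bin_edges)
  frac <- numeric(length(grid$bin_mids))
  for (m in source$modes) {
    p <- stats::pnorm(le, mean = log(m$gmd_nm), sd = log(max(m$gsd, 1 + 1e-12)))
    frac <- frac + m$n_total * diff(p)
  }
  counts <- source$number_per_puff * frac
  attr(counts, "capture_fraction") <- sum(frac)
  counts
}

#' Measurement noise specification
#'
#' Multiplicative lognormal noise (geometric standard deviation `gsd`) with
#' optional Poisson counting noise applied to the number of particles counted
#' in each sample (`conc * sample_volume_cm3` counts).
#'
#' @param gsd Geometric standard deviation of the multiplicative noise; 1
#'   disables it.
#' @param poisson Apply Poisson counting noise?
#' @param sample_volume_cm3 Air volume counted per sample, cm^3 (sets the
#'   Poisson counting statistics).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(gsd = 1.05, poisson = FALSE, sample_volume_cm3 = 16.7) {
  if (!is.numeric(gsd) || gsd < 1) stop("`gsd` must be >= 1", call. = FALSE)
  if (poisson && sample_volume_cm3 <= 0) {
    stop("`sample_volume_cm3` must be positive", call. = FALSE)
  }
  structure(list(gsd = gsd, poisson = poisson,
                 sample_volume_cm3 = sample_volume_cm3),
            class = "noise_spec")
}

#' Size-resolved concentration time series
#'
#' The central measurement object: a matrix of number concentrations (#/cm^3)
#' with one row per sampling time and one column per diameter bin, plus the
#' matching [size_grid()] and a logical matrix flagging samples at or above the
#' instrument detection ceiling.
#'
#' @param times Sampling times in seconds, uniformly spaced and increasing.
#' @param grid A [size_grid()] whose bin count matches `ncol(conc)`.
#' @param conc Numeric matrix `[time x bin]` of number concentrations, >= 0.
#' @param saturated Logical matrix of the same shape (default all `FALSE`).
#' @return An object of class `conc_series` with element `dt_s`.
#' @export
conc_series <- function(times, grid, conc, saturated = NULL) {
  stopifnot(inherits(grid, "size_grid"))
  times <- as.numeric(times)
  conc <- as.matrix(conc)
  if (length(times) != nrow(conc)) {
    stop("`times` length must equal `nrow(conc)`", call. = FALSE)
  }
  if (ncol(conc) != length(grid$bin_mids)) {
    stop("`conc` column count must match the grid bin count", call. = FALSE)
  }
  if (length(times) < 2L) stop("need at least two samples", call. = FALSE)
  dts <- diff(times)
  if (any(dts <= 0)) stop("`times` must be strictly increasing", call. = FALSE)
  if (diff(range(dts)) > 1e-9 * mean(dts)) {
    stop("`times` must be uniformly spaced", call. = FALSE)
  }
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("`conc` must be finite and non-negative", call. = FALSE)
  }
  if (is.null(saturated)) {
    saturated <- matrix(FALSE, nrow(conc), ncol(conc))
  }
  saturated <- as.matrix(saturated)
  stopifnot(identical(dim(saturated), dim(conc)))
  structure(
    list(times = times, grid = grid, conc = unname(conc),
         saturated_flags = unname(saturated), dt_s = mean(dts)),
    class = "conc_series"
  )
}

#' @export
print.conc_series <- function(x, ...) {
  cat(sprintf(
    "<conc_series: %d samples x %d bins (%s), dt = %.3g s, span %.3g-%.3g s>\n",
    nrow(x$conc), ncol(x$conc), x$grid$instrument_label, x$dt_s,
    min(x$times), max(x$times)))
  cat(sprintf("  total conc range: %.4g - %.4g #/cm3; %d saturated samples\n",
              min(rowSums(x$conc)), max(rowSums(x$conc)),
              sum(x$saturated_flags)))
  invisible(x)
}

#' Total number concentration trace
#'
#' @param series A [conc_series()].
#' @return Data frame with `time_s` and `conc` (summed over bins, #/cm^3).
#' @export
total_concentration <- function(series) {
  stopifnot(inherits(series, "conc_series"))
  data.frame(time_s = series$times, conc = rowSums(series$conc))
}

#' Simulate a well-mixed exposure chamber
#'
#' Forward model for the chamber: each diameter bin obeys the first-order mass
#' balance `dC/dt = S(t)/V_c - (lambda + beta_dep) * C`, with the ventilation
#' rate `lambda = ach / 3600` (1/s) and a deposition loss `beta_dep` (1/s,
#' scalar or per-bin). Puffs are injected as instantaneous well-mixed
#' additions of `E_bin / V_c` at their scheduled times, where `E_bin` is the
#' per-puff particle count allocated to each bin from the lognormal source
#' modes; the 3 s puff itself is far shorter than chamber time scales, so the
#' impulse approximation keeps the solution exactly analytic between events.
#' Optional measurement noise is applied after the deterministic solution.
#'
#' @param scenario A [chamber_scenario()].
#' @param schedule A [puff_schedule()] (possibly [empty_schedule()]).
#' @param source A [source_spec()].
#' @param beta_dep Deposition loss rate in 1/s; scalar or one value per bin.
#' @param dt_s Sampling interval in seconds, positive.
#' @param horizon_s End of the simulation in seconds; defaults to the last puff
#'   plus one hour (or one hour for an empty schedule).
#' @param grid A [size_grid()]; default composite SMPS+OPS grid.
#' @param noise `NULL` for a noiseless run, or a [noise_spec()].
#' @param seed Integer seed; required when `noise` is given. Identical seeds
#'   and inputs give identical output.
#' @param initial_conc Initial per-bin concentration, #/cm^3 (scalar or per
#'   bin).
#' @return A [conc_series()] sampled at `0, dt_s, 2 dt_s, ...`, with attributes
#'   `injected_per_puff` (per-bin counts entering the grid) and
#'   `capture_fraction`.
#' @examples
#' sc <- chamber_scenario(6, 0, "static")
#' sim <- simulate_chamber(sc, regular_schedule(4, 3600), mod_source(),
#'                         beta_dep = 2.2e-4, dt_s = 60)
#' @export
simulate_chamber <- function(scenario, schedule, source, beta_dep = 0,
                             dt_s = 10, horizon_s = NULL,
                             grid = composite_grid(), noise = NULL,
                             seed = NULL, initial_conc = 0) {
  stopifnot(inherits(scenario, "chamber_scenario"),
            inherits(schedule, "puff_schedule"),
            inherits(source, "source_spec"),
            inherits(grid, "size_grid"))
  if (!is.numeric(dt_s) || dt_s <= 0) stop("`dt_s` must be positive", call. = FALSE)
  n_bin <- length(grid$bin_mids)
  if (any(beta_dep < 0)) stop("`beta_dep` must be >= 0", call. = FALSE)
  if (!length(beta_dep) %in% c(1L, n_bin)) {
    stop("`beta_dep` must be a scalar or one value per bin", call. = FALSE)
  }
  if (is.null(horizon_s)) {
    horizon_s <- if (length(schedule$puff_times_s)) max(schedule$puff_times_s) + 3600 else 3600
  }
  tp <- schedule$puff_times_s
  if (length(tp) && max(tp) > horizon_s) {
    stop("puff times must lie within the simulation horizon", call. = FALSE)
  }
  lambda <- scenario$ach / 3600
  r <- lambda + rep_len(beta_dep, n_bin) # combined loss rate per bin, 1/s

  times <- seq(0, horizon_s, by = dt_s)
  vc_cm3 <- scenario$volume_m3 * 1e6
  e_bin <- allocate_source(source, grid)       # particles per puff per bin
  dC <- e_bin / vc_cm3                         # step increase per puff, #/cm3

  conc <- exp(-outer(times, r)) * rep(rep_len(initial_conc, n_bin),
                                      each = length(times))
  for (t0 in tp) {
    on <- times >= t0
    if (!any(on)) next
    conc[on, ] <- conc[on, , drop = FALSE] +
      exp(-outer(times[on] - t0, r)) * rep(dC, each = sum(on))
  }

  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_spec"))
    if (is.null(seed)) stop("`seed` is required for a noisy simulation", call. = FALSE)
    set.seed(as.integer(seed))
    if (noise$gsd > 1) {
      conc <- conc * exp(matrix(stats::rnorm(length(conc), 0, log(noise$gsd)),
                                nrow(conc)))
    }
    if (noise$poisson) {
      v <- noise$sample_volume_cm3
      conc <- matrix(stats::rpois(length(conc), pmax(conc, 0) * v) / v,
                     nrow(conc))
    }
  }

  out <- conc_series(times, grid, conc)
  attr(out, "injected_per_puff") <- e_bin
  attr(out, "capture_fraction") <- attr(e_bin, "capture_fraction")
  out
}

#' Composite SMPS + OPS grid
#'
#' @param n_smps,n_ops Bin counts of the two instrument segments.
#' @return A composite [size_grid()] spanning 7--10000 nm.
#' @export
composite_grid <- function(n_smps = 32L, n_ops = 16L) {
  s <- smps_grid(n_smps)
  o <- ops_grid(n_ops)
  size_grid(c(s$bin_edges, o$bin_edges[-1L]), "composite")
}

#' Apply an instrument detection ceiling
#'
#' Values at or above the ceiling are clipped to the ceiling and flagged as
#' saturated; all other values are unchanged. The optical particle sizer used
#' in the study saturates at 3000 #/cm^3.
#'
#' @param series A [conc_series()].
#' @param ceiling Detection ceiling in #/cm^3, positive (may be `Inf`).
#' @return A [conc_series()] with clipped values and updated
#'   `saturated_flags`.
#' @export
apply_instrument <- function(series, ceiling = 3000) {
  stopifnot(inherits(series, "conc_series"))
  if (!is.numeric(ceiling) || ceiling <= 0) {
    stop("`ceiling` must be positive", call. = FALSE)
  }
  sat <- series$conc >= ceiling
  series$conc[sat] <- ceiling
  series$saturated_flags <- series$saturated_flags | sat
  series
}

#' Stitch SMPS and OPS series into one composite series
#'
#' The two instruments must share identical sampling times and their grids must
#' abut (the upper SMPS edge equals the lower OPS edge, 300 nm for the study
#' instruments); bins and concentrations are concatenated.
#'
#' @param smps,ops [conc_series()] objects on abutting grids.
#' @return A composite [conc_series()].
#' @export
stitch_grids <- function(smps, ops) {
  stopifnot(inherits(smps, "conc_series"), inherits(ops, "conc_series"))
  if (length(smps$times) != length(ops$times) ||
      max(abs(smps$times - ops$times)) > 1e-9) {
    stop("instrument timestamps are misaligned", call. = FALSE)
  }
  lo <- smps$grid$bin_edges
  hi <- ops$grid$bin_edges
  join <- lo[length(lo)]
  if (abs(join - hi[1L]) > 1e-9 * join) {
    stop("grids must abut: upper edge of the first grid must equal the lower edge of the second",
         call. = FALSE)
  }
  grid <- size_grid(c(lo, hi[-1L]), "composite")
  conc_series(smps$times, grid,
              cbind(smps$conc, ops$conc),
              cbind(smps$saturated_flags, ops$saturated_flags))
}
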