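#' Loss-corrected total particle emission
#'
#' Reconstructs the number of particles released into the chamber over an
#' emission window from the measured concentration series, correcting each
#' sampling interval for first-order losses. For each interval ending at
#' `t_i` inside the window the emitted increment is
#' `dTP_i = V_c * (C(t_i) - C(t_{i-1}) * exp(-beta * dt))`, i.e. the part of
#' the concentration change not explained by decay of the particles already
#' airborne; the total emission is the sum of the increments. With `beta = 0`
#' the sum telescopes to `V_c * (C(t_stop) - C(t_start))`.
#'
#' @param series A [conc_series()] or a data frame with `time_s` and `conc`.
#' @param chamber A [chamber_scenario()]; its volume is converted to cm^3 so
#'   the result is a particle count.
#' @param beta Loss coefficient in 1/s, or a [fit_decay()] result.
#' @param window An [emission_window()] or numeric `c(t_start, t_stop)`; the
#'   increments with `t_start < t_i <= t_stop` are summed. Defaults to the
#'   full series.
#' @param per_bin If `TRUE` (conc_series input only), return the per-bin
#'   emission vector; its sum equals the total-trace result.
#' @param form `"recursion"` (default) uses the per-interval source
#'   reconstruction above; `"alt"` divides each increment by
#'   `exp(-beta * dt)`, an alternative reading of the published estimator that
#'   coincides with the default as `beta * dt -> 0`.
#' @param clip_negative Set negative interval increments (decay steeper than
#'   `beta` predicts, or noise) to zero before summing. Off by default:
#'   summing as-is is unbiased under symmetric noise.
#' @return Total emitted particles (#); with `per_bin = TRUE` a vector per
#'   diameter bin.
#' @examples
#' tr <- data.frame(time_s = c(0, 10, 20), conc = c(0, 100, 100))
#' total_emission(tr, chamber_scenario(6, 0, "static"), beta = 0) # 6e8
#' @export
total_emission <- function(series, chamber, beta, window = NULL,
                           per_bin = FALSE, form = c("recursion", "alt"),
                           clip_negative = FALSE) {
  form <- match.arg(form)
  stopifnot(inherits(chamber, "chamber_scenario"))
  if (inherits(beta, "decay_fit")) beta <- beta$beta_per_s
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0) {
    stop("`beta` must be a single non-negative rate in 1/s", call. = FALSE)
  }
  if (inherits(window, "emission_window")) window <- c(window$t_start_s, window$t_stop_s)

  if (inherits(series, "conc_series")) {
    times <- series$times
    conc <- if (per_bin) series$conc else as.matrix(rowSums(series$conc))
  } else {
    if (per_bin) stop("`per_bin` requires a conc_series input", call. = FALSE)
    if (!is.data.frame(series) || !all(c("time_s", "conc") %in% names(series))) {
      stop("`series` must be a conc_series or a data frame with `time_s` and `conc`",
           call. = FALSE)
    }
    times <- series$time_s
    conc <- as.matrix(series$conc)
    dts <- diff(times)
    if (length(dts) < 1L || any(dts <= 0) ||
        diff(range(dts)) > 1e-9 * mean(dts)) {
      stop("`time_s` must be uniform and increasing", call. = FALSE)
    }
  }
  dt <- mean(diff(times))
  if (is.null(window)) window <- range(times)
  if (window[2] <= window[1]) stop("`window` must be increasing", call. = FALSE)
  if (window[1] < min(times) - 1e-9 || window[2] > max(times) + 1e-9) {
    stop("emission window lies outside the series", call. = FALSE)
  }

  vc_cm3 <- chamber$volume_m3 * 1e6
  decay <- exp(-beta * dt)
  inc <- conc[-1L, , drop = FALSE] - conc[-nrow(conc), , drop = FALSE] * decay
  if (form == "alt") inc <- inc / decay
  keep <- times[-1L] > window[1] + 1e-9 & times[-1L] <= window[2] + 1e-9
  inc <- inc[keep, , drop = FALSE]
  if (clip_negative) inc[inc < 0] <- 0
  tp <- vc_cm3 * colSums(inc)
  if (per_bin) tp else sum(tp)
}

#' Emission windows
#'
#' Bounds of the emission period used by [total_emission()]. The default
#' window for a schedule runs from one sampling interval before the first puff
#' to a mixing lag after the last.
#'
#' @param t_start_s,t_stop_s Window bounds in seconds, `t_stop_s > t_start_s`.
#' @return An object of class `emission_window`.
#' @export
emission_window <- function(t_start_s, t_stop_s) {
  if (t_stop_s <= t_start_s) stop("`t_stop_s` must exceed `t_start_s`", call. = FALSE)
  structure(list(t_start_s = t_start_s, t_stop_s = t_stop_s),
            class = "emission_window")
}

#' @rdname emission_window
#' @param schedule A [puff_schedule()] with at least one puff.
#' @param dt_s Sampling interval of the series.
#' @param lag_s Mixing lag after the final puff, seconds.
#' @export
default_emission_window <- function(schedule, dt_s, lag_s = 120) {
  stopifnot(inherits(schedule, "puff_schedule"))
  if (!length(schedule$puff_times_s)) stop("schedule has no puffs", call. = FALSE)
  emission_window(max(0, min(schedule$puff_times_s) - dt_s),
                  max(schedule$puff_times_s) + lag_s)
}

#' Particle mass from per-bin counts
#'
#' Converts size-resolved particle counts to mass assuming spherical particles
#' of uniform density: per-bin mass is `count * (pi/6) * d_mid^3 * rho` with
#' the geometric bin midpoint in cm and density in g/cm^3; the total over bins
#' is reported in micrograms.
#'
#' @param counts Per-bin particle counts (e.g. per-bin total emission), one
#'   per grid bin.
#' @param grid The matching [size_grid()].
#' @param density_g_cm3 Particle density in g/cm^3 (1 for e-liquid aerosol).
#' @return Total mass in micrograms, with attribute `per_bin_ug`.
#' @examples
#' g <- size_grid(c(90, 111.2)) # single bin with geometric midpoint ~100 nm
#' number_to_mass(6e10, g)      # ~31.4 ug
#' @export
number_to_mass <- function(counts, grid, density_g_cm3 = 1) {
  stopifnot(inherits(grid, "size_grid"))
  counts <- as.numeric(counts)
  if (length(counts) != length(grid$bin_mids)) {
    stop("`counts` length must match the grid bin count", call. = FALSE)
  }
  if (density_g_cm3 <= 0) stop("`density_g_cm3` must be positive", call. = FALSE)
  d_cm <- grid$bin_mids * 1e-7
  per_bin_g <- counts * (pi / 6) * d_cm^3 * density_g_cm3
  out <- sum(per_bin_g) * 1e6
  attr(out, "per_bin_ug") <- per_bin_g * 1e6
  out
}

#' Per-puff emission factors
#'
#' The emission factor is the total emission divided by the number of puffs,
#' rescaled by the dilution factor when part of the generator output was
#' diverted before the chamber: `EF = dilution_factor * TP / puff_number`.
#'
#' @param tp_number Total particle number emission (#).
#' @param puff_number Number of puffs, >= 1.
#' @param dilution_factor Dimensionless flow ratio, > 0; 1 for the static
#'   chamber. Applied identically to number and mass.
#' @param tp_mass_ug Total mass emission in micrograms (optional).
#' @param beta_per_s Loss coefficient used, for provenance.
#' @param scenario_label Scenario name, for provenance.
#' @return An object of class `emission_result` with the totals, per-puff
#'   emission factors `ef_number_per_puff` and `ef_mass_ug_per_puff`, and
#'   provenance fields.
#' @export
emission_factor <- function(tp_number, puff_number, dilution_factor = 1,
                            tp_mass_ug = NA_real_, beta_per_s = NA_real_,
                            scenario_label = NA_character_) {
  if (!is.numeric(puff_number) || puff_number < 1) {
    stop("`puff_number` must be >= 1", call. = FALSE)
  }
  if (!is.numeric(dilution_factor) || dilution_factor <= 0) {
    stop("`dilution_factor` must be positive", call. = FALSE)
  }
  structure(
    list(tp_number = tp_number,
         tp_mass_ug = tp_mass_ug,
         ef_number_per_puff = dilution_factor * tp_number / puff_number,
         ef_mass_ug_per_puff = dilution_factor * tp_mass_ug / puff_number,
         puff_number = puff_number,
         dilution_factor = dilution_factor,
         beta_used_per_s = beta_per_s,
         scenario_label = scenario_label),
    class = "emission_result"
  )
}

#' @export
print.emission_result <- function(x, ...) {
  cat(sprintf("<emission_result [%s]: EF = %.4g #/puff, %.4g ug/puff (%d puffs, DF %.3g, beta %.3g /s)>\n",
              x$scenario_label, x$ef_number_per_puff, x$ef_mass_ug_per_puff,
              x$puff_number, x$dilution_factor, x$beta_used_per_s))
  invisible(x)
}

#' Estimate emissions from a measured series
#'
#' Convenience wrapper running the full estimation chain on one experiment:
#' pick the decay window, fit the loss coefficient, compute loss-corrected
#' number and mass total emissions over the emission window, and form per-puff
#' emission factors.
#'
#' @param series A [conc_series()].
#' @param chamber A [chamber_scenario()].
#' @param schedule The [puff_schedule()] of the run.
#' @param beta Optional known loss coefficient (1/s) or [fit_decay()] result;
#'   fitted from the post-vaping decay when `NULL`.
#' @param density_g_cm3 Particle density for the mass conversion.
#' @param lag_s Mixing lag used for both the decay and emission windows.
#' @param dilution Overrides [dilution_factor()] of the scenario.
#' @return An [emission_factor()] result with the fitted `decay_fit` attached
#'   as attribute `decay_fit`.
#' @export
estimate_emissions <- function(series, chamber, schedule, beta = NULL,
                               density_g_cm3 = 1, lag_s = 120,
                               dilution = NULL) {
  stopifnot(inherits(series, "conc_series"))
  fit <- NULL
  if (is.null(beta)) {
    win <- pick_decay_window(series, schedule, lag_s = lag_s)
    fit <- fit_decay(series, window = win)
    beta <- max(fit$beta_per_s, 0)
  } else if (inherits(beta, "decay_fit")) {
    fit <- beta
    beta <- max(fit$beta_per_s, 0)
  }
  ew <- default_emission_window(schedule, series$dt_s, lag_s = lag_s)
  tp_bins <- total_emission(series, chamber, beta, ew, per_bin = TRUE)
  tp_n <- sum(tp_bins)
  tp_m <- as.numeric(number_to_mass(tp_bins, series$grid, density_g_cm3))
  df <- if (is.null(dilution)) dilution_factor(chamber) else dilution
  out <- emission_factor(tp_n, length(schedule$puff_times_s), df,
                         tp_mass_ug = tp_m, beta_per_s = beta,
                         scenario_label = chamber$label)
  attr(out, "decay_fit") <- fit
  out
}

#' Ratio of emission factors between scenarios
#'
#' Compares the same metric (number or mass EF) between two emission results,
#' e.g. unventilated over ventilated.
#'
#' @param ef_a,ef_b [emission_factor()] results, or bare numbers.
#' @param metric `"number"` or `"mass"` when emission results are supplied.
#' @param rounding `"none"` or `"nearest_int"`.
#' @return Dimensionless ratio `ef_a / ef_b`.
#' @export
scenario_ratio <- function(ef_a, ef_b, metric = c("number", "mass"),
                           rounding = c("none", "nearest_int")) {
  metric <- match.arg(metric)
  rounding <- match.arg(rounding)
  pick <- function(x) {
    if (inherits(x, "emission_result")) {
      if (metric == "number") x$ef_number_per_puff else x$ef_mass_ug_per_puff
    } else as.numeric(x)
  }
  a <- pick(ef_a)
  b <- pick(ef_b)
  if (!is.finite(b) || b <= 0) stop("denominator EF must be positive", call. = FALSE)
  r <- a / b
  if (rounding == "nearest_int") round(r) else r
}
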