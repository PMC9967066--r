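#' Puff topography
#'
#' A `puff_profile` describes the volume and duration of a single machine puff.
#' The default is the CORESTA Recommended Method No. 81 square wave: 55 mL
#' drawn over 3 s, a mean flow of 1.1 LPM.
#'
#' @param volume_mL Puff volume in mL, positive.
#' @param duration_s Puff duration in s, positive.
#' @param shape Puff shape; only `"square"` is supported.
#' @return An object of class `puff_profile`.
#' @export
puff_profile <- function(volume_mL = 55, duration_s = 3, shape = "square") {
  shape <- match.arg(shape, "square")
  if (!is.numeric(volume_mL) || length(volume_mL) != 1L || !is.finite(volume_mL) ||
      volume_mL <= 0) {
    stop("`volume_mL` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(duration_s) || length(duration_s) != 1L ||
      !is.finite(duration_s) || duration_s <= 0) {
    stop("`duration_s` must be a single positive number", call. = FALSE)
  }
  structure(list(shape = shape, volume_mL = volume_mL, duration_s = duration_s),
            class = "puff_profile")
}

#' Mean volumetric flow of a square-wave puff
#'
#' For a square wave the flow is constant over the puff, so the mean flow is
#' volume over duration: `volume_mL / duration_s * 60 / 1000` LPM. The CORESTA
#' profile (55 mL, 3 s) gives 1.1 LPM.
#'
#' @param profile A [puff_profile()].
#' @return Mean flow in litres per minute.
#' @examples
#' mean_flow_lpm(puff_profile(55, 3)) # 1.1
#' @export
mean_flow_lpm <- function(profile) {
  stopifnot(inherits(profile, "puff_profile"))
  profile$volume_mL / profile$duration_s * 60 / 1000
}

#' Puff schedules
#'
#' A `puff_schedule` records when each puff is taken, the common puff profile,
#' and the puff-fraction boundaries used to stratify device ageing (initial =
#' puffs 1--50, middle = 51--100, late = 101--150 by default).
#'
#' @param puff_times_s Strictly increasing puff start times in seconds.
#' @param profile A [puff_profile()].
#' @param fraction_bounds Named list of inclusive `c(lo, hi)` puff-index
#'   ranges; defaults to the initial/middle/late split.
#' @return An object of class `puff_schedule` with derived `puff_rate_per_min`
#'   (mean rate over the span of the schedule; `NA` for a single puff).
#' @export
puff_schedule <- function(puff_times_s, profile = puff_profile(),
                          fraction_bounds = list(initial = c(1, 50),
                                                 middle = c(51, 100),
                                                 late = c(101, 150))) {
  puff_times_s <- as.numeric(puff_times_s)
  if (length(puff_times_s) == 0L) {
    stop("`puff_times_s` must contain at least one puff (use an empty schedule via `empty_schedule()`)",
         call. = FALSE)
  }
  if (any(!is.finite(puff_times_s)) || any(puff_times_s < 0)) {
    stop("`puff_times_s` must be finite and non-negative", call. = FALSE)
  }
  if (length(puff_times_s) > 1L) {
    gaps <- diff(puff_times_s)
    if (any(gaps <= 0)) stop("`puff_times_s` must be strictly increasing", call. = FALSE)
    if (any(gaps < profile$duration_s)) {
      stop("inter-puff gaps must be at least the puff duration", call. = FALSE)
    }
  }
  check_fraction_bounds(fraction_bounds)
  n <- length(puff_times_s)
  rate <- if (n > 1L) (n - 1L) / diff(range(puff_times_s)) * 60 else NA_real_
  structure(
    list(puff_times_s = puff_times_s, profile = profile,
         puff_rate_per_min = rate, fraction_bounds = fraction_bounds),
    class = "puff_schedule"
  )
}

#' @rdname puff_schedule
#' @export
empty_schedule <- function(profile = puff_profile()) {
  structure(
    list(puff_times_s = numeric(0), profile = profile,
         puff_rate_per_min = NA_real_,
         fraction_bounds = list(initial = c(1, 50), middle = c(51, 100),
                                late = c(101, 150))),
    class = "puff_schedule"
  )
}

#' @rdname puff_schedule
#' @param n_puffs Number of puffs.
#' @param interval_s Constant spacing between puff starts in seconds.
#' @param start_s Time of the first puff in seconds; the default leaves a
#'   60 s pre-vaping baseline so the first puff's concentration step is
#'   bracketed by samples.
#' @export
regular_schedule <- function(n_puffs, interval_s, start_s = 60,
                             profile = puff_profile()) {
  if (n_puffs < 1L) return(empty_schedule(profile))
  puff_schedule(start_s + (seq_len(n_puffs) - 1L) * interval_s, profile)
}

#' @export
print.puff_schedule <- function(x, ...) {
  cat(sprintf("<puff_schedule: %d puffs, %.3g mL / %.3g s profile, rate %.3g puff/min>\n",
              length(x$puff_times_s), x$profile$volume_mL, x$profile$duration_s,
              x$puff_rate_per_min))
  invisible(x)
}

check_fraction_bounds <- function(bounds) {
  if (!is.list(bounds) || is.null(names(bounds)) || any(names(bounds) == "")) {
    stop("`fraction_bounds` must be a named list of c(lo, hi) ranges", call. = FALSE)
  }
  m <- do.call(rbind, bounds)
  if (ncol(m) != 2L || any(m[, 1] > m[, 2])) {
    stop("each fraction bound must be an increasing c(lo, hi) pair", call. = FALSE)
  }
  o <- order(m[, 1])
  m <- m[o, , drop = FALSE]
  if (nrow(m) > 1L && any(m[-1L, 1] != m[-nrow(m), 2] + 1)) {
    stop("`fraction_bounds` must partition the puff indices with no gaps or overlaps",
         call. = FALSE)
  }
  invisible(bounds)
}

#' Assign a puff index to its ageing fraction
#'
#' Fractions are inclusive on both ends: puff 50 is `initial`, puff 51 is
#' `middle` under the default bounds.
#'
#' @param puff_index Integer puff index (1-based).
#' @param bounds Named list of inclusive ranges, as in [puff_schedule()].
#' @return The name of the fraction containing `puff_index`.
#' @examples
#' label_fraction(73) # "middle"
#' @export
label_fraction <- function(puff_index,
                           bounds = list(initial = c(1, 50), middle = c(51, 100),
                                         late = c(101, 150))) {
  check_fraction_bounds(bounds)
  if (length(puff_index) != 1L || !is.finite(puff_index) ||
      puff_index != round(puff_index)) {
    stop("`puff_index` must be a single integer", call. = FALSE)
  }
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (puff_index >= b[1] && puff_index <= b[2]) return(nm)
  }
  stop(sprintf("puff index %d is outside all fraction bounds", puff_index),
       call. = FALSE)
}

#' Device configurations
#'
#' Captures the atomizer setup of a pod- or mod-type device: coil resistance,
#' applied power, and the e-liquid used.
#'
#' @param device_type `"pod"` or `"mod"`.
#' @param coil_resistance_ohm Coil resistance in ohms, positive.
#' @param power_W Device power in watts, positive.
#' @param eliquid Optional list with `flavor`, `nicotine_pct`, `pg_vg`.
#' @return An object of class `device_config`.
#' @seealso [device_presets()] for the studied device/e-liquid combinations.
#' @export
device_config <- function(device_type = c("pod", "mod"), coil_resistance_ohm,
                          power_W, eliquid = list()) {
  device_type <- match.arg(device_type)
  if (!is.numeric(coil_resistance_ohm) || coil_resistance_ohm <= 0) {
    stop("`coil_resistance_ohm` must be positive", call. = FALSE)
  }
  if (!is.numeric(power_W) || power_W <= 0) {
    stop("`power_W` must be positive", call. = FALSE)
  }
  structure(
    list(device_type = device_type, coil_resistance_ohm = coil_resistance_ohm,
         power_W = power_W, eliquid = eliquid),
    class = "device_config"
  )
}

#' Per-puff power traces and the ageing trend
#'
#' `power_trace` pairs puff indices with per-puff coil power; `fit_power_trace`
#' fits the ordinary-least-squares line power ~ puff index that summarizes the
#' gradual power decline as a pod device ages, and `synth_power_trace`
#' generates a linear-decline trace for simulation (7 W intercept and a small
#' negative slope by default).
#'
#' @param puff_index Integer puff indices.
#' @param power_W Per-puff power in watts, positive.
#' @return `power_trace` returns an object of class `power_trace`;
#'   `fit_power_trace` returns the same object with a `linear_fit` element
#'   (slope in W/puff, intercept in W, `r_squared`, residuals).
#' @export
power_trace <- function(puff_index, power_W) {
  puff_index <- as.integer(puff_index)
  power_W <- as.numeric(power_W)
  if (length(puff_index) != length(power_W)) {
    stop("`puff_index` and `power_W` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(power_W)) || any(power_W <= 0)) {
    stop("`power_W` must be finite and positive", call. = FALSE)
  }
  structure(list(puff_index = puff_index, power_W = power_W, linear_fit = NULL),
            class = "power_trace")
}

#' @rdname power_trace
#' @param trace A [power_trace()].
#' @export
fit_power_trace <- function(trace) {
  stopifnot(inherits(trace, "power_trace"))
  if (length(unique(trace$puff_index)) < 2L) {
    stop("need at least 2 distinct puff indices to fit a line", call. = FALSE)
  }
  fit <- stats::lm(power_W ~ puff_index,
                   data = data.frame(puff_index = trace$puff_index,
                                     power_W = trace$power_W))
  co <- stats::coef(fit)
  trace$linear_fit <- list(
    slope_W_per_puff = unname(co["puff_index"]),
    intercept_W = unname(co["(Intercept)"]),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    residuals = unname(stats::resid(fit))
  )
  trace
}

#' @rdname power_trace
#' @param n_puffs Number of puffs to synthesize.
#' @param intercept_W Power at puff 0 in watts.
#' @param slope_W_per_puff Linear ageing slope in W/puff (typically small and
#'   negative).
#' @param sd_W Gaussian measurement noise standard deviation in watts.
#' @param seed Optional integer seed for the noise.
#' @export
synth_power_trace <- function(n_puffs = 150L, intercept_W = 7,
                              slope_W_per_puff = -0.005, sd_W = 0,
                              seed = NULL) {
  k <- seq_len(n_puffs)
  p <- intercept_W + slope_W_per_puff * k
  if (sd_W > 0) {
    if (!is.null(seed)) set.seed(seed)
    p <- p + stats::rnorm(n_puffs, 0, sd_W)
  }
  if (any(p <= 0)) stop("synthesized power is non-positive; adjust slope/intercept",
                        call. = FALSE)
  power_trace(k, p)
}

#' Correlation between per-fraction power and mass emission factor
#'
#' Pearson correlation between mean applied power and particle-mass emission
#' factor across puff fractions (or any paired per-fraction summaries).
#'
#' @param per_fraction_power Numeric vector of per-fraction mean power (W).
#' @param per_fraction_mass_ef Numeric vector of per-fraction mass EF, same
#'   length.
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
correlate_power_ef <- function(per_fraction_power, per_fraction_mass_ef) {
  x <- as.numeric(per_fraction_power)
  y <- as.numeric(per_fraction_mass_ef)
  if (length(x) != length(y)) stop("inputs must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired fractions", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in an input; correlation undefined", call. = FALSE)
  }
  stats::cor(x, y)
}
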